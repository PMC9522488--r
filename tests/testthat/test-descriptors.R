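test_that("gradient field handles constants, steps and transposition", {
  expect_true(all(gradient_field(matrix(7, 5, 5))$magnitude == 0))
  expect_true(all(gradient_field(matrix(7, 5, 5))$angle == 0))

  st <- matrix(0, 8, 8); st[, 5:8] <- 200
  g <- gradient_field(st)
  expect_equal(g$magnitude[4, 4], 200) # centred difference across the step
  expect_equal(g$magnitude[4, 5], 200)
  expect_equal(g$angle[4, 4], 0)

  for (i in 1:8) {
    img <- withr::with_seed(700 + i,
      matrix(sample(0:255, 64, replace = TRUE), 8, 8))
    a <- gradient_field(img)
    b <- gradient_field(t(img))
    expect_equal(b$magnitude, t(a$magnitude))
    nz <- t(a$magnitude) > 0
    expect_equal(b$angle[nz] %% 180, (90 - t(a$angle)[nz]) %% 180,
                 tolerance = 1e-9)
  }
  expect_error(gradient_field(matrix(0, 2, 5)), "3 x 3")
})

test_that("HOG has the documented geometry and degenerate behaviour", {
  img <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
  d <- hog_descriptor(img)
  expect_length(d, (64 / 8 - 2 + 1)^2 * 2^2 * 9) # 1764
  expect_true(all(d >= 0))
  # every 36-long block sub-vector has L2 norm <= 1
  blocks <- matrix(d, nrow = 36)
  expect_true(all(sqrt(colSums(blocks^2)) <= 1 + 1e-9))

  expect_true(all(hog_descriptor(matrix(128, 32, 32), resample_side = 32) == 0))
  expect_error(hog_descriptor(img, resample_side = 60, cell_side = 8),
               "divisible")
})

test_that("HOG is invariant to global intensity scaling after normalisation", {
  img <- matrix(sample(30:220, 48 * 48, replace = TRUE), 48, 48)
  a <- hog_descriptor(img, resample_side = 48)
  b <- hog_descriptor(img * 0.5, resample_side = 48)
  # halving intensities halves every gradient; block L2 normalisation cancels
  # it except for the epsilon guard
  expect_equal(a, b, tolerance = 1e-4)
})

test_that("CS-LBP codes follow the centre-symmetric comparison rule", {
  expect_equal(cslbp_code(rep(0.4, 8)), 0)
  expect_equal(cslbp_code(c(0.6, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)), 1)
  expect_equal(cslbp_code(c(0, 0.5, 0, 0, 0, 0.1, 0, 0)), 2)
  expect_equal(cslbp_code(rep(c(0.9, 0.1), each = 4)), 15)
  # just below threshold stays 0
  expect_equal(cslbp_code(c(0.59, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
                          threshold = 0.1), 0)
})

test_that("CS-LBP spans exactly 16 codes where plain LBP spans 256", {
  grid_vals <- c(0, 0.5, 1)
  combos <- expand.grid(rep(list(grid_vals), 8))
  cs <- apply(combos, 1, cslbp_code)
  expect_setequal(unique(cs), 0:15)
  lb <- apply(combos, 1, lbp_code, center = 0.5)
  expect_setequal(unique(lb), 0:255)
})

test_that("CS-LBP descriptor has the documented geometry", {
  img <- matrix(sample(0:255, 40 * 40, replace = TRUE), 40, 40)
  d <- cslbp_descriptor(img)
  expect_length(d, 4 * 4 * 16)
  expect_true(all(d >= 0))
  expect_equal(sqrt(sum(d^2)), 1)

  # constant image: every interior code is 0, so only bin-0 entries load
  dc <- cslbp_descriptor(matrix(90, 20, 20))
  loaded <- which(dc > 0)
  expect_true(all((loaded - 1) %% 16 == 0))
  expect_error(cslbp_descriptor(matrix(0, 4, 4)), "too small")
})

test_that("CS-LBP depends only on pairwise differences (gray-shift invariant)", {
  for (i in 1:6) {
    img <- withr::with_seed(800 + i,
      matrix(sample(20:180, 30 * 30, replace = TRUE), 30, 30))
    expect_equal(cslbp_descriptor(img), cslbp_descriptor(img + 51))
  }
})

test_that("snapped-ring CS-LBP matches a naive double-loop implementation", {
  naive <- function(img, grid = 4, threshold = 0.1) {
    x <- img / 255
    h <- nrow(x); w <- ncol(x)
    offs <- round(cbind(-2 * sin(2 * pi * (0:7) / 8),
                        2 * cos(2 * pi * (0:7) / 8)))
    hist <- numeric(grid * grid * 16)
    for (r in 3:(h - 2)) {
      for (cc in 3:(w - 2)) {
        d <- numeric(8)
        for (k in 1:8) d[k] <- x[r + offs[k, 1], cc + offs[k, 2]]
        code <- sum((d[1:4] - d[5:8] >= threshold) * 2^(0:3))
        cr <- min(grid, ceiling(r * grid / h))
        ccell <- min(grid, ceiling(cc * grid / w))
        pos <- ((cr - 1) * grid + ccell - 1) * 16 + code + 1
        hist[pos] <- hist[pos] + 1
      }
    }
    hist / sqrt(sum(hist^2))
  }
  for (i in 1:4) {
    img <- withr::with_seed(900 + i,
      matrix(sample(0:255, 24 * 24, replace = TRUE), 24, 24))
    expect_equal(unname(cslbp_descriptor(img, interpolate = FALSE)),
                 naive(img), tolerance = 1e-12)
  }
})

test_that("90-degree rotation permutes CS-LBP codes by the pair-sign rule", {
  # On values where every centre-symmetric difference is clearly away from
  # the threshold band, rotating the image by 90 degrees maps the pair
  # differences (s0, s1, s2, s3) to (s2, s3, -s0, -s1): a 2-bit cyclic shift
  # with sign flips (hence complementation of the thresholded bits for
  # nonzero differences).
  vals <- c(0, 0.35, 0.7)
  ring_codes <- function(img) {
    x <- img
    offs <- round(cbind(-2 * sin(2 * pi * (0:7) / 8),
                        2 * cos(2 * pi * (0:7) / 8)))
    h <- nrow(x); w <- ncol(x)
    out <- NULL
    for (r in 3:(h - 2)) for (cc in 3:(w - 2)) {
      d <- vapply(1:8, function(k) x[r + offs[k, 1], cc + offs[k, 2]],
                  numeric(1))
      s <- d[1:4] - d[5:8]
      if (any(abs(s) < 0.1 & s != 0)) next # skip threshold-ambiguous pixels
      out <- rbind(out, c(r, cc, sum((s >= 0.1) * 2^(0:3)), s))
    }
    out
  }
  img <- withr::with_seed(42, matrix(sample(vals, 14 * 14, TRUE), 14, 14))
  rot <- t(img[nrow(img):1, ]) # 90-degree rotation
  a <- ring_codes(img)
  b <- ring_codes(rot)
  # match pixels through the rotation map and check the predicted code
  predicted <- function(s) {
    s2 <- c(s[3], s[4], -s[1], -s[2])
    sum((s2 >= 0.1) * 2^(0:3))
  }
  h <- nrow(img)
  for (row in seq_len(nrow(a))) {
    r <- a[row, 1]; cc <- a[row, 2]
    rr <- cc; rc <- h - r + 1 # image rotation pixel map
    hit <- b[b[, 1] == rr & b[, 2] == rc, , drop = FALSE]
    if (nrow(hit) == 1) {
      expect_equal(hit[1, 3], predicted(a[row, 4:7]),
                   label = sprintf("pixel (%d,%d)", r, cc))
    }
  }
})
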