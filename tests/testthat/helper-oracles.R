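# Independent brute-force oracles. Deliberately naive: plain loops, no reuse
# of package internals.

# first-order moments by a per-pixel loop over the raw values
naive_first_order <- function(values) {
  S <- length(values)
  L <- 256
  p <- numeric(L)
  for (v in values) p[v + 1] <- p[v + 1] + 1 / S
  m <- 0
  for (i in 0:(L - 1)) m <- m + i * p[i + 1]
  va <- sk <- ku <- en <- ent <- 0
  for (i in 0:(L - 1)) {
    va <- va + (i - m)^2 * p[i + 1]
    sk <- sk + (i - m)^3 * p[i + 1]
    ku <- ku + (i - m)^4 * p[i + 1]
    en <- en + p[i + 1]^2
    if (p[i + 1] > 0) ent <- ent - p[i + 1] * log2(p[i + 1])
  }
  c(mean = m, variance = va, skewness = sk, kurtosis = ku,
    energy = en, entropy = ent)
}

# connected component (8- or 4-adjacency) of a logical grid containing start,
# by naive repeated dilation
oracle_component <- function(grid, start, connectivity = 8) {
  comp <- matrix(FALSE, nrow(grid), ncol(grid))
  if (!grid[start[1], start[2]]) return(comp)
  comp[start[1], start[2]] <- TRUE
  repeat {
    grew <- FALSE
    for (r in seq_len(nrow(grid))) {
      for (cc in seq_len(ncol(grid))) {
        if (comp[r, cc] || !grid[r, cc]) next
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          if (connectivity == 4 && abs(dr) + abs(dc) == 2) next
          nr <- r + dr; nc <- cc + dc
          if (nr >= 1 && nr <= nrow(grid) && nc >= 1 && nc <= ncol(grid) &&
              comp[nr, nc]) {
            comp[r, cc] <- TRUE
            grew <- TRUE
          }
        }
      }
    }
    if (!grew) break
  }
  comp
}

# thresholded-band connected component: region growing's seed-value oracle
oracle_band_component <- function(img, seed, tol, connectivity = 8) {
  band <- abs(img - img[seed[1], seed[2]]) <= tol
  oracle_component(band, seed, connectivity)
}

# hole filling by background flood fill from an added border ring
oracle_fill_holes <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  padded <- matrix(FALSE, h + 2, w + 2)
  padded[2:(h + 1), 2:(w + 1)] <- mask
  outside <- oracle_component(!padded, c(1, 1), connectivity = 4)
  filled <- !outside[2:(h + 1), 2:(w + 1)]
  filled | mask
}

# longest chord by brute force over ALL true pixels
oracle_major_axis <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  best <- 0
  if (nrow(pts) < 2) return(0)
  for (i in 1:(nrow(pts) - 1)) {
    for (j in (i + 1):nrow(pts)) {
      d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
      if (d > best) best <- d
    }
  }
  best
}

# small random connected mask: the component of a thresholded blurred noise
# field containing its maximum
random_connected_mask <- function(seed, side = 12) {
  withr::with_seed(seed, {
    z <- matrix(stats::rnorm(side * side), side, side)
    z <- z +
      z[c(1, 1:(side - 1)), ] + z[c(2:side, side), ] +
      z[, c(1, 1:(side - 1))] + z[, c(2:side, side)]
    top <- which(z == max(z), arr.ind = TRUE)[1, ]
    oracle_component(z >= stats::quantile(z, 0.6), top)
  })
}

# deterministic phantom batch reused across tests
phantom_batch <- function(n_per_class, seed) {
  specs <- lapply(seq_len(2 * n_per_class), function(i) {
    cls <- if (i <= n_per_class) "benign" else "malignant"
    mammocad::phantom_spec(cls, seed = seed + i)
  })
  lapply(specs, mammocad::generate_phantom)
}

expect_metric_identity <- function(report) {
  res <- tidy(report)
  for (i in seq_len(nrow(res))) {
    P <- res$tp[i] + res$fn[i]
    N <- res$tn[i] + res$fp[i]
    expect_equal(res$accuracy[i],
                 (res$sensitivity[i] * P + res$specificity[i] * N) / (P + N),
                 tolerance = 1e-12)
  }
}
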