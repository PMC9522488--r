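#' Image gradient magnitude and orientation
#'
#' Applies the centred 1-D derivative mask `[-1, 0, +1]` horizontally and
#' vertically (replicated borders), and returns per-pixel gradient magnitude
#' `sqrt(gu^2 + gv^2)` and unsigned orientation `atan(gv / gu)` folded into
#' `[0, 180)` degrees (0 where the magnitude is 0).
#'
#' @param image Gray matrix, at least 3 x 3.
#' @return A list with matrices `magnitude` and `angle` (degrees).
#' @export
gradient_field <- function(image) {
  assert_gray_image(image)
  h <- nrow(image); w <- ncol(image)
  if (h < 3L || w < 3L) stop("image must be at least 3 x 3", call. = FALSE)
  gu <- image[, c(2:w, w), drop = FALSE] - image[, c(1L, 1:(w - 1L)), drop = FALSE]
  gv <- image[c(2:h, h), , drop = FALSE] - image[c(1L, 1:(h - 1L)), , drop = FALSE]
  mag <- sqrt(gu^2 + gv^2)
  ang <- (atan2(gv, gu) * 180 / pi) %% 180
  ang[mag == 0] <- 0
  list(magnitude = mag, angle = ang)
}

#' Histogram-of-oriented-gradients descriptor
#'
#' Resamples the ROI to `resample_side` square (bilinear), computes the
#' gradient field, accumulates per-cell 9-bin orientation histograms over
#' unsigned angles 0--180 degrees with magnitude-weighted votes (each vote
#' linearly interpolated between the two nearest bin centres, bin width 20
#' degrees, circular), gathers cells into `block_side x block_side` blocks at
#' the given stride, L2-normalises each block with an epsilon guard, and
#' concatenates the normalised blocks.
#'
#' @param image Gray matrix.
#' @param resample_side Side of the resampled working image (divisible by
#'   `cell_side`).
#' @param cell_side Cell side in pixels.
#' @param block_side Block side in cells.
#' @param block_stride Block stride in cells.
#' @param n_bins Number of orientation bins (9, the unsigned standard).
#' @param interpolate Linear vote interpolation between adjacent bins; set
#'   `FALSE` for hard assignment to the nearest bin centre.
#' @param epsilon Normalisation guard added (squared) to each block norm.
#' @return Named numeric vector `hog_0001 ...` of length
#'   `n_blocks * block_side^2 * n_bins` (1764 at the defaults:
#'   `(64/8 - 2 + 1)^2 * 4 * 9`).
#' @export
hog_descriptor <- function(image, resample_side = 64L, cell_side = 8L,
                           block_side = 2L, block_stride = 1L, n_bins = 9L,
                           interpolate = TRUE, epsilon = 1e-6) {
  assert_gray_image(image)
  if (resample_side %% cell_side != 0L) {
    stop("resample_side must be divisible by cell_side", call. = FALSE)
  }
  img <- as.matrix(EBImage::resize(image, w = resample_side, h = resample_side))
  g <- gradient_field(clip255(img))
  n_cells <- resample_side %/% cell_side
  rows <- matrix(seq_len(resample_side), resample_side, resample_side)
  cols <- matrix(seq_len(resample_side), resample_side, resample_side, byrow = TRUE)
  cell_r <- (rows - 1L) %/% cell_side + 1L
  cell_c <- (cols - 1L) %/% cell_side + 1L
  bin_width <- 180 / n_bins
  pos <- (g$angle - bin_width / 2) / bin_width # distance in bins from first centre
  hist_acc <- numeric(n_cells * n_cells * n_bins)
  add_votes <- function(acc, bin, wgt) {
    idx <- (bin - 1L) * n_cells * n_cells + (cell_c - 1L) * n_cells + cell_r
    sums <- rowsum(as.vector(wgt), group = as.vector(idx))
    at <- as.integer(rownames(sums))
    acc[at] <- acc[at] + sums[, 1L]
    acc
  }
  if (interpolate) {
    lower <- floor(pos)
    frac <- pos - lower
    bin1 <- (as.integer(lower) %% n_bins) + 1L
    bin2 <- (as.integer(lower + 1) %% n_bins) + 1L
    hist_acc <- add_votes(hist_acc, bin1, g$magnitude * (1 - frac))
    hist_acc <- add_votes(hist_acc, bin2, g$magnitude * frac)
  } else {
    bin <- (as.integer(round(pos)) %% n_bins) + 1L
    hist_acc <- add_votes(hist_acc, bin, g$magnitude)
  }
  hist_arr <- array(hist_acc, dim = c(n_cells, n_cells, n_bins))
  starts <- seq(1L, n_cells - block_side + 1L, by = block_stride)
  blocks <- list()
  for (br in starts) {
    for (bc in starts) {
      v <- numeric(0)
      for (cr in br:(br + block_side - 1L)) {
        for (cc in bc:(bc + block_side - 1L)) {
          v <- c(v, hist_arr[cr, cc, ])
        }
      }
      blocks[[length(blocks) + 1L]] <- v / sqrt(sum(v^2) + epsilon^2)
    }
  }
  out <- unlist(blocks, use.names = FALSE)
  names(out) <- sprintf("hog_%04d", seq_along(out))
  out
}

#' Centre-symmetric LBP code of one sampled neighbourhood
#'
#' Computes the 4-bit centre-symmetric local binary pattern code from 8
#' neighbour values sampled on a circle: `code = sum_i [d_i - d_{i+4} >=
#' T] * 2^i` over the four centre-symmetric pairs, giving an integer in
#' `[0, 15]` (16 possible codes, against 256 for plain LBP).
#'
#' @param d Numeric vector of 8 neighbour values (intensities scaled to
#'   `[0, 1]`), ordered counter-clockwise from east.
#' @param threshold Comparison threshold `T` on the pair difference.
#' @return Integer code in `[0, 15]`.
#' @examples
#' cslbp_code(rep(0.5, 8))            # 0
#' cslbp_code(c(0.6, rep(0.1, 7)))    # 1
#' @export
cslbp_code <- function(d, threshold = 0.1) {
  stopifnot(length(d) == 8L)
  sum(((d[1:4] - d[5:8]) >= threshold) * 2^(0:3))
}

#' Plain LBP code of one sampled neighbourhood
#'
#' The classic 8-bit local binary pattern: each neighbour is compared with
#' the centre value, `code = sum_i [d_i >= center] * 2^i`, an integer in
#' `[0, 255]`. Provided for the code-space comparison with [cslbp_code()].
#'
#' @param d Numeric vector of 8 neighbour values.
#' @param center Centre pixel value.
#' @return Integer code in `[0, 255]`.
#' @export
lbp_code <- function(d, center) {
  stopifnot(length(d) == 8L)
  sum((d >= center) * 2^(0:7))
}

# neighbour offsets on the radius-R circle, east start, counter-clockwise in
# image coordinates (rows grow downward, so ccw means negative row offsets
# first)
cslbp_ring <- function(radius, n_neighbors = 8L) {
  k <- seq_len(n_neighbors) - 1L
  theta <- 2 * pi * k / n_neighbors
  round(cbind(dr = -radius * sin(theta), dc = radius * cos(theta)), 12L)
}

# sample image at (r + dr, c + dc) for all pixels of `sub` (an index grid)
# with a constant fractional offset, by bilinear mixing of integer shifts
shifted_sample <- function(image, rows, cols, dr, dc, interpolate = TRUE) {
  if (!interpolate) {
    return(image[rows + round(dr), cols + round(dc), drop = FALSE])
  }
  r0 <- floor(dr); c0 <- floor(dc)
  fr <- dr - r0; fc <- dc - c0
  s00 <- image[rows + r0, cols + c0, drop = FALSE]
  if (fr == 0 && fc == 0) return(s00)
  if (fr == 0) {
    s01 <- image[rows + r0, cols + c0 + 1L, drop = FALSE]
    return((1 - fc) * s00 + fc * s01)
  }
  if (fc == 0) {
    s10 <- image[rows + r0 + 1L, cols + c0, drop = FALSE]
    return((1 - fr) * s00 + fr * s10)
  }
  s01 <- image[rows + r0, cols + c0 + 1L, drop = FALSE]
  s10 <- image[rows + r0 + 1L, cols + c0, drop = FALSE]
  s11 <- image[rows + r0 + 1L, cols + c0 + 1L, drop = FALSE]
  (1 - fr) * (1 - fc) * s00 + (1 - fr) * fc * s01 +
    fr * (1 - fc) * s10 + fr * fc * s11
}

#' Centre-symmetric LBP descriptor of an ROI
#'
#' Scales intensities to `[0, 1]` (division by 255), samples 8 neighbours by
#' bilinear interpolation at equally spaced points on the radius-`radius`
#' circle (starting east, counter-clockwise), computes the CS-LBP code of
#' every pixel farther than `radius` from the border, splits the image into a
#' `grid x grid` location grid, histograms the 16 codes per cell, and
#' concatenates the cell histograms into one L2-normalised vector.
#'
#' @param image Gray matrix large enough to contain at least one interior
#'   pixel.
#' @param radius Sampling circle radius in pixels.
#' @param threshold CS-LBP comparison threshold on `[0, 1]`-scaled
#'   intensities.
#' @param grid Cells per image side.
#' @param interpolate Bilinear neighbour sampling; `FALSE` snaps the circle
#'   to the 8 nearest integer-offset pixels.
#' @return Named numeric vector `cslbp_0001 ...` of length `grid^2 * 16`
#'   (256 at the default grid of 4).
#' @export
cslbp_descriptor <- function(image, radius = 2, threshold = 0.1, grid = 4L,
                             interpolate = TRUE) {
  assert_gray_image(image)
  h <- nrow(image); w <- ncol(image)
  rpad <- ceiling(radius)
  if (h - 2L * rpad < 1L || w - 2L * rpad < 1L) {
    stop("image too small: no pixel farther than ", radius,
         " px from the border", call. = FALSE)
  }
  img <- image / 255
  rows <- (rpad + 1L):(h - rpad)
  cols <- (rpad + 1L):(w - rpad)
  ring <- cslbp_ring(radius)
  samples <- lapply(seq_len(8L), function(k) {
    shifted_sample(img, rows, cols, ring[k, "dr"], ring[k, "dc"], interpolate)
  })
  codes <- matrix(0L, length(rows), length(cols))
  for (i in 1:4) {
    codes <- codes + (samples[[i]] - samples[[i + 4L]] >= threshold) * 2L^(i - 1L)
  }
  cell_r <- pmin(grid, ceiling(rows * grid / h))
  cell_c <- pmin(grid, ceiling(cols * grid / w))
  hist <- numeric(grid * grid * 16L)
  idx <- (as.vector(codes)) * grid * grid +
    (rep(cell_c, each = length(rows)) - 1L) * grid +
    rep(cell_r, times = length(cols))
  sums <- rowsum(rep(1, length(idx)), group = idx)
  hist[as.integer(rownames(sums))] <- sums[, 1L]
  # reorder so each cell's 16 bins are contiguous, cells in row-major order
  arr <- array(hist, dim = c(grid, grid, 16L))
  out <- numeric(0)
  for (cr in seq_len(grid)) {
    for (cc in seq_len(grid)) {
      out <- c(out, arr[cr, cc, ])
    }
  }
  out <- out / sqrt(sum(out^2))
  names(out) <- sprintf("cslbp_%04d", seq_along(out))
  out
}
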