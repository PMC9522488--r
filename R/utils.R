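# internal validation helpers shared across modules

assert_gray_image <- function(img, arg = "image") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric matrix of gray levels", arg), call. = FALSE)
  }
  if (nrow(img) < 1L || ncol(img) < 1L) {
    stop(sprintf("`%s` must have at least one pixel", arg), call. = FALSE)
  }
  rng <- range(img)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255) {
    stop(sprintf("`%s` intensities must lie in [0, 255]", arg), call. = FALSE)
  }
  invisible(img)
}

assert_mask <- function(mask, img = NULL, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop(sprintf("`%s` must be a logical matrix", arg), call. = FALSE)
  }
  if (!is.null(img) && !identical(dim(mask), dim(img))) {
    stop(sprintf("`%s` dimensions must match the image", arg), call. = FALSE)
  }
  invisible(mask)
}

# pixel matrix of an ROI object or a plain matrix
roi_pixels <- function(x) {
  if (inherits(x, "mammocad_roi")) x$pixels else x
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

# flood fill over a logical grid from a start pixel; returns the connected
# component containing `start` (used for component checks and hole filling)
flood_component <- function(grid, start, connectivity = 8L) {
  h <- nrow(grid); w <- ncol(grid)
  offs <- if (connectivity == 4L) {
    cbind(c(-1L, 0L, 0L, 1L), c(0L, -1L, 1L, 0L))
  } else {
    cbind(c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
          c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  }
  comp <- matrix(FALSE, h, w)
  if (!grid[start[1L], start[2L]]) return(comp)
  queue <- integer(h * w)
  head <- 1L; tail <- 1L
  queue[1L] <- (start[2L] - 1L) * h + start[1L]
  comp[start[1L], start[2L]] <- TRUE
  while (head <= tail) {
    id <- queue[head]; head <- head + 1L
    r <- ((id - 1L) %% h) + 1L
    cc <- ((id - 1L) %/% h) + 1L
    for (k in seq_len(nrow(offs))) {
      nr <- r + offs[k, 1L]; nc <- cc + offs[k, 2L]
      if (nr >= 1L && nr <= h && nc >= 1L && nc <= w &&
          grid[nr, nc] && !comp[nr, nc]) {
        comp[nr, nc] <- TRUE
        tail <- tail + 1L
        queue[tail] <- (nc - 1L) * h + nr
      }
    }
  }
  comp
}

n_components <- function(mask, connectivity = 8L) {
  remaining <- mask
  n <- 0L
  while (any(remaining)) {
    start <- which(remaining, arr.ind = TRUE)[1L, ]
    remaining <- remaining & !flood_component(remaining, start, connectivity)
    n <- n + 1L
  }
  n
}
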