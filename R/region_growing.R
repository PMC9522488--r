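#' Seeded region growing segmentation
#'
#' Segments the lesion inside an ROI by breadth-first region growing from a
#' seed pixel. A frontier pixel joins the region iff its intensity differs
#' from the reference by at most `tolerance` gray levels, where the reference
#' is either the seed intensity (`criterion = "seed-value"`) or the running
#' mean of the pixels accepted so far (`criterion = "running-mean"`, the
#' default, which tolerates gradual drift across a noisy plateau). Growth is
#' FIFO breadth-first with a fixed neighbour order, each pixel is examined at
#' most once, and the procedure stops when no frontier pixel qualifies, so
#' the result is deterministic.
#'
#' With `criterion = "seed-value"` the result equals the connected component
#' of the thresholded band `|I - I(seed)| <= tolerance` containing the seed.
#'
#' @param roi A gray matrix or a `mammocad_roi` from [crop_roi()].
#' @param seed `"auto-center"` (the ROI centre pixel; tumour-centred crops
#'   place the lesion there) or a `(row, col)` pair.
#' @param tolerance Acceptance tolerance in gray levels, in `[0, 255]`.
#' @param connectivity Pixel adjacency, 4 or 8.
#' @param criterion `"running-mean"` or `"seed-value"`.
#' @return A logical mask matrix the size of the ROI; the seed pixel is
#'   always `TRUE` and every `TRUE` pixel is connected to the seed.
#' @examples
#' img <- matrix(50, 20, 20); img[6:15, 6:15] <- 200
#' mask <- region_grow(img, seed = c(10, 10), tolerance = 0)
#' sum(mask) # the 10 x 10 block
#' @export
region_grow <- function(roi, seed = "auto-center", tolerance = 45,
                        connectivity = 8L,
                        criterion = c("running-mean", "seed-value")) {
  criterion <- match.arg(criterion)
  img <- roi_pixels(roi)
  assert_gray_image(img, "roi")
  if (!(tolerance >= 0 && tolerance <= 255)) {
    stop("tolerance must lie in [0, 255]", call. = FALSE)
  }
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8", call. = FALSE)
  h <- nrow(img); w <- ncol(img)
  if (identical(seed, "auto-center")) {
    seed <- c(floor(h / 2) + 1L, floor(w / 2) + 1L)
  }
  seed <- as.integer(seed)
  if (length(seed) != 2L || seed[1L] < 1L || seed[1L] > h ||
      seed[2L] < 1L || seed[2L] > w) {
    stop("seed (", paste(seed, collapse = ", "),
         ") lies outside the ROI", call. = FALSE)
  }
  offs <- if (connectivity == 4L) {
    cbind(c(-1L, 0L, 0L, 1L), c(0L, -1L, 1L, 0L))
  } else {
    cbind(c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
          c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  }
  member <- matrix(FALSE, h, w)
  visited <- matrix(FALSE, h, w)
  queue <- integer(h * w)
  qhead <- 1L; qtail <- 1L
  queue[1L] <- (seed[2L] - 1L) * h + seed[1L]
  member[seed[1L], seed[2L]] <- TRUE
  visited[seed[1L], seed[2L]] <- TRUE
  seed_val <- img[seed[1L], seed[2L]]
  acc_sum <- seed_val
  acc_n <- 1L
  while (qhead <= qtail) {
    id <- queue[qhead]; qhead <- qhead + 1L
    r <- ((id - 1L) %% h) + 1L
    cc <- ((id - 1L) %/% h) + 1L
    ref <- if (criterion == "seed-value") seed_val else acc_sum / acc_n
    for (k in seq_len(nrow(offs))) {
      nr <- r + offs[k, 1L]; nc <- cc + offs[k, 2L]
      if (nr < 1L || nr > h || nc < 1L || nc > w || visited[nr, nc]) next
      visited[nr, nc] <- TRUE
      if (abs(img[nr, nc] - ref) <= tolerance) {
        member[nr, nc] <- TRUE
        acc_sum <- acc_sum + img[nr, nc]
        acc_n <- acc_n + 1L
        qtail <- qtail + 1L
        queue[qtail] <- (nc - 1L) * h + nr
      }
    }
  }
  member
}

#' Fill enclosed holes in a segmentation mask
#'
#' Fills background regions fully enclosed by the mask. A singleton mask
#' (growth accepted no neighbour of the seed) is returned unchanged with a
#' warning and attribute `singleton = TRUE`.
#'
#' @param mask Logical mask matrix with at least one `TRUE` pixel.
#' @return The hole-filled logical mask.
#' @export
postprocess_mask <- function(mask) {
  assert_mask(mask)
  n <- sum(mask)
  if (n == 0L) stop("mask is empty", call. = FALSE)
  if (n == 1L) {
    warning("region growing accepted no neighbours: singleton mask", call. = FALSE)
    attr(mask, "singleton") <- TRUE
    return(mask)
  }
  filled <- as.matrix(EBImage::fillHull(mask * 1L)) > 0
  dimnames(filled) <- NULL
  filled
}
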