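#' Gray-level histogram of an image or masked region
#'
#' Normalised first-order histogram `p[i] = N(v_i) / S` over the `L = 256`
#' gray levels, counting either all pixels or only those under a mask.
#'
#' @param image Gray matrix with integer values in `[0, 255]`.
#' @param mask Optional logical mask selecting the counted pixels (at least
#'   one `TRUE` pixel).
#' @return A list of class `gray_histogram` with `p` (length-256 probability
#'   vector over levels `0:255`) and `n_pixels`.
#' @export
gray_histogram <- function(image, mask = NULL) {
  assert_gray_image(image)
  vals <- if (is.null(mask)) {
    as.vector(image)
  } else {
    assert_mask(mask, image)
    if (!any(mask)) stop("mask is empty", call. = FALSE)
    image[mask]
  }
  counts <- tabulate(as.integer(round(vals)) + 1L, nbins = 256L)
  structure(list(p = counts / length(vals), n_pixels = length(vals)),
            class = "gray_histogram")
}

#' First-order histogram features
#'
#' The six histogram statistics used as first-order texture features: mean,
#' variance, skewness and kurtosis as the 1st--4th central moments of the
#' gray-level distribution (skewness and kurtosis deliberately left
#' unnormalised), energy `sum(p^2)` and Shannon entropy
#' `-sum(p * log2(p))` in bits.
#'
#' `printed_forms = TRUE` switches energy and entropy to the variant forms
#' `sum(v * p^2)` and `-sum(v * log2(p))` that weight each term by the gray
#' level itself; the standard forms are the default because only they behave
#' as homogeneity/uncertainty measures (energy of any constant image is 1,
#' entropy 0, regardless of the constant).
#'
#' @param h A [gray_histogram()], or a gray matrix (a histogram over all its
#'   pixels is then taken).
#' @param printed_forms Use the gray-level-weighted variant forms of energy
#'   and entropy.
#' @return A one-row tibble with columns `stat_mean`, `stat_variance`,
#'   `stat_skewness`, `stat_kurtosis`, `stat_energy`, `stat_entropy`.
#' @examples
#' first_order_features(gray_histogram(matrix(c(0, 1, 1, 1), 2, 2)))
#' @export
first_order_features <- function(h, printed_forms = FALSE) {
  if (is.matrix(h)) h <- gray_histogram(h)
  if (!inherits(h, "gray_histogram")) {
    stop("`h` must be a gray_histogram or a gray matrix", call. = FALSE)
  }
  p <- h$p
  v <- 0:255
  m <- sum(v * p)
  pos <- p > 0
  if (printed_forms) {
    energy <- sum(v * p^2)
    entropy <- -sum(v[pos] * log2(p[pos]))
  } else {
    energy <- sum(p^2)
    entropy <- -sum(p[pos] * log2(p[pos]))
  }
  tibble::tibble(
    stat_mean = m,
    stat_variance = sum((v - m)^2 * p),
    stat_skewness = sum((v - m)^3 * p),
    stat_kurtosis = sum((v - m)^4 * p),
    stat_energy = energy,
    stat_entropy = entropy
  )
}

glcm_offsets <- function(d) {
  list("0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L), "135" = c(-d, -d))
}

#' Gray-level co-occurrence matrices at the four standard orientations
#'
#' Quantises the image to `levels` gray levels by uniform binning of
#' `[0, 255]` and counts co-occurring pixel pairs at displacement `distance`
#' along 0 (horizontal), 45 (diagonal), 90 (vertical) and 135
#' (anti-diagonal) degrees. With `symmetric = TRUE` each matrix is made
#' symmetric by adding its transpose before normalisation to unit sum. When
#' a mask is given, a pair is counted only if both of its pixels lie inside
#' the mask.
#'
#' @param image Gray matrix.
#' @param mask Optional logical mask.
#' @param levels Number of quantised gray levels, in `[2, 256]`.
#' @param distance Pair displacement in pixels.
#' @param symmetric Symmetrise by adding the transposed counts.
#' @return A named list (`"0"`, `"45"`, `"90"`, `"135"`) of `levels x levels`
#'   matrices, each summing to 1, of class `mammocad_glcm`.
#' @export
glcm <- function(image, mask = NULL, levels = 8L, distance = 1L,
                 symmetric = TRUE) {
  assert_gray_image(image)
  if (!is.null(mask)) assert_mask(mask, image)
  if (levels < 2L || levels > 256L) stop("levels must lie in [2, 256]", call. = FALSE)
  if (distance < 1L) stop("distance must be at least 1", call. = FALSE)
  h <- nrow(image); w <- ncol(image)
  q <- matrix(pmin(floor(image / (256 / levels)), levels - 1L), h, w)
  mats <- lapply(names(glcm_offsets(distance)), function(ori) {
    off <- glcm_offsets(distance)[[ori]]
    dr <- off[1L]; dc <- off[2L]
    rows <- seq_len(h); cols <- seq_len(w)
    r1 <- rows[rows + dr >= 1L & rows + dr <= h]
    c1 <- cols[cols + dc >= 1L & cols + dc <= w]
    if (length(r1) == 0L || length(c1) == 0L) {
      stop("fewer than one valid pixel pair at orientation ", ori,
           " degrees", call. = FALSE)
    }
    i <- q[r1, c1, drop = FALSE]
    j <- q[r1 + dr, c1 + dc, drop = FALSE]
    keep <- if (is.null(mask)) TRUE else {
      mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
    }
    iv <- i[keep]; jv <- j[keep]
    if (length(iv) == 0L) {
      stop("fewer than one valid pixel pair at orientation ", ori,
           " degrees", call. = FALSE)
    }
    counts <- matrix(tabulate(iv * levels + jv + 1L, nbins = levels^2),
                     levels, levels, byrow = TRUE)
    if (symmetric) counts <- counts + t(counts)
    counts / sum(counts)
  })
  names(mats) <- names(glcm_offsets(distance))
  structure(mats, class = "mammocad_glcm", levels = levels,
            distance = distance, symmetric = symmetric)
}

glcm_features_one <- function(P) {
  levels <- nrow(P)
  idx <- 0:(levels - 1L)
  I <- matrix(idx, levels, levels)
  J <- matrix(idx, levels, levels, byrow = TRUE)
  pi_ <- rowSums(P); pj_ <- colSums(P)
  mu_i <- sum(idx * pi_); mu_j <- sum(idx * pj_)
  s_i <- sqrt(sum((idx - mu_i)^2 * pi_))
  s_j <- sqrt(sum((idx - mu_j)^2 * pj_))
  corr <- if (s_i == 0 || s_j == 0) 0 else {
    sum((I - mu_i) * (J - mu_j) * P) / (s_i * s_j)
  }
  pos <- P > 0
  c(correlation = corr,
    inertia = sum((I - J)^2 * P),
    inverse_difference = sum(P / (1 + abs(I - J))),
    asm = sum(P^2),
    absolute_value = sum(abs(I - J) * P),
    max_probability = max(P),
    entropy = -sum(P[pos] * log2(P[pos])))
}

#' Direction-averaged GLCM texture features
#'
#' Computes, for each orientation matrix, correlation, inertia (contrast),
#' inverse difference (homogeneity), angular second moment, absolute value
#' (dissimilarity), maximum probability and entropy (bits), and returns the
#' mean of each feature over the four orientations. Correlation is defined
#' as 0 when either marginal is degenerate.
#'
#' @param matrices A `mammocad_glcm` from [glcm()] (or any list of four
#'   normalised co-occurrence matrices).
#' @return A one-row tibble with columns `glcm_correlation`, `glcm_inertia`,
#'   `glcm_inverse_difference`, `glcm_asm`, `glcm_absolute_value`,
#'   `glcm_max_probability`, `glcm_entropy`.
#' @export
glcm_features <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) == 4L)
  per <- vapply(matrices, glcm_features_one, numeric(7L))
  avg <- rowMeans(per)
  tibble::tibble(
    glcm_correlation = avg[["correlation"]],
    glcm_inertia = avg[["inertia"]],
    glcm_inverse_difference = avg[["inverse_difference"]],
    glcm_asm = avg[["asm"]],
    glcm_absolute_value = avg[["absolute_value"]],
    glcm_max_probability = avg[["max_probability"]],
    glcm_entropy = avg[["entropy"]]
  )
}
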