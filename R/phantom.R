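#' Specify a synthetic lesion phantom
#'
#' Builds and validates the parameter set for one phantom mammogram: a bright
#' lesion plateau on a darker, smoothly textured background with additive
#' Gaussian noise. Benign lesions are smooth ellipses (axis ratio at least
#' 0.7); malignant lesions are spiculated stars whose support follows the
#' radial function `r(theta) = base_radius * (1 + amplitude * max(0,
#' cos(spicule_count * theta)))`.
#'
#' @param lesion_class `"benign"` or `"malignant"`.
#' @param image_side Image side length in pixels.
#' @param center Lesion centre `(row, col)`, 1-based; defaults to the image
#'   centre.
#' @param base_radius Lesion base radius in pixels.
#' @param spicule_count Number of spicules (0 for benign, at least 5 for
#'   malignant).
#' @param spicule_amplitude Spicule length as a fraction of `base_radius`,
#'   in `[0, 1]`.
#' @param axis_ratio Minor/major axis ratio of the benign ellipse (ignored
#'   for malignant lesions, whose base is circular).
#' @param lesion_intensity,background_intensity Gray levels of the lesion
#'   plateau and the background; the lesion must be brighter.
#' @param noise_sigma Standard deviation of the additive Gaussian pixel
#'   noise, in gray levels.
#' @param texture_scale Correlation length (Gaussian blur sigma, pixels) of
#'   the background texture.
#' @param texture_amplitude Standard deviation of the background texture
#'   after smoothing, in gray levels.
#' @param seed Integer seed making the phantom reproducible.
#' @return A validated list of class `phantom_spec`.
#' @seealso [generate_phantom()], [generate_dataset()]
#' @export
phantom_spec <- function(lesion_class = c("benign", "malignant"),
                         image_side = 128L,
                         center = NULL,
                         base_radius = 18,
                         spicule_count = NULL,
                         spicule_amplitude = NULL,
                         axis_ratio = NULL,
                         lesion_intensity = 180,
                         background_intensity = 90,
                         noise_sigma = 10,
                         texture_scale = 8,
                         texture_amplitude = 6,
                         seed = 1L) {
  lesion_class <- match.arg(lesion_class)
  benign <- lesion_class == "benign"
  if (is.null(spicule_count)) spicule_count <- if (benign) 0L else 8L
  if (is.null(spicule_amplitude)) spicule_amplitude <- if (benign) 0 else 0.5
  if (is.null(axis_ratio)) axis_ratio <- if (benign) 0.85 else 1
  if (is.null(center)) center <- rep(ceiling(image_side / 2), 2L)
  spec <- structure(
    list(lesion_class = lesion_class, image_side = as.integer(image_side),
         center = as.numeric(center), base_radius = base_radius,
         spicule_count = as.integer(spicule_count),
         spicule_amplitude = spicule_amplitude, axis_ratio = axis_ratio,
         lesion_intensity = lesion_intensity,
         background_intensity = background_intensity,
         noise_sigma = noise_sigma, texture_scale = texture_scale,
         texture_amplitude = texture_amplitude, seed = as.integer(seed)),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (lesion_intensity <= background_intensity) {
      stop("lesion_intensity must exceed background_intensity ",
           "(lesions are brighter masses)", call. = FALSE)
    }
    if (spicule_amplitude < 0 || spicule_amplitude > 1) {
      stop("spicule_amplitude must lie in [0, 1]", call. = FALSE)
    }
    if (noise_sigma < 0) stop("noise_sigma must be non-negative", call. = FALSE)
    if (base_radius <= 0) stop("base_radius must be positive", call. = FALSE)
    reach <- base_radius * (1 + spicule_amplitude)
    if (any(center - reach < 1) || any(center + reach > image_side)) {
      stop("lesion (centre ± base_radius * (1 + spicule_amplitude)) ",
           "must lie inside the image", call. = FALSE)
    }
    if (lesion_class == "benign") {
      if (spicule_count != 0L) {
        stop("benign phantoms must have spicule_count = 0", call. = FALSE)
      }
      if (axis_ratio < 0.7 || axis_ratio > 1) {
        stop("benign axis_ratio must lie in [0.7, 1]", call. = FALSE)
      }
    } else if (spicule_count < 5L) {
      stop("malignant phantoms must have spicule_count >= 5", call. = FALSE)
    }
  })
  spec
}

# noise-free lesion support on the pixel grid
phantom_mask <- function(spec) {
  side <- spec$image_side
  dr <- matrix(seq_len(side) - spec$center[1L], side, side)
  dc <- matrix(seq_len(side) - spec$center[2L], side, side, byrow = TRUE)
  if (spec$lesion_class == "benign") {
    a <- spec$base_radius
    b <- spec$base_radius * spec$axis_ratio
    (dc / a)^2 + (dr / b)^2 <= 1
  } else {
    theta <- atan2(dr, dc)
    rmax <- spec$base_radius *
      (1 + spicule_profile(theta, spec$spicule_count, spec$spicule_amplitude))
    sqrt(dr^2 + dc^2) <= rmax
  }
}

spicule_profile <- function(theta, count, amplitude) {
  amplitude * pmax(0, cos(count * theta))
}

#' Generate one labelled phantom mammogram
#'
#' Renders the phantom described by a [phantom_spec()]: pixels are the
#' background level plus Gaussian-smoothed white-noise texture, raised to the
#' lesion plateau inside the noise-free lesion support, plus i.i.d. Gaussian
#' noise, clipped to `[0, 255]` and rounded. The returned ground-truth mask
#' is the noise-free support itself. Bit-identical for identical spec and
#' seed.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `mammocad_phantom`: `pixels` (gray matrix),
#'   `truth_mask` (logical matrix), `label` (0 benign, 1 malignant) and
#'   `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec("malignant", seed = 7))
#' ph$label
#' sum(ph$truth_mask)
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    stop("`spec` must be created by phantom_spec()", call. = FALSE)
  }
  validate_phantom_spec(spec)
  side <- spec$image_side
  mask <- phantom_mask(spec)
  img <- withr::with_seed(spec$seed, {
    base <- matrix(spec$background_intensity, side, side)
    if (spec$texture_amplitude > 0) {
      tex <- matrix(stats::rnorm(side * side), side, side)
      tex <- as.matrix(EBImage::gblur(tex, sigma = spec$texture_scale))
      base <- base + tex / stats::sd(tex) * spec$texture_amplitude
    }
    base[mask] <- base[mask] + (spec$lesion_intensity - spec$background_intensity)
    if (spec$noise_sigma > 0) {
      base <- base + matrix(stats::rnorm(side * side, sd = spec$noise_sigma),
                            side, side)
    }
    base
  })
  structure(
    list(pixels = round(clip255(img)),
         truth_mask = mask,
         label = if (spec$lesion_class == "malignant") 1L else 0L,
         spec = spec),
    class = "mammocad_phantom"
  )
}

#' @export
print.mammocad_phantom <- function(x, ...) {
  cat("<mammocad_phantom> ", x$spec$lesion_class, ", ",
      x$spec$image_side, "x", x$spec$image_side, " px, lesion area ",
      sum(x$truth_mask), " px (seed ", x$spec$seed, ")\n", sep = "")
  invisible(x)
}

#' Generate a labelled phantom dataset on disk
#'
#' Draws per-image phantom specifications reproducibly from a master seed
#' (randomised centres, base radii in 14--22 px, benign axis ratios in
#' `[0.7, 1]`, malignant spicule counts in 5--12 with amplitude 0.5), writes
#' 8-bit PNG images and ground-truth masks, and returns (and writes) a CSV
#' manifest. The manifest's annotation radius is the enclosing radius
#' `ceiling(base_radius * (1 + spicule_amplitude)) + 3`, so a square crop of
#' that radius contains the whole lesion including spicule tips.
#'
#' @param n_benign,n_malignant Number of phantoms per class.
#' @param seed Master seed; all per-image randomness derives from it.
#' @param out_dir Output directory (created if missing).
#' @return The manifest tibble with columns `filename`, `mask_filename`,
#'   `label`, `center_row`, `center_col`, `radius`, `seed` (also written to
#'   `manifest.csv` in `out_dir`). Centres are 1-based row/col from the
#'   top-left.
#' @export
generate_dataset <- function(n_benign, n_malignant, seed, out_dir) {
  stopifnot(n_benign >= 0, n_malignant >= 0)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create out_dir: ", out_dir, call. = FALSE)
  n <- n_benign + n_malignant
  classes <- rep(c("benign", "malignant"), c(n_benign, n_malignant))
  specs <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n), function(i) {
      cls <- classes[i]
      base_radius <- sample(14:22, 1L)
      amp <- if (cls == "malignant") 0.5 else 0
      reach <- ceiling(base_radius * (1 + amp)) + 1L
      side <- 128L
      center <- c(sample((reach + 1L):(side - reach), 1L),
                  sample((reach + 1L):(side - reach), 1L))
      phantom_spec(
        lesion_class = cls, image_side = side, center = center,
        base_radius = base_radius,
        spicule_count = if (cls == "malignant") sample(5:12, 1L) else 0L,
        spicule_amplitude = amp,
        axis_ratio = if (cls == "benign") stats::runif(1L, 0.7, 1) else 1,
        seed = sample.int(.Machine$integer.max - 1L, 1L)
      )
    })
  })
  rows <- lapply(seq_len(n), function(i) {
    spec <- specs[[i]]
    ph <- generate_phantom(spec)
    stem <- sprintf("phantom_%03d", i)
    write_gray_image(ph$pixels, file.path(out_dir, paste0(stem, ".png")))
    write_gray_image(ifelse(ph$truth_mask, 255, 0),
                     file.path(out_dir, paste0(stem, "_mask.png")))
    tibble::tibble(
      filename = paste0(stem, ".png"),
      mask_filename = paste0(stem, "_mask.png"),
      label = ph$label,
      center_row = spec$center[1L],
      center_col = spec$center[2L],
      radius = ceiling(spec$base_radius * (1 + spec$spicule_amplitude)) + 3,
      seed = spec$seed
    )
  })
  manifest <- if (n == 0L) {
    tibble::tibble(filename = character(), mask_filename = character(),
                   label = integer(), center_row = numeric(),
                   center_col = numeric(), radius = numeric(), seed = integer())
  } else {
    dplyr::bind_rows(rows)
  }
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
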