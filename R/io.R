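#' Read an 8-bit grayscale image
#'
#' Reads a PGM (ASCII `P2` or binary `P5`) or an 8-bit single-channel PNG file
#' into a matrix of integer gray levels in `[0, 255]`, row-major with the
#' origin at the top-left, exactly as stored on disk.
#'
#' @param path Path to a `.pgm` or `.png` file.
#' @return A numeric matrix of integer intensities in `[0, 255]`.
#' @examples
#' img <- matrix(0:8, 3, 3, byrow = TRUE)
#' f <- tempfile(fileext = ".png")
#' write_gray_image(img, f)
#' identical(read_gray_image(f), img * 1)
#' @seealso [write_gray_image()], [crop_roi()]
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  magic <- readBin(path, "raw", n = 2L)
  if (identical(magic, charToRaw("P2")) || identical(magic, charToRaw("P5"))) {
    return(read_pgm(path))
  }
  x <- png::readPNG(path)
  if (length(dim(x)) != 2L) {
    stop("unsupported: not single-channel (expected grayscale, got ",
         dim(x)[3L], " channels)", call. = FALSE)
  }
  v <- x * 255
  if (max(abs(v - round(v))) > 1e-6) {
    stop("unsupported bit depth: image is not 8-bit", call. = FALSE)
  }
  round(v)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || ch == "") stop("malformed PGM header", call. = FALSE)
      if (ch == "#") { # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "" || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok)
      } else {
        tok <- paste0(tok, ch)
      }
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) stop("malformed PGM header: ", magic, call. = FALSE)
  w <- suppressWarnings(as.integer(read_token()))
  h <- suppressWarnings(as.integer(read_token()))
  maxval <- suppressWarnings(as.integer(read_token()))
  if (anyNA(c(w, h, maxval)) || w < 1L || h < 1L) {
    stop("malformed PGM header", call. = FALSE)
  }
  if (maxval > 255L) stop("unsupported bit depth: maxval ", maxval, call. = FALSE)
  n <- w * h
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n = n))
  } else {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(vals) != n) stop("malformed PGM: truncated pixel data", call. = FALSE)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) * 1
}

#' Write an 8-bit grayscale image
#'
#' Writes PGM (binary `P5` by default, ASCII `P2` on request) or 8-bit
#' grayscale PNG, chosen from the file extension. Round-trips losslessly
#' through [read_gray_image()].
#'
#' @param img Numeric matrix with integer values in `[0, 255]`.
#' @param path Output path ending in `.png` or `.pgm`.
#' @param ascii For PGM only: write ASCII `P2` instead of binary `P5`.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path, ascii = FALSE) {
  assert_gray_image(img)
  img <- round(img)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img / 255, path)
  } else if (ext == "pgm") {
    if (ascii) {
      lines <- c("P2", paste(ncol(img), nrow(img)), "255",
                 apply(img, 1L, paste, collapse = " "))
      writeLines(lines, path)
    } else {
      con <- file(path, "wb")
      on.exit(close(con))
      writeChar(sprintf("P5\n%d %d\n255\n", ncol(img), nrow(img)), con, eos = NULL)
      writeBin(as.raw(as.integer(t(img))), con)
    }
  } else {
    stop("unsupported extension: .", ext, " (use .png or .pgm)", call. = FALSE)
  }
  invisible(path)
}

#' Parse MIAS-convention annotation records
#'
#' Parses the whitespace-separated info-file format used by the MIAS
#' mammogram database: `ref tissue abnormality severity x y radius`, where
#' normal records (`NORM`) omit severity and geometry. Coordinates follow the
#' MIAS convention: 0-based, `x` from the left edge and `y` from the
#' **bottom** edge.
#'
#' @param lines Character vector of record lines (blank lines are skipped).
#' @return A tibble with one row per record: `ref_id`, `tissue`,
#'   `abnormality`, `severity` (`"benign"`, `"malignant"` or `"normal"`),
#'   `center_x`, `center_y`, `radius` (`NA` for normal records).
#' @examples
#' parse_mias_info(c("mdb001 G CIRC B 535 425 197", "mdb003 D NORM"))
#' @export
parse_mias_info <- function(lines) {
  stopifnot(is.character(lines))
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  rows <- lapply(idx, function(i) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    if (length(tok) == 3L) {
      if (toupper(tok[3L]) != "NORM") {
        stop("malformed annotation at line ", i,
             ": 3-field record must be NORM", call. = FALSE)
      }
      return(tibble::tibble(ref_id = tok[1L], tissue = tok[2L],
                            abnormality = "NORM", severity = "normal",
                            center_x = NA_real_, center_y = NA_real_,
                            radius = NA_real_))
    }
    if (length(tok) != 7L) {
      stop("malformed annotation at line ", i, ": expected 3 or 7 fields, got ",
           length(tok), call. = FALSE)
    }
    sev <- switch(toupper(tok[4L]), B = "benign", M = "malignant",
                  stop("malformed annotation at line ", i,
                       ": unknown severity '", tok[4L], "'", call. = FALSE))
    geo <- suppressWarnings(as.numeric(tok[5:7]))
    if (anyNA(geo)) {
      stop("non-numeric geometry at line ", i, call. = FALSE)
    }
    if (geo[3L] <= 0) {
      stop("malformed annotation at line ", i, ": radius must be positive",
           call. = FALSE)
    }
    tibble::tibble(ref_id = tok[1L], tissue = tok[2L], abnormality = tok[3L],
                   severity = sev, center_x = geo[1L], center_y = geo[2L],
                   radius = geo[3L])
  })
  dplyr::bind_rows(rows)
}

#' Crop a tumour-centred square region of interest
#'
#' Crops the axis-aligned square of side `2 * radius` centred on the
#' annotated lesion, clipped at the image borders (no padding). MIAS
#' annotations place the origin at the bottom-left with 0-based coordinates;
#' these are converted to the top-left, 1-based row/column convention used
#' for matrices in R. With `origin = "top-left"` the annotation's `center_y`
#' and `center_x` are taken directly as 1-based row and column.
#'
#' @param image Gray-level matrix (see [read_gray_image()]).
#' @param ann A one-row data frame (or list) with `center_x`, `center_y`,
#'   `radius`, and optionally `ref_id`, as returned by [parse_mias_info()].
#' @param origin `"mias-bottom-left"` (default) or `"top-left"`.
#' @return An object of class `mammocad_roi`: a list with `pixels` (the
#'   square crop), `source_ref`, `offset` (1-based row/col of the crop origin
#'   in the source image) and `center` (1-based row/col of the lesion centre
#'   within the crop).
#' @export
crop_roi <- function(image, ann, origin = c("mias-bottom-left", "top-left")) {
  assert_gray_image(image)
  origin <- match.arg(origin)
  if (is.null(ann$radius) || is.na(ann$radius) ||
      is.na(ann$center_x) || is.na(ann$center_y)) {
    stop("annotation carries no lesion geometry", call. = FALSE)
  }
  h <- nrow(image); w <- ncol(image)
  r <- as.integer(round(ann$radius))
  if (r < 1L) stop("annotation radius must be at least 1 pixel", call. = FALSE)
  if (origin == "mias-bottom-left") {
    crow <- h - as.integer(round(ann$center_y)) # h - 1 - y, then +1 for 1-based
    ccol <- as.integer(round(ann$center_x)) + 1L
  } else {
    crow <- as.integer(round(ann$center_y))
    ccol <- as.integer(round(ann$center_x))
  }
  if (crow < 1L || crow > h || ccol < 1L || ccol > w) {
    stop("converted lesion centre (", crow, ", ", ccol,
         ") lies outside the image", call. = FALSE)
  }
  r0 <- max(1L, crow - r); r1 <- min(h, crow + r - 1L)
  c0 <- max(1L, ccol - r); c1 <- min(w, ccol + r - 1L)
  structure(
    list(pixels = image[r0:r1, c0:c1, drop = FALSE],
         source_ref = if (!is.null(ann$ref_id)) ann$ref_id else NA_character_,
         offset = c(row = r0, col = c0),
         center = c(row = crow - r0 + 1L, col = ccol - c0 + 1L)),
    class = "mammocad_roi"
  )
}

#' @export
print.mammocad_roi <- function(x, ...) {
  cat("<mammocad_roi> ", nrow(x$pixels), "x", ncol(x$pixels),
      " crop of '", x$source_ref, "' at offset (", x$offset[1L], ", ",
      x$offset[2L], ")\n", sep = "")
  invisible(x)
}
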