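default_config <- function() {
  list(
    mode = "phantom",
    out_dir = "mammocad_run",
    seed = 1L,
    verbose = TRUE,
    phantom = list(n_benign = 20L, n_malignant = 20L),
    mias = list(image_dir = NULL, info_file = NULL,
                origin = "mias-bottom-left"),
    grow = list(tolerance = 45, connectivity = 8L, criterion = "running-mean"),
    features_on = "mask", # "mask" or "roi" for histogram/GLCM support
    glcm = list(levels = 8L, distance = 1L, symmetric = TRUE),
    hog = list(resample_side = 64L, cell_side = 8L, block_side = 2L,
               block_stride = 1L),
    cslbp = list(radius = 2, threshold = 0.1, grid = 4L),
    cv = list(k = 10L, stratified = TRUE, standardize = TRUE,
              classifiers = c("knn", "svm", "lda", "dtree", "ensemble")),
    families = c("stat", "glcm", "hog", "cslbp", "shape")
  )
}

merge_config <- function(cfg) {
  base <- default_config()
  for (nm in names(cfg)) {
    if (is.list(base[[nm]]) && is.list(cfg[[nm]])) {
      base[[nm]] <- utils::modifyList(base[[nm]], cfg[[nm]])
    } else {
      base[[nm]] <- cfg[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Missing entries fall back to the package defaults; the run-metadata JSON
#' written by [run_pipeline()] can be re-fed here to reproduce a run.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A complete configuration list.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: .", ext, call. = FALSE)
  }
  if (!is.null(cfg$config)) cfg <- cfg$config # run-metadata round-trip
  merge_config(cfg)
}

#' Extract one feature record from an annotated image
#'
#' Runs the single-image half of the CAD pipeline: read the image, crop the
#' tumour-centred square ROI, segment by seeded region growing, fill holes,
#' and compute all five feature families. First-order and GLCM features are
#' computed on the segmented lesion pixels (set `features_on = "roi"` for
#' the full rectangle); HOG and CS-LBP use the rectangular ROI, which their
#' grids require; shape features describe the mask.
#'
#' @param image Path to a PGM/PNG image, or a gray matrix.
#' @param annotation One-row data frame or list with `center_x`, `center_y`,
#'   `radius` and optionally `ref_id` (see [crop_roi()]).
#' @param config Pipeline configuration list (partial lists are completed
#'   with defaults).
#' @param origin Annotation coordinate origin, see [crop_roi()].
#' @return A one-row tibble: `ref_id`, `mask_area`, then `stat_*` (6),
#'   `glcm_*` (7), `hog_*`, `cslbp_*`, `shape_*` (7) columns; 2040 feature
#'   values at the defaults. `NULL` (with a message) if segmentation
#'   degenerates to a singleton.
#' @export
featurize_single <- function(image, annotation, config = list(),
                             origin = NULL) {
  cfg <- merge_config(config)
  if (is.null(origin)) origin <- cfg$mias$origin
  img <- if (is.character(image)) read_gray_image(image) else image
  roi <- crop_roi(img, annotation, origin = origin)
  mask <- region_grow(roi, seed = as.integer(roi$center),
                      tolerance = cfg$grow$tolerance,
                      connectivity = cfg$grow$connectivity,
                      criterion = cfg$grow$criterion)
  mask <- suppressWarnings(postprocess_mask(mask))
  if (isTRUE(attr(mask, "singleton"))) {
    message("segmentation degenerated to a singleton; record skipped")
    return(NULL)
  }
  support <- if (identical(cfg$features_on, "roi")) NULL else mask
  stat <- first_order_features(gray_histogram(roi$pixels, support))
  glcm_f <- glcm_features(glcm(roi$pixels, support,
                               levels = cfg$glcm$levels,
                               distance = cfg$glcm$distance,
                               symmetric = cfg$glcm$symmetric))
  hog <- hog_descriptor(roi$pixels,
                        resample_side = cfg$hog$resample_side,
                        cell_side = cfg$hog$cell_side,
                        block_side = cfg$hog$block_side,
                        block_stride = cfg$hog$block_stride)
  cs <- cslbp_descriptor(roi$pixels, radius = cfg$cslbp$radius,
                         threshold = cfg$cslbp$threshold,
                         grid = cfg$cslbp$grid)
  shape <- shape_features(mask)
  rec <- dplyr::bind_cols(
    tibble::tibble(ref_id = roi$source_ref, mask_area = sum(mask)),
    stat, glcm_f,
    tibble::as_tibble(as.list(hog)),
    tibble::as_tibble(as.list(cs)),
    shape
  )
  attr(rec, "mask") <- mask
  rec
}

#' Run the end-to-end CAD pipeline
#'
#' Orchestrates the full run: images and annotations (from the synthetic
#' phantom generator or a MIAS-style directory) are cropped to ROIs,
#' segmented by region growing, featurised with all requested families, and
#' evaluated with the classifier battery under stratified k-fold
#' cross-validation. Writes `features.csv`, segmentation masks under
#' `masks/`, `report.csv`, `report.json` and `run_metadata.json` (the full
#' configuration plus seed, version and skip log) into the output directory.
#' Failures on individual images are logged and skipped.
#'
#' @param config Configuration list (see [read_pipeline_config()] and the
#'   package vignette); partial lists are completed with defaults. In
#'   `"phantom"` mode `config$phantom$n_benign`/`n_malignant` phantoms are
#'   generated under `out_dir/images` with `config$seed`. In `"mias-dir"`
#'   mode `config$mias$image_dir` and `config$mias$info_file` name the
#'   inputs.
#' @return An object of class `cad_run`: list with `features` (tibble),
#'   `report` (`cad_eval`), `skipped` (tibble), `config` and `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- merge_config(config)
  say <- function(...) if (isTRUE(cfg$verbose)) message(...)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(cfg$out_dir, "masks"), showWarnings = FALSE)

  if (identical(cfg$mode, "phantom")) {
    say("generating ", cfg$phantom$n_benign, " benign + ",
        cfg$phantom$n_malignant, " malignant phantoms")
    img_dir <- file.path(cfg$out_dir, "images")
    manifest <- generate_dataset(cfg$phantom$n_benign, cfg$phantom$n_malignant,
                                 seed = cfg$seed, out_dir = img_dir)
    records <- tibble::tibble(
      ref_id = sub("\\.png$", "", manifest$filename),
      path = file.path(img_dir, manifest$filename),
      label = manifest$label,
      center_x = manifest$center_col, center_y = manifest$center_row,
      radius = manifest$radius
    )
    origin <- "top-left"
  } else if (identical(cfg$mode, "mias-dir")) {
    if (is.null(cfg$mias$image_dir) || is.null(cfg$mias$info_file)) {
      stop("mias-dir mode requires mias$image_dir and mias$info_file",
           call. = FALSE)
    }
    ann <- parse_mias_info(readLines(cfg$mias$info_file))
    ann <- ann[ann$severity %in% c("benign", "malignant"), , drop = FALSE]
    find_image <- function(ref) {
      for (ext in c(".pgm", ".png")) {
        p <- file.path(cfg$mias$image_dir, paste0(ref, ext))
        if (file.exists(p)) return(p)
      }
      NA_character_
    }
    records <- tibble::tibble(
      ref_id = ann$ref_id,
      path = vapply(ann$ref_id, find_image, character(1L)),
      label = as.integer(ann$severity == "malignant"),
      center_x = ann$center_x, center_y = ann$center_y, radius = ann$radius
    )
    origin <- cfg$mias$origin
  } else {
    stop("unknown pipeline mode: ", cfg$mode, call. = FALSE)
  }
  say("featurizing ", nrow(records), " annotated images")

  feats <- list(); skips <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    row <- tryCatch(
      suppressMessages(featurize_single(rec$path, rec, config = cfg,
                                        origin = origin)),
      error = function(e) conditionMessage(e)
    )
    if (is.null(row) || is.character(row)) {
      reason <- if (is.null(row)) "singleton segmentation" else row
      say("  skipping ", rec$ref_id, ": ", reason)
      skips[[length(skips) + 1L]] <- tibble::tibble(ref_id = rec$ref_id,
                                                    reason = reason)
      next
    }
    mask <- attr(row, "mask")
    write_gray_image(ifelse(mask, 255, 0),
                     file.path(cfg$out_dir, "masks",
                               paste0(rec$ref_id, "_mask.png")))
    attr(row, "mask") <- NULL
    row$label <- rec$label
    feats[[length(feats) + 1L]] <- row
  }
  if (length(feats) == 0L) stop("zero successfully processed images", call. = FALSE)
  features <- dplyr::bind_rows(feats)
  features <- features[, c("ref_id", "label",
                           setdiff(names(features), c("ref_id", "label")))]
  skipped <- if (length(skips)) dplyr::bind_rows(skips) else {
    tibble::tibble(ref_id = character(), reason = character())
  }
  say("featurized ", nrow(features), " ROIs (", nrow(skipped), " skipped)")
  readr::write_csv(features, file.path(cfg$out_dir, "features.csv"))

  cls <- table(features$label)
  if (length(cls) < 2L || cfg$cv$k > min(cls)) {
    stop("cross-validation k (", cfg$cv$k,
         ") exceeds the smallest class count (", min(cls), ")", call. = FALSE)
  }
  say("evaluating ", length(cfg$cv$classifiers), " classifiers, ",
      cfg$cv$k, "-fold CV")
  fams <- cfg$families
  sets <- as.list(fams)
  names(sets) <- fams
  if (length(fams) > 1L) sets$fused <- fams
  report <- evaluate(features, family_sets = sets,
                     classifiers = cfg$cv$classifiers,
                     k = cfg$cv$k, seed = cfg$seed,
                     stratified = cfg$cv$stratified,
                     standardize = cfg$cv$standardize)
  readr::write_csv(report$results, file.path(cfg$out_dir, "report.csv"))
  jsonlite::write_json(report$results, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  meta <- list(
    tool = "mammocad",
    version = as.character(utils::packageVersion("mammocad")),
    config = cfg,
    n_images = nrow(records),
    n_featurized = nrow(features),
    n_skipped = nrow(skipped),
    skipped = skipped
  )
  jsonlite::write_json(meta, file.path(cfg$out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  structure(list(features = features, report = report, skipped = skipped,
                 config = cfg, out_dir = cfg$out_dir),
            class = "cad_run")
}

#' @export
print.cad_run <- function(x, ...) {
  cat("<cad_run> ", nrow(x$features), " ROIs featurized (",
      nrow(x$skipped), " skipped) -> ", x$out_dir, "\n", sep = "")
  print(x$report)
  invisible(x)
}
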