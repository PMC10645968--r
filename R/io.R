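#' Session configuration for batch image processing
#'
#' Bundles the settings of one processing session: the images, the global
#' scale calibration (measured reference-line pixel length and its known
#' physical length, applied to every image of the session), the threshold
#' method, the particle area filter, the output directory and the seed.
#' Round-trips losslessly through a YAML file
#' ([write_session_config()] / [read_session_config()]).
#'
#' @param images Character vector of image paths, or a directory (all
#'   PNG/JPEG/TIFF files inside are taken, sorted).
#' @param scale_px,scale_mm Reference line length in pixels and mm.
#' @param threshold_method `"otsu"`, `"isodata"` or `"fixed"`.
#' @param min_area_mm2 Particle filter (default 2.5 mm^2).
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param full_precision Also write full-precision sidecar CSVs.
#' @param log_file Optional log file path (log always goes to stderr too).
#' @return Object of class `session_config`.
#' @export
session_config <- function(images, scale_px, scale_mm,
                           threshold_method = "otsu", min_area_mm2 = 2.5,
                           out_dir = ".", seed = 1L,
                           full_precision = FALSE, log_file = NULL) {
  if (length(images) == 1L && dir.exists(images))
    images <- sort(list.files(images, pattern = "\\.(png|jpe?g|tiff?)$",
                              ignore.case = TRUE, full.names = TRUE))
  if (length(images) < 1L) stop("no input images")
  if (scale_px <= 0 || scale_mm <= 0) stop("invalid scale")
  threshold_method <- match.arg(threshold_method,
                                c("otsu", "isodata", "fixed"))
  structure(list(images = images, scale_px = scale_px, scale_mm = scale_mm,
                 threshold_method = threshold_method,
                 min_area_mm2 = min_area_mm2, out_dir = out_dir,
                 seed = as.integer(seed),
                 full_precision = isTRUE(full_precision),
                 log_file = log_file),
            class = "session_config")
}

#' @rdname session_config
#' @param config A `session_config`.
#' @param path File path for the YAML serialization.
#' @export
write_session_config <- function(config, path) {
  stopifnot(inherits(config, "session_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname session_config
#' @export
read_session_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(session_config, raw[!vapply(raw, is.null, logical(1))])
}

log_msg <- function(level, ..., log_file = NULL) {
  line <- paste0("[", level, "] ", paste0(..., collapse = ""))
  message(line)
  if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE)
}

#' Read a grain image as a grayscale matrix
#'
#' Reads PNG/JPEG/TIFF; colour images are reduced to BT.601 luminance.
#' Values are in `[0, 1]`, matrix rows are raster lines (row 1 = top).
#'
#' @param path Image file path.
#' @return Numeric matrix.
#' @export
read_grain_image <- function(path) {
  img <- EBImage::readImage(path)
  a <- as.array(img)
  if (length(dim(a)) == 2L) return(t(a))
  # EBImage arrays are x,y(,channel); transpose to row = raster line
  a <- aperm(a, c(2, 1, 3))
  to_grayscale(a)
}

imagej_cols <- c(" " = "grain_id", Label = "label", Area = "area_mm2",
                 Perim. = "perimeter_mm", Circ. = "circularity",
                 Feret = "feret_mm", FeretAngle = "feret_angle_deg",
                 MinFeret = "minferet_mm", Major = "major_mm",
                 Minor = "minor_mm", Angle = "ellipse_angle_deg",
                 AR = "aspect_ratio", Round = "roundness",
                 Solidity = "solidity")

#' Write per-grain measurements as an ImageJ-dialect results CSV
#'
#' Header
#' `" ,Label,Area,Perim.,Circ.,Feret,FeretAngle,MinFeret,Major,Minor,Angle,AR,Round,Solidity"`
#' (units mm / mm^2 after calibration), plus provenance columns `Image`,
#' `SpikeID`, `Row`, `Region`. Numeric values are fixed at 3 decimals so
#' re-runs are byte-identical; set `full_precision` for a `%.15g` sidecar.
#'
#' @param morph A [measure_spike()] result.
#' @param path Output CSV path.
#' @param image,spike_id Provenance strings.
#' @param full_precision Also write `<path>_full.csv` at full precision.
#' @return Invisibly, `path`.
#' @export
write_results_csv <- function(morph, path, image = NA_character_,
                              spike_id = "spike", full_precision = FALSE) {
  build <- function(fmt) {
    num <- function(v) formatC(v, format = "f", digits = 3)
    if (identical(fmt, "full")) num <- function(v) formatC(v, format = "g", digits = 15)
    data.frame(
      ` ` = morph$grain_id,
      Label = paste0(spike_id, "_g", morph$grain_id),
      Area = num(morph$area_mm2), Perim. = num(morph$perimeter_mm),
      Circ. = num(morph$circularity), Feret = num(morph$feret_mm),
      FeretAngle = num(morph$feret_angle_deg),
      MinFeret = num(morph$minferet_mm), Major = num(morph$major_mm),
      Minor = num(morph$minor_mm), Angle = num(morph$ellipse_angle_deg),
      AR = num(morph$aspect_ratio), Round = num(morph$roundness),
      Solidity = num(morph$solidity),
      Image = image, SpikeID = spike_id, Row = morph$row_index,
      Region = ifelse(is.na(morph$region), "", morph$region),
      check.names = FALSE)
  }
  utils::write.csv(build("fixed"), path, row.names = FALSE, quote = FALSE)
  if (full_precision)
    utils::write.csv(build("full"),
                     sub("\\.csv$", "_full.csv", path),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ImageJ-dialect results CSV
#'
#' Tolerant reader for results tables exported by this package or by an
#' ImageJ particle-analysis session: the leading unnamed index column and
#' any optional column may be absent; `Area`, `Perim.`, `Feret` and
#' `MinFeret` are mandatory (units assumed mm / mm^2 from a calibrated
#' session). Enables ISVAD computation on externally produced measurements.
#'
#' @param path CSV path.
#' @return Data frame with this package's column names (`area_mm2`,
#'   `perimeter_mm`, `feret_mm`, `minferet_mm`, plus whichever optional
#'   columns were present). A header-only file gives a zero-row frame with
#'   a warning.
#' @export
read_results_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  nm <- names(raw)
  nm[nm == ""] <- " "
  names(raw) <- nm
  mandatory <- c("Area", "Perim.", "Feret", "MinFeret")
  miss <- setdiff(mandatory, nm)
  if (length(miss))
    stop("results CSV is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  keep <- intersect(names(imagej_cols), nm)
  out <- raw[, keep, drop = FALSE]
  names(out) <- imagej_cols[keep]
  for (cl in setdiff(unname(imagej_cols), c("label", "grain_id")))
    if (!is.null(out[[cl]])) out[[cl]] <- as.numeric(out[[cl]])
  if (is.null(out$grain_id)) out$grain_id <- seq_len(nrow(out))
  if (!is.null(raw$Row)) out$row_index <- as.integer(raw$Row)
  if (!is.null(raw$Region)) {
    rg <- as.character(raw$Region)
    rg[rg == ""] <- NA_character_
    out$region <- rg
  }
  if (!is.null(raw$SpikeID)) out$spike_id <- raw$SpikeID
  if (!is.null(raw$Image)) out$image <- raw$Image
  if (nrow(out) == 0L) warning("results CSV has a header but no rows")
  out
}

#' Analyze one spike image end to end
#'
#' [segment_spike()] then [measure_spike()] then [summarize_spike()].
#'
#' @param image Image matrix, or a file path.
#' @param calibration A [set_scale()] calibration.
#' @param min_area_mm2,threshold_method Segmentation settings.
#' @param spike_id Identifier for the summary.
#' @return List with `segmentation`, `morphometrics`, `summary`.
#' @export
analyze_spike <- function(image, calibration, min_area_mm2 = 2.5,
                          threshold_method = "otsu", spike_id = "spike") {
  if (is.character(image)) image <- read_grain_image(image)
  seg <- segment_spike(image, calibration, min_area_mm2 = min_area_mm2,
                       threshold_method = threshold_method)
  if (seg$labeled$n == 0L)
    stop("no grains found above ", min_area_mm2, " mm^2")
  morph <- measure_spike(seg$labeled, seg$layout, calibration)
  list(segmentation = seg, morphometrics = morph,
       summary = summarize_spike(morph, spike_id = spike_id))
}

#' Batch-process a session of spike images
#'
#' Processes every image of the session with the same global calibration:
#' per image an ImageJ-dialect results CSV, plus one combined per-spike
#' ISVAD summary CSV. A failure on an individual image is logged and
#' skipped, not fatal; the returned status records it and `exit_status` is 1
#' when any image failed.
#'
#' @param config A [session_config()].
#' @return Invisibly, a list with `results` (per-image analysis or the
#'   error), `summary` (combined data frame), `summary_csv`, `exit_status`.
#' @export
batch_process <- function(config) {
  stopifnot(inherits(config, "session_config"))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  cal <- set_scale(config$scale_px, config$scale_mm, global = TRUE)
  lf <- config$log_file
  log_msg("info", "session: ", length(config$images), " image(s), ",
          sprintf("%.4g px/mm, threshold %s, min area %.3g mm^2, seed %d",
                  cal$px_per_mm, config$threshold_method,
                  config$min_area_mm2, config$seed), log_file = lf)
  results <- list()
  summaries <- list()
  failed <- 0L
  for (path in config$images) {
    sid <- tools::file_path_sans_ext(basename(path))
    res <- tryCatch({
      a <- analyze_spike(path, cal, min_area_mm2 = config$min_area_mm2,
                         threshold_method = config$threshold_method,
                         spike_id = sid)
      out_csv <- file.path(config$out_dir, paste0(sid, "_results.csv"))
      write_results_csv(a$morphometrics, out_csv, image = basename(path),
                        spike_id = sid,
                        full_precision = config$full_precision)
      log_msg("info", sid, ": ", nrow(a$morphometrics), " grains -> ",
              out_csv, log_file = lf)
      summaries[[sid]] <- as.data.frame(a$summary)
      a
    }, error = function(e) {
      log_msg("error", sid, ": skipped (", conditionMessage(e), ")",
              log_file = lf)
      e
    })
    if (inherits(res, "error")) failed <- failed + 1L
    results[[sid]] <- res
  }
  summary_df <- if (length(summaries)) do.call(rbind, summaries) else NULL
  summary_csv <- file.path(config$out_dir, "isvad_summary.csv")
  if (!is.null(summary_df)) {
    fmt <- summary_df
    numcols <- vapply(fmt, is.numeric, logical(1)) &
      !(names(fmt) %in% c("n_grains", "n_bottom", "n_middle", "n_top"))
    fmt[numcols] <- lapply(fmt[numcols],
                           function(v) formatC(v, format = "f", digits = 3))
    utils::write.csv(fmt, summary_csv, row.names = FALSE, quote = FALSE)
    log_msg("info", "combined summary -> ", summary_csv, log_file = lf)
  }
  invisible(list(results = results, summary = summary_df,
                 summary_csv = summary_csv,
                 exit_status = if (failed > 0L) 1L else 0L))
}
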