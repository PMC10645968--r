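#' Scale calibration from a reference line
#'
#' Converts a measured pixel length of a drawn reference line of known
#' physical length into a pixels-per-millimetre calibration, the unit-bearing
#' substrate of every downstream measurement. Mirrors the set-scale step of a
#' typical image-analysis session; with `global = TRUE` the calibration is
#' meant to apply to every image of the session.
#'
#' @param line_length_px Measured line length in pixels (> 0).
#' @param known_length_mm Physical line length in millimetres (> 0).
#' @param global Whether the calibration applies to a whole session.
#' @return Object of class `scale_calibration` with `px_per_mm`.
#' @examples
#' cal <- set_scale(100, 10)  # 10 px/mm
#' px_to_mm(7, set_scale(1, 1))  # identity scale: 7 mm
#' @export
set_scale <- function(line_length_px, known_length_mm, global = TRUE) {
  if (!is.numeric(line_length_px) || line_length_px <= 0)
    stop("line_length_px must be > 0")
  if (!is.numeric(known_length_mm) || known_length_mm <= 0)
    stop("known_length_mm must be > 0")
  structure(list(line_length_px = line_length_px,
                 known_length_mm = known_length_mm,
                 px_per_mm = line_length_px / known_length_mm,
                 global = isTRUE(global)),
            class = "scale_calibration")
}

#' @rdname set_scale
#' @param px,mm Lengths to convert.
#' @param calibration A `scale_calibration`.
#' @export
px_to_mm <- function(px, calibration) px / calibration$px_per_mm

#' @rdname set_scale
#' @export
mm_to_px <- function(mm, calibration) mm * calibration$px_per_mm

#' @export
print.scale_calibration <- function(x, ...) {
  cat(sprintf("Scale calibration: %.6g px / %.6g mm = %.6g px/mm%s\n",
              x$line_length_px, x$known_length_mm, x$px_per_mm,
              if (x$global) " (global)" else ""))
  invisible(x)
}

# ITU-R BT.601 luminance for color arrays; pass-through for matrices.
to_grayscale <- function(image) {
  if (is.matrix(image)) return(image)
  if (length(dim(image)) == 3L && dim(image)[3L] >= 3L)
    return(0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L])
  if (length(dim(image)) == 3L && dim(image)[3L] == 1L)
    return(image[, , 1L])
  stop("unsupported image layout; expected a matrix or H x W x 3 array")
}

# Iterative intermeans (IsoData) threshold on a 256-bin histogram.
isodata_threshold <- function(x, levels = 256L) {
  h <- tabulate(pmin(levels, floor(x * levels) + 1L), nbins = levels)
  mids <- (seq_len(levels) - 0.5) / levels
  t <- sum(h * mids) / sum(h)
  repeat {
    lo <- mids <= t
    m1 <- sum(h[lo] * mids[lo]) / max(1e-12, sum(h[lo]))
    m2 <- sum(h[!lo] * mids[!lo]) / max(1e-12, sum(h[!lo]))
    t_new <- (m1 + m2) / 2
    if (abs(t_new - t) < 1 / (2 * levels)) break
    t <- t_new
  }
  t_new
}

#' Automatic thresholding to a binary grain mask
#'
#' Recomputes a threshold for each image (per-image auto-threshold) and
#' returns the mask of pixels brighter than it — grains are the bright mode
#' on a dark background. Colour input is first reduced to BT.601 luminance.
#'
#' @param image Numeric matrix in `[0,1]`, or an H x W x 3 colour array.
#' @param method `"otsu"` (default), `"isodata"`, or `"fixed"`.
#' @param fixed_level Threshold used when `method = "fixed"`.
#' @return Logical matrix (`TRUE` = grain), with the threshold attached as
#'   attribute `"threshold"`. A constant image yields an all-`FALSE` mask
#'   with a warning (no bimodality to separate).
#' @export
threshold_binarize <- function(image, method = c("otsu", "isodata", "fixed"),
                               fixed_level = 0.5) {
  method <- match.arg(method)
  m <- to_grayscale(image)
  rng <- range(m)
  if (diff(rng) < 1e-12) {
    warning("constant image: no foreground/background separation; ",
            "returning an empty mask")
    mask <- matrix(FALSE, nrow(m), ncol(m))
    attr(mask, "threshold") <- NA_real_
    return(mask)
  }
  thr <- switch(method,
    otsu = EBImage::otsu(m, range = c(0, 1), levels = 256L),
    isodata = isodata_threshold(m),
    fixed = fixed_level)
  mask <- m > thr
  attr(mask, "threshold") <- thr
  mask
}

# Merge 4-connected labels that touch diagonally -> 8-connected labelling.
merge_diagonal_labels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # (i,j) vs (i+1,j+1)
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]   # (i+1,j) vs (i,j+1)
  pairs <- rbind(
    cbind(a1[a1 > 0 & b1 > 0 & a1 != b1], b1[a1 > 0 & b1 > 0 & a1 != b1]),
    cbind(a2[a2 > 0 & b2 > 0 & a2 != b2], b2[a2 > 0 & b2 > 0 & a2 != b2]))
  if (nrow(pairs) == 0L) return(lab)
  k <- max(lab)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(k), find, integer(1))
  map <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- map[lab[lab > 0]]
  out
}

#' Label grain particles and filter by physical area
#'
#' Finds 8-connected foreground components, fills internal holes, converts
#' pixel counts to mm^2 via the calibration, removes components smaller than
#' `min_area_mm2` (default 2.5 mm^2, excluding non-grain debris), and
#' renumbers the survivors consecutively.
#'
#' @param mask Logical or 0/1 matrix.
#' @param calibration A [set_scale()] calibration.
#' @param min_area_mm2 Minimum particle area in mm^2 (default 2.5).
#' @param fill_holes Fill internal holes before measuring (default TRUE).
#' @return Object of class `labeled_grains`: list with `labels` (integer
#'   matrix, 0 = background), `n`, `px_count`, `area_mm2`, `calibration`,
#'   `min_area_mm2`.
#' @export
label_particles <- function(mask, calibration, min_area_mm2 = 2.5,
                            fill_holes = TRUE) {
  stopifnot(inherits(calibration, "scale_calibration"))
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  if (fill_holes) lab <- EBImage::fillHull(lab)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  lab <- merge_diagonal_labels(lab)
  k <- max(lab)
  if (k == 0L) {
    return(structure(list(labels = lab, n = 0L, px_count = integer(0),
                          area_mm2 = numeric(0), calibration = calibration,
                          min_area_mm2 = min_area_mm2),
                     class = "labeled_grains"))
  }
  px <- tabulate(lab[lab > 0L], nbins = k)
  area <- px / calibration$px_per_mm^2
  keep <- which(area >= min_area_mm2)
  map <- integer(k)
  map[keep] <- seq_along(keep)
  out <- lab
  out[lab > 0L] <- map[lab[lab > 0L]]
  structure(list(labels = out, n = length(keep), px_count = px[keep],
                 area_mm2 = area[keep], calibration = calibration,
                 min_area_mm2 = min_area_mm2),
            class = "labeled_grains")
}

#' @export
print.labeled_grains <- function(x, ...) {
  cat("Labeled grains:", x$n, "particle(s) >=", x$min_area_mm2, "mm^2 at",
      format(x$calibration$px_per_mm), "px/mm\n")
  invisible(x)
}

# Per-label centroids and bounding-box heights (in raster coordinates).
# Labels are assumed consecutive 1..max (true after label_particles).
label_centroids <- function(labels) {
  idx <- which(labels > 0L)
  lb <- labels[idx]
  rr <- (idx - 1L) %% nrow(labels) + 1L
  cc <- (idx - 1L) %/% nrow(labels) + 1L
  n <- tabulate(lb)
  data.frame(label = seq_len(max(lb)),
             centroid_row = rowsum(rr, lb)[, 1] / n,
             centroid_col = rowsum(cc, lb)[, 1] / n,
             height_px = as.numeric(tapply(rr, lb, max) -
                                      tapply(rr, lb, min) + 1L))
}

#' Order grains bottom-left to top-right and assign spike regions
#'
#' Groups grains into spikelet rows by their vertical centroid coordinate
#' (gap-based 1-D clustering: a new row starts where consecutive sorted
#' heights differ by more than half the median grain height), orders rows
#' from the bottom of the image upwards and grains within a row left to
#' right, and numbers them in that order. Rows are then split into
#' bottom/middle/top spike regions (see [region_of_rows()]); with fewer than
#' 3 rows the region is `NA`.
#'
#' Note raster row 1 is the top of the image, so "bottom" corresponds to the
#' maximal pixel-row coordinate.
#'
#' @param labeled A [label_particles()] result with at least one grain.
#' @param rows_hint Optional expected number of rows; a warning is issued if
#'   the recovered row count differs.
#' @return Object of class `spike_layout`: data frame with `grain_id`,
#'   `label` (original label), `row_index` (1 = bottom), `pos_in_row`
#'   (1 = leftmost), `region`, `centroid_x_px`, `centroid_y_px`.
#' @export
order_grains <- function(labeled, rows_hint = NULL) {
  stopifnot(inherits(labeled, "labeled_grains"))
  if (labeled$n < 1L) stop("order_grains needs at least one grain")
  cen <- label_centroids(labeled$labels)
  # vertical coordinate measured from the bottom of the image
  y_up <- nrow(labeled$labels) - cen$centroid_row
  ord <- order(y_up)
  gap <- diff(y_up[ord])
  thr <- max(1, stats::median(cen$height_px) / 2)
  row_of_sorted <- cumsum(c(1L, as.integer(gap > thr)))
  row_index <- integer(nrow(cen))
  row_index[ord] <- row_of_sorted
  n_rows <- max(row_index)
  if (!is.null(rows_hint) && rows_hint != n_rows)
    warning("recovered ", n_rows, " rows but rows_hint = ", rows_hint)
  ord2 <- order(row_index, cen$centroid_col)
  out <- data.frame(
    grain_id = seq_along(ord2),
    label = cen$label[ord2],
    row_index = row_index[ord2],
    centroid_x_px = cen$centroid_col[ord2],
    centroid_y_px = cen$centroid_row[ord2])
  out$pos_in_row <- stats::ave(out$grain_id, out$row_index,
                               FUN = seq_along)
  out$region <- region_of_rows(n_rows)[out$row_index]
  out <- out[, c("grain_id", "label", "row_index", "pos_in_row", "region",
                 "centroid_x_px", "centroid_y_px")]
  class(out) <- c("spike_layout", "data.frame")
  out
}

#' Segment a calibrated image into an ordered spike layout
#'
#' Convenience chain: [threshold_binarize()] then [label_particles()] then
#' [order_grains()].
#'
#' @param image Image matrix (or colour array).
#' @param calibration A [set_scale()] calibration.
#' @param min_area_mm2 Particle filter (default 2.5 mm^2).
#' @param threshold_method Passed to [threshold_binarize()].
#' @param rows_hint Passed to [order_grains()].
#' @return List with `mask`, `labeled`, `layout`.
#' @export
segment_spike <- function(image, calibration, min_area_mm2 = 2.5,
                          threshold_method = "otsu", rows_hint = NULL) {
  mask <- threshold_binarize(image, method = threshold_method)
  labeled <- label_particles(mask, calibration, min_area_mm2 = min_area_mm2)
  layout <- if (labeled$n > 0L) order_grains(labeled, rows_hint = rows_hint)
            else NULL
  list(mask = mask, labeled = labeled, layout = layout)
}
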