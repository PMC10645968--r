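#' Configuration for a synthetic spike-layout grain image
#'
#' Describes one virtual wheat spike whose threshed grains are laid out on a
#' dark background in spikelet order: `n_rows` spikelet rows from the bottom
#' of the spike to the top, `grains_per_row` grains per row (two by default,
#' one per paired floret), with a thin reference scale bar of known physical
#' length at the right margin. Grain length and width are sampled per grain
#' from normal distributions truncated to positive values, so the within-spike
#' standard deviations `sd_length_mm` / `sd_width_mm` directly control the
#' intra-spike variation that downstream ISVAD estimation should recover.
#'
#' Default sizes describe a typical bread-wheat grain (7.0 x 3.5 mm, projected
#' area about 19 mm^2); the default within-spike SDs (0.6 mm length, 0.35 mm
#' width) match mean intra-spike variation reported for unstressed field-grown
#' material.
#'
#' @param n_rows Number of spikelet rows (>= 1).
#' @param grains_per_row Grains laid side by side per row (default 2).
#' @param mean_length_mm,mean_width_mm Mean grain length/width in mm.
#' @param sd_length_mm,sd_width_mm Within-spike SD of length/width in mm.
#' @param region_effects Optional named multiplicative size factors for the
#'   bottom/middle/top thirds of the spike, e.g.
#'   `c(bottom = 1, middle = 1.05, top = 0.9)`. Applied to both axes of every
#'   grain in the region.
#' @param rotation_jitter_deg Half-range (degrees) of the uniform per-grain
#'   rotation about the vertical spike axis.
#' @param px_per_mm Image resolution in pixels per millimetre.
#' @param noise_sd SD of additive Gaussian pixel noise (grayscale units, in
#'   `[0, 1)`), applied after rendering.
#' @param gradient_strength Amplitude of a left-to-right linear illumination
#'   gradient added after rendering (grayscale units).
#' @param spacing_mm Clear spacing between neighbouring grains in mm; must
#'   correspond to at least 3 px at `px_per_mm`.
#' @param scale_bar_mm Physical length of the drawn scale bar (mm).
#' @param speckle_n Number of small sub-threshold debris speckles to scatter
#'   over the background (default 0).
#' @param speckle_max_mm2 Maximum speckle area in mm^2 (default 0.5, well
#'   under the 2.5 mm^2 particle filter).
#' @param background_level,grain_level Background and grain gray levels.
#' @param seed Integer seed; fixed seed gives a bit-identical image and truth
#'   table.
#' @return An object of class `spike_sim_config` (a validated list).
#' @seealso [generate_spike_image()]
#' @export
spike_sim_config <- function(n_rows,
                             grains_per_row = 2,
                             mean_length_mm = 7,
                             mean_width_mm = 3.5,
                             sd_length_mm = 0.6,
                             sd_width_mm = 0.35,
                             region_effects = NULL,
                             rotation_jitter_deg = 5,
                             px_per_mm = 10,
                             noise_sd = 0,
                             gradient_strength = 0,
                             spacing_mm = 2,
                             scale_bar_mm = 20,
                             speckle_n = 0,
                             speckle_max_mm2 = 0.5,
                             background_level = 0.05,
                             grain_level = 0.85,
                             seed = 1L) {
  cfg <- list(
    n_rows = as.integer(n_rows), grains_per_row = as.integer(grains_per_row),
    mean_length_mm = mean_length_mm, mean_width_mm = mean_width_mm,
    sd_length_mm = sd_length_mm, sd_width_mm = sd_width_mm,
    region_effects = region_effects,
    rotation_jitter_deg = rotation_jitter_deg, px_per_mm = px_per_mm,
    noise_sd = noise_sd, gradient_strength = gradient_strength,
    spacing_mm = spacing_mm, scale_bar_mm = scale_bar_mm,
    speckle_n = as.integer(speckle_n), speckle_max_mm2 = speckle_max_mm2,
    background_level = background_level, grain_level = grain_level,
    seed = as.integer(seed))
  validate_spike_sim_config(cfg)
  class(cfg) <- "spike_sim_config"
  cfg
}

validate_spike_sim_config <- function(cfg) {
  stop_bad <- function(what) stop("invalid spike_sim_config: ", what, call. = FALSE)
  if (is.na(cfg$n_rows) || cfg$n_rows < 1L) stop_bad("n_rows must be >= 1")
  if (is.na(cfg$grains_per_row) || cfg$grains_per_row < 1L)
    stop_bad("grains_per_row must be >= 1")
  if (cfg$mean_length_mm <= 0 || cfg$mean_width_mm <= 0)
    stop_bad("mean sizes must be > 0")
  if (cfg$sd_length_mm < 0 || cfg$sd_width_mm < 0)
    stop_bad("size SDs must be >= 0")
  if (cfg$px_per_mm <= 0) stop_bad("px_per_mm must be > 0")
  if (cfg$noise_sd < 0 || cfg$noise_sd >= 1)
    stop_bad("noise_sd must be in [0, 1)")
  if (cfg$spacing_mm <= 0) stop_bad("spacing_mm must be > 0")
  if (cfg$scale_bar_mm <= 0) stop_bad("scale_bar_mm must be > 0")
  if (!is.null(cfg$region_effects)) {
    if (is.null(names(cfg$region_effects)) ||
        !all(names(cfg$region_effects) %in% c("bottom", "middle", "top")))
      stop_bad("region_effects must be named with bottom/middle/top")
    if (any(cfg$region_effects <= 0)) stop_bad("region_effects must be > 0")
  }
  if (cfg$background_level < 0 || cfg$grain_level > 1 ||
      cfg$background_level >= cfg$grain_level)
    stop_bad("need 0 <= background_level < grain_level <= 1")
  invisible(cfg)
}

#' Assign bottom/middle/top regions to spikelet rows
#'
#' The spike is split into three contiguous blocks of rows counted from the
#' bottom: the first `ceiling(r/3)` rows are `bottom`, the last `floor(r/3)`
#' are `top`, and the remainder is `middle` (so middle >= top in size). With
#' fewer than 3 rows the regions are undefined and `NA` is returned, and
#' region-level summaries are reported as missing downstream.
#'
#' @param n_rows Number of spikelet rows.
#' @return Character vector of length `n_rows` with values
#'   `"bottom"`, `"middle"`, `"top"`, or all `NA` when `n_rows < 3`.
#' @export
region_of_rows <- function(n_rows) {
  n_rows <- as.integer(n_rows)
  if (n_rows < 1L) stop("n_rows must be >= 1")
  if (n_rows < 3L) return(rep(NA_character_, n_rows))
  n_bottom <- ceiling(n_rows / 3)
  n_top <- floor(n_rows / 3)
  n_middle <- n_rows - n_bottom - n_top
  rep(c("bottom", "middle", "top"), c(n_bottom, n_middle, n_top))
}

# Evaluate a deterministic expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Sample the per-grain ground truth (no rendering). Rows bottom -> top,
# within a row left -> right; grain_id follows that order.
sample_spike_truth <- function(cfg) {
  n <- cfg$n_rows * cfg$grains_per_row
  row_index <- rep(seq_len(cfg$n_rows), each = cfg$grains_per_row)
  region <- region_of_rows(cfg$n_rows)[row_index]
  L <- rnorm(n, cfg$mean_length_mm, cfg$sd_length_mm)
  W <- rnorm(n, cfg$mean_width_mm, cfg$sd_width_mm)
  # positive sizes: resample anything at or below 10% of its mean
  for (i in seq_len(n)) {
    while (L[i] <= 0.1 * cfg$mean_length_mm)
      L[i] <- rnorm(1, cfg$mean_length_mm, cfg$sd_length_mm)
    while (W[i] <= 0.1 * cfg$mean_width_mm)
      W[i] <- rnorm(1, cfg$mean_width_mm, cfg$sd_width_mm)
  }
  # width must not exceed length: swap the offending pair
  swap <- W > L
  if (any(swap)) {
    tmp <- L[swap]; L[swap] <- W[swap]; W[swap] <- tmp
  }
  if (!is.null(cfg$region_effects) && cfg$n_rows >= 3L) {
    fac <- cfg$region_effects[region]
    fac[is.na(fac)] <- 1
    L <- L * fac
    W <- W * fac
  }
  rot <- runif(n, -cfg$rotation_jitter_deg, cfg$rotation_jitter_deg)
  data.frame(
    grain_id = seq_len(n),
    row_index = row_index,
    region = region,
    true_length_mm = L,
    true_width_mm = W,
    true_area_mm2 = pi * (L / 2) * (W / 2),
    rotation_deg = rot,
    stringsAsFactors = FALSE)
}

#' Sample a spike's ground-truth grain table without rendering
#'
#' Draws the per-grain truth table of a virtual spike (lengths, widths,
#' analytic areas, regions) under the same sampling model as
#' [generate_spike_image()], but skips the raster. Useful for statistic-level
#' simulation studies (e.g. ISVAD recovery over many spikes) where rendering
#' would only add raster noise and run time.
#'
#' @param config A [spike_sim_config()].
#' @return The truth data frame (no centroid columns).
#' @export
simulate_spike_truth <- function(config) {
  validate_spike_sim_config(config)
  with_seed(config$seed, sample_spike_truth(config))
}

#' Render a synthetic spike image with exact per-grain ground truth
#'
#' Draws each grain as an anti-aliased filled ellipse (supersampled 4x then
#' block-averaged) on a dark background, rows ordered from the bottom of the
#' canvas upwards, plus a thin vertical scale bar of known physical length at
#' the right margin. Optionally scatters sub-threshold debris speckles and
#' applies pixel noise / an illumination gradient (see [add_noise()]).
#'
#' The returned truth table records, for every grain, the sampled length and
#' width (full ellipse diameters, mm), the analytic area
#' `pi * (L/2) * (W/2)`, the rotation, and the centroid in pixel coordinates
#' (`x` = column, `y` = row with row 1 at the top of the raster; the bottom of
#' the spike is therefore at maximal `y`).
#'
#' @param config A [spike_sim_config()].
#' @return A list of class `spike_sim` with elements `image` (numeric matrix
#'   in `[0,1]`, rows = raster lines), `truth` (data frame, one row per
#'   grain), `scale_bar` (list with `length_mm`, `length_px` and endpoint
#'   pixel coordinates), `px_per_mm` and `config`.
#' @examples
#' sim <- generate_spike_image(spike_sim_config(n_rows = 5, seed = 42))
#' nrow(sim$truth)  # 10 grains
#' @export
generate_spike_image <- function(config) {
  validate_spike_sim_config(config)
  cfg <- config
  with_seed(cfg$seed, {
    truth <- sample_spike_truth(cfg)
    ppmm <- cfg$px_per_mm

    if (cfg$spacing_mm * ppmm < 3)
      stop("layout-overflow: grain spacing of ", cfg$spacing_mm,
           " mm is under 3 px at ", ppmm, " px/mm; grains could touch",
           call. = FALSE)

    theta <- truth$rotation_deg * pi / 180
    # axis-aligned extent of each rotated ellipse
    ext_w <- truth$true_width_mm * abs(cos(theta)) +
      truth$true_length_mm * abs(sin(theta))
    ext_h <- truth$true_length_mm * abs(cos(theta)) +
      truth$true_width_mm * abs(sin(theta))
    cell_w <- max(ext_w) + cfg$spacing_mm
    cell_h <- max(ext_h) + cfg$spacing_mm
    margin <- cfg$spacing_mm + 1
    scale_margin <- 4  # mm reserved at the right for the scale bar

    width_mm <- 2 * margin + cfg$grains_per_row * cell_w + scale_margin
    height_mm <- 2 * margin + cfg$n_rows * cell_h
    height_mm <- max(height_mm, cfg$scale_bar_mm + 2 * margin)
    nc <- ceiling(width_mm * ppmm)
    nr <- ceiling(height_mm * ppmm)
    img <- matrix(cfg$background_level, nrow = nr, ncol = nc)

    # grain centres: x in mm from left, y in mm from the bottom of the canvas
    col_of <- (truth$grain_id - 1L) %% cfg$grains_per_row + 1L
    cx_mm <- margin + (col_of - 0.5) * cell_w
    cy_mm <- margin + (truth$row_index - 0.5) * cell_h
    cx_px <- cx_mm * ppmm
    cy_px <- nr - cy_mm * ppmm + 1  # raster row coordinate (row 1 = top)

    for (i in seq_len(nrow(truth))) {
      img <- draw_ellipse(img, cx_px[i], cy_px[i],
                          a_px = truth$true_length_mm[i] / 2 * ppmm,
                          b_px = truth$true_width_mm[i] / 2 * ppmm,
                          theta = theta[i],
                          level = cfg$grain_level,
                          background = cfg$background_level)
    }
    truth$centroid_x_px <- cx_px
    truth$centroid_y_px <- cy_px

    # scale bar: thin vertical line of known length at the right margin
    bar_len_px <- round(cfg$scale_bar_mm * ppmm)
    bar_w_px <- max(1L, round(0.1 * ppmm))
    bar_col <- nc - round((scale_margin / 2) * ppmm)
    bar_rows <- (nr - round(margin * ppmm)) - seq_len(bar_len_px) + 1L
    img[bar_rows, bar_col:(bar_col + bar_w_px - 1L)] <- cfg$grain_level
    scale_bar <- list(length_mm = cfg$scale_bar_mm, length_px = bar_len_px,
                      x0 = bar_col, y0 = max(bar_rows),
                      x1 = bar_col, y1 = min(bar_rows))

    if (cfg$speckle_n > 0L)
      img <- scatter_speckles(img, cfg, nr, nc)

    img <- add_noise(img, cfg$noise_sd, cfg$gradient_strength,
                     seed = cfg$seed + 1L)

    structure(list(image = img, truth = truth, scale_bar = scale_bar,
                   px_per_mm = ppmm, config = cfg),
              class = "spike_sim")
  })
}

# Anti-aliased filled ellipse: inside-test on a 4x supersampled grid within
# the bounding box, block-averaged to per-pixel coverage.
draw_ellipse <- function(img, cx, cy, a_px, b_px, theta, level, background) {
  ss <- 4L
  ext <- max(a_px, b_px) + 1
  r0 <- max(1L, floor(cy - ext)); r1 <- min(nrow(img), ceiling(cy + ext))
  c0 <- max(1L, floor(cx - ext)); c1 <- min(ncol(img), ceiling(cx + ext))
  nrr <- r1 - r0 + 1L; ncc <- c1 - c0 + 1L
  off <- (seq_len(ss) - 0.5) / ss - 0.5
  rows_f <- rep(r0:r1, each = ss) + off           # supersampled row centres
  cols_f <- rep(c0:c1, each = ss) + off
  # grain major axis runs along the spike (vertical); theta tilts it
  dy <- outer(rows_f - cy, rep(1, length(cols_f)))
  dx <- outer(rep(1, length(rows_f)), cols_f - cx)
  u <- -dy * cos(theta) + dx * sin(theta)   # along major axis
  v <- dy * sin(theta) + dx * cos(theta)    # along minor axis
  inside <- (u / a_px)^2 + (v / b_px)^2 <= 1
  # average ss x ss blocks -> coverage fraction per pixel
  s1 <- matrix(colSums(matrix(inside, ss)), nrr, ss * ncc)
  cov <- t(matrix(colSums(matrix(t(s1), ss)), ncc, nrr)) / (ss * ss)
  patch <- img[r0:r1, c0:c1]
  val <- background + cov * (level - background)
  img[r0:r1, c0:c1] <- pmax(patch, val)
  img
}

# Scatter small bright debris disks over free background.
scatter_speckles <- function(img, cfg, nr, nc) {
  ppmm <- cfg$px_per_mm
  for (k in seq_len(cfg$speckle_n)) {
    area <- runif(1, 0.05, cfg$speckle_max_mm2)
    r_px <- sqrt(area / pi) * ppmm
    for (try in 1:50) {
      cy <- runif(1, r_px + 2, nr - r_px - 2)
      cx <- runif(1, r_px + 2, nc - r_px - 2)
      rr <- max(1, floor(cy - r_px - 2)):min(nr, ceiling(cy + r_px + 2))
      cc <- max(1, floor(cx - r_px - 2)):min(nc, ceiling(cx + r_px + 2))
      if (all(img[rr, cc] <= cfg$background_level + 1e-9)) {
        img <- draw_ellipse(img, cx, cy, r_px, r_px, 0,
                            cfg$grain_level, cfg$background_level)
        break
      }
    }
  }
  img
}

#' Add pixel noise and an illumination gradient to an image
#'
#' Adds i.i.d. Gaussian noise (SD `noise_sd`) and a linear left-to-right
#' illumination ramp of amplitude `gradient_strength`, then clips to
#' `[0, 1]`. With both set to 0 the input is returned unchanged.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param gradient_strength Gradient amplitude; the ramp runs from
#'   `-gradient_strength/2` at the left edge to `+gradient_strength/2` at the
#'   right edge.
#' @param seed Integer seed for the noise draw.
#' @return Noisy image matrix, same dimensions.
#' @export
add_noise <- function(image, noise_sd, gradient_strength = 0, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (noise_sd == 0 && gradient_strength == 0) return(image)
  out <- image
  if (gradient_strength != 0) {
    ramp <- gradient_strength * ((seq_len(ncol(image)) - 1) /
                                   max(1L, ncol(image) - 1L) - 0.5)
    out <- out + matrix(ramp, nrow = nrow(image), ncol = ncol(image),
                        byrow = TRUE)
  }
  if (noise_sd > 0)
    out <- out + with_seed(seed, matrix(rnorm(length(image), 0, noise_sd),
                                        nrow = nrow(image)))
  matrix(pmin(1, pmax(0, out)), nrow(image), ncol(image))
}

#' @export
print.spike_sim <- function(x, ...) {
  cat("Synthetic spike image:", nrow(x$image), "x", ncol(x$image),
      "px at", x$px_per_mm, "px/mm\n")
  cat("  grains:", nrow(x$truth), "(", x$config$n_rows, "rows x",
      x$config$grains_per_row, ")\n")
  cat("  scale bar:", x$scale_bar$length_mm, "mm =",
      x$scale_bar$length_px, "px\n")
  invisible(x)
}

#' Write a synthetic spike image and its truth table to disk
#'
#' Writes an 8-bit grayscale PNG and a truth CSV
#' (`grain_id,row_index,region,true_length_mm,true_width_mm,true_area_mm2,rotation_deg,centroid_x_px,centroid_y_px`).
#'
#' @param sim A `spike_sim` object.
#' @param out_dir Output directory (created if needed).
#' @param name Basename for the two files.
#' @return Invisibly, the paths written.
#' @export
write_spike_sim <- function(sim, out_dir, name = "spike") {
  stopifnot(inherits(sim, "spike_sim"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  img_path <- file.path(out_dir, paste0(name, ".png"))
  csv_path <- file.path(out_dir, paste0(name, "_truth.csv"))
  EBImage::writeImage(EBImage::Image(t(sim$image)), img_path, bits.per.sample = 8L)
  utils::write.csv(sim$truth, csv_path, row.names = FALSE)
  invisible(c(image = img_path, truth = csv_path))
}
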