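#' Intra-spike variation as standard deviation (ISVAD)
#'
#' The population standard deviation of a grain-size parameter across the
#' grains of one spike (or one spike region):
#' `sigma = sqrt(sum((x_i - mu)^2)) / sqrt(N)`, with divisor `N` rather than
#' `N - 1`. A single grain gives exactly 0.
#'
#' @param values Numeric vector of one trait's per-grain values (length >= 1).
#' @return The ISVAD (population SD), a non-negative scalar.
#' @examples
#' isvad(c(2, 4))        # 1
#' isvad(c(1, 2, 3, 4))  # 1.118034
#' @export
isvad <- function(values) {
  if (length(values) == 0L) stop("isvad needs at least one value")
  if (anyNA(values)) stop("isvad values must not contain NA")
  mu <- mean(values)
  sqrt(sum((values - mu)^2)) / sqrt(length(values))
}

#' Per-spike and per-region ISVAD summary
#'
#' Computes, for one spike, the mean and ISVAD of grain width (MinFeret),
#' length (Feret), area and perimeter — over the whole spike and within the
#' bottom/middle/top spike regions — plus grain count and mean length/width
#' ratio. Region summaries are `NA` when the spike has fewer than 3 rows
#' (regions undefined).
#'
#' @param morph A [measure_spike()] result (or any data frame with columns
#'   `minferet_mm`, `feret_mm`, `area_mm2`, `perimeter_mm` and optionally
#'   `region`).
#' @param spike_id Identifier carried into the summary.
#' @return Object of class `isvad_summary`: list with `spike_id`,
#'   `n_grains`, `mean` and `isvad` (named vectors over
#'   width/length/area/perimeter), `lw_ratio`, and `regions` (data frame
#'   with one row per region or `NULL` when undefined).
#' @export
summarize_spike <- function(morph, spike_id = "spike") {
  stopifnot(nrow(morph) >= 1L)
  traits <- c(width = "minferet_mm", length = "feret_mm",
              area = "area_mm2", perimeter = "perimeter_mm")
  vals <- lapply(traits, function(cl) morph[[cl]])
  mu <- vapply(vals, mean, numeric(1))
  sg <- vapply(vals, isvad, numeric(1))
  lw <- mean(morph$feret_mm / morph$minferet_mm)
  regions <- NULL
  if (!is.null(morph$region) && !anyNA(morph$region)) {
    reg_levels <- c("bottom", "middle", "top")
    regions <- do.call(rbind, lapply(reg_levels, function(rg) {
      sub <- morph[morph$region == rg, , drop = FALSE]
      row <- data.frame(region = rg, n = nrow(sub))
      for (tr in names(traits)) {
        v <- sub[[traits[[tr]]]]
        row[[paste0("mean_", tr)]] <- if (length(v)) mean(v) else NA_real_
        row[[paste0("isvad_", tr)]] <- if (length(v)) isvad(v) else NA_real_
      }
      row
    }))
  }
  structure(list(spike_id = spike_id, n_grains = nrow(morph),
                 mean = mu, isvad = sg, lw_ratio = lw, regions = regions),
            class = "isvad_summary")
}

#' @export
print.isvad_summary <- function(x, ...) {
  cat("ISVAD summary for", x$spike_id, "-", x$n_grains, "grains\n")
  tab <- rbind(mean = x$mean, ISVAD = x$isvad)
  print(round(tab, 4))
  cat("mean length/width ratio:", round(x$lw_ratio, 3), "\n")
  if (is.null(x$regions)) {
    cat("regions: undefined (fewer than 3 spikelet rows)\n")
  } else {
    cat("per-region ISVAD:\n")
    print(x$regions[, c("region", "n", "isvad_width", "isvad_length",
                        "isvad_area", "isvad_perimeter")], row.names = FALSE)
  }
  invisible(x)
}

#' Flatten an ISVAD summary to a one-row data frame
#'
#' Wide layout used by the per-spike summary CSV: whole-spike means and
#' ISVADs, the length/width ratio, then `n`, mean and ISVAD per region with
#' `_bottom` / `_middle` / `_top` suffixes.
#'
#' @param x An `isvad_summary`.
#' @param row.names,optional,... Standard [as.data.frame()] arguments
#'   (ignored).
#' @export
as.data.frame.isvad_summary <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  out <- data.frame(spike_id = x$spike_id, n_grains = x$n_grains)
  for (tr in names(x$mean)) {
    out[[paste0("mean_", tr)]] <- x$mean[[tr]]
    out[[paste0("isvad_", tr)]] <- x$isvad[[tr]]
  }
  out$lw_ratio <- x$lw_ratio
  for (rg in c("bottom", "middle", "top")) {
    rrow <- if (!is.null(x$regions)) x$regions[x$regions$region == rg, ]
            else NULL
    out[[paste0("n_", rg)]] <- if (!is.null(rrow)) rrow$n else NA_integer_
    for (tr in names(x$mean)) {
      out[[paste0("isvad_", tr, "_", rg)]] <-
        if (!is.null(rrow)) rrow[[paste0("isvad_", tr)]] else NA_real_
    }
  }
  out
}

# Round half away from zero (printed-table convention), unlike round()'s
# banker's rounding: round_half_up(6.25, 1) is 6.3. A 9-decimal guard keeps
# values that are exact halves in decimal (but dust below in binary, e.g.
# 100*(0.48-0.45)/0.48) on the half-up side.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  trunc(round(x, 9) * p + sign(x) * 0.5) / p
}

#' Percent decrease of a treatment mean relative to control
#'
#' `100 * (control - treatment) / control`, by default rounded half-up to
#' one decimal — the convention used when reporting percent decreases of
#' shape descriptors under stress (e.g. control circularity 0.72 falling to
#' 0.69 under drought is a 4.2% decrease; roundness 0.48 to 0.44 is 8.3%).
#'
#' @param control_mean Control mean (> 0).
#' @param treatment_mean Treatment mean.
#' @param digits Decimal places for half-up rounding; `NULL` for full
#'   precision.
#' @return Percent decrease (negative for an increase).
#' @examples
#' percent_change(0.72, 0.69)  # 4.2
#' percent_change(0.48, 0.45)  # 6.3 (6.25 rounds half-up)
#' @export
percent_change <- function(control_mean, treatment_mean, digits = 1) {
  if (any(control_mean <= 0)) stop("control_mean must be > 0")
  pc <- 100 * (control_mean - treatment_mean) / control_mean
  if (is.null(digits)) pc else round_half_up(pc, digits)
}

#' Heat susceptibility index (HSI)
#'
#' Stress-tolerance index of Fischer & Maurer (1978):
#' `HSI = (1 - y_stress / y_control) / D`, where the depression
#' `D = 1 - (grand mean under stress) / (grand mean under control)` is the
#' trial-wide mean relative reduction of the trait. `HSI < 1` marks a
#' genotype whose trait is more stable under stress than the trial average.
#'
#' @param y_stress,y_control Genotype trait means under stress and control
#'   (`y_control > 0`).
#' @param depression Trial-wide depression `D` in `(0, 1]`; see
#'   [stress_depression()].
#' @return The HSI value.
#' @examples
#' heat_susceptibility_index(0.025, 0.038, 0.20)  # 1.711
#' @export
heat_susceptibility_index <- function(y_stress, y_control, depression) {
  if (any(y_control <= 0)) stop("y_control must be > 0")
  if (any(depression <= 0) || any(depression > 1))
    stop("depression must be in (0, 1]")
  (1 - y_stress / y_control) / depression
}

#' @rdname heat_susceptibility_index
#' @param stress_grand_mean,control_grand_mean Trial grand means of the
#'   trait under stress and control.
#' @export
stress_depression <- function(stress_grand_mean, control_grand_mean) {
  if (any(control_grand_mean <= 0)) stop("control grand mean must be > 0")
  1 - stress_grand_mean / control_grand_mean
}
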