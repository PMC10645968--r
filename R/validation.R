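#' Calibrate image-derived sizes against caliper reference measurements
#'
#' Ordinary least squares of the reference (caliper) measurements on the
#' image-derived values (Feret for length, MinFeret for width), the
#' regression used to validate image measurement against a vernier caliper.
#'
#' @param observed Reference measurements (response).
#' @param predicted_source Image-derived values (predictor), same length.
#' @return Object of class `calibration_fit`: `slope`, `intercept`,
#'   `r_squared`, `n`, and the underlying `lm` fit.
#' @export
fit_calibration <- function(observed, predicted_source) {
  n <- length(observed)
  if (n < 3L || length(predicted_source) != n)
    stop("need equal-length vectors with n >= 3")
  if (stats::var(predicted_source) < 1e-12)
    stop("zero variance in predicted_source")
  fit <- stats::lm(observed ~ predicted_source)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((observed - mean(observed))^2)
  r2 <- if (sst < 1e-12) 0 else 1 - sse / sst
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n = n, model = fit),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Calibration fit (n = %d): y = %.4f x + %.4f, R^2 = %.3f\n",
              x$n, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' k-fold cross-validation of a simple linear calibration model
#'
#' Seeded random partition of the observations into `k` near-equal folds
#' (shuffle, then contiguous blocks). For each fold a linear model
#' `y ~ x` is fitted to the complement and the fold is predicted; the
#' prediction errors are the absolute error and its square, averaged per
#' fold, and the overall error is the square root of the mean of the
#' per-fold mean squared errors. `k = n` gives leave-one-out CV.
#'
#' @param x,y Predictor and response vectors of equal length.
#' @param k Number of folds, `2 <= k <= n` (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return Object of class `cv_report`: `k`, `folds` (assignment per
#'   observation), `fold_stats` (per-fold `n`, `mae`, `mse`),
#'   `rms` (overall), `predictions` (each observation predicted exactly
#'   once, from the model that excluded it).
#' @export
kfold_cv <- function(x, y, k = 10L, seed = 1L) {
  n <- length(y)
  if (length(x) != n) stop("x and y must have the same length")
  k <- as.integer(k)
  if (k < 2L || k > n) stop("k must satisfy 2 <= k <= n")
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  folds <- integer(n)
  folds[perm] <- rep(seq_len(k), sizes)
  preds <- numeric(n)
  stats_list <- lapply(seq_len(k), function(f) {
    test <- which(folds == f)
    train <- which(folds != f)
    fit <- stats::lm(y ~ x, data = data.frame(x = x[train], y = y[train]))
    p <- stats::predict(fit, newdata = data.frame(x = x[test]))
    preds[test] <<- p
    err <- y[test] - p
    data.frame(fold = f, n = length(test), mae = mean(abs(err)),
               mse = mean(err^2))
  })
  fold_stats <- do.call(rbind, stats_list)
  structure(list(k = k, folds = folds, fold_stats = fold_stats,
                 rms = sqrt(mean(fold_stats$mse)), predictions = preds),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation: overall RMS error %.4g\n",
              x$k, x$rms))
  cat(sprintf("  fold MAE %.4g-%.4g, fold MSE %.4g-%.4g\n",
              min(x$fold_stats$mae), max(x$fold_stats$mae),
              min(x$fold_stats$mse), max(x$fold_stats$mse)))
  invisible(x)
}

check_trial_table <- function(table, trait) {
  need <- c("genotype", "environment", "block", trait)
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(table[[trait]])) stop("trait values must not contain NA")
  for (f in c("genotype", "environment"))
    if (length(unique(table[[f]])) < 2L)
      stop("factor '", f, "' needs at least 2 levels")
  cells <- table(table$genotype, table$environment, table$block)
  if (length(unique(as.vector(cells))) != 1L || any(cells == 0))
    stop("unbalanced design: every genotype x environment x block cell ",
         "must hold the same number of observations")
  invisible(TRUE)
}

#' Split-plot / factorial ANOVA for genotype-by-environment trials
#'
#' Fits the trial analysis of variance for a balanced randomized complete
#' block design with environments as main plots: blocks (replicates) and
#' environments are tested against the block-by-environment (main-plot)
#' error, genotype and the genotype-by-environment interaction against the
#' residual. With a `year` column holding more than one level, year and
#' block are folded into a single replicate factor so environments remain
#' the main plots within years and blocks. A plain two-way factorial mode
#' (`mode = "factorial"`) is also available.
#'
#' @param table Long-format data frame with columns `genotype`,
#'   `environment`, `block`, optionally `year`, and the trait column.
#' @param trait Name of the trait column (default `"value"`).
#' @param mode `"split_plot"` (default) or `"factorial"`.
#' @return Data frame of class `anova_table` with columns `source`, `df`,
#'   `sum_sq`, `mean_sq`, `statistic`, `p_value`; F and p are `NA` for
#'   error strata (and when residual variance is zero).
#' @export
anova_split_plot <- function(table, trait = "value",
                             mode = c("split_plot", "factorial")) {
  mode <- match.arg(mode)
  check_trial_table(table, trait)
  d <- data.frame(
    value = table[[trait]],
    genotype = factor(table$genotype),
    environment = factor(table$environment))
  d$rep <- if (!is.null(table$year) && length(unique(table$year)) > 1L)
    factor(interaction(table$year, table$block, drop = TRUE))
  else factor(table$block)

  if (mode == "split_plot") {
    # strata: rep (blocks), rep:environment (main plots), Within (subplots)
    fit <- stats::aov(value ~ environment * genotype + Error(rep / environment),
                      data = d)
    strata <- summary(fit)
    rows <- list()
    for (s in seq_along(strata)) {
      tab <- strata[[s]][[1]]
      src <- trimws(rownames(tab))
      stratum <- names(strata)[s]
      for (i in seq_len(nrow(tab))) {
        nm <- src[i]
        nm <- if (nm == "Residuals") {
          if (grepl("rep:environment", stratum)) "mainplot_error"
          else if (grepl("rep", stratum)) "block"
          else "residual"
        } else if (nm == "environment:genotype") "genotype:environment"
        else nm
        rows[[length(rows) + 1L]] <- data.frame(
          source = nm, df = tab[i, "Df"], sum_sq = tab[i, "Sum Sq"],
          mean_sq = tab[i, "Mean Sq"],
          statistic = if ("F value" %in% colnames(tab)) tab[i, "F value"]
                      else NA_real_,
          p_value = if ("Pr(>F)" %in% colnames(tab)) tab[i, "Pr(>F)"]
                    else NA_real_)
      }
    }
    out <- do.call(rbind, rows)
  } else {
    fit <- stats::aov(value ~ rep + environment * genotype, data = d)
    tab <- summary(fit)[[1]]
    src <- trimws(rownames(tab))
    src[src == "rep"] <- "block"
    src[src == "environment:genotype"] <- "genotype:environment"
    src[src == "Residuals"] <- "residual"
    out <- data.frame(source = src, df = tab[, "Df"],
                      sum_sq = tab[, "Sum Sq"], mean_sq = tab[, "Mean Sq"],
                      statistic = tab[, "F value"], p_value = tab[, "Pr(>F)"])
  }
  rownames(out) <- NULL
  out$statistic[!is.finite(out$statistic)] <- NA_real_
  out$p_value[!is.finite(out$p_value)] <- NA_real_
  # constant response: SS are numerical dust, F ratios are undefined
  if (sum(out$sum_sq) <= 1e-12 * (mean(d$value)^2 * nrow(d) + 1e-300)) {
    out$statistic <- NA_real_
    out$p_value <- NA_real_
  }
  attr(out, "mode") <- mode
  attr(out, "trait") <- trait
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Duncan's multiple range test with letter display
#'
#' Stepwise multiple comparison of group means after a significant ANOVA.
#' For means spanning `p` ranked positions the critical range is
#' `R_p = q(alpha_p, p, df_error) * sqrt(mse / n)` with the protection
#' levels `alpha_p = 1 - (1 - alpha)^(p - 1)` and `q` the upper studentized
#' range quantile. Two means differ only when their difference exceeds the
#' applicable `R_p` and no wider non-significant range contains them; the
#' letter display is built from the maximal non-significant ranges (means
#' sorted descending, letters from `"a"`).
#'
#' @param means Named vector of group means.
#' @param n_per_group Common per-group replication.
#' @param mse Error mean square from the ANOVA (> 0).
#' @param df_error Error degrees of freedom (>= 1).
#' @param alpha Significance level (default 0.05).
#' @return Data frame of class `dmrt_letters` with `group`, `mean`, `rank`,
#'   `letters` (groups sharing any letter do not differ at `alpha`);
#'   critical ranges are attached as attribute `"critical_ranges"`.
#' @export
dmrt <- function(means, n_per_group, mse, df_error, alpha = 0.05) {
  k <- length(means)
  if (k < 2L) stop("need at least 2 groups")
  if (is.null(names(means))) names(means) <- paste0("g", seq_len(k))
  if (mse <= 0) stop("mse must be > 0")
  if (df_error < 1) stop("df_error must be >= 1")
  if (n_per_group < 1) stop("n_per_group must be >= 1")

  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  se <- sqrt(mse / n_per_group)
  spans <- 2:k
  alpha_p <- 1 - (1 - alpha)^(spans - 1)
  Rp <- c(NA_real_, stats::qtukey(1 - alpha_p, spans, df_error) * se)

  # non-significance of the range [i, j], protected by containment:
  # a range inside a non-significant wider range is never declared
  ns <- matrix(FALSE, k, k)
  diag(ns) <- TRUE
  for (span in k:2) {
    for (i in 1:(k - span + 1)) {
      j <- i + span - 1
      if ((m[i] - m[j]) <= Rp[span] ||
          (i > 1 && ns[i - 1, j]) || (j < k && ns[i, j + 1]))
        ns[i, j] <- ns[j, i] <- TRUE
    }
  }
  # maximal non-significant runs -> letters
  runs <- list()
  for (i in 1:k) {
    j <- max(which(ns[i, i:k])) + i - 1
    if (length(runs) == 0L || runs[[length(runs)]][2] < j)
      runs[[length(runs) + 1L]] <- c(i, j)
  }
  letter_of <- function(r) {
    out <- character(0)
    while (r > 0) { out <- c(letters[(r - 1) %% 26 + 1], out); r <- (r - 1) %/% 26 }
    paste(out, collapse = "")
  }
  lets <- rep("", k)
  for (r in seq_along(runs)) {
    rng <- runs[[r]][1]:runs[[r]][2]
    lets[rng] <- paste0(lets[rng], letter_of(r))
  }
  out <- data.frame(group = names(m), mean = unname(m), rank = seq_len(k),
                    letters = lets, stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "mse") <- mse
  attr(out, "df_error") <- df_error
  attr(out, "critical_ranges") <- Rp
  class(out) <- c("dmrt_letters", "data.frame")
  out
}

#' @export
print.dmrt_letters <- function(x, ...) {
  cat("Duncan's multiple range test (alpha =", attr(x, "alpha"), ")\n")
  df <- as.data.frame(x)
  df$mean <- signif(df$mean, 5)
  print(df, row.names = FALSE)
  cat("Means sharing a letter are not significantly different.\n")
  invisible(x)
}

#' Run DMRT on the genotype means of a trial table
#'
#' Convenience wrapper: computes genotype means from a balanced trial table,
#' pulls the residual mean square and degrees of freedom from
#' [anova_split_plot()], and runs [dmrt()].
#'
#' @inheritParams anova_split_plot
#' @param alpha Significance level.
#' @return A `dmrt_letters` data frame.
#' @export
dmrt_genotypes <- function(table, trait = "value", alpha = 0.05,
                           mode = "split_plot") {
  at <- anova_split_plot(table, trait = trait, mode = mode)
  res <- at[at$source == "residual", ]
  means <- tapply(table[[trait]], table$genotype, mean)
  n_per <- nrow(table) / length(means)
  dmrt(means, n_per_group = n_per, mse = res$mean_sq,
       df_error = res$df, alpha = alpha)
}
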