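test_that("calibration OLS matches the normal-equation oracle", {
  set.seed(11)
  x <- runif(50, 4, 9)
  y <- 1.05 * x - 0.3 + rnorm(50, 0, 0.25)
  fit <- fit_calibration(y, x)
  # closed-form normal equations, computed independently
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit$slope, beta[2], tolerance = 1e-10)
  r2 <- 1 - sum((y - X %*% beta)^2) / sum((y - mean(y))^2)
  expect_equal(fit$r_squared, r2, tolerance = 1e-10)
})

test_that("calibration fit handles exact and degenerate relations", {
  x <- 1:10
  fit <- fit_calibration(x, x)  # y = x exactly
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  fit0 <- fit_calibration(rep(2, 10), x)  # constant response
  expect_equal(fit0$r_squared, 0)
  expect_error(fit_calibration(x, rep(1, 10)), "variance")
  expect_error(fit_calibration(1:2, 1:2), "n >= 3")
})

test_that("cross-validation is exact on noiseless linear data", {
  x <- seq(1, 20, length.out = 40)
  y <- 2 * x + 1
  for (k in c(2, 5, 10, 40)) {
    cv <- kfold_cv(x, y, k = k, seed = 3)
    expect_equal(max(cv$fold_stats$mae), 0, tolerance = 1e-10)
    expect_equal(cv$rms, 0, tolerance = 1e-10)
  }
})

test_that("fold assignment partitions the data and is seed-stable", {
  set.seed(5)
  x <- rnorm(47); y <- 1 + x + rnorm(47)
  cv1 <- kfold_cv(x, y, k = 10, seed = 42)
  cv2 <- kfold_cv(x, y, k = 10, seed = 42)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$fold_stats, cv2$fold_stats)
  expect_equal(sort(unique(cv1$folds)), 1:10)
  expect_equal(as.vector(table(cv1$folds)), rep(c(5, 4), c(7, 3)))
  cv3 <- kfold_cv(x, y, k = 10, seed = 43)
  expect_false(identical(cv1$folds, cv3$folds))
  expect_error(kfold_cv(x, y, k = 1), "k must")
  expect_error(kfold_cv(x, y, k = 48), "k must")
})

test_that("leave-one-out predictions obey the hat-matrix identity", {
  set.seed(7)
  x <- runif(25, 0, 10)
  y <- 3 + 0.8 * x + rnorm(25, 0, 0.5)
  cv <- kfold_cv(x, y, k = 25, seed = 1)
  fit <- lm(y ~ x)
  h <- hatvalues(fit)
  loo_resid <- residuals(fit) / (1 - h)
  expect_equal(unname(y - cv$predictions), unname(loo_resid),
               tolerance = 1e-8)
})

test_that("split-plot ANOVA partitions the total sum of squares", {
  d <- make_trial_table(n_geno = 6, n_env = 3, n_block = 3,
                        geno_sd = 1, env_sd = 1, noise_sd = 0.5, seed = 9)
  at <- anova_split_plot(d)
  expect_equal(sum(at$df), nrow(d) - 1)
  sst <- sum((d$value - mean(d$value))^2)
  expect_equal(sum(at$sum_sq), sst, tolerance = 1e-8 * sst)
  expect_setequal(at$source,
                  c("block", "environment", "mainplot_error", "genotype",
                    "genotype:environment", "residual"))
  # environment tested against the main-plot error, not the residual
  env <- at[at$source == "environment", ]
  mpe <- at[at$source == "mainplot_error", ]
  expect_equal(env$statistic, env$mean_sq / mpe$mean_sq, tolerance = 1e-9)
})

test_that("ANOVA detects an injected genotype effect", {
  d <- make_trial_table(n_geno = 16, n_env = 3, n_block = 3,
                        geno_sd = 3, env_sd = 0.5, noise_sd = 0.3, seed = 13)
  at <- anova_split_plot(d)
  expect_lt(at$p_value[at$source == "genotype"], 0.001)
  # factorial mode agrees on the genotype sum of squares
  af <- anova_split_plot(d, mode = "factorial")
  expect_equal(af$sum_sq[af$source == "genotype"],
               at$sum_sq[at$source == "genotype"], tolerance = 1e-9)
})

test_that("degenerate and malformed trial tables are handled", {
  d <- make_trial_table(n_geno = 3, n_env = 2, n_block = 2)
  d$value <- 5  # all observations equal
  at <- anova_split_plot(d)
  expect_equal(sum(at$sum_sq), 0, tolerance = 1e-12)
  expect_true(all(is.na(at$p_value)))
  expect_error(anova_split_plot(d[-1, ]), "unbalanced")
  d2 <- make_trial_table(); d2$environment <- "C"
  expect_error(anova_split_plot(d2), "at least 2 levels")
  expect_error(anova_split_plot(d[, -4]), "missing column")
})

test_that("multi-year tables fold year into the replicate stratum", {
  d1 <- make_trial_table(n_geno = 5, n_env = 3, n_block = 3, geno_sd = 1,
                         noise_sd = 0.4, seed = 21)
  d1$year <- "2019"
  d2 <- make_trial_table(n_geno = 5, n_env = 3, n_block = 3, geno_sd = 1,
                         noise_sd = 0.4, seed = 22)
  d2$year <- "2020"
  d <- rbind(d1, d2)
  at <- anova_split_plot(d)
  expect_equal(sum(at$df), nrow(d) - 1)
  expect_equal(at$df[at$source == "block"], 5)  # 2 years x 3 blocks - 1
  sst <- sum((d$value - mean(d$value))^2)
  expect_equal(sum(at$sum_sq), sst, tolerance = 1e-8 * sst)
})

test_that("null-simulation p-values are uniform", {
  set.seed(31)
  p <- replicate(500, {
    d <- make_trial_table(n_geno = 4, n_env = 3, n_block = 3,
                          noise_sd = 1, seed = sample.int(1e6, 1))
    at <- anova_split_plot(d)
    at$p_value[at$source == "genotype"]
  })
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})


test_that("letter displays agree with brute-force Duncan decisions", {
  set.seed(41)
  for (case in 1:100) {
    k <- 6
    means <- stats::setNames(rnorm(k, 10, runif(1, 0.2, 3)),
                             paste0("G", 1:k))
    mse <- runif(1, 0.1, 2)
    df <- sample(5:40, 1)
    n <- sample(3:6, 1)
    lt <- dmrt(means, n_per_group = n, mse = mse, df_error = df)
    bf <- duncan_bruteforce(means, n, mse, df)
    share <- function(a, b) {
      la <- strsplit(lt$letters[lt$rank == a], "")[[1]]
      lb <- strsplit(lt$letters[lt$rank == b], "")[[1]]
      length(intersect(la, lb)) > 0
    }
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      expect_identical(!share(i, j), bf$significant[i, j])
    }
  }
})

test_that("trivial letter configurations come out as expected", {
  lt <- dmrt(c(a = 5, b = 5, c = 5), 3, mse = 1, df_error = 10)
  expect_equal(unique(lt$letters), "a")
  # two groups split by far more than any critical range
  lt2 <- dmrt(c(hi = 100, lo = 0), 4, mse = 1, df_error = 10)
  expect_equal(lt2$letters, c("a", "b"))
  expect_equal(lt2$group, c("hi", "lo"))
  expect_error(dmrt(c(a = 1), 3, 1, 10), "2 groups")
  expect_error(dmrt(c(a = 1, b = 2), 3, -1, 10), "mse")
})

test_that("dmrt_genotypes letters an injected separation correctly", {
  d <- make_trial_table(n_geno = 4, n_env = 3, n_block = 3,
                        noise_sd = 0.2, seed = 51)
  d$value <- d$value + c(G1 = 0, G2 = 0.05, G3 = 5, G4 = 10)[d$genotype]
  lt <- dmrt_genotypes(d)
  expect_equal(lt$group[1], "G4")
  expect_equal(lt$letters[lt$group == "G4"], "a")
  expect_equal(lt$letters[lt$group == "G3"], "b")
  # G1 and G2 are indistinguishable: same letter
  expect_equal(lt$letters[lt$group == "G1"], lt$letters[lt$group == "G2"])
})
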