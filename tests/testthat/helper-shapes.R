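# Rasterized reference shapes: pixel-centre inside tests on a padded canvas.

raster_disk <- function(r_px, pad = 5) {
  n <- ceiling(2 * (r_px + pad))
  c0 <- (n + 1) / 2
  outer(seq_len(n), seq_len(n),
        function(i, j) ((i - c0)^2 + (j - c0)^2) <= r_px^2) * 1
}

raster_ellipse <- function(a_px, b_px, theta_deg = 0, pad = 5) {
  ext <- max(a_px, b_px) + pad
  n <- ceiling(2 * ext)
  c0 <- (n + 1) / 2
  th <- theta_deg * pi / 180
  outer(seq_len(n), seq_len(n), function(i, j) {
    dy <- i - c0; dx <- j - c0
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    (u / a_px)^2 + (v / b_px)^2 <= 1
  }) * 1
}

raster_rect <- function(h_px, w_px, pad = 5) {
  m <- matrix(0, h_px + 2 * pad, w_px + 2 * pad)
  m[pad + seq_len(h_px), pad + seq_len(w_px)] <- 1
  m
}

# Ramanujan's closed-form approximation of an ellipse perimeter
ellipse_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

# Measure a single standalone shape mask at a given calibration
measure_mask <- function(mask, px_per_mm = 10) {
  cal <- set_scale(px_per_mm, 1)
  lab <- label_particles(mask, cal, min_area_mm2 = 0)
  lay <- order_grains(lab)
  measure_spike(lab, lay, cal)
}

# Balanced synthetic genotype x environment trial table
make_trial_table <- function(n_geno = 4, n_env = 3, n_block = 3,
                             geno_sd = 0, env_sd = 0, noise_sd = 1,
                             seed = 1) {
  set.seed(seed)
  g_eff <- rnorm(n_geno, 0, geno_sd)
  e_eff <- rnorm(n_env, 0, env_sd)
  d <- expand.grid(genotype = paste0("G", seq_len(n_geno)),
                   environment = c("C", "D", "L")[seq_len(n_env)],
                   block = paste0("B", seq_len(n_block)),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$value <- g_eff[match(d$genotype, unique(d$genotype))] +
    e_eff[match(d$environment, unique(d$environment))] +
    rnorm(nrow(d), 0, noise_sd)
  d
}
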