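test_that("b-value split partitions the scheme at the threshold", {
  parts <- split_b(scheme10, 200)
  expect_equal(scheme10$b_values[parts$low], c(0, 30, 50, 80, 150, 200))
  expect_equal(scheme10$b_values[parts$high], c(400, 600, 800, 1000))
  expect_setequal(c(parts$low, parts$high), seq_along(scheme10$b_values))

  parts80 <- split_b(scheme10, 80)
  expect_equal(scheme10$b_values[parts80$low], c(0, 30, 50, 80))
  expect_equal(scheme10$b_values[parts80$high], c(150, 200, 400, 600, 800, 1000))

  expect_error(split_b(scheme10, 1000), "inside")
  expect_error(split_b(scheme10, 700), "fewer than 3")
})

test_that("high-b log-linear step recovers D and the extrapolated intercept", {
  # exact log-linear data: pure mono-exponential
  cv <- signal_curve(scheme10, exp(-scheme10$b_values * 1.0e-3), normalize = FALSE)
  hb <- fit_high_b_linear(cv)
  expect_equal(hb$D, 1.0e-3, tolerance = 1e-10)
  expect_equal(hb$intercept, 1.0, tolerance = 1e-10)

  # four hand-built collinear log-points with slope -2e-3: OLS is exact
  sch4 <- bvalue_scheme(c(0, 400, 600, 800, 1000))
  cv4 <- signal_curve(sch4, 0.7 * exp(-sch4$b_values * 2e-3), normalize = FALSE)
  hb4 <- fit_high_b_linear(cv4, fit_config(b_threshold = 200))
  expect_equal(hb4$D, 2e-3, tolerance = 1e-12)
  expect_equal(hb4$intercept, 0.7, tolerance = 1e-10)

  # noise-free bi-exponential WD curve: perfusion leakage above b = 400 is
  # negligible, so D comes back within 0.1% and the intercept near 1 - f
  hbw <- fit_high_b_linear(ivim_signal_curve(wd_mono, scheme10))
  expect_equal(hbw$D, 1.48e-3, tolerance = 1e-3)
  expect_equal(hbw$intercept, 0.84, tolerance = 1e-3)

  # an intercept above 1 is clamped and flagged
  rising <- signal_curve(scheme10, 1.2 * exp(-scheme10$b_values * 1e-3),
                         normalize = FALSE)
  expect_true(fit_high_b_linear(rising)$intercept_clamped)
  expect_equal(fit_high_b_linear(rising)$intercept, 1)
})

test_that("segmented fit recovers generating parameters from noise-free curves", {
  # PD means: f within 0.01 absolute, D within 2% (asymptotic bias tolerated)
  fit_pd <- fit_mono_segmented(ivim_signal_curve(pd_mono, scheme10))
  expect_equal(fit_pd$model_tag, "mono")
  expect_lt(abs(fit_pd$params$f - 0.32), 0.01)
  expect_lt(abs(fit_pd$params$D / 1.05e-3 - 1), 0.02)
  expect_lt(abs(fit_pd$params$D_star / 1.25e-2 - 1), 0.05)

  # WD means: D* step within 0.5%
  fit_wd <- fit_mono_segmented(ivim_signal_curve(wd_mono, scheme10))
  expect_lt(abs(fit_wd$params$D / 1.48e-3 - 1), 0.001)
  expect_lt(abs(fit_wd$params$f - 0.16), 0.001)
  expect_lt(abs(fit_wd$params$D_star / 2.65e-2 - 1), 0.005)

  # pure mono-exponential curve: f = 0, D exact, D* flagged
  pure <- signal_curve(scheme10, exp(-scheme10$b_values * 1.3e-3), normalize = FALSE)
  fit0 <- fit_mono_segmented(pure)
  expect_equal(fit0$params$f, 0, tolerance = 1e-9)
  expect_equal(fit0$params$D, 1.3e-3, tolerance = 1e-8)
  expect_true("dstar_not_identifiable" %in% fit0$diagnostics$flags)
})

test_that("fixed-D,f pseudo-diffusion step matches a brute-force grid search", {
  expect_error(fit_dstar_fixed(ivim_signal_curve(wd_mono, scheme10),
                               wd_mono$D, 0), "not identifiable")

  cfg <- fit_config()
  grid <- exp(seq(log(cfg$D_star_bounds[1]), log(cfg$D_star_bounds[2]),
                  length.out = 2000))
  set.seed(7)
  for (i in 1:5) {
    p <- ivim_params(runif(1, 8e-4, 2e-3), runif(1, 8e-3, 5e-2), runif(1, 0.1, 0.4))
    cv <- ivim_signal_curve(p, scheme10)
    rss_grid <- vapply(grid, function(ds) {
      pr <- ivim_params(p$D, ds, p$f)
      sum((ivim_signal(pr, scheme10$b_values) - cv$signal)^2)
    }, numeric(1))
    ds_grid <- grid[which.min(rss_grid)]
    ds_opt <- fit_dstar_fixed(cv, p$D, p$f, cfg)$D_star
    step <- log(grid[2]) - log(grid[1])
    expect_lt(abs(log(ds_opt) - log(ds_grid)), step * 1.5)
  }
})

test_that("full bi-exponential fit recovers noise-free truths exactly", {
  for (p in list(wd_bi, pd_bi, md_mono)) {
    ft <- fit_bi_full(ivim_signal_curve(p, scheme10))
    expect_equal(ft$model_tag, "bi")
    expect_true(ft$converged)
    expect_lt(abs(ft$params$D / p$D - 1), 1e-3)
    expect_lt(abs(ft$params$D_star / p$D_star - 1), 1e-3)
    expect_lt(abs(ft$params$f - p$f), 5e-4)
  }

  # pure mono-exponential input: f collapses to ~0, D recovered
  pure <- signal_curve(scheme10, exp(-scheme10$b_values * 1.1e-3), normalize = FALSE)
  f0 <- fit_bi_full(pure)
  expect_lt(f0$params$f, 0.01)
  expect_equal(f0$params$D, 1.1e-3, tolerance = 1e-3)
})

test_that("both initialization strategies reach the same optimum", {
  set.seed(11)
  for (i in 1:10) {
    p <- ivim_params(runif(1, 7e-4, 2.2e-3), runif(1, 1e-2, 5e-2),
                     runif(1, 0.08, 0.45))
    cv <- ivim_signal_curve(p, scheme10)
    a <- fit_bi_full(cv, fit_config(init_strategy = "segmented-init"))
    b <- fit_bi_full(cv, fit_config(init_strategy = "fixed-init"))
    expect_lt(abs(a$params$D / b$params$D - 1), 1e-3)
    expect_lt(abs(a$params$D_star / b$params$D_star - 1), 1e-3)
    expect_lt(abs(a$params$f - b$params$f), 1e-3)
  }
})

test_that("full fit never increases the residual of its segmented start", {
  set.seed(23)
  for (i in 1:10) {
    p <- ivim_params(runif(1, 7e-4, 2e-3), runif(1, 1e-2, 4e-2), runif(1, 0.1, 0.4))
    noisy <- add_rician_noise(ivim_signal(p, scheme10$b_values), 0.02, scheme10$nex)
    cv <- signal_curve(scheme10, noisy, normalize = TRUE)
    seg <- fit_mono_segmented(cv)
    seg_rss <- sum((ivim_signal(seg$params, scheme10$b_values) - cv$signal)^2)
    full <- fit_bi_full(cv)
    expect_lte(full$rss, seg_rss + 1e-12)
  }
})

test_that("noise-free identifiability holds across the physiological regime", {
  # regime: the perfusion term must actually have decayed above the b
  # threshold (D* >= max(10 D, 1.2e-2) mm^2/s), which is where the
  # asymptotic error bounds of the segmented estimator apply
  set.seed(31)
  for (i in 1:15) {
    D <- runif(1, 6e-4, 2.5e-3)
    Ds <- max(10 * D, 1.2e-2) * runif(1, 1, 3)
    p <- ivim_params(D, Ds, runif(1, 0.05, 0.5))
    cv <- ivim_signal_curve(p, scheme10)
    bi <- fit_bi_full(cv)
    expect_lt(abs(bi$params$D / p$D - 1), 1e-3)
    expect_lt(abs(bi$params$D_star / p$D_star - 1), 1e-3)
    expect_lt(abs(bi$params$f - p$f), 1e-3)
    seg <- fit_mono_segmented(cv)
    expect_lt(abs(seg$params$D / p$D - 1), 0.02)
    expect_lt(abs(seg$params$f - p$f), 0.02 * max(p$f, 0.25))
    expect_lt(abs(seg$params$D_star / p$D_star - 1), 0.05)
  }
})

test_that("estimator error shrinks monotonically with SNR", {
  # Monte-Carlo batches at SNR 20, 50, 100, Inf; RMSE of f under both
  # models must decrease as noise falls
  snrs <- c(20, 50, 100, Inf)
  nrep <- 60
  rmse_f_mono <- rmse_f_bi <- var_ds_mono <- var_ds_bi <- numeric(length(snrs))
  truth <- md_mono
  clean <- ivim_signal(truth, scheme10$b_values)
  for (k in seq_along(snrs)) {
    set.seed(1000 + k)
    sigma <- if (is.infinite(snrs[k])) 0 else 1 / snrs[k]
    fm <- fb <- dsm <- dsb <- numeric(nrep)
    for (r in 1:nrep) {
      cv <- signal_curve(scheme10, add_rician_noise(clean, sigma, scheme10$nex),
                         normalize = TRUE)
      m <- fit_mono_segmented(cv); b <- fit_bi_full(cv)
      fm[r] <- m$params$f; fb[r] <- b$params$f
      dsm[r] <- m$params$D_star; dsb[r] <- b$params$D_star
    }
    rmse_f_mono[k] <- sqrt(mean((fm - truth$f)^2))
    rmse_f_bi[k] <- sqrt(mean((fb - truth$f)^2))
    var_ds_mono[k] <- var(dsm); var_ds_bi[k] <- var(dsb)
  }
  expect_true(all(diff(rmse_f_mono) < 0))
  expect_true(all(diff(rmse_f_bi) < 0))

  # at matched noisy SNR, the segmented D* estimate is at least as variable
  # as the full-fit one on average (known high-variance behavior of D*)
  expect_gte(mean(var_ds_mono[1:3] / var_ds_bi[1:3]), 1)
})

test_that("fit_curves produces the per-ROI parameter table", {
  curves <- list(a = ivim_signal_curve(wd_mono, scheme10),
                 b = ivim_signal_curve(pd_mono, scheme10))
  tab <- fit_curves(curves, model = "both")
  expect_equal(nrow(tab), 4L)
  expect_setequal(tab$model, c("mono", "bi"))
  expect_true(all(tab$rss >= 0))
  mono_a <- tab[tab$roi_id == "a" & tab$model == "mono", ]
  expect_equal(mono_a$D, 1.48e-3, tolerance = 1e-3)
})
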