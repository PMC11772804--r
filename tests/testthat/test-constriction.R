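plateau_linear_trace <- function(d0 = 10, plateau = 4L, n = 16L, rate = 1,
                                 dt = 1) {
  t <- (seq_len(n) - 1) * dt
  d <- pmax(d0 - rate * pmax(t - (plateau - 1) * dt, 0), 0.2)
  diameter_trace(t, d)
}

test_that("trace validation rejects malformed inputs", {
  expect_error(diameter_trace(1:5, rep(1, 5)), "6")
  expect_error(diameter_trace(c(0, 1, 2, 2, 4, 5), rep(1, 6)), "increasing")
  expect_error(diameter_trace(c(0, 1, 2, 3.5, 4, 5), rep(1, 6)), "uniform")
  expect_error(diameter_trace(0:5, c(1, 1, 1, -1, 1, 1)))
})

test_that("onset is the frame before a sustained diameter drop", {
  tr <- plateau_linear_trace(plateau = 4L)
  expect_equal(detect_onset(tr), 4L)
  flat <- diameter_trace(0:9, rep(5, 10))
  expect_error(detect_onset(flat), "no constriction")
  # recovery within one frame on noisy simulated traces
  hits <- 0L
  for (s in 1:50) {
    tr <- generate_constriction_trace(trace_spec(noise_sd_um = 0.02 * 8,
                                                 seed = s))
    t0 <- detect_onset(tr)
    if (abs(t0 - attr(tr, "true_t0_index")) <= 1L) hits <- hits + 1L
  }
  expect_gte(hits, 45L)
})

test_that("normalization pins t0 to 1 and is scale invariant", {
  tr <- plateau_linear_trace()
  t0 <- detect_onset(tr)
  norm <- normalize_trace(tr, t0)
  expect_identical(norm[t0], 1)
  const <- diameter_trace(0:9, rep(4, 10))
  expect_equal(normalize_trace(const, 3L), rep(1, 10))
  scaled <- diameter_trace(tr$t_min, tr$d_um * 3.7)
  expect_equal(normalize_trace(scaled, t0), norm)
})

test_that("a perfectly linear decline is fitted exactly", {
  tr <- plateau_linear_trace(d0 = 10, plateau = 3L, rate = 0.5, n = 20L)
  t0 <- detect_onset(tr)
  fit <- fit_constant_phase(tr, t0)
  expect_equal(fit$beta_um_per_min, -0.5, tolerance = 1e-10)
  expect_equal(fit$rate_um_per_min, 0.5, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_length(fit$window, 4L)
  norm_win <- fit$normalized_trace[fit$window]
  expect_true(all(norm_win >= 0.40 & norm_win <= 0.80))
})

test_that("noise-only band and too-short traces are rejected as specified", {
  # in-band points that are pure noise around a constant fail the R2 gate
  set.seed(7)
  t <- 0:11
  d <- c(10, 10, rep(6, 10) + rnorm(10, 0, 0.3))
  tr <- diameter_trace(t, d)
  expect_error(fit_constant_phase(tr, 2L), "R2 threshold")
  # constant trace never enters the band
  const <- diameter_trace(0:9, rep(5, 10))
  expect_error(fit_constant_phase(const, 3L), "no constant phase")
})

test_that("window OLS agrees with brute-force least squares", {
  set.seed(123)
  for (i in 1:1000) {
    x <- sort(runif(4, 0, 10))
    y <- runif(4, 1, 10)
    o <- ols_bruteforce(x, y)
    m <- lm(y ~ x)
    expect_equal(unname(coef(m)[2]), o$beta, tolerance = 1e-10)
    expect_equal(unname(coef(m)[1]), o$alpha, tolerance = 1e-10)
  }
  # and the full fit pipeline reproduces the brute-force slope on real windows
  for (s in 1:25) {
    tr <- generate_constriction_trace(trace_spec(noise_sd_um = 0.1, seed = s))
    t0 <- detect_onset(tr)
    fit <- fit_constant_phase(tr, t0)
    o <- ols_bruteforce(tr$t_min[fit$window], tr$d_um[fit$window])
    expect_equal(fit$beta_um_per_min, o$beta, tolerance = 1e-10)
    expect_equal(fit$r2, o$r2, tolerance = 1e-10)
  }
})

test_that("rate estimates are unit-coherent and shift invariant", {
  tr <- generate_constriction_trace(trace_spec(noise_sd_um = 0.1, seed = 4))
  t0 <- detect_onset(tr)
  fit <- fit_constant_phase(tr, t0)
  # time shift changes alpha, not beta
  shifted <- diameter_trace(tr$t_min + 100, tr$d_um)
  fs <- fit_constant_phase(shifted, t0)
  expect_equal(fs$beta_um_per_min, fit$beta_um_per_min, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(fs$alpha_um, fit$alpha_um)))
  # scaling diameters scales beta exactly
  scaled <- diameter_trace(tr$t_min, tr$d_um * 2.5)
  fc <- fit_constant_phase(scaled, t0)
  expect_equal(fc$beta_um_per_min, fit$beta_um_per_min * 2.5,
               tolerance = 1e-9)
})

test_that("rate recovery over a simulated cohort is nearly unbiased", {
  # At 2% noise the R^2 > 0.95 gate rejects a noise-unlucky minority of traces
  # (simulated long-run success ~92%); the estimate itself is nearly unbiased.
  rates <- numeric(0); fitted <- 0L
  for (s in 1:100) {
    tr <- generate_constriction_trace(trace_spec(rate_um_per_min = 0.6,
                                                 noise_sd_um = 0.02 * 8,
                                                 seed = s))
    res <- tryCatch({
      t0 <- detect_onset(tr)
      fit_constant_phase(tr, t0)
    }, error = function(e) NULL)
    if (is.null(res)) next
    fitted <- fitted + 1L
    rates <- c(rates, res$rate_um_per_min)
    nw <- res$normalized_trace[res$window]
    expect_true(all(nw >= 0.40 & nw <= 0.80))
    expect_gt(res$r2, 0.95)
  }
  expect_gte(fitted, 88L)
  expect_lt(abs(mean(rates) - 0.6) / 0.6, 0.05)
})

test_that("mean +/- SD aggregation over aligned traces", {
  # identical traces: SD 0 everywhere
  tr <- rep(list(c(1, 0.9, 0.8, 0.7)), 3)
  m <- mean_trace_with_sd(tr, dt_min = 1)
  expect_equal(m$sd, rep(0, 4))
  expect_equal(m$mean, c(1, 0.9, 0.8, 0.7))
  # mirrored pair averages to the common centre
  m2 <- mean_trace_with_sd(list(c(1, 0.8, 0.6), c(1, 1.0, 1.0)), dt_min = 1.5)
  expect_equal(m2$mean, c(1, 0.9, 0.8))
  expect_equal(m2$t_min, c(0, 1.5, 3))
  # single trace at a timepoint: SD missing
  m3 <- mean_trace_with_sd(list(c(1, 0.9, 0.8), c(1, 0.9)), dt_min = 1)
  expect_true(is.na(m3$sd[3]))
  expect_equal(m3$n, c(2L, 2L, 1L))
})

test_that("simulated cohort mean matches the generative model closed form", {
  specs <- lapply(1:40, function(s) trace_spec(noise_sd_um = 0.02 * 8,
                                               seed = s))
  aligned <- lapply(specs, function(sp) {
    tr <- generate_constriction_trace(sp)
    t0 <- attr(tr, "true_t0_index")
    normalize_trace(tr, t0)[t0:nrow(tr)]
  })
  m <- mean_trace_with_sd(aligned, dt_min = 1)
  # analytic normalized mean during the constant phase: 1 - rate * t / d0
  analytic <- pmax(1 - 0.6 * m$t_min / 8, 0.3)
  phase <- m$t_min <= (8 * (1 - 0.3)) / 0.6
  mc_tol <- 3 * 0.02 / sqrt(40) + 0.01
  expect_true(all(abs(m$mean[phase] - analytic[phase]) < mc_tol + 0.02))
})
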