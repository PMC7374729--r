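# A five-point hand-made curve used by the stage-wise unit tests.
toy_curve <- tibble::tibble(
  concentration_M = c(0, 1, 2, 3, 5),
  ellipticity = c(-20, -12.5, -9, -6, -5)
)

test_that("folded fraction normalises ellipticity and flags endpoints", {
  fr <- folded_fraction(toy_curve, theta_folded = -20, theta_unfolded = -5)
  expect_equal(fr$alpha[1], 1) # fully folded endpoint
  expect_equal(fr$alpha[5], 0) # fully unfolded endpoint
  expect_equal(fr$alpha[2], 0.5) # midpoint by symmetry
  expect_false(fr$retained[1])
  expect_false(fr$retained[5])
  expect_true(fr$retained[2])
  expect_equal(nrow(fr), nrow(toy_curve)) # flagged, never dropped
})

test_that("degenerate baselines and transition-free curves are errors", {
  expect_error(
    folded_fraction(toy_curve, theta_folded = -5, theta_unfolded = -5),
    "degenerate baselines"
  )
  flat <- tibble::tibble(
    concentration_M = 0:4,
    ellipticity = rep(-20, 5) # all points fully folded
  )
  expect_error(
    folded_fraction(flat, theta_folded = -20, theta_unfolded = -5),
    "no transition data"
  )
  expect_error(
    analyze_curve(flat, baselines = BASELINES),
    "stage 'folded_fraction'"
  )
})

test_that("curve contract is enforced", {
  expect_error(
    folded_fraction(toy_curve[1:4, ], -20, -5),
    "at least 5 points"
  )
  shuffled <- toy_curve[c(2, 1, 3, 4, 5), ]
  expect_error(folded_fraction(shuffled, -20, -5), "strictly increasing")
})

test_that("folding constant is alpha/(1 - alpha) and guards its domain", {
  fr <- tibble::tibble(
    alpha = c(0.5, 0.9, 0.25),
    retained = TRUE
  )
  expect_equal(folding_constant(fr)$K, c(1, 9, 1 / 3))
  bad <- tibble::tibble(alpha = c(0.5, 1), retained = c(TRUE, TRUE))
  expect_error(folding_constant(bad), "offending point\\(s\\): 2")
})

test_that("point-wise free energy is -RT log K in kcal/mol", {
  series <- tibble::tibble(K = c(1, 9, exp(-1)), retained = TRUE)
  fe <- free_energy(series, temperature_K = 298.15)
  expect_equal(fe$dG[1], 0)
  expect_equal(fe$dG[2], -1.30182, tolerance = 1e-5)
  expect_equal(fe$dG[3], 0.5924837, tolerance = 1e-6) # equals RT
  expect_error(
    free_energy(tibble::tibble(K = c(1, -2), retained = TRUE)),
    "positive"
  )
})

test_that("fit_lem solves collinear points exactly", {
  pts <- tibble::tibble(
    concentration_M = c(1, 2, 3),
    dG = c(-3.6, -1.9, -0.2)
  )
  fit <- fit_lem(pts, sample_id = "collinear")
  expect_equal(fit$dg0, -5.3)
  expect_equal(fit$m_value, 1.7)
  expect_equal(fit$c_half, 5.3 / 1.7)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n_points_used, 3L)
  # the fitted line crosses zero free energy exactly at the midpoint
  expect_equal(fit$dg0 + fit$m_value * fit$c_half, 0)
})

test_that("fit_lem enforces its data requirements and flags bad slopes", {
  expect_error(
    fit_lem(tibble::tibble(concentration_M = c(1, 2), dG = c(-1, 0))),
    "insufficient data"
  )
  narrow <- tibble::tibble(
    concentration_M = c(1, 1.05, 1.1),
    dG = c(-1, -0.9, -0.8)
  )
  expect_error(fit_lem(narrow), "span")
  decreasing <- tibble::tibble(
    concentration_M = c(1, 2, 3),
    dG = c(0, -1, -2.1)
  )
  expect_warning(fit <- fit_lem(decreasing), "non-positive")
  expect_true(fit$noncooperative)
})

test_that("fit_lem agrees with an independent closed-form OLS oracle", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    x <- sort(runif(n, 0, 5))
    y <- -4 + 1.3 * x + rnorm(n, sd = 0.3)
    fit <- fit_lem(tibble::tibble(concentration_M = x, dG = y))
    oracle <- ols_oracle(x, y)
    expect_equal(fit$dg0, oracle$intercept)
    expect_equal(fit$m_value, oracle$slope)
    expect_equal(fit$dg0_se, oracle$se_intercept)
    expect_equal(fit$m_se, oracle$se_slope)
  }
})

test_that("noiseless curves from the measured panel round-trip exactly", {
  wt <- sim_fit(-5.3, 1.7, "WT")
  expect_equal(wt$dg0, -5.3, tolerance = 1e-6)
  expect_equal(wt$m_value, 1.7, tolerance = 1e-6)
  # derived midpoint: the printed 3.0 M is close but the derived value is
  # what -dg0/m actually gives
  expect_equal(wt$c_half, 5.3 / 1.7, tolerance = 1e-6)

  c807y <- sim_fit(-2.2, 1.1, "C807Y")
  expect_equal(c807y$dg0, -2.2, tolerance = 1e-6)
  expect_equal(c807y$m_value, 1.1, tolerance = 1e-6)

  w752r <- sim_fit(-1.7, 0.9, "W752R")
  expect_equal(round(w752r$c_half, 1), 1.9)
})

test_that("noisy replicate curves recover dg0 on average", {
  # at 2% noise the log-transform is biased near the baselines, so noisy
  # data is analysed with the transition-only window (see vignette)
  truth <- -4.2
  span <- abs(BASELINES$theta_folded - BASELINES$theta_unfolded)
  dg0s <- vapply(1:50, function(i) {
    sim_fit(truth, 1.5,
      noise_sd = 0.02 * span, seed = 1000 + i,
      window = c(0.1, 0.9)
    )$dg0
  }, 0)
  expect_lt(abs(mean(dg0s) - truth), 0.15)
})

test_that("relative ddG is antisymmetric and additive", {
  a <- sim_fit(-5.3, 1.7, "A")
  b <- sim_fit(-3.0, 1.3, "B")
  c <- sim_fit(-1.5, 0.6, "C")
  expect_equal(ddg_relative(b, a)$ddg_experimental, 2.3, tolerance = 1e-6)
  expect_equal(
    ddg_relative(a, b)$ddg_experimental,
    -ddg_relative(b, a)$ddg_experimental
  )
  expect_equal(ddg_relative(a, a)$ddg_experimental, 0)
  expect_equal(
    ddg_relative(a, b)$ddg_experimental + ddg_relative(b, c)$ddg_experimental,
    ddg_relative(a, c)$ddg_experimental
  )
})

test_that("analyze_curve emits a complete per-point audit table", {
  fit <- sim_fit(-5.3, 1.7, "WT")
  aud <- fit$audit
  expect_true(all(c(
    "concentration_M", "ellipticity", "alpha", "K", "dG", "retained"
  ) %in% names(aud)))
  expect_equal(nrow(aud), 21) # every input point, retained or not
  expect_equal(sum(aud$retained), fit$n_points_used)
})

test_that("baselines are estimated from the curve ends when not supplied", {
  curve <- simulate_curve(-5.3, 1.7, theta_folded = -20, theta_unfolded = -5)
  est <- estimate_baselines(curve)
  # at 0-0.25 M a dg0 = -5.3 protein is essentially fully folded
  expect_equal(est$theta_folded, -20, tolerance = 0.01)
  # the 5 M point is not perfectly unfolded for a dg0 = -5.3 protein, so
  # the estimated unfolded baseline carries a small systematic offset
  expect_equal(est$theta_unfolded, -5, tolerance = 0.02)
  fit <- analyze_curve(curve)
  expect_equal(fit$dg0, -5.3, tolerance = 0.05)
})

test_that("tidy and glance views expose the fitted parameters", {
  fit <- sim_fit(-5.3, 1.7, "WT")
  td <- tidy(fit)
  expect_equal(td$term, c("dg0", "m_value"))
  expect_equal(td$estimate, c(fit$dg0, fit$m_value))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$c_half, fit$c_half)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("curve CSV round-trips through read_curve_csv", {
  path <- withr::local_tempfile(fileext = ".csv")
  curve <- simulate_curve(-3, 1.2, sample_id = "x")
  readr::write_csv(curve[c("concentration_M", "ellipticity")], path)
  back <- read_curve_csv(path, sample_id = "x")
  expect_equal(back$ellipticity, curve$ellipticity)
  expect_error(read_curve_csv("/nonexistent/curve.csv"), "not found")
})
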