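# Shared fixtures and independent oracles for the suite.

# True baselines used throughout for simulated curves.
BASELINES <- list(theta_folded = -20, theta_unfolded = -5)

# Measured AR-LBD panel parameters (packaged fixture).
panel <- ar_lbd_reference()

sim_fit <- function(dg0, m_value, id = "s", noise_sd = 0, seed = NULL,
                    window = c(0.02, 0.98), ...) {
  curve <- simulate_curve(
    dg0 = dg0, m_value = m_value,
    theta_folded = BASELINES$theta_folded,
    theta_unfolded = BASELINES$theta_unfolded,
    noise_sd = noise_sd, seed = seed, sample_id = id, ...
  )
  analyze_curve(curve,
    baselines = BASELINES, alpha_window = window,
    sample_id = id
  )
}

# For noiseless synthetic curves every point carries exact free-energy
# information, so the retention window can be fully open; see the methods
# vignette on why noisy data instead needs a transition-only window.
FULL_WINDOW <- c(0, 1)

# Closed-form simple linear regression, written independently of fit_lem.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- sum((y - intercept - slope * x)^2)
  s2 <- rss / (n - 2)
  list(
    intercept = intercept, slope = slope,
    se_intercept = sqrt(s2 * (1 / n + mean(x)^2 / sxx)),
    se_slope = sqrt(s2 / sxx)
  )
}

# Closed-form Welch two-sample statistic and two-sided p-value.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = t, p_value = 2 * pt(-abs(t), df))
}
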