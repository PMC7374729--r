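#' Read a denaturation curve from CSV
#'
#' Reads one chemical-denaturation curve: paired observations of GdmHCl
#' concentration (M) and circular-dichroism ellipticity at 222 nm, one file
#' per sample, header `concentration_M,ellipticity`.
#'
#' @param path Path to a UTF-8 CSV file with columns `concentration_M` and
#'   `ellipticity`.
#' @param sample_id Optional sample label; defaults to the file name without
#'   extension.
#' @return A tibble with columns `sample_id`, `concentration_M`,
#'   `ellipticity`, sorted by concentration.
#' @export
read_curve_csv <- function(path, sample_id = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("curve file not found: %s", path), call. = FALSE)
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("concentration_M", "ellipticity"), arg = path)
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  df |>
    dplyr::transmute(
      sample_id = sample_id,
      concentration_M = as.numeric(.data$concentration_M),
      ellipticity = as.numeric(.data$ellipticity)
    ) |>
    dplyr::arrange(.data$concentration_M)
}

# Validate the curve contract shared by all denaturation operations.
validate_curve <- function(curve, arg = "curve") {
  check_columns(curve, c("concentration_M", "ellipticity"), arg = arg)
  conc <- curve$concentration_M
  if (nrow(curve) < 5) {
    stop(sprintf("`%s` must contain at least 5 points", arg), call. = FALSE)
  }
  if (anyNA(conc) || anyNA(curve$ellipticity)) {
    stop(sprintf("`%s` contains missing values", arg), call. = FALSE)
  }
  if (any(conc < 0)) {
    stop(sprintf("`%s` has negative denaturant concentrations", arg), call. = FALSE)
  }
  if (any(diff(conc) <= 0)) {
    stop(sprintf(
      "`%s` concentrations must be strictly increasing", arg
    ), call. = FALSE)
  }
  invisible(curve)
}

#' Estimate folded/unfolded ellipticity baselines from a curve
#'
#' The fully-unfolded baseline is taken as the mean ellipticity of all points
#' at or above `unfolded_above` M GdmHCl (the protein is assumed fully
#' unfolded in 5 M GdmHCl); the fully-folded baseline as the mean of points
#' at or below `folded_below` M. Both cutoffs are configurable and an
#' explicit user-supplied baseline always overrides this estimate.
#'
#' @param curve Data frame with `concentration_M` and `ellipticity`.
#' @param folded_below Concentration (M) at or below which points are treated
#'   as fully folded. Default 0.25 M.
#' @param unfolded_above Concentration (M) at or above which points are
#'   treated as fully unfolded. Default 5 M.
#' @return A list with `theta_folded` and `theta_unfolded`.
#' @export
estimate_baselines <- function(curve, folded_below = 0.25, unfolded_above = 5) {
  validate_curve(curve)
  folded <- curve$ellipticity[curve$concentration_M <= folded_below]
  unfolded <- curve$ellipticity[curve$concentration_M >= unfolded_above]
  if (length(folded) == 0) {
    stop(sprintf(
      "no points at <= %g M to estimate the folded baseline", folded_below
    ), call. = FALSE)
  }
  if (length(unfolded) == 0) {
    stop(sprintf(
      "no points at >= %g M to estimate the unfolded baseline", unfolded_above
    ), call. = FALSE)
  }
  list(theta_folded = mean(folded), theta_unfolded = mean(unfolded))
}

#' Folded fraction from ellipticity
#'
#' Converts raw ellipticity to the folded fraction
#' \eqn{\alpha_i = (\theta_i - \theta_U) / (\theta_F - \theta_U)}, where
#' \eqn{\theta_F} and \eqn{\theta_U} are the ellipticities of the fully
#' folded and fully unfolded states. Because the normalisation cancels
#' scale, ellipticity may be in any consistent instrument unit.
#'
#' Points whose folded fraction falls outside the retention window
#' (default 0.02–0.98) are flagged `retained = FALSE`, never dropped:
#' \eqn{\ln K} diverges as \eqn{\alpha} approaches 0 or 1, so only
#' transition-region points carry usable free-energy information.
#'
#' @param curve Data frame with `concentration_M` and `ellipticity`.
#' @param theta_folded,theta_unfolded Baseline ellipticities of the fully
#'   folded and fully unfolded states; must differ.
#' @param alpha_min,alpha_max Retention window for the folded fraction.
#' @return The input tibble with added columns `alpha` and `retained`.
#' @examples
#' curve <- simulate_curve(dg0 = -5.3, m_value = 1.7)
#' folded_fraction(curve, theta_folded = -20, theta_unfolded = -5)
#' @export
folded_fraction <- function(curve, theta_folded, theta_unfolded,
                            alpha_min = 0.02, alpha_max = 0.98) {
  validate_curve(curve)
  stopifnot(is.numeric(theta_folded), is.numeric(theta_unfolded))
  if (isTRUE(all.equal(theta_folded, theta_unfolded))) {
    stop("degenerate baselines: theta_folded equals theta_unfolded",
      call. = FALSE
    )
  }
  if (!(alpha_min < alpha_max)) {
    stop("`alpha_min` must be smaller than `alpha_max`", call. = FALSE)
  }
  out <- curve |>
    dplyr::mutate(
      alpha = (.data$ellipticity - theta_unfolded) /
        (theta_folded - theta_unfolded),
      retained = .data$alpha >= alpha_min & .data$alpha <= alpha_max
    )
  if (!any(out$retained)) {
    stop(paste0(
      "no transition data: no point has folded fraction inside [",
      alpha_min, ", ", alpha_max, "]"
    ), call. = FALSE)
  }
  out
}

#' Point-wise folding constant
#'
#' Computes the two-state folding constant \eqn{K_i = \alpha_i /
#' (1 - \alpha_i)} (the folded/unfolded concentration ratio for a monomeric
#' protein) at every retained point.
#'
#' @param fractions Output of [folded_fraction()]: a data frame with
#'   `alpha` and `retained` columns.
#' @return The input tibble with an added column `K` (set to `NA` on
#'   excluded points whose \eqn{\alpha} lies outside (0, 1)).
#' @export
folding_constant <- function(fractions) {
  check_columns(fractions, c("alpha", "retained"), arg = "fractions")
  bad <- which(fractions$retained &
    (fractions$alpha <= 0 | fractions$alpha >= 1))
  if (length(bad) > 0) {
    stop(sprintf(
      "folded fraction must lie strictly in (0, 1) for retained points; offending point(s): %s (alpha = %s)",
      paste(bad, collapse = ", "),
      paste(signif(fractions$alpha[bad], 4), collapse = ", ")
    ), call. = FALSE)
  }
  fractions |>
    dplyr::mutate(
      K = dplyr::if_else(
        .data$alpha > 0 & .data$alpha < 1,
        .data$alpha / (1 - .data$alpha),
        NA_real_
      )
    )
}

#' Point-wise folding free energy
#'
#' Converts folding constants to free energies,
#' \eqn{\Delta G_i = -RT \ln K_i}, in kcal/mol.
#'
#' @param series Output of [folding_constant()]: a data frame with a `K`
#'   column.
#' @param temperature_K Absolute temperature in kelvin. Default 298.15 K
#'   (25 °C, the temperature of the denaturation measurements).
#' @param gas_constant Gas constant, kcal mol⁻¹ K⁻¹.
#' @return The input tibble with an added column `dG` (kcal/mol).
#' @export
free_energy <- function(series, temperature_K = 298.15,
                        gas_constant = .R_KCAL) {
  check_columns(series, "K", arg = "series")
  stopifnot(temperature_K > 0, gas_constant > 0)
  retained <- if ("retained" %in% names(series)) series$retained else TRUE
  bad <- which(retained & (!is.na(series$K) & series$K <= 0))
  if (length(bad) > 0 || any(retained & is.na(series$K))) {
    stop("folding constant must be positive for retained points",
      call. = FALSE
    )
  }
  series |>
    dplyr::mutate(dG = -gas_constant * temperature_K * log(.data$K))
}

#' Fit the linear extrapolation model
#'
#' Ordinary least-squares fit of the point-wise folding free energy on
#' denaturant concentration, \eqn{\Delta G_i = \Delta G_0 + m\,[\mathrm{GdmHCl}]}.
#' The intercept is the folding free energy at zero denaturant
#' (\eqn{\Delta G_0}, kcal/mol), the slope is the m value
#' (kcal mol⁻¹ M⁻¹), and the transition midpoint is
#' \eqn{C_{1/2} = -\Delta G_0 / m}, the concentration at which
#' \eqn{\Delta G = 0}.
#'
#' For a stable, cooperatively unfolding protein \eqn{\Delta G_0 < 0} and
#' \eqn{m > 0}. A non-positive fitted slope is flagged (`noncooperative`)
#' with a warning rather than an error.
#'
#' @param series Data frame with columns `concentration_M` and `dG`
#'   (kcal/mol); a logical `retained` column, if present, selects the points
#'   used.
#' @param sample_id Sample label carried into the fit object.
#' @return An object of class `lem_fit`: a list with elements `sample_id`,
#'   `dg0`, `m_value`, `c_half`, `dg0_se`, `m_se`, `n_points_used`,
#'   `r_squared`, `noncooperative` and the per-point `audit` table.
#'   Use [glance()] / [tidy()] for tibble views.
#' @examples
#' pts <- tibble::tibble(
#'   concentration_M = c(1, 2, 3),
#'   dG = c(-3.6, -1.9, -0.2)
#' )
#' fit <- fit_lem(pts, sample_id = "toy")
#' glance(fit)
#' @export
fit_lem <- function(series, sample_id = NULL) {
  check_columns(series, c("concentration_M", "dG"), arg = "series")
  used <- series
  if ("retained" %in% names(series)) {
    used <- dplyr::filter(series, .data$retained)
  }
  used <- dplyr::filter(used, is.finite(.data$dG))
  if (nrow(used) < 3) {
    stop(sprintf(
      "insufficient data: %d retained point(s); at least 3 are required for the linear extrapolation",
      nrow(used)
    ), call. = FALSE)
  }
  span <- diff(range(used$concentration_M))
  if (span <= 0.2) {
    stop(sprintf(
      "retained points span only %.3g M in denaturant; need > 0.2 M",
      span
    ), call. = FALSE)
  }
  fit <- stats::lm(dG ~ concentration_M, data = used)
  # noiseless synthetic curves fit exactly; that is expected, not suspect
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- sm$coefficients
  dg0 <- unname(co["(Intercept)", "Estimate"])
  m_value <- unname(co["concentration_M", "Estimate"])
  noncoop <- m_value <= 0
  if (noncoop) {
    warning(
      "fitted m value is non-positive: non-cooperative or unstable fit",
      call. = FALSE
    )
  }
  structure(
    list(
      sample_id = sample_id %||%
        (if ("sample_id" %in% names(series)) series$sample_id[1] else "sample"),
      dg0 = dg0,
      m_value = m_value,
      c_half = -dg0 / m_value,
      dg0_se = unname(co["(Intercept)", "Std. Error"]),
      m_se = unname(co["concentration_M", "Std. Error"]),
      n_points_used = nrow(used),
      r_squared = sm$r.squared,
      noncooperative = noncoop,
      audit = tibble::as_tibble(series)
    ),
    class = "lem_fit"
  )
}

#' @export
print.lem_fit <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Two-state LEM fit: %s\n",
      "  dG0     = %.3f +/- %.3f kcal/mol\n",
      "  m value = %.3f +/- %.3f kcal/(mol*M)\n",
      "  C1/2    = %.3f M\n",
      "  points  = %d, R^2 = %.4f%s\n"
    ),
    x$sample_id, x$dg0, x$dg0_se, x$m_value, x$m_se, x$c_half,
    x$n_points_used, x$r_squared,
    if (isTRUE(x$noncooperative)) "  [non-cooperative]" else ""
  ))
  invisible(x)
}

#' Tidy a LEM fit
#'
#' @param x A `lem_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per model parameter (`dg0`, `m_value`) and
#'   columns `term`, `estimate`, `std.error`.
#' @export
tidy.lem_fit <- function(x, ...) {
  tibble::tibble(
    term = c("dg0", "m_value"),
    estimate = c(x$dg0, x$m_value),
    std.error = c(x$dg0_se, x$m_se)
  )
}

#' One-row summary of a LEM fit
#'
#' @param x A `lem_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with the fitted thermodynamic parameters.
#' @export
glance.lem_fit <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_id,
    dg0 = x$dg0,
    dg0_se = x$dg0_se,
    m_value = x$m_value,
    m_se = x$m_se,
    c_half = x$c_half,
    n_points_used = x$n_points_used,
    r_squared = x$r_squared,
    noncooperative = x$noncooperative
  )
}

#' Experimental ddG of a mutant relative to a reference
#'
#' \eqn{\Delta\Delta G = \Delta G_0(\mathrm{mutant}) -
#' \Delta G_0(\mathrm{reference})}; a positive value means the mutant is
#' destabilised, matching the sign convention of FoldX predictions.
#'
#' @param mutant,reference `lem_fit` objects (typically the mutant and the
#'   wild-type sample).
#' @return A one-row tibble with `mutant_id`, `reference_id`,
#'   `ddg_experimental` (kcal/mol) and its propagated standard error
#'   `ddg_se`.
#' @export
ddg_relative <- function(mutant, reference) {
  stopifnot(inherits(mutant, "lem_fit"), inherits(reference, "lem_fit"))
  tibble::tibble(
    mutant_id = mutant$sample_id,
    reference_id = reference$sample_id,
    ddg_experimental = mutant$dg0 - reference$dg0,
    ddg_se = sqrt(mutant$dg0_se^2 + reference$dg0_se^2)
  )
}

#' Analyse one denaturation curve end to end
#'
#' Deterministic composition of the two-state analysis: ellipticity to
#' folded fraction ([folded_fraction()]), folded fraction to folding
#' constant ([folding_constant()]), folding constant to point-wise free
#' energy ([free_energy()]), and linear extrapolation to zero denaturant
#' ([fit_lem()]). The returned fit carries a per-point audit table
#' (concentration, ellipticity, alpha, K, dG, retained flag) so every
#' reported parameter is traceable to the points that produced it.
#'
#' @param curve Data frame with `concentration_M` and `ellipticity`
#'   (optionally `sample_id`).
#' @param baselines Optional list with `theta_folded` and `theta_unfolded`.
#'   When `NULL` they are estimated from the curve ends via
#'   [estimate_baselines()].
#' @param alpha_window Length-2 numeric, the retained folded-fraction range.
#' @param temperature_K,gas_constant Passed to [free_energy()].
#' @param folded_below,unfolded_above Passed to [estimate_baselines()] when
#'   baselines are not supplied.
#' @param sample_id Optional sample label.
#' @return A `lem_fit` object (see [fit_lem()]).
#' @examples
#' curve <- simulate_curve(dg0 = -5.3, m_value = 1.7, sample_id = "WT")
#' fit <- analyze_curve(curve, baselines = list(
#'   theta_folded = -20, theta_unfolded = -5
#' ))
#' glance(fit)
#' @export
analyze_curve <- function(curve, baselines = NULL,
                          alpha_window = c(0.02, 0.98),
                          temperature_K = 298.15, gas_constant = .R_KCAL,
                          folded_below = 0.25, unfolded_above = 5,
                          sample_id = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  validate_curve(curve)
  if (is.null(baselines)) {
    baselines <- stage(
      "baselines",
      estimate_baselines(curve, folded_below, unfolded_above)
    )
  }
  fr <- stage("folded_fraction", folded_fraction(
    curve, baselines$theta_folded, baselines$theta_unfolded,
    alpha_min = alpha_window[1], alpha_max = alpha_window[2]
  ))
  kc <- stage("folding_constant", folding_constant(fr))
  fe <- stage("free_energy", free_energy(kc, temperature_K, gas_constant))
  stage("fit_lem", fit_lem(fe, sample_id = sample_id))
}

#' Plot a fitted linear extrapolation
#'
#' Point-wise folding free energies against GdmHCl concentration with the
#' fitted line; excluded (out-of-transition) points are hollow, and the
#' transition midpoint is marked where the line crosses \eqn{\Delta G = 0}.
#'
#' @param object A `lem_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lem_fit <- function(object, ...) {
  aud <- dplyr::filter(object$audit, is.finite(.data$dG))
  ggplot2::ggplot(aud, ggplot2::aes(.data$concentration_M, .data$dG)) +
    ggplot2::geom_abline(
      intercept = object$dg0, slope = object$m_value,
      linetype = "solid", colour = "steelblue"
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$retained), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::annotate("point",
      x = object$c_half, y = 0,
      shape = 4, size = 3, colour = "firebrick"
    ) +
    ggplot2::labs(
      title = sprintf("Linear extrapolation: %s", object$sample_id),
      x = "[GdmHCl] (M)", y = expression(Delta * G ~ "(kcal/mol)"),
      shape = "retained"
    )
}

#' Plot raw denaturation curves
#'
#' @param curves A data frame with `concentration_M`, `ellipticity` and
#'   optionally `sample_id` (one line per sample).
#' @return A ggplot object.
#' @export
plot_denaturation <- function(curves) {
  check_columns(curves, c("concentration_M", "ellipticity"), arg = "curves")
  if (!"sample_id" %in% names(curves)) curves$sample_id <- "sample"
  ggplot2::ggplot(curves, ggplot2::aes(
    .data$concentration_M, .data$ellipticity,
    colour = .data$sample_id
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(
      x = "[GdmHCl] (M)", y = "Ellipticity at 222 nm (instrument units)",
      colour = "sample"
    )
}
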