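#' Simulate a two-state denaturation curve
#'
#' Forward model of the two-state linear-extrapolation analysis: the folding
#' free energy is linear in denaturant, \eqn{\Delta G(c) = \Delta G_0 + m c};
#' the folding constant is \eqn{K(c) = \exp(-\Delta G(c)/RT)}; the folded
#' fraction \eqn{\alpha(c) = K/(1+K)}; and the observed ellipticity is
#' \eqn{\theta(c) = \theta_U + \alpha(c)(\theta_F - \theta_U)} plus optional
#' homoscedastic Gaussian noise. With `noise_sd = 0` the analysis pipeline
#' recovers `dg0` and `m_value` exactly (to numerical precision) when given
#' the true baselines.
#'
#' @param dg0 Folding free energy at zero denaturant, kcal/mol (negative for
#'   a stable protein).
#' @param m_value Slope of the free energy in denaturant, kcal mol⁻¹ M⁻¹
#'   (positive for cooperative unfolding).
#' @param theta_folded,theta_unfolded Baseline ellipticities (arbitrary
#'   instrument units).
#' @param concentrations Denaturant grid in M; at least 10 points within
#'   0–6 M. Default 0–5 M in 0.25 M steps, mirroring a typical GdmHCl
#'   titration in which 5 M fully unfolds the protein.
#' @param noise_sd Standard deviation of additive Gaussian ellipticity
#'   noise, in the same instrument units as the baselines.
#' @param seed Optional integer; all randomness flows through it and the
#'   global RNG state is left untouched.
#' @param temperature_K,gas_constant Thermodynamic constants used by the
#'   forward model.
#' @param sample_id Sample label stored in the output.
#' @return A tibble with columns `sample_id`, `concentration_M`,
#'   `ellipticity` (plus hidden truth columns `alpha_true`).
#' @examples
#' wt <- simulate_curve(dg0 = -5.3, m_value = 1.7, sample_id = "WT")
#' head(wt)
#' @export
simulate_curve <- function(dg0, m_value,
                           theta_folded = -20, theta_unfolded = -5,
                           concentrations = seq(0, 5, by = 0.25),
                           noise_sd = 0, seed = NULL,
                           temperature_K = 298.15, gas_constant = .R_KCAL,
                           sample_id = "sim") {
  stopifnot(
    is.numeric(dg0), is.numeric(m_value),
    is.numeric(concentrations), noise_sd >= 0,
    temperature_K > 0, gas_constant > 0
  )
  if (length(concentrations) < 10) {
    stop("concentration grid must have at least 10 points", call. = FALSE)
  }
  if (any(concentrations < 0) || any(concentrations > 6)) {
    stop("concentration grid must lie within [0, 6] M", call. = FALSE)
  }
  if (isTRUE(all.equal(theta_folded, theta_unfolded))) {
    stop("theta_folded and theta_unfolded must differ", call. = FALSE)
  }
  conc <- sort(concentrations)
  dG <- dg0 + m_value * conc
  K <- exp(-dG / (gas_constant * temperature_K))
  alpha <- K / (1 + K)
  noise <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(length(conc), sd = noise_sd))
  } else {
    0
  }
  tibble::tibble(
    sample_id = sample_id,
    concentration_M = conc,
    ellipticity = theta_unfolded + alpha * (theta_folded - theta_unfolded) +
      noise,
    alpha_true = alpha
  )
}

# Default per-class ddG (kcal/mol) distributions for simulated catalogs.
# Disease-associated variants centre above 2 kcal/mol, polymorphisms around
# 1 kcal/mol and somatic (tumour) variants slightly below polymorphisms.
default_ddg_params <- function() {
  list(
    disease = list(mean = 2.5, sd = 1.5, truncate_at = -1),
    somatic = list(mean = 0.8, sd = 1.0, truncate_at = NULL),
    polymorphism = list(mean = 1.0, sd = 0.8, truncate_at = NULL)
  )
}

draw_ddg <- function(n, par) {
  if (n == 0) {
    return(numeric(0))
  }
  x <- stats::rnorm(n, par$mean, par$sd)
  if (!is.null(par$truncate_at)) {
    while (any(bad <- x < par$truncate_at)) {
      x[bad] <- stats::rnorm(sum(bad), par$mean, par$sd)
    }
  }
  x
}

#' Simulate three overlapping variant catalogs with class-specific ddG
#'
#' Generates a disease-associated set (HGMD-like), a somatic/tumour set
#' (COSMIC-like) and a population-polymorphism set with exact requested
#' sizes and exact pairwise/triple overlap counts, keyed by
#' (position, ref_aa, alt_aa). Each unique variant receives a predicted
#' ddG drawn from its class distribution (disease taking priority over
#' somatic over polymorphism for shared variants) and a phenotype
#' annotation (AIS severity grades for disease variants, prostate cancer
#' for somatic-only, none for polymorphism-only).
#'
#' @param n_disease,n_somatic,n_polymorphism Catalog sizes. Defaults 337,
#'   323 and 39 match the sizes of the three AR single-residue-variant
#'   extracts the package emulates.
#' @param overlap Named numeric: intersection sizes `disease_somatic`,
#'   `disease_polymorphism`, `somatic_polymorphism` (each inclusive of the
#'   triple) and `all_three`. Checked for feasibility.
#' @param ddg_params Per-class normal ddG parameters; see
#'   `default_ddg_params()` for the defaults.
#' @param phenotype_mix Probabilities of the AIS severity grades assigned to
#'   disease variants.
#' @param positions Integer vector of candidate residue positions. Defaults
#'   to the DBD and LBD intervals of the 920-residue AR reference — the two
#'   domains with crystal structures, hence the ones structure-based ddG
#'   prediction covers.
#' @param seed Optional integer seed; generation is deterministic given it.
#' @return A list of class `catalog_sim` with elements `catalogs` (named
#'   list of three variant tibbles with columns `position`, `ref_aa`,
#'   `alt_aa`, `mutation_class`, `source`, `phenotype`), `ddg` (one row per
#'   unique variant: key columns plus `ddg_pred`, `ddg_class`) and
#'   `combined` (all catalogs stacked).
#' @examples
#' sim <- simulate_catalogs(seed = 1)
#' vapply(sim$catalogs, nrow, integer(1))
#' @export
simulate_catalogs <- function(n_disease = 337, n_somatic = 323,
                              n_polymorphism = 39,
                              overlap = c(
                                disease_somatic = 25,
                                disease_polymorphism = 3,
                                somatic_polymorphism = 3,
                                all_three = 2
                              ),
                              ddg_params = default_ddg_params(),
                              phenotype_mix = c(
                                CAIS = 0.35, PAIS = 0.45, MAIS = 0.20
                              ),
                              positions = c(560:620, 691:920),
                              seed = NULL) {
  need <- c(
    "disease_somatic", "disease_polymorphism",
    "somatic_polymorphism", "all_three"
  )
  if (!all(need %in% names(overlap))) {
    stop(
      "`overlap` must name disease_somatic, disease_polymorphism, somatic_polymorphism and all_three",
      call. = FALSE
    )
  }
  ab <- overlap[["disease_somatic"]]
  ac <- overlap[["disease_polymorphism"]]
  bc <- overlap[["somatic_polymorphism"]]
  abc <- overlap[["all_three"]]
  region <- c(
    abc = abc,
    ab = ab - abc, ac = ac - abc, bc = bc - abc,
    a = n_disease - ab - ac + abc,
    b = n_somatic - ab - bc + abc,
    c = n_polymorphism - ac - bc + abc
  )
  if (any(region < 0)) {
    stop(
      "infeasible overlap specification: some Venn region would be negative",
      call. = FALSE
    )
  }
  n_unique <- sum(region)

  with_seed(seed, {
    # Unique (position, ref, alt) keys; the candidate space is far larger
    # than any realistic request, so rejection sampling terminates fast.
    keys <- tibble::tibble(position = integer(), ref_aa = character(),
                           alt_aa = character())
    while (nrow(keys) < n_unique) {
      m <- n_unique - nrow(keys)
      pos <- sample(positions, m, replace = TRUE)
      ref <- sample(.AA_CODES, m, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(.AA_CODES, r), 1), "")
      keys <- dplyr::distinct(dplyr::bind_rows(
        keys,
        tibble::tibble(position = pos, ref_aa = ref, alt_aa = unname(alt))
      ))
    }
    keys <- keys[sample.int(n_unique), ]
    keys$region <- rep(names(region), region)

    in_a <- keys$region %in% c("a", "ab", "ac", "abc")
    in_b <- keys$region %in% c("b", "ab", "bc", "abc")
    in_c <- keys$region %in% c("c", "ac", "bc", "abc")
    cls <- dplyr::case_when(
      in_a ~ "disease",
      in_b ~ "somatic",
      TRUE ~ "polymorphism"
    )
    ddg <- numeric(n_unique)
    for (k in names(ddg_params)) {
      idx <- which(cls == k)
      ddg[idx] <- draw_ddg(length(idx), ddg_params[[k]])
    }
    phen <- dplyr::case_when(
      in_a ~ NA_character_,
      in_b ~ "prostate_cancer",
      TRUE ~ "none"
    )
    phen[in_a] <- sample(
      names(phenotype_mix), sum(in_a),
      replace = TRUE, prob = phenotype_mix
    )

    base <- keys |>
      dplyr::mutate(
        mutation_class = "missense",
        phenotype = phen,
        ddg_pred = ddg,
        ddg_class = cls
      )
    make_catalog <- function(sel, source) {
      base[sel, ] |>
        dplyr::transmute(
          .data$position, .data$ref_aa, .data$alt_aa, .data$mutation_class,
          source = source, phenotype = .data$phenotype
        ) |>
        dplyr::arrange(.data$position, .data$ref_aa, .data$alt_aa)
    }
    catalogs <- list(
      HGMD = make_catalog(in_a, "HGMD"),
      COSMIC = make_catalog(in_b, "COSMIC"),
      polymorphism = make_catalog(in_c, "polymorphism")
    )
    out <- list(
      catalogs = catalogs,
      ddg = base |>
        dplyr::transmute(
          .data$position, .data$ref_aa, .data$alt_aa,
          ddg_pred = .data$ddg_pred, ddg_class = .data$ddg_class
        ) |>
        dplyr::arrange(.data$position, .data$ref_aa, .data$alt_aa),
      combined = dplyr::bind_rows(catalogs)
    )
    class(out) <- "catalog_sim"
    out
  })
}

#' @export
print.catalog_sim <- function(x, ...) {
  sizes <- vapply(x$catalogs, nrow, integer(1))
  cat("Simulated variant catalogs:\n")
  for (nm in names(sizes)) cat(sprintf("  %-13s %d variants\n", nm, sizes[nm]))
  cat(sprintf("  unique variants: %d\n", nrow(x$ddg)))
  invisible(x)
}
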