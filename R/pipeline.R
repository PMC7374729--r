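#' Load a pipeline run configuration
#'
#' Reads a YAML run configuration and applies overrides. The configuration
#' drives [run_pipeline()]; any value may also be set programmatically by
#' passing a list. Relative paths in the file are resolved against the
#' file's directory.
#'
#' @param config Path to a YAML file, or a list.
#' @param overrides Named list merged over the file values (overrides win);
#'   this is the precedence used by the command-line wrapper, where flags
#'   override the file.
#' @return A list of class `run_config`.
#' @export
load_run_config <- function(config, overrides = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    }
    base_dir <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
    config$.base_dir <- base_dir
  }
  stopifnot(is.list(config))
  for (nm in names(overrides)) config[[nm]] <- overrides[[nm]]
  defaults <- list(
    seed = 1L,
    temperature_K = 298.15,
    gas_constant = .R_KCAL,
    alpha_window = c(0.02, 0.98),
    test = "welch",
    ddg_threshold = 3
  )
  for (nm in names(defaults)) {
    config[[nm]] <- config[[nm]] %||% defaults[[nm]]
  }
  if (config$temperature_K <= 0 || config$gas_constant <= 0) {
    stop("thermodynamic constants must be positive", call. = FALSE)
  }
  class(config) <- c("run_config", "list")
  config
}

resolve_path <- function(path, config) {
  if (is.null(path) || file.exists(path) || is.null(config$.base_dir)) {
    return(path)
  }
  file.path(config$.base_dir, path)
}

pipeline_log <- function(state, stage, event, ...) {
  entry <- list(stage = stage, event = event, ...)
  message(sprintf(
    "[%s] %s%s", stage, event,
    if (length(list(...)) > 0) {
      paste0(" | ", paste(names(list(...)), unlist(list(...)),
        sep = "=", collapse = " "
      ))
    } else {
      ""
    }
  ))
  state$log[[length(state$log) + 1]] <- entry
  state
}

#' Run the full variant-stability analysis pipeline
#'
#' Orchestrates the analysis stages in order: build or load the variant
#' catalogs, obtain predicted ddG values (FoldX Dif files or the simulated
#' table), join predictions onto the catalog, run the configured class-wise
#' comparisons, and (optionally) fit two-state denaturation curves and
#' compute experimental ddG against a reference sample. Every stage logs
#' its inputs, parameters and record counts; any stage error aborts the run
#' with the stage name attached.
#'
#' The configuration (see [load_run_config()]) has blocks:
#' \describe{
#'   \item{catalog}{either `simulate:` (arguments to [simulate_catalogs()])
#'     or `files:` (a list of `{path, source}` entries parsed with
#'     [parse_variant_table()]).}
#'   \item{ddg}{either `simulate: true` (use the simulated ddG table) or
#'     `file:` (a FoldX Dif file parsed with [parse_foldx_dif()]).}
#'   \item{comparisons}{a list of `{a, b}` class pairs contrasted on the
#'     joined ddG values with the configured `test`.}
#'   \item{denaturation}{`curves:` entries, each either `{id, file}` (CSV
#'     read with [read_curve_csv()]) or `{id, dg0, m_value, ...}` (curve
#'     simulated with [simulate_curve()]); plus an optional `reference:` id
#'     for experimental ddG.}
#' }
#'
#' @param config Path to a YAML config, or a list (see [load_run_config()]).
#' @param output_dir Directory for the report bundle; overrides the config
#'   value. `NULL` (and no config value) keeps everything in memory.
#' @return Invisibly, a list with `summary` (the machine-readable summary
#'   also written to `summary.json`), `tables` (catalog, joined, domain
#'   stats, venn, comparisons, fits, ddg_experimental as tibbles), `fits`
#'   (the `lem_fit` objects) and `log`.
#' @examples
#' cfg <- system.file("extdata", "demo_config.yaml", package = "stabscan")
#' res <- run_pipeline(cfg, output_dir = tempfile("stabscan_demo"))
#' res$tables$comparisons
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  config <- load_run_config(config)
  output_dir <- output_dir %||% config$output_dir
  state <- list(log = list())

  # -- validate referenced paths up front ------------------------------
  referenced <- c(
    vapply(
      config$catalog$files %||% list(),
      function(f) resolve_path(f$path, config), ""
    ),
    if (!is.null(config[["ddg"]]$file)) resolve_path(config[["ddg"]]$file, config),
    vapply(
      Filter(function(cu) !is.null(cu$file),
        config$denaturation$curves %||% list()
      ),
      function(cu) resolve_path(cu$file, config), ""
    )
  )
  missing <- referenced[!vapply(referenced, file.exists, TRUE)]
  if (length(missing) > 0) {
    stop(sprintf(
      "stage 'config': input file(s) not found: %s",
      paste(missing, collapse = ", ")
    ), call. = FALSE)
  }

  # -- catalog stage ---------------------------------------------------
  sim <- NULL
  if (!is.null(config$catalog$simulate) || is.null(config$catalog$files)) {
    sim_args <- config$catalog$simulate %||% list()
    if (isTRUE(sim_args)) sim_args <- list()
    if (!is.null(sim_args$overlap)) {
      sim_args$overlap <- unlist(sim_args$overlap)
    }
    sim_args$seed <- sim_args$seed %||% config$seed
    sim <- do.call(simulate_catalogs, sim_args)
    catalog <- sim$combined
    venn <- dataset_overlap(sim$catalogs)
    state <- pipeline_log(state, "catalog", "simulated",
      n_variants = nrow(catalog), seed = sim_args$seed
    )
  } else {
    parts <- purrr::map(config$catalog$files, function(f) {
      tab <- parse_variant_table(
        resolve_path(f$path, config),
        col_map = if (!is.null(f$col_map)) unlist(f$col_map) else NULL
      )
      if (!is.null(f$source)) tab$source <- f$source
      rej <- rejected_variants(tab)
      state <<- pipeline_log(state, "catalog", "parsed",
        path = f$path, accepted = nrow(tab), rejected = nrow(rej)
      )
      tab
    })
    catalog <- dplyr::bind_rows(parts)
    venn <- if (length(parts) == 3) {
      dataset_overlap(stats::setNames(
        parts,
        vapply(config$catalog$files, function(f) {
          f$source %||% basename(f$path)
        }, "")
      ))
    } else {
      NULL
    }
  }
  dstats <- domain_stats(catalog)
  state <- pipeline_log(state, "catalog", "domain_stats",
    domains = nrow(dstats)
  )

  # -- ddG stage -------------------------------------------------------
  if (!is.null(config[["ddg"]]$file)) {
    ddg <- parse_foldx_dif(resolve_path(config[["ddg"]]$file, config))
    state <- pipeline_log(state, "ddg", "parsed",
      path = config[["ddg"]]$file, n = nrow(ddg)
    )
  } else if (!is.null(sim)) {
    ddg <- sim$ddg
    state <- pipeline_log(state, "ddg", "simulated", n = nrow(ddg))
  } else {
    stop("stage 'ddg': no ddg source configured (file or simulate)",
      call. = FALSE
    )
  }
  joined <- join_ddg(catalog, ddg)
  acct <- join_accounting(joined)
  joined$stability_label <- classify_destabilizing(
    joined$ddg_pred,
    threshold = config$ddg_threshold
  )
  state <- pipeline_log(state, "join", "done",
    joined = acct$joined, unmatched = acct$unmatched,
    duplicate = acct$duplicate
  )

  # -- comparison stage ------------------------------------------------
  contrasts <- config$comparisons %||% list(
    list(a = "HGMD", b = "polymorphism"),
    list(a = "COSMIC", b = "polymorphism")
  )
  comparisons <- purrr::map_dfr(contrasts, function(ct) {
    res <- compare_groups(
      joined, .data$ddg_pred, .data$source, ct$a, ct$b,
      method = config$test
    )
    state <<- pipeline_log(state, "compare", "tested",
      a = ct$a, b = ct$b, p = signif(res$p_value, 3)
    )
    res
  })

  # -- denaturation stage ----------------------------------------------
  fits <- list()
  fit_tbl <- NULL
  ddg_exp <- NULL
  curves_cfg <- config$denaturation$curves %||% list()
  if (length(curves_cfg) > 0) {
    fits <- purrr::map(curves_cfg, function(cu) {
      id <- cu$id %||% stop("stage 'denaturation': curve entry without id",
        call. = FALSE
      )
      baselines <- NULL
      if (!is.null(cu$file)) {
        curve <- read_curve_csv(resolve_path(cu$file, config), sample_id = id)
      } else {
        curve <- simulate_curve(
          dg0 = cu$dg0, m_value = cu$m_value,
          theta_folded = cu$theta_folded %||% -20,
          theta_unfolded = cu$theta_unfolded %||% -5,
          noise_sd = cu$noise_sd %||% 0,
          seed = cu$seed %||% config$seed,
          temperature_K = config$temperature_K,
          gas_constant = config$gas_constant,
          sample_id = id
        )
        baselines <- list(
          theta_folded = cu$theta_folded %||% -20,
          theta_unfolded = cu$theta_unfolded %||% -5
        )
      }
      if (!is.null(cu$theta_f) || !is.null(cu$theta_u)) {
        baselines <- list(
          theta_folded = cu$theta_f, theta_unfolded = cu$theta_u
        )
      }
      fit <- analyze_curve(
        curve,
        baselines = baselines,
        alpha_window = as.numeric(config$alpha_window),
        temperature_K = config$temperature_K,
        gas_constant = config$gas_constant,
        sample_id = id
      )
      state <<- pipeline_log(state, "denaturation", "fitted",
        id = id, dg0 = signif(fit$dg0, 4), m = signif(fit$m_value, 4),
        points = fit$n_points_used
      )
      fit
    })
    names(fits) <- vapply(curves_cfg, function(cu) cu$id, "")
    fit_tbl <- purrr::map_dfr(fits, glance)
    ref_id <- config$denaturation$reference
    if (!is.null(ref_id)) {
      if (!ref_id %in% names(fits)) {
        stop(sprintf(
          "stage 'denaturation': reference sample '%s' has no fitted curve",
          ref_id
        ), call. = FALSE)
      }
      ddg_exp <- purrr::map_dfr(
        fits[setdiff(names(fits), ref_id)],
        ddg_relative,
        reference = fits[[ref_id]]
      )
    }
  }

  # -- report bundle ---------------------------------------------------
  summary <- list(
    package = "stabscan",
    seed = config$seed,
    parameters = list(
      temperature_K = config$temperature_K,
      gas_constant = config$gas_constant,
      alpha_window = as.numeric(config$alpha_window),
      test = config$test,
      ddg_threshold = config$ddg_threshold
    ),
    catalog = list(
      n_variants = nrow(catalog),
      domain_stats = dstats,
      venn = if (!is.null(venn)) venn[, c("region", "n")] else NULL
    ),
    join = as.list(acct),
    comparisons = comparisons,
    denaturation = list(
      fits = fit_tbl,
      ddg_experimental = ddg_exp
    )
  )
  tables <- list(
    catalog = catalog, joined = joined, domain_stats = dstats,
    venn = venn, comparisons = comparisons, fits = fit_tbl,
    ddg_experimental = ddg_exp
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      summary,
      file.path(output_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows", null = "null"
    )
    writeLines(
      vapply(state$log, function(e) {
        jsonlite::toJSON(e, auto_unbox = TRUE)
      }, ""),
      file.path(output_dir, "log.jsonl")
    )
    readr::write_tsv(catalog, file.path(output_dir, "catalog.tsv"))
    readr::write_tsv(joined, file.path(output_dir, "joined.tsv"))
    readr::write_tsv(dstats, file.path(output_dir, "domain_stats.tsv"))
    if (!is.null(venn)) {
      jsonlite::write_json(
        stats::setNames(as.list(venn$n), venn$region),
        file.path(output_dir, "venn.json"),
        auto_unbox = TRUE
      )
    }
    readr::write_tsv(comparisons, file.path(output_dir, "comparisons.tsv"))
    if (!is.null(fit_tbl)) {
      readr::write_tsv(fit_tbl, file.path(output_dir, "fits.tsv"))
      for (id in names(fits)) {
        readr::write_tsv(
          fits[[id]]$audit,
          file.path(output_dir, paste0("audit_", id, ".tsv"))
        )
      }
    }
    if (!is.null(ddg_exp)) {
      readr::write_tsv(ddg_exp, file.path(output_dir, "ddg_experimental.tsv"))
    }
    writeLines(render_report(summary), file.path(output_dir, "report.txt"))
    state <- pipeline_log(state, "report", "written", dir = output_dir)
  }

  invisible(list(
    summary = summary, tables = tables, fits = fits, log = state$log
  ))
}

# Plain-text report from the summary list.
render_report <- function(s) {
  lines <- c(
    "stabscan analysis report",
    "========================",
    sprintf("seed: %s", s$seed),
    "",
    sprintf("Catalog: %d variants", s$catalog$n_variants),
    "Per-domain mutation statistics:",
    utils::capture.output(print.data.frame(
      as.data.frame(s$catalog$domain_stats),
      row.names = FALSE
    )),
    ""
  )
  if (!is.null(s$comparisons) && nrow(s$comparisons) > 0) {
    lines <- c(
      lines, "Group comparisons (predicted ddG):",
      utils::capture.output(print.data.frame(
        as.data.frame(s$comparisons)[, c(
          "group_a", "group_b", "n_a", "n_b", "mean_a", "mean_b",
          "test_statistic", "p_value"
        )],
        row.names = FALSE, digits = 4
      )),
      ""
    )
  }
  if (!is.null(s$denaturation$fits)) {
    lines <- c(
      lines, "Two-state denaturation fits:",
      utils::capture.output(print.data.frame(
        as.data.frame(s$denaturation$fits)[, c(
          "sample_id", "dg0", "m_value", "c_half", "n_points_used",
          "r_squared"
        )],
        row.names = FALSE, digits = 4
      )),
      ""
    )
  }
  if (!is.null(s$denaturation$ddg_experimental)) {
    lines <- c(
      lines, "Experimental ddG vs reference:",
      utils::capture.output(print.data.frame(
        as.data.frame(s$denaturation$ddg_experimental),
        row.names = FALSE, digits = 4
      ))
    )
  }
  lines
}

#' Measured reference parameters of the AR-LBD sample panel
#'
#' Loads the packaged fixture of measured two-state parameters for the
#' AR-LBD wild type and four AIS mutants: m value, printed transition
#' midpoint, folding free energy at zero denaturant (each with standard
#' error), predicted and experimental ddG, and a qualitative solubility
#' grade.
#'
#' @return A tibble with one row per sample.
#' @examples
#' ar_lbd_reference()
#' @export
ar_lbd_reference <- function() {
  readr::read_tsv(
    system.file("extdata", "ar_lbd_reference.tsv", package = "stabscan"),
    show_col_types = FALSE, progress = FALSE
  )
}
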