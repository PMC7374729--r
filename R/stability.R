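#' Parse a FoldX "Dif" stability output file
#'
#' Reads the tab-separated `Dif_*.fxout` dialect FoldX writes for point
#' mutations: a free-form comment/header preamble, then one row per mutant
#' model whose first column is a PDB tag (containing the mutation code,
#' e.g. `AR_LBD_W752R_1.pdb`) and whose second column is the total folding
#' free-energy difference in kcal/mol (positive = destabilising). Replicate
#' rows for the same mutation are aggregated by their mean, with the
#' replicate count recorded.
#'
#' Rows that look like data but cannot be interpreted are rejected with
#' their line numbers (attached as the `"rejects"` attribute and reported in
#' a warning), never silently dropped.
#'
#' @param path Path to a Dif file.
#' @return A tibble with one row per mutation: `position`, `ref_aa`,
#'   `alt_aa`, `mutation`, `ddg_pred` (kcal/mol), `n_replicates`,
#'   `source_file`.
#' @export
parse_foldx_dif <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("FoldX Dif file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  is_data <- grepl("\\.pdb\t", lines)
  if (!any(is_data)) {
    stop(sprintf(
      "empty FoldX Dif file (no mutation rows): %s", path
    ), call. = FALSE)
  }
  rows <- lines[is_data]
  line_no <- which(is_data)
  tag <- vapply(strsplit(rows, "\t"), `[`, "", 1)
  val <- suppressWarnings(
    as.numeric(vapply(strsplit(rows, "\t"), `[`, "", 2))
  )
  code <- regmatches(tag, regexpr("[A-Z][0-9]+[A-Z](?=[^0-9]|$)",
    tag,
    perl = TRUE
  ))
  has_code <- grepl("[A-Z][0-9]+[A-Z](?=[^0-9]|$)", tag, perl = TRUE)
  ok <- has_code & !is.na(val)
  rejects <- tibble::tibble(
    line = line_no[!ok],
    content = rows[!ok],
    reason = dplyr::if_else(
      !has_code[!ok], "no mutation code in PDB tag",
      "non-numeric energy value"
    )
  )
  if (nrow(rejects) > 0) {
    warning(sprintf(
      "%d unparseable row(s) in %s (lines %s)",
      nrow(rejects), basename(path), paste(rejects$line, collapse = ", ")
    ), call. = FALSE)
  }
  mut <- character(length(tag))
  mut[has_code] <- code
  out <- tibble::tibble(mutation = mut[ok], ddg = val[ok]) |>
    dplyr::group_by(.data$mutation) |>
    dplyr::summarise(
      ddg_pred = mean(.data$ddg),
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ref_aa = substr(.data$mutation, 1, 1),
      position = as.integer(gsub("[A-Z]", "", .data$mutation)),
      alt_aa = substr(.data$mutation, nchar(.data$mutation),
        nchar(.data$mutation)
      ),
      source_file = basename(path)
    ) |>
    dplyr::select(
      "position", "ref_aa", "alt_aa", "mutation",
      "ddg_pred", "n_replicates", "source_file"
    ) |>
    dplyr::arrange(.data$position, .data$alt_aa)
  attr(out, "rejects") <- rejects
  out
}

#' Join predicted ddG values onto a variant catalog
#'
#' Inner join on the variant key (position, ref_aa, alt_aa), with full
#' accounting: every ddG record is classified as joined, unmatched in the
#' catalog, or a duplicate of an earlier record — the three counts sum to
#' the input size. The accounting tibble is attached as the
#' `"accounting"` attribute and retrievable with [join_accounting()].
#'
#' @param catalog Variant tibble with key columns `position`, `ref_aa`,
#'   `alt_aa`.
#' @param ddg ddG tibble with the same key columns and `ddg_pred`.
#' @return The catalog rows matched to a prediction, with `ddg_pred` (and
#'   `n_replicates` if present) appended.
#' @export
join_ddg <- function(catalog, ddg) {
  key <- c("position", "ref_aa", "alt_aa")
  check_columns(catalog, key, arg = "catalog")
  check_columns(ddg, c(key, "ddg_pred"), arg = "ddg")
  ddg_key <- paste(ddg$position, ddg$ref_aa, ddg$alt_aa, sep = ":")
  dup <- duplicated(ddg_key)
  cat_key <- unique(paste(catalog$position, catalog$ref_aa, catalog$alt_aa,
    sep = ":"
  ))
  matched <- ddg_key %in% cat_key
  accounting <- tibble::tibble(
    joined = sum(!dup & matched),
    unmatched = sum(!dup & !matched),
    duplicate = sum(dup),
    input = length(ddg_key)
  )
  joined <- dplyr::inner_join(
    catalog,
    ddg[!dup, , drop = FALSE],
    by = key
  )
  attr(joined, "accounting") <- accounting
  joined
}

#' Accounting report of a ddG join
#'
#' @param joined Output of [join_ddg()].
#' @return A one-row tibble with counts `joined`, `unmatched`, `duplicate`
#'   and `input`.
#' @export
join_accounting <- function(joined) {
  attr(joined, "accounting")
}

#' Compare predicted ddG between two variant classes
#'
#' Two-sample comparison of folding free-energy changes between two classes
#' of variants (e.g. disease-associated versus polymorphism). The default
#' is Welch's unpaired two-sided t-test, which does not assume equal group
#' sizes or variances; a pooled-variance Student test and the Mann–Whitney
#' (Wilcoxon rank-sum) test are available.
#'
#' @param data Data frame holding one row per variant.
#' @param value Column with the ddG values (tidy-eval).
#' @param group Column with the class labels (tidy-eval).
#' @param class_a,class_b The two labels to contrast.
#' @param method `"welch"` (default), `"student"` or `"wilcoxon"`.
#' @return A one-row tibble: `group_a`, `group_b`, `n_a`, `n_b`, `mean_a`,
#'   `mean_b`, `test_statistic`, `p_value`, `test_name`.
#' @examples
#' sim <- simulate_catalogs(seed = 1)
#' joined <- join_ddg(sim$combined, sim$ddg)
#' compare_groups(joined, ddg_pred, source, "HGMD", "polymorphism")
#' @export
compare_groups <- function(data, value, group, class_a, class_b,
                           method = c("welch", "student", "wilcoxon")) {
  method <- match.arg(method)
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  g <- rlang::eval_tidy(group, data)
  v <- rlang::eval_tidy(value, data)
  xa <- v[g == class_a & !is.na(v)]
  xb <- v[g == class_b & !is.na(v)]
  if (length(xa) < 2 || length(xb) < 2) {
    stop(sprintf(
      "insufficient data: group '%s' has %d value(s), group '%s' has %d; need at least 2 each",
      class_a, length(xa), class_b, length(xb)
    ), call. = FALSE)
  }
  if (method == "wilcoxon") {
    ht <- suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE))
    stat <- unname(ht$statistic)
    p <- ht$p.value
    test_name <- "Mann-Whitney U"
  } else {
    if (stats::var(xa) == 0 && stats::var(xb) == 0) {
      # t.test() refuses constant data; the contrast is still well defined
      stat <- if (mean(xa) == mean(xb)) 0 else sign(mean(xa) - mean(xb)) * Inf
      p <- if (mean(xa) == mean(xb)) 1 else 0
    } else {
      ht <- stats::t.test(xa, xb, var.equal = (method == "student"))
      stat <- unname(ht$statistic)
      p <- ht$p.value
    }
    test_name <- if (method == "student") {
      "Student t (pooled, two-sided)"
    } else {
      "Welch t (two-sided)"
    }
  }
  tibble::tibble(
    group_a = as.character(class_a),
    group_b = as.character(class_b),
    n_a = length(xa),
    n_b = length(xb),
    mean_a = mean(xa),
    mean_b = mean(xb),
    test_statistic = stat,
    p_value = p,
    test_name = test_name
  )
}

#' All pairwise class comparisons
#'
#' Runs [compare_groups()] on every unordered pair of class labels present
#' in the data, optionally applying a Bonferroni correction across the
#' pairs (none by default, matching the convention of reporting raw
#' per-contrast significance).
#'
#' @inheritParams compare_groups
#' @param p_adjust `"none"` (default) or `"bonferroni"`.
#' @return A tibble with one row per pair, plus `p_adjusted`.
#' @export
compare_all_pairs <- function(data, value, group,
                              method = c("welch", "student", "wilcoxon"),
                              p_adjust = c("none", "bonferroni")) {
  method <- match.arg(method)
  p_adjust <- match.arg(p_adjust)
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  labels <- sort(unique(as.character(rlang::eval_tidy(group, data))))
  pairs <- utils::combn(labels, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(p) {
    compare_groups(data, !!value, !!group, p[1], p[2], method = method)
  })
  out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  out
}

#' Label variants by predicted stability effect
#'
#' Symmetric three-way classification of predicted ddG values around a
#' destabilisation threshold: values at or above `threshold` are
#' `destabilizing`, at or below `-threshold` are `stabilizing`, and
#' everything between is `neutral`. The default threshold of 3 kcal/mol
#' reflects that a destabilisation of that order is typically enough to
#' trigger cellular degradation of the protein.
#'
#' @param ddg_pred Numeric vector of predicted ddG values (kcal/mol,
#'   positive = destabilising).
#' @param threshold Positive cutoff in kcal/mol. Default 3.
#' @return Character vector in `{stabilizing, neutral, destabilizing}`.
#' @examples
#' classify_destabilizing(c(1.4, 3.6, -3.6))
#' @export
classify_destabilizing <- function(ddg_pred, threshold = 3) {
  stopifnot(is.numeric(ddg_pred), threshold > 0)
  dplyr::case_when(
    ddg_pred >= threshold ~ "destabilizing",
    ddg_pred <= -threshold ~ "stabilizing",
    TRUE ~ "neutral"
  )
}

#' Strip plot of ddG by variant class
#'
#' Jittered per-variant ddG values by class with group means, the standard
#' visual for contrasting the stability impact of disease-associated,
#' somatic and polymorphic variants.
#'
#' @param data Data frame with one row per variant.
#' @param value ddG column (tidy-eval).
#' @param group Class column (tidy-eval).
#' @return A ggplot object.
#' @export
plot_ddg_groups <- function(data, value, group) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  ggplot2::ggplot(data, ggplot2::aes(!!group, !!value, colour = !!group)) +
    ggplot2::geom_jitter(width = 0.18, alpha = 0.55, size = 1.3) +
    ggplot2::stat_summary(
      fun = mean, geom = "crossbar",
      width = 0.45, colour = "black", linewidth = 0.35
    ) +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(
      x = NULL,
      y = expression(Delta * Delta * G ~ "predicted (kcal/mol)")
    )
}
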