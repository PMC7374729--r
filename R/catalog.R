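#' Domain map of the 920-residue androgen receptor
#'
#' Inclusive 1-based residue intervals on the NM_000044.2 reference (920
#' amino acids): the N-terminal transactivation domain (NTD), the DNA-binding
#' domain (DBD), the hinge and the ligand-binding domain (LBD). Residue 559,
#' the NTD–DBD linker, is assigned to the NTD so the intervals partition the
#' full sequence. The bipartite nuclear localisation signal spanning residues
#' 617–634 is carried as an annotation attribute only.
#'
#' @return A tibble with columns `domain`, `start`, `end`, `length`.
#' @examples
#' ar_domains()
#' @export
ar_domains <- function() {
  out <- tibble::tibble(
    domain = c("NTD", "DBD", "hinge", "LBD"),
    start = c(1L, 560L, 621L, 691L),
    end = c(559L, 620L, 690L, 920L)
  ) |>
    dplyr::mutate(length = .data$end - .data$start + 1L)
  attr(out, "nls") <- c(start = 617L, end = 634L)
  out
}

#' Assign residue positions to AR domains
#'
#' @param position Integer vector of 1-based residue positions.
#' @param domains Domain map tibble (see [ar_domains()]).
#' @return Character vector of domain names, same length as `position`.
#' @examples
#' assign_domain(c(300, 600, 752))
#' @export
assign_domain <- function(position, domains = ar_domains()) {
  position <- as.integer(position)
  lo <- min(domains$start)
  hi <- max(domains$end)
  if (anyNA(position) || any(position < lo | position > hi)) {
    stop(sprintf(
      "position out of range [%d, %d]", lo, hi
    ), call. = FALSE)
  }
  idx <- findInterval(position, domains$start)
  domains$domain[idx]
}

# Normalise an alt-allele token and derive the mutation class.
# Returns NA class for tokens that are not interpretable.
mutation_class_of <- function(ref_aa, alt_aa) {
  dplyr::case_when(
    alt_aa %in% c("*", "X", "Ter", "stop") ~ "nonsense",
    tolower(alt_aa) %in% c("fs", "frameshift") ~ "frameshift",
    alt_aa %in% .AA_CODES & ref_aa == alt_aa ~ NA_character_,
    alt_aa %in% .AA_CODES ~ "missense",
    TRUE ~ "other"
  )
}

#' Read and validate a variant table
#'
#' Reads a TSV/CSV of single-residue variants (protein coordinates on the
#' 920-residue AR reference), validates every row, and returns the accepted
#' records as a normalised catalog. Malformed rows are never silently
#' dropped: they are collected into a rejects report with a per-row reason,
#' retrievable with [rejected_variants()].
#'
#' @param path Path to a delimited file (delimiter inferred from the
#'   extension: `.csv` comma, otherwise tab).
#' @param col_map Named character vector mapping the standard column names
#'   `position`, `ref_aa`, `alt_aa`, `source`, `phenotype` to the file's
#'   column names; defaults to the identity mapping. `source` and
#'   `phenotype` are optional.
#' @param offset Integer added to file positions before validation; supports
#'   legacy 919-residue coordinates (poly-Q/poly-G repeat-length variation
#'   shifted the reference by one residue). Default 0.
#' @param domains Domain map used for annotation.
#' @return A tibble with columns `position`, `ref_aa`, `alt_aa`,
#'   `mutation_class`, `source`, `phenotype`, `domain`; the rejects report
#'   is attached as the `"rejects"` attribute.
#' @export
parse_variant_table <- function(path, col_map = NULL, offset = 0L,
                                domains = ar_domains()) {
  if (!file.exists(path)) {
    stop(sprintf("variant table not found: %s", path), call. = FALSE)
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  validate_variants(raw, col_map = col_map, offset = offset, domains = domains)
}

#' Validate an in-memory variant data frame
#'
#' The data-frame core of [parse_variant_table()]; useful when variants
#' arrive from simulation or another package rather than a file.
#'
#' @inheritParams parse_variant_table
#' @param df Data frame of raw variant rows.
#' @return See [parse_variant_table()].
#' @export
validate_variants <- function(df, col_map = NULL, offset = 0L,
                              domains = ar_domains()) {
  std <- c("position", "ref_aa", "alt_aa", "source", "phenotype")
  col_map <- col_map %||% stats::setNames(std, std)
  required <- c("position", "ref_aa", "alt_aa")
  miss <- setdiff(col_map[required], names(df))
  if (length(miss) > 0) {
    stop(sprintf(
      "variant table is missing mapped column(s): %s",
      paste(miss, collapse = ", ")
    ), call. = FALSE)
  }
  get_col <- function(std_name, default = NA_character_) {
    nm <- col_map[std_name]
    if (!is.na(nm) && nm %in% names(df)) as.character(df[[nm]]) else
      rep(default, nrow(df))
  }
  work <- tibble::tibble(
    row = seq_len(nrow(df)),
    position_raw = get_col("position"),
    ref_aa = toupper(trimws(get_col("ref_aa"))),
    alt_aa = trimws(get_col("alt_aa")),
    source = get_col("source", "unspecified"),
    phenotype_raw = get_col("phenotype", "")
  ) |>
    dplyr::mutate(
      position = suppressWarnings(as.integer(.data$position_raw)) +
        as.integer(offset),
      alt_aa = dplyr::if_else(
        nchar(.data$alt_aa) == 1, toupper(.data$alt_aa), .data$alt_aa
      ),
      mutation_class = mutation_class_of(.data$ref_aa, .data$alt_aa),
      reason = dplyr::case_when(
        is.na(.data$position) ~ "position not an integer",
        .data$position < 1 | .data$position > 920 ~
          "position out of range 1-920",
        !.data$ref_aa %in% .AA_CODES ~ "unknown reference amino acid",
        is.na(.data$mutation_class) ~
          "reference and alternate amino acids identical",
        TRUE ~ NA_character_
      )
    )
  rejects <- work |>
    dplyr::filter(!is.na(.data$reason)) |>
    dplyr::select("row", position = "position_raw", "ref_aa", "alt_aa",
                  "reason")
  accepted <- work |>
    dplyr::filter(is.na(.data$reason)) |>
    dplyr::mutate(
      phenotype = classify_phenotype(.data$phenotype_raw),
      domain = assign_domain(.data$position, domains)
    ) |>
    dplyr::select(
      "position", "ref_aa", "alt_aa", "mutation_class",
      "source", "phenotype", "domain"
    )
  attr(accepted, "rejects") <- rejects
  accepted
}

#' Rejects report of a parsed variant table
#'
#' @param catalog Output of [parse_variant_table()] or [validate_variants()].
#' @return A tibble of rejected rows with their one-line reasons (empty if
#'   every row validated).
#' @export
rejected_variants <- function(catalog) {
  attr(catalog, "rejects") %||%
    tibble::tibble(
      row = integer(), position = character(), ref_aa = character(),
      alt_aa = character(), reason = character()
    )
}

#' Normalise free-text phenotype annotations
#'
#' Maps free-text disease annotations onto the controlled vocabulary
#' `CAIS`, `PAIS`, `MAIS` (complete / partial / mild androgen insensitivity
#' syndrome), `prostate_cancer`, `POF` (premature ovarian failure), `none`,
#' with anything unmapped reported as `unknown`.
#'
#' @param x Character vector of annotations.
#' @param synonyms Optional named character vector of extra patterns
#'   (regular expressions, case-insensitive) to canonical labels, consulted
#'   before the built-in table.
#' @return Character vector of canonical phenotype labels.
#' @examples
#' classify_phenotype(c("CAIS", "partial androgen insensitivity", ""))
#' @export
classify_phenotype <- function(x, synonyms = NULL) {
  x <- as.character(x)
  builtin <- c(
    "^cais$" = "CAIS",
    "complete" = "CAIS",
    "^pais$" = "PAIS",
    "partial" = "PAIS",
    "^mais$" = "MAIS",
    "mild" = "MAIS",
    "prostate" = "prostate_cancer",
    "^pca$" = "prostate_cancer",
    "cancer" = "prostate_cancer",
    "somatic" = "prostate_cancer",
    "ovarian failure" = "POF",
    "^pof$" = "POF",
    "^none$" = "none",
    "benign" = "none",
    "polymorphism" = "none",
    "^health" = "none"
  )
  table <- c(synonyms, builtin)
  out <- rep("unknown", length(x))
  clean <- tolower(trimws(x))
  for (i in seq_along(table)) {
    hit <- out == "unknown" & grepl(names(table)[i], clean)
    out[hit] <- table[[i]]
  }
  # pass canonical labels through unchanged
  canonical <- c("CAIS", "PAIS", "MAIS", "prostate_cancer", "POF", "none")
  exact <- trimws(x) %in% canonical
  out[exact] <- trimws(x)[exact]
  out
}

#' Per-domain mutation statistics
#'
#' For each AR domain: the number of residues, the number of distinct
#' residues carrying at least one variant, the fraction of mutated residues
#' and the total variant count.
#'
#' @param catalog Variant tibble with at least a `position` column.
#' @param domains Domain map tibble.
#' @return A tibble with one row per domain: `domain`, `residues_total`,
#'   `residues_mutated`, `fraction_mutated`, `variant_count`.
#' @export
domain_stats <- function(catalog, domains = ar_domains()) {
  check_columns(catalog, "position", arg = "catalog")
  if (nrow(catalog) == 0) {
    stop("catalog is empty", call. = FALSE)
  }
  per_dom <- catalog |>
    dplyr::mutate(domain = assign_domain(.data$position, domains)) |>
    dplyr::group_by(.data$domain) |>
    dplyr::summarise(
      residues_mutated = dplyr::n_distinct(.data$position),
      variant_count = dplyr::n(),
      .groups = "drop"
    )
  domains |>
    dplyr::select("domain", residues_total = "length") |>
    dplyr::left_join(per_dom, by = "domain") |>
    dplyr::mutate(
      residues_mutated = dplyr::coalesce(.data$residues_mutated, 0L),
      variant_count = dplyr::coalesce(.data$variant_count, 0L),
      fraction_mutated = .data$residues_mutated / .data$residues_total
    ) |>
    dplyr::select(
      "domain", "residues_total", "residues_mutated",
      "fraction_mutated", "variant_count"
    )
}

#' Three-way dataset overlap (Venn region counts)
#'
#' Counts the seven non-empty intersection regions of three variant sets,
#' with variants keyed by (position, ref_aa, alt_aa). The region counts
#' always sum to the size of the union.
#'
#' @param catalogs Named list of exactly three data frames, each with
#'   columns `position`, `ref_aa`, `alt_aa`.
#' @return A tibble with one row per region: logical membership columns
#'   (named after the input sets), a human-readable `region` label and the
#'   count `n`.
#' @examples
#' sim <- simulate_catalogs(seed = 1)
#' dataset_overlap(sim$catalogs)
#' @export
dataset_overlap <- function(catalogs) {
  if (!is.list(catalogs) || length(catalogs) != 3) {
    stop("`catalogs` must be a named list of exactly three data frames",
      call. = FALSE
    )
  }
  nms <- names(catalogs) %||% c("A", "B", "C")
  if (is.null(names(catalogs)) || any(names(catalogs) == "")) {
    names(catalogs) <- nms <- c("A", "B", "C")
  }
  key_of <- function(df) {
    check_columns(df, c("position", "ref_aa", "alt_aa"), arg = "catalog")
    unique(paste(df$position, df$ref_aa, df$alt_aa, sep = ":"))
  }
  keys <- lapply(catalogs, key_of)
  all_keys <- unique(unlist(keys))
  member <- vapply(keys, function(k) all_keys %in% k,
    logical(length(all_keys))
  )
  member <- matrix(member, ncol = 3, dimnames = list(NULL, nms))
  grid <- expand.grid(
    a = c(TRUE, FALSE), b = c(TRUE, FALSE), c = c(TRUE, FALSE)
  )
  grid <- grid[rowSums(grid) > 0, ]
  counts <- apply(grid, 1, function(g) {
    sum(member[, 1] == g[1] & member[, 2] == g[2] & member[, 3] == g[3])
  })
  out <- tibble::tibble(
    !!nms[1] := grid$a, !!nms[2] := grid$b, !!nms[3] := grid$c,
    region = apply(grid, 1, function(g) {
      paste(nms[as.logical(g)], collapse = " & ")
    }),
    n = as.integer(counts)
  )
  dplyr::arrange(out, dplyr::desc(!!rlang::sym(nms[1])),
    dplyr::desc(!!rlang::sym(nms[2])), dplyr::desc(!!rlang::sym(nms[3]))
  )
}
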