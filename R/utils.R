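# Internal helpers shared across modules.

# Gas constant in kcal mol^-1 K^-1; matches the kcal/mol unit of all
# reported free energies.
.R_KCAL <- 1.9872e-3

# Evaluate `code` under a local RNG seeded with `seed`, restoring (or
# removing) the global .Random.seed afterwards so no global state leaks.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Require columns on a data-frame argument, with the caller's name in the
# error so pipeline stage messages stay readable.
check_columns <- function(df, cols, arg = deparse(substitute(df))) {
  if (!is.data.frame(df)) {
    stop(sprintf("`%s` must be a data frame", arg), call. = FALSE)
  }
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf(
      "`%s` is missing required column(s): %s",
      arg, paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}

# One-letter codes for the 20 standard amino acids.
.AA_CODES <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
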