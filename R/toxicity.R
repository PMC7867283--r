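# Toxicity-risk filtering over four ordinal parameters (mutagenic,
# tumorigenic, reproductive-effective, irritant), each at level none/low/high
# as predicted by a fragment-based profiler whose output table is consumed
# here. Only compounds with no predicted risk in any category survive:
# "low" already counts as a risk.

TOX_PARAMS <- c("mutagenic", "tumorigenic", "reproductive_effective", "irritant")
TOX_LEVELS <- c("none", "low", "high")

#' Read a toxicity-risk table
#'
#' CSV with columns `compound_id`, `mutagenic`, `tumorigenic`,
#' `reproductive_effective`, `irritant`. Levels parse case-insensitively
#' from the closed vocabulary No/None, Low, High; anything else is a parse
#' error naming the row and column.
#'
#' @param path CSV path (or a data frame already in that layout).
#' @return Tibble of profiles; the four parameters are ordered factors
#'   `none < low < high`.
#' @export
read_toxicity_table <- function(path) {
  raw <- if (is.data.frame(path)) path else
    read.csv(path, colClasses = "character", check.names = FALSE,
             strip.white = TRUE)
  missing_cols <- setdiff(c("compound_id", TOX_PARAMS), names(raw))
  if (length(missing_cols)) {
    stop("toxicity CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble(compound_id = as.character(raw$compound_id))
  for (param in TOX_PARAMS) {
    out[[param]] <- parse_tox_levels(raw[[param]], param)
  }
  out
}

parse_tox_levels <- function(x, column) {
  lev <- tolower(trimws(as.character(x)))
  lev[lev %in% c("no", "none")] <- "none"
  bad <- which(!lev %in% TOX_LEVELS)
  if (length(bad)) {
    stop("unknown toxicity level '", x[bad[1]], "' at row ", bad[1],
         ", column '", column, "'", call. = FALSE)
  }
  factor(lev, levels = TOX_LEVELS, ordered = TRUE)
}

#' Keep only risk-free toxicity profiles
#'
#' Retains exactly the compounds whose four risk levels are all `none`; any
#' predicted risk, including `low`, excludes a compound. The filter is
#' idempotent and monotone (downgrading a level toward `none` never removes
#' a survivor).
#'
#' @param profiles Tibble from [read_toxicity_table()].
#' @return The risk-free subset, order preserved.
#' @export
filter_risk_free <- function(profiles) {
  clean <- Reduce(`&`, lapply(TOX_PARAMS, function(p) profiles[[p]] == "none"))
  profiles[clean, , drop = FALSE]
}
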