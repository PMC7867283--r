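# Docking score tables and their normalization into activity probabilities.
#
# Scores are MolDock-style interaction energies (kcal/mol scale, more
# negative = stronger binding). A ligand is potentially active only if its
# energy lies strictly below the reference (crystallographic/commercial)
# inhibitor's energy; in that case its probability is E_lig / E_mlig, the
# ratio to the best (most negative) energy in the screened table, a value in
# (0, 1] reaching 1 only for the best ligand itself.

#' Read per-enzyme docking score tables
#'
#' The CSV dialect has columns `compound_id`, `enzyme_id`, `score`, optional
#' `heavy_atoms` and `secondary_score` (GoldScore-style; carried through for
#' reporting but never entering the probability), and `is_reference` (0/1).
#' Exactly one reference row is required per enzyme; its compound_id is the
#' reference inhibitor's name and it is excluded from the ligand scores.
#'
#' @param path CSV path (or a data frame already in that layout).
#' @return A named list of `docking_table` objects, one per enzyme.
#' @export
read_docking_tables <- function(path) {
  raw <- if (is.data.frame(path)) path else read.csv(path, check.names = FALSE)
  needed <- c("compound_id", "enzyme_id", "score", "is_reference")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("docking CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  score <- suppressWarnings(as.numeric(raw$score))
  bad <- which(is.na(score) & !is.na(raw$score) & nzchar(as.character(raw$score)))
  if (length(bad)) {
    stop("non-numeric docking score at row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  raw$score <- score
  tables <- lapply(split(raw, raw$enzyme_id), build_docking_table)
  tables[unique(raw$enzyme_id)]
}

build_docking_table <- function(df) {
  enzyme <- df$enzyme_id[1]
  is_ref <- as.logical(as.integer(df$is_reference))
  if (sum(is_ref) != 1L) {
    stop("enzyme '", enzyme, "' must have exactly one reference row, found ",
         sum(is_ref), call. = FALSE)
  }
  ligands <- df[!is_ref, , drop = FALSE]
  dup <- unique(ligands$compound_id[duplicated(ligands$compound_id)])
  if (length(dup)) {
    stop("enzyme '", enzyme, "': duplicate ligand(s) ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  ref <- df[is_ref, , drop = FALSE]
  if (!is.finite(ref$score)) {
    stop("enzyme '", enzyme, "': reference score must be finite", call. = FALSE)
  }
  docking_table(
    enzyme_id = enzyme,
    ligands = tibble(
      compound_id = as.character(ligands$compound_id),
      score = ligands$score,
      heavy_atoms = if ("heavy_atoms" %in% names(ligands))
        as.integer(ligands$heavy_atoms) else NA_integer_,
      secondary_score = if ("secondary_score" %in% names(ligands))
        as.numeric(ligands$secondary_score) else NA_real_
    ),
    reference_id = as.character(ref$compound_id),
    reference_score = ref$score
  )
}

#' Construct a docking score table
#'
#' @param enzyme_id Enzyme identifier (e.g. `"ache"`, `"nachr"`, `"cht"`).
#' @param ligands Tibble with `compound_id`, `score`, and optional
#'   `heavy_atoms`, `secondary_score`.
#' @param reference_id Name of the reference inhibitor.
#' @param reference_score Its docking energy (E_inib).
#' @return An object of class `docking_table`.
#' @export
docking_table <- function(enzyme_id, ligands, reference_id, reference_score) {
  if (!all(c("compound_id", "score") %in% names(ligands))) {
    stop("ligands need compound_id and score columns", call. = FALSE)
  }
  structure(
    list(enzyme_id = enzyme_id, ligands = as_tibble(ligands),
         reference_id = reference_id, reference_score = reference_score),
    class = "docking_table"
  )
}

#' @export
print.docking_table <- function(x, ...) {
  cat(sprintf("Docking table '%s': %d ligands, reference %s at %.2f\n",
              x$enzyme_id, nrow(x$ligands), x$reference_id, x$reference_score))
  invisible(x)
}

#' Docking-derived activity probability
#'
#' For a ligand energy strictly below the reference inhibitor's energy, the
#' probability is `e_lig / e_mlig`, where `e_mlig` is the lowest (most
#' negative) energy over the screened set; ligands not beating the reference
#' get `NA` (the not-active marker). All energies must be negative —
#' repulsive (positive) scores are rejected rather than silently producing
#' probabilities outside (0, 1].
#'
#' @param e_lig Ligand energy (vectorized).
#' @param e_mlig Minimum energy over the screened set; must satisfy
#'   `e_mlig <= e_lig`.
#' @param e_inib Reference inhibitor energy.
#' @return Numeric vector: probability in (0, 1] for potentially active
#'   ligands, `NA` otherwise.
#' @examples
#' docking_probability(-217.92, -223.77, -88.38) # 0.9739
#' @export
docking_probability <- function(e_lig, e_mlig, e_inib) {
  stopifnot_scalar_number(e_mlig, "e_mlig")
  stopifnot_scalar_number(e_inib, "e_inib")
  if (e_mlig == 0) stop("e_mlig must be non-zero", call. = FALSE)
  if (e_mlig > 0 || e_inib >= 0 || any(e_lig >= 0)) {
    stop("docking energies must be negative (attractive binding)", call. = FALSE)
  }
  if (any(e_lig < e_mlig)) {
    stop("e_lig below e_mlig contradicts e_mlig being the minimum", call. = FALSE)
  }
  ifelse(e_lig < e_inib, e_lig / e_mlig, NA_real_)
}

#' Call potentially active ligands from a docking table
#'
#' Takes `e_mlig` as the minimum score over the table's own ligands and
#' applies [docking_probability()] to every ligand. The scope of the
#' minimum is therefore the screened table itself. Ligand efficiency is
#' attached where heavy-atom counts are available.
#'
#' @param table A `docking_table`.
#' @return Tibble in table order with `compound_id`, `enzyme_id`, `score`,
#'   `prob_dc` (`NA` when not active), `is_potentially_active`, and
#'   `ligand_efficiency`.
#' @export
call_actives <- function(table) {
  stopifnot(inherits(table, "docking_table"))
  lig <- table$ligands
  if (nrow(lig) == 0L) {
    return(tibble(compound_id = character(), enzyme_id = character(),
                  score = numeric(), prob_dc = numeric(),
                  is_potentially_active = logical(),
                  ligand_efficiency = numeric()))
  }
  e_mlig <- min(lig$score)
  prob <- docking_probability(lig$score, e_mlig, table$reference_score)
  le <- if ("heavy_atoms" %in% names(lig)) {
    ifelse(is.na(lig$heavy_atoms), NA_real_, lig$score / lig$heavy_atoms)
  } else {
    NA_real_
  }
  tibble(
    compound_id = lig$compound_id,
    enzyme_id = table$enzyme_id,
    score = lig$score,
    prob_dc = prob,
    is_potentially_active = !is.na(prob),
    ligand_efficiency = le
  )
}

#' Ligand efficiency
#'
#' Docking score per heavy (non-hydrogen) atom; keeps the sign convention of
#' the score. Heavy-atom counting conventions vary between tools, so
#' printed efficiency columns from other software are not expected to be
#' reproduced digit-for-digit.
#'
#' @param score Docking score (vectorized).
#' @param heavy_atoms Positive integer count(s) of non-hydrogen atoms.
#' @return `score / heavy_atoms`.
#' @examples
#' ligand_efficiency(-100, 20) # -5
#' @export
ligand_efficiency <- function(score, heavy_atoms) {
  if (any(!is.finite(heavy_atoms)) || any(heavy_atoms < 1)) {
    stop("heavy_atoms must be >= 1", call. = FALSE)
  }
  score / heavy_atoms
}
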