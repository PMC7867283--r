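# Consensus of the ligand-based (QSAR) and structure-based (docking)
# channels: Prob_comb = (Prob_dc + (1 + ESP) * P_activity) / (2 + ESP),
# a convex combination weighting the QSAR probability by the model's
# specificity statistic ESP. Selection requires Prob_comb strictly > 0.5.

#' Combined ligand+structure activity probability
#'
#' `(prob_dc + (1 + esp) * p_activity) / (2 + esp)`: a weighted mean of the
#' docking probability (weight 1) and the QSAR probability (weight 1 + ESP),
#' so the result always lies between the two inputs, equals 1 only when both
#' are 1, and equals 0 only when both are 0.
#'
#' @param prob_dc Docking activity probability in \[0, 1\] (use 0 for
#'   compounds carrying the not-active docking marker, so a strong QSAR
#'   signal alone is capped at `(1 + esp) / (2 + esp)`).
#' @param p_activity QSAR active-class probability in \[0, 1\].
#' @param esp Specificity statistic of the QSAR model in \[0, 1\], the
#'   fusion weight.
#' @return Combined probability in \[0, 1\] (vectorized).
#' @examples
#' combined_probability(0.9739, 0.62, 0.76) # 0.7482
#' @export
combined_probability <- function(prob_dc, p_activity, esp) {
  check_unit_interval(prob_dc, "prob_dc")
  check_unit_interval(p_activity, "p_activity")
  check_unit_interval(esp, "esp")
  (prob_dc + (1 + esp) * p_activity) / (2 + esp)
}

check_unit_interval <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("`", name, "` must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

#' Build the per-compound, per-enzyme consensus table
#'
#' Joins docking calls (from [call_actives()], possibly several enzymes
#' stacked) with the QSAR probabilities and computes the combined
#' probability and the strict selection flag. Docking-inactive compounds
#' contribute `prob_dc = 0` rather than being dropped.
#'
#' @param calls Tibble with `compound_id`, `enzyme_id`, `prob_dc`,
#'   `is_potentially_active` (rows from one or more [call_actives()] outputs).
#' @param p_activity Named numeric vector of QSAR probabilities covering
#'   every compound in `calls`.
#' @param esp Specificity statistic used as the fusion weight.
#' @param threshold Strict selection threshold on the combined probability,
#'   default 0.5.
#' @return Tibble with `compound_id`, `enzyme_id`, `prob_dc`, `p_activity`,
#'   `esp`, `prob_comb`, `selected`.
#' @export
consensus_screen <- function(calls, p_activity, esp, threshold = 0.5) {
  stopifnot_scalar_number(threshold, "threshold", 0, 1)
  missing <- setdiff(unique(calls$compound_id), names(p_activity))
  if (length(missing)) {
    stop("no QSAR probability for compound(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  prob_dc <- ifelse(is.na(calls$prob_dc), 0, calls$prob_dc)
  p_act <- as.numeric(p_activity[calls$compound_id])
  prob_comb <- combined_probability(prob_dc, p_act, esp)
  tibble(
    compound_id = calls$compound_id,
    enzyme_id = calls$enzyme_id,
    prob_dc = prob_dc,
    p_activity = p_act,
    esp = esp,
    prob_comb = prob_comb,
    selected = prob_comb > threshold
  )
}

#' Select potentially active consensus results
#'
#' Keeps exactly the rows whose combined probability exceeds the threshold
#' strictly: a compound at 0.5 is excluded. Order preserved.
#'
#' @param results Consensus tibble with a `prob_comb` column; `NA` combined
#'   probabilities count as not selected.
#' @param threshold Strict threshold, default 0.5.
#' @return The selected subset of `results`.
#' @export
select_potentially_active <- function(results, threshold = 0.5) {
  stopifnot_scalar_number(threshold, "threshold", 0, 1)
  keep <- !is.na(results$prob_comb) & results$prob_comb > threshold
  results[keep, , drop = FALSE]
}

#' Intersect per-enzyme selections into a multi-target list
#'
#' A compound is multi-target iff it is selected for every required enzyme;
#' a compound missing an evaluation for a required enzyme counts as not
#' selected there. The list is ranked by mean combined probability over the
#' required enzymes, descending, ties broken by compound id.
#'
#' @param results Consensus tibble (`compound_id`, `enzyme_id`, `prob_comb`,
#'   `selected`).
#' @param required_enzymes Non-empty character vector of enzyme ids that a
#'   compound must hit.
#' @return Tibble with `compound_id` and `mean_prob_comb`, ranked.
#' @export
intersect_targets <- function(results, required_enzymes) {
  if (length(required_enzymes) == 0L) {
    stop("required_enzymes must be non-empty", call. = FALSE)
  }
  required_enzymes <- unique(required_enzymes)
  res <- results[results$enzyme_id %in% required_enzymes, , drop = FALSE]
  res$selected <- !is.na(res$selected) & res$selected
  groups <- split(res, res$compound_id)
  n_hit <- vapply(groups, function(g) sum(g$selected), integer(1))
  mean_pc <- vapply(groups, function(g) mean(g$prob_comb[g$selected]), numeric(1))
  hit <- n_hit == length(required_enzymes)
  out <- tibble(compound_id = names(groups)[hit],
                mean_prob_comb = unname(mean_pc[hit]))
  out[order(-out$mean_prob_comb, out$compound_id), , drop = FALSE]
}

#' Enrichment factor of a ranked selection
#'
#' Fraction of true actives in the top `fraction` of the ranking divided by
#' their prevalence in the whole set; 1 means no enrichment over random
#' picking.
#'
#' @param ranked_ids Compound ids in ranked order (best first).
#' @param active_ids Ids of the true actives.
#' @param all_ids All screened compound ids.
#' @param fraction Top fraction to inspect, default 0.1.
#' @return Single number; `NA` when prevalence is zero.
#' @export
enrichment_factor <- function(ranked_ids, active_ids, all_ids, fraction = 0.1) {
  stopifnot_scalar_number(fraction, "fraction", 0, 1)
  prevalence <- mean(all_ids %in% active_ids)
  if (prevalence == 0) return(NA_real_)
  n_top <- max(1L, floor(fraction * length(all_ids)))
  top <- ranked_ids[seq_len(min(n_top, length(ranked_ids)))]
  mean(top %in% active_ids) / prevalence
}
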