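# In-code fixtures shared across the suite.

# Write a minimal V2000 SDF (two atoms per molecule) with pLC50 and species
# data fields; returns the path.
write_toy_sdf <- function(records, path = tempfile(fileext = ".sdf")) {
  blocks <- vapply(seq_len(nrow(records)), function(i) {
    paste0(
      records$compound_id[i], "\n  toy\n\n",
      "  2  1  0  0  0  0  0  0  0  0999 V2000\n",
      "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0\n",
      "    1.5000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0\n",
      "  1  2  1  0  0  0  0\nM  END\n",
      ">  <pLC50>\n", records$plc50[i], "\n\n",
      ">  <species>\n", records$species_tag[i], "\n\n$$$$"
    )
  }, character(1))
  writeLines(paste(blocks, collapse = "\n"), path)
  path
}

write_toy_library_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

# Small labelled library + separable descriptors without the generator,
# for unit tests that should not depend on the synthetic module.
toy_labeled <- function(n_active = 5, n_inactive = 5) {
  tibble::tibble(
    compound_id = sprintf("t%02d", seq_len(n_active + n_inactive)),
    smiles = NA_character_,
    plc50 = c(rep(5, n_active), rep(4, n_inactive)),
    species_tag = "aphis",
    label = factor(rep(c("active", "inactive"), c(n_active, n_inactive)),
                   levels = c("inactive", "active"))
  )
}

toy_descriptors <- function(labeled, shift = 0, seed = 42) {
  set.seed(seed)
  n <- nrow(labeled)
  m <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(labeled$compound_id, paste0("d", 1:4)))
  m[labeled$label == "active", 1:2] <- m[labeled$label == "active", 1:2] + shift
  m
}

# Independent AUC oracle: brute force over all active-inactive pairs with
# ties counted as one half.
pairwise_auc <- function(scores, labels) {
  act <- scores[labels == "active"]
  ina <- scores[labels == "inactive"]
  total <- 0
  for (a in act) for (b in ina) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(act) * length(ina))
}

# Independent MCC oracle: the Pearson correlation of the expanded binary
# prediction/truth vectors (undefined correlation -> 0).
mcc_by_correlation <- function(tp, fp, tn, fn) {
  truth <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
  r <- suppressWarnings(stats::cor(truth, pred))
  if (is.na(r)) 0 else r
}

trapezoid_auc <- function(curve) {
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}
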