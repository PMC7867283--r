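# Bundled worked example: a published consensus screen of Lamiaceae
# diterpenes against three insect target enzymes (acetylcholinesterase,
# nicotinic acetylcholine receptor, chitinase) in the cotton aphid and the
# fruit fly. The extdata CSVs transcribe the screen's per-enzyme MolDock
# and GoldScore energies (with the commercial-insecticide reference row),
# the published combined probabilities and QSAR probabilities, the
# four-parameter toxicity profiles, and the RF model performance summary.
# The published combined probabilities are carried as data: they were
# computed against the full screened bank, whose energy minimum and exact
# fusion weight are not recoverable from the printed subset.

example_path <- function(file) {
  path <- system.file("extdata", file, package = "consensusVS")
  if (!nzchar(path)) stop("example file not installed: ", file, call. = FALSE)
  path
}

#' Load the worked-example screen for one species
#'
#' Returns the per-enzyme docking tables (ligand energies plus the
#' insecticide reference row), the published per-compound QSAR
#' probabilities, and the published combined-probability table in the
#' consensus layout accepted by [run_screen()]'s `consensus` argument.
#'
#' @param species `"aphis"` (three enzymes: ache, nachr, cht) or
#'   `"drosophila"` (multi-target set spans ache and nachr; its cht column
#'   has no below-reference ligand).
#' @return List with `docking_tables` (named list of `docking_table`),
#'   `consensus` (tibble: `compound_id`, `enzyme_id`, `prob_comb`,
#'   `selected`), `p_activity` (named vector), and `required_enzymes`.
#' @export
load_example_screen <- function(species = c("aphis", "drosophila")) {
  species <- match.arg(species)
  file <- paste0(species, "_screen.csv")
  raw <- read.csv(example_path(file), check.names = FALSE,
                  colClasses = "character", strip.white = TRUE)
  num <- function(x) suppressWarnings(as.numeric(x))
  is_ref <- as.integer(raw$is_reference) == 1L
  enzymes <- c("ache", "nachr", "cht")

  long <- do.call(rbind, lapply(enzymes, function(enz) {
    data.frame(
      compound_id = raw$compound_id,
      enzyme_id = enz,
      score = num(raw[[paste0("moldock_", enz)]]),
      secondary_score = num(raw[[paste0("goldscore_", enz)]]),
      prob_comb = num(raw[[paste0("prob_comb_", enz)]]),
      is_reference = as.integer(is_ref)
    )
  }))
  docking <- long[!is.na(long$score), c("compound_id", "enzyme_id", "score",
                                        "secondary_score", "is_reference")]
  tables <- read_docking_tables(docking)

  lig <- long[!as.logical(long$is_reference), , drop = FALSE]
  consensus <- tibble(
    compound_id = lig$compound_id,
    enzyme_id = lig$enzyme_id,
    prob_comb = lig$prob_comb,
    selected = !is.na(lig$prob_comb) & lig$prob_comb > 0.5
  )
  p_activity <- stats::setNames(num(raw$p_activity[!is_ref]),
                                raw$compound_id[!is_ref])
  list(
    docking_tables = tables,
    consensus = consensus,
    p_activity = p_activity,
    required_enzymes = if (species == "aphis") enzymes else c("ache", "nachr")
  )
}

#' Load the worked-example toxicity table for one species
#'
#' @param species `"aphis"` or `"drosophila"`.
#' @return Toxicity tibble as from [read_toxicity_table()].
#' @export
load_example_toxicity <- function(species = c("aphis", "drosophila")) {
  species <- match.arg(species)
  read_toxicity_table(example_path(paste0(species, "_toxicity.csv")))
}

#' Load the worked-example RF performance summary
#'
#' Test-set and cross-validation accuracy, sensitivity, specificity, PPV,
#' NPV and MCC of the published random-forest models for both species; the
#' specificity columns feed the ESP fusion weight.
#'
#' @return Tibble with one row per species x validation mode.
#' @export
load_example_performance <- function() {
  as_tibble(read.csv(example_path("rf_performance.csv"),
                     check.names = FALSE, strip.white = TRUE))
}
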