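# Seeded synthetic inputs with the statistical structure the pipeline
# assumes: a labelled compound bank with class-separable descriptor blocks,
# docking energies coupled to the planted activity signal, and toxicity
# profiles at a given clean rate. Defaults mirror the worked example's
# study conditions (166 compounds, 91 active at pLC50 >= 4.5; descriptor
# blocks named after the GETAWAY/WHIM/RDF families; MolDock-scale energies).

#' Generate a labelled synthetic compound library
#'
#' Actives draw pLC50 uniformly from \[4.5, 7\], inactives from \[2, 4.5).
#' Descriptors form three correlated Gaussian blocks (`getaway_*`, `whim_*`,
#' `rdf_*`; within-block correlation 0.3). A random informative subset of
#' columns (about a quarter) has its class means separated by
#' `effect_size` standard deviations; the remaining columns are pure noise.
#' The latent activity signal driving downstream docking energies is
#' `plc50 - 4.5`.
#'
#' @param n_compounds Library size, at least 4. Default 166.
#' @param n_descriptors Number of descriptor columns. Default 30.
#' @param active_fraction Fraction of actives in (0, 1). Default 91/166.
#' @param effect_size Class mean shift in descriptor standard deviations,
#'   >= 0. Default 2.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `compounds` (labelled library tibble), `descriptors`
#'   (descriptor matrix), and `truth` (list: `active_ids`,
#'   `informative`, `signal` — the named latent signal vector).
#' @export
generate_library <- function(n_compounds = 166, n_descriptors = 30,
                             active_fraction = 91 / 166, effect_size = 2,
                             seed = 1) {
  if (n_compounds < 4) stop("n_compounds must be at least 4", call. = FALSE)
  stopifnot_scalar_number(active_fraction, "active_fraction")
  if (active_fraction <= 0 || active_fraction >= 1) {
    stop("active_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  stopifnot_scalar_number(effect_size, "effect_size", lo = 0)
  n_active <- round(n_compounds * active_fraction)
  n_active <- min(max(n_active, 1L), n_compounds - 1L)
  n_inactive <- n_compounds - n_active

  set.seed(seed)
  ids <- sprintf("cpd_%04d", seq_len(n_compounds))
  label <- factor(c(rep("active", n_active), rep("inactive", n_inactive)),
                  levels = CLASS_LEVELS)
  plc50 <- c(runif(n_active, 4.5, 7), runif(n_inactive, 2, 4.5))

  block_names <- descriptor_block_names(n_descriptors)
  rho <- 0.3
  block_id <- attr(block_names, "block_id")
  common <- matrix(rnorm(n_compounds * 3), n_compounds, 3)
  x <- sqrt(rho) * common[, block_id, drop = FALSE] +
    sqrt(1 - rho) * matrix(rnorm(n_compounds * n_descriptors),
                           n_compounds, n_descriptors)
  n_informative <- max(1L, round(0.25 * n_descriptors))
  informative <- sort(sample.int(n_descriptors, n_informative))
  x[label == "active", informative] <- x[label == "active", informative] +
    effect_size
  dimnames(x) <- list(ids, block_names)

  compounds <- tibble(compound_id = ids, smiles = NA_character_,
                      plc50 = plc50, species_tag = "aphis", label = label)
  list(
    compounds = compounds,
    descriptors = as_descriptor_matrix(x),
    truth = list(
      active_ids = ids[label == "active"],
      informative = block_names[informative],
      signal = stats::setNames(plc50 - 4.5, ids)
    )
  )
}

descriptor_block_names <- function(n_descriptors) {
  prefixes <- c("getaway", "whim", "rdf")
  block_id <- rep_len(rep(1:3, each = ceiling(n_descriptors / 3)), n_descriptors)
  block_id <- sort(block_id)[seq_len(n_descriptors)]
  nm <- unlist(lapply(1:3, function(b) {
    k <- sum(block_id == b)
    if (k) sprintf("%s_%02d", prefixes[b], seq_len(k)) else character(0)
  }))
  structure(nm, block_id = block_id)
}

#' Generate activity-coupled docking score tables
#'
#' Per enzyme, each ligand's energy is a Gaussian baseline (mean -150,
#' sd 25, MolDock scale) minus `coupling` times the planted activity signal,
#' plus Gaussian noise; scores are clamped strictly negative. The reference
#' inhibitor's energy is placed at the `reference_quantile` of the generated
#' score distribution, so roughly that fraction of ligands beats it.
#'
#' @param truth The `truth` element of [generate_library()] (or any list
#'   with a named numeric `signal`).
#' @param enzyme_ids Enzymes to simulate. Default `c("ache", "nachr", "cht")`.
#' @param coupling Energy decrease per unit of activity signal, >= 0 (score
#'   units). Default 10.
#' @param noise_sd Score noise standard deviation, >= 0. Default 5.
#' @param reference_quantile Placement of the reference energy within the
#'   score distribution, in (0, 1). Default 0.85.
#' @param seed Integer seed.
#' @return Named list of `docking_table` objects.
#' @export
generate_docking_tables <- function(truth,
                                    enzyme_ids = c("ache", "nachr", "cht"),
                                    coupling = 10, noise_sd = 5,
                                    reference_quantile = 0.85, seed = 1) {
  if (length(enzyme_ids) == 0L) stop("need at least one enzyme", call. = FALSE)
  stopifnot_scalar_number(coupling, "coupling", lo = 0)
  stopifnot_scalar_number(noise_sd, "noise_sd", lo = 0)
  stopifnot_scalar_number(reference_quantile, "reference_quantile")
  if (reference_quantile <= 0 || reference_quantile >= 1) {
    stop("reference_quantile must lie strictly between 0 and 1", call. = FALSE)
  }
  signal <- truth$signal
  if (is.null(names(signal))) {
    stop("truth$signal must be a named numeric vector", call. = FALSE)
  }
  set.seed(seed)
  n <- length(signal)
  tables <- lapply(enzyme_ids, function(enz) {
    score <- rnorm(n, -150, 25) - coupling * signal + rnorm(n, 0, noise_sd)
    score <- pmin(score, -1)
    ref <- min(as.numeric(quantile(score, reference_quantile)), -1)
    docking_table(
      enzyme_id = enz,
      ligands = tibble(
        compound_id = names(signal),
        score = score,
        heavy_atoms = sample(15:35, n, replace = TRUE),
        secondary_score = -score / 3 + rnorm(n, 0, 2)
      ),
      reference_id = "reference_insecticide",
      reference_score = ref
    )
  })
  stats::setNames(tables, enzyme_ids)
}

#' Generate synthetic toxicity profiles
#'
#' Each compound is risk-free in all four parameters with probability
#' `clean_rate`; otherwise at least one randomly chosen parameter is set to
#' `low` or `high`.
#'
#' @param compound_ids Compound identifiers.
#' @param clean_rate Probability of an all-none profile, in \[0, 1\].
#'   Default 11/15.
#' @param seed Integer seed.
#' @return Toxicity tibble as from [read_toxicity_table()].
#' @export
generate_toxicity <- function(compound_ids, clean_rate = 11 / 15, seed = 1) {
  stopifnot_scalar_number(clean_rate, "clean_rate", 0, 1)
  set.seed(seed)
  n <- length(compound_ids)
  clean <- runif(n) < clean_rate
  levels_mat <- matrix("none", n, length(TOX_PARAMS),
                       dimnames = list(NULL, TOX_PARAMS))
  for (i in which(!clean)) {
    n_risky <- sample.int(length(TOX_PARAMS), 1)
    which_risky <- sample.int(length(TOX_PARAMS), n_risky)
    levels_mat[i, which_risky] <- sample(c("low", "high"), n_risky,
                                         replace = TRUE)
  }
  out <- tibble(compound_id = as.character(compound_ids))
  for (param in TOX_PARAMS) {
    out[[param]] <- factor(levels_mat[, param], levels = TOX_LEVELS,
                           ordered = TRUE)
  }
  out
}

#' Write synthetic inputs in the pipeline's CSV dialects
#'
#' Serializes a generated library, its descriptors, docking tables, and
#' toxicity profiles into the same CSV formats the ingestion functions
#' read, so generated fixtures double as format documentation.
#'
#' @param library_ A [generate_library()] result.
#' @param docking_tables A [generate_docking_tables()] result.
#' @param toxicity A [generate_toxicity()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_inputs <- function(library_, docking_tables, toxicity, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    library = file.path(dir, "library.csv"),
    descriptors = file.path(dir, "descriptors.csv"),
    docking = file.path(dir, "docking.csv"),
    toxicity = file.path(dir, "toxicity.csv")
  )
  write_library(library_$compounds, paths[["library"]])
  write_descriptors(library_$descriptors, paths[["descriptors"]])
  docking_rows <- do.call(rbind, lapply(docking_tables, function(tab) {
    rbind(
      data.frame(compound_id = tab$ligands$compound_id,
                 enzyme_id = tab$enzyme_id, score = tab$ligands$score,
                 heavy_atoms = tab$ligands$heavy_atoms,
                 secondary_score = round(tab$ligands$secondary_score, 4),
                 is_reference = 0L),
      data.frame(compound_id = tab$reference_id, enzyme_id = tab$enzyme_id,
                 score = tab$reference_score, heavy_atoms = NA_integer_,
                 secondary_score = NA_real_, is_reference = 1L)
    )
  }))
  write.csv(docking_rows, paths[["docking"]], row.names = FALSE, quote = FALSE)
  tox <- as.data.frame(lapply(toxicity, as.character))
  write.csv(tox, paths[["toxicity"]], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
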