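# Pipeline orchestration: a config object collecting every threshold and
# seed, a QSAR stage (label, split, train, test, cross-validate, domain),
# and a screening stage (docking calls, consensus, multi-target
# intersection, toxicity filter). Each stage reads and writes standalone
# artifacts so externally produced tables (e.g. published docking or
# consensus tables) can enter mid-pipeline. All outputs are deterministic
# under a fixed config, and every report embeds the config fingerprint.

#' Pipeline configuration
#'
#' Collects the tunable thresholds of the screening pipeline. Defaults are
#' the study settings: pLC50 activity cutoff 4.5, 80/20 stratified split,
#' 250-tree random forest, 10-fold pooled cross-validation, applicability-
#' domain multiplier Z = 0.5, strict consensus threshold 0.5, and the ESP
#' fusion weight taken as the mean of test and cross-validation specificity.
#'
#' @param plc50_threshold Activity labelling cutoff. Default 4.5.
#' @param train_fraction Training fraction of the stratified split. Default 0.8.
#' @param rf_trees Trees in the random forest. Default 250.
#' @param cv_folds Cross-validation folds. Default 10.
#' @param apd_z Applicability-domain multiplier. Default 0.5.
#' @param prob_cutoff Classification cutoff on P_Activity. Default 0.5.
#' @param prob_comb_threshold Strict consensus selection threshold. Default 0.5.
#' @param esp_mode Which specificity feeds the consensus weight: `"mean"`
#'   (of test and cross), `"test"`, or `"cross"`.
#' @param seed Integer seed driving every stochastic step.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(plc50_threshold = 4.5, train_fraction = 0.8,
                          rf_trees = 250, cv_folds = 10, apd_z = 0.5,
                          prob_cutoff = 0.5, prob_comb_threshold = 0.5,
                          esp_mode = c("mean", "test", "cross"), seed = 1) {
  esp_mode <- match.arg(esp_mode)
  stopifnot_scalar_number(plc50_threshold, "plc50_threshold")
  stopifnot_scalar_number(train_fraction, "train_fraction")
  stopifnot_scalar_number(prob_cutoff, "prob_cutoff", 0, 1)
  stopifnot_scalar_number(prob_comb_threshold, "prob_comb_threshold", 0, 1)
  stopifnot_scalar_number(apd_z, "apd_z", lo = 0)
  if (cv_folds < 2) stop("cv_folds must be at least 2", call. = FALSE)
  cfg <- list(plc50_threshold = plc50_threshold,
              train_fraction = train_fraction, rf_trees = rf_trees,
              cv_folds = cv_folds, apd_z = apd_z, prob_cutoff = prob_cutoff,
              prob_comb_threshold = prob_comb_threshold, esp_mode = esp_mode,
              seed = as.integer(seed))
  structure(cfg, class = "screen_config")
}

# MD5 of the canonical JSON serialization; used to stamp reports.
config_fingerprint <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(x), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

library_fingerprint <- function(lib) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_library(lib, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the QSAR stage
#'
#' Labels the library, performs the stratified split, trains the forest on
#' the training descriptors, evaluates it on the held-out test set, runs
#' pooled cross-validation on the training set, and fits the applicability
#' domain. When `out_dir` is given, writes `qsar_report.json` (both
#' performance reports, ESP values, thresholds, fingerprints) and
#' `roc_test.csv`.
#'
#' @param library_ Library tibble ([read_library()]); labelled or not.
#' @param descriptors Descriptor matrix covering every library compound.
#' @param config A [screen_config()].
#' @param out_dir Optional output directory.
#' @return Object of class `qsar_run`: list with `model`, `test_report`,
#'   `cv_report`, `domain`, `esp` (named vector: test, cross, mean),
#'   `split`, `config`.
#' @export
run_qsar <- function(library_, descriptors, config = screen_config(),
                     out_dir = NULL) {
  stopifnot(inherits(config, "screen_config"))
  labeled <- if ("label" %in% names(library_)) library_ else
    label_activity(library_, config$plc50_threshold)
  m <- as_descriptor_matrix(descriptors)
  split <- stratified_split(labeled, config$train_fraction, seed = config$seed)
  train_m <- descriptor_rows(m, split$train$compound_id)
  test_m <- descriptor_rows(m, split$test$compound_id)

  model <- train_forest(train_m, split$train$label, n_trees = config$rf_trees,
                        seed = config$seed)
  test_report <- evaluate_classifier(model, test_m, split$test$label,
                                     cutoff = config$prob_cutoff)
  cv_report <- cross_validate(train_m, split$train$label, k = config$cv_folds,
                              n_trees = config$rf_trees, seed = config$seed,
                              cutoff = config$prob_cutoff)
  domain <- fit_apd(train_m, z = config$apd_z)
  esp <- c(test = test_report$specificity, cross = cv_report$specificity)
  esp <- c(esp, mean = mean(esp))

  run <- structure(
    list(model = model, test_report = test_report, cv_report = cv_report,
         domain = domain, esp = esp, split = split, config = config,
         config_hash = config_fingerprint(config),
         library_hash = library_fingerprint(labeled)),
    class = "qsar_run"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    report <- list(
      config = unclass(config),
      config_hash = run$config_hash,
      library_hash = run$library_hash,
      n_train = nrow(split$train), n_test = nrow(split$test),
      esp = as.list(round(esp, 4)),
      apd = list(d_bar = domain$d_bar, sigma = domain$sigma,
                 z = domain$z, threshold = domain$threshold),
      test = performance_payload(test_report),
      cross_validation = performance_payload(cv_report)
    )
    jsonlite::write_json(report, file.path(out_dir, "qsar_report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
    roc <- compute_roc(
      predict_activity(model, test_m),
      split$test$label
    )
    write_roc_csv(roc, file.path(out_dir, "roc_test.csv"))
  }
  run
}

performance_payload <- function(report) {
  list(sensitivity = round(report$sensitivity, 4),
       specificity = round(report$specificity, 4),
       accuracy = round(report$accuracy, 4),
       ppv = round(report$ppv, 4), npv = round(report$npv, 4),
       mcc = round(report$mcc, 4), auc = round(report$auc, 4),
       counts = report$counts)
}

#' @export
print.qsar_run <- function(x, ...) {
  cat("QSAR run (seed ", x$config$seed, ")\n", sep = "")
  cat(sprintf("  ESP: test=%.4f cross=%.4f mean=%.4f\n",
              x$esp[["test"]], x$esp[["cross"]], x$esp[["mean"]]))
  cat("  Test set:\n"); print(x$test_report)
  cat("  Cross-validation (pooled):\n"); print(x$cv_report)
  invisible(x)
}

#' The ESP fusion weight of a QSAR run
#'
#' @param run A `qsar_run`.
#' @param mode `"mean"`, `"test"`, or `"cross"`; defaults to the run's
#'   configured mode.
#' @return Specificity statistic in \[0, 1\].
#' @export
esp_value <- function(run, mode = NULL) {
  mode <- mode %||% run$config$esp_mode
  unname(run$esp[[mode]])
}

#' Run the screening stage
#'
#' Applies [call_actives()] to every docking table, fuses with the QSAR
#' probabilities via [consensus_screen()], applies the strict selection
#' threshold, intersects the required enzymes into the multi-target list,
#' and — when toxicity profiles are given — keeps only risk-free
#' multi-target compounds. Alternatively a prebuilt `consensus` table
#' (e.g. an externally published one) can be supplied, in which case the
#' docking and fusion steps are skipped.
#'
#' @param docking_tables Named list of `docking_table` objects (or `NULL`
#'   when `consensus` is supplied).
#' @param p_activity Named vector of QSAR probabilities (see
#'   [predict_activity()]); required unless `consensus` is supplied.
#' @param esp ESP fusion weight; required unless `consensus` is supplied.
#' @param required_enzymes Enzymes a multi-target compound must hit.
#'   Defaults to all enzymes present.
#' @param toxicity Optional toxicity tibble ([read_toxicity_table()]).
#' @param consensus Optional prebuilt consensus tibble with `compound_id`,
#'   `enzyme_id`, `prob_comb` (and optionally `selected`).
#' @param config A [screen_config()].
#' @param out_dir Optional output directory for `consensus.csv`,
#'   `multitarget.json`, and `final_candidates.csv`.
#' @return Object of class `screen_run`: list with `consensus`,
#'   `multitarget`, `final` (risk-free multi-target tibble), `config`.
#' @export
run_screen <- function(docking_tables = NULL, p_activity = NULL, esp = NULL,
                       required_enzymes = NULL, toxicity = NULL,
                       consensus = NULL, config = screen_config(),
                       out_dir = NULL) {
  stopifnot(inherits(config, "screen_config"))
  if (is.null(consensus)) {
    if (is.null(docking_tables) || is.null(p_activity) || is.null(esp)) {
      stop("supply either a consensus table or docking tables plus ",
           "p_activity and esp", call. = FALSE)
    }
    required_enzymes <- required_enzymes %||% names(docking_tables)
    missing_enz <- setdiff(required_enzymes, names(docking_tables))
    if (length(missing_enz)) {
      stop("no docking table for required enzyme(s): ",
           paste(missing_enz, collapse = ", "), call. = FALSE)
    }
    calls <- do.call(rbind, lapply(docking_tables, call_actives))
    consensus <- consensus_screen(calls, p_activity, esp,
                                  threshold = config$prob_comb_threshold)
  } else {
    if (!"selected" %in% names(consensus)) {
      consensus$selected <- !is.na(consensus$prob_comb) &
        consensus$prob_comb > config$prob_comb_threshold
    }
    required_enzymes <- required_enzymes %||% unique(consensus$enzyme_id)
  }
  multitarget <- if (nrow(consensus)) {
    intersect_targets(consensus, required_enzymes)
  } else {
    tibble(compound_id = character(), mean_prob_comb = numeric())
  }
  final <- multitarget
  if (!is.null(toxicity) && nrow(final)) {
    survivors <- filter_risk_free(toxicity)$compound_id
    final <- final[final$compound_id %in% survivors, , drop = FALSE]
  }
  run <- structure(
    list(consensus = consensus, multitarget = multitarget, final = final,
         required_enzymes = required_enzymes, config = config,
         config_hash = config_fingerprint(config)),
    class = "screen_run"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cons_out <- consensus
    for (col in intersect(c("prob_dc", "p_activity", "esp", "prob_comb"),
                          names(cons_out))) {
      cons_out[[col]] <- round(cons_out[[col]], 4)
    }
    cons_out$selected <- as.integer(cons_out$selected)
    write.csv(cons_out, file.path(out_dir, "consensus.csv"),
              row.names = FALSE, quote = FALSE, na = "")
    jsonlite::write_json(
      list(config_hash = run$config_hash,
           required_enzymes = required_enzymes,
           n_multitarget = nrow(multitarget),
           multitarget = multitarget$compound_id,
           n_final = nrow(final),
           final = final$compound_id),
      file.path(out_dir, "multitarget.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(final, file.path(out_dir, "final_candidates.csv"),
              row.names = FALSE, quote = FALSE)
  }
  run
}

#' @export
print.screen_run <- function(x, ...) {
  cat(sprintf(
    "Screen over enzymes {%s}: %d consensus rows, %d multi-target, %d risk-free\n",
    paste(x$required_enzymes, collapse = ", "),
    nrow(x$consensus), nrow(x$multitarget), nrow(x$final)))
  invisible(x)
}
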