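test_that("library generation honours class sizes and the seed contract", {
  lib <- generate_library(n_compounds = 166, active_fraction = 91 / 166,
                          effect_size = 2, seed = 5)
  expect_identical(sum(lib$compounds$label == "active"), 91L)
  expect_identical(sum(lib$compounds$label == "inactive"), 75L)
  expect_true(all(lib$compounds$plc50[lib$compounds$label == "active"] >= 4.5))
  expect_true(all(lib$compounds$plc50[lib$compounds$label == "inactive"] < 4.5))
  expect_identical(rownames(lib$descriptors), lib$compounds$compound_id)
  expect_true(all(grepl("^(getaway|whim|rdf)_", colnames(lib$descriptors))))

  # relabelling the generated pLC50 values reproduces the planted classes
  relab <- label_activity(lib$compounds[, setdiff(names(lib$compounds), "label")])
  expect_identical(as.character(relab$label), as.character(lib$compounds$label))

  lib2 <- generate_library(n_compounds = 166, active_fraction = 91 / 166,
                           effect_size = 2, seed = 5)
  expect_identical(lib, lib2)
  expect_error(generate_library(n_compounds = 3), "at least 4")
})

test_that("generated inputs serialize byte-identically under one seed", {
  make <- function(dir) {
    lib <- generate_library(n_compounds = 40, seed = 8)
    dt <- generate_docking_tables(lib$truth, enzyme_ids = c("ache", "cht"),
                                  seed = 8)
    tox <- generate_toxicity(lib$compounds$compound_id, seed = 8)
    write_synthetic_inputs(lib, dt, tox, dir)
  }
  p1 <- make(file.path(tempdir(), "syn1"))
  p2 <- make(file.path(tempdir(), "syn2"))
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     info = nm)
  }
  # and the serialized dialects read straight back in
  lib_back <- read_library(p1[["library"]])
  expect_identical(nrow(lib_back), 40L)
  expect_identical(ncol(read_descriptors(p1[["descriptors"]])), 30L)
  expect_named(read_docking_tables(p1[["docking"]]), c("ache", "cht"))
  expect_identical(nrow(read_toxicity_table(p1[["toxicity"]])), 40L)
})

test_that("docking generation couples energies to the planted signal", {
  # null coupling: point-biserial correlation with activity stays small
  r_null <- sapply(1:20, function(s) {
    lib <- generate_library(n_compounds = 120, active_fraction = 0.5,
                            effect_size = 0, seed = s)
    tab <- generate_docking_tables(lib$truth, enzyme_ids = "ache",
                                   coupling = 0, noise_sd = 5, seed = s)$ache
    is_active <- tab$ligands$compound_id %in% lib$truth$active_ids
    cor(tab$ligands$score, as.numeric(is_active))
  })
  expect_lt(mean(abs(r_null)), 0.15)

  # strong coupling: planted actives dominate the top decile of prob_dc
  lib <- generate_library(n_compounds = 300, active_fraction = 0.25,
                          effect_size = 0, seed = 3)
  tab <- generate_docking_tables(lib$truth, enzyme_ids = "ache",
                                 coupling = 40, noise_sd = 2, seed = 3)$ache
  calls <- call_actives(tab)
  ranked <- calls$compound_id[order(-calls$prob_dc, na.last = TRUE)]
  ef <- enrichment_factor(ranked, lib$truth$active_ids,
                          calls$compound_id, fraction = 0.1)
  expect_gt(ef, 2)

  # scores strictly negative, reference inside the distribution
  expect_true(all(tab$ligands$score < 0))
  expect_gt(mean(tab$ligands$score < tab$reference_score), 0.5)

  dt1 <- generate_docking_tables(lib$truth, seed = 4)
  dt2 <- generate_docking_tables(lib$truth, seed = 4)
  expect_identical(dt1, dt2)
})

test_that("toxicity generation hits the requested clean rate", {
  ids <- sprintf("c%04d", 1:1500)
  all_clean <- generate_toxicity(ids, clean_rate = 1, seed = 2)
  expect_identical(nrow(filter_risk_free(all_clean)), 1500L)
  none_clean <- generate_toxicity(ids, clean_rate = 0, seed = 2)
  expect_identical(nrow(filter_risk_free(none_clean)), 0L)

  rate <- 11 / 15
  prof <- generate_toxicity(ids, clean_rate = rate, seed = 2)
  frac <- nrow(filter_risk_free(prof)) / length(ids)
  expect_lt(abs(frac - rate), 0.05)
})
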