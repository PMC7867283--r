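toy_docking_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

test_that("docking tables require exactly one reference row per enzyme", {
  df <- data.frame(
    compound_id = c("l1", "l2", "ref"), enzyme_id = "ache",
    score = c(-120, -150, -90), is_reference = c(0, 0, 1))
  tabs <- read_docking_tables(toy_docking_csv(df))
  expect_named(tabs, "ache")
  expect_identical(nrow(tabs$ache$ligands), 2L)
  expect_equal(tabs$ache$reference_score, -90)
  expect_identical(tabs$ache$reference_id, "ref")

  no_ref <- df; no_ref$is_reference <- 0
  expect_error(read_docking_tables(toy_docking_csv(no_ref)), "exactly one")
  two_ref <- df; two_ref$is_reference <- c(0, 1, 1)
  expect_error(read_docking_tables(toy_docking_csv(two_ref)), "exactly one")
  bad <- df; bad$score <- c("-120", "n/a", "-90")
  expect_error(read_docking_tables(toy_docking_csv(bad)), "row\\(s\\) 2")
})

test_that("docking probability is the energy ratio gated by the reference", {
  expect_equal(round(docking_probability(-217.92, -223.77, -88.38), 4), 0.9739)
  expect_equal(docking_probability(-223.77, -223.77, -88.38), 1.0)
  expect_true(is.na(docking_probability(-80, -223.77, -88.38)))
  expect_error(docking_probability(-100, 0, -88), "non-zero")
  expect_error(docking_probability(-300, -223.77, -88.38), "minimum")
  expect_error(docking_probability(10, -223.77, -88.38), "negative")
})

test_that("probability is monotone in the ligand energy, 1 only at the minimum", {
  e_mlig <- -200; e_inib <- -50
  e <- seq(-200, -60, by = 5)
  p <- docking_probability(e, e_mlig, e_inib)
  expect_true(all(diff(p) < 0)) # less negative energy -> smaller probability
  expect_true(all(p > 0 & p <= 1))
  expect_identical(which(p == 1), 1L)
})

test_that("calling actives scopes the minimum to the supplied table", {
  tab <- docking_table(
    "ache",
    tibble::tibble(compound_id = c("a", "b", "c"),
                   score = c(-150, -180, -70), heavy_atoms = c(20, 30, 10)),
    "ref", -100)
  calls <- call_actives(tab)
  expect_identical(calls$compound_id, c("a", "b", "c")) # order preserved
  expect_equal(calls$prob_dc, c(150 / 180, 1, NA))
  expect_identical(calls$is_potentially_active, c(TRUE, TRUE, FALSE))
  expect_equal(calls$ligand_efficiency, c(-7.5, -6, -7))

  # row order invariance
  tab_rev <- docking_table("ache", tab$ligands[3:1, ], "ref", -100)
  calls_rev <- call_actives(tab_rev)
  expect_equal(calls_rev[order(calls_rev$compound_id), ]$prob_dc,
               calls[order(calls$compound_id), ]$prob_dc)

  # a new best ligand rescales every probability downward
  tab_plus <- docking_table(
    "ache", rbind(tab$ligands,
                  tibble::tibble(compound_id = "best", score = -220,
                                 heavy_atoms = 25)),
    "ref", -100)
  calls_plus <- call_actives(tab_plus)
  shared <- intersect(calls$compound_id[calls$is_potentially_active],
                      calls_plus$compound_id[calls_plus$is_potentially_active])
  for (id in shared) {
    expect_lt(calls_plus$prob_dc[calls_plus$compound_id == id],
              calls$prob_dc[calls$compound_id == id])
  }

  # all ligands above the reference -> zero active calls
  weak <- docking_table(
    "cht", tibble::tibble(compound_id = c("w1", "w2"), score = c(-80, -90)),
    "ref", -120)
  expect_identical(sum(call_actives(weak)$is_potentially_active), 0L)

  # a lone ligand below the reference is its own minimum
  lone <- docking_table(
    "nachr", tibble::tibble(compound_id = "only", score = -150), "ref", -100)
  expect_equal(call_actives(lone)$prob_dc, 1.0)

  empty <- docking_table(
    "ache", tibble::tibble(compound_id = character(), score = numeric()),
    "ref", -100)
  expect_identical(nrow(call_actives(empty)), 0L)
})

test_that("ligand efficiency divides the score by the heavy-atom count", {
  expect_equal(ligand_efficiency(-100, 20), -5)
  expect_equal(round(ligand_efficiency(-88.38, 17), 2), -5.2)
  expect_equal(ligand_efficiency(0, 12), 0)
  expect_error(ligand_efficiency(-50, 0), ">= 1")
})

test_that("random tables agree with a brute-force recomputation", {
  set.seed(77)
  for (i in 1:10) {
    n <- sample(3:12, 1)
    scores <- -runif(n, 60, 250)
    ref <- -runif(1, 60, 250)
    tab <- docking_table(
      "e", tibble::tibble(compound_id = paste0("x", seq_len(n)), score = scores),
      "ref", ref)
    calls <- call_actives(tab)
    for (j in seq_len(n)) {
      expected <- if (scores[j] < ref) scores[j] / min(scores) else NA_real_
      expect_equal(calls$prob_dc[j], expected)
    }
  }
})
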