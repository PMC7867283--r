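test_that("combined probability is the specificity-weighted mean", {
  expect_equal(combined_probability(1, 1, 0.76), 1.0)
  expect_equal(combined_probability(0, 0, 0.4), 0.0)
  for (esp in seq(0, 1, 0.1)) {
    expect_equal(combined_probability(0.5, 0.5, esp), 0.5)
  }
  expect_equal(round(combined_probability(0.9739, 0.62, 0.76), 4), 0.7482)
  expect_error(combined_probability(1.2, 0.5, 0.5), "prob_dc")
  expect_error(combined_probability(0.5, -0.1, 0.5), "p_activity")
  expect_error(combined_probability(0.5, 0.5, 2), "esp")
})

test_that("combined probability is bounded by its inputs and strictly monotone", {
  set.seed(19)
  for (i in 1:200) {
    p_dc <- runif(1); p_act <- runif(1); esp <- runif(1)
    comb <- combined_probability(p_dc, p_act, esp)
    expect_gte(comb, min(p_dc, p_act) - 1e-12)
    expect_lte(comb, max(p_dc, p_act) + 1e-12)
  }
  grid <- seq(0, 1, 0.25)
  for (esp in c(0, 0.5, 1)) {
    for (fixed in grid) {
      expect_true(all(diff(combined_probability(grid, fixed, esp)) > 0))
      expect_true(all(diff(combined_probability(fixed, grid, esp)) > 0))
    }
  }
})

test_that("selection is strict at the 0.5 threshold", {
  res <- tibble::tibble(
    compound_id = c("at", "just", "below"),
    enzyme_id = "ache",
    prob_comb = c(0.5, 0.5000001, 0.4))
  kept <- select_potentially_active(res)
  expect_identical(kept$compound_id, "just")
  expect_identical(nrow(select_potentially_active(res[0, ])), 0L)
})

test_that("consensus table fuses calls with QSAR probabilities", {
  calls <- tibble::tibble(
    compound_id = c("a", "b"), enzyme_id = "ache",
    prob_dc = c(0.9, NA), is_potentially_active = c(TRUE, FALSE))
  p_act <- c(a = 0.8, b = 0.95)
  cons <- consensus_screen(calls, p_act, esp = 0.76)
  expect_equal(cons$prob_dc, c(0.9, 0)) # docking-inactive contributes 0
  expect_equal(cons$prob_comb,
               (cons$prob_dc + 1.76 * cons$p_activity) / 2.76)
  # ceiling for docking-inactive compounds: (1+esp)/(2+esp)
  expect_lt(cons$prob_comb[2], 1.76 / 2.76 + 1e-12)
  expect_error(consensus_screen(calls, p_act[1], esp = 0.76), "b")
})

test_that("multi-target intersection requires every enzyme and ranks by mean", {
  res <- tibble::tibble(
    compound_id = rep(c("x", "y", "z"), each = 3),
    enzyme_id = rep(c("ache", "nachr", "cht"), 3),
    prob_comb = c(0.9, 0.8, 0.7,  # x: all three
                  0.9, 0.9, 0.4,  # y: misses cht
                  0.8, 0.8, 0.8), # z: all three
    selected = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  three <- intersect_targets(res, c("ache", "nachr", "cht"))
  expect_identical(three$compound_id, c("x", "z"))
  expect_equal(three$mean_prob_comb, c(0.8, 0.8))
  # ties broken lexicographically
  expect_identical(three$compound_id[order(-three$mean_prob_comb,
                                           three$compound_id)],
                   three$compound_id)

  two <- intersect_targets(res, c("ache", "nachr"))
  expect_identical(two$compound_id, c("y", "x", "z"))
  # dropping a required enzyme never shrinks the list
  expect_true(all(three$compound_id %in% two$compound_id))
  # intersection is a subset of each per-enzyme selection
  for (enz in c("ache", "nachr", "cht")) {
    sel <- res$compound_id[res$enzyme_id == enz & res$selected]
    expect_true(all(three$compound_id %in% sel))
  }
  # a compound missing an evaluation counts as unselected there
  partial <- res[!(res$compound_id == "x" & res$enzyme_id == "cht"), ]
  expect_false("x" %in%
                 intersect_targets(partial, c("ache", "nachr", "cht"))$compound_id)
  expect_error(intersect_targets(res, character()), "non-empty")
})

test_that("enrichment factor compares top-fraction prevalence to the base rate", {
  all_ids <- sprintf("c%02d", 1:20)
  actives <- all_ids[1:5]
  ranked <- c(actives, setdiff(all_ids, actives)) # perfect ranking
  expect_equal(enrichment_factor(ranked, actives, all_ids, fraction = 0.25), 4)
  expect_equal(enrichment_factor(rev(ranked), actives, all_ids, fraction = 0.25), 0)
})
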