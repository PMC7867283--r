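# consensusVS

Consensus ligand- and structure-based virtual screening for prioritizing
multi-target, low-toxicity bioinsecticide candidates.

## The problem

Plant-derived compounds (e.g. Lamiaceae diterpenes) are screened against
insect pest enzymes — acetylcholinesterase (AChE), the nicotinic
acetylcholine receptor (nAChR), and chitinase (Cht) — with two independent
kinds of evidence per compound: a QSAR classifier trained on compounds with
measured potency (pLC50), and per-enzyme docking energies. Each channel
alone over-calls candidates. `consensusVS` implements the consensus
procedure that turns both into one decision per compound and enzyme, finds
compounds hitting *all* required enzymes, and removes anything with a
predicted toxicity risk.

## The method

* **QSAR channel** — random forest (250 trees, one seed) on a
  molecular-descriptor matrix after a stratified 80/20 split; evaluated by
  sensitivity, specificity, accuracy, PPV, NPV, ROC AUC (Mann–Whitney
  concordance) and the Matthews correlation coefficient
  `MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
  with pooled out-of-fold cross-validation and a Euclidean applicability
  domain `APD = d̄ + Zσ` (Z = 0.5).
* **Docking channel** — a ligand with energy `E_lig` strictly below the
  reference inhibitor's `E_inib` is potentially active with probability
  `Prob_Dc = E_lig / E_mlig ∈ (0, 1]`, the ratio to the best energy of the
  screened set.
* **Consensus** — `Prob_Comb = (Prob_Dc + (1+ESP)·P_Activity) / (2+ESP)`,
  where `P_Activity` is the QSAR probability and ESP the model's
  specificity; selection requires `Prob_Comb > 0.5` strictly. Multi-target
  candidates must be selected for every required enzyme and are ranked by
  mean `Prob_Comb`.
* **Toxicity filter** — four ordinal risk parameters (mutagenic,
  tumorigenic, reproductive-effective, irritant); only all-`none` profiles
  survive ("low" already excludes).

Seeded synthetic generators (`generate_library()`,
`generate_docking_tables()`, `generate_toxicity()`) emulate the assumed
statistical structure so the whole pipeline is testable end to end without
external data. Alignment utilities (`percent_identity()`,
`site_conservation()`) compute the usual active-site conservation
statistics from a supplied multiple alignment. See the vignette
(`vignettes/consensus-screening.Rmd`) for conventions and design choices.

## Worked example

The package bundles a published screen of Lamiaceae diterpenes: per-enzyme
docking tables (with the commercial-insecticide reference rows), the
published combined probabilities, and the four-parameter toxicity profiles
for both the cotton-aphid and fruit-fly candidate sets.

```r
library(consensusVS)

ex <- load_example_screen("aphis")
tox <- load_example_toxicity("aphis")
screen <- run_screen(consensus = ex$consensus,
                     required_enzymes = ex$required_enzymes, toxicity = tox)
screen
#> Screen over enzymes {ache, nachr, cht}: 45 consensus rows, 15 multi-target, 11 risk-free
head(screen$final, 5)
#> # A tibble: 5 × 2
#>   compound_id mean_prob_comb
#>   <chr>                <dbl>
#> 1 1836                 0.76
#> 2 1931                 0.733
#> 3 1800                 0.713
#> 4 1804                 0.71
#> 5 1842                 0.71
```

Fifteen diterpenes are selected for all three aphid enzymes; eleven of them
carry no predicted toxicity risk, led by compounds 1836 and 1931. The
fruit-fly set (`load_example_screen("drosophila")`, required enzymes AChE
and nAChR) gives 37 multi-target compounds, 27 of them risk-free.

Training a QSAR model on a synthetic library with a 2σ descriptor effect:

```r
lib <- generate_library(n_compounds = 166, effect_size = 2, seed = 1)
run <- run_qsar(lib$compounds, lib$descriptors, screen_config(seed = 1))
run$test_report
#> Performance report
#>   counts: TP=17 FP=0 TN=15 FN=1
#>   sensitivity 0.9444
#>   specificity 1.0000
#>   accuracy    0.9697
#>   ppv         1.0000
#>   npv         0.9375
#>   mcc         0.9410
#>   auc         1.0000
esp_value(run)  # mean of test and cross-validation specificity
#> [1] 0.9917355
```

The held-out test set (18 actives, 15 inactives after the stratified split
of 166 compounds) is classified almost perfectly at this effect size;
`esp_value()` is the weight the consensus formula gives the QSAR channel.

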