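---
title: "Consensus virtual screening: model, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus virtual screening: model, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consensusVS)
```

## The problem

Screening a natural-product library for bioinsecticide candidates against an
insect pest typically produces two independent lines of evidence per
compound: a ligand-based one (a QSAR classifier trained on compounds with
measured potency, here pLC50 against the pest) and a structure-based one
(docking energies against the pest's target enzymes — acetylcholinesterase,
the nicotinic acetylcholine receptor, and chitinase). Either channel alone
over-calls: QSAR models extrapolate poorly outside their training chemistry,
and docking scores rank but do not classify. `consensusVS` implements the
consensus procedure that fuses both channels into a single selection
probability per compound and enzyme, intersects selections across enzymes to
find multi-target candidates, and removes compounds with any predicted
toxicity risk.

## The model

**Activity labelling.** A compound is active iff pLC50 ≥ 4.5 (the boundary
value is active); `label_activity()` enforces this and refuses records
without a potency value.

**QSAR channel.** A random forest (250 trees, one seed) is trained on a
molecular-descriptor matrix after an 80/20 stratified split
(`stratified_split()`, per-class test sizes by round-half-even, membership
by a seeded per-class shuffle). Performance is reported as sensitivity,
specificity, accuracy, PPV, NPV, the Matthews correlation coefficient

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},$$

and the ROC AUC computed as the Mann–Whitney concordance (ties counted one
half); `compute_roc()`'s step curve integrates to the same number, and the
test suite holds the two routes to each other at 1e-9. When a marginal of
the confusion matrix is zero the MCC denominator vanishes; we return 0,
reading an undefined coefficient as "random forecast". Cross-validation
(`cross_validate()`, stratified folds, default k = 10) pools the out-of-fold
probabilities into a single confusion matrix scored once, rather than
averaging per-fold metrics — a published performance table with one value
per metric is only reproducible under pooling, and the alternative reading
remains available by scoring folds yourself from the attached out-of-fold
probabilities.

**Applicability domain.** `fit_apd()` implements the Euclidean domain
APD = d̄ + Zσ with Z = 0.5 by default. The phrase "mean distances and
standard deviation of the training set" admits several readings; we use the
most common published procedure: compute all pairwise training distances,
retain those no larger than their grand mean, and take d̄ and σ as mean and
*population* standard deviation of the retained subset (population form so
that a two-compound training set — one retained distance — gives σ = 0
rather than NA). A query is in-domain iff its nearest training neighbour is
within APD; boundary equality is in-domain, and shrinking Z can only shrink
the domain.

**Docking channel.** Docking energies arrive as tables
(`read_docking_tables()`), one per enzyme, each with a single reference row
holding the energy of a commercial insecticide or crystallographic
inhibitor. A ligand is *potentially active* only if its energy is strictly
below the reference; its probability is then

$$\mathrm{Prob_{Dc}} = E_{lig} / E_{mlig} \in (0, 1],$$

the ratio to the best (most negative) energy of the screened set, which
equals 1 only for the best ligand. Two conventions matter and are enforced
rather than assumed. First, energies must be negative: a positive
(repulsive) score would silently push the ratio outside (0, 1], so it is a
validation error. Second, the scope of $E_{mlig}$ is *the table supplied to*
`call_actives()`: when only a published subset of a larger screen is
available, probabilities recomputed from the subset differ from the
published ones, which is why the bundled worked example carries the
published combined probabilities as data rather than recomputing them.

**Consensus.** The two channels fuse as

$$\mathrm{Prob_{Comb}} =
\frac{\mathrm{Prob_{Dc}} + (1+\mathrm{ESP})\,P_{Activity}}{2+\mathrm{ESP}},$$

a convex combination weighting the QSAR probability by the model's
specificity statistic ESP — the channel that controls false actives gets
more say when the model is good at rejecting inactives. This is the only
reading of the formula that keeps the result in [0, 1] for all inputs, and
it makes the combined probability strictly increasing in both channels and
bounded between them. ESP itself is configurable (`esp_mode`): the test-set
specificity, the cross-validation specificity, or their mean (the default).
Compounds failing the docking energy gate enter with
$\mathrm{Prob_{Dc}} = 0$ instead of being dropped, capping what QSAR alone
can claim at $(1+\mathrm{ESP})/(2+\mathrm{ESP})$. Selection is *strict*:
$\mathrm{Prob_{Comb}} > 0.5$, so a compound at exactly 0.5 is excluded.
A multi-target candidate (`intersect_targets()`) must be selected for every
required enzyme; the ranking is by mean combined probability over those
enzymes, descending, ties broken by compound id (the ordering is not
otherwise determined and needs to be reproducible).

**Toxicity filter.** Four ordinal risk parameters (mutagenic, tumorigenic,
reproductive-effective, irritant) at levels none/low/high. The filter keeps
only all-none profiles: a single *low* excludes — the bundled fruit-fly
example pins this down, since its one low-irritant compound is absent from
the published clean list. "No" and "None" parse to the same level.

**Conservation statistics.** From a supplied multiple alignment,
`percent_identity()` counts identical columns over columns where at least
one of the pair has a residue (gap–gap columns excluded; an optional flag
also trims terminal-gap regions, the usual "unshared ends" convention), and
`site_conservation()` maps active-site positions given in the template's
ungapped 1-based coordinates (the convention of residue labels like W245)
to alignment columns and scores the query, a query gap counting as not
conserved. Alignment construction is out of scope; published identity
values for specific species pairs require the original sequences and are
not targets.

## The synthetic generator

`generate_library()` emulates the statistical structure the pipeline
assumes, not chemistry: actives draw pLC50 uniformly on [4.5, 7], inactives
on [2, 4.5); descriptors form three correlated Gaussian blocks named after
the GETAWAY/WHIM/RDF descriptor families (within-block correlation 0.3,
unit variance), with a random quarter of the columns shifted by
`effect_size` standard deviations in actives. Defaults are the worked
example's conditions: 166 compounds, 91 active. `generate_docking_tables()`
couples energies to the latent signal (pLC50 − 4.5): baseline N(−150, 25)
on the MolDock magnitude scale, minus `coupling` per signal unit, plus
N(0, `noise_sd`) noise, clamped strictly negative; the reference energy
sits at the 0.85 quantile of the generated distribution, so roughly 85% of
ligands pass the energy gate — the permissive regime a real screen against
a weak commercial reference shows. `generate_toxicity()` makes a compound
all-clean with probability `clean_rate` (default 11/15, the worked
example's clean fraction), otherwise flags at least one random parameter.

What passing on this generator shows: that the pipeline recovers planted
signal at realistic operating points (null descriptors give chance AUC;
3σ separation is solved; the end-to-end screen enriches planted actives at
least two-fold at 2σ descriptors, coupling 10, noise 5, clean rate 0.7,
n = 500, averaged over 20 seeds). What it does not show: robustness to
real descriptor distributions (heavy tails, block rank deficiency),
activity-cliff chemistry, or docking-score biases that correlate with
molecular size rather than activity.

## Numerical and design choices

* Problem sizes in the test suite (n = 200 for the single-channel AUC
  suites, n = 500 for the end-to-end suite, 20 seeds each) were chosen once
  as the smallest sizes at which the binomial noise of the measured
  quantities is small against the stated bands.
* All randomness flows from explicit integer seeds; per-fold forests use
  `seed + fold`. Reports embed an MD5 fingerprint of the configuration and
  of the labelled library so that two runs can be compared by hash.
* Duplicate compound ids are rejected at ingestion rather than aggregated:
  how repeated potency measurements were merged upstream is unknowable from
  a curated table, and silently averaging would fabricate a convention.
* Constant descriptor columns are dropped with a warning before training;
  they carry no signal and some forest implementations mishandle them.
* The probability cutoff for classification metrics is 0.5, the natural
  choice for a probability-output classifier; it is a parameter, not a
  constant.
* Heavy-atom counts for ligand efficiency are taken as supplied; published
  efficiency columns computed with unknown counting conventions are not
  reproduced digit-for-digit and are not asserted against.
* The orchestration layer is the R API itself (`screen_config()`,
  `run_qsar()`, `run_screen()`), each stage reading and writing standalone
  CSV/JSON artifacts so that externally produced tables (published docking
  or consensus tables) can enter mid-pipeline; a shell wrapper would add a
  dependency without adding capability for an analysis package.

## Known limitations

* The consensus weight ESP is a single scalar per model; per-enzyme or
  per-chemotype weights are not supported.
* The docking probability is scale-dependent through $E_{mlig}$: adding a
  stronger ligand to a table rescales every probability downward. This is
  inherent to the normalization, documented, and tested, but it means
  probabilities are comparable only within one screened table.
* The applicability domain is fit in the full descriptor space with
  unweighted Euclidean distance; descriptors on wildly different scales
  should be standardized upstream.
* `read_library()` validates structures syntactically only; no chemical
  standardization is performed.
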