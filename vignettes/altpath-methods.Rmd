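---
title: "Methods: activity-call pathway analysis, alteration patterns and condition networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activity-call pathway analysis, alteration patterns and condition networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altpath)
```

## The model

`altpath` compares two sample groups on a *binary* representation of gene
activity. Each microarray probe carries a detection call — Present, Marginal
or Absent — and a gene is **active** in a sample when at least one of its
probes is Present there. Marginal calls count as inactive: only Present is
ever defined as evidence of activity, and Marginal is ambiguous in practice,
so the conservative reading is made explicit rather than left to chance.
Working on calls instead of intensities trades effect-size information for
robustness: absent transcripts produce low, noisy intensities whose fold
changes are meaningless, and calls transfer across array platforms far better
than intensities do.

The statistical model behind the gene step is that, within a group, a gene's
activity indicators are exchangeable Bernoulli draws with a group-specific
probability. Under the null the two probabilities are equal, and conditioning
on the margins of the 2×2 activity table gives the hypergeometric
distribution of the first cell — the Fisher exact test, applied once per
tail. Because both one-sided p-values include the observed table,
`p_left + p_right ≥ 1`, and the three classes (group1-active, group2-active,
not significant) are mutually exclusive at any α ≤ 0.5.

The pathway step treats the resulting gene classes as colours on the
measured-gene universe and asks, per pathway and per direction, whether the
pathway's share of coloured genes exceeds the genome-wide share — again a
one-tailed Fisher test. Two properties deserve emphasis:

* the **universe** `N` is the set of measured genes (genes with at least one
  mapped probe), not the union of pathway members. This is the standard
  enrichment background; the pathway-union alternative can be supplied via
  the `universe` argument of `classify_pathways()`.
* **no multiple-testing correction** is applied at the gene or pathway stage
  by default; the method is defined on raw p < 0.05 thresholds and the
  pathway stage consumes the classes, not the p-values. A `fdr = TRUE`
  switch exists in `classify_genes()` for users who want it. The
  crosstalk-network stage, in contrast, is explicitly FDR-controlled.

## Gene-pair alteration patterns

For a gene pair (A, B), each sample occupies a joint state `00/01/10/11`
(A's bit first). A transition `X→Y` is tested by conditioning on the samples
occupying `X` or `Y` in each group and testing, with a one-tailed Fisher
test, whether `X` is over-represented in group 1 relative to group 2 — the
fingerprint of a shift from `X` to `Y` between conditions. All 12 ordered
transitions are tested for eligible pairs: the worked example that motivates
this module reports significance for one-bit and concordant transitions as
well as inverse ones, which implies a full scan rather than a Pattern-4-only
test. Pattern types are a pure function of the transition: one bit changed
(type 2, 8 transitions), both concordant `00↔11` (type 3, 2), both inverse
`01↔10` (type 4, 2).

Decisions made where the procedure was under-specified:

* **Eligibility gate.** Pairs whose two genes are both NS in the gene step
  are assigned Pattern 1 without testing; `gate = FALSE` lifts this.
* **Tie-break.** Equal minimal p-values resolve lexicographically on
  `(from, to)`. Ties do occur with discrete data, so the rule is explicit
  and deterministic.
* The transition test conditions on the two states involved only, exactly
  mirroring the four-count construction (S1–S4) given for the inverse
  pattern.

## Greedy equivalence search on activity data

Condition-specific gene networks are learned by GES over the group's binary
activity matrix. The local model is a *saturated Bernoulli conditional
table*: the score of a node with k parents is its conditional log-likelihood
minus `PD · (2^k / 2) · ln(n)`, where the penalty discount PD multiplies the
BIC complexity term (the TETRAD convention; default PD = 6, `depth = -1`
meaning no cap on parent-set size). Activity calls are the package's native
currency, so the discrete score is the natural choice; a Gaussian score over
intensities is out of scope. The search is the two-phase
equivalence-class algorithm: forward Insert operators (validated by the
clique and blocked-semi-directed-path conditions) while the score improves,
then backward Delete operators, with the CPDAG recompleted after every
operator via a consistent extension (Dor–Tarsi) followed by v-structure
orientation and the Meek rules R1–R3. Determinism: genes are scanned in
lexicographic order and ties keep the first candidate. Zero-variance genes
are dropped with a warning (they carry no structure) and re-enter the result
as isolated nodes. The implementation is practical to a few hundred nodes;
the test suite exercises it up to tens of nodes, with 3-node systems checked
exhaustively against all 25 DAG scores.

## Pathway expansion and the crosstalk network

Expansion adds to each pathway every network neighbour of its members,
*including* undirected CPDAG edges — those are orientations the data cannot
decide, and the expansion rule is adjacency-based in both directions anyway.
Three rounds per condition network produce 7 collections (1 raw + 3 + 3).
Re-testing uses the same gene classes and universe, so collection-to-
collection differences isolate the networks' contribution. Expansion
inflates membership and with it significance; reports therefore default to
the one-step collections, and step-k sets are exactly the k-ball of the raw
set in the network's adjacency graph (a property the tests assert).

The crosstalk network tests every unordered pair of Step-2-significant
pathways for membership overlap. The overlap p-value is the hypergeometric
upper tail `P(X ≥ nab)` with `nall` the size of the pathway-union gene set.
Two variants are implemented because the truncated sum is sometimes printed
with its lower index at 1 instead of 0; the two differ by exactly the point
mass `P(X = 0)`, and the upper-tail (`standard`) form is the default since
it is the named test. The multiple-testing family is the set of pairs
actually tested, and Benjamini–Hochberg q-values (step-up, implemented
explicitly and cross-checked against `stats::p.adjust`) gate the edges at
q < 0.05.

## Robustness analysis

With groups of very different size (the motivating design has ~3.5× more
group-1 samples), `run_robustness()` repeatedly subsamples the larger group
to the smaller group's size *without replacement* — the procedure describes
random selection of a fixed number of samples, not a bootstrap — re-runs both
classification steps, and summarises per-iteration call counts, the overlap
of subsample calls with full-data calls, and the Pearson correlation between
the subsample's and the full run's per-pathway `−log10 p` vectors per
direction. The correlated quantity is a package decision: the method's only
continuous per-pathway output is the p-value, and `−log10 p` is the scale on
which enrichment strength is usually read.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with known truth:

* `simulate_activity()` — per-gene, per-sample independent Bernoulli
  activity; planted genes get a probability gap of `effect`, half more
  active in each group. Defaults mirror the motivating study's design at
  reduced gene count: balanced 43 + 43 samples (150 vs 43 for the imbalanced
  robustness design), baseline activity 0.3, effect 0.4, 50 planted genes
  among `n_genes = 1000`. The gene count is the one scale knob the design
  leaves open; 1000 keeps the planted fraction (5%) and the pathway-size to
  universe ratio in a realistic regime while keeping the full suite fast.
* `simulate_pma()` — emits the probe layer: an active cell always gets at
  least one Present probe; inactive cells get Marginal/Absent with a
  spurious-Present probability `flip_prob` per probe, so recovery
  disagreement has the closed form `1 − (1 − flip_prob)^k`.
* `simulate_pathways()` — 50 sets of 15–40 genes, 5 of them drawing half
  their members from the planted genes.
* `simulate_dag_data()` — ordered Erdős–Rényi DAGs (or an explicit edge
  list) with majority-vote binary CPDs of strength `cpd_strength`
  (a single parent is copied with that probability), sampled ancestrally.

What the generator does **not** emulate matters for interpreting green
tests: real detection-call data have heavily bimodal activity rates (most
genes are active in nearly all or nearly none of the samples), correlated
genes within pathways, probe-quality heterogeneity and platform-specific
call biases. The flat Bernoulli null used here is *harder* than real data in
one specific way: every null gene sits at the same intermediate activity
level, which maximises borderline calls that flicker between a subsample
and the full data. Robustness overlap proportions around 0.9 under this
null correspond to the high-90s overlap seen on real data, where null genes
are near-degenerate and essentially never called. Passing tests demonstrate
the statistics and algorithms are correct under the stated model, not that
any particular biological dataset will behave identically.

## Numerical and interface choices

* Exact tails come from `stats::phyper`; test oracles re-derive them by
  explicit binomial-coefficient summation, keeping implementation and check
  independent. Agreement is asserted to 10⁻¹² over all 2×2 tables with
  total ≤ 40 and all overlap configurations with `nall ≤ 60`.
* Degenerate tables (an empty row or column) return p = 1 — the observed
  table is then the only one possible.
* `0 · log 0 = 0` in all likelihood terms; GES accepts an operator only on a
  strict score gain (> 10⁻¹⁰) so exact plateaus terminate.
* Group roles are explicit (`group1` names the label playing the
  "primary" role); every symmetric claim is tested via `swap_groups()`.
* All randomised operations take an integer `seed` (default 1) and are
  byte-deterministic given it.
* Problem sizes in the test suite: the acceptance checks run 200 null
  replicates of 2000 genes, 20 planted-recovery seeds at 1000 genes,
  20 chain-recovery fits at n = 2000 and 50 exhaustive 3-node comparisons;
  the whole suite completes in well under a minute of CPU.

## Known limitations

* Genes measured on a single platform are kept with Absent fills by default
  (`merge_pma_tables(require_all_platforms = TRUE)` drops them); there is no
  probe-quality weighting.
* The saturated conditional table limits practical parent-set sizes
  (score tabulation is capped at 12 parents); very dense networks need a
  positive `depth`.
* The crosstalk network does no community detection; cluster structure is
  left to visual inspection in Cytoscape.
* Raw-threshold gene/pathway classification is intentionally uncorrected;
  users comparing many pathways across many conditions should treat the
  per-pathway flags as screening, not confirmatory, calls.
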