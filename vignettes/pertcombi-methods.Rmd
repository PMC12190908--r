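---
title: "Methods: from perturbation proteomes to drug-combination candidates"
author: "pertcombi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from perturbation proteomes to drug-combination candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis problem

`pertcombi` implements a desk-scale analysis pipeline for perturbation
proteomics in cancer cell lines. The experimental design it models is:
treat a cell line (the motivating use case is high-grade serous ovarian
cancer) with a panel of small-molecule inhibitors at their IC50, measure the
proteome of treated and DMSO-control samples in biological triplicate, and
ask which proteins and protein modules respond to each drug. Responses that
are *pro-proliferative and up-regulated* (or *anti-proliferative and
down-regulated*) after treatment are candidate resistance mechanisms; the
pipeline nominates partner drugs against those mechanisms as ranked
combination-therapy candidates. A companion module quantifies tested
combinations from checkerboard viability assays with Chou–Talalay
combination indices.

The pipeline runs as five stages over plain TSV/SIF/GMT inputs:

1. **response** — per-protein differential response vs batch-matched DMSO;
2. **modules** — NetBox-style seed + linker module detection on one or more
   background interaction networks;
3. **enrich** — hypergeometric over-representation per module and preranked
   GSEA per drug;
4. **nominate** — functional scoring, mechanism flagging, candidate ranking;
5. **synergy** — median-effect fits and combination indices (standalone).

## Differential response

For each drug condition, each protein's log2 intensities from the treated
replicates are compared with the DMSO replicates of the same batch using a
two-sided unpaired t-test; the effect size is the log2 expression ratio
(`log2ratio`, difference of group means on the log2 scale). q-values are
Benjamini–Hochberg within each condition, because each drug is its own
contrast.

A protein is **strongly responsive** when
|log2ratio| ≥ 0.5 *and* nominal p < 0.05 *and* BH q < 0.2 — the conjunction
of the magnitude and significance rules used throughout the pipeline. The
network **seed list** uses the stricter nominal p < 0.01 with
|log2ratio| > 0.5 and no FDR condition. A protein is **frequently
responsive** when it is strong in ≥ 4 conditions; these are interpreted as
general stress/resistance responses rather than drug-specific signals, and
they are reported but not used for module detection.

Choices worth making explicit:

* **Pooled vs Welch.** The default is the pooled (equal-variance) two-sample
  t-test. With balanced biological triplicates measured under a single
  protocol, homoscedasticity is a reasonable working assumption, and at
  n = 3 + 3 the pooled test has exact power 0.95 against a 1.0 log2 shift at
  replicate SD 0.25, versus ≈ 0.88 for Welch — the difference decides
  whether a realistically-sized planted effect is recovered at the ≥ 90%
  level the test suite demands. `var_equal = FALSE` switches to Welch.
* **Degenerate variance.** If the pooled variance is exactly zero, a nonzero
  mean difference is decisive evidence: p is set to the smallest positive
  double rather than NA, so a clean 1.0-unit shift with identical replicate
  values is classified strong, not dropped.
* **Missingness.** A contrast needs ≥ 2 present values per group, otherwise
  the protein is `untestable` for that condition. The MDS quality-control
  projection (classical Torgerson scaling on Euclidean distances) uses only
  proteins present in every sample, so that distances are comparable.
* **Protein groups.** Each protein group carries one gene symbol (the first
  listed); downstream network and enrichment stages operate on symbols.

## Module detection (NetBox-style)

The module stage re-implements the NetBox idea: start from the altered
("seed") genes, pull in statistically justified connector ("linker") nodes
from a background interaction network, and split the resulting subnetwork
into functional modules.

* **Linker statistic.** For a non-seed candidate with global degree *k* and
  *s* seed neighbors in a network of *N* nodes containing *m* seeds, the
  p-value is the upper-tail hypergeometric probability of drawing ≥ *s*
  seeds when *k* neighbors are drawn from the other *N* − 1 nodes. The
  population is the whole network (the global formulation); candidates are
  all non-seed nodes adjacent to ≥ 1 seed, i.e. path length 1, matching the
  default NetBox shortest-path cutoff. p-values are BH-adjusted across the
  candidate pool and linkers are admitted at q < 0.005, the stringent
  threshold that keeps modules compact.
* **Clustering.** Girvan–Newman divisive clustering (iterative removal of
  maximum edge-betweenness edges), cut at the maximum of Newman–Girvan
  modularity Q over the dendrogram — the algorithm of the original NetBox —
  via `igraph::cluster_edge_betweenness`. Vertices are stored sorted, so
  results do not depend on input row order; module ids are renumbered by
  smallest member symbol. The modularity of an edgeless graph is defined
  as 0, and isolated seeds become singleton modules.
* **Two backgrounds.** Functional-interaction-style and INDRA-style networks
  are analyzed independently and never merged; seeds missing from a
  background are reported in a side list rather than silently dropped.

## Enrichment

* **ORA.** Hypergeometric upper-tail per gene set on each detected module,
  with the universe restricted to genes quantified in the condition
  (proteomics never sees the whole genome, so a genome universe would
  inflate significance); BH across sets.
* **Preranked GSEA.** The per-drug ranking is the seed-list genes ordered by
  decreasing log2ratio — the same input list as module detection. The
  enrichment score is the weighted Kolmogorov–Smirnov running sum with hit
  increments ∝ |score|^1 (weight 1, the conventional default; ties broken
  by gene symbol). Significance is by gene-label permutation: `n_perm`
  random same-size sets, sign-aware comparison (observed ES against
  permuted ES of the same sign), NES = ES / mean(|same-sign permuted ES|),
  and a +1-smoothed permutation p. The FDR is BH on the nominal
  permutation p-values — deliberately simpler than the original
  NES-histogram FDR, and exact to reproduce. Set sizes outside 3–500 after
  intersection with the ranking are skipped. Fixed seeds make every result
  bit-reproducible.

## Functional scores, flags and nomination

Cancer-census-style roles give each gene a functional score: +1 for
oncogenes (pro-proliferative), −1 for tumor suppressors, undefined for
dual-role or unlisted genes. Aggregate scores are means over *defined*
member scores only — a dual-role gene is evidence of nothing, not evidence
of zero.

A mechanism is **flagged** when (score > 0 and direction up) or (score < 0
and direction down) — i.e. the response plausibly protects the cell —
with three evidence kinds: detected modules (requiring |mean log2ratio| ≥
0.5 over measured members), GSEA processes at q < 0.25 (the conventional
GSEA cutoff; direction from the ES sign, same magnitude rule), and
individual strongly responsive proteins with a defined score of matching
sign.

Candidates pair the profiled drug with every annotated drug whose target
matches a flagged mechanism's entity or member gene. Ranking is by clinical
stage (1 = FDA-approved, 2 = clinical trial, 3 = preclinical), then by
evidence magnitude |score × mean log2ratio| (or |log2ratio| for single
proteins), then by partner name — a deterministic total order; the
magnitude key is an artifact decision for reproducibility, since clinical
stage alone leaves ties. A flagged mechanism with no matching inhibitor is
emitted with an empty partner and a "no inhibitor available" note, because
an untargetable mechanism is still a finding.

## Dose-response models and combination indices

Single-agent viability (fraction of the DMSO-control mean) is modeled two
ways:

* **Variable-slope logistic** `v(d) = bottom + (top − bottom)/(1 +
  (d/ic50)^hill)` fitted by least squares on log dose with a deterministic
  multi-start grid (hill ∈ {0.5, 1, 2} × ic50 at the dose quartiles) to
  avoid local minima; the reported IC50 is the relative IC50, halfway
  between the fitted asymptotes. Flat data (no inhibition) is an error, not
  a fit.
* **Median-effect (Chou)** `fa/fu = (D/Dm)^m` with `fa = 1 − viability`,
  fitted as the linear regression of log10(fa/(1−fa)) on log10(D).
  Replicates are averaged per dose before fitting. Wells with fa ≤ 0.01 or
  ≥ 0.99 are excluded (log-odds blow-up), and viability > 1 maps to fa ≤ 0
  and is likewise excluded from this regression (it is retained for the
  logistic fit). When the data truly come from a logistic with top 1 and
  bottom 0 the two models coincide and their IC50/Dm agree within a few
  percent.

The **combination index** for a well at observed fraction affected fa is
the mutually exclusive (Loewe) form CI = d1/DxA(fa) + d2/DxB(fa), with
Dx(fa) = Dm·(fa/(1−fa))^(1/m) from the single-agent fits. A checkerboard
(here 6 × 9 three-fold dilution grids with a DMSO column) is summarized as
the arithmetic mean CI over wells with fa in [0.2, 0.8], the stable
mid-effect range; wells outside the window are counted but excluded.
CI < 1 is called synergistic, > 1 antagonistic. Per-well (non-constant-
ratio) CIs are the right form for a full factorial grid; published
single-number CI tables from other tools may summarize differently, so
exact reproduction of any specific published CI value is out of scope.
Single-agent fits come from dedicated dose-response curves when available,
else from the checkerboard's own single-agent wells.

## Synthetic data: what it emulates and what it does not

Every input kind has a seeded generator, so the whole pipeline is testable
with known ground truth and no downloads:

* **Proteome.** Baseline log2 intensities ~ Normal(25, 2) per protein (a
  typical DIA log2 range; arbitrary but fixed), replicate noise
  Normal(0, 0.25), three replicates per condition, drugs split over two
  batches each with its own DMSO triplicate, and completely-at-random
  missingness (default 5%). Planted effects are additive log2 shifts per
  (gene, condition). The test suite's power checks use a study-scale
  proteome (5,858 proteins with 2,714 planted responders — the scale and
  responsive fraction of a typical IC50-dose perturbation screen) with
  complete 3 vs 3 replicates.
* **Network.** Stochastic-block-model communities (default two of 12 nodes,
  intra-edge probability 0.6, inter 0.02) plus background nodes and planted
  linkers. Linkers are wired to 10 members of their community by default:
  at this small network scale (~56 nodes, 24 seeds) roughly ten seed
  neighbors are needed for a linker's BH-adjusted hypergeometric p to clear
  the stringent 0.005 admission threshold — in a genome-scale background
  the same threshold admits far less connected nodes.
* **Gene sets.** One set per planted community plus size-matched decoys.
* **Roles and drugs.** One community is oncogene-rich (90% oncogene) and
  carries a rank-1 inhibitor of one member; decoys target other genes at
  ranks 2–3.
* **Checkerboards.** Ground truth is defined directly on the CI scale: each
  well's fa solves d1/DxA(fa) + d2/DxB(fa) = α by monotone root finding, so
  a correct CI computation recovers α exactly at zero noise — a closed-loop
  test of the synergy module rather than an independent response-surface
  model. Viability gets multiplicative log-normal noise of a chosen CV.

Features of real data deliberately **not** emulated: intensity-dependent
(informative) missingness, protein-group ambiguity beyond a single symbol
per group, correlated replicate noise and batch effects beyond the two-batch
control split, scale-free network topology, GO-style nested set hierarchies,
and plate-position effects in viability assays. Passing tests therefore
demonstrate correctness of the algorithms under the stated generative
assumptions, not robustness to every real-data pathology.

## Numerical conventions

* BH adjustment everywhere via the standard step-up with monotonicity
  (`stats::p.adjust`); inputs outside [0, 1] are errors.
* Ties: GSEA rankings break score ties by gene symbol; candidate ranking is
  a total order (stage, magnitude, partner, target, evidence); module ids
  are renumbered by smallest member symbol; edge-betweenness ties follow
  igraph's deterministic traversal of the sorted vertex set.
* Degenerate inputs: empty gene lists, missing control batches, flat
  dose-response curves, checkerboards with no well in the fa window, and
  malformed rows in any input format are errors with informative messages —
  never silent NA propagation.
* All simulations take a mandatory seed and are bit-reproducible; pipeline
  reruns with the same config produce byte-identical outputs.
* Test-suite problem sizes: the recovery tests use 20 seeded replicates per
  property (two 12-node planted communities for module recovery; 1,000
  proteins per end-to-end nomination bundle; 200 gene sets × 1,000
  permutations per GSEA-calibration replicate, pooled over 10 replicates so
  the Kolmogorov–Smirnov distance estimates the true deviation from
  uniformity rather than the finite-sample noise floor).

## Known limitations

* The hypergeometric linker population is the whole network; original
  NetBox implementations differ in whether nodes beyond the shortest-path
  cutoff enter the population, which can shift borderline linker p-values.
* GSEA FDR by BH on permutation p-values is conservative relative to the
  NES-histogram FDR for correlated sets.
* The median-effect regression is unweighted, as in the classical method;
  wells near the fa exclusion bounds carry disproportionate log-odds noise,
  which dominates Dm error for very steep or very shallow slopes on coarse
  dilution grids.
* Candidate nomination automates the scoring and ranking logic only; the
  literature review that a practitioner would apply before testing a
  combination is out of scope (an allow/deny list can be applied to the
  candidate table downstream).
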