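# pertcombi

Analysis pipeline for drug-perturbation proteomics in cancer cell lines,
from differential protein response to ranked anti-resistance
drug-combination candidates, plus Chou–Talalay combination-index analysis
of checkerboard viability assays.

## Who this is for

Groups running perturbation-proteomics screens: treat a cell line with a
panel of inhibitors at IC50, measure the proteome of treated and
DMSO-control samples in biological triplicate, and ask which protein
responses look like resistance mechanisms worth co-targeting. The package
takes plain TSV/SIF/GMT inputs, is fully seeded/deterministic, and ships
synthetic-data generators with known ground truth so every stage is
testable without any external download.

## What it computes

1. **Differential response.** Per (protein, drug): log2 expression ratio vs
   the batch-matched DMSO control group, unpaired t-test (pooled by
   default, Welch optional), BH q-values within condition. *Strongly
   responsive*: |log2ratio| ≥ 0.5, p < 0.05, q < 0.2. *Frequently
   responsive*: strong in ≥ 4 conditions (a general stress/resistance
   signature). Classical MDS of samples for QC.
2. **NetBox-style modules.** Seed genes (|log2ratio| > 0.5, p < 0.01) are
   mapped onto a background protein-interaction network; non-seed
   neighbors are admitted as *linkers* when their hypergeometric
   seed-connectivity p-value passes BH q < 0.005 (with `N` network nodes,
   `m` seeds, candidate degree `k`, `s` seed neighbors:
   upper-tail Hypergeom(`s`; `N−1`, `m`, `k`)); the seed+linker subgraph is
   split by Girvan–Newman divisive clustering at maximal modularity Q. Two
   background networks (functional-interaction-style and INDRA-style) are
   analyzed independently.
3. **Enrichment.** Hypergeometric over-representation per module against
   the quantified-gene universe, and preranked GSEA per drug (weighted
   Kolmogorov–Smirnov running sum, weight 1; gene-label permutations,
   sign-aware p; NES = ES / mean |same-sign permuted ES|; BH FDR).
4. **Nomination.** Genes get functional scores (+1 oncogene, −1 tumor
   suppressor, undefined for dual roles); modules/processes/proteins that
   are pro-proliferative-and-up or anti-proliferative-and-down are flagged
   as candidate resistance mechanisms; annotated drugs targeting flagged
   entities become combination partners, ranked by clinical stage
   (FDA-approved first), then evidence magnitude |score × mean log2ratio|.
5. **Synergy.** Median-effect fits fa/fu = (D/Dm)^m per single agent
   (and variable-slope logistic IC50 fits), per-well combination index
   CI = d1/DxA(fa) + d2/DxB(fa) over checkerboard wells with
   fa ∈ [0.2, 0.8], summarized by the mean; CI < 1 synergy, > 1 antagonism.

See `vignettes/pertcombi-methods.Rmd` for the models, assumptions,
parameter defaults and limitations.

## Worked example

Everything below runs offline on a generated study (1,000 proteins, 6
drugs + two-batch DMSO controls, a planted up-regulated oncogene-rich
module and a planted down-regulated tumor-suppressor module for `drug01`,
12 frequently responsive genes, ~10% drug-specific responders per
condition, and two checkerboards simulated at known interaction levels
α = 0.5 and α = 1.5):

```r
library(pertcombi)

dir <- tempfile()
b <- simulate_bundle(dir, seed = 42)

cfg <- list(
  matrix = b$paths$matrix, design = b$paths$design,
  networks = list(fi = b$paths$network_fi, indra = b$paths$network_indra),
  gmt = b$paths$gmt, roles = b$paths$roles, drugs = b$paths$drugs,
  dose_response = b$paths$dose_response,
  checkerboard_dir = b$paths$checkerboard_dir,
  output_dir = file.path(dir, "out"), control = "DMSO",
  linker_q_max = 0.005, thresholds = response_thresholds(),
  ci_window = c(0.2, 0.8),
  gsea = list(weight = 1, n_perm = 1000, seed = 1, min_size = 3,
              max_size = 500, q_max = 0.25))
class(cfg) <- "pipeline_config"

run_response_to_nomination(cfg)   # response -> modules -> enrich -> nominate
run_synergy(cfg, file.path(dir, "out"))

tab <- read_response_table(file.path(dir, "out", "response.tsv"))
table(tab$condition[tab$response_class %in% c("strong_up", "strong_down")])
#> drug01 drug02 drug03 drug04 drug05 drug06
#>    104     85     88     78     87     94
nrow(frequently_responsive(tab))
#> [1] 11
```

`drug01` is the profiled inhibitor with the planted resistance module; its
top-ranked candidates name the planted rank-1 (FDA-approved-like)
inhibitor, supported by all three evidence routes:

```r
cand <- read.delim(file.path(dir, "out", "candidates.tsv"))
head(cand[cand$tested_drug == "drug01",
          c("partner", "target_of_partner", "clinical_stage",
            "analysis_evidence")], 5)
#>          partner target_of_partner clinical_stage          analysis_evidence
#>  inhibitor_rank1            G00004              1          netbox_module:fi:module_1
#>  inhibitor_rank1            G00004              1       netbox_module:indra:module_1
#>  inhibitor_rank1            G00004              1 individual_protein:response:G00004
#>  inhibitor_rank1            G00004              1    gsea_process:gsea:PLANTED_SET_1
#>     decoy_drug_1            G00018              2 individual_protein:response:G00018
```

The synergy subcommand recovers the generated interaction levels from the
6 × 9 checkerboards (5% viability noise, three replicates):

```r
read.delim(file.path(dir, "out", "ci_summary.tsv"))
#>             combination            dataset summary_CI n_wells_used         call
#>     drug01+decoy_drug_1 combo_antagonistic       1.64           21 antagonistic
#>  drug01+inhibitor_rank1  combo_synergistic       0.54           17  synergistic
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/pertcombi.R`
(`pertcombi.R <simulate|respond|modules|enrich|nominate|synergy|all>
--config cfg.yaml`), with the configuration as a single YAML file.

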