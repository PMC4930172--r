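# ffldyn

Stage-resolved transcriptomic analysis of disease progression through
miRNA–transcription-factor (TF) co-regulatory networks.

## The problem

In staged diseases such as myocardial infarction, blood transcriptomes are
profiled at an acute, a subacute and a chronic phase against a single
shared control group. Two questions drive the analysis: *which regulatory
circuits are active at each phase and how do they rewire as the disease
progresses*, and *can a small gene panel drawn from the phase-specific
circuitry serve as a diagnostic signature*. `ffldyn` implements the full
computational pipeline for both, for bioinformaticians who have a log2
expression matrix, curated regulatory interaction catalogs and gene-set
collections in hand.

The regulatory unit is the miRNA–TF **feed-forward loop (FFL)**: a miRNA
*m* and a TF *t* that regulate each other, plus a common target gene *g* —
four typed directed edges (*m→t*, *t→m*, *m→g*, *t→g*). Per stage, motifs
are enumerated over the stage's significantly differentially expressed
(SDE) genes and merged into a network whose nodes are scored by degree and
by betweenness centrality over ordered node pairs,

    BC_i = Σ_{s≠i≠t} σ_i(s,t) / σ(s,t),

where σ(s,t) counts shortest paths and σ_i(s,t) those passing through *i*.
Differential expression uses an empirical-Bayes moderated t with shrunken
variance s̃²_g = (d₀s₀² + df·s²_g)/(d₀ + df) and the screening rule
BH-adjusted p < 0.001 with linear fold change > 1.2; enrichment is a
one-sided hypergeometric test with a minimum-p subpathway collapse; stage
networks are compared by exact-subset (Venn) decomposition of nodes and
edges; and the classifier is Gaussian naive Bayes evaluated by
leave-one-out cross-validation (LOOCV) ROC AUC.

A synthetic-data generator with planted ground truth (DE genes, FFLs,
enriched sets, a two-gene biomarker signal) makes the package
self-contained: every stage has a recovery test that does not depend on
external downloads. See the methods vignette
(`vignettes/ffl-dynamics.Rmd`) for the model, the parameter choices and
their rationale.

## Worked example

The whole analysis runs from one configuration object; with no input
files it simulates its own world (here: 2000 genes, 14 controls vs 28
cases per stage, 10 planted FFLs among 200 decoy edges):

```r
library(ffldyn)
report <- run_pipeline(pipeline_config(sim = sim_config(seed = 1)),
                       out_dir = "ffldyn-run")

report$sde$per_stage
#> # A tibble: 3 × 2
#>   stage n_sde
#>   <int> <int>
#> 1     1   195
#> 2     2    74
#> 3     3    10

report$networks[, c("stage", "n_motifs", "n_nodes", "n_mirnas", "n_edges")]
#>   stage n_motifs n_nodes n_mirnas n_edges
#> 1     1       10      30       10      40
#> 2     2        2       6        2       8
#> 3     3        0       0        0       0

tidy(report$comparison)   # exact-subset (Venn) regions over the 3 stages
#>   region n_nodes n_edges
#> 1      1      24      32
#> 2    1+2       6       8
#> 3  1+2+3       0       0   (empty regions omitted here)

report$classification
#>           panel      task n_train train_auc
#> 1 G00582+G00465 diagnosis      42 0.9464286
#> 2        G00582 diagnosis      42 0.8520408
#> 3        G00465 diagnosis      42 0.9132653
```

Reading the output: SDE counts fall from 195 to 10 across stages because
the planted effect decays (acute phase strongest) — all 10 planted FFLs
surface as stage-1 motifs, forming a 30-node network, while by the chronic
phase too few TFs stay significant to support motifs. The Venn regions
show the stage-2 network nested inside stage 1 (regions `2`, `3` empty;
overlap `1+2` populated). The planted two-gene biomarker panel separates
cases from controls with LOOCV AUC 0.946, beating both single genes —
mirroring the combination-beats-singles pattern such signatures show.

Per-stage tables (DE statistics, SDE lists, enrichment, network edge and
node attributes with degree/betweenness/hub flags, region memberships,
classification) are written as TSV under `out_dir`, along with a
`manifest.json` recording the configuration and md5 of every output.
Rerunning the same configuration reproduces every file byte-for-byte.

Each stage is equally usable on its own — `filter_low_intensity()` →
`moderated_t_test()` / `diffexpr_stages()` → `hcluster_profiles()`,
`hypergeom_enrich()`, `enumerate_motifs()` → `merge_motifs()` →
`centrality_table()`, `venn_decompose()`, `evaluate_panel()` — all take
and return tibbles (or small classed objects with `tidy()` / `glance()` /
`autoplot()` methods) and chain with the pipe.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the installed package's full synthetic pipeline end-to-end at the
default configuration (logging stage summaries to stderr) and writes the
JSON report. The quantitative guarantees of the implementation —
motif-enumeration exactness, betweenness against exhaustive path
counting, BH/hypergeometric exactness, DE calibration and power, Venn
conservation, classifier calibration, byte-level reproducibility — are
asserted by the test suite in `tests/testthat/test-acceptance.R`.
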