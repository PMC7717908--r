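# sineb2 — quantifying SINE B2 RNA processing from paired short- and long-RNA-seq

Mouse SINE B2 elements are high-copy retrotransposon repeats whose Pol III
transcript, B2 RNA (~188 nt), binds RNA polymerase II at stress response
genes and holds their transcription off; cleavage ("processing") of B2 RNA
into short fragments releases that suppression. The processing state of the
B2 RNA pool is therefore a compact readout of stress-response activation,
relevant for example in amyloid-pathology models where processing rises
during active neurodegeneration. No single library measures it: short-RNA-seq
sees the fragments, long-RNA-seq the full-length transcripts. `sineb2` is an
R package for analysts who have both.

## What it computes

**Fragment metagene.** Every primary sense short read overlapping an
annotated B2 locus (subfamilies B2_Mm1a, B2_Mm1t, B2_Mm2) contributes the
element-relative position of its 5′ base to a metagene aligned at the
element start (+1), over positions 1..W (default W = 120). Peaks of this
profile are **processing points** — cleavage sites, the prominent ones near
positions 99 and 33.

**Processing ratio.** Per sample, from five counts:

```
        F / (T / Ns)
ratio = ------------
          B / Nl
```

where `F` = fragment 5′ ends at element positions 95–110, `T` = short reads
with 5′ base within −5..15 of a tRNA start (a Pol III normalizer class),
`Ns`/`Nl` = short/long library totals, `B` = long reads overlapping B2 loci
(full-length B2 abundance). A depth-invariant variant `(F/T)/(B/Nl)` is
provided (`mode = "trna_relative"`).

**Comparisons and the correlation census.** Positional distributions are
compared by two-sample Kolmogorov–Smirnov on the raw positions; group
ratios by unpaired t-tests (pooled or Welch, directional or not). Per-gene
expression is correlated with the per-sample ratio (Pearson, t-transform
p), and genes are classified as strong (r ≥ 0.5), weak (0.25 ≤ r < 0.5) or
none (r < 0.25).

**Simulator with ground truth.** `simulate_cohort()` generates a toy genome
with diverged B2 copies, tRNA loci, and directional short/long reads under
a configurable cleavage landscape and per-group processing fraction, with
every realized count recorded — so the whole pipeline is testable against
known truth, exactly.

## Worked example

```r
library(sineb2)
groups <- data.frame(group = c("WT", "APP"), n_samples = 3,
                     processing_fraction = c(0.05, 0.15))
cohort <- simulate_cohort(groups, seed = 2026)
ratios <- process_cohort(cohort)
ratios[, c("sample_id", "group", "F", "T", "B", "ratio")]
#>  sample_id group   F    T    B     ratio
#>       WT_1    WT  51 1000 1905  323.5615
#>       WT_2    WT  47 1000 1891  300.6687
#>       WT_3    WT  70 1000 1881  450.4725
#>      APP_1   APP 145 1000 1685 1051.2091
#>      APP_2   APP 169 1000 1709 1207.0614
#>      APP_3   APP 142 1000 1713 1011.7090

test <- compare_groups(ratios$ratio, ratios$group, sided = "less",
                       group_order = c("WT", "APP"))
sprintf("APP > WT: t = %.2f, df = %d, p = %.4g", test$t, test$df, test$p)
#> "APP > WT: t = -9.67, df = 4, p = 0.00032"

ev <- extract_events(cohort$alignments[["APP_1"]]$short, cohort$loci,
                     sample_id = "APP_1")
call_processing_points(build_profile(ev))$positions
#> 33 48 89 98
```

The APP-like group, simulated with three-fold higher processing, shows a
~3× higher ratio driven by larger fragment-window counts `F` and slightly
lower full-length counts `B`; the called processing points sit within ±1 of
the simulated cleavage sites {33, 47, 90, 99} (±1 jitter is part of the
generative model). Reading real data instead of simulating replaces
`simulate_cohort()` with `read_repeat_annotation()`,
`read_sample_manifest()` and `compute_sample()`.

## Analysis workflow

The `analysis/` scripts run the same stages as a narrated workflow, writing
tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R        # cohort + ground truth
Rscript analysis/02_fragment_metagene.R      # per-group metagenes, KS, points
Rscript analysis/03_processing_ratio.R       # per-sample ratios, group test
Rscript analysis/04_expression_correlation.R # 11-sample correlation census
```

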