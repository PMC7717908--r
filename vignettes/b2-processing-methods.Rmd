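---
title: "Quantifying SINE B2 RNA processing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying SINE B2 RNA processing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biology and the measurement problem

Mouse SINE B2 elements are retrotransposon repeats present in very many
genomic copies. Their Pol III transcript, B2 RNA (~188 nt consensus), binds
RNA polymerase II at stress response genes and suppresses their
transcription; B2 RNA is also intrinsically unstable and is processed
(cleaved) into short fragments during stress, which releases the suppression.
The processing state of the cellular B2 RNA pool is therefore a biologically
meaningful scalar, but it cannot be read off either sequencing library
alone: a short-RNA library sees the fragments and a standard long-RNA
library sees mostly full-length transcripts. `sineb2` quantifies processing
by integrating the two.

The pipeline has four stages, each exposed as ordinary functions and driven
end to end by the numbered scripts under `analysis/`:

1. **Fragment metagene** (`extract_events()`, `build_profile()`): every
   primary, sense short read overlapping a B2 locus contributes the
   element-relative position of its 5' base to a metagene aligned at the
   element start (+1). Fragment 5' ends pile up at discrete cleavage
   positions — prominently near 99 and 33 — and those peaks are called as
   processing points (`call_processing_points()`).
2. **Processing ratio** (`compute_ratio()`): per sample,
   `(F / (T / Ns)) / (B / Nl)` where `F` counts fragment 5' ends at
   positions 95–110, `T` counts short reads whose 5' base lies within
   −5..15 of an annotated tRNA start (tRNAs are Pol III transcripts not
   regulated by B2 RNA, hence a stable short-library normalizer), `Ns`/`Nl`
   are the short/long library totals, and `B` counts long reads overlapping
   B2 loci (full-length B2 abundance).
3. **Comparisons**: positional distributions are compared with a two-sample
   Kolmogorov–Smirnov test on the raw position samples
   (`compare_profiles()`), group ratios with an unpaired t-test
   (`compare_groups()`).
4. **Correlation census** (`correlate_table()`,
   `classify_correlations()`): per-gene Pearson correlation between
   expression and the per-sample ratio, classified as strong (r ≥ 0.5),
   weak (0.25 ≤ r < 0.5) or none (r < 0.25) over the genes that pass the
   expression and significance screens.

## Coordinate conventions and event mapping

Internally everything is 1-based closed, the GRanges convention; BED input
(0-based half-open) and SAM (1-based) are converted at the boundary. The 5'
base of a plus-strand alignment is its start and of a minus-strand
alignment its end; for a locus on the minus strand the element start is the
locus's genomic end and positions increase toward lower coordinates. A read
is scored only if (i) it is a primary alignment, (ii) it is sense with
respect to the locus (directional libraries; an `antisense` escape hatch
exists via `sense_only = FALSE`), and (iii) its 5' base falls at positions
1..`W` of the element. Reads with a 5' base upstream of +1 are discarded,
not clamped. A read whose 5' base falls inside the windows of two loci is
assigned to the locus whose element start is nearest, breaking ties by
smallest locus id, so each read contributes exactly one event.

`W` defaults to 120 nt. The B2 consensus is 188 nt, but many genomic copies
are truncated; restricting the metagene to the first 120 positions avoids
counting artifacts downstream of short copies while retaining both
prominent processing points and the 95–110 fragment window. `W` can be
raised to 188 for full-length work. Positions are element-start offsets,
not consensus-corrected: per-copy indels shift downstream positions by a
few nucleotides, which is an accepted approximation of a genomic-anchor
metagene and one reason processing points are compared with a ±1 tolerance.

## The ratio estimator and its two modes

The default (`literal`) mode is `(F / (T / Ns)) / (B / Nl)`. Note that
`Ns` enters multiplicatively: scaling the short library by a constant `c`
(F, T and Ns all ×c) scales the literal ratio by `c`. This makes the
literal estimator depth-sensitive across short libraries of very different
sizes. The `trna_relative` mode, `(F / T) / (B / Nl)`, is invariant to
joint scaling of F and T and satisfies `literal = trna_relative × Ns`
exactly; both invariances are asserted as tests. Cohorts produced by the
built-in simulator use equal depths across samples, so either mode orders
groups identically; for real cross-depth comparisons `trna_relative` is
the safer choice and the mode is always recorded on the result. The
bracketing ambiguity between the two readings is deliberate: both are
implemented, neither is asserted to be the "intended" one.

tRNA counting is strand-blind on the read (the offset is computed in the
tRNA's orientation, 0 at the annotated first base) because the upstream
tool that inspired the contract counts plain overlaps. Long-read counting
deduplicates reads spanning several adjacent loci (one read, one count);
`dedup = FALSE` restores a per-locus sum. The group t-test defaults to
Student's pooled variance — the sample sizes in play are 3–4 per group,
where Welch's correction costs more in df than it buys — with Welch
available.

## Processing-point calling

A position is a processing point when it is a maximum over a ±`flank`
(default 2) window and at least `min_frac` (default 0.1) of the profile
maximum. The height floor suppresses single-read noise while keeping minor
sites: with the default simulated landscape {99: 0.5, 33: 0.3, 90: 0.1,
47: 0.1} and ±1 jitter, each minor site carries ~3% of events per position
against a ~17% maximum, comfortably above 10% of max. Plateaus (adjacent
equal qualifying positions) report their smallest position, so a constant
profile yields the single point 1. Point sets from two conditions are
matched greedily nearest-first within ±1 (`diff_processing_points()`),
which reproduces the expected shared/{only-a}/{only-b} split for patterns
like {33, 90, 99} vs {33, 47, 99}.

## KS tests on tied integer data

Positions are integers, so the two-sample KS statistic is computed on
heavily tied data. D — the supremum of the ECDF difference — is exact and
is the primary reported quantity; the p-value uses the asymptotic
Kolmogorov distribution and is approximate under ties. The tests verify D
against an independent ECDF sweep to 1e−12.

## What the simulator emulates, and what it does not

`simulate_cohort()` builds a toy chromosome: B2 copies (consensus 188 nt,
binomial deletions, geometrically truncated tails with probability 0.2,
random strands, ≥1 kb spacing), a downstream tRNA block, and a reserved
background region. Each B2 transcript is processed into a short sense
fragment with the group's processing fraction, its 5' end drawn from the
cleavage landscape with ±1 jitter; unprocessed transcripts become long
reads spanning their locus. tRNA reads start within ±2 nt of a tRNA start;
background reads of both libraries fall only in the reserved region.
Because alignments are emitted directly (no sequence, no aligner), the
pipeline must — and does — recover the realized truth counts *exactly*;
this closure is an invariant, not a statistical statement.

Default depths are modest by design (2000 B2 transcripts, 1000 tRNA reads,
2000 background reads per library): they reproduce the count regimes that
matter (F of tens to hundreds, Poisson-level noise) while keeping the full
test suite and the acceptance script within a few minutes on one core.
Default group fractions 0.05 vs 0.15 encode a three-fold processing
increase, the kind of effect separating a pathology group from controls.

The simulator does *not* model sequencing error, PCR duplicates,
multi-mapping ambiguity (each fragment is emitted at its true locus),
consensus-coordinate drift from indels, or realistic mouse genome
structure. Passing recovery tests therefore demonstrates the correctness
of the quantification logic, not robustness to alignment noise — on real
data the multi-mapping policy (primary alignments only) and the aligner's
placement choices add variance the tests do not exercise.

## Expression simulation and correlation recovery

`simulate_expression()` writes each gene as
`base + amplitude · (r* z + √(1−r*²) e)` with `z` the standardized ratio
vector. With `empirical = TRUE` (default) the noise `e` is residualized
against `z` and rescaled so the *sample* correlation equals `r*` exactly —
the same construction as `MASS::mvrnorm(empirical = TRUE)`. This choice is
what makes class-recovery testing sharp at realistic cohort sizes: at
n = 11 the sampling sd of r̂ is ≈ 0.3, so under population-level
calibration a gene with true r = 0.35 lands in the weak bin barely a third
of the time and no implementation could pass a 90% recovery bar; with
exact calibration, recovery failures indicate real defects in the
correlation or classification code rather than sampling noise.
`empirical = FALSE` provides the population-calibrated variant, which the
tests use for Fisher-z coverage checks. Classification recovery is
assessed with the significance screen disabled (`alpha = 1`): with n = 11,
r = 0.35 is never significant at 0.05, so the screen would empty the weak
bin by construction; the screen's own behaviour is exercised separately.

The per-gene screen (expressed above 0 in all samples, p ≤ 0.05
uncorrected) mirrors a census-style analysis; it is a screen, not an
inference, and `stats::p.adjust()` can be applied to the output table when
FDR control is wanted. The expression floor is configurable
(`min_expr`), as "sufficiently expressed" has no canonical numeric value.

## Numerical and degenerate-input choices

Zero-variance expression or ratio vectors are excluded with an explicit
reason rather than propagating `NaN`. A zero fragment count gives ratio 0;
zero tRNA or long-read counts are an error naming the failing normalizer,
since the ratio is undefined rather than zero. The all-zero profile yields
an empty point set. Percentages in the classification summary are rounded
to one decimal (344/659 → 52.2%, 240/659 → 36.4%, 75/659 → 11.4%). All
generators are pure functions of their seed; cohort per-sample seeds are
derived from the master seed so cohorts are reproducible as a whole.

## Problem sizes used by the test and acceptance runs

Recovery properties are measured at: a 5-point processing-fraction grid
(0.05–0.25, 10 cohorts) for rank agreement; 50 two-group cohorts (n = 4
per group, fractions 0.05 vs 0.15) for directional-test power; 20 runs of
5000 fragments for processing-point recovery; and 200 genes over an
11-sample cohort (2+3+3+3 across four groups) for correlation-class
recovery. These sizes give binomial error bars well inside the asserted
bounds while completing in minutes on a single core.

## Known limitations

Beyond the simulator gaps above: the metagene ignores per-copy indels;
KS p-values under ties are approximate; the literal ratio is not
comparable across short libraries of very different depths; the
correlation census inherits the uncorrected screening character of its
design; and `peak_tss_profile()` summarizes peaks by midpoint (summit
information, when available, is more precise).
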