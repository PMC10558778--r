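---
title: "Methods: isomiR classification and quantitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isomiR classification and quantitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Microprocessor (Drosha + Dgcr8) defines the 5′ end of most mature
miRNAs by cleaving the primary transcript at a fixed position on the
hairpin. When cleavage shifts upstream or downstream — for example when
a hairpin is processed by a different nuclease — the resulting reads
carry extra or missing terminal nucleotides relative to the annotated
mature sequence (*isomiRs*). Because the miRNA seed is positions 2–8, a
5′ shift changes the seed and hence the target repertoire, so the 5′
offset distribution of a miRNA is a biologically meaningful readout,
not a technical artifact.

isomiRq classifies collapsed small RNA-seq reads against hairpin
references with embedded mature coordinates, quantifies canonical and
shifted variants (reads per million, between-condition ratio tables),
summarizes global differential abundance after TMM scaling, and
provides the standard bench-assay formulas used alongside such
experiments. A seeded simulator generates references, read sets and
assay tables with ground truth so that every stage is testable without
external data.

## Classification model

Coordinates are 0-based and half-open throughout: a mature annotated
`[start, end)` on its hairpin has `mature_seq = hairpin[start:end)`.
For a read and a candidate mature, every 5′ offset
$o_5 \in [-k, k]$ (default $k = 5$) is considered by placing the read's
5′ end at hairpin position $\mathrm{start} - o_5$; the 3′ offset is
then forced by the read length,
$o_3 = \ell_\mathrm{read} - \ell_\mathrm{mature} - o_5$, and candidates
with $|o_3| > k$ are discarded. Positive offsets mean extra
nucleotides (cleavage upstream of the reference start), negative mean
missing ones. Mismatches are counted over hairpin-overlapping
positions; read positions overhanging the hairpin each count as one
mismatch. A 5′ extension is *templated* when every extension position
lies on the hairpin and matches it.

Among candidates with `mismatches <= max_mismatch` (default 0: the
terminal-variant isomiRs of interest match the hairpin exactly), the
call minimizes the tuple (mismatches, $|o_5|+|o_3|$, $|o_5|$)
lexicographically. If the minimum is achieved by more than one mature,
the read is reported `ambiguous` and not assigned (configurable to
first-by-reference-order). Within one mature, exact score ties (only
possible with internal sequence repeats) are broken deterministically:
larger $o_5$, then larger $o_3$, then reference order. Reads with no
surviving candidate are `unassigned`.

With `max_mismatch = 0` the implementation uses an exact-match index of
every hairpin window within $\pm k$ of each mature; this is provably
equivalent to enumerating all placements, and the test suite checks the
equivalence against an independent brute-force enumerator. One
consequence of exact matching is that non-templated 5′ additions land
in `unassigned` unless `max_mismatch > 0`; with mismatches allowed, an
assigned read whose only deviation is internal mismatches (zero
offsets) is labelled `other`, since it is neither canonical (which
requires a perfect match) nor an end variant.

## Quantitation

* **Counting.** One row per distinct `(mature, sequence)` pair;
  ambiguous and unassigned reads are excluded.
* **RPM.** Each sample column is scaled to reads per million. The
  denominator is the sample's *classified miRNA* total, because the
  ratio-table analysis lives in miRNA space and raw library totals are
  not generally available for collapsed input; the denominator is the
  column sum, so every non-empty column sums to $10^6$.
* **Condition means and ratios.** RPM is averaged across the replicate
  samples of a condition (normalize first, then average), and the
  case/control ratio of means is reported per variant. The ratio is
  undefined (printed `-`) when the control mean is zero; a zero case
  mean over a positive control mean is a defined ratio of 0. Rows are
  grouped by mature with 5′ extensions first (descending $o_5$),
  mirroring the layout such tables are published in.
* **TMM.** Scaling factors follow the published
  trimmed-mean-of-M-values recipe: for sample $s$ against reference
  $r$, over features positive in both,
  $M = \log_2\frac{y_s/N_s}{y_r/N_r}$,
  $A = \tfrac12\log_2\frac{y_s}{N_s}\frac{y_r}{N_r}$; the top and
  bottom 30% of $M$ and 5% of $A$ are discarded; the factor is
  $2^{\sum w M / \sum w}$ with inverse delta-method-variance weights
  $w = \left(\frac{N_s-y_s}{N_s y_s} + \frac{N_r-y_r}{N_r y_r}\right)^{-1}$.
  The reference is the sample whose upper-quartile count fraction is
  closest to the mean upper quartile, and factors are rescaled to
  geometric mean 1. The test suite verifies agreement with edgeR's
  independent implementation to $10^{-9}$ on random tables.
* **Differential abundance.** Counts are aggregated per mature;
  matures with pooled count below `min_count = 10` are not tested. The
  declared test is an exact conditional binomial on pooled counts: the
  case share of a mature's pooled count is compared with the case
  conditions' share of TMM-adjusted effective library size. Fold
  changes are $\log_2$ ratios of group-mean scaled RPM with a 0.5
  RPM-equivalent pseudocount. BH correction gives the FDR. This is
  deliberately simpler than negative-binomial dispersion modelling;
  consequences are discussed below.

## What the simulator emulates — and what it cannot

`sim_config()` draws per-mature relative abundances from a log-normal
(meanlog 0, sdlog 1.5, spanning roughly the four orders of magnitude
seen across published miRNA RPM tables), multiplies the case
condition's abundances by a per-mature fold-change map, renormalizes to
probabilities, and draws per-sample counts from a negative binomial
with mean `depth * p` and size 20 (moderate biological overdispersion;
`Inf` gives the Poisson limit). Each counted read then draws its
(5′, 3′) offsets from per-condition categorical distributions and is
emitted as the corresponding hairpin window, with optional per-base
substitution error (default 0 so classification recovery is exact).
Synthetic hairpins are flank + mature + flank with uniform random
bases (flank 10 nt, so every offset up to ±5 is templated), rejection
sampled so that no hairpin window within the offset range is shared
between matures — classification of error-free simulated reads is
therefore exact by construction, and the tests assert 100% recovery.

`drosha_loss_scenario()` packages the study conditions this package is
built around: 100 matures, 4 control vs 5 case replicates, expected
depth $10^5$ classified reads per sample, 95% of matures programmed at
least 2-fold down (fold changes uniform in [0.1, 0.5]), a designated
3-mature cluster level-or-slightly-up whose case-condition 5′ offsets
put 40% of mass at +1/+2 nt (upstream cleavage by an alternative
nuclease), and 2 unchanged matures. Control samples carry a small
(5%) −1 trimming fraction, as real libraries do.

Features of real data that are *not* modelled: cross-mapping between
paralogous matures (ambiguity handling is tested only with constructed
collisions), adapter/quality artifacts, 3′ non-templated tailing, and
multi-mature hairpins. Passing tests therefore demonstrate the
correctness of the computations, not robustness to every artifact of
real libraries.

### Compositional limits of the depletion read-out

Sequencing counts are compositional: per-sample totals carry no
absolute scale, and the simulator's renormalization of case
probabilities makes this explicit. When 95% of matures are depleted,
any within-library normalization — library size or TMM — recentres the
fold-change distribution on the depleted majority: most depleted
matures then appear unchanged and the stable minority appears up. On
scenario data the pipeline's detected `pct_down` consequently lands
near 50%, and edgeR's own TMM + exact test behaves the same way on the
identical counts (the acceptance test records both the programmed
truth fraction and the detected value). Recovering a *global* loss
requires an external anchor — spike-ins, a stable co-sequenced RNA
class, or absolute yield measurements — which a miRNA-only count table
cannot provide. This is a property of the data model, not of the
implementation, and it is the main caveat when interpreting
global-depletion summaries from composition-only counts.

### Calibration of the binomial test

The pooled conditional binomial test is exactly calibrated when
within-condition counts are Poisson; its null calibration is therefore
checked in the simulator's Poisson limit (dispersion `Inf`, 500
matures, 4 vs 5 replicates, depth $5 \times 10^5$), where the
empirical type-I error at $\alpha = 0.05$ sits in the expected
slightly-conservative band. Under biological overdispersion the test
is anticonservative — pooled counts ignore replicate-to-replicate
variance — so on real data its p-values should be read as a ranking,
not as calibrated error rates. This is the declared trade-off for
avoiding negative-binomial dispersion estimation, which is out of
scope here.

## Numerical and design choices

* 0-based half-open coordinates everywhere; the annotation dialect is
  declared in this convention.
* DNA input is converted to RNA (`T -> U`) on load; all comparison is
  in RNA space.
* Collapsed-FASTA counts use the fastx `_x<count>` suffix, the de facto
  standard for collapsed small RNA reads.
* Read-length window 18–26 nt by default, spanning the 21–25 nt range
  of published variant tables with margin.
* `max_shift` must be ≥ 2 (the analysis exists to see ±1/±2 shifts);
  the default 5 gives headroom without inflating ambiguity.
* TMM trim fractions are the published defaults (30% M, 5% A); factors
  are invariant to joint rescaling of all columns (the weights scale
  inversely, which the tests check).
* Undefined ratios are serialized as `-` and read back as `NA`;
  write-then-read round-trips values exactly.
* Replicate Cts are averaged (configurable to median) before ΔΔCt.
  Doubling time is the slope of an ordinary least-squares fit of
  ln(count) on time, $T_d = \ln 2 / \hat\beta$, undefined for
  non-positive slopes; $R^2$ is computed directly from residuals so
  noiseless fixtures do not trip the perfect-fit warning. The ChIP
  input adjustment subtracts $\log_2(\text{input fraction})$ from the
  input Ct (default fraction 1/10). The RIP/ChIP enrichments use the
  ΔΔCt form; percent-of-input is a trivial variant the user can
  compute from the same Cts.
* `fraction_distribution()` returns `pct_b = 100 - pct_a` so the two
  percentages sum to exactly 100 in floating point.

## Problem sizes used by the test suite

The suite runs the full scenario (100 matures, 9 samples, $10^5$
reads/sample) once for classification recovery and twenty times for
the depletion summary; null calibration pools 2,500 p-values from five
Poisson datasets of 500 matures; the TMM oracle comparison covers 100
random 50 × 6 tables; assay recovery uses 100 seeded noisy growth
curves. These sizes were chosen to bound Monte-Carlo error on every
asserted quantity while keeping a full run comfortably interactive.

## A worked example

```{r example}
library(isomiRq)

sc <- drosha_loss_scenario(seed = 1)
calls <- lapply(sc$read_sets, classify_reads, ref = sc$reference,
                verbose = FALSE)
counts <- build_count_table(calls, sc$design)
rpm <- to_rpm(counts)
ratio_table(rpm, "control", "case") |> head()

de <- de_test(counts, case = "case", control = "control")
glance(de)        # de_summary()
ggplot2::autoplot(de)  # volcano plot
```

The bundled table
`system.file("extdata", "dn_drosha_isomir_rpm.tsv", package = "isomiRq")`
carries published per-variant mean RPM values; `isomir_ratio()` on its
two RPM columns reproduces the published condition ratios at their
printed precision (see the README and `scripts/acceptance.R`).
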