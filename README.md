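# isomiRq

IsomiR classification and quantitation for small RNA-seq, with the
bench-assay formulas that accompany such experiments.

## The problem

The 5′ end of a mature miRNA is set by where Microprocessor
(Drosha + Dgcr8) cuts the primary-transcript hairpin. When cleavage
shifts — for instance when a hairpin is processed by an alternative
nuclease — reads gain or lose terminal nucleotides relative to the
annotated mature sequence (**isomiRs**). Because the seed is read
positions 2–8, a 5′ shift changes the seed and the miRNA's target
repertoire, so quantifying the per-miRNA 5′-offset distribution between
conditions is a biological measurement in its own right.

isomiRq is for analysts who have (i) hairpin references with embedded
mature coordinates, (ii) collapsed FASTA (fastx `_x<count>` dialect) or
FASTQ small RNA reads, and (iii) a sample → condition design, and who
want reproducible variant-level tables and summaries — or who want to
prototype against fully synthetic data with ground truth.

## What it computes

- **Classification** — each read is placed at every 5′ offset
  `o5 ∈ [−k, k]` relative to each mature start (the 3′ offset
  `o3 = len(read) − len(mature) − o5` follows); the call minimizes
  (mismatches, |o5|+|o3|, |o5|) lexicographically, ties across matures
  are `ambiguous`. Positive offsets = extra (upstream) nucleotides;
  templated status, seed and seed-shift are reported.
- **Quantitation** — per-variant counts; RPM (columns sum to 10⁶ over
  classified reads); per-condition means; case/control ratio tables
  with `-` for undefined ratios; TMM scaling factors per the published
  trimmed-mean-of-M-values recipe
  (M-trim 30%, A-trim 5%, inverse-variance weights, geometric mean 1);
  a per-mature differential-abundance test (exact conditional binomial
  on pooled TMM-scaled counts) with BH FDR and a down/up/2-fold
  summary.
- **Assay formulas** — ΔΔCt fold change `2^−ΔΔCt`, in-vitro processing
  activity `(pre/(pre+pri))/protein`, RIP fold enrichment (ΔΔCt over
  IgG), ChIP fold enrichment over fraction-adjusted input, doubling
  time `Td = ln2/slope` from log-linear OLS, nuclear/cytoplasmic
  percent distribution.
- **Simulation** — seeded synthetic hairpin references (rejection
  sampled to be unambiguous within the offset range), log-normal
  abundances, negative-binomial replicate counts, per-condition
  categorical 5′/3′-offset distributions, optional per-base error, and
  exact truth tables; `drosha_loss_scenario()` packages a
  global-depletion study (100 matures, 4 vs 5 replicates, 95%
  programmed ≥ 2-fold down, a 3-mature cluster with case-specific
  +1/+2 5′ shifts).

## Worked example

The bundled table transcribes published per-variant mean RPM values for
the miR-183/96/182 cluster and control miRNAs in cells expressing
full-length versus N-terminally truncated Drosha. Feeding its RPM
columns to `isomir_ratio()` reproduces the published ratios:

```r
library(isomiRq)
tab <- read_isomir_table(system.file("extdata", "dn_drosha_isomir_rpm.tsv",
                                     package = "isomiRq"))
tab$ratio <- round(isomir_ratio(tab$mean_rpm_control, tab$mean_rpm_case),
                   tab$printed_digits)
subset(tab, mature_id %in% c("miR-183-5p", "miR-21-5p"))
#>   mature_id offset5 length_nt mean_rpm_control mean_rpm_case ratio
#>  miR-183-5p       2        24            4.653        50.750 10.90
#>  miR-183-5p       1        23            1.338         9.896  7.40
#>  miR-183-5p       0        22         1566.000      2122.000  1.40
#>  miR-183-5p      -1        21          353.500       543.100  1.50
#>   miR-21-5p       1        23            0.000         0.000    NA
#>   miR-21-5p       0        22         2641.900       223.600  0.08
#>   miR-21-5p      -1        21            0.000         0.000    NA
```

The +1/+2-extended miR-183-5p variants are enriched ~7–11-fold in the
truncated-Drosha condition while canonical miR-21-5p drops to 0.08 —
the 5′-shift signature the classifier is built to detect. On synthetic
data the whole path runs from reads to calls:

```r
sc <- drosha_loss_scenario(seed = 1, n_matures = 20, depth = 2e4)
calls <- classify_reads(sc$read_sets[["case_1"]], sc$reference)
#> classified 20247 reads: canonical=16985, iso5=3262
head(calls[, c("read_sequence", "count", "mature_id", "offset5", "category")], 3)
#>   read_sequence           count mature_id   offset5 category
#> 1 AAAACAACUCAAUUAGUCCUA     370 syn-mir-013      -1 iso5
#> 2 AACCCAUGAUGCCCCGUUUCUAG   174 syn-mir-001       1 iso5
#> 3 AAGCUUAAGAACACUGAUUAG       6 syn-mir-019      -1 iso5
```

and the assay helpers are one-liners:

```r
ddct_fold(20, 15, 24, 15)
#> [1] 16
doubling_time(c(8, 16, 24, 32, 40), 1e5 * 2^(c(8, 16, 24, 32, 40) / 20))
#> Exponential growth fit: rate = 0.03466 /h, Td = 20 h, R2 = 1.000
```

`run_pipeline()` (or `inst/scripts/isomir-pipeline.R` from a shell)
chains classify → count → RPM → ratio table → TMM → test → summary and
writes every stage plus a manifest; reruns with the same configuration
are byte-identical.

## Documentation

The methods vignette (`vignettes/isomir-quantitation.Rmd`) describes
the classification model, the TMM and testing choices, the simulator's
generative model, and known limitations.
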