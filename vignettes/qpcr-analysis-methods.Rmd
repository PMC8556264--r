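---
title: "Methods: replicate filtering, quantification models and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replicate filtering, quantification models and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrflow)
```

# The analysis problem

A qPCR results export is a table of wells: each row carries a sample name, a
target (gene, amplicon or genomic region), a task (unknown, standard, or
no-template control), and a cycle-threshold (CT) value. Technical replicates
of the same sample × target must be reconciled, normalized against
endogenous controls, and turned into relative or absolute quantities before
any biology can be read off. `qpcrflow` implements that path as a
deterministic pipeline: the same input and configuration always produce the
same output files, byte for byte.

## Reading exports

Thermocycler exports vary: metadata preambles of arbitrary length, differing
header spellings ("CT" vs "Cq", "Target Name" vs "gene"), comma- or
tab-separated. The reader scans for the first line whose cells match all
mandatory fields (well, sample, target, CT) under a normalized
(lowercase-alphanumeric) alias match, and treats everything above it as
preamble. The alias table — target also matches "gene", CT also matches "Cq"
— is a reconstruction of common instrument vocabularies, and any mapping can
be overridden per file. CT cells reading "Undetermined", "N/A" or empty
become missing values: they are excluded from replicate groups with a logged
warning rather than imputed, because assigning them the maximum cycle count
would bias every downstream RQ. Comma-decimal exports are rejected with a
pointed error rather than silently misparsed. A missing Task column demotes
every well to UNKNOWN with a warning; no-template-control (NTC) wells are
carried but never quantified.

# Replicate filtering

Two rules, applied to each sample × target group within one input file:

1. **CT-SD cut-off with recursive removal.** If the group's CT standard
   deviation (sample estimator, n − 1 denominator) exceeds
   `ct_sd_cutoff` (cycles, default 0.3 — the conventional agreement
   threshold for technical triplicates), the replicate furthest from the
   group mean is moved to the outlier set, and the test repeats on what
   remains. Removal stops when the CT-SD passes, or when the budget
   `n − ceiling(n × max_proportion)` is spent (`max_proportion` default 0.5:
   a triplicate loses at most one member).
2. **Preserve highly variable groups.** Evaluated once, on the initial
   group: if CT-SD exceeds the cut-off but |mean − median| / median <
   `preserve_ratio` (default 0.1), the group is kept whole. This captures
   the case of three replicates spread almost symmetrically around the mean,
   where no single well is the outlier and removal would be arbitrary.

Numerical choices where the rules leave freedom:

- The group mean is **recomputed after every removal** (the "furthest from
  the sample mean" candidate is judged against the current retained set).
  The alternative — distances frozen against the initial mean — changes
  results only for multi-removal groups; recomputation is the natural
  reading of a recursive rule and is what the tests' exhaustive-search
  oracle encodes.
- The preserve rule is **not re-evaluated after removals**: it is an
  all-or-nothing verdict on the group as measured.
- **Tie-break**: two replicates equidistant from the mean — the one with
  the larger CT goes (deterministic; large CT is the low-template,
  high-variance side).
- **Pairs are never split.** Both members of an n = 2 group are equidistant
  from their mean, so any removal is arbitrary; a high-SD pair is kept and
  flagged in the log. Note a side effect of the preserve rule: a high-SD
  pair always has mean = median, so with the rule on it is "preserved" by
  construction.
- The preserve ratio divides by the group median (raw CT scale, typically
  15–30 cycles), so single-replicate offsets of a few cycles can still pass
  the preserve gate. That is intended behaviour of the published rule —
  it keeps ambiguous, low-expression groups — but it means the filter's
  outlier *detection* is best characterised with the preserve rule off,
  which is how the recall properties in the test suite are measured.

The filter's budget rule also makes unconditional idempotence impossible: a
group that stops on the budget with CT-SD still high would get a fresh
budget if refiltered. Re-filtering a retained set removes nothing further
whenever filtering stopped at the SD rule, and the tests assert exactly
that.

# Quantification models

All models compute per-replicate normalized values first and aggregate by
the arithmetic mean of those values — the mean of normalized replicates,
never the normalized mean. Outlier replicates are carried through
`clean_data.csv` with their values and an `Outlier = TRUE` flag, but are
excluded from every control mean, calibrator mean and summary.

**Relative ΔCT.** For sample s with endogenous controls c: the control's CT
enters as the mean over its retained replicates; ΔCT_i = mean_c(CT_i −
mean CT_c) per target replicate i; RQ_i = 2^−ΔCT_i. Base 2 throughout —
one cycle is one doubling at the assumed 100 % amplification efficiency.

**Relative ΔΔCT.** ΔΔCT_i = ΔCT_i − mean ΔCT(calibrator sample, same
target); RQ_i = 2^−ΔΔCT_i. The calibrator mean uses its retained replicates.
Because sample-level RQs aggregate arithmetically, the identity
RQ_ΔΔCT(s) = RQ_ΔCT(s) / RQ_ΔCT(calibrator) is exact when the calibrator's
replicate ΔCTs are constant (noiseless data) and approximate otherwise —
the arithmetic mean of 2^−x is not 2^−mean(x). The alternative aggregation
(exponentiate the mean ΔCT) was deliberately not exposed: one behaviour,
stated, beats a switch nobody can compare across labs.

**Absolute.** Per target, ordinary least squares of CT on log2(quantity)
over the STANDARD-task wells gives CT = a·log2[RNA] + b (slope a in
cycles per log2(ng), negative for valid amplification); unknowns invert to
2^((CT − b)/a). If the export already carries instrument-computed
quantities, `quantity_source = "use_quantity_column"` bypasses the fit.
Each replicate quantity is divided by each control's mean quantity for the
same sample and the per-control ratios averaged. Relative models never mix
input files (reference genes are computed per file); the absolute model
pools all files, so a single control-gene file serves every gene file.

**Genomic stability.** The ΔΔCT machinery applied to genomic regions, with
a stable reference region as the control and known-normal DNA as the
calibrator. The per-sample mean RQ is classified: below 0.7 **deletion**,
above 1.3 **insertion**, otherwise **normal** — the interval is a ±0.3
allowance around the diploid expectation of 1, acknowledging mixed cell
populations; the bounds themselves count as normal. A single-copy region
(male chromosome X) is expected at RQ 0.5.

Summaries report mean, SD (n − 1) and SE = SD/√n over retained replicates;
a single-replicate group reports SD = SE = 0 with a warning rather than NA,
so downstream tables stay numeric.

# Statistics

Statistics consume the per-sample summary means — biological replicates
(cell lines, animals) — never technical replicates. Group labels come
either from case-insensitive substring matches on sample names ("AIW002-D0"
→ group "D0", subject "AIW002", which also supplies the pairing key for
repeated-measures designs) or from an explicit grouping column.

Dispatch: two groups → Welch t test (paired t when paired; Wilcoxon
signed-rank / Mann–Whitney for the nonparametric switch); one factor, >2
levels → one-way ANOVA, repeated-measures ANOVA when paired
(Kruskal–Wallis / Friedman nonparametric); two factors → two-way ANOVA with
interaction using type-II sums of squares, which keeps main effects
interpretable in unbalanced designs (group sizes of 4 vs 5 animals are the
norm in the datasets this tool targets). Normality is never auto-tested;
parametric vs nonparametric is the user's call. This dispatch table is a
reconstruction from the analyses the tool is meant to reproduce, not a
copy of any published mapping.

Post-hocs are all pairwise t tests (within each level of factor 1 across
factor 2 levels, for two-way designs), with Benjamini–Hochberg step-up FDR
adjustment applied per target across its pairs. BH is the only correction
offered; both unadjusted and adjusted p values are reported, and pairs with
fewer than two observations per side are flagged untestable rather than
dropped.

# The synthetic-plate generator

Every test input is generated, none downloaded. The generator emulates the
export layout and a standard CT error model: control CTs at a base level
(default 20 cycles for expression plates, 25 for genomic DNA — arbitrary
but realistic mid-range values), target CTs offset by the true ΔCT, and
i.i.d. Gaussian noise on the CT scale per technical replicate. Outliers are
injected as fixed CT offsets on chosen replicates; copy-number scenarios
shift CT by −log2(copy/2) so a one-copy region emerges at RQ 0.5; standard
plates lay out a serial dilution (default 8 points, four-fold, from 50 ng —
bottoming at 50/4⁷ ≈ 0.00305 ng) on an exact line CT = a·log2(q) + b plus
noise. Output is byte-identical for a fixed seed.

What the generator does **not** emulate — and what passing tests therefore
do not certify about real data: amplification-efficiency variation between
targets (the models assume 100 % efficiency; no correction is applied),
inter-plate calibration drift, duplex reactions, heavy-tailed or
CT-dependent noise, and instrument-specific quirks beyond header/preamble
variation.

# Problem sizes and tolerances in the test suite

Deterministic identities (curve recovery, ΔΔCT consistency, shift
invariance) are asserted at 1e−9–1e−12. Stochastic properties use fixed
seeds at sizes chosen to make the checks sharp but quick on one core:
10,000 null simulations for t-test type-I calibration (expected 5 % ± 1 %),
1,000 random p-vectors against a brute-force BH oracle, 500 random replicate
groups against an exhaustive-search filter oracle (n ≤ 5), and 100 simulated
plates at CT noise SD 0.1 for fold-change recovery (mean RQ within 3 SE of
0.5; the small Jensen bias of arithmetically averaged 2^−ΔΔCT, about 0.002
at this noise level, sits well inside that band).

# Known limitations

- No amplification-efficiency correction or efficiency-aware (base ≠ 2)
  mode; no inter-plate calibrators; no duplex support.
- Excel workbooks are not parsed — convert to csv/txt (this also avoids
  Excel's notorious auto-conversion of gene names).
- Comma-decimal locales must re-export with dot decimals.
- The ΔΔCT sample aggregation is the arithmetic mean of per-replicate RQs;
  labs that exponentiate mean ΔCTs will see small differences on noisy
  calibrators (see above).
- Statistics assume one summary value per biological replicate; mixed
  models, power analysis and robust tests are out of scope.
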