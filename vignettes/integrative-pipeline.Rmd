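---
title: "Methods: multi-platform tumor cohort integration with survival screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-platform tumor cohort integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`omicsurv` implements an integrative analysis of the kind used for
glioblastoma multiforme cohorts profiled on many platforms at once: exon and
gene expression arrays with a small set of non-cancer brain controls, aCGH
copy-number arrays with blood-vs-blood control hybridizations, germline SNP
arrays, promoter methylation arrays, miRNA arrays, clinical follow-up, and a
downstream siRNA validation screen. The goal of the analysis is to rank
genes and splice variants by their association with patient survival and to
ask, gene by gene, whether chromosomal amplification explains
overexpression. Every stage is exercised end to end on synthetic cohorts
with planted ground truth, so the pipeline is testable without any external
download.

# Transcript deconvolution

Exon arrays measure exons; the biological unit of interest is the
transcript. For a gene with $m$ measured exons and $n$ annotated
transcripts, let $\mathbf{e}$ be the vector of exon intensities and
$\mathbf{A}$ the binary $m \times n$ incidence matrix with $A_{jk} = 1$ iff
exon $j$ belongs to transcript $k$. Transcript values $\mathbf{t}$ solve the
least-squares problem

$$\hat{\mathbf{t}} = \arg\min_{\mathbf{t}} \lVert \mathbf{A}\mathbf{t} -
\mathbf{e} \rVert_2,$$

computed through a QR factorization for numerical stability. Two numerical
choices matter:

* **Rank deficiency.** When two transcripts share exactly the same measured
  exons, $\mathbf{A}$ loses column rank and the least-squares solution is
  not unique. We return the minimum-norm solution (via the SVD
  pseudoinverse) and flag the gene rather than failing or silently picking
  an arbitrary solution.
* **Negativity.** The problem is solved unconstrained; a negative
  $\hat{t}_k$ (possible under noise) is reported and flagged, not truncated,
  so that downstream fold changes remain an honest function of the fit.

Incidence rows are restricted to exons actually measured on the array; exons
annotated to no transcript of their gene are dropped with a logged count.
Coordinates are 0-based half-open internally; GTF input (1-based closed) is
converted at the parsing boundary. Exons are keyed by coordinates, so a
reused exon id with different spans is an error rather than a silent merge.

# Differential expression and DET selection

Gene-level exon-platform values are the median across the gene's exons
(midpoint for even counts). Fold change is the ratio of group means,
tumor over control, on the intensity scale. Differential testing uses the
Welch two-sample t-test; the same unequal-variance flavor is used everywhere
in the package (the screen stage states it explicitly, and one convention
throughout is easier to reason about). Multiple testing uses
Benjamini-Hochberg, the standard FDR procedure. Differentially expressed
transcripts (DETs) are those with absolute fold change above 2 — read
symmetrically on the ratio scale as FC > 2 or FC < 0.5 — and adjusted
P < 0.05. Intensities are analyzed on the scale provided; a `log2_input`
toggle is exposed for cohorts delivered in log space.

# Survival screening

Per-sample fold changes (sample value over the control mean) are discretized
into classes: $-1$ (FC < 0.5, underexpression), $1$ (FC > 2,
overexpression), $0$ (stable). Classes with fewer than 20 patients are
excluded, and features with fewer than two surviving classes are skipped. A
log-rank test (hypergeometric variance at ties, $\chi^2$ upper-tail P with
df = groups − 1) compares the remaining classes; Kaplan-Meier curves carry
Greenwood-based 95% confidence bands. Both are computed through the
`survival` package; hand-built product-limit and O/E/V tables serve as
independent oracles in the tests.

The SNP screen applies, in order: per-sample signal-to-noise filter
(SNR ≥ 5), per-call probability filter (≥ 0.95, failing calls set missing),
marker-level minor-allele-frequency filter (MAF ≥ 0.1, allele-counted over
called genotypes), administrative censoring of all records at the 36-month
study horizon (deaths after 36 months become censored-at-36 — the standard
reading of a fixed study time), merging of the rare-homozygote group into
the heterozygote group when it has fewer than 15 patients or a
called-genotype frequency below 0.1, a log-rank test over the remaining
genotype groups (all of them, df = groups − 1, when no merging triggers),
and a raw P < 10⁻⁴ reporting limit. "Frequency" of the rare homozygote is
its fraction among called patients at that marker.

# Copy number

Profiles are segmented by circular binary segmentation: on each chromosome
the maximal standardized arc statistic

$$Z_{ij} = \frac{\bar{x}_{(i,j]} - \bar{x}_{\text{rest}}}
{s\sqrt{1/k + 1/(n-k)}}$$

is maximized over all arcs (wrap-around arcs are covered through their
complements, whose $|Z|$ is identical), its significance assessed by
permuting the probes within the segment, and significant splits recursed.
Defaults: 1000 permutations, acceptance level α = 0.01, minimum segment
width 3 probes. The permutation loop terminates early once significance is
unattainable, and the kernel is compiled (Rcpp) as is usual for
segmentation code; it draws from R's RNG so `set.seed()` controls it. The
statistic scan is quadratic in probes per chromosome, sized for profiles of
a few hundred probes per chromosome — the synthetic study scale.

Gain/loss thresholds are estimated from control arrays as the mean ± 2
standard deviations of the **pooled** control probe log-ratios (a per-array
variant is a trivial caller-side change; pooling matches reading the
controls as one null distribution). Degenerate or absent controls fall back
to ±0.632 with a warning. A segment is a gain when its mean is strictly
above the upper threshold ("over"), a loss when strictly below the lower.

Per-feature frequencies use any-base overlap between the feature span and
called segments. A sample whose overlapping segments include both a gain
and a loss is *ambiguous* and excluded from both counts; a sample with no
covering segment counts as neutral. This keeps the counting unambiguous at
the cost of dropping rare straddling cases.

# Amplification-expression integration

For each feature the samples are split into amplified and non-amplified
groups and the weight

$$w = \frac{\bar{x}_{\text{amp}} - \bar{x}_{\text{non}}}
{s_{\text{amp}} + s_{\text{non}}}$$

is tested by permuting the group labels at fixed group sizes. The test is
one-sided toward overexpression-with-amplification (the mirrored,
sign-flipped statistic with the loss mask serves deletion-underexpression);
a `two_sided` flag is exposed because the comparison direction is a genuine
design choice. When $\binom{n}{k} \le 10\,000$ all assignments are
enumerated and P is the exact tail fraction; otherwise 10,000 (default)
Monte-Carlo permutations with the add-one estimator
$P = (1 + b)/(B + 1)$, which cannot return zero. A counting tolerance of
$10^{-9}\max(1, |w|)$ guarantees the observed split ties with itself under
floating-point reordering. Candidates require P < 0.01 and aberration
frequency > 5%.

# Methylation and miRNA

Methylation beta is $M/(M+U)$, zero for fully unmethylated; probes of one
promoter combine to the per-gene median beta per sample over non-missing
probes (a probe with $M+U=0$ is missing, never zero). miRNA differential
expression reuses the expression machinery verbatim. Target annotations are
filtered at target-site P < 10⁻⁵; a synthetic target table (log-uniform
P-values) stands in for a curated miRNA target database.

# siRNA screen scoring

Plates are corrected with a robust locally weighted polynomial surface over
(row, column): degree 2, span 0.35, two robustness reweighting passes
(`family = "symmetric"`), fitted to all non-empty wells. The background
subtracted is the surface's deviation from its plate-wide median, so
gradients and edge effects are removed while the plate's overall level — and
with it the meaning of "relative to negative controls" — is preserved; a
flat plate passes through unchanged, and a degree-2 polynomial background is
removed exactly. Correction runs before control-based scaling for
LOESS-flagged batches. Signals are then scaled so the negative-control mean
is 1; per-siRNA values are the median of replicate wells; robust z-scores
divide by $1.4826 \times \text{MAD}$ (the normal-consistency constant used
by the screening literature) against the negative-control reference; a
Welch two-tailed t-test against the negative-control wells maps to
significance tiers at P < 0.05 / 0.01 / 0.001. A gene is a *consistent hit*
when at least two distinct siRNAs reach $|z| \ge 2$ in the effect direction
in every tested cell line — two constructs guard against off-target
artifacts; the thresholds are configurable because "consistent" is a
qualitative judgment made quantitative here.

# The report

All stage outputs fuse into one row per gene (outer join on canonicalized
gene ids, per-field provenance recorded, missing fields blank — never zero).
The static website sorts by the best transcript survival P by default,
colors fold-change cells on a two-color log₂ ramp saturating at
$|\log_2 \text{FC}| = 3$ (red up, green down) and P cells by significance,
links out to annotation/pathway/interaction databases via URL templates, and
embeds a Kaplan-Meier plot (hand-rendered SVG, so the site is plain text and
self-contained) only for features with survival P < 0.01. Rendering never
recomputes: every number on the site equals the fused-table value.

# The synthetic cohort generator

The generator is first-class, tested code. It emulates: ~10 brain controls
against a large tumor arm; exon matrices generated exactly as
$\mathbf{e} = \mathbf{A}\mathbf{t} + \varepsilon$ with additive Gaussian
noise (keeping the least-squares model exact, matching pre-normalized
intensity-scale input); exponential proportional-hazards survival (baseline
hazard log(2)/12 per month, i.e. a 12-month median — the scale of
glioblastoma — with administrative censoring at a 60-month horizon plus a
configurable fraction lost to follow-up at a uniform time before their
event); copy-number probe profiles as planted segment means plus Gaussian
noise, with 64 blood-control arrays; Hardy-Weinberg genotypes at uniform
MAFs with call probabilities and per-sample SNR; promoter methylation with
1-3 probes per gene; and 384-well screen plates printed as a contiguous
shuffled block with a low-order polynomial spatial background (what a
degree-2 LOESS can remove by construction) and spiked hit siRNAs. Transcript
structures give every transcript at least one private exon, so incidence
matrices are full column rank by construction and zero-noise recovery is
exact.

Planted effects tie platforms together: an expression effect overexpresses
a gene in a fraction of tumors and multiplies those patients' hazard; a
copy-number effect plants an aberrant segment over the gene in a fraction
of samples, overexpresses exactly those samples, and applies the hazard
ratio; a SNP effect gives minor-allele carriers the hazard ratio. Controls
are drawn from the same noise model with the control-arm means — the control
tissue's own covariance structure is not modeled.

What the generator does **not** emulate: probe-level normalization and raw
CEL/IDAT artifacts, batch effects, population structure (cohorts are
homogeneous by construction), correlated biological variation between genes,
and dose-response in the screen. Passing tests therefore demonstrate the
correctness and calibration of the statistical machinery on its stated
model, not robustness to the messiness of real arrays.

# Problem sizes and determinism

The default study cohort is 200 tumors, 10 controls, 40 genes (1-3
transcripts each), 200 SNP markers, 120 aCGH probes per chromosome on 2
chromosomes with 64 control arrays, 30 miRNAs and a 4-cell-line screen —
large enough for every gate in the pipeline (e.g. the 20-patient class
filter) to be meaningfully exercised, small enough that an end-to-end run
takes seconds. A fixed configuration and seed reproduce every table byte
for byte; segmentation and permutation tests draw from R's RNG so a single
`set.seed()` before `run_pipeline()` fixes the whole analysis.

# Known limitations

* The CBS scan is exact but quadratic per segment; very dense profiles
  (tens of thousands of probes per chromosome) would need the usual
  windowing tricks, which are out of scope here.
* The SNP screen uses the log-rank test only (no Cox modeling, no
  population-structure correction), as in the original design.
* Methylation is summarized descriptively (combined beta per gene); no
  differential methylation testing is performed.
* The amplification-expression statistic treats samples as exchangeable
  under the null; clinical covariates are not adjusted for.
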