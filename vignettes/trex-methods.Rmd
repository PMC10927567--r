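---
title: "Statistical methods behind trexkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind trexkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trexkit)
```

trexkit implements the computational side of targeted RNase H-mediated
extraction (TREX) of RNA-binding proteins: an experiment in which cells are
UV-crosslinked, RNA-protein adducts are isolated by phase separation, a
chosen RNA (or RNA region) is degraded by RNase H over annealed antisense
DNA oligonucleotides, and the proteins thereby released are identified and
quantified by label-free mass spectrometry against a mock-digested (-RNase
H) control. This vignette explains the models and procedures implemented,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the design decisions taken where
more than one reasonable implementation exists.

## Probe design

RNase H digests RNA only within RNA:DNA hybrids, so region specificity
comes entirely from where the DNA oligonucleotides anneal.
`design_tiling_probes()` tiles a target region completely — no gaps, no
overlaps — with antisense DNA probes. The probe count for a region of
length $L$ is

$$ n = \mathrm{clamp}\!\left(\mathrm{round}_{1/2\uparrow}(L / 60),\;
   \lceil L/90 \rceil,\; \lfloor L/30 \rfloor\right), $$

after which $L$ is split as evenly as possible (lengths differ by at most
1 nt). The 60-nt target length balances annealing stability against
resolution; the 30-nt floor keeps hybrids long enough for efficient RNase H
cleavage, and the 90-nt ceiling limits the chance of stable off-target
annealing. This rule yields 3 probes for a 164-nt target (the length of U1
snRNA) and 223 probes for a 13.4-kb target (the 45S pre-rRNA precursor).
No melting-temperature optimization is attempted: TREX anneals probes over
a 95 → 50 °C gradient, which tolerates a wide $T_m$ range, so GC content is
reported per probe for information only.

`screen_off_targets()` guards against depleting unintended transcripts. For
each probe it searches a transcriptome for the longest exact match to the
probe's sense (target-strand) window, using seeded k-mer containment
(default seed 12 nt) refined to the exact maximum by bisection, and flags
any match of at least 18 nt to a non-target transcript. The 18-nt cut-off
is a conservative proxy for a "strong" BLAST hit — 18 contiguous matching
bases under TREX annealing conditions could support a stable off-target
hybrid; it is configurable, and borderline probes should simply be
replaced, since the tiling is dense enough to tolerate dropping windows.

## Differential release statistics

The statistical core mirrors the Perseus label-free workflow, because TREX
release calls are made exactly the way conventional enrichment proteomics
calls are made.

**Filtering.** Intensities of zero in MaxQuant output mean "not
quantified", never "abundance zero", so they are recoded as missing at
parse time. After log2 transformation, proteins are kept only if quantified
in at least `min_valid = 3` biological replicates in at least one group.
The 3-in-at-least-one-group rule keeps the interesting asymmetric case —
released proteins may be absent from every control replicate.

**Imputation.** Label-free missingness is concentrated at low abundance
(left-censored, missing-not-at-random), so missing values are drawn from a
Gaussian shifted below each sample's observed distribution:
$\mathcal{N}(m - 1.8\,s,\ (0.3\,s)^2)$ per column, where $m$ and $s$ are
the column's observed mean and standard deviation. The 1.8/0.3 defaults
are the established convention for this imputation; imputation is
per-column so that each run's own depth determines where its censoring
tail sits. Columns with fewer than two observed values cannot supply
moments and raise an error naming the column.

**The S0-moderated test.** For each protein the statistic is

$$ d = \frac{\bar{x}_{+} - \bar{x}_{-}}{s_{\mathrm{pooled}}
  \sqrt{1/n_{+} + 1/n_{-}} + S_0}, $$

the pooled-variance two-sample t statistic with an artificial within-group
standard deviation $S_0 = 0.1$ added to the denominator. $S_0$ damps
proteins whose difference is statistically stable but biologically tiny —
at $S_0 = 0$ the classical Student statistic is recovered exactly (a unit
test asserts this reduction). Pooled variance rather than Welch matches the
Perseus default; a Welch option was considered and rejected to keep the
permutation null exchangeable under equal-variance label swaps. The
t-distribution p value reported alongside $d$ is an approximation (the
moderated statistic is not t-distributed); it is used only for volcano-plot
axes, never for significance calls.

**Permutation FDR.** Significance rests on sample-label permutations. All
distinct two-group splits are enumerated when there are at most `n_perm`
of them (for 4 vs 4, all 70 splits, identity included); otherwise `n_perm
= 250` uniform random splits excluding the identity are drawn. For each
threshold $c$ among the sorted observed $|d|$,

$$ \widehat{\mathrm{FDR}}(c) = \frac{\overline{\#\{|d_{\mathrm{perm}}|
   \ge c\}}}{\#\{|d_{\mathrm{obs}}| \ge c\}}, $$

and a protein's q value is the minimum of $\widehat{\mathrm{FDR}}$ over
all thresholds that would still call it, capped at 1 — which makes q
monotone non-increasing in $|d|$. A protein is significant when
$q \le 0.05$. Perseus does not publish its exact permutation-FDR
internals (side handling, $\pi_0$ treatment), so this ratio estimator is
this package's documented choice; it is validated exactly against
brute-force enumeration on exhaustively enumerable designs, controls its
error rate on null simulations, and may differ slightly from Perseus
output on real deposited tables.

**The volcano boundary.** A point with difference $x$ and p value $p$
implies a standard error $x / t(p)$, so the significance region
$|d| \ge d_{\mathrm{cut}}$ maps to the curve $p(x) = 2\,F_t(-x / (x /
d_{\mathrm{cut}} - S_0))$, defined for $|x| > S_0\, d_{\mathrm{cut}}$ —
the familiar hyperbolic volcano boundary, horizontal when $S_0 = 0$. The
cut-off $d_{\mathrm{cut}}$ is taken from the permutation result as the
smallest $|d|$ among significant proteins.

**Replicate QC.** PCA on the centered, imputation-complete sample matrix;
a replicate whose distance to its own group centroid in the first two
components exceeds 3 times the median within-group centroid distance is
flagged. The multiplier formalizes what is usually an
inspection call; flags are advisory and nothing is removed automatically.

**Which intensity column?** Whether LFQ-normalized or raw intensities feed
the test is not something the downstream statistics can decide; the parser
defaults to `"LFQ intensity "` columns (the normal choice for
between-sample comparison) and accepts any prefix.

## Affinity estimation

For each released protein the relative affinity for the target RNA is
estimated from intensity-based absolute quantification:

$$ K_a = \frac{[\text{RNA bound}]}{[\text{Total}]}
       = \frac{\mathrm{iBAQ}_{\mathrm{TREX}}}{\mathrm{iBAQ}_{\mathrm{total}}}, $$

where $\mathrm{iBAQ}_{\mathrm{TREX}}$ is the mean iBAQ in the +RNase H
eluates minus the mean in the -RNase H controls, and
$\mathrm{iBAQ}_{\mathrm{total}}$ comes from a matched total-proteome run.
iBAQ (summed intensity over the number of theoretically observable tryptic
peptides, 6–30 residues, cleavage after K/R except before P) cancels
protein length, so the ratio compares molar amounts. Missing-value policy:
a missing control iBAQ is treated as 0 (no detectable background release);
a missing total-proteome value is averaged over the quantified total runs
only, and $K_a$ is undefined if there are none; a protein undetected in
every +RNase H replicate, or with non-positive released amount, has
undefined $K_a$ — released material cannot be negative, so such values are
reported but excluded from ranking rather than clamped.

## Regional integration

Region-by-region TREX along one transcript produces one enrichment result
per region. `assemble_tscore_matrix()` keeps the union of proteins
significant in at least one region and records each region's moderated
t score; a protein absent from a region's table contributes 0 (no measured
enrichment) with the absence tracked in a mask, consistent with the
display convention that the lowest color bin is "0 or less". Raw
(untruncated) t scores are clustered; the (0, 2, 6, 10) bin edges are
applied only for display.

Clustering follows "k-means preprocessing, then complete-linkage Euclidean
clustering": rows are pre-grouped by seeded k-means (default
$k = \min(300, n/2)$ — no k is canonical, this merely caps the tree size),
centroids are merged hierarchically, and proteins inherit their centroid's
tree position. When the requested group count reaches the number of
distinct profiles, the exact assignment (one group per distinct profile) is
used directly, which is the k-means optimum with zero within-group
scatter.

A protein significant in at least `multiregion_min = 3` regions is called
multiregional; otherwise it is region-specific, with its primary region
the argmax t score (ties broken by region order and flagged). The
threshold of 3 deliberately keeps binders that straddle one junction
between two adjacent regions — a geometric fact about contiguous tiling,
not evidence of multi-site binding — in the region-specific class.

## Depletion and specificity QC

qPCR depletion checks use $2^{-\Delta C_T}$ with $\Delta C_T$ the target
$C_T$ minus the arithmetic mean of the housekeeping $C_T$s (equivalently
the geometric mean of their expression; no aggregation rule is canonical,
and the arithmetic-mean-of-cycles choice is the common one). Depletion
efficiency is $1 - \text{level}_{\mathrm{treated}} /
\text{level}_{\mathrm{control}}$. Inputs are assumed to be
melt-curve-corrected where the assay needs it; no correction is applied
here.

Transcriptome-wide specificity is tested on TPM tables processed with the
same log/filter/impute steps as the proteomics data. Scores are computed
on group means (not per-replicate points), matching how such scatters are
averaged and plotted: $\text{score} = \overline{\log_2
\mathrm{TPM}}_{\mathrm{control}} - \overline{\log_2
\mathrm{TPM}}_{\mathrm{treated}}$, the displacement from the identity
line. The null spread is estimated robustly from the bulk of undepleted
transcripts as $\hat\sigma = q_{0.95}(|\text{score} - \tilde m|) /
\Phi^{-1}(0.975)$ (with $\tilde m$ the median score), each transcript gets
a two-sided Gaussian tail p value, and outliers are called at BH FDR 0.05.
The underlying "multidimensional outlier test" has no published reference
implementation; this quantile-calibrated Gaussian tail is this package's
documented stand-in, keeping the stated 0.95 quantile and BH correction.

## Category enrichment

Over-representation of hit lists against GMT annotation sets uses the
two-sided Fisher exact test — implemented as a vectorized hypergeometric
tail summation (all tables with point probability at most $(1 +
10^{-7})$ times the observed one), the same convention as
`stats::fisher.test`, which serves as an independent cross-check in the
test suite. The universe is all proteins quantified in the corresponding
experiment, not the whole proteome: hits can only be drawn from what was
measured. The default enrichment call is BH FDR $\le 0.02$ with odds ratio
above 1; 0.05 is equally defensible (both levels circulate for this test),
and `alpha` is exposed.

## The synthetic-data generator

`simulate_trex()` emulates the statistical structure the pipeline assumes,
not mass spectra. Per protein, a baseline log2 abundance
$\mu_i \sim \mathcal{N}(25, 2^2)$; eluates are modelled as released
material with a background release fraction $b = 0.05$ common to both TREX
groups, so the -RNase H control sits at $\mu_i + \log_2 b$ and the
+RNase H eluate of a released protein at $\mu_i + \log_2(b + f_i)$, where
$f_i$ is the planted bound fraction. The planted log2 group difference is
therefore exactly $\delta_i = \log_2(1 + f_i/b)$, and the affinity
module's $K_a$ recovers $f_i$ directly — the reason this
parameterization was chosen over simply adding $\delta$ to a shared
baseline, which would leave the "bound fraction" with no defined truth
value. Release effects are drawn as $\delta_i = \delta \cdot U(0.5, 2)$
around the default $\delta = 2$ (4-fold release), giving bound fractions
of roughly 0.05–0.75 — a spread of the order seen in ranked-affinity
plots. Replicate noise is $\mathcal{N}(0, 0.3^2)$ on the log2 scale
(~23% CV, typical for label-free quantification with match-between-runs).
Missingness is logistic in the true intensity — probability 0.5 at the
15th percentile of the simulated values, slope 0.7 log2 units — which is
precisely the left-censoring premise that downshift imputation relies on.
iBAQ columns divide linear intensities by a per-protein observable-peptide
count drawn from 5–40. Five replicates per group is the default design;
3-vs-3 and 4-vs-4 designs are a config change.

What the generator does **not** emulate: peptide-level identity and
shared-peptide ambiguity, intensity-dependent variance (noise is
homoscedastic in log space), correlated missingness across samples of a
batch, contaminant and reverse hits, or ratio compression between
co-eluting proteins. Passing tests therefore demonstrate that the
statistics behave as specified under the assumed model — calibrated error
rates, recoverable planted signal — not that any particular real dataset
will reproduce published hit counts.

`simulate_multiregion()` shares one background proteome across regions and
releases each planted binder in one region (95% of binders by default) or
in at least three regions with independent effects. `simulate_tpm()` plants
fold depletions into log-normal TPM tables; `simulate_qpcr()` inverts the
$2^{-\Delta C_T}$ formula so zero-noise tables round-trip exactly. All
generators are pure functions of their configuration and seed.

## Numerical choices and degenerate inputs

- Probe coordinates are 0-based half-open everywhere; remainders in the
  even split go to the leading probes.
- The off-target search is exact for all match lengths (bisection below
  the seed as well), so screens agree with a quadratic-time
  longest-common-substring computation.
- Permutation q values are computed by threshold counting on sorted
  absolute statistics (`findInterval`), which handles ties by value, not
  by rank: tied $|d|$ always receive identical q.
- `two_sample_s0_test` refuses groups smaller than 2 (pooled variance
  needs a degree of freedom); imputation refuses columns with fewer than
  2 observed values; PCA QC refuses fewer than 3 samples.
- Duplicate protein ids in a proteinGroups file keep the first row with a
  warning; flagged rows (reverse, contaminant, site-only) are dropped by
  default and retained with `remove_flagged = FALSE`.
- Specificity-classifier ties at the argmax are broken by region order and
  reported in a `tie` column.
- Quantification tables are serialized with 17 significant digits and
  parsed with `strtod`, so write-then-read round trips are bit-exact.

Test problem sizes were chosen to keep the full suite fast on a laptop
while leaving the statistical checks well-powered: 20-seed null
calibrations at 1,000 proteins, exhaustive permutation oracles at 3-vs-3
and 4-vs-4, the full 8-region simulation at ~1,100 proteins per region,
and the exhaustive Fisher sweep over all 635,375 tables with $n \le 60$.

## Known limitations

- The permutation-FDR estimator and the transcriptome outlier statistic
  are documented stand-ins for unpublished Perseus internals; calls near
  the significance boundary can differ from Perseus on identical input.
- The off-target screen considers exact matches only; it does not model
  mismatched or gapped hybrids, and 18 nt is a heuristic threshold, not a
  thermodynamic computation.
- $K_a$ is a relative affinity: comparable within an experiment, not an
  absolute dissociation constant, and it inherits iBAQ's assumption that
  observable-peptide counts capture detectability.
- The t-approximation p values on volcano plots are descriptive; only
  permutation q values carry inferential weight.
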