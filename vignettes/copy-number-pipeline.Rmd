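---
title: "From TMT reporter intensities to protein copies per cell: methods and design"
author: "tmtRuler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From TMT reporter intensities to protein copies per cell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmtRuler)
```

# Overview

`tmtRuler` converts MaxQuant-style protein-group tables from multiplexed
TMT SPS-MS3 experiments into absolute per-cell protein copy numbers and
carries them through a complete comparative analysis: per-cell protein
content, replicate quality control, moderated-t differential expression with
Storey q-values and fold-change-distribution significance classes,
hypergeometric gene-set overrepresentation, and global structure summaries
(PCA, population correlations, proteome mass fractions, gene-set copy
sums). The motivating application is comparative immunology — e.g. profiling
tissue-resident intestinal intraepithelial T-cell (T-IEL) subsets against
naive lymph-node CD8 T cells — but nothing in the package is specific to
those cell types.

This vignette documents the model, its assumptions, the tunable parameters,
and the design decisions taken where the methodology left genuine choices.

# The quantification model

## Two-level quantification and MS1 allocation

SPS-MS3 TMT quantification operates at two levels: the summed MS1 precursor
intensity quantifies a protein group across the whole multiplexed set, and
the MS3 reporter ions apportion that signal among channels. The pipeline
mirrors this: for protein group $p$ with summed MS1 intensity $I_p$ and
reporter vector $r_{p1}, \dots, r_{pK}$,

$$ I_{pk} = I_p \cdot \frac{r_{pk}}{\sum_j r_{pj}} . $$

Allocation conserves the MS1 total exactly and assigns zero to silent
channels. A record with $I_p > 0$ but an all-zero reporter vector cannot be
apportioned; such records are dropped with a logged count rather than
imputed, because any imputation would invent signal.

## The histone proteomic ruler

Absolute scaling uses the histone ruler: every cell carries a fixed DNA
mass $m_{\mathrm{DNA}}$, and histone protein mass closely tracks DNA mass,
so the summed histone MS signal is an internal standard present in every
sample. For protein $p$ with molecular weight $M_p$ (Da) in sample $s$:

$$ \mathrm{copies}_{ps} = \frac{I_{ps}}{M_p}\cdot
   \frac{m_{\mathrm{DNA}} N_A}{\sum_{h \in \mathrm{histones}} I_{hs}} , $$

with $N_A$ Avogadro's number and $m_{\mathrm{DNA}}$ in grams. Two algebraic
consequences are used as correctness invariants throughout the test suite:

* **Ruler conservation** — summed histone protein mass per cell equals
  $m_{\mathrm{DNA}}$ in every sample, by construction;
* **Scale invariance** — the estimator is a ratio, so rescaling all
  intensities of a sample (instrument drift, loading differences) leaves
  its copy numbers unchanged.

Per-cell protein content is then
$\sum_p \mathrm{copies}_{ps} \cdot M_p / N_A$, reported in picograms.

**DNA mass default.** `dnaMassPg = 5.52` pg corresponds to a diploid mouse
genome (about $2 \times 2.7$ Gbp at roughly 615 g/mol per base pair). The
absolute scale of every copy number is proportional to this anchor, so it
is an explicit, overridable argument rather than a buried constant. No
ploidy or cell-cycle correction is applied; for largely quiescent primary
T cells a single constant is adequate, but proliferating populations carry
more than 2n DNA on average and their copy numbers would be inflated
accordingly.

**Histone selection.** Histones are flagged by case-insensitive gene-symbol
match against a shipped list of mouse core and linker histone symbols (both
`Hist*` and current nomenclature), overridable by file. Symbol matching is
auditable and independent of any annotation service.

# Filtering and replicate QC

Row filters follow standard MaxQuant practice: protein groups flagged as
potential contaminant, reverse (decoy) or only-identified-by-site are
removed, as are groups with fewer than two razor + unique peptides. The
filter report counts a row once per failing reason. We filter on MaxQuant's
"Razor + unique peptides" column (the count credited to the group) rather
than "Unique peptides"; the reader exposes the choice as an argument since
both conventions appear in practice.

Replicate QC formalises an exclusion that is usually a judgement call:
within each population, a replicate is flagged when its protein content
deviates from the median of the *other* replicates by at least a relative
threshold (default 0.15). The leave-one-out median makes the reference
robust to the outlier itself; populations with fewer than three replicates
are skipped with a warning because that reference is unstable. The default
threshold was chosen so that content discrepancies of the magnitude that
typically motivates exclusion (about 15% low or 30% high) are flagged.
Note one sharp edge, exercised deliberately in the tests: a replicate whose
content sits *exactly* at the threshold satisfies the `>=` rule only up to
measurement noise, so detection of an exactly-15% outlier is deterministic
only in noise-free data.

# Differential expression

Copy numbers are compared on the $\log_2(\mathrm{copies} + 1)$ scale. The
pseudocount of 1 copy/cell is far below quantifiable abundance, so it
perturbs real measurements negligibly while keeping zeros finite.

## Moderated t-statistics

Per-protein variances from a handful of replicates are noisy; empirical
Bayes moderation shrinks them toward a prior fitted across the proteome.
For the two-group contrast with pooled residual variance $s_g^2$ on
$d_g = n_a + n_b - 2$ degrees of freedom, the prior
$(d_0, s_0^2)$ is estimated by moment matching of $\log s_g^2$ against a
scaled F distribution (digamma/trigamma equations, with a Newton inversion
of the trigamma function), and

$$ \tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}, \qquad
   t_g = \frac{\bar x_{ga} - \bar x_{gb}}
              {\tilde s_g \sqrt{1/n_a + 1/n_b}} $$

is referred to a t distribution on $d_0 + d_g$ degrees of freedom
($d_0 = \infty$ is allowed and reduces to a normal reference with the
common variance; $d_0 = 0$ recovers the ordinary pooled t-test). The test
suite verifies the implementation against a step-by-step scalar oracle and,
independently, against the established empirical-Bayes implementation in
the `limma` package, which serves as a cross-check only.

Contrasts are pairwise (each population of interest against a reference),
matching the "T-IEL vs LN" structure of the motivating design; multi-factor
models are out of scope.

## q-values

Storey q-values estimate the null proportion $\pi_0$ from the flat right
tail of the p-value histogram (grid $\lambda = 0.05, \dots, 0.95$, cubic
spline smoother, read off at the largest $\lambda$, clipped to $(0, 1]$)
and report the estimated positive FDR. With fewer than 20 p-values the grid
is unstable and $\pi_0$ falls back to 1, which reduces exactly to
Benjamini–Hochberg — an identity the tests assert.

## Significance classes and candidate sets

Star classes and enrichment candidates are defined relative to the
*distribution of the contrast's log2 fold changes* (median $m$, standard
deviation $\sigma$), symmetric about the median:

* `***`: $p < 10^{-4}$ and $|\mathrm{log2fc} - m| \ge 1.5\sigma$;
* `**`: $p < 10^{-3}$ and $|\mathrm{log2fc} - m| \ge 1\sigma$;
* candidates for overrepresentation: $p < 10^{-3}$ and
  $\mathrm{log2fc} \ge m + 1.5\sigma$ (up) or
  $\le m - 1.5\sigma$ (down).

"Fold change" here means the log2 fold change; the two-sided reading of the
thresholds is the only one under which a "median $-$ 1.5 sd" down-rule is
coherent. Stars are gated on the moderated p-value (q-values are reported
alongside, not gated on).

**Exclusive proteins.** Proteins detected in one population (nonzero copies
in at least half of its replicates) and absent in all replicates of the
other are classed `a_only`/`b_only` instead of being interpreted as fold
changes. This matters numerically, not just presentationally: with a
pseudocount of 1, an absent-vs-present protein shows $|\mathrm{log2fc}|$
around 15, and a few percent of such rows inflate $\sigma$ several-fold,
which would destroy the power of the $m \pm k\sigma$ gates. The fold-change
distribution is therefore computed over non-exclusive proteins only, and
exclusives are unioned back into the candidate lists before
overrepresentation analysis, mirroring the "exclusive to or significantly
increased" hit-list convention.

# Overrepresentation and signatures

Gene-set overrepresentation uses the one-sided hypergeometric upper tail
(equivalently one-sided Fisher) of the overlap between a hit list and each
set, both intersected with a fixed background universe. The background is
the set of proteins identified in either of the two contrast populations —
a deliberately narrow universe that prevents detection bias from inflating
enrichment. Multiple testing across sets uses Benjamini–Hochberg FDR with a
conventional 0.05 reporting cut. Gene-set collections are user-supplied GMT
files (including literature-derived exhaustion signatures split into "up"
and "down" sets); no annotation database is bundled or queried.
`signatureOverlap()` provides the exact Venn partition used when comparing
signatures across conditions. Term-clustering of redundant sets (as in
DAVID's functional annotation clustering) is intentionally not implemented;
the package emits flat per-set rows.

# Landscape summaries

* **PCA** of samples on mean-centred $\log_2(\mathrm{copies}+1)$,
  restricted to proteins detected in every sample so absence patterns do
  not masquerade as variance; components via SVD with a deterministic sign
  convention (largest-magnitude loading positive).
* **Population correlations**: Pearson r on
  $\log_{10}(\mathrm{median\ copies} + 1)$ over proteins detected in both
  populations of each pair. Raw copies span about six orders of magnitude,
  so correlations on the natural scale would be dominated by a handful of
  proteins; the log transform is stated in the output and switchable.
  Degenerate (zero-variance) vectors give `NA`, never a fabricated 0.
* **Mass fractions**: proteins are ranked by per-sample mass
  (copies × MW / $N_A$; a copies basis is available) and the ranking is cut
  where cumulative mass reaches a `topFraction` (default 0.5) of the
  sample total, including the protein that crosses the boundary; category
  shares are reported within that selection plus an "other" remainder.
* **Gene-set copy sums** with Welch's unequal-variance t-test per set for a
  two-population contrast — the convention for aggregate quantities, as
  opposed to the moderated test used per protein.

# The synthetic-data generator

`simulateProteinGroups()` produces a protein-group table with the
statistical structure the analysis assumes, plus exact ground truth, so the
entire pipeline is testable without any deposited raw data.

The default configuration emulates the motivating study design: five
populations (two lymph-node CD8 populations with 6 replicates each, three
T-IEL subsets with 4 — pre-QC counts, so the QC stage has work to do) in
one 24-channel set, 8000 quantified protein groups, 30 histone anchors,
baseline abundances log-normal with mean 4.0 and sd 1.0 on the
$\log_{10}$ copies scale, multiplicative log-normal reporter noise with
CV 0.10, 40 contaminant and 40 reverse decoy rows, 60 low-peptide rows, and
5% of proteins absent in one random population. Histones are drawn from the
high-abundance tail (baseline + 1.5 sd, with tighter spread) so the anchor
is stable. The reporter CV default is a generator choice of a plausible
channel-level noise magnitude, not a claim about any particular instrument.

Key construction choices:

* True copies are rescaled so summed histone mass per cell equals the
  configured DNA mass exactly; the ruler inversion is then exact, and a
  noise-free run recovers the truth to floating-point precision — the
  pipeline's end-to-end identity test.
* Noise is applied to reporter intensities only, after the MS1 intensity is
  computed as the noise-free channel sum. This mirrors the two-level
  MS1/MS3 structure and makes allocation a genuine estimation problem
  rather than an identity.
* Population absence is simulated as all-zero reporters in that
  population's channels, exactly how absent proteins appear in real TMT
  tables.
* A planted content-outlier replicate is specified by its *total content*
  multiplier. Because histone content is pinned by the ruler, the generator
  solves for the non-histone copy multiplier that achieves the requested
  total-content ratio exactly.

What the generator does **not** emulate: co-isolation interference and
ratio compression, peptide-to-protein roll-up, missingness that depends on
abundance, batch structure across multiple TMT sets, and correlated
biological variation between proteins. Passing tests therefore demonstrate
correctness of the estimators and decision rules under the stated noise
model, not robustness to every artefact of real acquisitions. One
consequence worth knowing: because sample-level quantities (the histone
anchor sum, heavy-tail proteins) are shared across all proteins in a
sample, p-values from the full simulated pipeline are slightly correlated
across proteins even under the null; the calibration test for the
moderated t therefore feeds the statistic i.i.d. matrices, which is the
contract the statistic itself makes.

# Numerical choices and degenerate inputs

* Tolerances: conservation identities are asserted at $10^{-9}$ relative
  or better; oracle equivalences at $10^{-10}$–$10^{-12}$.
* All-zero reporter rows with positive MS1 are excluded and counted, never
  zeroed silently; samples with zero histone signal are an error naming the
  sample.
* Zero fold-change sd suppresses all star labels with a warning rather
  than dividing by zero.
* $\pi_0$ is clipped to $(0, 1]$; q-values are clipped at 1 and made
  monotone by the running-minimum construction.
* Ties at the top-fraction boundary include the crossing protein.
* The trigamma inversion runs Newton from Stirling-motivated start values
  with closed-form limits for extreme arguments.

# Problem sizes in the test suite

The shipped tests run the full generator-to-summary pipeline at 8000
proteins × 24 channels for the noise-free identity, and use 1000–2000
protein fixtures for recovery and QC properties — sizes at which
heavy-tailed proteome mass no longer makes per-sample content jitter
comparable to the QC threshold. Calibration and prior-recovery simulations
use 5000 features. The whole suite completes in well under a minute on a
single CPU.

# Limitations

* Absolute copy numbers inherit the uncertainty of the DNA-mass constant
  and the histone list; comparisons *between* samples are unaffected
  (scale invariance), absolute values shift proportionally.
* Only two-group contrasts are provided; no multi-factor designs, trended
  priors or fold-change-threshold (TREAT-style) tests.
* ORA is hit-list based; no rank-based (GSEA-style) or topology-aware
  enrichment.
* Isotope-impurity correction is assumed to have been applied upstream
  (corrected reporter columns are preferred when present, and the choice
  is logged).
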