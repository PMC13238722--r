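---
title: "Methods: from PTEN immunohistochemistry to a prognostic stromal signature"
author: "stromasig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from PTEN immunohistochemistry to a prognostic stromal signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromasig)
```

# The problem

Genomic loss of *PTEN* is among the most frequent events in prostate
cancer, but DNA assays miss non-genomic inactivation, and
immunohistochemistry (IHC), while spatially precise, says nothing about the
downstream remodeling of the tumor microenvironment. `stromasig`
implements an inference chain that connects the two: semi-quantitative
scoring of epithelial PTEN protein on tissue-microarray cores, a
data-driven cutoff separating PTEN-loss from PTEN-presence tumors,
covariate-adjusted differential expression and signed co-expression
network analysis on matched bulk RNA-seq, derivation of a stromal module
signature from the module-by-DEG intersection, and Cox
proportional-hazards sub-stratification of recurrence-free survival by
that signature.

Because the original patient data cannot ship with a package, a synthetic
cohort generator with planted ground truth stands in for them; every
stage is tested against that ground truth or against an independent
oracle.

# IHC scoring and quality control

Each patient contributes up to two 1-mm tumor cores. A core passes QC iff
tumor tissue is present **and** the stromal PTEN stain is positive —
stromal cells physiologically retain PTEN, so a negative stroma flags a
preservation or staining problem rather than biology. Failure reasons are
recorded (`no_tumor`, `stroma_negative`, `staining_failure`,
`core_absent`), and a patient is included iff at least one core is valid.

On valid cores the H-score weights the percentage of epithelial cells per
staining intensity:

$$H = 3\cdot\%\text{strong} + 2\cdot\%\text{moderate} + 1\cdot\%\text{weak} \in [0, 300],$$

and the patient value is the mean over valid cores. The binary PTEN call
is `loss` iff $H \le t$ for a cutoff $t$; with the calibrated cutoff
$t = 0$, loss means an exactly-zero H-score. This "$\le$" reading is the
only one under which a zero cut on a non-negative score produces two
non-trivial groups.

**Threshold calibration.** The cutoff is not fixed a priori: for every
candidate $t$ (by default all distinct observed H-scores up to the
median) the cohort is split at $t$ and the groups' PI3K–AKT–mTOR activity
signature scores are compared with a two-sided Wilcoxon rank-sum test
(exact enumeration when $n \le 12$ without ties; the normal approximation
with tie and continuity corrections otherwise). The candidate with the
smallest p-value among splits leaving both groups at least `min_group`
patients (default 10) wins; ties break toward the smaller threshold. The
source study monitored "statistical differences in the mean expression"
across thresholds while reporting Wilcoxon tests for all displayed group
comparisons; we adopt the rank-sum test throughout for consistency and
robustness to the skewed score distributions.

# Expression preprocessing

Counts are filtered (a gene is dropped when it has fewer than 5 counts in
*more than* 70% of samples — 90% for the mouse profile), then TMM
normalization factors are computed exactly in the canonical form: trimmed
(30% on M, 5% on A) precision-weighted mean of log-ratios against a
reference column chosen by upper-quartile proximity, factors rescaled to
geometric mean one. Log-CPM uses
$\log_2\!\big((y + 0.5)/(N f + 1)\cdot 10^6\big)$ with effective library
size $Nf$.

The variance-stabilizing transform is approximated by a shifted log,
$\log_2(\tilde y + 2)$ on library-size-normalized counts. The pseudo-count
of 2 was chosen once by measuring the slope of log gene variance against
log gene mean on negative-binomial simulations at FFPE-like dispersion
(0.2): the slope is ≈ +0.04 at pseudo-count 2, versus −0.27 at 1 and
+0.52 at 4, comfortably inside the |slope| < 0.3 flatness requirement.
Because the network stage consumes only correlations, the approximation
is adequate there; it is *not* a substitute for a dispersion-fit VST in
settings where absolute stabilized values matter.

# Differential expression

Per-gene linear models are fitted on log-CPM with group (loss vs
presence) plus z-scored age and DV200 covariates for the human profile
(the mouse profile is group-only; the study does not state covariates for
the mouse design). Precision weights follow the voom recipe: quarter-root
residual standard deviations are smoothed against average log-count with
lowess (span 0.5, predictions clipped at the curve ends), and each
observation receives the inverse fourth power of its predicted
quarter-root SD at its fitted log-count. Residual variances are then
shrunk empirically-Bayes style: hyperparameters $(d_0, s_0^2)$ are
estimated by moment matching on the log variances (mirroring the
established implementation, including the offset of exact-zero variances
to $10^{-5}$ of the median), the posterior variance is
$(d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, and the moderated t carries
$d_g + d_0$ degrees of freedom. A closed-form fallback ($d_0 = 4$) covers
degenerate tiny inputs. p-values are two-sided throughout; BH step-up
gives the FDR.

DEGs are called at strict inequalities: $|\log_2 FC| > 0$ and FDR < 0.05
(human), $|\log_2 FC| > 1$ and FDR < 0.05 (mouse).

# Co-expression network and modules

The network is signed: adjacency $a = ((1+r)/2)^\beta$, so
anti-correlated genes are pushed toward zero and modules are
co-directional. The correlation $r$ is the biweight midcorrelation with
outlier capping (`maxPOutliers = 0.1`: weights are rescaled so at most
10% of observations per side can receive zero weight), with per-vector
Pearson fallback when the MAD is zero. The power defaults to the study's
profiles (human β = 14, mouse β = 18); `pickSoftThreshold()` reproduces
the scale-free selection using a signed Spearman correlation — the
statistic the study names at this step — binning log connectivity and
regressing log frequency on log mean connectivity.

Topological overlap converts shared neighborhoods into similarity,
$TOM_{ij} = (\ell_{ij} + a_{ij})/(\min(k_i,k_j) + 1 - a_{ij})$ with
$\ell_{ij} = \sum_u a_{iu}a_{uj}$, and $1 - TOM$ is clustered with
average linkage. Module detection simplifies the dynamic hybrid tree cut
to a static cut at a quantile of the merge heights mapped from
`deepSplit` (1 → 0.995, 2 → 0.99, 3 → 0.98, 4 → 0.95; deeper split, lower
cut), followed by the standard size filter (min 30, below which genes go
"grey") and iterative merging of modules whose eigengene dissimilarity
$1 - r$ falls under `mergeCutHeight` (human 0.1, mouse 0.25). On the
planted-block simulations in the test suite this simplification recovers
the blocks essentially perfectly; it will be cruder than the hybrid cut
on tangled empirical dendrograms, which is a documented limitation.
Block-wise decomposition is not re-implemented; a single block with a
variance-ranked gene cap (default 8000) covers desk-scale inputs.

Module eigengenes are the first principal component of the standardized
member matrix, unit variance, sign-aligned to positive mean member
correlation. Module–trait association is Pearson r with BH correction
across all module × trait pairs, significant at |r| > 0.2 and FDR < 0.05.
Module names follow the conventional color order by size rank
(turquoise, blue, brown, ...), so labels are reproducible across runs.

# Signature derivation and scoring

The candidate module is the one with the highest Jaccard overlap
$|D \cap M| / |D \cup M|$ with the DEG set among modules significantly
and positively associated with PTEN loss. Its signature is the sorted
DEG ∩ module gene set. Both up- and down-regulated members are kept by
default — the study describes the green-module signature simply as "the
DEGs in the green module" — and a `direction = "up"` option exposes the
upregulated-only variant. Scores are the per-sample mean of gene-wise
z-scores (n−1 denominator; zero-variance genes contribute 0 so degenerate
synthetic inputs stay defined), with coverage reported as the fraction of
signature genes found.

# Survival stratification

Kaplan–Meier curves use the product-limit estimator; the log-rank test
uses observed-minus-expected sums with hypergeometric variance. Cox
models are fitted by Newton–Raphson (step-halving; convergence at
gradient norm < 1e-8) on the **Efron** tie-corrected partial likelihood —
month-resolution times tie heavily and the study does not state its tie
method, so the better tie approximation was chosen. Standard errors come
from the inverse observed information, confidence intervals are Wald on
the log-hazard scale, and Harrell's concordance is computed over usable
pairs with half-credit for risk ties.

Stratification follows the study's three analyses: (i) extreme quartiles
of the signature score (linear-interpolation quantiles; ties at a
cutpoint fall to the lower quartile, making strata invariant under
monotone transforms) compared Q1 vs Q4 by log-rank; (ii) nested Cox
models PSA + Gleason versus PSA + Gleason + z-scored signature compared
by likelihood ratio, with the combined linear predictor split at its
median (ties to low risk); (iii) the same Q1/Q4 contrast inside the
PTEN-loss subset, with quartiles recomputed **within the subset** — the
study is ambiguous on this ordering, and the within-subset choice is the
default because it keeps the subset strata balanced; the cohort-wide
alternative is available by stratifying before subsetting. Gleason
enters as the numeric score sum (6–10); the study does not state its
encoding, and the encoding is the caller's choice.

No proportional-hazards diagnostics are run; with a single planted
exponential hazard the assumption holds by construction in the synthetic
world, and on real data the usual caveats apply.

# The synthetic cohort: what it emulates

`simulateCohort()` draws, per patient: a zero-inflated right-skewed
H-score (point mass at zero — default half the cohort, matching the
roughly half/half split at the zero cut — plus a rounded Gamma(0.9,
scale 72) right tail); two cores whose intensity percentages are the
deterministic inverse of the H-score formula, each failing QC
independently with probability 0.5, so both cores fail for ≈ 25% of
patients (the study excluded 50/197); and clinical covariates with
cohort-like moments (age ~ N(62.8, 6.2²), PSA log-normal around 6.4
ng/mL, Gleason 6–9, DV200 uniform 40–90).

Counts are gene-wise negative binomial (dispersion 0.2, FFPE-like) with
log-normal baselines and mean $2^{\text{baseline} + \text{factors} +
\text{effects}}$: a handful of planted modules driven by per-sample
latent factors (SD 1 in log2 units), a 105-gene PI3K-activity set
up-shifted by 1 log2 unit in loss samples, and the first planted module
("stromal", 75 genes — the size of the study's green signature)
up-shifted likewise. Loss effects appear exactly in the patients with
H-score 0, so the true calibration threshold is 0. Library sizes are
log-normal (CV 0.2) around 1e6 — desk-scale, not sequencing-scale.
Survival times are exponential with hazard
$\lambda_0 \exp(\beta z)$ where $z$ is the z-scored planted signature
(latent factor plus loss shift), $\beta = \log 0.68$ per SD (the study's
reported effect), baseline median 120 months, and independent uniform
censoring over a ~110-month administrative window; at the default
settings roughly a quarter of patients experience events, the same order
as the cohort's 49/188. The effect sizes on the log2 scale are free
parameters — the study reports none — chosen once at 1.0 as a clearly
detectable but not overwhelming two-fold shift.

Each output block (counts, IHC, clinical, survival) draws from its own
stream derived from the master seed, so adding one block never perturbs
another's draws, and identical configuration + seed is bit-identical.

**What a green test does and does not establish.** Recovery of the
planted threshold, module, signature and hazard ratio shows the chain is
implemented correctly and has the claimed operating characteristics
*under this generative model*: independent NB noise around low-rank
structure, a single binary driver, proportional hazards, ignorable
censoring. Real FFPE cohorts add batch structure, GC/length biases,
correlated dropouts, subclonal heterogeneity and non-proportional
hazards, none of which the generator emulates — so green tests validate
the software and the statistics, not the biology.

# Numerical choices

* TMM: canonical trim fractions 0.30/0.05 with precision weighting;
  all-zero genes are dropped before reference selection (library sizes
  keep full column sums); factor forced to 1 when the trimmed mean is
  numerically zero.
* Rank-sum: exact enumeration bound at combined n ≤ 12 without ties;
  continuity correction 0.5 in the normal branch.
* voom lowess span 0.5; weights floored to positive finite values;
  single-gene input falls back to unit weights with a warning.
* Eigengene sign: aligned to positive mean member correlation; kME of
  constant genes set to 0.
* Cox: covariates centered internally (the partial likelihood is
  invariant); singular information reported as likely separation;
  100-iteration cap.
* Quartiles: type-7 quantiles; ties at cutpoints to the lower stratum.
  Median risk split: ties to low risk.
* H-scores kept at full precision internally; displayed rounding only.

# Known limitations

* The static-cut module detection underfits nested or unbalanced module
  structure relative to the dynamic hybrid cut.
* The shifted-log VST is calibrated for correlation work, not for
  absolute variance-stabilized values.
* The moment-matching empirical-Bayes estimate of $d_0$ is unstable on
  near-homoscedastic data (it diverges, correctly, toward infinity); the
  moderated t then approaches the normal, which is the intended limit.
* The generator's stated world is intentionally simple; see above for
  what it does not emulate.
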