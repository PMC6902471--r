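---
title: "Methods: the longitudinal linear combination test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the longitudinal linear combination test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(llct)
```

## The problem

A longitudinal omics study measures a set of phenotypes repeatedly per
subject at subject-specific times, together with a single
subjects-by-genes expression matrix. A self-contained gene set test asks:
is *this* set of genes associated with how the phenotypes change over
time? The data are high-dimensional in an awkward way — a set may contain
more genes than there are subjects — and visit counts are unbalanced, so
neither a mixed model per gene nor a classical canonical correlation is
directly usable. `llct` addresses both with a two-step construction.

## Step 1: within-subject trends

For subject $i$ with $n_i$ visits, phenotypes $Y_i$ ($n_i \times M$),
polynomial time design $Z_i$ ($n_i \times Q_{\text{full}}$) and optional
time-varying covariates $W_i$ ($n_i \times Q'$), we fit one joint OLS
regression

$$Y_i = Z_i \beta_i + W_i \gamma_i + \varepsilon_i .$$

Choices made here, and why:

* **Per-subject fixed regression, not a mixed model.** Each subject's
  trend is a summary statistic carried into Step 2; no strength is
  borrowed across subjects, so unbalanced and incomplete visit schedules
  are handled for free. Random-effect fitting is deliberately out of
  scope.
* **Joint estimation of $\gamma_i$**, not residualisation: the covariate
  adjustment is part of one linear model. The $\gamma_i$ are never passed
  to Step 2 — the test is about time trends, adjusted for the covariates.
* **Intercept included in the design but not passed on** (default). The
  test targets correlation between expressions and *trends*; the fitted
  baseline level is passed only when `pass_intercept = TRUE`, which is
  how the time-course baseline ("is the set expressed differently before
  treatment at all?") comparison is run, together with `degree = 0`. The
  constructor otherwise enforces `degree >= 1`.
* **Degree is a user choice, default 1.** There is no automatic degree
  selection: a selection rule would change the null distribution and
  nothing principled is specified for it.
* **Subjects that cannot support the design are excluded**, not fitted
  with a reduced design: the stacked block needs a common $Q$ across
  subjects. Exclusions (too few visits, duplicated times) are listed
  with reasons in the `trend_block`. With two visits and two time-varying
  covariates this exclusion is exactly the practical restriction to
  subjects with more than two measurements.
* **Times enter raw** (no centering/rescaling) so that the simulation's
  generative model and the analysis see the same time scale;
  `center_time = TRUE` is available for numerical conditioning with
  high-degree polynomials.

The retained rows are stacked into
$B = [\beta_1^\top | \dots | \beta_I^\top]^\top$, an $(I\cdot Q) \times M$
block; gene expressions are stacked into the row-duplicated
$(I\cdot Q) \times P$ block $G$ (each subject's gene row repeated $Q$
times, keeping the two blocks row-aligned).

## Step 2: the shrinkage linear combination statistic

With $\Sigma_{G,B}$ the sample cross-covariance and
$\Sigma^*_{G,G}, \Sigma^*_{B,B}$ shrinkage estimates of the within-block
covariances, the statistic is

$$T^{2*} = \max_{A,\Gamma}
\frac{(A^\top \Sigma_{G,B} \Gamma)^2}
     {A^\top \Sigma^*_{G,G} A \cdot \Gamma^\top \Sigma^*_{B,B} \Gamma},$$

computed as the largest squared singular value of
$D_G^{-1/2}\Psi^\top \Sigma_{G,B} \Omega D_B^{-1/2}$ after
eigendecomposing $\Sigma^*_{G,G} = \Psi D_G \Psi^\top$ and
$\Sigma^*_{B,B} = \Omega D_B \Omega^\top$. With zero shrinkage and full
rank this is exactly the squared first canonical correlation, so
$T^{2*} \in [0,1]$ there; shrinkage trades that exact interpretation for
existence when $P \ge I$.

* **Shrinkage target and intensity.** The target is the diagonal of the
  sample covariance, with the analytic intensity
  $\lambda^* = \operatorname{clip}\!\big(\sum_{i \ne j}
  \widehat{\operatorname{Var}}(s_{ij}) \big/ \sum_{i \ne j} s_{ij}^2,\,
  0, 1\big)$ (Schäfer–Strimmer style). This target preserves the
  variances appearing in the statistic's denominator and guarantees
  positive definiteness when any column varies. The literature the
  method builds on does not pin down the exact estimator variant; the
  diagonal-target covariance shrinkage is this package's documented
  choice. Both degenerate cases ($d = 1$; exactly uncorrelated columns
  giving 0/0) return intensity 0.
* **Only the within-block covariances are shrunk.** The cross-covariance
  in the numerator is left untouched — shrinking it would bias the
  statistic toward zero without improving conditioning.
* **Centering, $n-1$ denominators.** Both blocks are column mean-centered
  before any covariance; all covariances are unbiased ($n-1$). No
  variance standardisation by default (`standardize = TRUE` flips this;
  it changes the statistic when gene scales differ wildly).
* **Rank tolerance.** Eigencomponents with eigenvalue
  $\le 10^{-10} \times$ the largest are treated as null space and dropped
  from the whitening; configurable via `rank_tolerance`.
* **Sign convention.** Singular vectors are defined up to sign; the first
  nonzero entry of $\eta$ is made positive and $\theta$ follows, so
  loadings are reproducible.

## Permutation inference

P-values permute **whole subjects**: the $Q$ consecutive gene rows of a
subject move together relative to the trend rows. A subject permutation
changes neither within-block covariance, so $\Psi, D_G, \Omega, D_B$ are
computed once per gene set and only the cross-covariance (and its largest
singular value) is recomputed per replicate — the computational point of
the orthogonal-basis form. The estimator is the add-one rule
$p = (1 + \#\{T^{2*}_{\text{perm}} \ge T^{2*}_{\text{obs}}\}) /
(1 + n_{\text{perm}})$, a valid Monte-Carlo p-value that never returns 0.
Default $n_{\text{perm}} = 1000$, matching the method's original
evaluation; 199 is used in the package's own simulation harness to keep
runtimes down, and is stated wherever it is used.

Each gene set draws its permutations from a seed derived from the master
seed and a stable hash of the set's *name*, so per-set p-values are
independent of the order (or parallel grouping) in which sets are
analysed.

## Family-clustered data

When subjects are nested in families they are not exchangeable
individually. The permutation unit becomes the family: labels are
permuted **among families of equal size**, and a family's subjects move
together (within-family order fixed). With all families singletons this
reduces replicate-for-replicate to the subject permutation. If no two
families share a size the scheme has no non-trivial permutations and the
function refuses to run rather than return an anticonservative answer.
The formal derivation in the method's supplementary material is not
available; equal-size label swaps are this package's concrete,
exchangeability-preserving choice, and the clustered-null test in the
suite checks that it holds its size when within-family correlation is
strong.

## Time-course mode

When gene expressions are themselves the repeated measurements, the roles
swap: Step 1 fits each *gene's* time trend per subject (genes play the
role of the $M$ phenotypes), and Step 2 correlates subject-level
covariates (the "G" side) with the stacked gene-trend coefficients.
Stage-wise analysis restricts visits to a closed time window
$[t_0, t_1]$ (endpoints inclusive; a time listed in two windows belongs
to both); a window leaving fewer than two distinct times cannot support a
trend and errors, unless the intercept-only baseline design is used.

## The simulation world

The generator states one fixed evaluation world; its defaults are not
tuning knobs. Gene sets are $\text{MVN}(M_G, \Sigma_G)$ per subject with
compound-symmetric $\Sigma_G$ (variance $\sigma_G^2 = 0.5$, common
correlation $\rho_G$, default 0.5; AR(1) available for robustness
studies), and $M_G$ redrawn per simulated set from an exponential with
rate 0.7 truncated to $[0, 5]$. The phenotype follows

$$y_{ij} = B_1\,GS_i + B_2\,t_{ij} + B_3\,GS_i\,t_{ij}
 + b_{0i} + b_{1i}\,t_{ij} + \varepsilon_{ij},$$

with $GS_i = \sum_p G_{ip}$, $B_2 = 0.3$, $b_{0i} \sim N(0,1)$,
$b_{1i} \sim N(0,2)$, visit times uniform on $(1, 10)$ sorted within
subject, and AR(1) errors
$\operatorname{cor}(\varepsilon_k, \varepsilon_l) = \rho_\varepsilon^{|k-l|}$
indexed by **measurement order**, not time gap. Three quantities are not
stated in the source evaluation and are package choices, configurable and
held fixed: $\sigma^2_\varepsilon = 1$, the truncation bound 5 (nothing
downstream depends on it — the means shift columns, and the statistic
centers them away), and $B_1, B_3$ applied as common scalars across
genes. The null world sets $B_1 = B_3 = 0$.

What the generator emulates: unbalanced continuous visit times,
within-set gene correlation, between-subject heterogeneity in level and
slope, serially correlated errors. What it does not: measurement-level
missingness, family structure (built separately in the clustered tests),
non-Gaussian expression distributions, and any real-data normalisation
artifacts — a green simulation test says the statistic and its
permutation null behave as designed, not that any particular biological
dataset will.

The rejection-rate harness runs the *full* pipeline (simulation →
Step 1 → Step 2 → permutation) per replicate and reports an exact
Clopper–Pearson 95% binomial interval. The suite's acceptance tests use
500 null sets / 199 permutations (type-I error, p-value uniformity) and
200 sets per condition (power ordering in $\rho_G$, $I$, $P$;
insensitivity to $\rho_\varepsilon$ and visit count), a deliberate
scale-down from the original 1000/1000 to fit a test-suite budget; the
full setting is one `simulation_config()`/`estimate_rejection_rate()`
call away.

## Numerical and degenerate-input policy

* OLS via QR; a rank-deficient per-subject design is an identifiability
  error naming the subject (or an exclusion, in block assembly).
* Constant genes are dropped per set (with counts); a set with no usable
  genes is a recorded per-set failure, not a fatal error.
* An all-constant block, or a covariance with no eigenvalue above
  tolerance, is a degenerate-analysis error.
* Ties in the permutation distribution count against rejection
  ($\ge$ in the add-one rule), the conservative direction.
* Prioritization scores use the one-based min-rank fraction
  $(\#\{p_j < p_i\} + 1)/N$, so tied sets share a score and a unique
  minimum among $N = 247$ sets prints as $1/247 = 0.4\%$ at one decimal.

## Known limitations

* Step 1 offers polynomial bases only (no splines), and no automatic
  degree selection.
* The family scheme permutes only across equal-size families; highly
  unequal family-size distributions lose permutations and hence
  resolution.
* The test is self-contained (subject permutation); it does not answer
  the competitive question of whether a set stands out against the rest
  of the genome.
* Shrinkage intensities are estimated once from the observed blocks and
  reused across permutation replicates, consistent with the
  fixed-whitening construction; with very few subjects this is a known
  source of mild miscalibration common to all fixed-transform
  permutation tests.
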