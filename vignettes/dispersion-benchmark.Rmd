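---
title: "Benchmarking negative-binomial dispersion estimators by simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking negative-binomial dispersion estimators by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbdispbench)
```

## The model

Counts for gene $g$ in library $j$ are modeled as
$y_{gj} \sim \mathrm{NB}(\mu_{gj}, \phi_g)$ with
$\mathrm{Var}(y_{gj}) = \mu_{gj} + \phi_g \mu_{gj}^2$ and
$\mu_{gj} = \lambda_{g,\tau(j)} \, L_j$, where $\tau(j)$ is the treatment
group of library $j$ and $L_j$ an effective library size. As
$\phi_g \to 0$ the distribution converges to Poisson($\mu_{gj}$), so
$\phi_g$ measures extra-Poisson variance. The package fixes this
parameterization throughout; the size parameter $r = 1/\phi$ appears only
inside calls to the `stats` NB routines. Below $\phi < 10^{-10}$ all
probability computations switch to the Poisson limit — at that point the two
pmfs agree to well below double-precision resolution and the switch avoids
log-gamma cancellation.

The study design is deliberately narrow: two treatment groups, completely
randomized, no additional covariates. `DesignInfo`-style inputs (normalization
factors, library sizes) do not forbid richer designs, but no estimator here is
exercised beyond two groups.

## The simulator

`generate_pseudo_dataset()` produces a count matrix with a full per-gene truth
table:

1. **Parameter pool.** A pool of per-gene pairs (baseline geometric mean
   $m_g$, true dispersion $\phi_g$) is sampled *without replacement*, keeping
   each pair together so the joint mean–dispersion structure of the pool
   survives into the truth table exactly.
2. **DE flags.** Exactly `n_genes * de_fraction` genes (20% by default) are
   flagged differentially expressed — the count is deterministic, not
   binomial.
3. **Log fold changes.** DE genes receive $\delta_g$ drawn from a
   block-diagonal multivariate normal: 40 blocks of 50 by default, each
   block's correlation matrix drawn uniformly over the space of correlation
   matrices by the C-vine construction (`rcorr_matrix()`), with
   standard-normal marginals. `block_size = 1` gives independent draws; EE
   genes have $\delta_g = 0$.
4. **Group means.** The split is symmetric,
   $\mu_{g1} = m_g e^{+\delta_g/2}$, $\mu_{g2} = m_g e^{-\delta_g/2}$, chosen
   so that $m_g$ remains the across-treatment geometric mean — the property
   that defines $m_g$ in the pool.
5. **Counts.** Each $y_{gj} \sim \mathrm{NB}(\mu_{g,\tau(j)}, \phi_g)$.
6. **All-zero redraw.** A gene whose simulated counts are all zero keeps its
   $(m_g, \phi_g)$ pair and its DE flag (preserving the exact DE fraction and
   the pool pairing), has $\delta_g$ redrawn from its marginal (0 for EE
   genes), and its counts redrawn until at least one read appears.

Randomness is organized as one master seed per dataset with deterministic
sub-streams for pool sampling, DE flagging, fold changes and counts, so
changing only the group sizes leaves the gene-level truth untouched.

### Pool presets

Real pools would be harvested from deeply replicated datasets; the package
emulates two contrasting regimes parametrically (`emulate_pool()`). All
constants live in one place (`pool_presets`):

| preset | log-mean | log-dispersion trend | scatter |
|---|---|---|---|
| `pickrell-like` | $N(1.6, 1.8^2)$ | $0.3 - 0.25\log m$ | $0.8\,t_4$ |
| `hammer-like`   | $N(4.5, 1.8^2)$ | $-1.5 - 0.25\log m$ | $0.25\,t_4$ |

The presets encode three qualitative contrasts: the hammer-like pool has
higher mean counts, lower dispersions, and a markedly tighter dispersion
scatter around its trend, whereas the pickrell-like pool has low counts and
wide, high dispersions (center near 1, spanning orders of magnitude). The
heavy-tailed $t_4$ scatter produces the occasional extreme dispersion that
real pools show. Dispersions are clamped to $[10^{-4}, 20]$ and means floored
at 0.05. These are invented emulators: passing benchmarks under them shows
that method orderings hold in these regimes, not that any particular tissue
or organism is reproduced. Users with real (mean, dispersion) pairs can load
them from TSV (`load_pool()`), where zero counts should be replaced by a
small constant (0.5 by convention here) before geometric means are taken.

`study_settings()` returns the six benchmark designs — pickrell-like with
3+3, 3+15 and 9+9 libraries and hammer-like with 3+3, 3+16 and 9+9 — each
with 10,000 genes, 20% DE, 40 blocks of 50.

## Normalization

`median_of_ratios()` computes the Anders–Huber factors: each count is divided
by its gene's across-library geometric mean, and the library's factor is the
median of those ratios (genes containing any zero are skipped). Because the
published conversion from factors to adjusted library sizes is not fully
specified, the package uses the total-conserving rescaling
$L_j = c_j \sum_j N_j / \sum_j c_j$: it preserves the factors' relative sizes
and reduces to equal sizes when all factors agree, which is the typical state
of the simulator's output (library sizes do not vary systematically there).
An option to bypass normalization entirely (`normalization = "none"`) is
exposed since results under the two choices are expected to agree.

The conditional-likelihood estimators require equal library sizes.
`quantile_adjust()` maps each count through its fitted NB cdf at the
library's effective size and back through the inverse cdf at the geometric
mean size. The mapping uses the deterministic mid-distribution probability
$(F(y-1) + F(y))/2$ rather than a randomized correction: determinism was
preferred over distributional exactness because in this study the adjustment
is nearly an identity (it *is* the identity when sizes are equal), and it
keeps the whole pipeline reproducible bit for bit. The adjustment is iterated
twice with the current common-dispersion estimate.

## The estimators

All estimators floor their output at `min_dispersion = 1e-4` (configurable).
The floor mirrors the common minimum that genewise methods assign to genes
showing no overdispersion; it is visible as a vertical bar in scatter plots
of genewise estimates.

* **`ql.genewise`** alternates NB mean MLEs at fixed $\phi$ (per-group 1-D
  Newton in log-rate; the weighted-mean closed form is exact only at
  $\phi = 0$ and serves as the start) with solving the quasi-likelihood
  moment equation $\sum_j (y_{gj}-\hat\mu_{gj})^2 / (\hat\mu_{gj} +
  \phi\hat\mu_{gj}^2) = J - 2$ by vectorized bisection; genes whose Pearson
  statistic never exceeds the residual df have no positive root and take the
  floor.
* **`qcml.common` / `wqcml.tagwise`** work on quantile-adjusted pseudo-counts.
  The conditional likelihood of a group's counts given their sum has a
  mean-free log-gamma closed form; groups with one library contribute
  nothing. The common estimator maximizes the genewise sum; the tagwise
  estimator maximizes $\ell_g(\phi) + W\,\bar\ell(\phi)$ with $\bar\ell$ the
  per-gene average common curve, so $W$ counts equivalent genes.
* **`apl.common` / `apl.trended` / `apl.tagwise`** use the Cox–Reid adjusted
  profile likelihood: NB GLM fit at fixed $\phi$ (log link, log-size offset)
  minus $\tfrac12 \log\det(X^\top W X)$. The common variant maximizes the
  mean APL; the trended variant estimates a common dispersion in each of 20
  equal-occupancy abundance bins (bins are cut on abundance *values* at
  quantile breakpoints, so tied abundances share a bin and the fit is
  invariant to gene order), smooths log-dispersion against abundance by
  degree-1 local regression, and clamps fitted values to the range of the bin
  estimates; the tagwise variant shrinks each gene toward the mean APL of its
  $K = 50$ nearest abundance neighbors ($K$ capped at $G/4$; the window
  includes the gene itself).
* **`mom.genewise` / `mom.trended` / `mom.maximum`** follow the
  method-of-moments route on directly normalized counts: raw variance
  $v_g = w_g - \hat q_g\,\overline{1/c}$, where $w_g$ is the pooled
  within-group sample variance of $y_{gj}/c_j$ and the bias term is chosen so
  that $v_g \approx 0$ under Poisson truth; $\hat\phi_g = v_g^+/\hat q_g^2$.
  The trend is a local regression of $\log v$ on $\log \hat q$ (non-positive
  $v$ excluded; fitting on the log scale keeps fitted variances positive),
  and the maximum variant takes the elementwise max of genewise and trended —
  conservative by construction.
* **`dss`** is the empirical-Bayes posterior mode: genewise moment estimates
  set a log-normal prior by method of moments (prior log-mean = mean log
  genewise estimate over genes with positive raw variance; prior log-variance
  = their variance minus the median estimation noise, approximated by the
  chi-square log-variance $2/\mathrm{df}$, floored at 0.01), and each gene
  maximizes profile NB log-likelihood plus log prior density over $\phi$.

### The tagwise shrinkage weight

The default weight for `wqcml.tagwise` and `apl.tagwise` is set by
empirical-Bayes moment matching: the between-gene variance $V$ of the
genewise log-dispersion maximizers, minus the approximate per-gene estimation
variance $2/\mathrm{df}$, estimates the true between-gene spread $\tau^2$
(floored at 0.01), and $W = (2/\mathrm{df})/\tau^2$ equates the prior's
precision with the spread. The consequence is the behavior one wants from
moderate shrinkage: in a wide-spread regime (pickrell-like) the data carry
real gene-specific signal and $W$ stays near or below 1; in a tight-spread
regime (hammer-like) genewise noise dominates and $W$ grows. A fixed $W$
cannot do both — it over-shrinks exactly where per-gene signal matters most —
which is why the adaptive rule is the default and fixed weights remain
available as arguments (and as the $W=0$ / $W\to\infty$ limits used in
tests).

### Numerical strategy

Common estimators use Brent optimization on $\log\phi \in [\log 10^{-6},
\log 50]$. The tagwise and posterior-mode estimators first evaluate their
objective on a coarse log-spaced grid (vectorized across genes), then refine
within the bracketing grid cells by a vectorized golden-section search to
$10^{-4}$ in $\log\phi$. For `apl.tagwise` at large $G$ the smooth, slowly
varying neighborhood term is approximated inside the bracket by its local
quadratic through the three bracketing grid values while the gene's own APL
is evaluated exactly; at small $G$ ($\le 200$) the exact windowed objective
is optimized directly, which is the path the oracle-equivalence tests
exercise. On five-gene fixtures every likelihood-based estimator agrees with
an independent brute-force maximizer of its stated objective to $10^{-3}$ in
log dispersion.

## The tests

The **exact tests** condition the two group sums on their total. On
size-equalized pseudo-counts the group sum of $n$ i.i.d.
$\mathrm{NB}(\mu_0, \phi)$ variables is exactly
$\mathrm{NB}(n\mu_0, \phi/n)$; with unequal sizes (the factor-based variant)
the sum is approximated by the NB with matched mean and variance,
$\phi_A = \phi \sum c_j^2 / (\sum c_j)^2$, which reduces to the exact form at
equal sizes. The two-sided p-value is the total conditional probability of
all splits no more probable than the observed one (the doubling-free
convention; a doubled-smaller-tail rule sits behind `tail_rule =
"doubled"`). Splits are enumerated fully up to totals of $10^5$; beyond
that, enumeration is restricted to a window outside which terms underflow
double precision relative to the conditional mode, leaving tail sums and the
normalizing constant unchanged at working precision.

The **quasi-likelihood family** gives each gene a quasi-dispersion
$\sigma^2_g$ = residual deviance / residual df from the full NB GLM at fixed
$\hat\phi_g$; under the exact NB model these concentrate near 1. The F
statistic is the deviance drop from the intercept-only fit divided by
$\sigma^2_g$ (test df = 1 for two groups). `QL` uses the raw value;
`QLShrink` shrinks $\log\sigma^2$ toward a common value by moment matching
with digamma/trigamma identities (the scaled-inverse-chi-square conjugate
form), adding the estimated `prior_df` to the denominator df; `QLSpline`
first fits a natural cubic spline (4 df) of $\log\sigma^2$ on abundance and
shrinks residuals around the fitted trend the same way. Both shrinkage rules
are exposed with `prior_df` and `sigma2` hooks so alternative rules can be
swapped without touching callers. The family requires replication (residual
df ≥ 1) and errors otherwise.

## Evaluation

`transformed_mse()` averages squared errors of $t(\phi) = \phi/(1+\phi)$, a
bounded transform that caps any single gene's contribution at 1 and thereby
robustifies the MSE against extreme estimates. `roc_points()` counts, at each
significance level $\alpha$ of a fixed grid (400 log-spaced points in
$[10^{-6}, 1]$, shared by every curve), the EE genes (false positives) and DE
genes (true positives) with $p < \alpha$. `partial_auc()` integrates the
left-continuous step function through the points — each interval contributes
width × TPR at its left endpoint, the curve starts at (0, 0) and the last
TPR extends to the cutoff — restricted to FPR ≤ 0.1. The step interpolation
deliberately lies beneath the linear one, which would inflate areas across
the gaps the discrete grid leaves in FPR. The 0.1 cutoff confines the
comparison to significance levels anyone would actually use; both the cutoff
and the grid are configurable but fixed package-wide by default.

`run_benchmark()` crosses settings × replicates × estimators × tests,
records MSE and partial AUC in a long-format table, always evaluates each
test with the *true* dispersions as the gold standard, and records per-cell
failures without aborting the run.

## Problem sizes

The package's own benchmark runs are scaled to 2,000 genes with 5 replicates
per setting (against the full study design of 10,000 genes × 30 replicates
× 6 settings). At this scale the method orderings of interest — shrinkage
beating the unshrunken method-of-moments estimator on MSE in the
hammer-like settings, and the moderate-shrinkage trio (`dss`,
`wqcml.tagwise`, `apl.tagwise`) leading the partial-AUC ranking in the
low-count pickrell-like setting — are stable across seeds, while a full run
of the test suite and the acceptance script stays in the minutes range on a
single core. One full-scale (10,000-gene) dataset is still generated when
checking the simulator's structural contract, since that contract is exact
and cheap to verify.

## Limitations

* The pool presets are parametric caricatures: they reproduce location,
  spread and trend contrasts between two published regimes, not any real
  gene catalog; conclusions about absolute performance on a specific tissue
  require a user-supplied pool.
* Library sizes are homogeneous by design; the benchmark does not probe
  normalization under systematic depth differences, multi-factor designs, or
  designs with more than two groups.
* The factor-based exact-test variant relies on a variance-matched NB
  approximation to a sum of non-identical NB variables (exact only at equal
  factors).
* Absolute partial-AUC values depend strongly on the standard-normal
  fold-change magnitudes and the FPR cutoff; only orderings across methods
  are meaningful, and only those orderings are asserted by the test suite.
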