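---
title: "Estimating gene-environment interaction heritability with gxeherit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating gene-environment interaction heritability with gxeherit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

For a quantitative trait measured together with genome-wide SNP genotypes and
many environmental variables, we want the proportion of phenotypic variance
explained by gene-environment (GxE) interactions — not at individual SNPs,
but genome-wide.  The environment of an individual is high dimensional, and
an unobserved driver of interactions is often better reflected by a
*combination* of measured environments than by any single one.  `gxeherit`
implements two method-of-moments estimators for this setting, both built on
randomized Haseman-Elston (HE) regression so that no $N \times N$ kernel
matrix is ever formed:

* **MEMMA** assumes each environmental variable interacts with the genome
  independently and fits one variance component per environment;
* **GPLEMMA** assumes interactions act through a single linear
  *environmental score* (ES) $\eta = Ew$ and estimates the score weights $w$
  jointly with the variance components by non-linear least squares.

Throughout, $X$ is the $N \times M$ genotype matrix standardized so each
column has mean 0 and variance 1 (denominator $N$, so
$\mathrm{tr}(XX^T)/M = N$ exactly), $E$ is the $N \times L$ standardized
environment matrix, $K = XX^T/M$ the genomic relationship kernel,
$F_l = \mathrm{diag}(E_l)X$, and $C$ the $N \times D$ covariate matrix.
Every column of $E$ is always included in $C$ (so $D > L$): covariate
projection then removes all *linear* environmental effects, and only
interaction structure can feed the GxE components.

## Randomized Haseman-Elston regression

HE regression picks variance components to minimize the squared Frobenius
distance between the observed trait covariance $yy^T$ and its model
expectation.  With covariates this is done on projected data: with
$W = I - C(C^TC)^{-1}C^T$, the multi-component normal equations are
$T\theta = c$ with

$$T_{kl} = \mathrm{tr}(W K_k W K_l W), \qquad c_k = y^T W K_k W y.$$

The quadratic forms $c_k$ are computed exactly in one pass over the
genotypes.  The traces $T_{kl}$ are estimated with Hutchinson's estimator,
$\mathrm{tr}(A) = \mathbb{E}[z^T A z]$ for $z \sim N(0, I_N)$, using a
single probe set shared across *every* trace term of an analysis.  Sharing
probes positively correlates the Monte-Carlo errors of the entries of $T$,
which stabilizes the subsequent solve.  The residual diagonal uses the
exact value $\mathrm{tr}(W) = N - D$ rather than an estimate.

Rather than transcribing per-term shortcut formulas, every trace is
assembled by *operator composition*: the full operator word (every $W$ and
every $\mathrm{diag}(E_l)$ the projected trace expression contains) is
applied to each probe, and the estimate is an inner product of
operator-applied probe vectors.  Because $W$ is idempotent,
$z^T W A W B W z = \langle WAWz,\; WBWz \rangle$, so all required traces are
entries of one Gram matrix over the dictionary

$$\{\, WKWz_b,\;\; Wz_b,\;\; W(F_lF_m^T/M)Wz_b \;\}.$$

This is the package's central data structure (`rhe_precompute()`).  One
streaming pass over genotype blocks accumulates $u_b = XX^TWz_b$,
$v_{b,l} = XX^T(E_l \odot Wz_b)$, the data quadratic forms
$q_K = \|X^TWy\|^2$ and $H_{l,m} = (E_l \odot Wy)^T XX^T (E_m \odot Wy)$,
and then the Gram matrix.  The `apply_operator()` / `estimate_trace()` pair
evaluates arbitrary operator words directly and is used by the test suite
to check every randomized trace against dense-matrix oracles on small
fixtures.

## MEMMA

The per-environment model places independent Gaussian effect-size priors on
main effects and on each environment's interaction effects, giving the
$(L+2)$-component covariance $\sum_k \theta_k K_k$ with $K_1 = K$,
$K_{l+1} = F_lF_l^T/M$ and $K_{L+2} = I$.  The moment system is solved
analytically and converted to per-component proportions of variance
explained (PVE)

$$\hat h^2_k = \frac{\hat\theta_k\,\mathrm{tr}(WK_kW)}
{\sum_j \hat\theta_j\,\mathrm{tr}(WK_jW)}.$$

Method-of-moments estimates are unbiased but unconstrained, so individual
components can be negative.  `memma()` reports both the raw solution (the
right object for averaging across replicates, e.g. in null calibrations)
and a zero-truncated copy used for the headline PVE.  Because each
environment enters only quadratically through $\mathrm{diag}(E_l)$, MEMMA
is invariant to the sign of any environment column: interaction-weight
signs, and hence an environmental score, are unrecoverable by design.

## GPLEMMA

The constrained model replaces the $L$ independent interaction components
with a single score:

$$y \sim N\!\left(C\alpha,\;\sigma_\beta^2 K + K_2(\tilde w) +
\sigma_e^2 I\right), \qquad
K_2(\tilde w) = \mathrm{diag}(E\tilde w)\,K\,\mathrm{diag}(E\tilde w),$$

where the interaction effect scale $\sigma_\gamma$ has been absorbed into
$\tilde w$ (only $\sigma_\gamma w$ is identified, and only up to an overall
sign).  Minimizing the projected Frobenius loss

$$S(\theta) = \left\| Wyy^TW - \left(\sigma_\beta^2\,WKW + WK_2(\tilde w)W +
\sigma_e^2\,W\right) \right\|_F^2$$

is a non-linear least-squares problem in $\theta = (\sigma_\beta^2, \tilde
w, \sigma_e^2)$, solved by a Levenberg-Marquardt (LM) algorithm: damped
normal equations $(J^TJ + \mu I)\delta = J^T\epsilon$, with $\mu$ divided
by 3 after an accepted step and doubled after a rejection, starting from
$\mu_0 = 10^{-3}\,\overline{\mathrm{diag}(J^TJ)}$.  These damping defaults
are the classic multiplicative schedule; all are configurable and none
affect the fixed point, only the path to it.

Two algebraic points matter for correctness and are covered by
finite-difference oracle tests:

* $K_2$ is quadratic in $\tilde w$, so the analytic Jacobian entry for
  $\tilde w_l$ is the *symmetrized* derivative
  $(F_lF_{\tilde w}^T + F_{\tilde w}F_l^T)/M$ — the factor 2 and the
  symmetrization must be kept for the damped steps to be true descent
  directions at any $\mu$;
* the data term of $J^T\epsilon$ for $\tilde w_l$ is the weighted sum
  $2\sum_m \tilde w_m H_{l,m}/M$, with the weights and the $1/M$ scale.

Since $S$, $J^TJ$ and $J^T\epsilon$ are quadratic/quartic forms in
$\tilde w$ over the precomputed Gram matrix, each LM iteration costs
$O(L^4)$ *independent of $N$, $M$ and $B$* after the one-off
$O(NL^2B)$-sized dictionary has been built.  This front-loaded design is a
deliberate trade: for the moderate numbers of environments this package
targets (tens), the $L^2 \times L^2$ pair-kernel Gram is small, iterations
are essentially free, and multistart restarts cost nothing extra.  For very
large $L$ the Gram grows as $L^4$ and a per-iteration streaming evaluation
would become preferable; `memma()` only needs the $L$ diagonal pairs
(`pairs = "diag"`) and scales accordingly.

**Initialization and restarts.**  The loss is non-convex, so `gplemma()`
performs 10 independent LM runs (configurable) and keeps the solution with
the lowest squared error.  Each restart draws
$\tilde w_{init} = \tfrac{1}{L}\mathbf{1} + N(0, \tfrac{2}{L^2} I_L)$,
solves the three-component linear moment system with kernels
$\{K, K_2(\tilde w_{init}), I\}$ for
$(\hat\sigma_\beta^2, \hat\sigma_\gamma^2, \hat\sigma_e^2)$, and starts
from $(\hat\sigma_\beta^2,\;
\sqrt{\hat\sigma_\gamma^2}\,\tilde w_{init},\; \hat\sigma_e^2)$: the
square-root scaling makes the implied interaction covariance of the
starting point match the moment solve.  Moment solutions can be negative
by sampling noise; they are clamped at $\varepsilon = 10^{-6}$ so the LM
run starts at a finite, near-null point.  Convergence is declared when the
relative decrease of $S$ stays below `tol` ($10^{-6}$) for three
consecutive accepted steps, or after `max_iter` (200) iterations.

**Reported quantities.**  The fitted component variances are
$\hat\sigma_\beta^2\,\mathrm{tr}(WKW)$, $\mathrm{tr}(WK_2(\hat{\tilde
w})W)$ and $\hat\sigma_e^2(N-D)$; PVE is each over their sum (negative
main/residual components truncated at zero first).  The ES is reported as
unit-norm weights with the largest-magnitude weight made positive — the
global sign is unidentifiable, so this canonicalization is purely for
reproducible reports — together with the scale $\|\hat{\tilde w}\|$ and
the per-sample score $\hat\eta = E\hat w$.

## The simulator

`simulate_dataset()` generates the study conditions the estimators are
validated under, with complete ground truth:

* **Genotypes**: independent SNPs, $G_{ij} \sim \mathrm{Bin}(2, p_j)$ with
  $p_j \sim U(0.05, 0.5)$; monomorphic columns are redrawn.  This
  deliberately omits linkage disequilibrium, realistic allele-frequency
  spectra, relatedness and population structure — recovery results here
  validate the estimator algebra and sampling behaviour, not robustness to
  those features of real cohorts.
* **Environments**: standard Gaussian, or binomial-ordinal with 3-5 levels
  and $p \sim U(0, 0.5)$, standardized either way.
* **Phenotype** $y = C\alpha + X\beta + (\eta \odot X)\gamma + \epsilon$
  with spike-and-slab effects: `M_G` non-zero main effects and `M_GxE`
  non-zero interaction effects at uniformly random positions, values
  standard Gaussian.  The interaction weights follow the deterministic
  alternating decreasing sequence
  $w_i = (-1)^i(1 - i/(2L_{active}))$ for $i \le L_{active}$ (a square-root
  variant of the decreasing factor is available behind
  `weight_form = "sqrt"`, an equally defensible reading of a decreasing
  sequence; the linear form is the default).
* **Exact variance fractions**: the covariate, main and interaction
  components are successively residualized against each other (and the
  noise against all three) before scaling, so each component's realized
  share of $\mathrm{var}(y)$ equals its target *exactly*, not just in
  expectation.  This makes parameter-recovery assertions sharp: a
  deviation of the estimate from the target is estimator error, never
  generator error.  The cost is a slight perturbation of the planted
  coefficient vectors (the projection residue), negligible at the sample
  sizes used.
* **Three-score phenotype**: $K = 3$ orthonormal weight columns over a
  common set of `L_active` active rows, disjoint interaction supports, and
  per-score scales chosen so the singular values of the implied effect
  matrix $\Lambda = \sum_k W_k\gamma_k^T$ are proportional to the requested
  values (default 80, 60, 40) — with orthonormal $W$ and disjoint supports
  those singular values are exactly $\|\gamma_k\|$, which is how the
  scaling is implemented.  The global GxE rescale preserves their ratios.
* **Misspecified phenotype**: a heritable environment $S$ (genetic share
  exactly 30%, 2500 causal SNPs at $M = 10^5$ and pro-rata counts at other
  $M$, keeping the polygenicity fraction constant) is standardized,
  substituted as the first environment column, and $\alpha_s S^2$ is added
  to the baseline phenotype.  The squared-effect pre-screen
  (`squared_effect_screen()`) tests each $E_l^2$ by a two-sided t-test *on
  top of the existing covariates* — adjusting for $C$ rather than testing
  marginally, since the linear part of every environment is already in $C$
  — and appends standardized squared terms with $p < \alpha/L$.

## Numerical choices and degenerate inputs

* Standardization always uses denominator $N$; zero-variance genotype or
  environment columns are an error (or are dropped with a warning at
  source construction), and missing genotype calls are mean-imputed per
  SNP, leaving exactly 0 after centering so they contribute nothing to any
  cross-product.
* Rank-deficient covariate assemblies (duplicated environments, collinear
  covariates) are repaired by dropping later columns with a warning, so
  $W$ is always a genuine projection and $N - D$ is its exact trace.
* A numerically singular moment matrix falls back to a least-squares solve
  with a warning; a singular damped LM system raises $\mu$ and retries.
* Probe draws, restarts and simulations all derive from explicit integer
  seeds; identical inputs and seeds are bit-reproducible, and precompute
  results are invariant to the genotype block size up to accumulation
  order ($<10^{-10}$ relative).

## What the validation suite establishes

The test suite checks three layers: exact algebra (every randomized trace
against dense-matrix oracles within Monte-Carlo error; the analytic
Jacobian against central finite differences; the dense-trace LM fixed
point against an independent generic non-linear least-squares solver);
estimator calibration (signed MEMMA components centered on zero across
200 null replicates; the squared-effect screen holding its $\alpha/L$
false-inclusion rate across 1000 null datasets); and parameter recovery on
scaled-down replicates of the default simulation design — ten datasets at
$N = 5000$, $M = 10000$, $L = 10$ with six active weights and pro-rata
causal counts, fitted with $B = 50$ probes and 10 restarts.  These problem
sizes were chosen so the whole suite runs on a single desktop core in
minutes; `scripts/acceptance.R` re-runs the recovery layer end to end.

Two caveats the recovery numbers themselves make visible.  First, the
GPLEMMA GxE variance term $\mathrm{tr}(WK_2(\hat{\tilde w})W)$ is
non-negative by construction and the weights adapt to noise, so — like any
boundary-constrained variance estimator — its estimates carry an upward
finite-sample bias that shrinks as $N$ grows relative to the number of
environments; the unconstrained (signed) MEMMA solution is the unbiased
counterpart, which is why null-calibration checks use MEMMA's raw
components.  Second, with a single planted score the two estimators agree
in mean while MEMMA shows the larger spread, reflecting the variance cost
of its $L$ unconstrained components.

## Known limitations

* No standard errors are attached to the estimates: the single-pass Gram
  design keeps no per-SNP-block partial sums, so a block-jackknife would
  require a second streaming mode.
* Quantitative traits only; no liability-scale transformation for binary
  traits.
* One environmental score; multiple orthogonal scores are not fitted
  (MEMMA's per-environment decomposition is the available complement).
* Independent-SNP simulation only (see above); PLINK BED is the only
  genotype format, with dosage/BGEN input out of scope.
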