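---
title: "Mapping QTLs for interspecific interactions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping QTLs for interspecific interactions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlvqtl)
```

This vignette documents the models implemented in `hlvqtl`, the
estimation machinery, the design choices that were genuinely open, and
what the simulation framework does and does not emulate.

## The growth model

Two species with abundances $E$ and $S$ grow in co-culture according to

$$\frac{dE}{dt} = r_e E\left(1 - \frac{E}{K_e}\right)
  + r_e E \frac{\alpha_{E\leftarrow S}}{1+E} S, \qquad
  \frac{dS}{dt} = r_s S\left(1 - \frac{S}{K_s}\right)
  + r_s S \frac{\alpha_{S\leftarrow E}}{1+S} E.$$

Each species follows logistic self-limited growth towards its carrying
capacity, perturbed by a Holling type II interaction: the per-capita
influence of the partner saturates with the focal species' own density
through the factor $E/(1+E)$ (respectively $S/(1+S)$). The signed
scalars $\alpha$ encode mutualism (both positive), antagonism (both
negative), commensalism or amensalism (one zero), and predation-like
asymmetry (opposite signs). Setting both $\alpha$ to zero recovers two
uncoupled logistic equations — the monoculture model.

The *independent* component of a trajectory is defined as the standalone
logistic solution with the same rate, capacity and initial state (what
the species would do in monoculture); the *dependent* component is net
minus independent (`decompose_trajectory()`). An alternative definition
— integrating the interaction term along the coupled trajectory — was
considered and rejected because the monoculture interpretation of the
independent part is what links the co-culture and monoculture arms of a
mapping experiment. The two definitions agree when $\alpha = 0$ and
differ only through feedback of the interaction on the self-limitation
term.

Parameters and units: $r_e, r_s$ are per hour; $K_e, K_s$ are in the
abundance units of the data; $\alpha$ values are dimensionless. Time is
measured in hours; observation grids need not be equally spaced or
integer.

## Numerical integration

Trajectories are solved by the classical fixed-step fourth-order
Runge–Kutta method, implemented in C++ because it sits inside the
likelihood of the estimator. Every inter-observation interval is split
into equal sub-steps no longer than `step`, so the integration grid
always lands exactly on the observation times. The user-facing default
is `step = 0.01` h; the fitting default is `step = 0.3` h, whose
integration error on growth-scale problems is orders of magnitude below
the residual noise while being 30× cheaper (the test suite checks the
solver against the logistic closed form and verifies the fourth-order
convergence rate). A state exceeding $10^{12}$
in magnitude aborts integration with an error naming the divergence
time rather than propagating overflow.

## The longitudinal likelihood

At a locus pair, each interspecific pair $i$ contributes a stacked
$2T$-vector $(E_i(1),\dots,E_i(T);S_i(1),\dots,S_i(T))$ modelled as
multivariate normal. Its mean is the ODE solution under the parameter
set $\theta_j$ of the pair's genotype combination
$j \in \{AB, Ab, aB, ab\}$; its covariance $\Sigma$ is shared by all
combinations and structured by a first-order antedependence (SAD(1))
model: residuals follow

$$e_k(t) = \phi_k\, e_k(t-1) + \varepsilon_k(t), \qquad e_k(1) = \varepsilon_k(1),$$

per species $k \in \{E, S\}$, with innovation SDs $\nu_k$ and a
contemporaneous cross-species innovation correlation $\rho$. This is
the minimal bivariate SAD(1): five parameters producing nonstationary
within-species variance that accumulates over the course of growth,
banded temporal correlation, and cross-species covariance blocks. The
likelihood is evaluated from sufficient statistics (per-combination
mean vectors and the pooled within-class scatter), so its cost does not
grow with the number of pairs.

## Estimation

Maximization is a hybrid of derivative-free search and Runge–Kutta
integration, on transformed parameters: $\log$ for rates, capacities
and innovation SDs; $\tanh^{-1}$ for $\rho$ and for $\phi$ scaled into
$(-3, 3)$; identity for the interaction scalars. Stages:

1. **Starts.** Rates and capacities from a coarse logistic least-squares
   grid on each combination's mean curve; $\alpha = 0$; $\phi = 0.5$;
   $\nu$ from the first-time residual SD; $\rho = 0$. Additional
   restarts jitter the transformed start (SD 0.3). When a null fit is
   available, the alternative is warm-started from it, which makes
   $LR \ge 0$ hold structurally.
2. **Joint simplex.** Nelder–Mead with per-coordinate scaling
   (`parscale`): ~10% moves for log-scale parameters and much finer
   moves for the interaction scalars, whose natural scale is two orders
   of magnitude smaller. Rebuilding the simplex at the incumbent
   (`cycles`) escapes premature collapse.
3. **Block refinement.** With $\Sigma$ fixed, a combination's free
   parameters enter only through its own mean curve, so each
   combination is refined by a cheap low-dimensional simplex against
   the Cholesky factor, alternating with the shared/SAD/initial-state
   block, then polished jointly.
4. **Quasi-Newton polish.** A final BFGS stage with numerical gradients.
   The likelihood surface has a curved ridge linking initial states,
   rates and interaction scalars on which pure simplex/coordinate
   search stalls; the gradient polish traverses it, restoring
   parameter recovery on near-noiseless data to better than 1%
   relative error (asserted by the test suite).
   Convergence quality also matters for test calibration: without the
   polish the high-dimensional alternative under-exploits its extra
   dimensions and the null LR runs a little below its asymptotic
   chi-square distribution, so the Monte-Carlo power study keeps a
   short (40-iteration) polish in its fit control. The stage can be
   disabled with `polish = "none"`.

**Initial states.** By default one initial abundance per species is
estimated, shared by all combinations under both hypotheses: inocula
are standardized in this experimental design, so the genotype test
concerns the dynamic parameters, and the null stays exactly nested in
the alternative (df of the four-combination test is exactly 18).
Fixing the initial state at each combination's observed first-time mean
is available (`init = "observed"`) but is only sensible when early-time
noise is small relative to the inoculum — under heritability-calibrated
noise the observed first-time class means are frequently negative and
would strand the logistic at the origin. A per-combination free initial
state (`init = "per_combination"`) is provided for sensitivity
analysis.

**Symmetric testing.** In every likelihood-ratio test the null is
re-polished from the collapsed alternative solution and the better of
the two null fits is used. Without this, incomplete convergence of the
(easier) alternative-seeded search inflates the null statistic by
several units and the false positive rate roughly triples.

## Tests and thresholds

The overall test at a locus compares one shared $\theta$ against one
$\theta$ per combination ($LR = 2(\ell_1 - \ell_0)$, df = 18 for four
combinations, df = 6 for a single-genome co-culture scan, df = 2 per
species in monoculture). Two subset tests attribute a significant
locus: constraining $(r_e, K_e, r_s, K_s)$ equal across combinations
(interaction scalars free) tests action on *independent* growth;
constraining $(r_e, \alpha_{E\leftarrow S}, r_s, \alpha_{S\leftarrow E})$
(capacities free) tests action on *interaction* growth. One printed
form of the second constraint omits a genotype subscript on $r_s$; both
rates are constrained symmetrically here, treating that as a
typographical slip.

Thresholds are either chi-square with Bonferroni correction
(`bonferroni_chisq_threshold(n_tests, alpha, df)`), or genome-wide
permutation: whole phenotype trajectories are permuted against
genotypes (preserving the longitudinal covariance and, in two-genome
scans, the pair structure), the per-permutation maximum LR is recorded,
and the critical value is the order statistic
$\lfloor(1-\alpha)B\rfloor + 1$ of $B$ maxima, which requires
$(B+1)\alpha \ge 1$.

## Effect partition

For a significant marker pair, the four genotypic value curves of the
focal species are decomposed at every time point by orthogonal 2×2
factorial contrasts: grand mean; own-genome contrast (the *direct*
effect); partner-genome contrast (the *indirect* effect); and the
interaction contrast (the *genome–genome epistatic* effect). The
partition is exactly invertible. Variance curves per effect use the
supplied combination frequencies (observed proportions by default);
under equal frequencies the contrasts are orthogonal and the three
variances sum exactly to the genotypic variance of the four curves —
the package's brute-force check. Under unequal frequencies the
orthogonality (and hence the additive decomposition of total variance)
no longer holds, which is why the equal-frequency option exists.
Haploid panels have no dominance terms.

## Growth-model comparison

`compare_growth_models()` mirrors the classical model comparison:
logistic $K/(1+ae^{-bt})$, Gompertz $K\exp(-ae^{-bt})$ and Richards
$K/(1+ae^{-bt})^{1/m}$ fitted per species by nonlinear least squares,
against the coupled model fitted jointly to both mean curves, ranked by
AIC, BIC and Hannan–Quinn from the Gaussian profile likelihood. The
three classical parameterizations are not uniquely standardized in the
literature; the forms above are documented as this package's
convention, and negative shape parameters are representable. Criteria
are reported both raw and per observation, since published tables of
this kind sometimes normalize by sample size. $R^2$ of constant data is
reported as 0 by convention. Standard errors come from the numerical
Hessian of the least-squares objective.

## The simulator and the power study

`simulate_community()` emulates the structure of a two-species
co-culture mapping experiment: `n` interspecific pairs, biallelic
haploid marker panels (default 1000 markers per genome, allele
frequency 0.5, markers independent — no linkage map), 16 observation
times over 36 h, one causal marker per genome, and SAD(1) residuals.
All generator defaults live in `inst/extdata/default_sim_config.json`:

* **Backbone.** $r_e = 0.5$, $K_e = 23.94$, $r_s = 0.4$, $K_s = 21.56$,
  $E_0 = S_0 = 0.5$: capacities on the published co-culture abundance
  scale, rates placing the fast-growth phase in the first third of the
  36 h window.
* **Antagonism.** $\alpha_{E\leftarrow S} = -0.01$,
  $\alpha_{S\leftarrow E} = -0.02$: mutual harm, with the second
  species harmed more, matching the qualitative asymmetry of the
  motivating experiment.
* **Causal effects.** Multiplicative: the own-genome allele scales the
  species' rate (+8%) and capacity (+6%); the partner-genome allele
  scales the interaction scalar (+60%). This spreads genetic variance
  over timing, plateau and interaction features of the curve, and the
  ODE nonlinearity itself generates genome–genome epistasis from
  marginal parameter effects. Effect profiles were fixed at design time
  by an asymptotic noncentrality calculation against the published
  power table (see below) and not revisited.
* **Noise.** $\phi_e = \phi_s = 0.75$, $\rho = 0.3$, template
  $\nu = 1$: strong positive residual autocorrelation typical of
  repeated growth measurements, moderate cross-species environmental
  correlation.
* **Heritability calibration.** Given $H^2$, the innovation SDs are set
  so that at the reference time — each species' time of maximum genetic
  variance, mid-to-late trajectory in practice — the genotype share of
  phenotypic variance equals $H^2$. A Monte-Carlo round trip at
  $n = 2000$ recovers the configured $H^2$ to within $\pm 0.02$. A
  useful consequence of this calibration is scale invariance: scaling
  all combination-mean deviations rescales the noise identically, so
  detection power depends on the *temporal geometry* of the effects,
  not their absolute size.

`power_fpr_study()` reproduces the operating-characteristics study:
for each (n, $H^2$) setting it simulates replicate datasets, tests the
causal locus (null vs four-combination fit), and reports the detection
rate — power when $H^2 > 0$, false positive rate when $H^2 = 0$ (no
genotype effect anywhere, template noise). The detection threshold is
the df-18 chi-square critical value at the 0.05 level: the published
study is a single-locus design, and its printed false positive rates
(0.07–0.11) are consistent with a nominal 5% test mildly inflated at
n = 45, not with a genome-wide corrected threshold. Defaults: 200
replicates per setting, a reduced-budget fit control (single start,
short simplex stages, 40-iteration polish, 0.6 h integration step), and
a 16-marker panel (the
statistic involves only the causal locus; a `full_scan` flag enables
complete scans). On one CPU the nine-cell study runs in under 20
minutes.

What the simulator does *not* emulate: linkage disequilibrium between
markers, multi-QTL architectures (one causal locus per genome),
genotype effects on the inoculum, non-Gaussian measurement error, and
batch structure. Passing the power study therefore demonstrates correct
behaviour of the estimator and test under the model's own assumptions,
not robustness to their violation on real data.

## Known limitations

* The interaction scalars are weakly identified at realistic noise
  levels: under the default study conditions ($H^2 = 0.10$, four
  combination cells of ~50 pairs) the replicate RMSE of $\hat\alpha$ is
  several times the magnitude of the true values, because $\alpha$
  trades off against the capacity and the initial state along a
  likelihood ridge; this matches the Cramér–Rao bound, so it is a
  property of the design, not of the optimizer. Rates and capacities
  are recovered to a few percent at the same sizes (both measured by
  the acceptance suite). Detection (the LR test)
  is unaffected — it integrates signal over the whole curve — but
  per-component interpretation of $\hat\alpha$ from small panels should
  rely on the subset tests rather than point estimates.
* Two species only; no Holling type I/III responses; no adaptive or
  stiff solvers (growth-scale dynamics are non-stiff).
* Permutation thresholds for the two-genome scan are computationally
  heavy; the chi-square/Bonferroni route is the practical default
  there.
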