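---
title: "Estimating spillover effects of treatment in risk networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating spillover effects of treatment in risk networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In networks of people who inject drugs, treatment of one person (for
example, medication for opioid use disorder) can plausibly change the
outcomes of their untreated contacts — through medication sharing, diffusion
of harm-reduction knowledge, or behavior change within drug-use
partnerships. This package estimates such *spillover* alongside the usual
individual-level effect, from an observed undirected risk network with a
binary treatment $A$, a binary outcome $Y$, and measured baseline
confounders $X$.

Identification rests on *partial interference*: the network is partitioned
into disjoint communities (interference sets), spillover may operate within
a community but not across communities. Because risk networks come with no
predefined groups, communities are discovered by modularity-based community
detection, and the robustness of that structure is itself examined (see
"Significance of the community structure" below). We additionally assume
*stratified interference*: a participant's potential outcome depends on
others' treatments only through the proportion treated in their community.

## Estimands and estimator

Treatment allocations are standardized to counterfactual Bernoulli policies:
under coverage $\alpha$, each participant is independently treated with
probability $\alpha$, giving vector probabilities
$\pi_i(a_i;\alpha)=\prod_j \alpha^{a_{ij}}(1-\alpha)^{1-a_{ij}}$ (and the
same product excluding participant $j$ for $\pi_i(a_{i,-j};\alpha)$).
Four risk differences are reported, all on the probability scale:

* **direct** $DE(\alpha)$: treated vs untreated at the same coverage;
* **spillover** $SE(\alpha,\alpha')$: untreated under coverage $\alpha$ vs
  untreated under $\alpha'$;
* **total** $TE(\alpha,\alpha') = DE(\alpha) + SE(\alpha,\alpha')$;
* **overall** $OE(\alpha,\alpha')$: marginal population contrast.

Confounding is adjusted with a *community-level propensity score*
$$f(A_i \mid X_i) = \int \prod_{j=1}^{n_i} h(X_{ij},b_i)^{A_{ij}}
\{1-h(X_{ij},b_i)\}^{1-A_{ij}} \, \phi(b_i;0,\sigma_b^2)\, db_i,$$
where $h$ is the inverse-logit of a mixed-effects logistic model of
treatment with a community random intercept. The community-level group
estimators are inverse probability weighted sums, e.g. for the treated arm
$$\hat Y_i(1;\alpha) = \frac{\sum_j \pi_i(A_{i,-j};\alpha) A_{ij} Y_{ij}}
{n_i\, f(A_i\mid X_i)},$$
averaged unweighted across communities; the denominator deliberately uses
the full-vector propensity exactly as the estimator is defined by its
source, not an exclude-$j$ variant. All probability products are
accumulated in log space, so large communities cannot underflow.

Communities of size one are excluded automatically (with a message): no
spillover is possible within them.

### Mixed-model fitting and quadrature

The mixed logit is fitted by directly maximizing the adaptive Gauss–Hermite
(AGH) marginal likelihood; per community the integrand is centered at its
conditional mode and scaled by the local curvature, with 21 nodes by
default (41 nodes changes community-level scores by less than $10^{-6}$
relative for communities up to size 30 with linear predictors within
$\pm 5$). This is the same integral that defines $f(A_i\mid X_i)$, which
has a practical consequence: the score functions used by the sandwich
variance below are exactly zero at the fitted parameters, keeping the
M-estimation stack internally consistent. `lme4::glmer` (nAGQ = 21) agrees
with the fitted parameters to about $10^{-3}$ and serves as an independent
cross-check in the test suite, not as the implementation. $\hat\sigma_b$
is truncated to zero below $10^{-6}$ (the boundary case degenerates to a
plain Bernoulli product, evaluated without quadrature).

### Robust variance

Standard errors treat communities as independent units and stack, per
community, the propensity-model score equations with the target-mean
equations $\hat Y_i(\cdot) - \mu$. The bread uses the numerically
differentiated Hessian of the marginal log-likelihood; the cross block uses
the identity $\partial \hat Y_i / \partial\phi = -\hat Y_i s_i$, which holds
because the parameters enter only through $\log f_i$. Effect standard
errors follow by the delta rule on contrasts of the $\mu$'s; intervals are
95% Wald with a fixed 1.96 multiplier (no small-sample $t$ correction).
With known (supplied) propensity scores the whole stack collapses to the
i.i.d. CLT form $\mathrm{sd}(\hat Y_i)/\sqrt{N}$, which the tests assert to
$10^{-8}$; with estimated scores the tests require agreement with a
1000-resample community bootstrap within 20% relative.

When $\hat\sigma_b = 0$ the $\sigma_b$ row is dropped from the stack (the
parameter sits on the boundary and its score is one-sided); the remaining
rows are unaffected.

### Extreme weights

Community IPWs $\pi_i(A_i;\alpha)/f(A_i\mid X_i)$ can be extreme when the
observed allocation is improbable under either law. `trim_extreme()` flags
communities whose weight falls outside `[low, high]` at *any* configured
coverage (the flagging coverage is not prescribed by the source analysis;
flag-at-any is the conservative reading), removes them, and re-estimates
everything — including the propensity model — on the retained set, so the
trimmed analysis is a complete M-estimation in its own right.

## Community detection

Both modularity maximizers are implemented deterministically:

* **Greedy agglomeration (`cfg`)** starts from singletons, repeatedly merges
  the edge-joined pair with the largest modularity gain
  ($\Delta Q = e_{ab}/m - d_a d_b / 2m^2$), continues through the full merge
  path, and returns the step of maximum modularity. Ties within $10^{-12}$
  are broken by the lexicographically smallest (min label, max label) pair.
* **Leading eigenvector (`le`)** recursively bisects by the sign pattern of
  the leading eigenvector of the generalized modularity matrix, accepting a
  split only when it strictly increases $Q$; groups whose leading eigenvalue
  is below $10^{-10}$ are indivisible. Dense symmetric eigendecomposition is
  used up to 256 nodes, shifted power iteration above. The eigenvector sign
  is fixed by making its first non-negligible entry positive.

Detection runs per connected component, with the component's own edge count
as $m$; labels are then unified. This makes the result on a disconnected
graph equal, component by component, to running the detector on each
component alone — a property the tests check — and coincides with global
maximization whenever components are (as in practice) kept whole or split
internally. Isolated nodes, which can arise in perturbed copies of a
network, become singleton communities.

Both algorithms are greedy heuristics, exactly as the igraph reference
implementations are: on small two-block graphs with strong separation they
attain the exhaustively enumerated modularity optimum essentially always,
but no variant of either method is an exact maximizer. A documented case in
the test suite shows greedy agglomeration (ours and igraph's, identically)
returning $Q = 0.25$ where the optimum is $0.305$. Likewise, recursive
bisection recovers four planted blocks unreliably (it must carve four groups
out of nested two-way splits and will sometimes chip off single nodes —
again byte-identical to igraph's behavior), while greedy agglomeration
recovers them in $\ge 95\%$ of seeds. This asymmetry is a real property of
the methods, worth knowing when the two detectors disagree on data.

## Significance of the community structure

A community structure is credible when it resists small random rewiring.
`perturbation_curve()` reassigns a proportion $\gamma$ of edges (delete
$\lceil \gamma|E|\rceil$ edges; replace each with a pair absent from the
original graph — so exactly that many edges differ; a degree-biased
replacement variant is available), re-detects, and measures the normalized
variation of information
$\mathrm{VOI} = \{H(C\mid C') + H(C'\mid C)\}/\log n \in [0,1]$
against the unperturbed structure, 30 replicates per $\gamma$ over a default
grid of 0 to 1 in steps of 0.02. Natural logarithms are used throughout;
the base cancels in the ratio. The curve is read against two yardsticks:

* a **null network** (`null_network()`): degree-preserving double-edge-swap
  randomization (100 attempted swaps per edge), whose curve shows what the
  same detector does when there is no structure at all; and
* **node-reassignment references** (`reassignment_reference()`): the VOI
  level equivalent to moving 10% or 20% of nodes to other communities
  (500 replicates by default; the replicate count behind such reference
  lines is a free choice). `crossing_gamma()` reads off, with linear
  interpolation, the edge-reassignment proportion at which the mean curve
  reaches a reference level.

A curve that stays well below the null band but crosses the 10% reference
at tiny $\gamma$ indicates structure that is distinguishable from noise yet
fragile — exactly the situation in which effect estimates should be
reported under more than one detection method.

## Missing data

Covariates are completed by iterative random-forest imputation
(missForest-style: initialize with mode/mean, cycle covariates in order of
increasing missingness, refit a 100-tree forest of each on the others,
stop when the change criterion first rises or after 10 sweeps). Outcomes
are completed by a single stochastic imputation from a mixed-effects logit
with a community random intercept fitted to observed-outcome rows,
predicting at each community's empirical-Bayes mode (drawing the intercept
afresh instead is a config option); a no-random-effect variant makes the
imputations identical under every detection method, and deterministic
best/worst-case rules (treated $\to$ no risk behavior, untreated $\to$ risk
behavior, and the reverse) bound the range of effect estimates compatible
with the observed data. Observed cells are never altered, and every imputed
cell is recorded in an audit table with its seed. Single imputation mirrors
the source analysis; it understates the variance contribution of the
imputation step, which multiple imputation would capture at the cost of a
different reporting convention.

The imputation covariates default to the propensity covariate set (the
regressors of the imputation model are otherwise unspecified in the source
analysis).

## Covariate screening

`screen_covariates()` reproduces a three-stage propensity-model screen:
generalized VIFs (Fox–Monette determinant formula) against a threshold of
10, dropping the worst and recomputing; pairwise chi-square tests among
categorical candidates at $p < 0.05$, iteratively dropping the variable in
the most significant pairs; and finally removal of variables that produce
empty treatment-by-level cells or break convergence of the mixed logit.
Ties at every stage are broken by dropping the *later* variable in the
candidate list, so an a-priori ordering of candidates is honored and the
procedure is reproducible. Which member of an associated pair to drop is a
declared convention here, not something the source analysis specifies.

## The synthetic-study generator

`generate_study()` draws studies whose ground truth is known exactly:

* **Network**: planted-partition graph; 24 communities by default with
  log-normal sizes clipped to 3–40 (about 275 participants), within-block
  edge probability 0.3, between-block 0.004. Any isolated node is attached
  to a random member of its own block, so the network satisfies the
  degree $\ge 1$ invariant without dropping anyone.
* **Covariates**: one binary ($\Pr = 0.5$) and one standard-normal
  age-like covariate, both confounding treatment and outcome — the smallest
  set that exercises confounding adjustment.
* **Treatment**: mixed logit with $\theta_0 = -1.6$, effects $(0.5, 0.3)$,
  $\sigma_b = 0.5$, calibrated by simulation to about 22% treated.
* **Outcome**: stratified interference,
  $\mathrm{logit}\,P(Y=1) = 0.9 - 1.0\,A - 1.0\,\rho_{-j} + 0.5 x_{b} +
  0.3 x_{a}$, where $\rho_{-j}$ is the treated proportion among the *other*
  community members (excluding self avoids double-counting the direct
  term); about 75% of untreated participants at zero coverage engage in the
  risk behavior.
* **Missingness**: outcome missing at random with probability
  $\mathrm{expit}(-1.8 + 0.5A + 0.5x_b)$, about 20% overall — depending on
  treatment and the binary covariate but never on $Y$, so the main
  imputation path's assumptions hold by construction. Optional MCAR
  missingness for the binary covariate.

`true_effects()` evaluates the generator's own estimands. Because the
outcome law depends on others' treatments only through the treated count
among the $n_i - 1$ others, the average over counterfactual allocation
vectors is a binomial sum, evaluated exactly for any community size; a
Monte-Carlo path (`method = "mc"`) exists purely as an independent
cross-check.

What the generator does *not* emulate: degree heterogeneity of real
recruitment-driven networks, outcome-model misspecification (the analysis
model matches the generative family), informative (MNAR) missingness, and
communities whose boundaries are themselves uncertain. Passing tests
therefore demonstrate internal correctness and calibration of the
machinery under its stated assumptions, not robustness to their violation.

## Validation scale and numerical choices

The replication studies used by the tests and the acceptance script run at
sizes chosen for precision per CPU-minute: estimator validation uses 500
studies of 200 communities with 3–5 members each (community-level IPW is
asymptotic in the number of communities, and with a 22% treated fraction
contrasted against coverages up to 0.6 the weights are heavy-tailed for
larger communities — at 30 communities the robust-Wald coverage measurably
undershoots, recovering to nominal by about 150–200); unbiasedness checks pool
2000 communities with the true propensity supplied; bracketing and
imputation checks use 100 replicates at 30 communities. Quadrature uses 21
adaptive nodes; merge/split tolerances are $10^{-12}$, eigenvalue
positivity $10^{-10}$; numerical derivatives use central differences with
relative steps of $10^{-6}$ (gradients) and $10^{-4}$ (Hessians).

## Known limitations

* Partial interference is assumed, not tested; many between-community edges
  should lower confidence in it.
* The leading-eigenvector detector under-resolves multi-block structure
  (see above); effect estimates inherit whatever partition it returns.
* Single imputation understates imputation uncertainty.
* The sandwich variance is asymptotic in the number of communities; with a
  few dozen communities, intervals are mildly anticonservative.
* Plugging an estimated propensity into the weights leaves a small
  finite-sample bias (about $-0.01$ risk-difference units for the direct
  effect at 60–200 communities of size 3–5 in our replications, against a
  per-study SD an order of magnitude larger); with the true propensity
  supplied the estimator is unbiased.
* Estimands are defined under Bernoulli allocation policies; policies with
  dependence between members (for example, budget-constrained allocation)
  are out of scope.
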