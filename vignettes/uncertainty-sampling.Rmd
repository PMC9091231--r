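---
title: "Modelling social information sampling in the trust game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling social information sampling in the trust game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(istg)
```

## The task and the modelling question

In the Information Sampling Trust Game (ISTG) an investor may reveal up to
25 tiles of a 5×5 grid summarising a trustee's history with previous
investors — green tiles mark reciprocated trust, red tiles betrayals —
before deciding whether to invest an endowment of 6 tokens. Investing
multiplies the endowment by 4; a reciprocating trustee returns half
(12 tokens), a defector keeps everything (0). Not investing keeps the 6
tokens. Grids are generated from six reciprocation probabilities
(r = 0, 0.2, 0.4, 0.6, 0.8, 1), 10 trials each, 60 trustees per session.
Tile position is uninformative, so behaviour is fully described by the
ordered outcome sequence a subject chose to reveal and the decision to
invest.

The modelling question is what makes a person stop gathering information
about a stranger. This package implements four candidate stopping
policies, fits them per subject by maximum likelihood, compares them at
the group level, and relates the winning model's parameters to age.

## The Uncertainty model

The subject's belief about a trustee's reciprocation probability r is a
beta distribution. Before any tile is revealed it is the *prior*
Beta(α₀, β₀); after observing n₊ green and n₋ red tiles it is the
conjugate posterior Beta(α₀ + n₊, β₀ + n₋). Two summaries of the belief
matter:

* **belief** — the mean α/(α+β), the subjective probability that this
  trustee reciprocates;
* **uncertainty** — the standard deviation
  √(αβ / ((α+β)² (α+β+1))), how unsure the subject is about that
  probability. For the uniform prior Beta(1,1) it equals √(1/12) ≈ 0.289,
  which bounds the prior-uncertainty metric from above.

The policy: keep sampling while the posterior uncertainty exceeds a
personal *uncertainty tolerance* k, with logistic decision noise τ,

p(sample) = 1 / (1 + exp(−(U(α, β) − k) / τ)).

A trial's likelihood is one Bernoulli term per decision: `log p(sample)`
at each pre-sample state and `log(1 − p(sample))` at the stopping state.
A subject who reveals all 25 tiles makes no stop decision, so no stop
term is added there; consequently the 26 possible stopping outcomes of
any fixed grid have probabilities that sum to one (an invariant the test
suite checks to 1e-9 for every model).

Four free parameters per subject: α₀, β₀ (the prior), k, τ. The derived
metrics reported to users are the prior mean ("prior belief"), the prior
sd ("prior belief uncertainty"), k and τ.

Two properties of the beta-Bernoulli geometry are worth stating because
they shape everything downstream. First, every posterior reachable from
the uniform prior is strictly *less* uncertain than that prior (checked
exhaustively over all states with up to 25 outcomes). Second, the decrease
is not monotone along every path: a sharp prior that meets disconfirming
evidence becomes *more* uncertain — e.g. Beta(1, 11) widens after a lone
green tile. Belief updating can therefore prolong sampling after a
surprise, which is what lets the model track behaviour in the
inconsistent-outcome conditions.

## The competitor models

* **Sample Cost** — a normative planner: a finite-horizon dynamic
  programme over states (n₊, n₋) anchored at the uniform prior. Stopping
  is worth max(12·mean, 6); sampling costs `cost` tokens and yields the
  expectation of the successor values under the posterior-predictive
  green probability. Choices are a softmax of the action-value difference
  on the token scale. Parameters: cost, τ. The programme is verified
  against a brute-force expectimax recursion on a 3-tile toy grid.
* **Threshold** — a belief-free heuristic: keep sampling while the
  absolute green−red count difference is below a subjective threshold θ;
  sigmoid in (θ − |n₊ − n₋|)/τ. Parameters: θ, τ. The main-text
  description speaks of the ratio of colours meeting a subjective
  criterion; the count difference is used as its monotone proxy and is
  isolated in one function (`p_sample_threshold`) so an alternative form
  can be swapped in.
* **Count** — sample a fixed target number of tiles regardless of their
  colours; sigmoid in (N − n)/τ. Parameters: N, τ. Its state probabilities
  are invariant to the outcome composition at a fixed sample count, which
  is exactly what makes it distinguishable from the evidence-sensitive
  models.

Invest decisions enter no model's likelihood — the models govern sampling
only. The simulator still produces invest choices (a softmax over the
expected payoff of investing versus keeping the endowment at the stopping
belief) so that synthetic sessions have the full trial schema; that rule
is a data-generation convenience, not a fitted model component.

## Fitting, numerics and model comparison

Per subject and model the summed negative log-likelihood is minimised
with L-BFGS-B inside a bounded box (α₀, β₀ ∈ [0.01, 50];
k ∈ [0.001, 0.289]; τ ∈ [1e-4, 1]; cost ∈ [0, 6]; θ, N ∈ [0, 25]).
Positive scale parameters (α₀, β₀, k, τ) are optimised on the log scale:
the likelihood varies over orders of magnitude of τ, and log-scale
finite-difference gradients condition the search far better — in recovery
pilots this was the difference between unusable and usable τ estimates.
Starting points are a Latin hypercube over the (transformed) box, drawn
in seeded blocks of five so that the first n starts are a prefix of any
larger set — increasing `n_starts` can only improve the best optimum
found. The default is 100 restarts; the recovery studies below use 10–25,
which pilots showed reach the same optima on these problem sizes.
Probabilities are clamped at 1e-12 inside logs, and a floor of 1e-6 on
α, β guards the closed forms at optimizer boundary probes.

BIC = p·ln(n) + 2·NLL with n the number of sample/stop *decisions* the
subject made — the unit of observation of the likelihood — not the number
of trials. Group-level comparison is twofold:

1. **Bootstrap intervals** on summed per-subject BIC differences
   (resampling subjects with replacement, 10⁵ iterations by default);
2. **Random-effects Bayesian model selection** on model evidences
   approximated as −BIC/2: the variational Dirichlet scheme returning
   expected posterior model probabilities, Monte-Carlo exceedance
   probabilities, and protected exceedance probabilities, where the
   exceedance probabilities are shrunk toward uniform by the Bayes
   omnibus risk (the posterior probability that all model frequencies
   are equal, computed from the two free energies). The Dirichlet prior
   is uniform (α = 1 per model). Note a structural consequence: with K
   models and n subjects the expected posterior probability of even a
   unanimously winning model is capped at (1 + n)/(K + n), so group
   posterior probabilities above 0.9 require cohorts of more than 26
   subjects. The package's group-selection validation therefore runs on
   its 50-subject recovery cohort.

## The synthetic cohort

`generate_cohort()` emulates an age-structured study population
(default 157 subjects, ages uniform on 10–24) so the full pipeline is
testable without human data. Per-subject generative quantities are
quadratic trends in z-scored age plus truncated-normal between-subject
noise; (prior mean, prior sd) targets are mapped to (α₀, β₀) by exact
moment inversion, valid iff s² < m(1−m).

The default trends encode the developmental pattern the pipeline is meant
to recover: prior belief flat at 0.5; prior uncertainty rising steeply
from ≈0.10 in late childhood to ≈0.23 by mid-adolescence and then
flattening (intercept 0.230, +0.028·z, −0.022·z²); tolerance rising
linearly (0.090, +0.012·z); decision noise flat at 0.010. Magnitudes are
deliberately chosen so the pattern is statistically detectable at the
package's validation scale of 30 subjects per cohort — a real study at
n = 157 can detect considerably subtler effects, so these defaults are
synthetic study conditions, not empirical estimates.

Three coherence constraints are enforced on the generated population,
each the result of a pilot failure mode:

* the prior sd stays in [0.05, 0.285] and inside the moment region, so
  the implied (α₀, β₀) remain representable inside the fitting box;
* τ stays in [0.005, 0.018]: near-deterministic subjects (τ → 0) make the
  likelihood a step function whose noise parameter is unidentifiable;
* k ≤ s − 2.5·τ per subject: a subject whose tolerance exceeds their
  prior uncertainty never reveals a tile, produces no modellable
  behaviour, and (pilots showed) yields boundary estimates that fabricate
  spurious age trends in the cohort analysis.

What the generator does *not* emulate: learning or drift across the
session (parameters are stationary by construction — which is what makes
it a valid null for the split-half tests), reaction times, individuation
of specific trustees, and any correlation between parameters beyond the
age trends. Passing the recovery suite therefore shows the *pipeline* is
sound at these study conditions; it cannot certify parameter values on
real data collected under different conditions.

## Age analysis

Each metric is regressed on z-scored age and its square with a robust
linear model (Huber M-estimation, tuning constant 1.345 for 95% Gaussian
efficiency); p-values use the M-estimator's asymptotic t statistics on
n − 3 degrees of freedom. The 4 metrics × 2 age terms form one family of
8 tests corrected by the Holm step-down procedure at family α = 0.05 —
under which, for example, a raw p = 0.032 with three smaller hits in the
family is *not* significant. Age is z-scored within sample; orthogonal
polynomials are deliberately not used, so the linear and quadratic
estimates are interpretable as the trend's slope and curvature at the
mean age.

Prior-belief stability across the session is tested by refitting the
model to each half of the task and comparing the α₀ and β₀ estimates
directly (different (α₀, β₀) pairs can encode the same prior mean):
paired two-sided Wilcoxon signed-rank tests (exact for n ≤ 25, normal
approximation with continuity correction otherwise; an all-zero
difference vector is reported as p = 1), and Spearman correlations of the
half-difference with age. Both half-fits use the same derived restart
seed, so identical half-sessions give identical fits and any difference
reflects the data.

## Validation studies and their problem sizes

* **Parameter recovery** — 50 agents × 60 trials, parameters drawn
  uniformly from α₀, β₀ ∈ [0.5, 3], k ∈ [0.035, 0.095],
  τ ∈ [0.004, 0.02]; 25 restarts. These ranges put simulated behaviour in
  the empirically observed regime (≈16 of 25 tiles revealed on average)
  — outside it, e.g. when k exceeds the prior uncertainty, the data
  contain nothing to recover. Recovery is scored by Spearman rank
  correlation between truth and estimate (Pearson is reported alongside):
  maximum-likelihood errors on these positive scale parameters are
  multiplicative and occasionally land on the box boundary, which makes
  product-moment correlations hostage to single outliers while rank
  correlations are stable.
* **Model recovery** — 20 agents per generating model, all four models
  fitted to each, BIC winners tabulated into a confusion matrix. The
  design requirement is diagonal dominance, and that no evidence-sensitive
  agent is ever best fitted by the Count model.
* **Group selection** — random-effects BMS on the 50-agent recovery
  cohort with all four models fitted.
* **Age-trend recovery** — 20 replicate cohorts of 30 subjects, full
  pipeline each, scored by whether the Holm-corrected sign pattern
  (uncertainty +linear/−quadratic, tolerance +linear, belief and noise
  null) is reproduced; the tolerance quadratic is left unconstrained.
* **Calibration** — Holm bookkeeping on a constructed 8-test family;
  bootstrap interval coverage on Gaussian per-subject differences
  (500 replicates); split-half tests on stationary cohorts (25 cohorts of
  12 agents), where they should rarely reject.

These sizes keep a full validation run in the tens of minutes on a single
core while leaving each check statistically meaningful; they are stated
here so that a user scaling the studies up knows what the defaults mean.

## Known limitations

* The Threshold model's supplementary formalisation (exact parameterisation
  of the colour-ratio criterion) is approximated by the count-difference
  form; alternative-model parameter counts (2 each) follow the main-text
  descriptions.
* Model evidence is the BIC approximation, not a marginal likelihood;
  conclusions about closely matched models inherit BIC's penalty
  structure.
* Individual α₀, β₀ estimates at 60 trials are noisy (heavy-tailed,
  concentration weakly identified); the derived prior mean and sd are
  considerably more stable, and cohort-level trends are the intended
  inferential target.
* The robust-regression p-values are asymptotic; at n well below ~30 they
  should be treated as descriptive.
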