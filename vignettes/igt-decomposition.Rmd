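---
title: "Decomposing Iowa Gambling Task choices with reinforcement-learning models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing Iowa Gambling Task choices with reinforcement-learning models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

igtrl models trial-by-trial choices on a modified, computerized Iowa
Gambling Task (IGT): 100 trials, four decks of 60 cards each, decks A and
B paying an average of \$100 per pick but losing more than they pay over
any 10 cards, decks C and D paying an average of \$50 with a net gain,
and all amounts escalating across each block of ten cards. Overt indices
such as per-block net scores often fail to separate clinical groups even
when the underlying psychology differs; the package therefore estimates
the latent components of performance — reward sensitivity, loss aversion,
learning/memory and choice consistency — with the standard
reinforcement-learning model family for this task, and decides group
contrasts with a Bayesian highest-density-interval rule.

## Models

All three candidate models share one skeleton. Each deck $j$ carries an
expectancy $E_j(t)$, initialized at zero so the first choice is uniform.
On trial $t$ the probability of picking deck $j$ is softmax,

$$\Pr[D(t)=j] = \frac{e^{\theta\,E_j(t-1)}}{\sum_k e^{\theta\,E_k(t-1)}},$$

the realized outcome is evaluated to a utility $u(t)$, and the chosen
deck's expectancy is updated.

**PVL (Prospect Valence Learning) utility.** The net outcome
$x(t) = \mathrm{win}(t) + \mathrm{loss}(t)$ is evaluated by the prospect
utility function

$$u(t) = \begin{cases} x(t)^\alpha & x(t) \ge 0 \\
 -\lambda\,|x(t)|^\alpha & x(t) < 0,\end{cases}$$

with reward sensitivity $0<\alpha<1$ (curvature; small $\alpha$ makes all
gains and all losses subjectively similar) and loss aversion
$0<\lambda<5$ ($\lambda>1$ means losses loom larger than gains).

**Learning rules.** The *decay-reinforcement* rule discounts every deck
and reinforces the chosen one,
$E_j(t) = A\,E_j(t-1) + \delta_j(t)\,u(t)$, where $0<A<1$ is the recency
parameter (high $A$ = good retention, low $A$ = rapid decay) and
$\delta_j(t)$ indicates the chosen deck. The *delta* rule moves only the
chosen deck toward the current utility,
$E_j(t) = E_j(t-1) + A\,\delta_j(t)\,(u(t) - E_j(t-1))$.

**Consistency.** For the PVL models the softmax sensitivity is
trial-independent, $\theta = 3^c - 1$ with $0<c<5$: $c = 0$ gives fully
random choice and large $c$ near-deterministic choice. The classic EVL
(Expectancy Valence Learning) model instead uses a linear valence
$u(t) = (1-w)\,\mathrm{win}(t) - w\,|\mathrm{loss}(t)|$ with attention
weight $w$, a delta update with rate $\varphi$, and a trial-dependent
sensitivity $\theta(t) = (t/10)^{c}$ with $-5<c<5$, so consistency can
grow or decay over the session. These are the formulations of the
original model papers (Busemeyer & Stout's EVL; Ahn and colleagues' PVL);
the package treats them as fixed definitions.

The three models are `"evl"`, `"pvl_delta"` and `"pvl_decay"` throughout.

## Task environment

Card-by-card amounts of the modified task are not published, so
`payoff_schedule()` ships a deterministic fixture with the documented
structure: block-1 wins average exactly \$100 (A/B) and \$50 (C/D); deck
A spreads five losses per ten cards summing to $-\$1250$, deck B takes
one $-\$1250$ loss, decks C/D the same pattern at $-\$250$; every ten
cards net $-\$250$ on A/B and $+\$250$ on C/D. Escalation multiplies all
amounts in block $k$ by $1 + r\,(k-1)$ with $r = 0.1$ by default
(configurable); the magnitude of the escalation is not documented for the
original task, and it is applied to wins and losses alike, keeping every
block's good/bad structure intact. Amounts are whole dollars.

A deck picked 60 times is depleted and the task becomes a three-deck
choice, so model fitting uses only trials up to and including the
depleting trial (`truncate_at_depletion()`); that trial is retained
because it was still a four-deck choice. Behavioral indices
(`net_scores()`, `deck_proportions()`) deliberately use **all** trials —
truncation is a modeling rule, not a behavioral one.

## Synthetic cohorts

Raw choice data for the motivating study design are not public, so
`generate_cohort()` stands in for them. The default design
(`default_study_design()`) is four groups of 14/17/14/12 subjects —
labeled by HIV serostatus crossed with drug-use history — with 100 trials
per subject and PVL-decay as the generating model (the best-fitting model
for this population). Group-level parameter means and SDs are the
published group summaries (e.g. loss aversion 0.06/0.25/0.07/1.84 with
SDs 0.01/0.16/0.01/0.75; recency 0.20/0.50/0.21/0.64), and ages are
normal with the published group means/SDs, truncated to 18–80.

Subject parameters are bounded probit transforms of latent normals,
$y = \mathrm{lb} + (\mathrm{ub}-\mathrm{lb})\,\Phi(z)$,
$z \sim N(\mu, \sigma^2)$, so draws respect the bounds by construction.
The published summaries are on the natural scale, so the latent
$(\mu, \sigma)$ are calibrated at build time: the mean has the closed
form $\Phi(\mu/\sqrt{1+\sigma^2})$ and the SD is matched by
one-dimensional quadrature and root finding, keeping simulated group
means within Monte-Carlo error of their targets (the test suite checks
5%).

Everything is a pure function of the design and one master seed: group
parameters and ages are drawn under the master seed, and subject $i$'s
session uses seed `master + i`. The generator reports the deck-depletion
rate so users can judge plausibility; it emulates the study's group
structure and task, but not dropout, missing trials, response times, or
any non-stationarity of real participants — passing recovery tests here
demonstrates internal consistency of the pipeline, not validity of the
model for any particular empirical population.

## Inference

**Hierarchical Bayesian fit** (`fit_hba()`). Each group is fit with its
own hyperparameters — mirroring how group-wise posteriors are usually
displayed for this design; whether a joint fit with shared structure
would be preferable is an open design question we resolve in favor of
group-wise independence, which also makes the pairwise HDI comparisons
self-contained. On the latent scale, $z_{ip} \sim N(\mu_p, \sigma_p)$
with priors $\mu_p \sim N(0,1)$ and $\sigma_p \sim$ half-normal(1) —
standard weakly-informative choices for probit-transformed parameters With
`covariate = "age"`, the latent mean gains a linear term
$\beta_p \tilde a_i$ on the cohort-standardized age, $\beta_p \sim N(0,1)$,
for every parameter.

Sampling is Metropolis-within-Gibbs with a compiled likelihood:
component-wise adaptive random-walk updates per subject, adaptive-
covariance joint proposals per subject (learned during warmup, with
occasional triple-scale jumps to traverse the $\alpha$–$c$ ridge),
per-parameter and joint "group-shift" moves that translate a hypermean
together with all its subjects (the standard cure for the centered-
parameterization funnel when a hyper-SD is small), conjugate Gibbs
updates for $\mu_p$ (and $\beta_p$), and log-scale Metropolis for
$\sigma_p$. All adaptation stops at the end of warmup. Defaults are 4
chains of 1000 warmup + 1000 draws; `mcmc_config(profile = "smoke")`
(2 × 200/200) is the fast profile used by the pipeline default. Split
R-hat and an autocorrelation-based effective sample size are attached to
every saved quantity; any R-hat above 1.1 flags the fit as non-converged
with a warning — deliberately not an error, since short smoke chains on
hard posteriors are still useful for structural checks.

**Natural-scale group means.** Group comparisons and summaries use the
derived draws $\mathrm{gm}_p = \mathrm{lb} + (\mathrm{ub}-\mathrm{lb})\,
\Phi(\mu_p/\sqrt{1+\sigma_p^2})$ — the population mean implied by the
latent hyperparameters. The simpler back-transform $\Phi(\mu_p)$ is the
population *median*, which is biased relative to natural-scale means
whenever $\sigma_p > 0$; using the population mean keeps the posterior
comparable to the natural-scale summaries the generator is calibrated to.

**HDI decision rule** (`compute_hdi()`, `group_difference()`). The 95%
highest density interval is the shortest window of sorted draws holding
$\lceil 0.95\,n\rceil$ of them (ties broken toward the first window). A
contrast is *credible* when the 95% HDI of the draw-wise difference in
natural-scale group means excludes zero. The test suite checks the
implementation against a brute-force window search, normal/uniform
closed forms, the rule's power at the published loss-aversion gap, and
its false-positive rate under identical generators.

**Maximum likelihood** (`fit_mle()`) serves as the non-Bayesian oracle
and feeds model comparison. Optimization runs on the unconstrained
latent scale (box $[-8, 8]$, so parameters stay strictly inside bounds),
from multistart points: a Latin hypercube of candidates mapped through
$\Phi^{-1}$ is screened by likelihood and the best `n_starts` (default
10) are polished with L-BFGS-B. The screen matters: the PVL-decay
likelihood surface is multimodal and sparse starts can hand the
comparison to the wrong model.

**Model comparison** (`compare_models()`). Per subject,
$\mathrm{BIC} = k\,\ln(\text{horizon}) - 2\,\hat\ell$, summed over
subjects; the mean one-step-ahead predictive log-loss per trial (the
likelihood is already a product of one-step-ahead predictions) is
reported as the secondary short-term-prediction criterion. Selection is
by summed BIC.

## Numerical choices and degenerate inputs

- Softmax is computed with max-subtraction; $\theta E$ of several
  hundred is exact, and the log-likelihood stays finite for any
  in-bounds parameters.
- Sessions shorter than 10 modeled trials fit with a warning; empty
  sessions are errors. Horizon 0 (empty session) is returned as 0 by the
  truncation rule.
- `compute_hdi()` requires two finite draws; identical draws give a
  width-zero interval.
- Comparing a group with itself returns a zero difference and
  `credible = FALSE`.
- Cohort CSVs are validated on read: unknown deck labels, duplicated
  (subject, trial) pairs and non-contiguous trial indices are rejected
  with the offending row named.

## Scale of the shipped checks

The test suite and the acceptance script run the full design at desk
scale, a deliberate package choice: hierarchical recovery on the default
57-subject cohort with 2 chains × 500/500; power and calibration of the
loss-aversion contrast with 20 replicates each at the smoke profile;
model recovery on 20 ten-subject cohorts; likelihood-oracle agreement on
120 random sessions. The full MCMC profile (4 × 1000/1000) is available
for final analyses via `mcmc_config(profile = "full")`.

## Known limitations

- Recovery of $\alpha$ and $c$ from 100-trial sessions is weak at the
  individual level (their likelihood contributions trade off along a
  ridge); hierarchical pooling is essential, and even then group-level
  posteriors for these two parameters are wide.
- The EVL parameter ranges are the ones conventional for that model, and
  the consistency bound $[-5, 5]$ is a package choice; published bounds
  for this design exist only for the PVL parameters.
- Whether escalation applies to wins, losses or both is undocumented for
  the original task; the package applies it to both, and this is
  configurable only through the shared `escalation_rate`.
- One-step-ahead log-loss is computed in-sample at the MLE; it is a
  descriptive secondary criterion, not cross-validation.
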