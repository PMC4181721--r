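---
title: "Sequential Bayesian design for gene-circuit kinetics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential Bayesian design for gene-circuit kinetics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circuitdesign)
```

This vignette is the package's account of its science: the circuit model
and its assumptions, the noise and prior models, the posterior-exploration
pipeline, the expected-risk estimator behind experiment ranking, the
budgeted design loop, and the numerical and design choices made along the
way. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The circuit model

Each gene $g$ contributes two state variables, its mRNA $m_g$ and protein
$P_g$:

$$
\dot m_g = a_g \prod_{r:\,\mathrm{target}(r)=g} H_r(P_{\mathrm{reg}(r)})
           - d_g\, m_g,
\qquad
\dot P_g = r_g\, m_g - \delta_p\, P_g,
$$

with the Hill response $H = P^h/(K^h + P^h)$ for activation and
$K^h/(K^h + P^h)$ for inhibition, multiplied over all incoming reactions.
The unknown parameter vector $\theta$ holds the promoter strengths $a_g$
(concentration/time), ribosomal strengths $r_g$ (1/time), per-reaction
binding affinity $K$ (concentration) and Hill coefficient $h$
(dimensionless), and one shared protein degradation rate $\delta_p$
(1/time): $p = 2G + 2R + 1$ parameters for $G$ genes and $R$ reactions.
The mRNA degradation rates $d_g$ are *known constants* (default 1/time per
gene), not estimated — this keeps the parameter count at $2G + 2R + 1$ and
gives the knockdown perturbation a well-defined meaning.

Assumptions worth making explicit: deterministic ODE dynamics (no
intrinsic noise), product-form regulation for multiple inputs, a shared
protein degradation rate, and an all-zero initial condition (fresh
induction; configurable via `initial_state`). The simulation horizon is
$[0, 20]$ time units on a 41-point grid; the two observation resolutions
(11 and 41 points) are sub-grids of it, so one solve serves every
observable of an action.

Two presets ship with the package. `subnet3` is a 3-gene cascade (g6, g7,
g8) whose only reaction is the inhibition g7 ⊣ g8 — 6 state variables, 9
parameters, and a catalogue of 50 assays plus one parameter purchase.
`full9` is a 9-gene, 13-reaction circuit with 18 state variables and 45
parameters. Its edge list is a synthetic reconstruction constrained by
those counts, by gene 7 sitting unregulated at the top of the cascade with
g7 ⊣ g8, and by protein 8 inhibiting protein 5; the remaining edges are
plausible fill-in and should not be read as a map of any particular
published circuit. `preset_parameters()` supplies a deterministic,
biologically plausible ground truth (promoter strengths 1.2–3
concentration/time, ribosomal strengths 0.7–1.6/time, affinities 1.5–4
near the operating protein concentrations, Hill coefficients 2 or 4,
$\delta_p = 0.5$/time) used as $\theta^*$ in the in-silico loops.

### Perturbations

* `wildtype` — no change.
* `knockdown` — the target's mRNA degradation rate × 10.
* `rbs_decrease` — the target's ribosomal strength ÷ 10.
* `delete` — the target's two species are *removed from the system* (not
  zeroed). Regulatory inputs from the deleted protein are evaluated at zero
  concentration: a lost activating input silences its target's
  transcription, a lost inhibiting input is released. Deleting the only
  gene of a 1-gene network leaves nothing to observe; the risk machinery
  scores such an experiment as exactly uninformative rather than failing.

## Observations, costs and noise

An assay pairs an action (1 + 3G of them) with an observable: all mRNAs at
low (11-point) or high (41-point) resolution, or protein time courses —
single proteins in `single_protein` mode (natural for small circuits),
pairs in `protein_pair` mode ($\binom{G}{2}$ choices, the full-scale
setting). Protein assays use the low grid. In addition the two kinetic
constants $(K, h)$ of any one reaction can be purchased directly; the
reported values are the true constants perturbed on the natural-log scale
with sd `purchase_sd` (default 0.05), and they enter the likelihood as
independent Gaussian terms on $\log K$ and $\log h$ — modeling the
purchase as data keeps the sampling and risk machinery uniform instead of
special-casing clamped parameters.

Costs are additive fixtures (action cost + observable cost; see
`cost_table()`): they reproduce the anchor totals 1200 (delete + protein
pair), 850 (RBS + pair), 750 (knockdown + pair) and 500 (wildtype + pair),
with mRNA low/high at 200/400, single proteins at 300 and purchases at
400. They are configurable and carry no claim beyond internal consistency.

Measurement noise is heteroscedastic Gaussian: a signal $y \ge 0$ is
reported as $y + z_1 + z_2$ with $z_1 \sim N(0, 0.1^2)$ and
$z_2 \sim N(0, (0.2\,y)^2)$. Observations are not truncated at zero. The
likelihood evaluates the same model generatively, with variance
$\sigma_a^2 + (\sigma_m\, y_\theta)^2$ at the *predicted* signal
$y_\theta$ — higher concentrations are intrinsically harder to pin down.

## Prior and regularity

Every parameter gets an independent log-normal prior, by default median 1
and log-scale sd $3\ln 10 \approx 6.9$, so that $\pm 3$ prior sd span
$10^{-9}$ to $10^{9}$ — wide enough for any physically sensible rate, yet
proper. Properness is not cosmetic: with non-identifiable likelihoods an
improper prior yields an improper posterior that MCMC cannot sample.

A smoothness penalty $-\lambda \max_{i,t} (Y_{i,t+1} - Y_{i,t})^2$,
computed on the wildtype trajectory at the fine grid (default
$\lambda = 10^{-3}$, small against the likelihood), discourages parameter
regions whose dynamics jump abruptly — typically extremely stiff systems
that are poor models of reality and can defeat the integrator. The penalty
is used *only* during mode finding, never during the Monte-Carlo
exploration, so the sampled posterior is the unpenalized one. Evaluating
it on the wildtype condition only is a package choice: the wildtype solve
is needed anyway and one condition suffices to veto pathological kinetics.

## Posterior exploration

All optimization and sampling happens in $x = \log\theta$, with the
change-of-variables Jacobian folded in: the log-normal prior on $\theta$
is then an exact Gaussian on $x$, positivity is automatic, and one
proposal scale serves parameters living on very different scales.

1. **Mode finding.** BFGS (finite-difference gradients, `optim`) from
   `n_starts` prior draws, on the penalized objective; starts with
   non-finite objective are redrawn. Local optima closer than
   `dedup_tol = 0.5` (Euclidean, log scale) merge; up to `max_modes`
   survive, best first.
2. **Chains.** One random-walk Metropolis–Hastings chain per mode on the
   unpenalized posterior, mixing an isotropic Gaussian proposal
   (probability `prob_iso = 0.5`, sd 0.1) with single-coordinate moves
   (sd 0.5); symmetric proposals give the acceptance rule
   $\min(1, e^{\Delta \log \pi})$.
3. **Recombination.** Chains seeded at different modes over-represent
   whatever received more chains. We fit one diagonal-covariance Gaussian
   per chain *by moments* (chain provenance gives the mixture assignment
   for free — this is EM with known hard labels, deterministic and robust
   at small chain sizes) and give each pooled draw the self-normalized
   importance weight $w(x) \propto \pi(x) / q_{\mathrm{mix}}(x)$.
   Degenerate fits fall back to uniform weights with a warning.
4. **Resampling.** Weighted resampling down to `n_draws` equally weighted
   draws, the form the risk estimator consumes.

Defaults (`sampler_settings()`): 30 starts, ≤ 5 modes, 20 000 iterations,
5 000 burn-in, thin 10, $N = 200$ draws, $M = 100$ noise replicates. The
tests and the acceptance script run deliberately scaled-down versions
(3–8 starts, chains of 2 000–3 000, $N = 50$–100, $M = 30$) chosen as the
smallest sizes at which the pipeline's behavior is representative.

Two further choices matter in the sequential loop. Each round warm-starts
one BFGS run from the previous round's best draw — posterior mass moves
continuously as datasets accumulate, and reusing the last solution
prevents a short mode search from losing a region it had already found;
the prior-draw starts are unchanged, so new modes can still appear. And
the multi-seed **dispersion diagnostic** (`dispersion_diagnostic()`)
compares, per parameter, the mean within-sample sd to the sd of all
samples concatenated (population variances, so identical samples give
exactly 1); ratios well below 1 flag chains stuck in disjoint regions.
Ten seeds is the conventional choice; any number ≥ 2 works.

## The expected-risk estimator

With draws $\theta_1 \dots \theta_N \sim \pi$ and the loss
$\ell(\theta, \theta') = \sum_i \log(\theta_i/\theta'_i)^2$ (squared
Euclidean is available for natural-scale work):

$$
R^N(e;\pi) = \frac{1}{N} \sum_{i,j} \ell(\theta_i,\theta_j)\, w_{ij}(e),
\qquad
w_{ij}(e) = \frac{1}{M}\sum_{u=1}^M
  \frac{P(o_u^i \mid \theta_j; e)}{\sum_k P(o_u^i \mid \theta_k; e)}.
$$

The $1/N$ prefactor is deliberate, paired with the *unaveraged* sum in
$w$'s denominator: with this scale an experiment whose predicted signals
are identical across draws has $w_{ij} = 1/N$ exactly and
$R^N = (1/N^2)\sum \ell = R(\pi)$, the baseline risk — so risk
*reductions* $R(\pi) - R^N(e;\pi)$, which the cost-normalized selection
rule divides by $C_e$, are on a meaningful scale. (A $1/N^2$ prefactor
against the same denominator would make the uninformative experiment score
$R(\pi)/N$; rankings would survive, the selection rule's numerator would
not.) The discrete-model test enumerates the observation integral exactly
and confirms the $1/N$ scale to within Monte-Carlo error.

Implementation notes: one deterministic solve per draw per *action*,
cached and shared across all observables of that action and across the
whole catalogue ranking; $M$ noise corruptions per draw are nearly free.
All likelihood ratios go through log-sum-exp, so $w$'s rows sum to 1 to
machine precision by construction. Draws whose solve fails under any
required action are dropped once per ranking round (with a warning), which
keeps $w$ row-stochastic over the survivors. Purchases are scored by the
same machinery with $(\log K, \log h)$ as the two-dimensional observation.
Ties in the ranking break by lower cost, then catalogue order.

## The budgeted loop

`run_design_loop()` starts from a free low-resolution wildtype mRNA
dataset (its catalogue entry is marked purchased at no charge), then
repeats: sample the posterior given all data; record the true risk
$\frac1N \sum_i \ell(\theta_i, \theta^*)$ (computable only in
simulation); rank the remaining affordable candidates and buy the
argmax of $(R(\pi_k) - R^N(e;\pi_k))/C_e$ — or, under the `random`
strategy, buy uniformly among affordable unpurchased candidates; simulate
the purchase from $\theta^*$, corrupt it, pay. The loop stops when nothing
is affordable. Every experiment can be bought at most once. All
randomness derives deterministically from one master seed, so runs are
bit-reproducible. The default demo budget of 5000 credits allows roughly
4–7 purchases under the default costs; the scaled-down comparisons in the
tests use 1000 credits (3–4 purchases), enough for the strategies to
separate.

## What the generator emulates — and what it does not

The synthetic loop reproduces the structure of a parameter-inference
challenge: a hidden ground truth, a costed catalogue, heteroscedastic
Gaussian noise, and perturbations with exact, known semantics. It does
*not* emulate intrinsic stochasticity of gene expression, model
misspecification (the fitted model is the generating model), correlated
or non-Gaussian measurement error, dropout, or imperfect perturbations
(a "deletion" that leaves residual expression). Passing tests therefore
demonstrate the method's behavior under a well-specified model — the
setting in which parameter estimation is already hard because of
sloppiness — not robustness to the additional pathologies of real data.

## Numerical choices and degenerate inputs

* Integrator: `deSolve::lsoda` (automatic stiff/non-stiff switching) with
  rtol $10^{-6}$, atol $10^{-8}$, at most 2000 internal steps per output
  interval; the right-hand side is compiled C. Integration failure raises
  a distinct `circuit_solver_error` condition; the prior/posterior
  machinery converts it to $-\infty$, the risk machinery to a dropped
  draw.
* Hill inputs are clamped at 0 before exponentiation so that tiny negative
  solver undershoots cannot produce NaN.
* An observable whose every species was deleted yields a zero-width
  signal and is scored as exactly uninformative.
* `find_modes` errors if no finite starting point can be drawn;
  `mh_chain` requires a finite initial log-target; the empty dataset list
  is legal everywhere and makes the posterior the prior.

## Known limitations

Greedy one-step-ahead selection, not a global optimization over purchase
sequences. Random-walk sampling without adaptation or tempering — the
mode-hopping burden rests on the multi-start + recombination layer, and
the dispersion diagnostic should be consulted before trusting a sample on
a new circuit. Risk estimates share one posterior sample across the whole
catalogue (cheap, but estimator noise is correlated across candidates).
The 9-gene preset's topology is a constrained reconstruction, suitable for
method exercise rather than biological inference.
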