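---
title: "Models and methods behind svoconform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind svoconform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The task and the quantity of interest

svoconform studies social-attitude conformity in a repeated
resource-allocation game. On every trial a decision maker chooses between a
fixed *default* allocation — 100 points for themselves, 50 for an anonymous
recipient (1 point = 0.10 EUR) — and an *alternative* drawn from the integer
points within one point of the circle of radius 50 centred at (50, 50).
Alternatives always pay the chooser less than the default but move the
recipient's payoff up (prosocial) or down (antisocial); nine catch trials
pay the chooser more while leaving the recipient at the default's 50.
Filtering the circle band to polar angles within ±112.5° of the self axis,
payoffs to self of at most 100, recipient payoffs in [0, 100] and different
from 50, leaves exactly 406 alternatives, half prosocial and half
antisocial, which `partition_subsets()` deals round-robin by angle into two
subsets of 102 and two of 101 trials.

Choices identify the decision maker's social value orientation (SVO): the
angle $\alpha$ in

$$V(\pi_y, \pi_o) = \pi_y + \tan(\alpha)\,\pi_o,$$

where $\tan\alpha$ is the exchange rate between the other's points and own
points ($\alpha = 30^\circ$ makes one other-point worth about 0.58 own
points). The study design measures $\alpha$ twice — before and after a
middle block in which the participant predicts, with feedback, the choices
of an extremely prosocial or antisocial agent ($\alpha_{obs} \approx \pm
45^\circ$; a computer, a single previous participant, or the majority of a
five-member group, depending on condition) — and asks whether and why the
participant's attitude converges towards the agent's.

## The six cognitive models

Two families describe how a single choice is generated.

**Stable Attitude (softmax).** $\alpha$ is a fixed trait; choice noise is a
value-comparison error with temperature $\tau$ (in points):
$\mathrm{logit}\,\Pr(D) = (V_D - V_A)/\tau$, where
$V_D = 100 + 50\tan\alpha - \kappa$ includes the default-penalty bias
$\kappa$ (below).

**Variable Attitude (random preference).** The acted-on attitude is redrawn
every trial from $\mathrm{Normal}(\mu, \sigma)$ (degrees) and compared with
the trial's indifference attitude

$$T_\alpha = \arctan\!\left(\frac{\pi_y - 100 + \kappa}{50 - \pi_o}\right),$$

the angle at which default and alternative have equal value. The default's
probability is the attitude mass on its side of the threshold:
$\Phi((T_\alpha - \mu)/\sigma)$ when $\pi_o > 50$ and
$\Phi((\mu - T_\alpha)/\sigma)$ when $\pi_o < 50$. Note the plain
$\arctan$: the threshold is an attitude and lives in $(-90^\circ,
90^\circ)$; a two-argument arctangent would map some trials outside the
attitude's meaningful range.

Both families share two further mechanisms. The bias $\kappa$ (points) acts
as a penalty ($\kappa > 0$) or bonus on the default and captures a
demand-driven tendency to pick alternatives regardless of their payoffs.
The lapse rate $\varepsilon$ mixes the model probability with a coin flip:
$\Pr(D) = (1-\varepsilon)\Pr_{model} + \varepsilon/2$.

Crossing the two families with three parameter schemes — both $\alpha$ (or
$\mu$) and the variability estimated separately per phase ("full"), one
attitude for the whole task, or one variability for the whole task — gives
the six model variants of `model_spec()`. $\kappa$ and $\varepsilon$ are
always phase-specific.

**Degenerate trials.** When $\pi_o = 50$ the attitude cancels exactly from
the value difference ($V_A - V_D = \pi_y - 100 + \kappa$). The stable rule
needs no special case; for the variable family the choice becomes the 0/1
step of $\mathrm{sign}(\pi_y - 100 + \kappa)$ (0.5 at exact equality),
which is the $\sigma$-free limit of the threshold rule. These trials thus
inform $\kappa$ and $\varepsilon$ but not the attitude.

**Numerical guards.** Attitudes are constrained to $(-90^\circ, 90^\circ)$
where $\tan$ is defined; $\varepsilon$ is restricted to $[0, 0.5]$ during
fitting (a larger lapse rate is indistinguishable from label flipping);
probabilities are floored at $10^{-300}$ before logs. Unanswered trials are
treated as missing and never enter a likelihood.

## Hierarchical estimation

`fit_attitude_model()` fits a two-level model: group-level
location and scale per parameter, and subject-by-phase parameters drawn
from them. The sampling scales are degrees for the attitude, $\log$ for
$\sigma$ / $\tau$, points for $\kappa$, and $\mathrm{logit}(\varepsilon /
0.5)$ for the lapse. Before/after values are treated as exchangeable draws
from the group level; the package does not model a subject-level
correlation between phases (nothing in the measures below requires one,
and the data contain little information about it).

Priors (all weakly informative, chosen to cover the parameter ranges the
task can express): group attitude location $\sim N(0^\circ, 30^\circ)$,
scale half-$N(0, 20^\circ)$; $\log$-variability location $\sim N(\log 10,
2)$, scale half-$N(0, 1)$; $\kappa$ location $\sim N(0, 10)$ points, scale
half-$N(0, 10)$; lapse-logit location $\sim N(-2, 2)$, scale
half-$N(0, 1.5)$.

The sampler is Metropolis-within-Gibbs with a compiled subject sweep:
per-component random walks whose scales adapt towards 44% acceptance
during burn-in only (so the post-burn-in chain is a fixed Markov kernel);
conjugate Gibbs updates for group locations; slice sampling on the log
scale for group scales; and, for the log-variability and lapse families, an
ancillarity move that proposes rescaling all subject deviations together
with the group scale. The last move matters: those two families exhibit
the usual hierarchical funnel, and without it the group scales' split-
$\hat R$ stalled around 1.2–1.5 at desk scale. Chains are initialised from
a per-subject profile of the likelihood over a coarse attitude grid, plus
jitter.

Desk-scale defaults are 4 chains × 2000 iterations with 500 burn-in and no
thinning, which fits 60 subjects × 200 trials in about a minute on one
CPU; `mcmc_control(full_scale = TRUE)` switches to 4 × 100000 with 5000
burn-in and thinning 4 for production runs. A fit is flagged unconverged
when any split-$\hat R$ exceeds 1.05; the flag is a warning, never a
silent failure, and values within a few hundredths of the threshold at
small n are common and benign.

Point estimates are maximum a posteriori values per marginal: the mode of
a Gaussian-kernel density estimate (Silverman's bandwidth) over the pooled
chains, which is robust to the skew of $\sigma$ and $\varepsilon$
posteriors. Model comparison uses the deviance information criterion in
the classic Spiegelhalter form, $\mathrm{DIC} = \bar D + p_D$ with $p_D =
\bar D - D(\bar\theta)$ and the plug-in deviance evaluated at the
posterior means of the subject-level parameters on their sampling scales.

## The synthetic population

`sample_population()` generates the whole experiment so that every
downstream stage is testable without participant data. Its defaults are
the study's conditions:

* sample sizes 132 / 74 / 66 / 97 for baseline / computer / individual /
  group;
* a 75/25 prosocial/antisocial mixture with attitude means
  $20^\circ$ (SD $14^\circ$) and $-22^\circ$ (SD $20^\circ$);
* a 17% "compliant" subtype whose $\kappa$ centres at 11.48 points versus
  1.14 for the rest. The SDs (11 and 2.6 points) are derived from the
  reported group-mean confidence intervals (half-width / 1.96 ×
  $\sqrt{n}$ with n = 63 and 305);
* choice variability $\sigma \sim$ lognormal$(\log 12, 0.4)$ degrees
  before the manipulation, multiplied after it by a lognormal$(\log 0.85,
  0.15)$ shrink — participants get more consistent in every condition;
* lapse rates $\sim$ Beta(2, 38) (mean 0.05);
* observed agents at exactly $\pm 45^\circ$ with $\sigma_{obs} =
  2^\circ$, $\varepsilon_{obs} = 0.01$ — agents were calibrated to be
  easily predictable, and these values make them so;
* manipulation-phase prediction accuracy 0.93 (matching the reported 18.6
  correct of the last 20 trials), used only descriptively.

The after-phase attitude is the before-phase attitude shifted towards the
agent by the condition's convergence amount (0 / 4 / 6 / 5 degrees),
capped at the agent's attitude, plus $N(0, 3^\circ)$ jitter. The shift is
a deterministic displacement rather than a learning process: the study
measures conformity, it does not model the trial-by-trial learning that
produces it, and neither does the generator. Compliance is defined
*behaviourally* throughout: a participant whose simulated before-phase
choices cross the 25% cross-type threshold counts as
compliant, whatever their latent $\kappa$. In the computer condition such
participants receive an extra 5° shift. This reproduces the reported
pattern — convergence in all treatment conditions, with the
computer-condition effect concentrated in (but not exclusive to) the
compliant subgroup — and keeps the subgroup contrast stable across seeds,
which a shift keyed on the latent subtype does not, because the
$\kappa \to$ behaviour mapping is noisy. For the same reason the measured
compliant fraction comes out near 10%, somewhat below the 17% subtype
rate; only the subtype rate is a dial.

Norm ratings are generated from a latent appropriateness proportional to
the recipient's payoff advantage, signed by the participant's classified
attitude, with Gaussian noise (SD 0.75) cut into the 4-point scale. This
is invented plumbing: the study reports rating distributions only
graphically, so the rating generator supports procedure tests (monotone
trends, noise washout) and is not an acceptance surface.

What the generator deliberately does not emulate: reaction times,
screen-side randomisation, payment realisation, trial-by-trial learning
dynamics, and any dependence of the lapse rate on time on task. Tests that
pass on this population therefore validate the pipeline's arithmetic and
inferential machinery on data with the assumed structure — they do not
show that real participants satisfy that structure.

## Derived measures

* **Model-free classification**: the sum over chosen alternatives of the
  half polar angle, $\arctan\big((\pi_o - 50)/(\sqrt{(\pi_y - 50)^2 +
  (\pi_o - 50)^2} + \pi_y - 50)\big)$; prosocial iff the score is $\ge 0$
  (ties, e.g. a participant who never chose an alternative, classify
  prosocial — the majority base rate; the case is logged as degenerate).
* **Attitude convergence** $\delta_{diff} = |\alpha_{before} -
  \alpha_{obs}| - |\alpha_{after} - \alpha_{obs}|$: positive means closer
  to the agent; overshooting past the agent to a larger distance counts
  negative.
* **Attitude polarisation** $\delta_\alpha = \mathrm{sign}(\alpha_{obs})
  (\alpha_{after} - \alpha_{before})$: signed change towards the agent,
  overshoot not penalised.
* **Compliance index**: the smaller of the percentages of prosocial and
  antisocial alternatives chosen, over answered trials only; undefined
  (and the participant excluded from compliance analyses) when either
  side has no answered trials. The threshold 25% is inclusive.
* **Consistency change** $\sigma_{before} - \sigma_{after}$ (degrees;
  positive = more consistent after).

## The statistical battery

Standard tests are delegated to their canonical implementations
(`stats::wilcox.test`, `stats::kruskal.test`, `stats::cor.test`,
`MASS::rlm`, `stats::p.adjust`); the package adds the effect sizes,
bootstrap intervals, Bayes factors and reporting conventions around them.

* Wilcoxon signed-rank: exact for n ≤ 25 without ties, otherwise normal
  approximation with continuity correction; matched rank-biserial effect
  size; the natural log of V is carried as a report field.
* Kruskal-Wallis with $\varepsilon^2 = H/(n-1)$ and Dunn-type pairwise z
  tests on mean ranks with tie correction.
* Spearman's tie-aware $\rho$.
* Robust regression: Huber M-estimation with tuning constant 1.345 (95%
  Gaussian efficiency), per-coefficient t tests, and a nested-model
  quasi-likelihood-ratio test $2(\sum\rho_0 - \sum\rho_1) \cdot
  \overline{\psi'} / \overline{\psi^2}$ referred, divided by q, to
  $F(q, n - p)$. Simulation showed the $\chi^2_q$ reference mildly
  anticonservative at n = 100 while the F reference calibrates, mirroring
  how the Gaussian likelihood ratio is referred in finite samples.
* JZS Bayes factors by adaptive quadrature of the non-central t density
  over a Cauchy effect-size prior; scale $\sqrt{2}/2$ by default and the
  wide r = 2 prior for the norm-rating battery, where many comparisons
  are evaluated at once; directional variants use the half-Cauchy.
* Sample-size search under the exact noncentral-t power function. One
  detail worth recording: with very large effects the search floors at
  n = 2, but at d = 5 a two-observation one-sample test still only
  reaches 73% power (df = 1), so the minimum there is 3 — the exact
  calculation, not a rule of thumb, decides.
* Effect-size intervals are 2000-replicate seeded percentile bootstraps
  throughout. The bracketed intervals in the literature this package
  accompanies do not name their method; the bootstrap choice is a
  documented deviation of unknown fidelity.
* Multiplicity correction is Holm everywhere a family of tests is run
  (post-hoc comparisons, the per-allocation rating battery): it dominates
  Bonferroni at no extra assumptions.

Calibration of the battery is itself part of the test suite: every test's
p-value is checked for uniformity under its null on 2000 seeded
continuous-data replicates (Kolmogorov-Smirnov at $\alpha = 0.01$), and
the exact Wilcoxon path is checked against full $2^n$ enumeration.
Continuous null data is the right bench for these checks: on 4-point
ordinal ratings any rank test's p-value is inherently discrete and no
implementation could make it uniform.

## Problem sizes used by the checks

The package's own verification runs at sizes chosen to make each question
answerable in minutes on a single core: parameter recovery fits 60
subjects × 100 trials per phase (91 ring trials plus the 9 catch trials)
at the desk MCMC settings; model identification runs 10 replicates of 12
subjects × 100 trials per phase over all six models, with each phase's
attitude and variability drawn independently from the population
distributions so that the generating process is genuinely the full model
(under the small treatment shifts of the study conditions the tied-
parameter variants are near-indistinguishable from the full model within
a few DIC points — expected behaviour, not a fitting defect); the
direction-pattern check simulates 100 participants per condition and
evaluates the measures on generator ground truth, which is what that
check is about — the generator and measures, not the fitter.

## Known limitations

* The sampler is a bespoke Metropolis-within-Gibbs scheme; it is validated
  by parameter recovery, prior recovery on information-free data,
  posterior contraction and model recovery, but it is not a
  gradient-based sampler and very small data sets can leave group scales
  near the $\hat R$ flag.
* DIC with a plug-in at posterior means is the classic choice and keeps
  comparability with JAGS-era analyses, but it is known to under-penalise
  strongly skewed posteriors; WAIC/LOO are deliberately out of scope.
* Hybrid models mixing comparison noise ($\tau$) and attitude noise
  ($\sigma$), and any reaction-time extension, are out of scope.
* The norm-rating generator is a stand-in with an invented parametric
  form; conclusions about rating-level phenomena should not rest on it.
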