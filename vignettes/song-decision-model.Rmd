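---
title: "Modelling grasshopper mate-choice decisions as bounded evidence accumulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling grasshopper mate-choice decisions as bounded evidence accumulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songddm)
```

## The decision problem

Female *Chorthippus biguttulus* grasshoppers answer a male calling song with
a response song of their own when they judge the male acceptable.  Playback
experiments exploit this: artificial song models — sequences of 33
*subunits*, each a noise syllable plus a pause — are presented repeatedly,
and the fraction of presentations a female answers measures the song's
attractiveness.  By mixing an attractive and an unattractive subunit type in
varying proportions and positions, the experiments probe how acoustic
evidence for and against a male is combined over the course of a song.

`songddm` implements the analysis chain for such experiments: stimulus
construction, a drift-diffusion decision model, parameter fitting, and
synthetic-cohort generation for validating the fitting machinery.

## The model

The decision variable \(E\) starts at 0.  Subunit \(k\) of a song
contributes its type's weight \(\omega(s_k)\) plus Gaussian noise, in one
joint increment per subunit:

\[ E_k = E_{k-1} + \omega(s_k) + \varepsilon_k, \qquad
   \varepsilon_k \sim \mathcal{N}(0, \sigma^2). \]

The subunit index is the model's clock: one noise draw per subunit,
regardless of the subunit's physical duration (a mollis subunit lasts
240 ms, a block subunit 84 ms; both are one step).  Accumulation is
perfect — no leak or decay within a song.  After each step the two
absorbing thresholds are tested: if \(E_k > \theta_+\) the female's
response is fixed (respond); if \(E_k < \theta_-\) rejection is fixed.
Crossing is *strict*: evidence exactly equal to a threshold does not fix a
decision.  This convention reconciles the published noise-free counts — a
weight of 15 against an upper threshold of 420 requires 29 subunits, since
\(28 \times 15 = 420\) only reaches the threshold — with the threshold
ratio of 420 reported for the block subunit.  After absorption the
evidence is clamped at the crossed threshold.  If the song ends without a
crossing, the decision follows the sign of \(E_L\): respond if positive,
reject otherwise (exactly zero counts as reject; under noise this is a
measure-zero tie, and the no-response default is the conservative choice).

The weight of the standard block subunit is fixed at \(+1\): it defines
the unit of evidence.  All other weights, the noise level \(\sigma\), and
the thresholds are expressed in these units and shared across stimulus
sets.

## Computing response probabilities

Two backends compute \(P(\text{respond})\) for a song:

* **Monte Carlo** (`response_probability_mc()`, `simulate_trials()`):
  direct simulation, default 50,000 repetitions (the resolution used for
  the averaged-evidence figures).  Reproducible from a seed.
* **Density propagation** (`response_probability_exact()`): the surviving
  evidence density is tracked on a bin grid spanning
  \([\theta_-, \theta_+]\); each step convolves it with the Gaussian
  increment kernel (normal-CDF differences at the bin edges) and moves the
  tail masses beyond each threshold into per-step absorbed-mass
  accounters.  A bin edge is pinned at 0 so the end-of-song sign rule is
  exact at grid level, and the first step is taken analytically from the
  initial point mass, which makes single-step probabilities exact.  Mass
  beyond the thresholds is absorbed at every step, so no grid margin
  outside the thresholds is needed.  The default resolution is 20 bins per
  noise SD; halving the bin width changes probabilities by less than
  \(10^{-4}\).  Probability is conserved exactly by construction.

The exact backend is the reference: it is deterministic, which also makes
the fitting objective deterministic.  The Monte-Carlo backend serves as an
independent cross-check (the two agree within Monte-Carlo error on random
instances; see the test suite) and provides trajectory-level output.

Decision dynamics are summarised by `first_passage_profile()` (per-step
threshold-crossing probabilities plus terminal sign-rule masses),
`mean_trajectory()` (mean evidence with absorbed paths clamped at their
threshold), and `thirds_decomposition()` (crossing mass per third of a
33-subunit song).

## Stimuli

`subunit_catalog()` encodes the tested subunit envelopes: the standard
block (72-ms syllable at 64 dB SPL + 12-ms silent pause) and its
duration-matched 76 + 14 ms variant, heterospecific mimics of *C.
dorsatus* (four 8-ms pulses separated by 6-ms gaps, 40-ms pause) and *C.
mollis* (120 + 120 ms), degraded conspecific patterns (shallow 8-dB-offset
pause, 4-ms pause, gaps in the syllable plateau), and accented patterns
(3-dB and 9-dB onset accents, and a 70-dB syllable with a 10-ms 82-dB
accent at its start or end).  Levels are envelope annotations only — the
package models amplitude-envelope timing, not audio.

The mixture sequences of the original playback series are not published;
`default_sequence_patterns()` generates a 35-song parametric family with
the same statistical structure: both pure songs, uniform-random placements
covering negative-subunit proportions from 0 to 1, contiguous negative
blocks of one and two thirds, and the two valence-switch songs (11
subunits of one valence followed by 22 of the other).  The gap subunit's
internal timing is likewise an emulation (a 72-ms window with two 2-ms
gaps carved into the plateau, configurable).  Song assembly is
deterministic given the set seed.

## Fitting

`fit_ddm()` estimates the free subunit weights and the shared integrator
parameters by minimising, by default, the mean squared error between the
exact response probabilities and the observed response rates.  (The
original analyses do not state their objective; MSE makes the coefficient
of determination of predicted vs observed rates the natural summary.  A
trial-count-weighted binomial likelihood is available via
`objective = "binomial"`.)  The optimiser is a real-coded genetic
algorithm — tournament selection (size 3), uniform crossover (rate 0.7),
Gaussian mutation with SD 5% of each bound range decaying by 0.99 per
generation, elitism 2, population 200, up to 300 generations with early
stopping when the best loss improves by less than \(10^{-6}\) over 25
generations.  These are conventional settings, declared rather than
inherited: the original GA's hyperparameters are not recoverable.  Bounds
are weights \([-200, 50]\), \(\sigma \in (0, 500]\),
\(\theta_+ \in (0, 2000]\), \(\theta_- \in [-5000, 0)\).

Two numerical choices matter:

* During fitting the propagation grid uses a *fixed bin count* (default
  120 negative-side, 64 positive-side bins) instead of bins-per-sigma.
  A per-sigma grid changes its bin count discontinuously as \(\sigma\) or
  the thresholds move, which injects micro-jumps into the objective; a
  fixed count keeps the loss smooth in all parameters.
* `polish = TRUE` refines the GA's best individuals with bounded
  L-BFGS-B on the unit-scaled parameters (tight tolerance, finite
  differences of \(10^{-5}\)).  The loss surface has an extremely shallow
  ridge (next section), and the polish is what pins the optimum to
  numerical precision on noise-free data.

`loocv()` runs leave-one-out cross-validation over songs, reporting
per-fold parameters (mean ± SD), held-out predictions and their
\(r^2 = 1 - SS_\mathrm{res}/SS_\mathrm{tot}\).
`compare_integrator_models()` cross-validates the shared-integrator model
against a per-set-integrator variant on identical folds, and
`profile_theta_minus()` traces the loss over fixed lower thresholds.

## Synthetic cohorts

`generate_cohort()` emulates the behavioral design: each song's
ground-truth response probability comes from the exact backend; each
female contributes a binomial response count over 18 presentation cycles;
a negative-control stage (response probability 0.02 per presentation by
default) excludes females responding more than 2 of 18 times.  Responses
are conditionally independent given the song — the experiments randomized
stimulus order within every cycle precisely to suppress carry-over, so no
sequential dependence is modelled.  The motivation song preceding each
cycle has no analysed response and is not modelled.  An optional
logit-normal per-female perturbation (`female_sd`) stress-tests fitting
against cohort heterogeneity; it is off by default.  The generator does
not emulate acoustic degradation or motivational drift, so passing
recovery tests demonstrate correctness of the fitting machinery under the
design's sampling noise, not robustness to every feature of real data.

## Identifiability: what the data can and cannot pin down

With the block weight as the only absolute anchor, the model is almost
invariant under a joint rescaling of all free weights, \(\sigma\) and both
thresholds: only the block subunit's +1-per-step drift (7 per mille of the
noise SD at the published values) breaks the symmetry.  On noise-free
response rates this residual anchor suffices — the loss ridge has its
minimum exactly at the generating parameters, and the polished fit
recovers them to numerical precision.  At the behavioral design scale
(around 20 females by 18 cycles, i.e. a standard error near 0.026 per
song rate), however, the ridge is flatter than the sampling noise: the
fitted *scale* wanders by tens of percent from cohort to cohort, while
all weight *ratios*, and every quantity invariant under the rescaling
(response probabilities, crossing orderings, subunit counts computed from
fitted ratios), remain tightly determined.  The lower threshold
\(\theta_-\) is additionally identified only up to a minimal magnitude:
it must be deep enough to prevent early noise-driven vetoes, but the data
barely penalise extra depth.  `profile_theta_minus()` and
`recovery_report()` (which flags \(\theta_-\) as `bounded_only`) make
both limitations visible.  Consumers of fitted parameters should
therefore interpret weight ratios and derived dynamics, not absolute
magnitudes, unless the data volume is far beyond the published design.

## Problem sizes and defaults

The package's study-scale defaults are the design values: 35 songs per
stimulus set, 33 subunits per song, 7 subunit pairs (covering all nine
free weights), 20 females, 18 cycles, control response probability 0.02
with exclusion above 2 of 18.  The test suite exercises reduced GA
budgets (populations of 16-32, tens of generations, a 60 + 32-bin fitting
grid) with the quasi-Newton polish doing the final convergence; the
recovery study in the acceptance tests uses five independent cohorts at
the full design scale.  Monte-Carlo cross-checks use \(10^4\) to \(10^5\)
repetitions.

## Known limitations

* Decision *times* are modelled only at subunit resolution; there is no
  continuous-time variant, no collapsing bounds, and no reaction-time
  likelihood.
* The per-set figures printed alongside the published switch-song
  dynamics (e.g. a first-third rejection mass near 0.35 for
  heterospecific subunits) are not exactly reproducible from the mean
  parameter estimates alone — they plausibly average over the full set of
  cross-validation fits, with \(\theta_-\) only bounded below.  The
  package reproduces the orderings between stimulus sets, and treats the
  printed magnitudes as qualitative.
* Absolute parameter magnitudes are weakly identified at behavioral data
  volumes (see the identifiability section); synthetic-recovery checks of
  \(\sigma\) and \(\theta_+\) to tight tolerances fail for this
  statistical reason even though the estimator is exact on noise-free
  data.

## A short session

```{r, eval = FALSE}
params <- reference_ddm_params()

# decision dynamics of a song switching from negative to positive valence
song <- build_song("switch_at_11_reversed",
                   c(positive = "block", negative = "mollis"),
                   set_id = "mollis")
prof <- first_passage_profile(song, params)
thirds_decomposition(prof)

# a synthetic cohort and a reduced-budget refit
songs <- build_paper_stimulus_sets(n_songs = 35, seed = 1)
cohort <- generate_cohort(synthetic_cohort_config(params, songs, seed = 1))
fit <- fit_ddm(cohort$dataset,
               fit_config(population = 32, generations = 30,
                          n_bins = c(60L, 32L), seed = 1))
recovery_report(fit, params)
```
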