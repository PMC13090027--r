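---
title: "Modeling SunTag run-off experiments: simulation and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling SunTag run-off experiments: simulation and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suntagr)
```

## The measurement

SunTag imaging makes translation of a single mRNA visible: an N-terminal
array of `n_S = 24` GCN4 epitopes on the nascent peptide is bound
co-translationally by fluorescent single-chain antibodies, so the spot
intensity of one mRNA reports how many ribosomes are translating it and how
far each has progressed.  In a harringtonine (HT) run-off assay, new
initiation is blocked (taking effect roughly 60 s after drug addition);
already-loaded ribosomes finish, and the fluorescence decays over the total
elongation time.  The decay of a single trace depends on how many ribosomes
were loaded and where they sat when initiation stopped — the quantities this
package simulates and infers.

## Ribosome traffic: the $\ell$-TASEP

Ribosome dynamics on one transcript of $L$ codons follow the totally
asymmetric exclusion process with extended particles: each ribosome covers
$\ell = 10$ codons, hops forward one codon at rate $\lambda$ (codons/s,
uniform along the transcript; termination is treated as one more hop off the
lattice at the same rate), and initiates at rate $\alpha$ whenever the first
$\ell$ codons are free.  `simulate_steady_state()`, `simulate_runoff()` and
`simulate_bursting()` run this process exactly with an event-driven
(Gillespie) algorithm: every enabled move carries an exponential waiting
time, pending events live in a binary min-heap keyed on absolute event time,
and a move is (re)enabled exactly when the site ahead clears.  In the
telegraph extension the transcript toggles between an initiation-competent
and a silent state with exponential dwell times `Exp(k_off)` and
`Exp(k_on)`.

Two conventions are worth stating because the process description leaves
them open:

* **Bootstrapped initiation.** From an empty lattice no event is pending, so
  the simulation arms one initiation event at start-up; afterwards
  initiation is re-armed whenever the leading ribosome clears codon
  $\ell-1$, as the update rules prescribe.  An empty lattice would otherwise
  deadlock.
* **Stationary sampling.** Burn-in is counted in reaction events
  ($10^3$ by default), which ends the run at an event epoch.  States sampled
  at event epochs follow the embedded jump chain, whose stationary law
  over-weights high-activity (high-$N$) configurations — at
  $\alpha = 1/60$ s$^{-1}$, $\lambda = 3$ aa/s the mean occupancy measured
  at the $10^3$-rd event is about 60% above the time-stationary mean.  The
  engine therefore follows every event-count burn-in (and the inter-trace
  decorrelation) with a deterministic settling period of $2L/\lambda$
  seconds — a complete lattice turnover — which restores the time-stationary
  law.  The run-off protocol then purges pending initiations, sets
  $\alpha = 0$, and records from $t = 0$.

In the initiation-limited regime the stationary current is
$J = \alpha(\lambda-\alpha)/(\lambda + (\ell-1)\alpha)$, the density is
$\rho = \langle N\rangle \ell / L \approx \ell\alpha/\lambda$, and the
stationary ribosome count is close to Poisson with mean $\alpha L/\lambda$.
The test suite checks the simulator against these closed forms (current
within Monte-Carlo error, Poisson mean and dispersion of run-off initial
counts at $\rho \le 0.03$).

## From occupancy to fluorescence

A ribosome at codon $x$ has synthesized
$n(x) = n_S (x-1)/(L_S-1)$ epitopes for $x \le L_S$ and all $n_S$ beyond,
where $L_S$ is the SunTag length in codons.  The noiseless intensity of a
frame is $b_0 + (i_\mathrm{MP}/n_S)\, \mathbf{w}\cdot\boldsymbol\tau$, with
$\mathbf w$ the cumulative-epitope weights, so a ribosome past the SunTag
contributes exactly the intensity of one mature protein, $i_\mathrm{MP}$.
Acquisition noise is multiplicative lognormal: $y = \mu\,e^{s_0 X}$ with $X$
standard normal, so the median of replicate frames equals the noiseless
value.  Observation windows mimic single-particle tracking: durations are
exponential with mean 10 min, resampled below 5 min; tracking continues past
run-off completion (baseline frames), and a window that ends while ribosomes
remain marks the trace as censored.

Defaults and their provenance:

| parameter | default | meaning |
|---|---|---|
| $L$ | 1066 codons | reporter length |
| $L_S$ | 528 codons | SunTag length; 24 repeats of a 22-codon epitope–linker unit (the construct length in codons is not published, so this is the package's single fixed choice, about half the reporter) |
| $\ell$ | 10 codons | ribosome footprint |
| $i_\mathrm{MP}$ | 14 a.u. | measured one-mature-protein intensity (14 ± 2) |
| $b_0$ | 6 a.u. | offset, mean intensity of untranslated spots |
| $s_0$ | 0.34 | baseline lognormal scale (untranslated traces give 0.31–0.38, mean 0.34; arrested traces give 0.36) |
| $dt$ | 20 s | imaging frame interval |

Weights are rounded to integer epitope counts by default
(`weights = "integer"`); the closed-form correction factors below assume the
continuous ramp, and tests that compare against them use
`weights = "continuous"`.

## Closed-form run-off corrections

During run-off the surviving ribosomes sit (approximately uniformly)
downstream of the front $x_t = \lambda t$, so the mean brightness of one
ribosome relative to a mature protein is
$$\gamma(t) = 1 - \frac{(L_S-\lambda t)^2}{2L_S(L-\lambda t)}, \qquad
\lambda t \le L_S,$$
and 1 afterwards; $\gamma(0) = 1 - L_S/2L$.  The corresponding per-ribosome
normalized variance $\nu(t)$ vanishes once every ribosome has cleared the
SunTag.  `gamma_t()` and `nu_t()` implement both the continuous forms and
the exact discrete-position sums (which agree to $O(1/L_S)$; the package
treats differences up to $10^{-2}$ absolute near $\lambda t = L_S$ as the
discretization allowance).  The waiting time between successive termination
events at stationarity is
$P(t) = \alpha\frac{\lambda-\alpha}{\lambda-2\alpha}
(e^{-\alpha t} - e^{-(\lambda-\alpha)t})$, essentially exponential with rate
$\alpha$ when $\alpha \ll \lambda$.

These formulas neglect excluded volume.  The Monte-Carlo comparison in the
test suite (2000 simulated run-offs at $\alpha = 1/60$ s$^{-1}$,
$\lambda = 3$ aa/s, $\rho \approx 0.056$) reproduces $\gamma(t)$ to better
than 0.5% everywhere; $\nu(t)$ runs 5–10% below the independent-position
formula, and an independent oracle (uniform sampling with a minimum spacing
of $\ell$ codons, no TASEP involved) reproduces the same deficit.  The
deficit is real physics — excluded volume anti-correlates positions and
shrinks the configurational variance — and grows with density, so the
strict three-standard-error comparison at 2000 traces flags it even at
$\rho = 0.056$ while a visual comparison would not.

## The run-off hidden Markov model

Each trace $y_{r,t}$ is a noisy observation of the hidden number of
translating ribosomes $N_{r,t} \in \{0,\dots,N_\mathrm{max}\}$,
$N_\mathrm{max} = 100$ (density $\approx 0.94$ — effectively uncapped).

* **Initial law.** $N$ at run-off start is Poisson with mean
  $\alpha(L/\lambda - t_r)$ for a trace first observed $t_r$ seconds into
  the run-off; the probability that the transcript is silent is a separate
  parameter $p_\mathrm{off}$, with the zero-truncated Poisson renormalized
  over $1..N_\mathrm{max}$ carrying the rest.
* **Transitions.** With initiation blocked, $N$ can only fall; drops per
  frame are Poisson with mean $\alpha\,dt$ (the stationary termination rate
  equals the initiation rate), truncated at $k_\mathrm{max} = 6$ — at the
  fastest initiation rates reported for comparable reporters
  ($\alpha \approx 0.08$ s$^{-1}$) the probability of six events in one
  frame is already $\approx 0.005$ — and renormalized row-wise, preserving
  stochasticity.  State 0 is absorbing.
* **Emissions.** Lognormal with median
  $\mu(N,t) = b_0 + \gamma(t)\,N\,i_\mathrm{MP}$ and scale
  $$s(t) = \sqrt{\ln\!\Big(1 + (e^{s_0^2}-1) +
  \tfrac{\lambda}{\alpha L}\tfrac{\nu(t)}{\gamma^2(t)}\Big)},$$
  which folds the configurational uncertainty of the ribosome positions
  into the noise using the ensemble mean $\alpha L/\lambda$ in place of the
  hidden $N$; state 0 uses the baseline scale $s_0$.  The scale is
  re-evaluated from the current parameter iterate at every likelihood
  evaluation.

`forward_loglik()` marginalizes over hidden paths with the scaled forward
recursion (checked against exhaustive path enumeration to ten significant
digits on small instances).  Censored traces contribute the likelihood of
their observed frames only; no explicit censoring term is added, and the
decoded run-off time of a censored trace is reported as a lower bound.

### Estimation

`fit_runoff()` maximizes the summed forward log-likelihood by bounded
quasi-Newton (L-BFGS-B) on log/logit scales, from both a default and a
data-driven start (elongation from the median signal-extinction time,
initiation from the mean initial intensity).  Bounds are
$\alpha \in (10^{-4}, 0.2)$ s$^{-1}$ and $\lambda \in (0.1, 10)$ aa/s,
spanning the literature ranges for mammalian reporters, with
$p_\mathrm{off} \in [0,1]$ and, when freed, $i_\mathrm{MP} \in (0.5, 200)$
a.u.; within the bounds the objective is the plain likelihood.  Posterior
sampling is a valid alternative backend, but the package's reference
implementation is the maximizer plus observed-information (Laplace) 95%
intervals on the transformed scale; non-convergence and non-positive-definite
information are reported, never silent.  With several conditions in one
table, $\alpha, \lambda, p_\mathrm{off}$ are condition-specific while
$i_\mathrm{MP}$ is shared — the design used to cross-validate the measured
mature-protein intensity.

`decode()` returns the forward–backward posterior per frame and a
max-product path; the run-off time is the first frame at which the path
reaches zero.  `runoff_summary()` aggregates run-off times, the censored
fraction, the fraction still translating at a reference time, and the
waiting times between decoded termination events.  Decoded event times are
interval-censored to the frame grid; for goodness-of-fit against the
continuous waiting-time law the summary can impute event times uniformly
within their frame (`impute = "uniform"`), the standard randomized treatment
of interval censoring.

### A quantified limitation: the homogeneous termination approximation

The Poisson$(\alpha\,dt)$ transition is a stationary approximation.  In the
actual run-off the lattice drains: given $N$ survivors at time $t$, the
termination rate is close to $N\lambda/(L-\lambda t)$, which accelerates as
the front advances and forces every trace to finish by about $L/\lambda$.
The ensemble mean of $N(t)$ still decays at rate $\alpha$, so the mismatch
hides in the path law, not the mean.  Its consequence, measured on this
package's own simulations by fitting ensembles of 100–500 traces: the
maximum-likelihood $\hat\alpha$ (and, through the initial-mean coupling
$\alpha L/\lambda$, also $\hat\lambda$) is biased upward, mildly when the
mean load $m = \alpha L/\lambda$ is large (about +15% at $m \approx 12$,
+20% at $m \approx 7$) and strongly when it is small (up to roughly +90% at
$m \approx 1.8$).  Truncating traces to frames before the drain phase
removes the bias, which localizes its source.  Fitting data simulated from
the HMM itself recovers $\alpha$ within 2%, so the inference machinery is
not the cause.  Practically: rate estimates from this model are most
trustworthy when the transcript carries at least a handful of ribosomes at
run-off start, and the acceptance benchmark at the small-$m$ corner of the
grid reflects this bias rather than an implementation defect.

The opposite regime is also reproduced: at high density
($\rho \ge 0.3$), where excluded volume throttles effective initiation, the
fit overestimates $\alpha$, underestimates a freed $i_\mathrm{MP}$, and
overestimates the density — direction checks in the test suite.

At very early run-off times a just-initiated ribosome has synthesized almost
no epitopes, so hidden states $N$ and $N-1$ can emit identical intensities;
exact path decoding is only guaranteed once every ribosome has cleared the
SunTag, and the decoding test requires exactness there and near-exactness
before.

## Trace preprocessing

The preprocessing mirrors what a run-off imaging pipeline needs before
fitting:

* **Noise estimation** (`estimate_multiplicative_noise()`): on
  translation-arrested traces, a linear bleach trend is regressed out per
  trace, the CV around the trace mean is averaged over traces, and
  $s_0 = \sqrt{\ln(1+\mathrm{CV}^2)}$.
* **Despiking** (`despike()`): a zero-phase order-2 Butterworth low-pass at
  1/120 Hz defines the smooth reference (order and phase are the package's
  choice; zero-phase avoids shifting burst boundaries); frames whose
  relative deviation exceeds twice the multiplicative noise are replaced by
  the smoothed value.  A 3-point running median is applied before the
  filter so the reference is robust to the single-frame spikes being
  flagged — without it, a large spike drags the reference toward itself and
  escapes its own threshold.
* **Filtering** (`filter_runoff_traces()`): traces must start no later than
  100 s after drug addition (start offsets are measured from run-off start,
  60 s later, so the rule is $t_r \le 40$ s), span at least 5 min, and
  experiments keep at least 10 traces or are dropped entirely; every
  exclusion is logged with its rule.
* **Burst segmentation** (`segment_bursts()`): no published rule exists, so
  the package uses hysteresis on the smoothed trace (enter active above
  $b_0 + 3 b_0\sigma$, exit below $b_0 + b_0\sigma$, minimum two frames) for
  robust detection, then refines each boundary to the half-amplitude
  crossing on the median-prefiltered raw trace — the asymmetric thresholds
  alone bias interval durations by a few frames, and the mid-level crossing
  removes that.  Square-wave fixtures are recovered to within a frame per
  boundary.
* **Empirical density** (`empirical_density()`): assuming uniformly
  distributed ribosomes, an interval's mean intensity converts to
  $\hat N = (\bar y - b_0)/(\gamma(0)\, i_\mathrm{MP})$ and
  $\hat\rho = \hat N \ell/L$; the $\gamma(0)$ factor keeps $\hat N$
  unbiased under that assumption.

## Spot quantification

`fit_spot()` implements the single-spot model used to produce intensity
traces from image patches: an integrated 2D Gaussian (total intensity $I$,
width $w$, center $x_0,y_0$) on a tilted-plane background
$c + a(x-x_0) + b(y-y_0)$, with fixed pixel noise estimated from the
cytoplasmic background.  The per-pixel Gaussian mass is integrated
analytically (products of normal CDF differences), so the summed spot equals
$I$ — at the default 0.27 μm pixels (16 μm camera pixels through a 60×
objective) point sampling at pixel centers would misallocate several percent
of the mass.  Priors: centers normal around the tracked position (sd
0.2 μm), width inverse-gamma with mean 0.20 μm and sd 0.02 μm (read as
moments and converted to shape 102, scale 20.2), intensity half-normal
(sd 1000), background level normal with cytoplasm moments, tilts normal
(sd 50).  The reference backend is MAP with Laplace intervals, the same
contract as the trace fit.  `flatfield_correct()` applies the standard
$(O-DC)/(FF-DC)\,\langle FF-DC\rangle$ normalization, and
`power_calibration()` extrapolates calibration intensities linearly in laser
power — the route by which $i_\mathrm{MP}$ is measured.

## Problem sizes in the test suite

The suite builds every fixture in code.  Distributional checks use
1500–2000 simulated run-offs (seconds of compute); the correction-factor
comparison uses 2000 traces at $\alpha = 1/60$ s$^{-1}$,
$\lambda = 3$ aa/s; recovery benchmarks fit 100 traces per grid point, the
scale at which the Laplace intervals are well behaved and a fit takes under
a minute.  What passing tests show — and what they do not — follows from the
generator: it reproduces the statistical structure of run-off ensembles
(Poisson loading, exponential terminations, lognormal noise, truncated
exponential tracking durations) but not photobleaching, spot-tracking
failures, codon-specific elongation, ribosome drop-off, or stalling; tests
green on this generator validate the algorithms, not the biology of any
particular reporter.
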