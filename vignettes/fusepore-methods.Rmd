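---
title: "Models and methods in fusepore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in fusepore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fusepore)
```

# The measurement and the two halves of the package

In the nanodisc-to-cell fusion assay, a ~25 nm nanolipoprotein particle
(NLP) carrying v-SNAREs, with or without Synaptotagmin-1 (Syt1), fuses
with a cell presenting "flipped" t-SNAREs on its surface. Each fusion
event opens a single nanometer-scale pore between the nanodisc and the
cell membrane, and the current through that pore, recorded in a
cell-attached patch at a small holding potential, reports the pore's
size over time. The raw observable is therefore a conductance time
series punctuated by *current bursts*: episodes that begin when a pore
opens, are interrupted by transient full closures (*flickers*), and end
in a permanent closure.

`fusepore` implements both halves of the computational work such data
require:

1. an **analysis pipeline** - a synthetic-recording generator with the
   statistical structure the analysis assumes, burst/flicker
   idealization, per-pore metrics, conductance-to-radius conversion,
   pore-size distributions, Boltzmann-inverted apparent free-energy
   profiles, and Hill-equation calcium titrations;
2. a **mechanical model** - a statistical-mechanical "lever" model in
   which SNARE zippering and crowding act on a Helfrich membrane, and
   calcium reorients the Syt1 C2B domain so that the SNARE-C2B complex
   props the two membranes apart and thereby dilates the pore.

Everything below states what is computed, which parameters matter and
why their defaults were chosen, and what the synthetic data do and do
not establish about real recordings.

# The synthetic-recording generator

No raw traces are distributed with the assay's published summary
statistics, so the generator (`generator_params()`,
`simulate_burst()`, `simulate_patch_recording()`) emulates exactly the
stochastic structure that the downstream analysis assumes:

* pore nucleation is a Poisson process per patch (`nucleation_rate`,
  default 0.5 pores/min), truncated at `max_pores_per_patch`
  (default 3) because only a few pores can be analyzed per patch;
* burst lifetimes $T_o$ are exponential (`burst_mean_duration`,
  default 3000 ms - pore lifetimes are seconds);
* flicker counts $N_{\mathrm{flickers}}$ are geometric with support
  $\{0, 1, 2, \dots\}$ (`flicker_success_prob`, default 0.25, mean 3
  flickers per burst), since square bursts with no closures are
  observed;
* flicker (blocked) dwells are exponential (`flicker_mean_closed`,
  default 20 ms), and flickers are full closures to baseline;
  sub-conductance states are not generated;
* the open level is the condition mean plus point-wise Gaussian noise
  (`conductance_noise_sd`, 30 pS), on top of baseline noise
  (`baseline_noise_sd`, 5 pS), sampled at `sample_interval` (0.1 ms,
  i.e. 10 kHz) at a holding potential of 15 mV (the assay holds below
  20 mV).

A burst is constructed by drawing $T_o$ and $N_{\mathrm{flickers}}$
directly from their stated distributions and placing the closures
inside the burst with Dirichlet-distributed open spacings, each open
segment at least a few milliseconds long. A two-state Markov chain
would give only approximately exponential $T_o$; the direct
construction makes both tested marginals exact. When drawn closures do
not fit inside a short burst they are rescaled (rarely dropped), which
preserves the geometric flicker-count marginal to well below the
resolution of a goodness-of-fit test at $10^4$ bursts. The mean open
dwell is derived from the other parameters,
$\mu_{open} = p\,\mu_{T_o} - (1-p)\,\mu_{closed}$, so the expected
open fraction of a burst is
$\mu_{open} / (\mu_{open} + (1-p)\mu_{closed}) = 0.98$ by
construction.

The calcium dependence of the open level follows the Hill law
(`hill_law()`)
$$ G(x) = c + \frac{a}{1 + (K/x)^n}, $$
with defaults $a = 343.7$ pS, $c = 164.2$ pS, $n = 2.3$,
$K = 23\ \mu M$, the best-fit values of the assay's conductance
titration. Condition presets (`condition_preset()`) reproduce the
direction of the measured condition effects: wild-type Syt1 or C2AB
(and the avid 4W mutant) are calcium-sensitive when PI(4,5)P$_2$ is
present, roughly tripling the open level at 100 µM calcium, while the
calcium-binding, polybasic-patch, SNARE-interface and
membrane-insertion mutants collapse to the calcium-insensitive
baseline $c$.

**What passing tests show, and what they do not.** The generator
produces data that satisfy the distributional assumptions of the
pipeline *by construction*. Tests against it therefore validate the
implementation of the estimators (idealization, metrics, inversion,
fitting), not the assumptions themselves. Real recordings additionally
contain baseline drift, capacitance transients, seal leaks, sub-state
gating, and filtering correlations, none of which are simulated; an
optional low-pass step is deliberately left out because the
recordings' filter settings are not parameterized here.

# Idealization and per-pore metrics

`detect_bursts()` is a threshold idealizer: contiguous supra-threshold
activity separated by sub-threshold gaps shorter than `min_burst_gap`
(500 ms) is one burst; within a burst, sub-threshold intervals of at
least `min_dwell` (1 ms) are flickers; shorter deviations in either
direction are absorbed as noise. The `open_threshold` default of 25 pS
sits five baseline standard deviations above zero and far below open
levels of hundreds of pS. These defaults recover at least 95% of
generator ground-truth bursts with boundary errors below 5 ms on
default-noise traces; they are configuration, not claims about the
assay's own (unpublished) idealization settings.

`burst_metrics()` computes, per burst: the mean point-by-point
open-pore conductance $G_{po}$; the lifetime $T_o$; the flicker count
and rate; the open probability $P_o$ (open time over $T_o$); and the
conductance fluctuation, defined here as the RMS deviation of
open-dwell samples about $G_{po}$ (the source analysis does not define
its fluctuation statistic; this is the natural point-wise choice).

`nucleation_rate()` pools patches into pores/min. Because recordings
stop being informative after the per-patch cap, the naive estimator
$\sum n_i / \sum T_i$ is biased low at high rates. The
censoring-aware variant ends each capped patch's exposure at its last
countable pore; by the optional-stopping property of the Poisson
process ($\mathbb{E}[N(\tau)] = \lambda\,\mathbb{E}[\tau]$ for a
stopping time $\tau$), the pooled ratio is asymptotically unbiased.
With zero pores the exact one-sided Poisson 95% bound $3.689/T$ is
reported.

`expansion_rate()` aligns bursts at their first supra-threshold
sample, averages them point-wise over a 100 ms window, and reports
$0.8\,G_{100}/(t_{90} - t_{10})$, the 10-90% rise of the averaged
conductance divided by the time it took. For an instantaneous step the
two crossings coincide and the denominator is clamped to one sample
interval - the rate is then explicitly resolution-limited.

# Pore statistics

`conductance_to_radius()` treats the pore as a water-filled cylinder
of length $L = 15$ nm spanning both membranes:
$G = \sigma \pi r^2 / L$. The default conductivity
$\sigma = 1.65$ S/m is the value for which this model simultaneously
reproduces the assay's two printed correspondences (200 pS at 0.76 nm
and 1 nS at 1.70 nm); the two pairs are mutually consistent only for
the cylinder-only form, which is why the access-resistance correction
($1/G = L/\sigma\pi r^2 + 1/2\sigma r$) is implemented but off by
default. At a 10 nm diameter the model gives 8.64 nS, consistent with
the quoted ~9 nS ceiling of the NLP geometry.

Distributions are built by transforming *samples*, not densities:
conductance samples are mapped through the cylinder model and then
binned (20 pS and 0.05 nm default bin widths, which resolve a ~200 pS
peak without empty interior bins at $10^3$-$10^4$ samples). No
Jacobian is applied to binned counts. `boltzmann_invert()` converts a
binned density to an apparent free-energy profile
$U(r) = -\ln P(r) + \text{const}$ in kT, min-shifted to zero, keeping
only bins with at least `min_count` (5) samples to bound the noise the
logarithm amplifies. Interpreting $U$ as a free energy assumes the
recorded pore is near equilibrium and only weakly perturbed by the
small holding potential; profiles should be read as *effective* free
energies. `barrier_force()` converts a rise $\Delta U$ between two
radii into a mean resisting force with kT = 4.114 pN nm (298 K): 2 kT
over 1 to 2.5 nm is 5.5 pN, and 6-7 kT over the same span is 16-19 pN.

`fit_hill()` performs Levenberg-Marquardt least squares on the Hill
law with optional fixing of $n$ and/or $K$ (used when a
conductance-derived pair is reused for the expansion-rate titration).
Confidence intervals are Wald intervals from the local curvature; in
simulation they cover the truth in 96-98% of noisy titrations at a
nominal 95%, and the recovery study in the test suite asserts at
least 90%.

# The lever model

## Membrane mechanics

The pore membrane is a single axisymmetric surface running from a
remote, flat, zero-slope boundary on the cell side (default 50 nm from
the axis), through a waist of radius $r$, up to the nanodisc rim
(radius 12.5 nm) at height $h$, clamped horizontal there by the ApoE
scaffold (a freely hinged and an elastic-ring edge are available; the
clamped default is an acknowledged approximation of the scaffold's
unspecified elasticity). Its energy is Helfrich bending plus tension,
$$ E = \int \frac{\kappa}{2}\,(2H - c_0)^2\, dA + \gamma\,\Delta A, $$
with $\Delta A$ the excess area over the projected reference. The
Gaussian-curvature term is dropped (fixed topology; its boundary
contribution is absorbed by calibration), and $c_0 = 0$.

`solve_shape()` parameterizes the profile by its tangent angle on two
arc-length segments (remote-to-waist, waist-to-rim) as natural cubic
splines through control nodes graded toward the waist, and minimizes
the discretized energy (compiled kernel) under boundary and waist
conditions enforced by a quadratic penalty ramp; the stationary
discretized energy is the collocated shape equation. Nine control
nodes and 33 quadrature nodes per segment reproduce a
higher-resolution reference within ~1% and an independent dense
direct minimization (different parameterization and curvature
formula) within 2%. Tension-free necks reproduce the catenoid
($2H \equiv 0$) limit. Two numerical caveats are documented rather
than hidden: absolute energies retain a slowly decaying offset in the
remote-boundary radius (a tension-decay-tail effect), while the energy
*differences* across $(r, h)$ that determine all ensemble output are
insensitive to doubling it; and solutions are obtained on an
$(r, h)$ lattice (0.1 nm in $r$, interpolated to the 0.05 nm ensemble
grid; 0.5 nm in $h$ with parabolic refinement of the height optimum),
sizes chosen so a full model scan completes in about 90 seconds.

## SNARE statistical mechanics

Four SNARE complexes are each either *trans* (partially zippered, free
to roam an area `trans_area` of the disc face, default the full
~490 nm$^2$) or fully zippered *cis* at the waist. Zippered complexes
are one-dimensional hard rods of length `rod_footprint` on the waist
circumference (a Tonks gas with ring partition factor
$Z_n = L(L - nb)^{n-1}/n!$, $L = 2\pi r$, and zero weight when the
rods cannot fit). The state sum over the number of zippered complexes,
$$ Z(r) = \sum_{n=0}^{N} \binom{N}{n} e^{n\,\Delta G_{zip}}
   Z_{crowd}(n, r)\, Z_{trans}^{N-n}, $$
encodes the two SNARE-side forces on the pore: zippering pulls
complexes to the waist, and crowding among them favors either partial
unzippering or a wider waist - the entropic expansion force. With
more SNAREs the predicted mean pore grows monotonically (0.58, 0.77,
0.88, 1.05 nm for $N$ = 0, 2, 4, 8 at zero calcium).

`dG_zip` is the free-energy *increment* of the final C-terminal
zippering step from the membrane-spanning trans state - the only
portion that competes with waist crowding - not the ~35 kT total
assembly energy of a SNARE complex. Its calibrated value of 7 kT is
accordingly below commonly quoted whole-complex numbers.

## The calcium-dependent lever constraint

Each zippered SNARE carries a C2B domain bound at the primary
interface. With calcium, the C2B calcium-binding loops bury in the
cell membrane with Hill probability
$p = 1/(1 + (K/x)^n)$, $n = 2.3$, $K = 20\ \mu M$ (the measured C2AB
affinity for PI(4,5)P$_2$ membranes; the conductance titration's
fitted 23 µM is its experimental analogue). Burial pivots the rigid
SNARE-C2B complex (capsule, 13 nm long, 3 nm maximum thickness) about
its membrane contact point, raising the distal end by the lever arm
(complex length minus the 4 nm anchor offset) times $\sin 15^\circ$.

The geometric constraint is evaluated as a *separation* requirement.
The solved surfaces are bilayer midplanes, so the sterically available
lumen is the rim height minus one bilayer thickness (4 nm). A tilted
complex requires
$$ h \ge t_{bil} + h_{patch} + d\cos\theta +
   (L_c - t_c)\sin\theta \approx 9.7\ \text{nm}, $$
whereas the unburied, membrane-parallel complex imposes no constraint
in the default configuration - following the source's statement that
the untilted complex leaves the pore shape unconstrained. (The
alternative reading, in which the untilted complex also enforces its
minimum-thickness separation, is selectable via
`untilted_constrains = TRUE`, and a "buried" anchoring variant that
pulls the anchored end down by the loop depth is selectable via
`tilt_anchor`; both weaken or distort the lever in this membrane
model, which is why they are not the defaults.) States failing their
clearance are excluded from the Boltzmann sum; with at least one
buried complex among the zippered ones, the tilted constraint applies
(the strongest constraint dominates; multi-complex coupling beyond
that is not specified by the source and is not modeled). Burial
patterns are independent Bernoulli($p$) across zippered complexes,
which factorizes to a per-state gate
$(1-p)^n + (1-(1-p)^n)\,\mathbf{1}[\text{tilted fits}]$ - verified in
the tests against brute-force enumeration.

## Ensembles and predictions

For each radius on the grid, `total_free_energy()` minimizes
$E_{mem}(r, h) - \ln Z_{gated}(r, h)$ over the height grid - the
height takes the value that minimizes the free energy - and
`ensemble_statistics()` forms $P(r) \propto e^{-U(r)}$ on
$r \in [0.3, 4]$ nm (the upper limit mirrors the experimental sampling
limit). The reported pore height is the structural height of the pore:
the rim height of the midplane profile plus one bilayer thickness,
i.e. the distance between the outer monolayer midplanes of the two
membranes.

Calibration (`calibrate_lever_model()`) pins everything measured
(Hill response, tilt, loop depth, patch height, $N$, disc size) and
fits the remaining mechanical parameters against the *zero-calcium*
targets only (mean radius ~0.9 nm, mean height ~9.0 nm, a 6-7 kT
free-energy rise from 1 to 2.5 nm). The frozen defaults are
$\kappa = 12$ kT, $\gamma = 0.12$ kT/nm$^2$ (~0.5 mN/m),
$\Delta G_{zip} = 7$ kT, rod footprint 2.7 nm, capsule
13 nm x 3.0 nm with a 4 nm anchor offset. Everything at nonzero
calcium is then a parameter-free prediction. At the defaults:

* zero calcium: $\langle r \rangle = 0.88$ nm,
  $\langle h \rangle = 9.2$ nm, $U$ rises 7.1 kT from 1 to 2.5 nm;
* saturating calcium (1 mM): $\langle r \rangle = 1.33$ nm
  (1.51-fold), conductance 2.32-fold, $U$ rises 1.4 kT from 1 to
  2.5 nm, and the pore-size variance roughly triples
  (0.12 to 0.31 nm$^2$) - calcium broadens the distribution;
* removing the clearance constraint entirely collapses the calcium
  dependence to exactly zero: the lever constraint is the sole
  calcium coupling in the model.

One emergent feature deserves note: the mean radius is *not* globally
monotone in calcium. Near 10-30 µM, partial burial penalizes mid-size
pores (which would zipper several SNAREs) before the lever's height
gain can pay for itself, producing a shallow ~6% dip in
$\langle r \rangle$ before the strong rise toward saturation. This is
a genuine property of the Hill-weighted exclusion mixture, not
numerical noise; the property tests therefore assert monotonicity
from $K$ upward plus a strict overall increase, and treat the dip as
model behavior to be documented rather than suppressed.

## Design choices where the design was open

* **Idealization thresholds** (25 pS, 500 ms, 1 ms) were chosen so
  default generator bursts are recovered at 95% or better; all are
  exposed in configuration.
* **Fluctuation statistic**: RMS about the burst mean over open
  points.
* **Geometry conventions**: pore height and clearance are defined
  through bilayer midplanes plus a 4 nm steric thickness, as above;
  the remote boundary sits at 50 nm; the waist is constrained to be
  the global minimum radius.
* **Hinged vs clamped rim**: both are implemented; the clamped
  default is marginally stiffer and the model's conclusions do not
  depend on the choice.
* **Unzippered-state escape**: trans SNAREs are treated as
  unconstrained by pore geometry. In reality a trans SNARE spans both
  membranes and large separations would strain it; this coupling is
  not modeled.
* **Kinetics are out of scope**: the model is an equilibrium
  ensemble. Expansion rates in the analysis half are empirical
  metrics, not model outputs.

## Known limitations

The membrane model knows nothing about leaflet asymmetry, spontaneous
curvature generated by protein insertion (deliberately: the source
argues curvature generation by loop insertion is not required),
Gaussian rigidity, or the scaffold's true elasticity. The capsule
replaces the atomistic SNARE-C2B envelope; a space-filling refinement
against deposited coordinates would sharpen the clearance thresholds
but was not needed to reproduce the target statistics. The calibrated
$\kappa$ and $\gamma$ are effective constants of this geometry, not
independent measurements of the bilayer. And all experimental-scale
statistics quoted for the analysis half (e.g. a ~595 pS mean
conductance under optimal conditions) enter only as generator
defaults and documentation - they are not desk-scale reproducible
results.
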