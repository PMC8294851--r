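# fusepore

Single-pore electrophysiology of membrane fusion, plus the mechanics
that explain it.

When a v-SNARE-bearing nanodisc fuses with a cell displaying "flipped"
t-SNAREs, the nascent fusion pore conducts a measurable current, and
that current reports the pore's size sample by sample. `fusepore` is an
R package for this kind of data. It covers the full analysis chain -
from raw (or simulated) conductance traces, through burst/flicker
idealization and per-pore metrics, to pore-size distributions, apparent
free-energy profiles and calcium titrations - and implements a
statistical-mechanical model of how Synaptotagmin-1 and SNAREs
cooperate to dilate the pore when calcium arrives.

## What is inside

**Analysis** (`simulate_*`, `detect_bursts()`, `burst_metrics()`,
`nucleation_rate()`, `expansion_rate()`, `estimate_pdf()`,
`boltzmann_invert()`, `barrier_force()`, `fit_hill()`):

* a seeded synthetic-recording generator with the statistical
  structure the analysis assumes: Poisson pore nucleation per patch
  (with per-patch censoring), exponential burst lifetimes, geometric
  flicker counts, and a calcium-dependent mean open conductance
  following the Hill law
  `G(x) = c + a / (1 + (K/x)^n)`
  with defaults a = 343.7 pS, c = 164.2 pS, n = 2.3, K = 23 µM;
* threshold idealization into bursts and flickers, and the standard
  per-pore metrics (mean open-pore conductance G_po, open probability
  P_o, lifetime T_o, flicker count and rate, conductance fluctuation);
* conversion between conductance and pore radius through a cylindrical
  pore model, `G = sigma * pi * r^2 / L` with L = 15 nm and
  sigma = 1.65 S/m (an access-resistance variant is available);
* pore-size densities and Boltzmann inversion,
  `U(r) = -kT ln P(r) + const`, with barrier-to-force conversion
  (kT = 4.114 pN nm);
* a censoring-aware pore nucleation (fusion) rate estimator.

**Model** (`solve_shape()`, `snare_free_energy()`,
`buried_probability()`, `clearance_ok()`, `total_free_energy()`,
`ensemble_statistics()`, `lever_titration()`, `calibrate_lever_model()`):

a Helfrich membrane (bending modulus kappa, tension gamma) shaped by an
axisymmetric shape-equation solver; four SNARE complexes that are
either free (*trans*) or fully zippered at the pore waist, where they
crowd as one-dimensional hard rods (Tonks gas); and a Syt1 C2B domain
on each zippered SNARE whose calcium-binding loops bury in the cell
membrane with a Hill probability, pivoting the rigid SNARE-C2B complex
upward by ~15 degrees. The tilted complex demands more membrane
separation than the pore would otherwise provide, and the cheapest way
for the membrane to supply height is to widen the waist - a mechanical
lever that converts calcium binding into pore dilation. The pore-size
distribution is the Boltzmann weight of the height-minimized total free
energy, `P(r) ~ exp(-U(r)/kT)`.

## Worked example

Simulate six one-minute patches at 100 µM free calcium, idealize them,
and summarize:

```r
library(fusepore)

conductance_to_radius(c(200, 1000))   # pS -> nm
#> [1] 0.76 1.70

gp   <- generator_params(nucleation_rate = 2, patch_duration = 1,
                         sample_interval = 0.2, max_pores_per_patch = 60,
                         seed = 7)
pre  <- condition_preset("c2ab_wt", calcium = 100, nucleation_scale = 1)
recs <- simulate_patches(6, gp, pre)

bursts <- unlist(lapply(recs, function(r) detect_bursts(r$trace)),
                 recursive = FALSE)
met <- bursts_metrics(bursts)
round(colMeans(met), 2)
#>         G_po_pS          T_o_ms      n_flickers flicker_rate_hz
#>          496.39         2596.26            2.70            2.94
#>             P_o  fluctuation_pS
#>            0.94           31.03

nucleation_rate(recs)$naive          # pores per minute
#> [1] 1.666667
```

The detected mean open-pore conductance (496.4 pS) recovers the Hill
law's value at 100 µM (496.6 pS). Pooling the point-by-point open-pore
samples, converting to radii and inverting the histogram gives the
apparent free-energy profile:

```r
pooled <- pool_point_conductances(bursts)
radii  <- conductance_to_radius(pmax(pooled, 0))
prof   <- boltzmann_invert(estimate_pdf(radii, bin_width = 0.05))
head(prof, 3)
#>       r     P     U
#> 1 1.025 0.001 8.678
#> 2 1.075 0.097 4.454
#> 3 1.125 1.865 1.497
```

`U` is in kT, min-shifted to zero; `barrier_force(prof, r1, r2)`
converts any rise into a mean resisting force in pN.

The mechanical model runs from a single parameter bundle. One membrane
table serves any number of calcium conditions:

```r
lp  <- lever_params()                 # calibrated defaults
tab <- membrane_table(lp)             # ~1.5 min, done once
lever_titration(lp, calcium = c(0, 1000), table = tab)
#>   calcium mean_r mean_h mean_G  var_r fold_r fold_G
#> 1       0 0.8838  9.162  311.8 0.1211  1.000  1.000
#> 2    1000 1.3321 12.396  721.9 0.3144  1.507  2.315
```

At zero calcium the ensemble sits at a mean radius of 0.88 nm and mean
pore height of 9.2 nm; saturating calcium dilates the mean radius
1.5-fold and the mean conductance 2.3-fold. The zero-calcium values are
calibration constraints; the with-calcium values are predictions of the
lever mechanism.

## Package layout

* `R/` - analysis and model sources (`synthdata`, `traces`,
  `porestats`, `levermodel-*`, `workflow`)
* `src/` - compiled Helfrich energy kernel (Rcpp)
* `tests/testthat/` - unit, property and end-to-end suites
* `vignettes/fusepore-methods.Rmd` - the models, their assumptions,
  parameter choices and limitations
* `scripts/acceptance.R` - the reproduction script above
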