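# hemekin

Pre-steady-state kinetics of heme and flavin redox reactions in R.

`hemekin` is for biochemists analysing stopped-flow and rapid-scan
absorbance data from membrane-bound hemoproteins — in particular the STEAP
family of metalloreductases, where a diffusible flavin (FADH⁻) shuttles
electrons from NAD(P)H to a transmembrane *b*-type heme and on to a ferric
substrate such as Fe³⁺-NTA. The package provides both the forward problem
(simulating the spectra and kinetics such an instrument records) and the
full inference chain used in this field:

- **Multi-exponential time-course fits.** A trace at a single wavelength
  (e.g. the ferrous Soret band at 427 nm) is fitted with
  A(t) = offset + Σᵢ aᵢ·(1 − e^(−k₍obs,i₎ t)) (rise) or
  offset + Σᵢ aᵢ·e^(−k₍obs,i₎ t) (decay), by multistart variable
  projection; phases are reported fast-first with amplitude fractions.
- **Secondary fits.** Saturation of k_obs with the donor concentration,
  k_obs = V_max[S]/(K_M + [S]); and the pseudo-first-order binding law
  k_obs = k_on[S] + k_off, whose slope and intercept give k_on, k_off and
  K_D = k_off/k_on.
- **Global deconvolution of rapid-scan matrices.** A time × wavelength
  matrix A is decomposed as A ≈ C(t; k)·Sᵀ, where C is the Bateman
  concentration matrix of a sequential first-order chain (A → B → C …) and
  S holds the species spectra, solved linearly (nonnegativity-constrained)
  at each rate iterate — SVD-based rank estimation chooses the number of
  species.
- **Kinetic simulators.** Closed-form Bateman chains with a stiff ODE
  fallback, two-population pseudo-first-order heme oxidation, and a
  mass-action model of the diffusible-FAD electron shuttle with strict
  electron bookkeeping.
- **Synthetic data generators** with seeded Gaussian photometric noise,
  instrument dead time, and a catalog of named fixtures encoding published
  experiment conditions (`fixture_catalog()`), so every fit can be tested
  against known ground truth.

Everything takes data frames and returns tibbles; fitted objects have
broom-style `tidy()`/`glance()` methods and ggplot2 `autoplot()` methods.

## Worked example

Generate a biphasic heme-reduction trace (1.1 μM ferric STEAP1 mixed with
FADH⁻, monitored at 427 nm; true rates 7.7 and 0.67 s⁻¹ with a 60/40
amplitude split, 0.002 AU noise) and fit it:

```r
library(hemekin)

tc  <- hemekin_fixture("fig2A_fadh_steap1", seed = 42)
fit <- fit_multiexponential(tc, n_phases = 2, direction = "rise")
fit
#> <multiexp_fit> 2-phase rise
#> # A tibble: 2 × 6
#>   phase k_obs k_obs_se amplitude amplitude_se fraction_pct
#>   <int> <dbl>    <dbl>     <dbl>        <dbl>        <dbl>
#> 1     1 7.39    0.262     0.0405     0.000861         61.2
#> 2     2 0.626   0.0384    0.0257     0.000836         38.8
```

The fast phase comes back at 7.39 ± 0.26 s⁻¹ carrying 61% of the
amplitude — within noise of the generating 7.7 s⁻¹ / 60%. A substrate
titration of observed oxidation rates yields the binding constants:

```r
tt <- generate_titration("linear", list(k_on = 1.5e5, k_off = 7.5),
                         c(25, 75, 125, 175), noise_frac = 0.05, seed = 1)
fit_linear_kobs(tt)
#> <linear_kobs_fit> k_on = 165700 M^-1 s^-1, k_off = 6.281 s^-1, K_D = 37.9 uM
```

and a three-species rapid-scan experiment (ferric heme + oxidized b₅R →
intermediate → ferrous heme + reduced b₅R) is deconvolved globally:

```r
ds <- hemekin_fixture("fig3A_b5r", seed = 42)
deconvolve_sequential(ds, n_species = 3)
#> <deconvolution> 3 sequential species; rates (s^-1): 176.6, 0.1295; residual norm 0.7478
```

recovering the generating interconversion rates (177.9 and 0.13 s⁻¹) from
noisy data. `autoplot()` on any of these objects draws the standard
diagnostic figure, and `reproduction_report()` runs the whole battery of
recovery checks in one call.

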