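---
title: "Models and methods: heme/flavin redox kinetics in hemekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: heme/flavin redox kinetics in hemekin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemekin)
```

## The scientific problem

STEAP metalloreductases carry a single *b*-type heme in their transmembrane
domain. Electrons arrive from NAD(P)H via FAD: the reduced, deprotonated
flavin (FADH⁻, pKa 6.7) is not permanently bound but diffusible, so it can
be reduced at the oxidoreductase site of one protein and deliver its
electrons to the heme of another. The heme in turn reduces extracellular
ferric substrates such as Fe³⁺-NTA. The observable throughout is optical:
the ferric heme has its Soret band at 413 nm and a broad Q band near
550 nm; on reduction the Soret shifts to 427 nm and sharp α/β bands appear
at 560/532 nm. Stopped-flow instruments record either a single wavelength
versus time or, in rapid-scan mode, a full time × wavelength absorbance
matrix.

`hemekin` implements the complete analysis chain for such data — and,
because raw instrument files are rarely portable, a synthetic-data layer
that reproduces the statistical structure of each experiment with known
ground truth.

## Spectral forward model

Species spectra are sums of Gaussian bands in wavelength,
$\epsilon(\lambda) = \sum_b \epsilon_b \exp[-4\ln 2\,(\lambda-c_b)^2/w_b^2]$,
on a uniform grid (default 350–700 nm at 1 nm, the plotted range of typical
heme spectra). Real heme bands are not exactly Gaussian, but for generating
test data with the right landmarks the form is adequate and analytically
convenient. Mixture absorbance follows Beer–Lambert,
$A(\lambda) = \sum_i \epsilon_i(\lambda)\,(c_i/1000)\,\ell$ with
concentrations in μM, absorptivities in mM⁻¹ cm⁻¹ and pathlength in cm;
the composition is exactly linear in each concentration.

The peak absorptivities of the built-in spectra (`canonical_spectra()`) are
**synthetic placeholders** — roughly 100 mM⁻¹ cm⁻¹ for Soret bands and
~10 for Q/α/β and flavin bands, typical magnitudes for *b* hemes — because
measured extinction coefficients for these proteins are determined by
pyridine hemochrome assays that we do not model. Recovery tests therefore
validate rate constants and amplitude *fractions*, which are insensitive to
the absolute epsilon scale.

`find_isosbestic()` locates wavelengths where two spectra coincide. For a
closed two-species interconversion, absorbance at an isosbestic point is
time-invariant; the test suite verifies this to 1e-10 on noiseless data by
constructing a grid that contains the analytic crossing wavelength.

## Kinetic models

**Sequential chains.** A → B → C … with rate constants $k_1 \dots k_{n-1}$
is solved in closed form (Bateman). Closed-form evaluation suffers
catastrophic cancellation when two decay constants nearly coincide, so when
any pair agrees to better than 1e-6 relative the simulator switches to
stiff numerical integration (`deSolve::lsoda`, defaults rtol 1e-8 /
atol 1e-12 — the fixtures span rates from 1e-4 to ~1e3 s⁻¹, so a
stiff-capable integrator is required). The test suite checks the two routes
against each other over 1000 random rate sets.

**Two-population oxidation.** Ferrous heme oxidation by an excess ferric
substrate is biphasic, interpreted as two enzyme populations (conformations
of the substrate site or heme geometry). Electron transfer upon binding is
collapsed into the pseudo-first-order form $k_{obs} = k_{on}[S] + k_{off}$
per population rather than an explicit enzyme–substrate intermediate: that
is exactly the model the slope/intercept analysis parameterises, and it is
what the reported $k_{on}$, $k_{off}$ and $K_D = k_{off}/k_{on}$ mean. A
warning is raised when the substrate excess falls below 10× the enzyme,
where the approximation degrades.

**Diffusible-FAD shuttle.** `simulate_shuttle_chain()` integrates a
mass-action network: NADPH reduces bound FAD (effective rate `k_hyd`,
scaled by the remaining NADPH fraction so the donor depletes smoothly),
FADH⁻ is released and re-binds the heme site of either STEAP1 or STEAP2,
delivers two electrons in two sequential one-electron steps (whether one
or two electrons move per encounter is not experimentally settled; two
equal-rate steps is the default and the second step's rate is a separate
parameter internally), and ferrous heme reduces the ferric substrate pool.
A docked reductase such as cytochrome *b*₅R, which never releases its
flavin, is represented by the sequential-chain model instead (pre-reduced
donor, single electron-transfer rate) — that is the model the three-species
deconvolution resolves. The simulator enforces electron bookkeeping at
every stored time point: electrons held on flavin, heme and Fe²⁺ never
exceed twice the NADPH consumed.

No spatial diffusion is modelled: whether reduced FAD physically diffuses
between proteins or repositions within one protein is observationally
indistinguishable here, and both appear only as effective binding rates.

## Synthetic data and the fixture catalog

Generators add Gaussian photometric noise (default σ = 0.002 AU, a
realistic photodiode-array noise floor; no published figure exists for
these instruments) and are pure functions of their parameters and an
integer seed, recorded in the output provenance together with the true
parameters. Time grids are log-spaced with 400 points by default, which
resolves phases separated by more than a thousand-fold. The stopped-flow
dead time defaults to 1.5 ms (a typical mixer value); recorded time zero
is the end of the dead time, and the dataset stores `dead_time_s` so the
deconvolution can evaluate concentration profiles at reaction time
`t + dead_time_s` — this keeps noiseless round trips exact while honouring
the fact that the earliest reaction is unobserved. Mixing is assumed 1:1
(the ratio is stored as metadata only), and Fe³⁺-NTA is treated as a fully
formed chelate.

`fixture_catalog()` lists the named fixtures; each encodes the published
concentrations, rate constants, amplitude fractions and observation windows
of one characterized experiment (biphasic FADH⁻ reduction of STEAP1, the
three-species b₅R chain, the slow NADPH-driven reductions, the Fe³⁺-NTA
oxidation titrations, the BLI dose-response). Where a study value is not
printed the fixture makes one documented choice: the donor-titration
substrate series uses 5 log-spaced points spanning 1–20 μM; the STEAP2
oxidation populations use equal fractions (only the STEAP1 85/15 split is
published); BLI traces use Rmax = 1 response unit, k_off = 0.05 s⁻¹ and
300 s phases, ordinary Octet settings. These defaults are the study
conditions for all recovery tests and are not tuned.

What the generators deliberately do **not** emulate: baseline drift, lamp
flicker and other photodiode-array artifacts, dithionite side reactions,
anaerobic-titration chemistry, or non-specific binding in BLI. Passing
recovery tests therefore demonstrate correctness of the inference chain
under ideal instrument statistics, not robustness to every real-data
pathology.

## Fitting

**Multi-exponential fits** use variable projection: for fixed rates the
offset and amplitudes are linear and solved exactly, so the nonlinear
search runs over log-rates only. Initialisation is multistart: a 12-point
log-spaced rate grid between $1/(10\,t_{max})$ and $10/t_{min}$ is scanned
combinatorially, the five best combinations seed Nelder–Mead. (Because
amplitudes are profiled out, no amplitude-split heuristics are needed.)
The baseline offset is always floated — whether published fits floated one
is unstated, and floating is the safer default. Phases are ordered by
descending $k_{obs}$, ties broken by larger amplitude; fractions
$100|a_i|/\sum_j|a_j|$ always sum to 100. Standard errors come from the
numerical Jacobian of the full residual at the optimum. Two fitted rates
agreeing within 1% trigger a warning to drop a phase.
`select_phase_count()` formalises the phase-count choice (made by eye in
practice) as the smallest count within 2 AIC units of the minimum.

**Secondary fits** are unweighted least squares throughout (no weighting
scheme is published): `fit_hyperbolic()` via Levenberg–Marquardt started
from a half-maximum interpolation, `fit_linear_kobs()` by ordinary least
squares with $K_D$ from the intercept/slope ratio (delta-method error),
`fit_bli()` by per-trace monophasic association fits (equilibrium response
profiled out) followed by a dose-response fit of $R_{eq}$ versus analyte.
Non-monotone $R_{eq}$ beyond the noise level raises a non-specific-binding
warning. For the STEAP2 oxidation series the analysis window defaults to
the first 2 s; later times show multiphasic behaviour without clear
substrate dependence and are left unanalysed.

## Global deconvolution

Rank estimation combines two criteria per SVD component: singular value
above 1e-3 of the largest, and lag-1 autocorrelation of the right singular
vector above 0.8 — genuine spectra are smooth in wavelength, noise vectors
are not, so the autocorrelation test rejects noise components whose
singular values are inflated by long records. Both thresholds are
arguments and are reported in the result.

The deconvolution itself is variable projection over the bilinear model
$\|A - C(t;k)\,S^\top\|_F^2$, with $C$ the Bateman fraction matrix and the
spectra solved linearly at each rate iterate. Nonnegativity of the spectra
is enforced by default (difference-spectrum workflows can disable it); the
constrained solves use an exact support-enumeration NNLS written for this
purpose — with at most a handful of species the $2^p$ candidate supports
can be enumerated and solved for all wavelengths at once, which is both
exact and fast inside the optimisation loop. The scale/permutation
ambiguity of bilinear models is fixed deterministically: concentration
profiles are fractions of the conserved total (summing to 1 at every time)
and species are ordered by their time of maximal population, which for a
sequential chain is the chain order. Only unidirectional sequential schemes
are fitted — parallel, branched or reversible schemes, and MCR-style
rotational-ambiguity analysis, are out of scope. The fit starts at the
first recorded point (no back-extrapolation into the dead time); fixtures
for fast phases therefore sample at least five points inside the first
30 ms, and recovery of a ~178 s⁻¹ phase from 20-s records is treated as
approximate (±20%) rather than exact, mirroring its large experimental
uncertainty.

Vendor deconvolution programs used with these instruments do not document
their objective function, so agreement is claimed with generator truth,
not with any specific program's output.

## Numerical choices and degenerate inputs

- Bateman/ODE switchover at 1e-6 relative rate coincidence; integrator
  rtol 1e-8, atol 1e-12.
- One-dimensional searches (`optimize`) run at tol 1e-12 so noiseless
  round trips recover truth to 1e-6 relative or better; Nelder–Mead uses
  reltol 1e-14.
- Static data forced into a two-species model yields near-identical
  spectra and an ill-conditioning warning rather than an error.
- Empty band lists give all-zero spectra; zero-amplitude phases give
  constant traces; `[S] = 0` in the linear law returns `k_off` exactly.
- CSV writers emit 17 significant digits, so write/read round trips are
  exact to 1e-12; every file carries a `# provenance:` JSON comment with
  generator parameters and seed.

## Problem sizes used in the test battery

The shipped tests and `reproduction_report()` use 400-point time grids,
20 seeds for the single-trace and BLI recovery averages and 10 seeds for
the deconvolution averages, and 1000 random rate sets for the Bateman/ODE
cross-check — sizes chosen so the full battery represents each experiment
faithfully while running in minutes on a laptop.

## Known limitations

- Absolute absorptivities (and hence absolute concentrations from fitted
  spectra) are placeholder-scaled; only rates and fractions are validated.
- The shuttle model's hydride-transfer and substrate-reduction steps are
  effective first-order rates scaled by donor/substrate depletion, not
  fully bimolecular mass action.
- No Marcus-theory distance dependence: mutations that perturb electron
  transfer (e.g. the leucine between flavin and heme) enter only as
  different rate-constant values.
- BLI fits assume 1:1 binding with a shared Rmax; the non-specific binding
  seen experimentally at high analyte concentrations is flagged, not
  modelled.
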