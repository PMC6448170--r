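---
title: "ctdosim: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ctdosim: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ctdosim` simulates the dosimetry of a wide-beam CT scanner end to end: a
characterized x-ray source, an acquisition trajectory, a voxelized patient
or phantom, a photon transport kernel, and dose reporting. This vignette
documents the model, its assumptions, the tunable parameters, the numerical
choices, and what the synthetic-data generators do and do not establish.

## 1. Source model

### Spectrum and equivalent filtration

The beam is a histogram of photon fluence per 1-keV bin
(photons/mm²/mAs), tied to a reference distance from the focal spot and
rescaled between distances by the inverse square law. Vendors rarely
publish tube spectra, so inherent filtration is recovered as an *equivalent
filter*: carbon and aluminum thicknesses \((t_C, t_{Al}) \ge 0\) fitted so
that the Beer–Lambert-filtered spectrum reproduces a measured air kerma and
half value layer (HVL). The fit is a bounded least squares on the two
relative residuals with multistart at \((0,0)\) and \((5,10)\) mm — the
surface is smooth and two targets determine two unknowns, so the fit
round-trips known thicknesses to better than 0.1% in the test suite.

When no measured spectrum is available the package ships an analytic
fallback: a Kramers-law photon-number shape \(\phi(E)\propto(E_{max}-E)/E\)
with optional tungsten K lines at 58/59/67/69 keV carrying a fixed 8% of
the bremsstrahlung fluence. Its total fluence is normalized to a stated
package constant (10⁶ photons/mm²/mAs at 100 cm for 120 kV). This
constant was chosen once as a plausible order of magnitude; it fixes the
*absolute* kerma scale of fallback-driven simulations and is deliberately
not tuned — every validated quantity in the package is a ratio, a relative
error, or a round-trip. With the equivalent filter (3.6 mm C + 9.3 mm Al)
the fallback beam's HVL comes out at 7.6 mm Al, which happens to sit in
the range typical of 120 kV CT beams; this is a consequence of the shape,
not a calibration.

### Attenuation data

Elemental mass attenuation (μ/ρ) and mass energy-absorption
(μ_en/ρ) coefficients for H, C, N, O, Mg, Al, P, Cl, Ar, Ca are packaged as
versioned CSV tables at 11 grid energies (5–150 keV), hand-curated from the
standard public compilations; interpolation is log-log, clamped at the grid
ends. Compounds (air, water, PMMA, carbon fiber, foam) are *mixed from the
elements at load time* by the weight-fraction rule, so compound and element
tables can never disagree. Accuracy in the diagnostic range is ~1% for the
well-characterized low-Z totals (the test suite pins water at 60 keV to the
published 0.2059 cm²/g within 1%) and a few % for the minor high-Z
elements, which carry weight fractions ≤ 0.25 in tissue.

The partial interaction channels are constructed self-consistently rather
than transcribed: incoherent scattering uses the free-electron
Klein–Nishina cross section times electron density, coherent scattering a
small calibrated \(Z^{2.2}/(A\,E^2)\) model, and photoelectric absorption
is the residual (clamped at zero), so the channel-closure invariant
`total = pe + incoh + coh` holds exactly. Consequence: channel *fractions*
inherit a few-% model error, which moves scatter-to-primary ratios slightly
but cancels in total attenuation, which is exact by construction.

### Bowtie and heel

The bowtie filter is characterized exactly as one measures it: normalized
in-air exposure ratios at 1-cm radial intervals from isocenter are inverted
per bin — a bracketed 1-D root find for the thickness whose kerma
transmission matches the ratio. Measurements exist on one side only; the
profile is mirrored about isocenter by default (`mirror = FALSE` for
asymmetric input). The bowtie material defaults to aluminum, a choice the
user can override; the fitted profile is then *by construction* the
aluminum-equivalent profile, which is all the sampling model needs. The
emission PDF across bowtie bins is proportional to the total photon count
exiting each bin.

The z-axis beam profile (heel effect) is supplied as (z, intensity) samples
— film digitization is out of scope — binned into 1-cm intervals; its FWHM
(linear interpolation of the half-maximum crossings) is taken as the
effective collimation. The fan-direction angle is called `fan_angle` and
the z-direction angle `cone_angle` throughout, avoiding the ambiguous
polar/azimuthal naming.

### Source strength

Total photon output Q sums, over bowtie bin i and profile bin j, the
normalized intensity \(H_j\), a geometry factor, and the per-bin fluence
summed over energies, scaled linearly by mAs. The geometry factor is
implemented exactly as the source formula prints it,
\(A_{ij} D_{ij}/SDD^2\) — dimensionally odd (it carries a length unit) but
kept verbatim for fidelity; a replaceable `geometry = "inverse_square"`
strategy (\(A_{ij}(SDD/D_{ij})^2\)) is provided. Because Q only scales
absolute doses, this choice does not affect any relative quantity.

## 2. Acquisition sampling

Frame: right-handed, origin at isocenter, +z along table travel, +y up,
gantry angle β from +y; the phantom is static and the tube translates.

* Axial: z fixed at the station; β uniform on the circumference (the real
  stepped rotation is unresolvable and well approximated by uniform
  sampling), or parked for service-mode geometries (`rotating = FALSE`).
* Helical: z uniform over the travel
  \(T_z = P \cdot Col \cdot Exp_{time}/Rot_{time}\) (direction flag resolves
  head-first/feet-first), and β advances deterministically by
  \(2\pi\,|z_p-z_i|/(P \cdot Col)\) — the helix-closure property
  \(\Delta\beta/\Delta z = 2\pi/(P\,Col)\) is exact.
* TCM: per-slice average currents form a histogram PDF along z (uniform
  within a slice, since only slice averages are available); β follows the
  same helix relation from the sampled z. Whether a real scanner keeps the
  deterministic helix phase under TCM is not documented; the deterministic
  choice is flagged in the code. In-plane (x–y) current modulation is out
  of scope.

Photon emission composes tube state, bowtie exit (fan angle), heel z (cone
angle) and a per-bowtie-bin energy draw (uniform within the chosen 1-keV
bin). Directions are exact unit vectors from the focal spot through the
sampled exit point in the isocenter plane.

## 3. Phantoms and calibration

The packaged HU→density calibration is piecewise linear with nodes at
(−1500, −1000 → air 0.001205 g/cm³), (−104 → 0.930), (0 → water 1.000),
(160 → 1.100) and (2000 → 2.120), nondecreasing above −1000 and clamped
outside. The published curve for any specific scanner is scanner-specific;
these nodes reproduce the standard four-group (air-fat / fat-water / soft /
skeletal) behaviour with exact air and water anchors, and the calibration
is fully overridable by CSV.

The HU→composition table maps inclusive integer HU ranges to weight
fractions over {H, O, C, N, Cl, Ca, P, Mg}. It is packaged verbatim from
its published form, in which each fraction is rounded to three decimals;
row sums consequently deviate from 1 by up to 0.012 (two soft-tissue rows
sum to 0.994 and 0.988). Load-time validation therefore accepts
[0.985, 1.005]; fractions are used as printed, without renormalization.
Non-integer HU are rounded half away from zero; out-of-range HU are
clamped with the end rows.

Fixture phantoms (`make_fixture`) — the CTDI body cylinder (Ø320 × 150 mm
with 13 mm center hole), the all-air chamber volume, a water cylinder, a
carbon-fiber/foam couch, and a layered lung/soft/bone block — are emitted
as HU grids so that the calibration path is exercised. Material HU values
are chosen by *inverting the density calibration* at the material's nominal
density (PMMA 1.19 → HU 322, carbon fiber 1.60, foam 0.03), which
guarantees the calibrated density is right; the composition row that HU
lands in is then tissue-like rather than exactly PMMA — an acknowledged
approximation that keeps the whole pipeline on one calibration path.

DICOM reading is not available in the supported dependency set, so
`voxelize_series()` consumes a documented plain-text slice series (JSON
metadata + per-slice CSV of raw pixel values) with the same semantics a
DICOM loader needs: slices sorted by position, rescale slope/intercept
applied, geometry consistency enforced. `write_series()` provides the
inverse for round-trip testing and for converting externally.

Couch merging keeps the patient HU wherever it exceeds an air threshold
(−900 HU default) and substitutes the vertically offset couch HU
elsewhere, using nearest-voxel lookup with half-up rounding (patient and
couch grids are routinely offset by half a voxel).

## 4. Transport kernel

Woodcock delta tracking with a global majorant per 1-keV energy grid point
(maximum over composition rows present in the phantom times each row's
maximum density). Flight lengths are exponential in the majorant; real
collisions are accepted with probability μ(x,E)/μ_max, making the scheme
exact regardless of voxel size. Distances are mm; mass coefficients are
converted to linear μ per mm at preparation time.

Physics approximations, all stated and testable:

* **Kerma approximation** — energy transferred to electrons is deposited at
  the interaction site. At ≤ 150 keV the CSDA range of secondaries is
  well below typical voxel sizes, so collision kerma ≈ absorbed dose.
  No electron transport, bremsstrahlung or fluorescence.
* **Compton** — free-electron Klein–Nishina (no binding or Doppler
  broadening), sampled by rejection against the forward maximum; the
  sampler's mean scattered-energy fraction matches numerical quadrature to
  Monte Carlo precision at 10⁶ draws.
* **Rayleigh** — Thomson angular shape without form factors; channel
  probability from the tabulated coherent coefficients; no energy deposit.
* **Cutoff** — photons below 1 keV (configurable) deposit locally.

Tallies: axis-aligned cylinders scoring either deposited energy or
track-length fluence in uniform energy bins (default 30 bins spanning
(cutoff, kV]); one optional voxel-mask deposit tally. Track-length scoring
clips every flight segment — including segments ending in virtual
collisions or escape — against the cylinder analytically, so the fluence
estimate is independent of the voxelization.

Energy accounting (emitted = deposited + escaped) is closed by
construction and asserted to 1×10⁻⁹ relative in the acceptance suite.

Uncertainties use batch statistics: histories are split into `n_batches`
(default 10) batches, batch b seeded as `master_seed + b`, so results are
reproducible, independent of execution order, and parallelizable by
contract; σ_MC is the standard deviation of batch means divided by √n.
The fluence→kerma conversion is applied per batch, so its σ propagates
exactly.

One estimator subtlety: the deposit tally measures sampled energy
*transfer* (photoelectric events deposit all of E, Compton events the KN
recoil), whereas the fluence→kerma conversion uses the tabulated
μ_en/ρ. The hand-curated μ_en and the residual-constructed channels agree
only to a few % in air, so the estimator-equivalence test compares the
deposit tally against the fluence tally folded with the *kernel-consistent*
transfer coefficient (photoelectric + KN-average recoil fraction from
quadrature). That is the mathematically matched pair; the remaining
μ_en-vs-transfer difference is a data-accuracy statement, not an estimator
bug, and is invisible in every relative quantity.

## 5. Dose reporting

CTDI correction (measured/simulated kerma at the CTDI phantom center) and
the table-attenuation factor (simulation with table / without) are post-hoc
multiplicative corrections, off by default and applied at most once each
(idempotence is enforced in the report metadata). Helical runs average
four start angles (0°, 90°, 180°, 270°) with σ propagated as
\(\sqrt{\sum\sigma_i^2}/4\); repeated measurements average as
\(\bar D\) with \(\sigma = \sqrt{\sum (D_i r_{cf})^2}/n\). Doses are Gy
internally, cGy in reports, two decimals for display only.

## 6. Synthetic data: what it emulates, what it does not

`synthetic_bowtie_measurement()` produces the radial exposure scan of a
parabolic aluminum bowtie (30 mm at 25 cm); `synthetic_beam_profile_scan()`
a flat-topped profile of the nominal collimation with 6 mm linear penumbra
and an 8% heel tilt; `make_fixture()` the standard test geometries. These
state a plausible wide-beam scanner at 120 kV. They do **not** contain:
real bowtie materials and shapes, focal-spot blur, off-focal radiation,
detector response, scanner-specific spectra, or anatomical heterogeneity.
A green test therefore establishes that the *pipeline* — fitting, sampling,
transport, tallying, statistics — is self-consistent and agrees with
analytic physics; it does not validate any specific scanner. Validating a
real scanner requires feeding measured spectra, bowtie scans and beam
profiles through the same interfaces.

## 7. Numerical choices and degenerate inputs

* Root finds (HVL, bowtie thickness) bracket from zero and double the
  upper bound until the sign flips; relative tolerance 10⁻⁶ (HVL).
* The two-parameter filter fit declares failure (with residuals) above a
  0.5% relative tolerance; a target HVL below the unfiltered HVL is
  rejected as infeasible before fitting.
* Zero-thickness layers, ratio-1 bowtie bins and all-equal TCM tables are
  exact identities, not special cases.
* An all-zero bowtie spectrum (fully opaque) raises a degenerate-PDF error.
* Profiles that never fall below half maximum raise an error in `fwhm()`.
* The Woodcock majorant interpolation takes the maximum of the two
  bracketing grid values, so it can never under-majorize between nodes.
* A zero-density (vacuum) phantom transports every photon straight out.

## 8. Known limitations

* Absolute dose requires a measured tube output; the fallback spectrum's
  normalization is a stated constant, and the as-printed source-strength
  geometry factor carries a stray length unit.
* No electron transport: wrong inside high-gradient interfaces at the
  sub-mm scale (the MOSFET-sized tally caveat).
* Rayleigh without form factors slightly over-forward-scatters at low
  energies; incoherent without binding slightly overestimates scatter
  below ~30 keV.
* Cylindrical tallies are axis-aligned.
* The TCM model reproduces longitudinal modulation only.
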