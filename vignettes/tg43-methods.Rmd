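---
title: "Methods: Monte Carlo TG-43 dosimetry of an HDR Ir-192 source"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Monte Carlo TG-43 dosimetry of an HDR Ir-192 source}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its physics and its numerical
choices: what is modelled, what is deliberately simplified, and what the
tests do and do not demonstrate.

## The source model and coordinate convention

The GammaMed Plus source is modelled as nested finite right cylinders: a
0.6 mm diameter × 3.5 mm long iridium core (22.42 g/cm³) inside an AISI 316L
capsule of 0.9 mm outer diameter, and a 6 cm AISI 304 cylinder for the drive
cable at the effective density 5.6 g/cm³ (a woven cable, not bulk steel).
The running text of the published source descriptions fixes only those
numbers; the distal tip thickness (0.062 cm), proximal steel (0.040 cm) and
cable radius (0.045 cm) are configuration defaults taken from the published
engineering drawing, and every dimension can be overridden through
`source_model()` so alternative published dimension sets can be swapped in.
The capsule tip is a flat disc rather than the slightly rounded real tip —
the simplest shape consistent with nested-cylinder ray tracing; this is a
small documented bias for polar angles near 0°.

Coordinates follow TG-43: origin at the centre of the active core, +z toward
the distal tip, polar angle θ from +z (the cable sits near θ = 180°),
reference point (r₀, θ₀) = (1 cm, 90°).  Points on a region boundary belong
to the inner region; ray segments are built from the exact quadric
intersections of all region surfaces, so segment lengths sum to the ray
length to 10⁻¹⁰ cm (a tested invariant, not an accumulation of nudged
steps).

## Emission spectra

Two photon line spectra ship as fixtures: the current NNDC/ENSDF evaluation
and the older Duchemin–Coursol evaluation, both restricted to photons above
10 keV.  The NNDC list is normalised to the published total yield of 2.363
photons per decay — the same constant the air-kerma-strength formula uses —
which leaves sampling probabilities untouched (they are intensities divided
by their sum).  Individual transcribed intensities carry ~1% uncertainty;
`inst/extdata/MANIFEST.md` documents the provenance.  Line energies are
sampled by inverse CDF with the convention that a uniform draw of 0 maps to
the lowest line.

## Interaction data

The per-material tables (photoelectric, incoherent, coherent, total, and
μ_en/ρ for water and dry air over 10 keV–1.5 MeV) are a physics-anchored
construction, generated by `data-raw/make_attenuation_tables.R`:

* incoherent scattering is the free-electron Klein–Nishina closed form —
  exactly the model the engine samples, which keeps the transport internally
  consistent;
* coherent scattering is a two-parameter saturating power law per atom
  calibrated at published water and lead values;
* photoelectric absorption is the residual of published total-attenuation
  anchors (water, dry air, Fe, Pb) after subtracting the two scattering
  terms, scaled in Z per atom to neighbouring elements (iridium from lead,
  with an approximate K-edge jump at 76.1 keV);
* μ_en/ρ for water and dry air are direct transcriptions of the standard
  tables — these dominate the dosimetric result.

Constructed water/air totals sit within ~0.5% of the published anchors over
0.03–1.5 MeV; the iridium and steel tables are good to an estimated 2–3%.
Mixtures for arbitrary compositions use the mass-fraction rule over the
elemental table (`build_material()`), and the shipped per-material fixtures
are consistent with that rule (tested).  Lookups interpolate log-log and are
exact at grid points; no extrapolation is permitted.  Pair production is not
modelled (sub-percent even in iridium at the 1.378 MeV top line).

## Transport physics and its declared simplifications

Histories are analog: emit from a uniformly sampled point in the core volume
(or a point source for verification), isotropic direction, line energy;
alternate free flights and interactions until escape or the 10 keV cutoff.
Free-flight distances follow the piecewise-exponential law across the
heterogeneous material segments.  Interactions select a process with
probability μ_process/μ_total; photoelectric absorbs (fluorescence is
neglected — the iridium K X-rays it would produce are largely reabsorbed in
the core); incoherent scattering samples the Klein–Nishina distribution by
rejection, with the scattered energy tied to the cosine by the Compton
relation.

Coherent (Rayleigh) scattering deserves its own paragraph.  At 0.3–0.6 MeV
the atomic form factor confines coherent deflections in iridium to a few
degrees, so a coherent event is dosimetrically almost a non-event.  Two
treatments are available through `run_config(coherent = ...)`:

* `"forward"` (default): coherent scattering is treated as transparent — it
  is excluded from the attenuation coefficient, equivalent to scattering
  exactly forward.  This is the better approximation for the uncollided flux
  through 1.75 mm of iridium along the source axis, where the alternative
  visibly depresses F(1 cm, 0°);
* `"thomson"`: the tabulated coherent cross section with Thomson-sampled
  angles.  This overstates large-angle coherent deflection in high-Z media
  and is retained as a sensitivity check (`"off"` is numerically identical
  to `"forward"`).

There is no electron transport: collision kerma (track-length fluence folded
with μ_en/ρ) stands in for dose under charged-particle equilibrium, which
holds beyond 2 mm from the capsule — exactly the region the published tables
restrict themselves to.  Energies below the 10 keV cutoff terminate the
history and are not tallied.

## Estimators

Both pipelines split the estimate into a deterministic uncollided part and
an analog collided part:

* **Uncollided (first-flight / next-event)**: for each field point, the
  average of exp(−Στᵢ)/(4πd²) over a fixed 8 × 8 × 16 midpoint lattice of
  emission points in the core, with exact ray-traced optical depths.  Zero
  variance, and the lattice is converged to ≪0.1% at r ≥ 0.2 cm.
* **Collided**: only photons that have scattered at least once are scored by
  track-length tallies — ring (annular) voxels on an (r, θ) grid in water,
  exploiting the azimuthal symmetry of the problem for an
  orders-of-magnitude variance reduction over Cartesian voxels, and the
  10 × 10 × 0.05 cm³ box at 1 m (5 keV energy bins) in air.  Ring-bin edges
  are midpoints between the sample radii/angles, so bin widths track the
  0.1–2 mm voxel schedule of the full-scale study; volumes use the exact
  shell integral.  Chords are computed from exact sphere/cone intersections.

This split is why 10⁶–10⁷ histories suffice: the uncollided term carries
most of the dose (≈85% at 1 cm) and all of its angular structure, while the
smooth collided term converges quickly.  For table rows within 12° of the
poles the collided component is volume-averaged over a ±3° window of
neighbouring bins (the uncollided part stays point-exact); the bias is small
because the scatter field varies slowly in θ, and the alternative — per-row
polar bins of vanishing volume — is exactly the statistical problem the
full-scale study reports at those angles.

Air-kerma strength applies the finite-voxel inverse-square correction only
to the box-averaged collided component; the uncollided estimate is already a
point value at the box centre.  `voxel_correction_factor()` computes the
factor as the ratio of the point inverse square to the volume average of
1/(4πr²) (midpoint quadrature, with a Monte Carlo cross-check); the default
region gives ≈1.0017 (+0.17%), consistent with an independent mean
inverse-square integration and slightly below the 0.22% quoted in earlier
literature, whose precise definition is not recoverable.  Both conventions
are within 0.1% of each other and of unity.

One bookkeeping subtlety: the printed air-kerma sum multiplies the fluence
by both φ(Eᵢ) and ΔE, which is dimensionally consistent only if φ is a
spectral density (cm⁻²·MeV⁻¹).  The implementation stores per-bin fluence
(the density times the 5 keV bin width) and computes
k = 1.602×10⁻¹⁰ Σ φᵢ Eᵢ (μ_en/ρ)ᵢ, equivalent to the density reading.

Randomness comes from a self-contained xoshiro256** generator; batch b uses
the b-th output of a splitmix64 stream started at the root seed, so a run is
bit-reproducible for a given seed on any platform (a tested contract).
Uncertainties are the standard error over batches (default ten, as in the
full-scale study).

## TG-43 extraction

`geometry_function_line()` implements G_L = β/(L·r·sinθ) with the closed
axial form, verified against an independent line-integral quadrature oracle
to 0.01% everywhere.  g_L and F are ratio estimators off the dose table;
g_L(r₀) = 1 and F(r, 90°) = 1 hold exactly by construction.  The
fifth-order g_L fit is unweighted least squares without constraining
g_L(1) = 1, because the published coefficients themselves evaluate to
0.99999 at 1 cm, implying no constraint was imposed.  Anisotropy cells are
marked unavailable ("/" in the published layout) when the field point lies
inside the capsule/cable structure or within 2 mm of the capsule surface;
proximity to the cable alone does not exclude a cell (the published table
keeps, e.g., (1 cm, 170°)).  The published table's exact exclusion pattern
depends on its voxel sizes and is not exactly reproducible; comparisons
simply exclude cells unavailable on either side.  Reconstruction
(`reconstruct_dose_rate()`) interpolates g_L linearly in r and F bilinearly
in (r, θ), returns S_K·Λ exactly at the reference point, and refuses to
extrapolate.

## Verification design

Every stage has a synthetic input with a closed-form answer, implemented
independently of the production path: vacuum runs with a bare point source
recover 1/(4πr²) fluence with zero interactions; the Klein–Nishina sampler
is checked against adaptive quadrature of the differential cross section
(whose total is itself checked against the closed form); synthetic dose
tables invert the 2D dose-rate equation for arbitrary g_L/F specifications
(optionally with seeded Gaussian noise for robustness checks), so extraction
must round-trip them to machine precision; the analog air tally and the
first-flight estimator are compared on the same run.

What passing these tests shows — and does not.  The synthetic generator
emulates noiseless (or Gaussian-noised) dose tables obeying the TG-43
factorisation exactly, monoenergetic point sources, and vacuum phantoms.
It does not emulate bound-electron Compton profiles, fluorescence,
electron transport, or the real (slightly rounded) capsule tip, so green
tests certify the estimators, the geometry, the extraction algebra and the
declared physics model — not those effects.

## Problem sizes

The test suite runs the full pipelines at 4 × 10⁶ water histories and 10⁶
air histories per spectrum (eight batches); the reproduction script uses
8 × 10⁶ and 2 × 10⁶ with ten batches; the analysis workflow defaults to
2 × 10⁶ / 10⁶.  These sizes give ≲0.1% statistical uncertainty on Λ, ~0.5%
on the air-scatter component of S_K, and a few percent on the deep polar
anisotropy cells — the same cells the full-scale study flags at ≤5%.

## Known limitations

* The radial dose function runs ~1% high at 10 cm, growing to ~10–15% at
  20 cm against the published fit: multiple-scatter buildup is overestimated
  by the free-electron Klein–Nishina model (no incoherent-function
  suppression) together with the approximate low-energy photoelectric chain.
  Near-field quantities (Λ, F, g_L within a few cm) are unaffected at the
  percent level.
* S_K/A reproduces the consensus value to better than 1%, but not the
  ~3% spectrum-driven elevation the original study attributes to its NNDC
  spectrum file: the public NNDC and Duchemin–Coursol gamma-line lists as
  transcribed differ by <0.3% in the air-kerma-weighted mean, so that
  elevation cannot be reproduced without knowing the exact content of the
  authors' spectrum file (for instance, whether X-ray lines were included).
* The iridium K-edge and the below-edge photoelectric continuation are
  approximate; they matter only for the 61–78 keV X-ray lines, which barely
  escape the core.
* Dry air only (the published composition); no humidity model.
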