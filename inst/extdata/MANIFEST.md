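# Fixture provenance

Transcription/construction date: 2026-09-29.

## spectra/

`ir192_nndc.csv` — Ir-192 photon line spectrum transcribed from the NNDC/ENSDF
decay-data evaluation (Baglin 2012 evaluation for A = 192; gamma lines plus Os
and Pt K and L X-rays above 10 keV).  The transcribed intensities sum to 2.350
photons per decay; a single global normalisation factor (1.00547) was applied
so the total photon yield equals the published 2.363 photons per decay that the
air-kerma-strength formalism uses.  Relative line intensities are untouched.

`ir192_duchemin_coursol.csv` — the older Duchemin & Coursol (1993) evaluation,
approximate transcription (total 2.347 photons per decay, left unnormalised).
The five weak lines between 0.70 and 1.38 MeV present in the NNDC evaluation
are absent here, as expected for this spectrum.

Both transcriptions carry an estimated ~1% uncertainty on individual line
intensities; this is a documented fixture limitation, not a statement about
the decay-data evaluations themselves.

## xs/

`elements.csv`, `attenuation_*.csv` — photon interaction coefficients
constructed by `data-raw/make_attenuation_tables.R`.  NOT a verbatim database
transcription: incoherent scattering is the free-electron Klein-Nishina closed
form (identical to the transport sampling model); coherent scattering is a
two-parameter saturating power law calibrated at published water and lead
values; photoelectric absorption is the residual of published Hubbell-Seltzer
total mass-attenuation anchors (water, dry air, Fe, Pb) after subtracting the
two scattering terms, scaled across Z per atom (Ir from Pb, Z^4.65; K-edge
jumps approximated for Mo and Ir).  `mu_en` columns for water and dry air are
direct transcriptions of the Hubbell-Seltzer mass energy-absorption tables.
Estimated accuracy: <0.5% for water/air totals over 0.03-1.5 MeV, ~2-3% for
the iridium and steel tables.  `mu_total` is exactly the sum of the three
process columns.

## reference/

`table2_anisotropy_nndc.csv` — verbatim transcription of the published 2D
anisotropy-function table for this source (NNDC spectrum); "/" marks cells
inside the source or within 2 mm of its surface.

`published_scalars.json` — published air-kerma strength per unit activity,
dose-rate constant, and fifth-order radial-dose-function fit coefficients for
both spectra, plus the consensus reference values.
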