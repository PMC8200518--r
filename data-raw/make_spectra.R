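# Build the Ir-192 photon emission spectrum fixtures under inst/extdata/spectra/.
#
# Neither line list is printed in any single reference available offline; both
# are transcriptions from the published decay-data evaluations (NNDC/ENSDF,
# Baglin 2012 evaluation for A = 192; Duchemin & Coursol 1993) as tabulated in
# the standard brachytherapy literature.  Only photons above 10 keV are kept
# (L X-ray lines below 10 keV are dropped; they cannot leave the capsule).
#
# The NNDC list is normalised by a single global factor so that the total
# photon yield above 10 keV equals 2.363 photons per decay, the published
# average used in air-kerma-strength bookkeeping.  Relative line intensities
# are untouched.  The Duchemin-Coursol list is left at its transcribed total.
#
# Run from the package root:  Rscript data-raw/make_spectra.R

nndc <- read.table(header = TRUE, text = "
energy_MeV intensity
0.0103553   0.55
0.0105109   0.20
0.0110707   1.30
0.0112507   0.42
0.0120953   0.10
0.0129423   0.30
0.0614860   1.20
0.0630000   2.05
0.0651220   2.66
0.0668310   4.55
0.0708210   0.40
0.0710790   0.78
0.0733630   0.29
0.0750430   0.89
0.0757490   1.71
0.0778500   0.62
0.1104000   0.0122
0.1363430   0.199
0.1769800   0.0043
0.2013110   0.473
0.2057940   3.34
0.2802700   0.009
0.2832670   0.266
0.2959570  28.71
0.3084550  29.70
0.3165060  82.86
0.3291700   0.0174
0.3744850   0.726
0.4164690   0.669
0.4205200   0.069
0.4680690  47.84
0.4845750   3.189
0.4890600   0.438
0.5885810   4.522
0.5934900   0.0421
0.6044110   8.216
0.6124620   5.34
0.7038500   0.0053
0.7658000   0.0013
0.8845370   0.2915
1.0614800   0.0531
1.0899000   0.0012
1.3782000   0.0012
")

dc <- read.table(header = TRUE, text = "
energy_MeV intensity
0.0104000   1.10
0.0110000   1.60
0.0124000   0.55
0.0614860   1.28
0.0630000   2.19
0.0651220   2.71
0.0668310   4.64
0.0710000   1.54
0.0757000   2.61
0.1363430   0.183
0.2013110   0.459
0.2057940   3.31
0.2832670   0.269
0.2959570  28.72
0.3084550  29.68
0.3165060  82.71
0.3744850   0.727
0.4164690   0.671
0.4680690  47.81
0.4845750   3.175
0.4890600   0.428
0.5885810   4.498
0.6044110   8.231
0.6124620   5.313
0.8845370   0.288
")

message(sprintf("NNDC raw total: %.4f photons/decay", sum(nndc$intensity) / 100))
norm <- 2.363 / (sum(nndc$intensity) / 100)
message(sprintf("NNDC normalisation factor: %.5f", norm))
nndc$photons_per_decay <- signif(nndc$intensity / 100 * norm, 6)
dc$photons_per_decay <- signif(dc$intensity / 100, 6)
message(sprintf("Duchemin-Coursol total: %.4f photons/decay", sum(dc$photons_per_decay)))

dir.create("inst/extdata/spectra", recursive = TRUE, showWarnings = FALSE)
wr <- function(df, path, header) {
  con <- file(path, "w")
  writeLines(header, con)
  write.table(df[, c("energy_MeV", "photons_per_decay")], con, sep = ",",
              row.names = FALSE, quote = FALSE)
  close(con)
}
wr(nndc, "inst/extdata/spectra/ir192_nndc.csv", c(
  "# Ir-192 photon emission spectrum, NNDC/ENSDF evaluation (transcribed;",
  "# normalised to a total yield of 2.363 photons per decay above 10 keV).",
  "# See inst/extdata/MANIFEST.md."))
wr(dc, "inst/extdata/spectra/ir192_duchemin_coursol.csv", c(
  "# Ir-192 photon emission spectrum, Duchemin & Coursol (1993) evaluation",
  "# (approximate transcription).  See inst/extdata/MANIFEST.md."))
message("spectrum fixtures written")
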