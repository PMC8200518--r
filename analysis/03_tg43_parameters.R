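#!/usr/bin/env Rscript
# TG-43 parameter extraction from the saved runs: dose-rate constant Lambda,
# radial dose function with its fifth-order fit, and the 2D anisotropy table
# in the published layout.  Requires 01_air_kerma.R and 02_water_dose.R.

library(irtg43mc)

for (label in c("NNDC", "DuchemCoursol")) {
  key <- tolower(label)
  dt <- read.csv(sprintf("results/dose_table_%s.csv", key))
  air <- jsonlite::read_json(sprintf("results/air_kerma_%s.json", key),
                             simplifyVector = TRUE)
  p <- extract_tg43(dt, air$sk_gycm2, air$Sk_per_A_U_per_Bq)
  cat(sprintf("%s: Lambda = %.4f cGy/h/U; g_L fit a0..a5 = %s\n",
              label, p$Lambda,
              paste(signif(p$fit$coefficients, 4), collapse = ", ")))
  write_gl_csv(p, sprintf("results/gl_%s.csv", key))
  write_fit_json(p, sprintf("results/gl_fit_%s.json", key))
  write_anisotropy_csv(p$F, sprintf("results/anisotropy_%s.csv", key))
  write_scalars_json(p, sprintf("results/scalars_%s.json", key),
                     extra = list(spectrum = label,
                                  histories = attr(dt, "histories")))
}
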