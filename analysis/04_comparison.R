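#!/usr/bin/env Rscript
# Comparison against the published values and the consensus dataset, and the
# deterministic markdown report.  Requires 03_tg43_parameters.R.

library(irtg43mc)

results <- list()
refs <- list(NNDC = reference_dataset("this-paper-NNDC"),
             DuchemCoursol = reference_dataset("this-paper-DC"))
for (label in c("NNDC", "DuchemCoursol")) {
  key <- tolower(label)
  sc <- jsonlite::read_json(sprintf("results/scalars_%s.json", key),
                            simplifyVector = TRUE)
  fit <- jsonlite::read_json(sprintf("results/gl_fit_%s.json", key),
                             simplifyVector = TRUE)
  f <- read_anisotropy_csv(sprintf("results/anisotropy_%s.csv", key))
  results[[label]] <- list(params = structure(list(
    Sk_per_A = sc$Sk_per_A_U_per_Bq, Lambda = sc$Lambda_cGy_per_h_per_U,
    Lambda_rel_unc = 0, F = f,
    fit = list(coefficients = unlist(fit[paste0("a", 0:5)]),
               residual_rms = fit$residual_rms)), class = "tg43_parameters"))
  ref <- refs[[label]]
  cat(sprintf("%s: S_K/A %+.2f%% vs published, Lambda %+.2f%%\n", label,
              relative_difference(sc$Sk_per_A_U_per_Bq, ref$Sk_per_A),
              relative_difference(sc$Lambda_cGy_per_h_per_U, ref$Lambda)))
  if (!is.null(ref$F)) {
    cmp <- compare_anisotropy(f, ref$F)
    cat(sprintf("  F table: max |diff| %.2f%% (15<theta<165), %.2f%% overall\n",
                cmp$max_abs_mid, cmp$max_abs_all))
    write.csv(cmp$cells, sprintf("results/anisotropy_diff_%s.csv", key),
              row.names = FALSE)
  }
}
render_report(results, refs, path = "results/report.md")
cat("wrote results/report.md\n")
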