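# Shared helpers: tiny spectra written to temp files, hand-built attenuation
# tables for degenerate cases, and cached default physics/model objects.

write_spectrum_file <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("energy_MeV,photons_per_decay", lines), path)
  path
}

one_line_spectrum <- function(energy = 0.3165, intensity = 1.0) {
  load_spectrum(write_spectrum_file(sprintf("%g,%g", energy, intensity)))
}

two_line_spectrum <- function() {
  load_spectrum(write_spectrum_file(c("0.2,0.5", "0.4,0.5")))
}

# attenuation table with a single interaction process
fake_process_table <- function(process = "photoelectric", value = 1.0) {
  E <- c(0.01, 0.1, 1.5)
  df <- data.frame(energy_MeV = E,
                   mu_photoelectric = rep(1e-8, 3),
                   mu_incoherent = rep(1e-8, 3),
                   mu_coherent = rep(1e-8, 3))
  df[[paste0("mu_", process)]] <- rep(value, 3)
  df$mu_total <- df$mu_photoelectric + df$mu_incoherent + df$mu_coherent
  structure(df, class = c("attenuation_table", "data.frame"),
            material = "fake", has_mu_en = FALSE)
}

default_physics <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- physics_set()
    cache
  }
})

# published fifth-order radial-dose-function fit coefficients (NNDC spectrum)
published_gl_coefficients <- function() {
  reference_dataset("this-paper-NNDC")$gl_fit_coefficients
}
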