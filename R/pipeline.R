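# End-to-end runs: air-kerma strength at 1 m in dry air, dose-rate table in
# the 80 cm water cube, and the TG-43 parameter set.
#
# Both runs use the same estimator split: the uncollided (first-flight)
# component is computed deterministically by quadrature over the core volume
# with exact ray-traced attenuation, and only collided photons are taken from
# the analog tallies.  This removes the dominant variance at desk-scale
# history counts; the estimated quantities are identical.

#' Air-kerma strength run
#'
#' Transports the spectrum through the source model into a dry-air sphere,
#' scores the collided fluence spectrum (5 keV bins) in the
#' 10 x 10 x 0.05 cm^3 region at 1 m on the transverse plane, adds the
#' deterministic uncollided component, and converts to air kerma per initial
#' photon and S_K/A.  The finite-voxel inverse-square correction is applied
#' to the box-averaged (collided) component only; the uncollided estimate is
#' a point value at the box centre.
#'
#' @param spectrum an `emission_spectrum` (or label passed to
#'   [load_spectrum()]).
#' @param histories,batches,seed analog-run controls.
#' @param model,physics source model and interaction data.
#' @param constants an [air_kerma_constants()] list.
#' @param phantom air phantom (default 150 cm radius sphere).
#' @return object of class `air_kerma_result`.
#' @export
air_kerma_run <- function(spectrum, histories = 1e6, batches = 10, seed = 1,
                          model = source_model(), physics = physics_set(),
                          constants = air_kerma_constants(),
                          phantom = phantom_spec("air"),
                          coherent = c("forward", "thomson", "off")) {
  coherent <- match.arg(coherent)
  if (is.character(spectrum)) spectrum <- load_spectrum(spectrum)
  cfg <- run_config(phantom, histories, batches, seed, spectrum = spectrum,
                    coherent = coherent, tally = "airbox")
  run <- run_histories(cfg, model, physics)
  box <- .air_box(constants$d_cm)
  vbox <- prod(box$box[2:4])
  hpb <- run$histories_per_batch
  # collided fluence per bin per batch (cm^-2 per initial photon)
  phi_sc_b <- run$fluence_scatter / (vbox * hpb)
  phi_tot_b <- run$fluence_total / (vbox * hpb)
  sc <- estimate_uncertainty(phi_sc_b)
  # deterministic uncollided line fluence at the box centre
  fl_un <- next_event_fluence(matrix(c(constants$d_cm, 0, 0), 1), spectrum,
                              model, physics, phantom, coherent = coherent)
  lineE <- attr(fl_un, "line_energies")
  lineP <- attr(fl_un, "line_probs")
  phi_un_line <- drop(fl_un) * lineP
  mid <- box$ebin_min + (seq_len(box$ebin_n) - 0.5) * box$ebin_width
  ebin <- findInterval(lineE, box$ebin_min + (0:box$ebin_n) * box$ebin_width,
                       rightmost.closed = TRUE)
  phi_un <- numeric(box$ebin_n)
  for (i in seq_along(lineE)) phi_un[ebin[i]] <- phi_un[ebin[i]] + phi_un_line[i]
  fl <- data.frame(energy_MeV = mid, phi = phi_un + constants$correction * sc$mean,
                   phi_uncollided = phi_un, phi_scatter = sc$mean,
                   phi_se = sc$se)
  air_tab <- physics$tables$air
  k <- air_kerma_per_photon(data.frame(energy_MeV = mid, phi = fl$phi),
                            air_tab, constants)
  k_un <- air_kerma_per_photon(data.frame(energy_MeV = mid, phi = phi_un),
                               air_tab, constants)
  # per-batch k for the uncertainty on the collided part
  k_b <- vapply(seq_len(batches), function(b) {
    air_kerma_per_photon(data.frame(energy_MeV = mid,
                                    phi = constants$correction * phi_sc_b[, b]),
                         air_tab, constants)
  }, numeric(1))
  k_sc <- estimate_uncertainty(matrix(k_b, 1))
  sk_gycm2 <- k * constants$d_cm^2
  structure(list(
    fluence = fl, k_per_photon = k, k_uncollided = k_un,
    k_scatter = k - k_un, k_se = k_sc$se,
    sk_gycm2 = sk_gycm2,
    Sk_per_A = sk_per_activity(k, constants, apply_correction = FALSE),
    rel_unc = k_sc$se / k,
    analog_total_batches = phi_tot_b, analog_scatter_batches = phi_sc_b,
    counters = run$counters, constants = constants,
    spectrum_label = attr(spectrum, "label"), histories = histories,
    seed = seed), class = "air_kerma_result")
}

# volume-weighted aggregation window for the collided dose near the poles
.scatter_windows <- function(theta_samples, halfwidth = 3, polar = 12) {
  lapply(seq_along(theta_samples), function(j) {
    th <- theta_samples[j]
    if (th >= polar && th <= 180 - polar) return(j)
    which(abs(theta_samples - th) <= halfwidth &
            (theta_samples < polar) == (th < polar))
  })
}

#' Water-phantom dose-rate table
#'
#' Dose rate to water per initial photon on the (r, theta) sample grid:
#' deterministic uncollided dose (track-length fluence folded with the water
#' mass energy-absorption coefficient, collision kerma = dose under CPE) plus
#' the collided component from the analog ring tallies.  Near the poles
#' (theta < 12 deg or > 168 deg) the collided component is volume-averaged
#' over a +/- 3 degree window of neighbouring bins.
#'
#' @inheritParams air_kerma_run
#' @param layout from [water_tally_grid()].
#' @return a `dose_rate_table` data frame with columns `r_cm`, `theta_deg`,
#'   `dose` (Gy per initial photon), `rel_unc`, `dose_uncollided`,
#'   `dose_scatter`.
#' @export
water_dose_run <- function(spectrum, histories = 1e6, batches = 10, seed = 1,
                           model = source_model(), physics = physics_set(),
                           layout = water_tally_grid(),
                           phantom = phantom_spec("water"),
                           coherent = c("forward", "thomson", "off")) {
  coherent <- match.arg(coherent)
  if (is.character(spectrum)) spectrum <- load_spectrum(spectrum)
  cfg <- run_config(phantom, histories, batches, seed, spectrum = spectrum,
                    grid = layout$grid, coherent = coherent, tally = "ring")
  run <- run_histories(cfg, model, physics)
  hpb <- run$histories_per_batch
  vol <- as.vector(ring_volumes(layout$grid))   # bin (ir, it) column-major
  nr <- layout$grid$nr
  # uncollided dose at the sample points
  rs <- layout$r_samples; ths <- layout$theta_samples
  pts <- expand.grid(r = rs, theta = ths)
  det <- cbind(pts$r * sin(pts$theta * pi / 180), 0,
               pts$r * cos(pts$theta * pi / 180))
  fl_un <- next_event_fluence(det, spectrum, model, physics, phantom,
                              coherent = coherent)
  lineE <- attr(fl_un, "line_energies")
  lineP <- attr(fl_un, "line_probs")
  muen_w <- interpolate_mu_en(physics$tables$water, lineE)
  d_un <- GY_PER_MEV_G * drop(fl_un %*% (lineP * lineE * muen_w))
  # collided dose, with polar aggregation windows
  wins <- .scatter_windows(ths)
  d_sc <- se_sc <- numeric(nrow(pts))
  for (j in seq_along(ths)) {
    for (i in seq_len(nr)) {
      bb <- (wins[[j]] - 1L) * nr + i
      raw_b <- colSums(run$dose_scatter[bb, , drop = FALSE])
      vb <- sum(vol[bb])
      u <- estimate_uncertainty(matrix(raw_b / (vb * hpb), 1))
      k <- (j - 1L) * nr + i
      d_sc[k] <- GY_PER_MEV_G * u$mean
      se_sc[k] <- GY_PER_MEV_G * u$se
    }
  }
  dose <- d_un + d_sc
  out <- data.frame(r_cm = pts$r, theta_deg = pts$theta, dose = dose,
                    rel_unc = ifelse(dose > 0, se_sc / dose, 0),
                    dose_uncollided = d_un, dose_scatter = d_sc)
  structure(out, class = c("dose_rate_table", "data.frame"),
            histories = histories, seed = seed,
            spectrum_label = attr(spectrum, "label"),
            counters = run$counters, L = model$core_length)
}

#' Extract the TG-43 parameter set
#'
#' @param dose_table a `dose_rate_table` (Gy per initial photon).
#' @param sk_gycm2 air-kerma strength per initial photon (Gy cm^2), from
#'   [air_kerma_run()].
#' @param Sk_per_A S_K/A in U/Bq (reporting only).
#' @param L active length, cm.
#' @param model source model for the anisotropy availability rule.
#' @return object of class `tg43_parameters`: `Sk_per_A`, `Lambda`, `gL`,
#'   `fit` (a0..a5 + residual rms), `F`, `L`, uncertainties.
#' @export
extract_tg43 <- function(dose_table, sk_gycm2, Sk_per_A = NA, L = 0.35,
                         model = source_model()) {
  ref <- tg43_reference()
  d0 <- .dose_lookup(dose_table, ref$r0_cm, ref$theta0_deg)
  if (is.na(d0)) stop("dose table lacks the (1 cm, 90 deg) reference sample",
                      call. = FALSE)
  lambda <- dose_rate_constant(d0, sk_gycm2)
  gl <- radial_dose_function(dose_table, L)
  fit <- fit_radial_polynomial(gl)
  Ft <- anisotropy_function(dose_table, L, model)
  i0 <- which(abs(dose_table$r_cm - ref$r0_cm) < 1e-9 &
              abs(dose_table$theta_deg - ref$theta0_deg) < 1e-9)
  lam_unc <- if (!is.null(dose_table$rel_unc)) dose_table$rel_unc[i0] else 0
  structure(list(Sk_per_A = Sk_per_A, Lambda = lambda,
                 Lambda_rel_unc = lam_unc, gL = gl, fit = fit, F = Ft, L = L),
            class = "tg43_parameters")
}

#' Full TG-43 pipeline for one spectrum
#'
#' Runs the air-kerma and water-dose simulations and extracts the parameter
#' set.  The air and water runs use child seeds `seed` and `seed + 1`.
#'
#' @param spectrum spectrum label or `emission_spectrum`.
#' @param histories_water,histories_air analog history counts.
#' @param batches,seed run controls.
#' @inheritParams air_kerma_run
#' @return list with `air` (an `air_kerma_result`), `dose_table`, and
#'   `params` (a `tg43_parameters`).
#' @export
tg43_pipeline <- function(spectrum, histories_water = 2e6,
                          histories_air = 5e5, batches = 10, seed = 1,
                          model = source_model(), physics = physics_set(),
                          constants = air_kerma_constants()) {
  if (is.character(spectrum)) spectrum <- load_spectrum(spectrum)
  air <- air_kerma_run(spectrum, histories_air, batches, seed, model, physics,
                       constants)
  dt <- water_dose_run(spectrum, histories_water, batches, seed + 1, model,
                       physics)
  params <- extract_tg43(dt, air$sk_gycm2, air$Sk_per_A, model$core_length,
                         model)
  list(air = air, dose_table = dt, params = params)
}

#' Write the g_L samples, fit coefficients, and scalar results
#'
#' @param params a `tg43_parameters`.
#' @param path output file.
#' @export
write_gl_csv <- function(params, path) {
  df <- params$gL
  df$gL <- signif(df$gL, 6); df$rel_unc <- signif(df$rel_unc, 3)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gl_csv
#' @export
write_fit_json <- function(params, path) {
  a <- as.list(params$fit$coefficients)
  names(a) <- paste0("a", 0:5)
  jsonlite::write_json(c(a, list(residual_rms = params$fit$residual_rms)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gl_csv
#' @param extra named list merged into the scalar report.
#' @export
write_scalars_json <- function(params, path, extra = list()) {
  jsonlite::write_json(c(list(Sk_per_A_U_per_Bq = params$Sk_per_A,
                              Lambda_cGy_per_h_per_U = params$Lambda), extra),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
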