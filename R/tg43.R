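# TG-43 parameter extraction: geometry function, air-kerma strength,
# dose-rate constant, radial dose function + fifth-order fit, 2D anisotropy
# function, and the dose-rate reconstruction.

GY_PER_MEV_G <- 1.602e-10   # Gy per (MeV/g)
SK_HOURS_FACTOR <- 3.6e9    # (cGy/Gy) x (s/h) x (cm/m)^2 bookkeeping factor
PHOTONS_PER_DECAY <- 2.363  # published average photon yield per Ir-192 decay

#' Air-kerma bookkeeping constants
#'
#' Energy cutoff delta, scoring distance d, the Gy/(MeV/g) conversion, the
#' hours/activity factor of the S_K formula, the average photon yield per
#' decay, and the inverse-square correction factor for the finite scoring
#' region (computed by [voxel_correction_factor()] unless supplied).
#'
#' @param delta_MeV energy cutoff (default 0.010).
#' @param d_cm scoring distance (default 100).
#' @param correction inverse-square voxel correction factor; computed for the
#'   default 10 x 10 x 0.05 cm^3 region if `NULL`.
#' @export
air_kerma_constants <- function(delta_MeV = 0.010, d_cm = 100,
                                correction = NULL) {
  if (is.null(correction)) correction <- voxel_correction_factor(d = d_cm)
  stopifnot(correction > 0.995, correction < 1.005)
  list(delta_MeV = delta_MeV, d_cm = d_cm, gy_per_mev_g = GY_PER_MEV_G,
       hours_factor = SK_HOURS_FACTOR, photons_per_decay = PHOTONS_PER_DECAY,
       correction = correction)
}

#' Line-source geometry function G_L(r, theta)
#'
#' `G_L = beta / (L r sin(theta))` with `beta` the angle subtended by the
#' active length at the field point, and `G_L = (r^2 - L^2/4)^-1` on the
#' axis.  Reduces to `1/r^2` as `L -> 0`.
#'
#' @param r distance from the source centre, cm.
#' @param theta_deg polar angle from the source axis, degrees.
#' @param L active length, cm (default 0.35).
#' @return G_L in cm^-2.
#' @export
geometry_function_line <- function(r, theta_deg, L = 0.35) {
  stopifnot(L > 0)
  n <- max(length(r), length(theta_deg))
  r <- rep_len(r, n); theta_deg <- rep_len(theta_deg, n)
  th <- theta_deg * pi / 180
  x <- r * sin(th); z <- r * cos(th)
  on_axis <- abs(x) < 1e-12
  if (any(on_axis & abs(z) <= L / 2 + 1e-12) || any(r <= 0)) {
    stop("field point on the active line segment", call. = FALSE)
  }
  out <- numeric(n)
  # beta via the angles to the two segment ends
  b1 <- atan2(x, z - L / 2)
  b2 <- atan2(x, z + L / 2)
  beta <- abs(b1 - b2)
  out[!on_axis] <- (beta / (L * x))[!on_axis]
  out[on_axis] <- 1 / (r[on_axis]^2 - L^2 / 4)
  out
}

#' Air kerma per initial photon from a binned fluence spectrum
#'
#' `k = 1.602e-10 * sum_i phi_i E_i (mu_en/rho)(E_i)` in Gy per initial
#' photon, with `phi_i` the per-bin fluence (cm^-2; the per-MeV density times
#' the 5 keV bin width) and `E_i` the bin midpoint.  Bins at or below the
#' cutoff `delta` are excluded.
#'
#' @param fluence data frame with `energy_MeV` (bin midpoints) and `phi`
#'   (fluence per initial photon, cm^-2).
#' @param air_table the dry-air `attenuation_table` (for mu_en/rho).
#' @param constants an [air_kerma_constants()] list.
#' @return Gy per initial photon.
#' @export
air_kerma_per_photon <- function(fluence, air_table = load_attenuation("air"),
                                 constants = air_kerma_constants()) {
  keep <- fluence$phi > 0 & fluence$energy_MeV > constants$delta_MeV
  if (!any(keep)) return(0)
  f <- fluence[keep, ]
  rng <- range(air_table$energy_MeV)
  if (any(f$energy_MeV < rng[1] | f$energy_MeV > rng[2])) {
    stop("fluence bins outside the mu_en/rho table span", call. = FALSE)
  }
  muen <- interpolate_mu_en(air_table, f$energy_MeV)
  constants$gy_per_mev_g * sum(f$phi * f$energy_MeV * muen)
}

#' Air-kerma strength per unit activity
#'
#' `S_K / A = 3.6e9 * (k d^2) * correction * 2.363` U/Bq with `k` the air
#' kerma per initial photon (Gy), `d` in metres inside the bookkeeping factor
#' (`d_cm/100`), and the finite-voxel inverse-square correction.
#'
#' @param k_per_photon air kerma per initial photon at distance `d`, Gy.
#' @param constants an [air_kerma_constants()] list.
#' @param apply_correction apply the voxel correction (TRUE for box-averaged
#'   fluence, the study's convention).
#' @return S_K/A in U/Bq (U = cGy cm^2 / h).
#' @export
sk_per_activity <- function(k_per_photon, constants = air_kerma_constants(),
                            apply_correction = TRUE) {
  stopifnot(k_per_photon >= 0)
  corr <- if (apply_correction) constants$correction else 1
  constants$hours_factor * k_per_photon * (constants$d_cm / 100)^2 * corr *
    constants$photons_per_decay
}

#' Inverse-square voxel correction factor
#'
#' Ratio of the point inverse-square value at distance `d` to the volume
#' average of `1/(4 pi r^2)` over the finite scoring region (the track-length
#' fluence of an isotropic point source averages to exactly that integral).
#' Computed by midpoint quadrature or by Monte Carlo integration.
#'
#' @param region `c(dx, dy, dz)` box dimensions in cm, the x axis pointing
#'   away from the source (default `c(0.05, 10, 10)`).
#' @param d box-centre distance, cm.
#' @param n nodes per axis (quadrature) or total points (MC).
#' @param method `"quadrature"` or `"mc"`.
#' @param seed RNG seed for the MC method.
#' @export
voxel_correction_factor <- function(region = c(0.05, 10, 10), d = 100,
                                    n = 101, method = c("quadrature", "mc"),
                                    seed = 1) {
  method <- match.arg(method)
  if (all(region == 0)) return(1)
  if (method == "quadrature") {
    gx <- d + region[1] * ((seq_len(n) - 0.5) / n - 0.5)
    gy <- region[2] * ((seq_len(n) - 0.5) / n - 0.5)
    gz <- region[3] * ((seq_len(n) - 0.5) / n - 0.5)
    inv <- outer(gx^2, outer(gy^2, gz^2, `+`), `+`)
    mean_inv_r2 <- mean(1 / inv)
  } else {
    set.seed(seed)
    x <- d + runif(n, -region[1] / 2, region[1] / 2)
    y <- runif(n, -region[2] / 2, region[2] / 2)
    z <- runif(n, -region[3] / 2, region[3] / 2)
    mean_inv_r2 <- mean(1 / (x^2 + y^2 + z^2))
  }
  (1 / d^2) / mean_inv_r2
}

#' Dose-rate constant
#'
#' `Lambda = D(r0, theta0) / S_K` with both per initial photon; the activity
#' normalisation cancels.  With the dose in Gy per photon and
#' `sk = k d^2 * correction` in Gy cm^2 per photon, the ratio is numerically
#' Lambda in cGy h^-1 U^-1.
#'
#' @param dose_r0 dose rate to water at (1 cm, 90 deg) per initial photon, Gy.
#' @param sk_gycm2 air-kerma strength per initial photon, Gy cm^2.
#' @export
dose_rate_constant <- function(dose_r0, sk_gycm2) {
  if (sk_gycm2 <= 0) stop("S_K must be positive", call. = FALSE)
  dose_r0 / sk_gycm2
}

.dose_lookup <- function(dose_table, r, theta_deg) {
  i <- which(abs(dose_table$r_cm - r) < 1e-9 &
             abs(dose_table$theta_deg - theta_deg) < 1e-9)
  if (length(i) != 1) return(NA_real_)
  dose_table$dose[i]
}

#' Radial dose function g_L(r)
#'
#' `g_L(r) = [D(r, theta0) G_L(r0, theta0)] / [D(r0, theta0) G_L(r, theta0)]`,
#' exactly 1 at r0 by construction.
#'
#' @param dose_table data frame with `r_cm`, `theta_deg`, `dose` (+ optional
#'   `rel_unc`).
#' @param L active length, cm.
#' @return data frame `r_cm`, `gL`, `rel_unc`.
#' @export
radial_dose_function <- function(dose_table, L = 0.35) {
  ref <- tg43_reference()
  rows <- dose_table[abs(dose_table$theta_deg - ref$theta0_deg) < 1e-9, ]
  rows <- rows[order(rows$r_cm), ]
  i0 <- which(abs(rows$r_cm - ref$r0_cm) < 1e-9)
  if (length(i0) != 1) stop("dose table lacks the r0 = 1 cm sample",
                            call. = FALSE)
  G <- geometry_function_line(rows$r_cm, ref$theta0_deg, L)
  G0 <- geometry_function_line(ref$r0_cm, ref$theta0_deg, L)
  gL <- (rows$dose / rows$dose[i0]) * (G0 / G)
  ru <- if (!is.null(rows$rel_unc)) {
    sqrt(rows$rel_unc^2 + rows$rel_unc[i0]^2)
  } else rep(0, nrow(rows))
  ru[i0] <- 0
  data.frame(r_cm = rows$r_cm, gL = gL, rel_unc = ru)
}

#' Fifth-order polynomial fit of g_L(r)
#'
#' Unweighted least squares of `g = a0 + a1 r + ... + a5 r^5` (no constraint
#' at r0).
#'
#' @param gl data frame from [radial_dose_function()] (or columns `r_cm`, `gL`).
#' @return list with `coefficients` (a0..a5), `residual_rms`, `fitted`.
#' @export
fit_radial_polynomial <- function(gl) {
  if (nrow(gl) < 6) stop("need at least 6 samples for a fifth-order fit",
                         call. = FALSE)
  X <- outer(gl$r_cm, 0:5, `^`)
  if (qr(X)$rank < 6) stop("rank-deficient design (degenerate r grid)",
                           call. = FALSE)
  fit <- lm.fit(X, gl$gL)
  a <- unname(fit$coefficients)
  list(coefficients = a,
       residual_rms = sqrt(mean(fit$residuals^2)),
       fitted = drop(X %*% a))
}

#' Evaluate a fifth-order radial-dose-function polynomial
#' @param a coefficients a0..a5; `r` radii in cm.
#' @export
eval_radial_polynomial <- function(a, r) {
  drop(outer(r, 0:5, `^`) %*% a)
}

# availability rule for the anisotropy table: a cell is unavailable when the
# field point lies inside the source structure (capsule or cable region) or
# within 2 mm of the sealed capsule's surface.  Proximity to the cable alone
# does not exclude a cell (the published table keeps e.g. theta = 170 deg at
# r = 1 cm).
.unavailable_cells <- function(r, theta_deg, model = source_model()) {
  th <- theta_deg * pi / 180
  x <- r * sin(th); z <- r * cos(th)
  zc_lo <- -model$core_length / 2 - model$proximal_thickness
  zc_hi <- model$core_length / 2 + model$tip_thickness
  in_capsule <- x <= model$capsule_radius & z >= zc_lo & z <= zc_hi
  in_cable <- x <= model$cable_radius & z < zc_lo &
    z >= zc_lo - model$cable_length
  dx <- pmax(x - model$capsule_radius, 0)
  dz <- pmax(zc_lo - z, z - zc_hi, 0)
  in_capsule | in_cable | (sqrt(dx^2 + dz^2) <= 0.2)
}

#' 2D anisotropy function F(r, theta)
#'
#' `F(r, theta) = [D(r, theta) / D(r, theta0)] x [G_L(r, theta0) / G_L(r, theta)]`,
#' exactly 1 on the transverse plane.  Cells inside the source structure or
#' within 2 mm of its surface are set to `NA` (the published table's "/"
#' convention).
#'
#' @inheritParams radial_dose_function
#' @param model the `source_model` used for the 2 mm proximity rule.
#' @return data frame with `r_cm`, `theta_deg`, `F`, `rel_unc`.
#' @export
anisotropy_function <- function(dose_table, L = 0.35, model = source_model()) {
  ref <- tg43_reference()
  radii <- sort(unique(dose_table$r_cm))
  out <- do.call(rbind, lapply(radii, function(r) {
    rows <- dose_table[abs(dose_table$r_cm - r) < 1e-9, ]
    i0 <- which(abs(rows$theta_deg - ref$theta0_deg) < 1e-9)
    if (length(i0) != 1) stop("dose table lacks the theta0 = 90 deg column",
                              call. = FALSE)
    G <- geometry_function_line(r, rows$theta_deg, L)
    G0 <- geometry_function_line(r, ref$theta0_deg, L)
    f <- (rows$dose / rows$dose[i0]) * (G0 / G)
    ru <- if (!is.null(rows$rel_unc)) {
      sqrt(rows$rel_unc^2 + rows$rel_unc[i0]^2)
    } else rep(0, nrow(rows))
    ru[i0] <- 0
    f[i0] <- 1
    data.frame(r_cm = r, theta_deg = rows$theta_deg, F = f, rel_unc = ru)
  }))
  near <- .unavailable_cells(out$r_cm, out$theta_deg, model)
  out$F[near] <- NA_real_
  out$rel_unc[near] <- NA_real_
  rownames(out) <- NULL
  out
}

.interp1 <- function(x, y, xout) {
  if (xout < min(x) || xout > max(x)) {
    stop("extrapolation beyond the parameter table", call. = FALSE)
  }
  approx(x, y, xout)$y
}

#' Reconstruct the dose rate from TG-43 parameters
#'
#' `D(r, theta) = S_K Lambda [G_L(r, theta) / G_L(r0, theta0)] g_L(r) F(r, theta)`
#' with g_L linear in r and F bilinear in (r, theta).  At (r0, theta0) the
#' result is exactly `S_K * Lambda`.
#'
#' @param params list with `gL` (data frame `r_cm`, `gL`), `F` (data frame
#'   `r_cm`, `theta_deg`, `F`) and `L`.
#' @param sk,lambda air-kerma strength (U) and dose-rate constant
#'   (cGy h^-1 U^-1).
#' @param r,theta_deg field point.
#' @return dose rate in cGy/h.
#' @export
reconstruct_dose_rate <- function(params, sk, lambda, r, theta_deg) {
  ref <- tg43_reference()
  gl <- .interp1(params$gL$r_cm, params$gL$gL, r)
  Ft <- params$F
  radii <- sort(unique(Ft$r_cm))
  if (r < min(radii) || r > max(radii)) {
    stop("extrapolation beyond the parameter table", call. = FALSE)
  }
  i <- findInterval(r, radii, rightmost.closed = TRUE)
  i2 <- min(i + 1L, length(radii))
  fcol <- function(rr) {
    sub <- Ft[abs(Ft$r_cm - rr) < 1e-9 & !is.na(Ft$F), ]
    .interp1(sub$theta_deg, sub$F, theta_deg)
  }
  f1 <- fcol(radii[i])
  w <- if (i2 == i) 0 else (r - radii[i]) / (radii[i2] - radii[i])
  fv <- if (w == 0) f1 else (1 - w) * f1 + w * fcol(radii[i2])
  G <- geometry_function_line(r, theta_deg, params$L)
  G0 <- geometry_function_line(ref$r0_cm, ref$theta0_deg, params$L)
  sk * lambda * (G / G0) * gl * fv
}
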