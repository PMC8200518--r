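test_that("the line-source geometry function matches its closed forms and oracle", {
  expect_equal(geometry_function_line(1, 90, 0.35), 0.9900, tolerance = 1e-4)
  expect_equal(geometry_function_line(1, 0, 0.35), 1 / (1 - 0.030625),
               tolerance = 1e-12)
  # against the independent line-integral oracle, <= 0.01% everywhere tested
  for (r in c(0.5, 1, 2, 5, 10, 20)) {
    for (th in c(0, 1, 5, 15, 30, 60, 90, 120, 150, 175, 180)) {
      if (th %in% c(0, 180) && r <= 0.175) next
      expect_equal(geometry_function_line(r, th, 0.35),
                   gl_line_integral_oracle(r, th, 0.35),
                   tolerance = 1e-4)
    }
  }
  # point-source limit
  expect_equal(geometry_function_line(2, 47, 1e-6), 1 / 4, tolerance = 1e-9)
  # field point on the active segment
  expect_error(geometry_function_line(0.1, 0, 0.35), "on the active line")
})

test_that("air kerma per photon is the mu_en-weighted bin sum", {
  ph <- default_physics()
  const <- air_kerma_constants(correction = 1.001665)
  expect_equal(air_kerma_per_photon(data.frame(energy_MeV = 0.3, phi = 0),
                                    constants = const), 0)
  muen <- interpolate_mu_en(ph$tables$air, 0.3)
  k1 <- air_kerma_per_photon(data.frame(energy_MeV = 0.3, phi = 1),
                             constants = const)
  expect_equal(k1, 1.602e-10 * 0.3 * muen, tolerance = 1e-12)
  # linearity
  fl <- data.frame(energy_MeV = c(0.1, 0.3, 0.6), phi = c(1, 2, 3))
  expect_equal(air_kerma_per_photon(transform(fl, phi = 2 * phi),
                                    constants = const),
               2 * air_kerma_per_photon(fl, constants = const))
  # bins below delta are excluded
  fl2 <- data.frame(energy_MeV = c(0.005, 0.3), phi = c(10, 1))
  expect_equal(air_kerma_per_photon(fl2, constants = const), k1)
})

test_that("S_K/A bookkeeping inverts the published value", {
  const <- air_kerma_constants(correction = 1.001665)
  expect_equal(sk_per_activity(0, const), 0)
  # k * d^2 = 1.1917e-17 Gy m^2 per photon reproduces the published S_K/A
  expect_equal(sk_per_activity(1.1917e-17, const, apply_correction = FALSE),
               1.0139e-7, tolerance = 3e-4)
})

test_that("the voxel correction factor matches its dual oracle", {
  expect_equal(voxel_correction_factor(region = c(0, 0, 0)), 1)
  q <- voxel_correction_factor(n = 101)
  m <- voxel_correction_factor(n = 4e5, method = "mc", seed = 8)
  expect_equal(q, m, tolerance = 1e-4)
  expect_gt(q, 1.0015)
  expect_lt(q, 1.0025)
})

test_that("dose-rate constant is a pure per-photon ratio", {
  expect_equal(dose_rate_constant(2.2e-13, 2e-13), 1.1)
  expect_equal(dose_rate_constant(3 * 2.2e-13, 3 * 2e-13), 1.1)
  expect_error(dose_rate_constant(1, 0), "positive")
})

test_that("radial dose function extraction is exact on synthetic tables", {
  # table proportional to G_L -> g_L identically 1
  tab <- make_synthetic_dose_table()
  gl <- radial_dose_function(tab)
  expect_equal(gl$gL, rep(1, nrow(gl)), tolerance = 1e-12)
  # g_L(r0) = 1 by construction for any table
  tab2 <- make_synthetic_dose_table(gl_spec = function(r) exp(-r / 7))
  gl2 <- radial_dose_function(tab2)
  expect_equal(gl2$gL[gl2$r_cm == 1], 1)
  expect_equal(gl2$gL, exp(-gl2$r_cm / 7) / exp(-1 / 7), tolerance = 1e-12)
  tab3 <- tab2[abs(tab2$r_cm - 1) > 1e-9, ]
  expect_error(radial_dose_function(tab3), "r0")
})

test_that("the fifth-order fit recovers known coefficients", {
  a_true <- c(1.01, -0.03, 0.004, -2e-4, 5e-6, -5e-8)
  r <- c(0.2, 0.3, 0.5, 0.8, 1, 1.5, 2, 3, 5, 7, 10, 14, 20)
  gl <- data.frame(r_cm = r, gL = eval_radial_polynomial(a_true, r))
  fit <- fit_radial_polynomial(gl)
  expect_equal(fit$coefficients, a_true, tolerance = 1e-9)
  expect_lt(fit$residual_rms, 1e-12)
  # constant samples
  flat <- fit_radial_polynomial(data.frame(r_cm = r, gL = rep(1, length(r))))
  expect_equal(flat$coefficients, c(1, 0, 0, 0, 0, 0), tolerance = 1e-9)
  # published coefficients evaluate to ~1 at the reference radius
  expect_equal(eval_radial_polynomial(published_gl_coefficients(), 1), 1,
               tolerance = 1e-4)
  expect_error(fit_radial_polynomial(gl[1:5, ]), "at least 6")
  expect_error(fit_radial_polynomial(
    data.frame(r_cm = rep(1, 7), gL = rep(1, 7))), "rank")
})

test_that("anisotropy extraction round-trips the published table exactly", {
  ref <- reference_dataset("this-paper-NNDC")$F
  radii <- sort(unique(ref$r_cm))
  thetas <- sort(unique(ref$theta_deg))
  tab <- make_synthetic_dose_table(f_spec = ref, r = radii, theta_deg = thetas)
  tab <- tab[!is.na(tab$dose), ]
  f <- anisotropy_function(tab)
  cmp <- compare_anisotropy(f, ref)
  expect_gt(nrow(cmp$cells), 300)
  expect_lt(cmp$max_abs_all, 1e-9)
  # F = 1 on the transverse plane by construction
  expect_true(all(f$F[f$theta_deg == 90] == 1, na.rm = TRUE))
  # trivial case: dose proportional to G_L
  f1 <- anisotropy_function(make_synthetic_dose_table())
  expect_equal(f1$F[!is.na(f1$F)],
               rep(1, sum(!is.na(f1$F))), tolerance = 1e-12)
  expect_error(anisotropy_function(tab[abs(tab$theta_deg - 90) > 1e-9, ]),
               "theta0")
})

test_that("cells inside or near the capsule are unavailable", {
  tab <- make_synthetic_dose_table(r = c(0.21, 1), theta_deg = c(0, 90, 170, 180))
  f <- anisotropy_function(tab)
  pick <- function(r, th) f$F[abs(f$r_cm - r) < 1e-9 & f$theta_deg == th]
  expect_true(is.na(pick(0.21, 0)))    # 1.6 mm from the capsule tip
  expect_true(is.na(pick(1, 180)))     # inside the cable region
  expect_false(is.na(pick(1, 170)))    # near the cable but published
  expect_false(is.na(pick(1, 0)))
})

test_that("dose-rate reconstruction is exact at the reference point and idempotent", {
  a <- published_gl_coefficients()
  ref <- reference_dataset("this-paper-NNDC")$F
  mid <- ref[ref$theta_deg >= 10 & ref$theta_deg <= 150 &
               ref$r_cm >= 0.6 & ref$r_cm <= 10 & !is.na(ref$F), ]
  radii <- sort(unique(mid$r_cm))
  thetas <- sort(unique(mid$theta_deg))
  tab <- make_synthetic_dose_table(gl_spec = a, f_spec = mid,
                                   r = radii, theta_deg = thetas)
  params <- list(gL = radial_dose_function(tab), F = anisotropy_function(tab),
                 L = 0.35)
  sk <- 40000; lambda <- 1.11
  expect_equal(reconstruct_dose_rate(params, sk, lambda, 1, 90), sk * lambda,
               tolerance = 1e-12)
  # transverse plane: D = Sk Lambda g_L(r) G(r)/G(r0); the extracted g_L is
  # normalised to 1 at r0, so the generating polynomial enters as a ratio
  G <- geometry_function_line(3, 90, 0.35) / geometry_function_line(1, 90, 0.35)
  expect_equal(reconstruct_dose_rate(params, sk, lambda, 3, 90),
               sk * lambda * G * eval_radial_polynomial(a, 3) /
                 eval_radial_polynomial(a, 1),
               tolerance = 1e-9)
  # reconstruct on the grid, re-extract: identity
  tab2 <- tab
  tab2$dose <- mapply(function(r, th)
    reconstruct_dose_rate(params, sk, lambda, r, th),
    tab$r_cm, tab$theta_deg)
  p2 <- list(gL = radial_dose_function(tab2), F = anisotropy_function(tab2),
             L = 0.35)
  expect_equal(p2$gL$gL, params$gL$gL, tolerance = 1e-9)
  expect_equal(p2$F$F, params$F$F, tolerance = 1e-9)
  expect_error(reconstruct_dose_rate(params, sk, lambda, 50, 90),
               "extrapolation")
})
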