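test_that("the Klein-Nishina oracle agrees with the closed-form total", {
  for (E in c(0.05, 0.1, 0.3165, 0.468, 1.0, 1.378)) {
    orc <- kn_quadrature_oracle(E)
    expect_equal(orc$sigma_total_cm2, orc$sigma_closed_form_cm2,
                 tolerance = 1e-8)
  }
  # Thomson limit: mean scattered energy -> E as E -> 0
  orc0 <- kn_quadrature_oracle(1e-4)
  expect_equal(orc0$mean_scattered_MeV, 1e-4, tolerance = 1e-3)
  # sampled mean within 4 sigma of the quadrature mean
  s <- sample_compton(0.468, 1e5, seed = 14)
  se <- sd(s$energy) / sqrt(length(s$energy))
  expect_lt(abs(mean(s$energy) - kn_quadrature_oracle(0.468)$mean_scattered_MeV),
            4 * se)
})

test_that("the geometry-function oracle is symmetric and has the point-source limit", {
  expect_equal(gl_line_integral_oracle(2, 35, 0.35),
               gl_line_integral_oracle(2, 145, 0.35), tolerance = 1e-10)
  expect_equal(gl_line_integral_oracle(3, 90, 1e-6), 1 / 9, tolerance = 1e-9)
})

test_that("synthetic dose tables expose known ground truth", {
  # g_L = 1, F = 1: table proportional to the geometry function
  tab <- make_synthetic_dose_table()
  G0 <- geometry_function_line(1, 90, 0.35)
  expect_equal(tab$dose,
               geometry_function_line(tab$r_cm, tab$theta_deg, 0.35) / G0,
               tolerance = 1e-12)
  # noise option is reproducible and scales with sigma
  n1 <- make_synthetic_dose_table(noise_sd = 0.01, seed = 4)
  n2 <- make_synthetic_dose_table(noise_sd = 0.01, seed = 4)
  expect_identical(n1$dose, n2$dose)
  expect_gt(sd(n1$dose / tab$dose), 0.005)
  # extraction tolerates modest noise
  gl <- radial_dose_function(n1)
  expect_lt(max(abs(gl$gL - 1)), 0.06)
})

test_that("the vacuum configuration is a faithful verification harness", {
  v <- make_vacuum_config(histories = 2e4, batches = 2, seed = 3)
  expect_true(v$model$bare)
  expect_identical(v$config$phantom$medium, "vacuum")
  expect_identical(v$config$source, "point")
  run <- run_histories(v$config, v$model)
  expect_equal(sum(run$counters["escaped", ]),
               2 * run$histories_per_batch)   # escape fraction = 1
  expect_true(all(run$fluence_scatter == 0))
})
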