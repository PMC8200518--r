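test_that("bundled spectra load with the documented yields and ordering", {
  sp <- ir192_spectrum("NNDC")
  expect_s3_class(sp, "emission_spectrum")
  expect_equal(attr(sp, "total_yield"), 2.363, tolerance = 0.005)
  expect_true(all(diff(sp$energy_MeV) > 0))
  expect_true(all(sp$photons_per_decay > 0))
  expect_true(all(sp$energy_MeV > 0.01 & sp$energy_MeV < 1.5))
  dc <- ir192_spectrum("DuchemCoursol")
  # five weak lines between 0.7 and 1.4 MeV appear only in the newer evaluation
  extra <- setdiff(sp$energy_MeV[sp$energy_MeV > 0.7], dc$energy_MeV)
  expect_equal(length(extra), 5)
  expect_equal(sum(dc$energy_MeV > 0.9), 0)
})

test_that("spectrum validation names the offending row", {
  expect_equal(nrow(one_line_spectrum()), 1)
  expect_equal(attr(one_line_spectrum(), "total_yield"), 1.0)
  p <- write_spectrum_file(c("0.4,1.0", "0.2,1.0"))
  expect_error(load_spectrum(p), "row 2")
  p <- write_spectrum_file(c("0.2,1.0", "0.4,-1"))
  expect_error(load_spectrum(p), "row 2")
  p <- write_spectrum_file(character(0))
  expect_error(load_spectrum(p), "empty")
  p <- write_spectrum_file("0.005,1.0")
  expect_error(load_spectrum(p), "outside")
})

test_that("emission sampling follows the inverse-CDF convention", {
  one <- one_line_spectrum(0.3165)
  expect_equal(sample_emission_energy(one, c(0, 0.5, 1)), rep(0.3165, 3))
  two <- two_line_spectrum()
  expect_equal(sample_emission_energy(two, 0), 0.2)     # u = 0 -> lowest line
  expect_equal(sample_emission_energy(two, 1), 0.4)
  set.seed(42)
  draws <- sample_emission_energy(two, runif(1e5))
  # binomial oracle: split 0.5/0.5 within 4 sigma
  expect_lt(abs(mean(draws == 0.2) - 0.5), 4 * sqrt(0.25 / 1e5))
})

test_that("attenuation tables satisfy their invariants and interpolate log-log", {
  for (m in c("ir", "steel316l", "steel304", "water", "air")) {
    tab <- load_attenuation(m)
    expect_true(all(diff(tab$energy_MeV) > 0))
    expect_lte(tab$energy_MeV[1], 0.010)
    expect_gte(tab$energy_MeV[nrow(tab)], 1.5)
    s <- tab$mu_photoelectric + tab$mu_incoherent + tab$mu_coherent
    expect_true(all(abs(tab$mu_total / s - 1) < 0.005))
    if (isTRUE(attr(tab, "has_mu_en"))) {
      expect_true(all(tab$mu_en <= tab$mu_total))
    }
  }
  tab <- load_attenuation("water")
  i <- match(0.3, tab$energy_MeV)
  # exact at grid points
  expect_identical(interpolate_mu(tab, 0.3), tab$mu_total[i])
  expect_identical(interpolate_mu_en(tab, 0.3), tab$mu_en[i])
  # geometric-mean consistency of log-log interpolation
  e1 <- tab$energy_MeV[i]; e2 <- tab$energy_MeV[i + 1]
  gm <- sqrt(e1 * e2)
  expect_equal(interpolate_mu(tab, gm),
               sqrt(tab$mu_total[i] * tab$mu_total[i + 1]),
               tolerance = 1e-12)
  # no extrapolation
  expect_error(interpolate_mu(tab, 0.005), "outside")
  expect_error(interpolate_mu_en(tab, 2.0), "outside")
  expect_error(interpolate_mu_en(load_attenuation("ir"), 0.3),
               "only available")
})

test_that("interpolation is monotone between grid points on monotone segments", {
  tab <- load_attenuation("water")
  seg <- tab$energy_MeV >= 0.1 & tab$energy_MeV <= 1.5   # decreasing mu
  E <- exp(seq(log(0.1), log(1.5), length.out = 200))
  v <- interpolate_mu(tab, E)
  expect_true(all(diff(v) < 0))
  expect_true(all(diff(tab$mu_total[seg]) < 0))
})

test_that("material mixtures follow the mass-fraction rule", {
  mats <- table1_materials()
  # Table 1 compositions sum to exactly 100
  for (m in mats) expect_equal(sum(m$fractions), 100)
  expect_equal(mats$ir$density, 22.42)
  expect_equal(mats$steel316l$density, 7.8)
  expect_equal(mats$steel304$density, 5.6)
  expect_equal(mats$water$density, 0.998)
  expect_equal(mats$air$density, 1.197e-3)
  # pure element: mixture equals the elemental table
  ir_fix <- load_attenuation("ir")
  built <- mats$ir$attenuation
  idx <- match(ir_fix$energy_MeV, built$energy_MeV)
  expect_equal(built$mu_total[idx], ir_fix$mu_total, tolerance = 1e-5)
  # 50/50 two-element mixture -> arithmetic mean of elemental values
  m5050 <- build_material("ho", c(H = 50, O = 50), 1)
  h <- build_material("h", c(H = 100), 1)$attenuation
  o <- build_material("o", c(O = 100), 1)$attenuation
  expect_equal(m5050$attenuation$mu_total, (h$mu_total + o$mu_total) / 2,
               tolerance = 1e-12)
  # scaling fractions then renormalising leaves the mixture unchanged
  a <- build_material("w1", c(H = 11.1, O = 88.9), 0.998)$attenuation
  b <- build_material("w2", c(H = 22.2, O = 177.8) / 2, 0.998)$attenuation
  expect_equal(a$mu_total, b$mu_total, tolerance = 1e-12)
  # validation errors
  expect_error(build_material("bad", c(H = 50, O = 49), 1), "sum")
  expect_error(build_material("bad", c(H = -1, O = 101), 1), "negative")
})

test_that("built 316L mixture matches the shipped per-material fixture", {
  built <- table1_materials()$steel316l$attenuation
  fix <- load_attenuation("steel316l")
  idx <- match(fix$energy_MeV, built$energy_MeV)
  expect_equal(built$mu_total[idx], fix$mu_total, tolerance = 1e-5)
})
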