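test_that("free-flight distances follow the exponential law across segments", {
  ph <- default_physics()
  mu <- interpolate_mu(ph$tables$water, 0.3165) * 0.998
  d <- sample_free_flight(1e5, mu, 1e4, seed = 3)   # effectively infinite water
  expect_lt(abs(mean(d) - 1 / mu), 4 * sd(d) / sqrt(length(d)))
  # a zero-length segment cannot host an interaction
  d2 <- sample_free_flight(1e4, c(5, 1), c(0, 10), seed = 4)
  expect_true(all(d2[is.finite(d2)] > 0))
  # very dense segment: interaction at entry within numerical tolerance
  d3 <- sample_free_flight(1e4, 1e9, 1, seed = 5)
  expect_true(all(d3 < 1e-6))
  # escape beyond the last segment is flagged as Inf
  d4 <- sample_free_flight(1e4, 0.1, 0.01, seed = 6)
  expect_gt(mean(is.infinite(d4)), 0.99)
})

test_that("interaction types are chosen in proportion to the process cross sections", {
  ph <- default_physics()
  pr <- sample_interaction_type(ph$tables$water, 0.3)
  expect_equal(sum(pr), 1)
  set.seed(9)
  lab <- sample_interaction_type(ph$tables$water, 0.3, n = 1e5)
  for (nm in names(pr)) {
    expect_lt(abs(mean(lab == nm) - pr[[nm]]),
              4 * sqrt(pr[[nm]] * (1 - pr[[nm]]) / 1e5))
  }
  fake <- fake_process_table("photoelectric")
  expect_equal(unname(sample_interaction_type(fake, 0.3)["photoelectric"]),
               1, tolerance = 1e-7)
})

test_that("Compton sampling obeys the kinematic bounds and matches quadrature", {
  E <- 0.3165
  s <- sample_compton(E, 2e5, seed = 10)
  expect_true(all(s$energy <= E))
  emin <- E / (1 + 2 * E / 0.51099895)
  expect_true(all(s$energy >= emin - 1e-12))
  expect_equal(emin, 0.1414, tolerance = 1e-3)
  orc <- kn_quadrature_oracle(E)
  expect_lt(abs(mean(s$energy) / orc$mean_scattered_MeV - 1), 0.003)
  # scattered energy and cosine satisfy the Compton relation
  pred <- E / (1 + (E / 0.51099895) * (1 - s$cosine))
  expect_equal(s$energy, pred, tolerance = 1e-9)
})

test_that("Rayleigh sampling leaves energy unchanged with Thomson angles", {
  s <- sample_rayleigh_angle(0.3165, 5e4, seed = 12)
  expect_true(all(s$energy == 0.3165))
  # K-S against the Thomson CDF (mu + mu^3/3 + 4/3) / (8/3)
  cdf <- function(x) (x + x^3 / 3 + 4 / 3) / (8 / 3)
  ks <- suppressWarnings(ks.test(s$cosine, cdf))
  expect_gt(ks$p.value, 1e-4)
})

test_that("ring chords are exact and the vacuum run recovers the inverse square law", {
  grid <- ring_grid(c(1, 2), c(0, 180))
  # ray through the full shell along x: chord = 2 cm in [1,2]
  ch <- score_track_length(c(-5, 0, 1e-9), c(1, 0, 0), 10, grid)
  expect_equal(sum(ch$length), 2, tolerance = 1e-10)
  v <- make_vacuum_config(histories = 1e5, batches = 4, seed = 5)
  run <- run_histories(v$config, v$model)
  hpb <- run$histories_per_batch
  # per-shell track length per history equals the shell thickness exactly in
  # expectation (volume-average of 1/(4 pi r^2) times 4 pi r^2 dr)
  m <- matrix(rowMeans(run$fluence_total), nrow = v$grid$nr)
  per_shell <- rowSums(m) / hpb
  dr <- diff(v$config$grid$r_edges)
  mb <- sapply(seq_len(ncol(run$fluence_total)), function(b) {
    rowSums(matrix(run$fluence_total[, b], nrow = v$grid$nr)) / hpb / dr
  })
  u <- estimate_uncertainty(mb)
  expect_true(all(abs(per_shell / dr - 1) <= pmax(3 * u$se, 1e-3)))
  # no interactions, all histories escape
  cnt <- run$counters
  expect_equal(sum(cnt[c("photoelectric", "compton", "rayleigh"), ]), 0)
  expect_equal(sum(cnt["escaped", ]), hpb * 4)
})

test_that("identical seeds give bit-identical tallies and zero histories give empty ones", {
  cfg <- run_config(phantom_spec("water"), 2e4, batches = 2, seed = 99,
                    spectrum = 0.3165,
                    grid = ring_grid(c(0.5, 1, 2), c(60, 90, 120)))
  r1 <- run_histories(cfg, physics = default_physics())
  r2 <- run_histories(cfg, physics = default_physics())
  expect_identical(r1$fluence_total, r2$fluence_total)
  expect_identical(r1$dose_scatter, r2$dose_scatter)
  cfg3 <- run_config(phantom_spec("water"), 2e4, batches = 2, seed = 100,
                     spectrum = 0.3165,
                     grid = ring_grid(c(0.5, 1, 2), c(60, 90, 120)))
  r3 <- run_histories(cfg3, physics = default_physics())
  expect_false(identical(r1$fluence_total, r3$fluence_total))
  cfg0 <- run_config(phantom_spec("water"), 0, batches = 2, seed = 1,
                     spectrum = 0.3165,
                     grid = ring_grid(c(0.5, 1, 2), c(60, 90, 120)))
  r0 <- run_histories(cfg0, physics = default_physics())
  expect_true(all(r0$fluence_total == 0))
  expect_equal(estimate_uncertainty(r0$fluence_total)$se, rep(0, 4))
})

test_that("scored energies stay within [cutoff, max line] and never increase", {
  sp <- ir192_spectrum("NNDC")
  cfg <- run_config(phantom_spec("water"), 3e4, batches = 2, seed = 21,
                    spectrum = sp, grid = ring_grid(c(0.5, 1, 2), c(0, 180)))
  run <- run_histories(cfg, physics = default_physics())
  cnt <- run$counters
  expect_lte(max(cnt["max_scored_E", ]), max(sp$energy_MeV) + 1e-12)
  expect_gte(min(cnt["min_scored_E", ]), 0.010)
})

test_that("batch uncertainty follows the ten-run recipe", {
  expect_equal(estimate_uncertainty(matrix(5, 1, 4))$se, 0)
  u <- estimate_uncertainty(matrix(c(1, 3), 1))
  expect_equal(u$mean, 2)
  expect_equal(u$se, abs(1 - 3) / 2)
  expect_error(estimate_uncertainty(matrix(1, 1, 1)), "2 batches")
  # sampling-distribution oracle at n = 10 batches
  set.seed(30)
  reps <- replicate(300, estimate_uncertainty(matrix(rnorm(10), 1))$se)
  expect_lt(abs(mean(reps) / (1 / sqrt(10)) - 1), 0.30)
})

test_that("the next-event estimator reduces to closed forms", {
  ph <- default_physics()
  # bare point source in vacuum: exactly 1/(4 pi d^2)
  fl <- next_event_fluence(matrix(c(100, 0, 0), 1), 0.3165,
                           model = source_model(bare = TRUE),
                           physics = ph, phantom = phantom_spec("vacuum"),
                           point_source = TRUE)
  expect_equal(as.numeric(fl), 1 / (4 * pi * 1e4), tolerance = 1e-12)
  # one absorbing slab on the ray: factor exp(-mu t); query at a grid energy
  # so the table lookup is exact
  fl2 <- next_event_fluence(matrix(c(100, 0, 0), 1), 0.3,
                            model = source_model(bare = FALSE),
                            physics = ph, phantom = phantom_spec("vacuum"),
                            point_source = TRUE)
  mu_ir <- (interpolate_mu(ph$tables$ir, 0.3, "photoelectric") +
            interpolate_mu(ph$tables$ir, 0.3, "incoherent")) * 22.42
  mu_st <- (interpolate_mu(ph$tables$steel316l, 0.3, "photoelectric") +
            interpolate_mu(ph$tables$steel316l, 0.3, "incoherent")) * 7.8
  pred <- exp(-mu_ir * 0.03 - mu_st * 0.015) / (4 * pi * 1e4)
  expect_equal(as.numeric(fl2), pred, tolerance = 1e-10)
})
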