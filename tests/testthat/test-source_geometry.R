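test_that("core-position sampling is uniform in the core volume", {
  model <- source_model()
  pts <- sample_core_position(1e5, model, seed = 2)
  rho <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  expect_true(all(rho <= model$core_radius))
  expect_true(all(abs(pts[, 3]) <= model$core_length / 2))
  # symmetry: mean within 4 sigma of the centre
  se_xy <- sd(pts[, 1]) / sqrt(nrow(pts))
  se_z <- sd(pts[, 3]) / sqrt(nrow(pts))
  expect_lt(abs(mean(pts[, 1])), 4 * se_xy)
  expect_lt(abs(mean(pts[, 2])), 4 * se_xy)
  expect_lt(abs(mean(pts[, 3])), 4 * se_z)
  # uniform-in-area oracle: rho^2 ~ U(0, core_radius^2)
  ks <- suppressWarnings(ks.test(rho^2 / model$core_radius^2, "punif"))
  expect_gt(ks$p.value, 1e-4)
})

test_that("trace_path reproduces the closed-form source transects", {
  tp <- trace_path(c(0, 0, 0), c(1, 0, 0))
  expect_equal(tp$material, c("Ir", "316L", "water"))
  expect_equal(tp$length[1:2], c(0.030, 0.015), tolerance = 1e-12)
  tp <- trace_path(c(0, 0, 0), c(0, 0, 1))
  expect_equal(tp$material, c("Ir", "316L", "water"))
  expect_equal(tp$length[1:2], c(0.175, 0.062), tolerance = 1e-12)
  # far away, pointing outward: a single water segment to the cube boundary
  tp <- trace_path(c(50, 0, 0) * 0.5, c(1, 0, 0))
  expect_equal(tp$material, "water")
  expect_equal(tp$length, 15, tolerance = 1e-10)
  expect_error(trace_path(c(0, 0, 0), c(0, 0, 0)), "degenerate")
})

test_that("segments sum to the ray length and agree with locate_material", {
  model <- source_model()
  phantom <- phantom_spec("water")
  set.seed(7)
  for (i in 1:60) {
    o <- runif(3, -0.2, 0.2)
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    tp <- trace_path(o, d, model, phantom)
    expect_equal(sum(tp$length), attr(tp, "ray_length"), tolerance = 1e-10)
    # material at each segment midpoint matches the segment label
    ends <- cumsum(tp$length)
    mids <- ends - tp$length / 2
    for (j in seq_len(nrow(tp))) {
      p <- o + mids[j] * d
      expect_identical(locate_material(p, model, phantom), tp$material[j])
    }
  }
})

test_that("geometry is azimuthally symmetric", {
  model <- source_model()
  phantom <- phantom_spec("water", shape = "sphere", size = 40)
  set.seed(11)
  for (i in 1:25) {
    o <- runif(3, -0.3, 0.3)
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    a <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
    t1 <- trace_path(o, d, model, phantom)
    t2 <- trace_path(drop(R %*% o), drop(R %*% d), model, phantom)
    expect_identical(t1$material, t2$material)
    expect_equal(t1$length, t2$length, tolerance = 1e-9)
  }
})

test_that("locate_material assigns boundary points to the inner region", {
  model <- source_model()
  expect_identical(locate_material(c(0, 0, 0)), "Ir")
  tipz <- model$core_length / 2 + model$tip_thickness / 2
  expect_identical(locate_material(c(0, 0, tipz)), "316L")
  expect_identical(locate_material(c(10, 0, 0)), "water")
  expect_identical(locate_material(c(model$core_radius, 0, 0)), "Ir")
  expect_identical(locate_material(c(model$capsule_radius, 0, 0)), "316L")
  cab_z <- -model$core_length / 2 - model$proximal_thickness - 1
  expect_identical(locate_material(c(0, 0, cab_z)), "304")
  expect_identical(locate_material(c(0, 0, 45)), "outside")
})

test_that("trace_path clips at a target point", {
  tp <- trace_path(c(0, 0, 0), c(1, 0, 0), target = c(1, 0, 0))
  expect_equal(sum(tp$length), 1, tolerance = 1e-12)
  expect_equal(tp$material, c("Ir", "316L", "water"))
})

test_that("source model validates its dimensions", {
  expect_error(source_model(core_radius = 0.05), "smaller")
  expect_error(source_model(core_length = -1))
  expect_equal(source_model()$cable_length, 6)
})
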