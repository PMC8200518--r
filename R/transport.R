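#' Ring-voxel tally grid on (r, theta)
#'
#' Half-open annular bins bounded by spheres `r_edges` and cones
#' `theta_edges_deg`; volumes from the exact shell integral
#' `(2*pi/3) (r2^3 - r1^3) (cos(theta1) - cos(theta2))`.
#'
#' @param r_edges ascending radial edges, cm.
#' @param theta_edges_deg ascending polar-angle edges, degrees, in `[0, 180]`.
#' @export
ring_grid <- function(r_edges, theta_edges_deg) {
  stopifnot(all(diff(r_edges) > 0), all(diff(theta_edges_deg) > 0),
            theta_edges_deg[1] >= 0,
            theta_edges_deg[length(theta_edges_deg)] <= 180)
  structure(list(r_edges = r_edges, theta_edges_deg = theta_edges_deg,
                 nr = length(r_edges) - 1L,
                 nt = length(theta_edges_deg) - 1L),
            class = "ring_grid")
}

#' @rdname ring_grid
#' @param grid a `ring_grid`.
#' @return matrix `nr x nt` of bin volumes in cm^3.
#' @export
ring_volumes <- function(grid) {
  r3 <- diff(grid$r_edges^3)
  dc <- -diff(cos(grid$theta_edges_deg * pi / 180))  # cos decreasing
  outer(r3, dc) * (2 * pi / 3)
}

# contiguous edges centred on a set of sample values
.midpoint_edges <- function(x, lo, hi) {
  c(lo, (x[-1] + x[-length(x)]) / 2, hi)
}

#' Default water-phantom tally layout
#'
#' Radial samples follow the published sampling distances (2 mm to 20 cm) plus
#' the anisotropy-table radii; polar samples replicate the published
#' anisotropy-table angles (1 degree rows near the poles).  Bin edges are the
#' midpoints between neighbouring samples, so bin widths track the
#' 0.1 mm - 2 mm voxel-size schedule of the study.
#'
#' @return list with `grid` (a [ring_grid()]), `r_samples`, `theta_samples`.
#' @export
water_tally_grid <- function() {
  r_samples <- c(0.2, 0.3, 0.4, 0.5, 0.6, 0.8, 1, 1.25, 1.5, 2, 2.5, 3, 4, 5,
                 6, 8, 10, 12, 15, 20)
  theta_samples <- c(0:10, 15, 20, 30, 40, 50, 60, 70, 80, 90, 100, 110, 120,
                     130, 140, 150, 160, 165, 170:180)
  grid <- ring_grid(.midpoint_edges(r_samples, 0.15, 20.5),
                    .midpoint_edges(theta_samples, 0, 180))
  list(grid = grid, r_samples = r_samples, theta_samples = theta_samples)
}

#' Transport run configuration
#'
#' @param phantom a [phantom_spec()].
#' @param histories total photon histories (split evenly across batches).
#' @param batches independent batches for uncertainty estimation (>= 2;
#'   default 10, as in the study).
#' @param seed root seed; per-batch child seeds are consecutive outputs of a
#'   splitmix64 stream started at the root (documented splitting rule).
#' @param spectrum an `emission_spectrum`, or a single energy in MeV for a
#'   monoenergetic source.
#' @param cutoff_MeV photon energy cutoff (>= 0.010; photons falling below it
#'   are terminated and not further tallied).
#' @param grid a [ring_grid()] for water/vacuum runs; ignored for air runs.
#' @param source `"model"` (volumetric emission from the core) or `"point"`.
#' @param coherent coherent (Rayleigh) scattering treatment: `"forward"`
#'   (default; treated as transparent because the form-factor angular
#'   distribution is strongly forward-peaked at these energies, so it is
#'   excluded from the attenuation), `"thomson"` (tabulated cross section
#'   with Thomson-sampled angles, for sensitivity checks), or `"off"`
#'   (numerically identical to `"forward"`).
#' @param tally `"ring"` or `"airbox"` (the 10 x 10 x 0.05 cm^3 region at
#'   1 m on the transverse plane, 5 keV energy bins).
#' @export
run_config <- function(phantom, histories, batches = 10, seed = 1,
                       spectrum = NULL, cutoff_MeV = 0.010, grid = NULL,
                       source = c("model", "point"),
                       coherent = c("forward", "thomson", "off"),
                       tally = c("ring", "airbox")) {
  source <- match.arg(source)
  coherent <- match.arg(coherent)
  tally <- match.arg(tally)
  if (!inherits(phantom, "phantom_spec")) stop("invalid phantom", call. = FALSE)
  if (batches < 2) stop("at least 2 batches are required", call. = FALSE)
  if (cutoff_MeV < 0.010) stop("cutoff below 10 keV not supported", call. = FALSE)
  if (histories < 0) stop("negative histories", call. = FALSE)
  if (is.numeric(spectrum) && length(spectrum) == 1) {
    spectrum <- structure(data.frame(energy_MeV = spectrum,
                                     photons_per_decay = 1,
                                     below_delta = FALSE),
                          class = c("emission_spectrum", "data.frame"),
                          label = "mono", total_yield = 1)
  }
  if (!inherits(spectrum, "emission_spectrum")) {
    stop("spectrum must be an emission_spectrum or a single energy",
         call. = FALSE)
  }
  structure(list(phantom = phantom, histories = histories, batches = batches,
                 seed = seed, spectrum = spectrum, cutoff_MeV = cutoff_MeV,
                 grid = grid, source = source, coherent = coherent,
                 tally = tally), class = "run_config")
}

.air_box <- function(d_cm = 100) {
  list(box = c(d_cm, 0.05, 10, 10), ebin_min = 0.010, ebin_width = 0.005,
       ebin_n = 280L)
}

#' Run photon histories
#'
#' Analog transport: emit (core position or point, isotropic direction,
#' spectrum line energy), alternate free flights sampled from the
#' piecewise-exponential law across material segments with interactions
#' (photoelectric absorption, Klein-Nishina incoherent scattering, coherent
#' scattering with Thomson angles) until escape or energy cutoff.
#' Track-length tallies are accumulated per batch, separately for all photons
#' and for collided (scattered at least once) photons.  Identical
#' (config, seed) gives bit-identical tallies.
#'
#' @param config a [run_config()].
#' @param model a [source_model()].
#' @param physics a [physics_set()].
#' @return object of class `transport_tallies`: per-batch raw track-length
#'   matrices (`fluence_total`, `fluence_scatter`, cm), dose-weighted tallies
#'   (`dose_total`, `dose_scatter`, MeV cm / g), counters, and the
#'   normalisation metadata.
#' @export
run_histories <- function(config, model = source_model(),
                          physics = physics_set()) {
  stopifnot(inherits(config, "run_config"))
  ph <- config$phantom
  medium <- ph$medium
  dose_medium <- if (medium == "vacuum") "none" else medium
  xs <- .xs_for_transport(physics, medium, dose_medium,
                          coherent_in_mu = identical(config$coherent,
                                                     "thomson"))
  sp <- config$spectrum
  p <- sp$photons_per_decay / sum(sp$photons_per_decay)
  cfg <- list(histories_per_batch = floor(config$histories / config$batches),
              batches = as.integer(config$batches),
              seed = as.double(config$seed),
              cutoff_MeV = config$cutoff_MeV,
              coherent = identical(config$coherent, "thomson"),
              point_source = identical(config$source, "point"),
              line_energies = sp$energy_MeV,
              line_cdf = cumsum(p),
              tally_mode = if (config$tally == "ring") 0L else 1L)
  if (config$tally == "ring") {
    grid <- config$grid
    if (is.null(grid)) grid <- water_tally_grid()$grid
    cfg$r_edges <- grid$r_edges
    cfg$theta_edges_deg <- grid$theta_edges_deg
  } else {
    cfg <- c(cfg, .air_box())
    grid <- NULL
  }
  res <- cpp_run_transport(unclass(model), unclass(ph), xs, cfg)
  structure(c(res, list(config = config, grid = grid,
                        histories_per_batch = cfg$histories_per_batch)),
            class = "transport_tallies")
}

#' Free-flight distance sampling across heterogeneous segments
#'
#' Samples interaction distances from the piecewise-exponential law with the
#' given per-segment linear attenuation coefficients; `Inf` marks escape
#' beyond the final segment.
#'
#' @param n number of draws; `seed` engine seed.
#' @param mu_per_cm,length_cm per-segment linear attenuation (cm^-1) and
#'   lengths (cm).
#' @export
sample_free_flight <- function(n, mu_per_cm, length_cm, seed = 1) {
  stopifnot(length(mu_per_cm) == length(length_cm), all(length_cm >= 0))
  cpp_sample_free_flight(as.integer(n), as.double(mu_per_cm),
                         as.double(length_cm), as.double(seed))
}

#' Interaction-type probabilities and sampling
#'
#' P(process) = mu_process / mu_total at the interaction energy.
#'
#' @param material an `attenuation_table`.
#' @param energy photon energy, MeV.
#' @param n optional number of sampled process labels (uses R's RNG).
#' @return if `n` is `NULL`, the named probability vector; otherwise sampled
#'   process labels.
#' @export
sample_interaction_type <- function(material, energy, n = NULL) {
  pr <- c(photoelectric = interpolate_mu(material, energy, "photoelectric"),
          incoherent = interpolate_mu(material, energy, "incoherent"),
          coherent = interpolate_mu(material, energy, "coherent"))
  pr <- pr / sum(pr)
  if (is.null(n)) return(pr)
  sample(names(pr), n, replace = TRUE, prob = pr)
}

#' Sample Klein-Nishina incoherent scattering
#'
#' Free-electron Klein-Nishina differential cross section, sampled by
#' rejection on the scattered-to-incident energy ratio; the scattered energy
#' obeys the Compton relation
#' `E' = E / (1 + (E / 0.511)(1 - cos(theta)))`.
#'
#' @param energy incident photon energy, MeV.
#' @param n number of samples; `seed` engine seed.
#' @return list with `energy` (MeV) and `cosine`.
#' @export
sample_compton <- function(energy, n, seed = 1) {
  stopifnot(energy > 0)
  m <- cpp_sample_compton(as.double(energy), as.integer(n), as.double(seed))
  list(energy = m[, 1], cosine = m[, 2])
}

#' Sample a coherent (Rayleigh) scattering angle
#'
#' Thomson angular distribution, `p(cos) = 3/8 (1 + cos^2)`; the photon
#' energy is unchanged.
#'
#' @param energy photon energy, MeV (unchanged; kept for interface symmetry).
#' @param n number of samples; `seed` engine seed.
#' @return list with `energy` and `cosine`.
#' @export
sample_rayleigh_angle <- function(energy, n, seed = 1) {
  list(energy = rep(energy, n),
       cosine = cpp_sample_rayleigh(as.integer(n), as.double(seed)))
}

#' Exact ring-voxel chords of a flight
#'
#' Splits the flight `[0, smax]` from `origin` along `direction` at every
#' sphere and cone boundary of the grid and returns the chord length deposited
#' in each traversed bin.
#'
#' @inheritParams trace_path
#' @param smax flight length, cm.
#' @param grid a [ring_grid()].
#' @return data frame with 1-based `ir`, `itheta` bin indices and `length`.
#' @export
score_track_length <- function(origin, direction, smax, grid) {
  m <- cpp_ring_chords(as.double(origin), as.double(direction),
                       as.double(smax), grid$r_edges, grid$theta_edges_deg)
  as.data.frame(m)
}

#' Batch-mean uncertainty
#'
#' Mean and standard error of per-batch means (rows of `batch_matrix` are
#' tally bins, columns batches), the study's ten-run uncertainty recipe.
#'
#' @param batch_matrix numeric matrix (or vector of batch means).
#' @export
estimate_uncertainty <- function(batch_matrix) {
  if (is.vector(batch_matrix)) batch_matrix <- matrix(batch_matrix, nrow = 1)
  nb <- ncol(batch_matrix)
  if (nb < 2) stop("at least 2 batches required", call. = FALSE)
  m <- rowMeans(batch_matrix)
  se <- apply(batch_matrix, 1, sd) / sqrt(nb)
  list(mean = m, se = se)
}

#' Deterministic first-flight (next-event) estimate of uncollided fluence
#'
#' For each detector point, averages `exp(-sum_i mu_i t_i) / (4 pi d^2)` over
#' a fixed midpoint lattice of emission points in the core volume, with exact
#' ray-traced material segments.  The collided component is supplied by the
#' analog run; this estimator replaces the analog tally of the uncollided
#' flux.
#'
#' @param det_points `n x 3` matrix of detector points (cm).
#' @param spectrum an `emission_spectrum` (or single energy).
#' @param model,physics,phantom as elsewhere.
#' @param n_rho,n_phi,n_z emission-lattice resolution (default 8 x 8 x 16).
#' @param point_source collapse the emission lattice to the origin.
#' @param coherent coherent treatment, as in [run_config()]; determines
#'   whether the coherent cross section contributes to the optical depth.
#' @return matrix `n x nlines` of uncollided fluence per initial photon
#'   (cm^-2) for each spectrum line, with line energies and probabilities as
#'   attributes.
#' @export
next_event_fluence <- function(det_points, spectrum, model = source_model(),
                               physics = physics_set(),
                               phantom = phantom_spec("water"),
                               n_rho = 8, n_phi = 8, n_z = 16,
                               point_source = FALSE,
                               coherent = c("forward", "thomson", "off")) {
  coherent <- match.arg(coherent)
  if (is.numeric(spectrum) && length(spectrum) == 1) {
    lineE <- spectrum; lineP <- 1
  } else {
    stopifnot(inherits(spectrum, "emission_spectrum"))
    lineE <- spectrum$energy_MeV
    lineP <- spectrum$photons_per_decay / sum(spectrum$photons_per_decay)
  }
  det_points <- matrix(as.double(det_points), ncol = 3)
  xs <- .xs_for_transport(physics, phantom$medium, "none",
                          coherent_in_mu = identical(coherent, "thomson"))
  m <- cpp_uncollided(det_points, lineE, unclass(model), unclass(phantom),
                      xs, as.integer(n_rho), as.integer(n_phi),
                      as.integer(n_z), isTRUE(point_source))
  attr(m, "line_energies") <- lineE
  attr(m, "line_probs") <- lineP
  m
}
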