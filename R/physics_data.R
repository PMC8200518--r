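#' @useDynLib irtg43mc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx integrate lm.fit rnorm runif sd setNames
#' @importFrom utils read.csv write.table
NULL

# cached package environment for fixture tables
.irtg43_cache <- new.env(parent = emptyenv())

.extdata <- function(...) {
  p <- system.file("extdata", ..., package = "irtg43mc", mustWork = FALSE)
  if (!nzchar(p)) stop("fixture not found: ", file.path(...), call. = FALSE)
  p
}

#' Load an Ir-192 photon emission spectrum
#'
#' Reads a two-column table (`energy_MeV`, `photons_per_decay`; `#` comments,
#' header optional) and validates it: energies strictly ascending and inside
#' (0.01, 1.5) MeV, intensities positive.  Lines at or below the air-kerma
#' energy cutoff `delta_MeV` are kept but flagged.  For the bundled NNDC
#' spectrum the total photon yield is additionally checked against the
#' published 2.363 photons per decay (within 0.5%).
#'
#' @param path path to a spectrum CSV, or one of the labels `"NNDC"`,
#'   `"DuchemCoursol"` for the bundled fixtures.
#' @param delta_MeV air-kerma energy cutoff used for flagging (default 10 keV).
#' @return an object of class `emission_spectrum`: a data frame with columns
#'   `energy_MeV`, `photons_per_decay`, `below_delta`, with attributes `label`
#'   and `total_yield`.
#' @export
load_spectrum <- function(path, delta_MeV = 0.010) {
  label <- path
  if (identical(path, "NNDC")) {
    path <- .extdata("spectra", "ir192_nndc.csv")
  } else if (identical(path, "DuchemCoursol")) {
    path <- .extdata("spectra", "ir192_duchemin_coursol.csv")
  } else {
    label <- basename(path)
  }
  first <- readLines(path, n = 50L)
  first <- first[!grepl("^\\s*#", first) & nzchar(first)]
  has_header <- length(first) > 0 && grepl("[A-Za-z]", first[1])
  df <- read.csv(path, comment.char = "#", header = has_header,
                 col.names = c("energy_MeV", "photons_per_decay"))
  if (nrow(df) == 0) stop("empty spectrum file: ", path, call. = FALSE)
  bad <- which(!is.finite(df$photons_per_decay) | df$photons_per_decay <= 0)
  if (length(bad)) {
    stop("non-positive intensity in spectrum row ", bad[1], call. = FALSE)
  }
  nonasc <- which(diff(df$energy_MeV) <= 0)
  if (length(nonasc)) {
    stop("energies not strictly ascending at spectrum row ", nonasc[1] + 1,
         call. = FALSE)
  }
  out <- which(df$energy_MeV <= 0.01 | df$energy_MeV >= 1.5)
  if (length(out)) {
    stop("energy outside (0.01, 1.5) MeV in spectrum row ", out[1], call. = FALSE)
  }
  df$below_delta <- df$energy_MeV <= delta_MeV
  total <- sum(df$photons_per_decay)
  if (identical(label, "NNDC") && abs(total / 2.363 - 1) > 0.005) {
    stop(sprintf("NNDC total photon yield %.4f differs from 2.363 by > 0.5%%",
                 total), call. = FALSE)
  }
  structure(df, class = c("emission_spectrum", "data.frame"),
            label = label, total_yield = total, delta_MeV = delta_MeV)
}

#' @rdname load_spectrum
#' @export
ir192_spectrum <- function(path = c("NNDC", "DuchemCoursol")) {
  load_spectrum(match.arg(path))
}

#' Sample emission line energies by inverse-CDF lookup
#'
#' Line `i` is drawn with probability `intensity_i / sum(intensity)`.  The
#' boundary convention is that of the right-continuous inverse CDF: a draw
#' `u = 0` maps to the lowest-energy line, `u = 1` to the highest.
#'
#' @param spectrum an `emission_spectrum`.
#' @param u uniform draws in `[0, 1]`.
#' @return line energies in MeV, same length as `u`.
#' @export
sample_emission_energy <- function(spectrum, u) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  cdf <- cumsum(spectrum$photons_per_decay) / sum(spectrum$photons_per_decay)
  idx <- findInterval(u, cdf, left.open = TRUE) + 1L
  idx[idx > nrow(spectrum)] <- nrow(spectrum)
  spectrum$energy_MeV[idx]
}

.read_attenuation_csv <- function(path, material) {
  df <- read.csv(path, comment.char = "#")
  n <- nrow(df)
  if (n == 0) stop("empty attenuation table: ", path, call. = FALSE)
  if (any(diff(df$energy_MeV) <= 0)) {
    stop("attenuation grid not strictly ascending: ", material, call. = FALSE)
  }
  if (df$energy_MeV[1] > 0.010 || df$energy_MeV[n] < 1.5) {
    stop("attenuation grid does not span [0.01, 1.5] MeV: ", material,
         call. = FALSE)
  }
  proc_sum <- df$mu_photoelectric + df$mu_incoherent + df$mu_coherent
  if (any(abs(df$mu_total / proc_sum - 1) > 0.005)) {
    stop("process sum differs from total by > 0.5%: ", material, call. = FALSE)
  }
  cols <- c("mu_photoelectric", "mu_incoherent", "mu_coherent", "mu_total")
  if (any(sapply(df[cols], function(x) any(x <= 0)))) {
    stop("non-positive coefficient in attenuation table: ", material,
         call. = FALSE)
  }
  if (!is.null(df$mu_en) && any(df$mu_en > df$mu_total)) {
    stop("mu_en exceeds mu_total in attenuation table: ", material,
         call. = FALSE)
  }
  structure(df, class = c("attenuation_table", "data.frame"),
            material = material, has_mu_en = !is.null(df$mu_en))
}

#' Load a bundled photon attenuation table
#'
#' Mass interaction coefficients (cm^2/g) per process over 10 keV - 1.5 MeV
#' for the five materials of the source model; water and dry air also carry
#' mass energy-absorption coefficients.
#'
#' @param material one of `"ir"`, `"steel316l"`, `"steel304"`, `"water"`, `"air"`.
#' @return an `attenuation_table` data frame.
#' @export
load_attenuation <- function(material = c("ir", "steel316l", "steel304",
                                          "water", "air")) {
  material <- match.arg(material)
  key <- paste0("atten_", material)
  if (is.null(.irtg43_cache[[key]])) {
    .irtg43_cache[[key]] <- .read_attenuation_csv(
      .extdata("xs", paste0("attenuation_", material, ".csv")), material)
  }
  .irtg43_cache[[key]]
}

.loglog_interp <- function(x, y, xout) {
  lx <- log(x); ly <- log(y)
  i <- findInterval(log(xout), lx, rightmost.closed = TRUE)
  i[i < 1] <- 1L; i[i >= length(lx)] <- length(lx) - 1L
  w <- (log(xout) - lx[i]) / (lx[i + 1L] - lx[i])
  exp(ly[i] * (1 - w) + ly[i + 1L] * w)
}

#' Interpolate a mass attenuation coefficient
#'
#' Log-log linear interpolation between bracketing grid points; exact at grid
#' points; refuses to extrapolate.
#'
#' @param table an `attenuation_table`.
#' @param energy photon energies in MeV, inside the table span.
#' @param process `"total"`, `"photoelectric"`, `"incoherent"`, or `"coherent"`.
#' @return mu/rho in cm^2/g.
#' @export
interpolate_mu <- function(table, energy,
                           process = c("total", "photoelectric", "incoherent",
                                       "coherent")) {
  stopifnot(inherits(table, "attenuation_table"))
  process <- match.arg(process)
  rng <- range(table$energy_MeV)
  if (any(energy < rng[1] | energy > rng[2])) {
    stop(sprintf("energy outside table span [%g, %g] MeV", rng[1], rng[2]),
         call. = FALSE)
  }
  col <- paste0("mu_", if (process == "total") "total" else process)
  .loglog_interp(table$energy_MeV, table[[col]], energy)
}

#' Interpolate the mass energy-absorption coefficient
#'
#' Only the water and dry-air tables carry mu_en/rho.
#'
#' @inheritParams interpolate_mu
#' @return mu_en/rho in cm^2/g.
#' @export
interpolate_mu_en <- function(table, energy) {
  stopifnot(inherits(table, "attenuation_table"))
  if (!isTRUE(attr(table, "has_mu_en"))) {
    stop("mu_en/rho is only available for air and water", call. = FALSE)
  }
  rng <- range(table$energy_MeV)
  if (any(energy < rng[1] | energy > rng[2])) {
    stop(sprintf("energy outside table span [%g, %g] MeV", rng[1], rng[2]),
         call. = FALSE)
  }
  .loglog_interp(table$energy_MeV, table$mu_en, energy)
}

.element_table <- function() {
  if (is.null(.irtg43_cache$elements)) {
    .irtg43_cache$elements <- read.csv(.extdata("xs", "elements.csv"),
                                       comment.char = "#")
  }
  .irtg43_cache$elements
}

#' Build a material from elemental mass fractions
#'
#' Mass fractions are given in percent and must sum to 100 within 0.01.  The
#' mixture mass attenuation coefficient for each process is the mass-fraction
#' weighted sum of the bundled elemental coefficients.
#'
#' @param name material name.
#' @param fractions named numeric vector of mass percentages (element symbols).
#' @param density g/cm^3.
#' @return an object of class `material` with fields `name`, `fractions`,
#'   `density` and an `attenuation` table.
#' @export
build_material <- function(name, fractions, density) {
  if (any(fractions < 0)) stop("negative mass fraction", call. = FALSE)
  if (abs(sum(fractions) - 100) > 0.01) {
    stop(sprintf("mass fractions sum to %.4f, not 100 +/- 0.01",
                 sum(fractions)), call. = FALSE)
  }
  el <- .element_table()
  unknown <- setdiff(names(fractions), unique(el$element))
  if (length(unknown)) stop("no elemental data for: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  E <- sort(unique(el$energy_MeV))
  pe <- ic <- co <- numeric(length(E))
  for (sym in names(fractions)) {
    sub <- el[el$element == sym, ]
    sub <- sub[order(sub$energy_MeV), ]
    w <- fractions[[sym]] / 100
    pe <- pe + w * sub$mu_photoelectric
    ic <- ic + w * sub$mu_incoherent
    co <- co + w * sub$mu_coherent
  }
  tab <- data.frame(energy_MeV = E, mu_photoelectric = pe, mu_incoherent = ic,
                    mu_coherent = co, mu_total = pe + ic + co)
  tab <- structure(tab, class = c("attenuation_table", "data.frame"),
                   material = name, has_mu_en = FALSE)
  structure(list(name = name, fractions = fractions, density = density,
                 attenuation = tab), class = "material")
}

#' Materials of the published source description
#'
#' The five materials with their elemental compositions and densities:
#' iridium (22.42), AISI 316L steel (7.8), AISI 304 steel at the cable's
#' effective density (5.6), liquid water (0.998) and dry air (1.197e-3 g/cm^3).
#'
#' @return named list of `material` objects.
#' @export
table1_materials <- function() {
  list(
    ir = build_material("ir", c(Ir = 100), 22.42),
    steel316l = build_material("steel316l",
      c(C = 0.03, N = 0.1, Si = 0.75, P = 0.045, S = 0.03, Cr = 17, Mn = 2,
        Fe = 65.545, Ni = 12, Mo = 2.5), 7.8),
    steel304 = build_material("steel304",
      c(C = 0.08, N = 0.1, Si = 0.75, P = 0.045, S = 0.03, Cr = 19, Mn = 2,
        Fe = 67.995, Ni = 10), 5.6),
    water = build_material("water", c(H = 11.1, O = 88.9), 0.998),
    air = build_material("air", c(C = 0.012, N = 75.527, O = 23.178,
                                  Ar = 1.283), 1.197e-3)
  )
}

#' Assemble the physics data used by the transport engine
#'
#' Bundles the per-material attenuation tables (from the package fixtures,
#' which carry mu_en/rho for water and air) with the densities of the source
#' description.
#'
#' @return an object of class `physics_set`.
#' @export
physics_set <- function() {
  mats <- c("ir", "steel316l", "steel304", "water", "air")
  tabs <- lapply(mats, load_attenuation)
  names(tabs) <- mats
  dens <- c(ir = 22.42, steel316l = 7.8, steel304 = 5.6, water = 0.998,
            air = 1.197e-3)
  structure(list(tables = tabs, densities = dens), class = "physics_set")
}

# matrix of log(E), log(linear mu per process) for the C++ engine
.xs_matrix <- function(physics, material) {
  tab <- physics$tables[[material]]
  rho <- physics$densities[[material]]
  cbind(log(tab$energy_MeV),
        log(tab$mu_photoelectric * rho),
        log(tab$mu_incoherent * rho),
        log(tab$mu_coherent * rho),
        log(tab$mu_total * rho))
}

# xs list for the C++ engine: core, capsule, cable, medium (+ medium muen).
# With coherent_in_mu = FALSE the attenuation column is photoelectric +
# incoherent only: coherent scattering is treated as transparent (its
# form-factor angular distribution is sharply forward-peaked at these
# energies, so the photon effectively continues undisturbed).
.xs_for_transport <- function(physics, medium, dose_medium = medium,
                              coherent_in_mu = FALSE) {
  one <- function(mat) {
    m <- .xs_matrix(physics, mat)
    if (!coherent_in_mu) m[, 5] <- log(exp(m[, 2]) + exp(m[, 3]))
    m
  }
  tabs <- list(one("ir"), one("steel316l"), one("steel304"),
               if (medium == "vacuum") matrix(numeric(0), 0, 5)
               else one(medium))
  if (dose_medium %in% c("water", "air")) {
    mt <- physics$tables[[dose_medium]]
    muen <- cbind(log(mt$energy_MeV), log(mt$mu_en))
  } else {
    muen <- matrix(numeric(0), 0, 2)
  }
  list(tables = tabs, muen = muen)
}
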