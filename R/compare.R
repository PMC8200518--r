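# Comparison against the published datasets: reference fixtures, relative
# differences, anisotropy-table comparison, and the deterministic report.

#' Published reference datasets
#'
#' The published S_K/A, dose-rate constant and g_L fit coefficients for both
#' spectra, the consensus reference scalars, and the published anisotropy
#' table (NNDC spectrum).
#'
#' @param label `"this-paper-NNDC"`, `"this-paper-DC"`, or `"consensus"`.
#' @return list with `Sk_per_A`, `Lambda`, and (where published)
#'   `gl_fit_coefficients` and `F` (long-format data frame).
#' @export
reference_dataset <- function(label = c("this-paper-NNDC", "this-paper-DC",
                                        "consensus")) {
  label <- match.arg(label)
  sc <- jsonlite::read_json(.extdata("reference", "published_scalars.json"),
                            simplifyVector = TRUE)
  out <- switch(label,
    "this-paper-NNDC" = list(Sk_per_A = sc$this_paper_nndc$Sk_per_A_U_per_Bq,
                             Lambda = sc$this_paper_nndc$Lambda_cGy_per_h_per_U,
                             gl_fit_coefficients = sc$this_paper_nndc$gl_fit_coefficients,
                             F = read_anisotropy_csv(
                               .extdata("reference", "table2_anisotropy_nndc.csv"))),
    "this-paper-DC" = list(Sk_per_A = sc$this_paper_dc$Sk_per_A_U_per_Bq,
                           Lambda = sc$this_paper_dc$Lambda_cGy_per_h_per_U,
                           gl_fit_coefficients = sc$this_paper_dc$gl_fit_coefficients),
    "consensus" = list(Sk_per_A = sc$consensus$Sk_per_A_U_per_Bq,
                       Lambda = sc$consensus$Lambda_cGy_per_h_per_U))
  c(out, list(label = label))
}

#' Read / write an anisotropy table in the published layout
#'
#' First column `theta_deg`, one column `r<value>` per radius; unavailable
#' cells hold `/`.  The reader keeps the original cell tokens so a
#' read-write round trip is byte-identical.
#'
#' @param path CSV path.
#' @return long-format data frame `r_cm`, `theta_deg`, `F` (NA for `/`),
#'   with the raw token matrix as attribute `tokens`.
#' @export
read_anisotropy_csv <- function(path) {
  raw <- read.csv(path, comment.char = "#", colClasses = "character",
                  check.names = FALSE)
  radii <- as.numeric(sub("^r", "", names(raw)[-1]))
  long <- do.call(rbind, lapply(seq_along(radii), function(j) {
    tok <- raw[[j + 1]]
    data.frame(r_cm = radii[j], theta_deg = as.numeric(raw[[1]]),
               F = suppressWarnings(as.numeric(ifelse(tok == "/", NA, tok))))
  }))
  attr(long, "tokens") <- raw
  attr(long, "radii") <- radii
  long
}

#' @rdname read_anisotropy_csv
#' @param f long-format anisotropy data (from [read_anisotropy_csv()] or
#'   [anisotropy_function()]); values are formatted to three decimals unless
#'   raw tokens are attached.
#' @param digits decimals for numeric formatting.
#' @param header comment lines to prepend.
#' @export
write_anisotropy_csv <- function(f, path, digits = 3, header = NULL) {
  tok <- attr(f, "tokens")
  if (is.null(tok)) {
    radii <- sort(unique(f$r_cm))
    thetas <- sort(unique(f$theta_deg))
    tok <- data.frame(theta_deg = format(thetas, trim = TRUE),
                      check.names = FALSE)
    for (r in radii) {
      sub <- f[abs(f$r_cm - r) < 1e-9, ]
      v <- sub$F[match(thetas, sub$theta_deg)]
      tok[[paste0("r", format(r, trim = TRUE))]] <-
        ifelse(is.na(v), "/", formatC(v, digits = digits, format = "f"))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  writeLines(paste(names(tok), collapse = ","), con)
  writeLines(do.call(paste, c(unname(tok), sep = ",")), con)
  invisible(path)
}

#' Relative difference in percent
#'
#' `100 * (value / reference - 1)`; exactly zero on equal inputs.
#'
#' @param value,reference numeric; `reference` must be non-zero.
#' @export
relative_difference <- function(value, reference) {
  if (any(reference == 0)) stop("zero reference", call. = FALSE)
  100 * (value / reference - 1)
}

#' Compare two anisotropy tables
#'
#' Cell-wise percent differences on the common (r, theta) grid (cells
#' unavailable in either table are excluded), with the summary statistics
#' used in the study: maximum absolute difference for 15 < theta < 165 deg,
#' maximum overall, and mean difference per radius.
#'
#' @param f_computed,f_reference long-format data frames (`r_cm`,
#'   `theta_deg`, `F`).
#' @return list with `cells` (data frame incl. `diff_pct`), `max_abs_mid`,
#'   `max_abs_all`, `mean_by_r`.
#' @export
compare_anisotropy <- function(f_computed, f_reference) {
  key <- function(d) paste(signif(d$r_cm, 8), signif(d$theta_deg, 8))
  m <- match(key(f_computed), key(f_reference))
  ok <- !is.na(m)
  cells <- data.frame(r_cm = f_computed$r_cm[ok],
                      theta_deg = f_computed$theta_deg[ok],
                      F = f_computed$F[ok],
                      F_ref = f_reference$F[m[ok]])
  cells <- cells[!is.na(cells$F) & !is.na(cells$F_ref), ]
  if (nrow(cells) == 0) stop("disjoint grids", call. = FALSE)
  cells$diff_pct <- relative_difference(cells$F, cells$F_ref)
  mid <- cells$theta_deg > 15 & cells$theta_deg < 165
  mean_by_r <- vapply(split(cells$diff_pct, cells$r_cm), mean, numeric(1))
  list(cells = cells,
       max_abs_mid = if (any(mid)) max(abs(cells$diff_pct[mid])) else NA_real_,
       max_abs_all = max(abs(cells$diff_pct)),
       mean_by_r = mean_by_r)
}

.fmt <- function(x, d = 4) formatC(x, digits = d, format = "g")

#' Render a deterministic comparison report
#'
#' Markdown text summarising scalars, their differences to the published and
#' consensus values, fit coefficients, the anisotropy comparison, and run
#' metadata.  Identical inputs give byte-identical output.
#'
#' @param results named list of per-spectrum results, each a list with
#'   `params` (a `tg43_parameters`) and optionally `air`
#'   (an `air_kerma_result`).
#' @param references named list of [reference_dataset()] lists keyed like
#'   `results`.
#' @param path optional output file.
#' @return character vector of report lines (invisibly if written).
#' @export
render_report <- function(results, references = list(), path = NULL) {
  lines <- c("# TG-43 dosimetry report", "")
  for (nm in names(results)) {
    res <- results[[nm]]
    p <- res$params
    lines <- c(lines, sprintf("## Spectrum: %s", nm), "")
    if (!is.null(p)) {
      lines <- c(lines,
        sprintf("- S_K/A = %s U/Bq", .fmt(p$Sk_per_A, 5)),
        sprintf("- Lambda = %s cGy/h/U (rel. unc. %s)", .fmt(p$Lambda, 5),
                .fmt(p$Lambda_rel_unc, 2)),
        sprintf("- g_L fit a0..a5: %s",
                paste(.fmt(p$fit$coefficients, 5), collapse = ", ")),
        sprintf("- g_L fit residual rms: %s", .fmt(p$fit$residual_rms, 3)))
      ref <- references[[nm]]
      if (!is.null(ref)) {
        lines <- c(lines,
          sprintf("- vs %s: S_K/A %+.2f%%, Lambda %+.2f%%", ref$label,
                  relative_difference(p$Sk_per_A, ref$Sk_per_A),
                  relative_difference(p$Lambda, ref$Lambda)))
        if (!is.null(ref$F) && !is.null(p$F)) {
          cmp <- compare_anisotropy(p$F, ref$F)
          lines <- c(lines,
            sprintf("- F vs %s: max |diff| %.2f%% (15<theta<165), %.2f%% overall",
                    ref$label, cmp$max_abs_mid, cmp$max_abs_all))
        }
      }
    }
    if (!is.null(res$air)) {
      lines <- c(lines, sprintf("- air run: %s histories, seed %s",
                                .fmt(res$air$histories, 8), res$air$seed))
    }
    if (!is.null(res$meta)) {
      lines <- c(lines, sprintf("- %s", res$meta))
    }
    lines <- c(lines, "")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
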