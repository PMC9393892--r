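# Quantitative spectral comparison: the normalized overlap integral between
# two spectra over a restricted frequency region, and the joint IR+VCD
# frequency-scaling search that maximizes it.

#' Restrict a spectrum to a frequency region
#'
#' Truncates the grid and intensities to `region` (order-insensitive;
#' endpoints included when on-grid).
#'
#' @param spec A `vcd_spectrum`.
#' @param region `c(lo, hi)` in cm^-1.
#' @return The truncated `vcd_spectrum`.
#' @export
restrict_region <- function(spec, region) {
  region <- sort(as.numeric(region))
  sel <- spec$wavenumber >= region[1] & spec$wavenumber <= region[2]
  if (sum(sel) < 2) stop("empty region", call. = FALSE)
  out <- spec[sel, ]
  class(out) <- class(spec)
  attr(out, "modality") <- attr(spec, "modality")
  attr(out, "fwhm") <- attr(spec, "fwhm")
  out
}

# Resample both spectra onto the finer of the two grids, restricted to region.
common_grid <- function(a, b, region = NULL) {
  lo <- max(min(a$wavenumber), min(b$wavenumber))
  hi <- min(max(a$wavenumber), max(b$wavenumber))
  if (!is.null(region)) {
    region <- sort(as.numeric(region))
    lo <- max(lo, region[1]); hi <- min(hi, region[2])
  }
  if (lo >= hi) stop("empty region", call. = FALSE)
  step <- min(min(diff(a$wavenumber)), min(diff(b$wavenumber)))
  nu <- seq(lo, hi, by = step)
  list(nu = nu,
       ia = stats::approx(a$wavenumber, a$intensity, xout = nu)$y,
       ib = stats::approx(b$wavenumber, b$intensity, xout = nu)$y)
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

#' Normalized overlap between two spectra
#'
#' The overlap estimate
#' `S_ab = int(I_a I_b) / sqrt(int(I_a^2) int(I_b^2))`
#' over the chosen region, with integrals evaluated by the trapezoid rule on
#' a common grid (both spectra linearly resampled to the finer of the two).
#' By Cauchy-Schwarz, `S_ab` lies in \[-1, 1\]: 1 means identical band
#' shapes, -1 a perfect mirror image (as for the VCD spectra of opposite
#' enantiomers). The value is symmetric in its arguments and invariant to
#' positive rescaling of either spectrum, so absolute intensity units never
#' matter.
#'
#' @param a,b `vcd_spectrum` objects.
#' @param region Optional `c(lo, hi)` in cm^-1; default is the grid overlap.
#' @return A single number in \[-1, 1\].
#' @export
overlap_estimate <- function(a, b, region = NULL) {
  g <- common_grid(a, b, region)
  na <- trapz(g$nu, g$ia^2)
  nb <- trapz(g$nu, g$ib^2)
  if (na == 0 || nb == 0)
    stop("undefined overlap (zero norm): a spectrum is identically zero in the region",
         call. = FALSE)
  s <- trapz(g$nu, g$ia * g$ib) / sqrt(na * nb)
  max(-1, min(1, s))
}

#' Optimize the frequency scaling factor against experiment
#'
#' Grid search over multiplicative frequency scaling factors `f`: for each
#' candidate, all stick spectra are scaled, rebuilt into Boltzmann-weighted
#' broadened IR and VCD ensemble spectra, and compared to the experimental
#' spectra via [overlap_estimate()] over `region`. The objective is the
#' weighted sum `S_IR + vcd_weight * S_VCD` (equal weighting by default);
#' the maximizing `f` is returned, with ties broken toward the factor
#' closest to 1.
#'
#' @param calc_ir,calc_vcd Lists of `vcd_sticks` (one per conformer). Either
#'   may be `NULL` to compare a single modality.
#' @param weights A `vcd_weights` tibble matching the stick spectra.
#' @param exp_ir,exp_vcd Experimental `vcd_spectrum` objects (required for
#'   the corresponding calculated set).
#' @param region `c(lo, hi)` comparison region in cm^-1 (default 1800-1500,
#'   the amide I+II window).
#' @param f_range `c(lo, hi, step)` for the factor search; default
#'   0.94-1.01 in steps of 0.001, covering the factors typical of hybrid
#'   density functionals.
#' @param fwhm Lorentzian width in cm^-1.
#' @param vcd_weight Weight of the VCD overlap in the combined objective.
#' @param match_intensities If `TRUE` (default), the returned result records
#'   the IR intensity factor matching the strongest calculated band to the
#'   experimental one at the optimal `f`.
#' @return A `vcd_comparison` object: list with elements `s_ir`, `s_vcd`,
#'   `scaling_factor`, `region`, `intensity_factor`, `scan` (tibble of `f`,
#'   `s_ir`, `s_vcd`, `objective`), and the matched spectra `ir`, `vcd`.
#' @export
optimize_scaling <- function(calc_ir = NULL, calc_vcd = NULL, weights,
                             exp_ir = NULL, exp_vcd = NULL,
                             region = c(1500, 1800),
                             f_range = c(0.94, 1.01, 0.001),
                             fwhm = 10, vcd_weight = 1,
                             match_intensities = TRUE) {
  if (is.null(calc_ir) && is.null(calc_vcd))
    stop("need at least one calculated stick-spectrum set", call. = FALSE)
  if (!is.null(calc_ir) && is.null(exp_ir))
    stop("experimental IR spectrum required", call. = FALSE)
  if (!is.null(calc_vcd) && is.null(exp_vcd))
    stop("experimental VCD spectrum required", call. = FALSE)
  region <- sort(as.numeric(region))
  fs <- seq(f_range[[1]], f_range[[2]], by = f_range[[3]])
  # pad the build grid so every scaled stick keeps its full band inside
  pad_grid <- function(lst) {
    g <- default_grid(lst)
    c(lo = max(1, floor(g[["lo"]] * f_range[[1]] - 5 * fwhm)),
      hi = ceiling(g[["hi"]] * f_range[[2]] + 5 * fwhm), step = g[["step"]])
  }
  grid_ir <- if (!is.null(calc_ir)) pad_grid(calc_ir)
  grid_vcd <- if (!is.null(calc_vcd)) pad_grid(calc_vcd)
  eval_f <- function(f) {
    s_ir <- s_vcd <- NA_real_
    if (!is.null(calc_ir)) {
      spec <- ensemble_spectrum(lapply(calc_ir, scale_frequencies, f = f),
                                weights, fwhm = fwhm, grid_spec = grid_ir)
      s_ir <- overlap_estimate(spec, exp_ir, region = region)
    }
    if (!is.null(calc_vcd)) {
      spec <- ensemble_spectrum(lapply(calc_vcd, scale_frequencies, f = f),
                                weights, fwhm = fwhm, grid_spec = grid_vcd)
      s_vcd <- overlap_estimate(spec, exp_vcd, region = region)
    }
    c(s_ir = s_ir, s_vcd = s_vcd,
      objective = sum(c(s_ir, vcd_weight * s_vcd), na.rm = TRUE))
  }
  scan <- t(vapply(fs, eval_f, c(s_ir = 0, s_vcd = 0, objective = 0)))
  scan <- tibble::tibble(f = fs, s_ir = scan[, "s_ir"],
                         s_vcd = scan[, "s_vcd"],
                         objective = scan[, "objective"])
  best_obj <- max(scan$objective)
  cand <- which(scan$objective >= best_obj - 1e-12)
  best <- cand[which.min(abs(fs[cand] - 1))]
  f_opt <- fs[best]
  ir_out <- vcd_out <- NULL
  intensity_factor <- NA_real_
  if (!is.null(calc_ir)) {
    ir_out <- ensemble_spectrum(lapply(calc_ir, scale_frequencies, f = f_opt),
                                weights, fwhm = fwhm, grid_spec = grid_ir)
    if (match_intensities) {
      m <- match_intensity(restrict_region(ir_out, region),
                           restrict_region(exp_ir, region))
      intensity_factor <- m$factor
    }
  }
  if (!is.null(calc_vcd))
    vcd_out <- ensemble_spectrum(lapply(calc_vcd, scale_frequencies, f = f_opt),
                                 weights, fwhm = fwhm, grid_spec = grid_vcd)
  structure(
    list(s_ir = unname(scan$s_ir[best]), s_vcd = unname(scan$s_vcd[best]),
         scaling_factor = f_opt, region = region,
         intensity_factor = intensity_factor, scan = scan,
         ir = ir_out, vcd = vcd_out, fwhm = fwhm),
    class = "vcd_comparison")
}

#' @export
print.vcd_comparison <- function(x, ...) {
  cat("Spectral comparison (normalized overlap)\n")
  cat(sprintf("  region: %g-%g cm^-1, fwhm %g cm^-1\n",
              x$region[1], x$region[2], x$fwhm))
  cat(sprintf("  scaling factor f = %.3f\n", x$scaling_factor))
  if (is.finite(x$s_ir %||% NA)) cat(sprintf("  S(IR)  = %.3f\n", x$s_ir))
  if (is.finite(x$s_vcd %||% NA)) cat(sprintf("  S(VCD) = %.3f\n", x$s_vcd))
  invisible(x)
}

#' Tidy a spectral comparison
#'
#' @param x A `vcd_comparison` from [optimize_scaling()].
#' @param ... Unused.
#' @return One row per modality: `modality`, `overlap`, `scaling_factor`,
#'   `region_lo`, `region_hi`.
#' @method tidy vcd_comparison
#' @export
tidy.vcd_comparison <- function(x, ...) {
  rows <- list()
  if (is.finite(x$s_ir %||% NA))
    rows <- c(rows, list(tibble::tibble(modality = "IR", overlap = x$s_ir)))
  if (is.finite(x$s_vcd %||% NA))
    rows <- c(rows, list(tibble::tibble(modality = "VCD", overlap = x$s_vcd)))
  dplyr::bind_rows(rows) |>
    dplyr::mutate(scaling_factor = x$scaling_factor,
                  region_lo = x$region[1], region_hi = x$region[2])
}

#' Glance at a spectral comparison
#'
#' @inheritParams tidy.vcd_comparison
#' @return A one-row tibble with the combined objective and its components.
#' @method glance vcd_comparison
#' @export
glance.vcd_comparison <- function(x, ...) {
  tibble::tibble(s_ir = x$s_ir, s_vcd = x$s_vcd,
                 objective = sum(c(x$s_ir, x$s_vcd), na.rm = TRUE),
                 scaling_factor = x$scaling_factor,
                 intensity_factor = x$intensity_factor,
                 n_scan = nrow(x$scan))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
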