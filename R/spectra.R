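# Stick spectra (frequency, strength pairs from a harmonic frequency job),
# Lorentzian broadening into continuous spectra, frequency scaling, and
# Boltzmann-weighted ensemble averaging.

#' Construct a stick spectrum
#'
#' A stick spectrum pairs each vibrational frequency with its intensity
#' quantity: dipole strength for IR (non-negative, conventionally in
#' 10^-40 esu^2 cm^2) or rotational strength for VCD (signed, in
#' 10^-44 esu^2 cm^2).
#'
#' @param frequency Frequencies in cm^-1; strictly positive. Stored sorted
#'   ascending.
#' @param strength Strengths, same length as `frequency`.
#' @param modality `"IR"` or `"VCD"`.
#' @param label Conformer label the sticks belong to.
#' @return A `vcd_sticks` tibble with columns `frequency`, `strength` and
#'   attributes `modality`, `label`.
#' @export
stick_spectrum <- function(frequency, strength, modality = c("IR", "VCD"),
                           label = "1") {
  modality <- match.arg(modality)
  stopifnot(length(frequency) == length(strength))
  if (length(frequency) && any(frequency <= 0))
    stop("frequencies must be strictly positive", call. = FALSE)
  if (modality == "IR" && length(strength) && any(strength < 0))
    stop("IR dipole strengths must be non-negative", call. = FALSE)
  ord <- order(frequency)
  out <- tibble::tibble(frequency = as.numeric(frequency[ord]),
                        strength = as.numeric(strength[ord]))
  attr(out, "modality") <- modality
  attr(out, "label") <- as.character(label)
  class(out) <- c("vcd_sticks", class(out))
  out
}

#' Construct a continuous spectrum on a uniform wavenumber grid
#'
#' @param wavenumber Ascending, uniformly spaced grid in cm^-1.
#' @param intensity Intensity at each grid point.
#' @param modality `"IR"` or `"VCD"`.
#' @param fwhm,scale Optional provenance metadata (broadening width, cm^-1;
#'   frequency scaling factor applied).
#' @return A `vcd_spectrum` tibble with columns `wavenumber`, `intensity`.
#' @export
continuous_spectrum <- function(wavenumber, intensity,
                                modality = c("IR", "VCD"),
                                fwhm = NA_real_, scale = NA_real_) {
  modality <- match.arg(modality)
  stopifnot(length(wavenumber) == length(intensity), length(wavenumber) >= 2)
  steps <- diff(wavenumber)
  if (any(steps <= 0) || diff(range(steps)) > 1e-9)
    stop("grid must be ascending and uniform", call. = FALSE)
  out <- tibble::tibble(wavenumber = as.numeric(wavenumber),
                        intensity = as.numeric(intensity))
  attr(out, "modality") <- modality
  attr(out, "fwhm") <- fwhm
  attr(out, "scale") <- scale
  class(out) <- c("vcd_spectrum", class(out))
  out
}

spectrum_modality <- function(x) attr(x, "modality") %||% "IR"

#' Scale the frequencies of a stick spectrum
#'
#' Multiplies every frequency by a factor, leaving strengths untouched. A
#' multiplicative scaling factor is the standard correction for the
#' systematic overestimation of harmonic frequencies by the electronic
#' structure method.
#'
#' @param sticks A `vcd_sticks` tibble.
#' @param f Positive dimensionless factor.
#' @return The scaled `vcd_sticks`.
#' @export
scale_frequencies <- function(sticks, f) {
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f <= 0)
    stop("invalid scaling factor", call. = FALSE)
  sticks$frequency <- sticks$frequency * f
  sticks
}

default_grid <- function(sticks_list, step = 1, pad = 100) {
  freqs <- unlist(lapply(sticks_list, function(s) s$frequency))
  if (!length(freqs)) stop("no sticks to derive a grid from", call. = FALSE)
  lo <- max(step, floor(min(freqs) - pad))
  hi <- ceiling(max(freqs) + pad)
  c(lo = lo, hi = hi, step = step)
}

grid_points <- function(grid_spec) {
  seq(grid_spec[[1]], grid_spec[[2]], by = grid_spec[[3]])
}

#' Broaden a stick spectrum with Lorentzian line shapes
#'
#' Each stick contributes `strength * nu * L(nu - nu_i; fwhm) * C`, where
#' `L(x; G) = (G / (2 pi)) / (x^2 + (G/2)^2)` is the unit-area Lorentzian and
#' `C` converts dipole/rotational strength to molar absorptivity (the factor
#' cancels in normalized overlap comparisons). The resulting band attains
#' half its peak height at approximately `nu_i +/- fwhm/2`.
#'
#' @param sticks A `vcd_sticks` tibble.
#' @param fwhm Full width at half maximum in cm^-1 (default 10, the value
#'   typically used for amide-region peptide spectra; 16 is common for
#'   spectra measured with broader bands).
#' @param grid_spec `c(lo, hi, step)` in cm^-1; default spans the sticks
#'   padded by 100 cm^-1 at step 1.
#' @return A `vcd_spectrum` on the requested grid.
#' @export
lorentzian_broaden <- function(sticks, fwhm = 10, grid_spec = NULL) {
  stopifnot(fwhm > 0)
  if (is.null(grid_spec)) grid_spec <- default_grid(list(sticks))
  stopifnot(grid_spec[[1]] < grid_spec[[2]], grid_spec[[3]] > 0)
  nu <- grid_points(grid_spec)
  modality <- spectrum_modality(sticks)
  cmod <- if (modality == "VCD") .const$vcd_epsilon else .const$ir_epsilon
  intensity <- rep(0, length(nu))
  if (nrow(sticks)) {
    lo_cov <- min(sticks$frequency) - 5 * fwhm
    hi_cov <- max(sticks$frequency) + 5 * fwhm
    if (nu[1] > lo_cov || nu[length(nu)] < hi_cov)
      warning("grid does not cover all sticks +/- 5*fwhm; band tails truncated",
              call. = FALSE)
    hw2 <- (fwhm / 2)^2
    for (k in seq_len(nrow(sticks))) {
      lor <- (fwhm / (2 * pi)) / ((nu - sticks$frequency[k])^2 + hw2)
      intensity <- intensity + sticks$strength[k] * cmod * nu * lor
    }
  }
  continuous_spectrum(nu, intensity, modality = modality, fwhm = fwhm)
}

#' Boltzmann-weighted ensemble spectrum
#'
#' Broadened spectra of all conformers combined as `sum_i w_i * spectrum_i`
#' on a common grid. Weights and stick spectra are matched by conformer
#' label; every weighted conformer must supply a stick spectrum of the same
#' modality.
#'
#' @param sticks_list List of `vcd_sticks`, one per conformer (matched to
#'   `weights$label` via their `label` attribute).
#' @param weights A `vcd_weights` tibble.
#' @param fwhm Lorentzian width, cm^-1.
#' @param grid_spec `c(lo, hi, step)`; default derived from all sticks.
#' @return A `vcd_spectrum`.
#' @export
ensemble_spectrum <- function(sticks_list, weights, fwhm = 10,
                              grid_spec = NULL) {
  labs <- vapply(sticks_list, function(s) attr(s, "label"), character(1))
  if (!setequal(labs, weights$label) || anyDuplicated(labs))
    stop("inconsistent ensemble: stick-spectrum labels do not match weights",
         call. = FALSE)
  mods <- unique(vapply(sticks_list, spectrum_modality, character(1)))
  if (length(mods) != 1L)
    stop("inconsistent ensemble: mixed modalities", call. = FALSE)
  if (is.null(grid_spec)) grid_spec <- default_grid(sticks_list)
  w <- stats::setNames(weights$weight, weights$label)
  acc <- NULL
  for (s in sticks_list) {
    b <- lorentzian_broaden(s, fwhm = fwhm, grid_spec = grid_spec)
    contrib <- w[[attr(s, "label")]] * b$intensity
    acc <- if (is.null(acc)) contrib else acc + contrib
  }
  continuous_spectrum(grid_points(grid_spec), acc, modality = mods,
                      fwhm = fwhm)
}

#' Match the intensity of a calculated spectrum to a reference
#'
#' Multiplies the calculated spectrum so that the maximum absolute intensity
#' of its strongest band equals that of the reference (for VCD the band of
#' maximum absolute intensity is used, so sign is preserved). The reference
#' is linearly resampled onto the calculated grid before comparison.
#'
#' @param calc,ref `vcd_spectrum` objects with overlapping grids.
#' @return List with `spectrum` (scaled calc) and `factor`.
#' @export
match_intensity <- function(calc, ref) {
  mc <- max(abs(calc$intensity))
  if (mc == 0) stop("cannot scale zero spectrum", call. = FALSE)
  ri <- stats::approx(ref$wavenumber, ref$intensity, xout = calc$wavenumber,
                      rule = 1)$y
  if (all(is.na(ri))) stop("spectra do not overlap", call. = FALSE)
  factor <- max(abs(ri), na.rm = TRUE) / mc
  out <- calc
  out$intensity <- out$intensity * factor
  list(spectrum = out, factor = factor)
}

#' Extract the sign pattern of bands in a region
#'
#' Locates local extrema of the spectrum inside `region` with absolute
#' intensity at least `min_prominence` times the region's maximum absolute
#' intensity, and reports them from high to low frequency with their sign.
#' This reproduces the way VCD band patterns are conventionally quoted, e.g.
#' "-/+/+/-" for the amide I region.
#'
#' @param spec A `vcd_spectrum`.
#' @param region `c(lo, hi)` in cm^-1 (order-insensitive).
#' @param min_prominence Fraction of the region's maximum absolute intensity
#'   below which extrema are ignored (default 0.05).
#' @return Tibble with `wavenumber`, `intensity`, `sign` (+1/-1), ordered by
#'   descending wavenumber; attribute `pattern` gives the compact string.
#' @export
sign_pattern <- function(spec, region, min_prominence = 0.05) {
  region <- sort(as.numeric(region))
  sel <- spec$wavenumber >= region[1] & spec$wavenumber <= region[2]
  if (!any(sel)) stop("empty region", call. = FALSE)
  x <- spec$wavenumber[sel]
  y <- spec$intensity[sel]
  n <- length(y)
  thr <- min_prominence * max(abs(y))
  peaks <- integer(0)
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      if (abs(y[i]) < thr) next
      if ((y[i] > 0 && y[i] >= y[i - 1] && y[i] > y[i + 1]) ||
          (y[i] < 0 && y[i] <= y[i - 1] && y[i] < y[i + 1]))
        peaks <- c(peaks, i)
    }
  }
  ord <- order(x[peaks], decreasing = TRUE)
  out <- tibble::tibble(wavenumber = x[peaks][ord],
                        intensity = y[peaks][ord],
                        sign = sign(y[peaks][ord]))
  attr(out, "pattern") <- paste(ifelse(out$sign >= 0, "+", "-"),
                                collapse = "/")
  out
}
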