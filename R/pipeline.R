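# End-to-end pipeline on precomputed per-conformer results: energy-window
# selection -> duplicate removal -> Boltzmann weights -> ensemble spectra ->
# optional comparison against experiment, with a JSON manifest recording
# every parameter and intermediate count.

#' Pipeline configuration
#'
#' Bundles all inputs and protocol parameters of one run. Only `xyz` and
#' `freq_dir` are required; the remaining paths are optional stages.
#'
#' @param xyz Multi-XYZ ensemble path.
#' @param freq_dir Directory of `freq_<label>.tsv` frequency tables.
#' @param energies Optional energy CSV (overrides XYZ comment energies).
#' @param exp_ir,exp_vcd Optional experimental two-column spectra; when both
#'   are given the comparison stage runs.
#' @param out_dir Output directory for artifacts.
#' @param window Energy window for the single-point selection, kcal/mol.
#' @param sp_field Energy field for window selection and dedup ordering.
#' @param weight_field Energy field for Boltzmann weighting.
#' @param temperature Temperature in K.
#' @param thresholds Duplicate thresholds from [dedup_thresholds()].
#' @param fwhm Lorentzian width, cm^-1.
#' @param region Comparison region `c(lo, hi)`, cm^-1.
#' @param f_range Scaling-factor search `c(lo, hi, step)`.
#' @param cutoff Significance cutoff on Boltzmann weights (reporting).
#' @param significant_only If `TRUE`, restrict spectral averaging to
#'   conformers above `cutoff` (renormalized); default `FALSE`, averaging
#'   over all retained unique conformers.
#' @return A `run_config` list.
#' @export
run_config <- function(xyz, freq_dir, energies = NULL,
                       exp_ir = NULL, exp_vcd = NULL,
                       out_dir = tempfile("vcdrun"),
                       window = 2.5, sp_field = "electronic",
                       weight_field = "gibbs", temperature = 298.15,
                       thresholds = dedup_thresholds(), fwhm = 10,
                       region = c(1500, 1800),
                       f_range = c(0.94, 1.01, 0.001),
                       cutoff = 0.05, significant_only = FALSE) {
  structure(list(xyz = xyz, freq_dir = freq_dir, energies = energies,
                 exp_ir = exp_ir, exp_vcd = exp_vcd, out_dir = out_dir,
                 window = window, sp_field = sp_field,
                 weight_field = weight_field, temperature = temperature,
                 thresholds = thresholds, fwhm = fwhm, region = region,
                 f_range = f_range, cutoff = cutoff,
                 significant_only = significant_only),
            class = "run_config")
}

#' Run the post-processing pipeline
#'
#' Stages, mirroring the conformer bookkeeping of an ensemble VCD protocol:
#' read the ensemble (conformers "found"), keep those within the energy
#' window of the most stable one, remove duplicates ("unique"), compute
#' Boltzmann weights and count significant conformers, average the stick
#' spectra into broadened IR and VCD ensemble spectra, and — when
#' experimental spectra are supplied — optimize the frequency scaling and
#' report overlap estimates. Artifacts (report CSVs, spectra, manifest
#' JSON) are written to `config$out_dir`; any stage error removes partial
#' artifacts and aborts with a stage-tagged message. Reruns with the same
#' config produce byte-identical manifests.
#'
#' @param config A [run_config()].
#' @return List with `manifest` (named list, also written as JSON),
#'   `weights`, `spectra` (list of `vcd_spectrum`), and `comparison`
#'   (a `vcd_comparison` or `NULL`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(fn, name, ...) {
    path <- file.path(config$out_dir, name)
    fn(..., path)
    written <<- c(written, path)
    path
  }
  stage <- "input"
  tryCatch({
    ens <- read_multixyz(config$xyz)
    if (!is.null(config$energies))
      ens <- attach_energies(ens, read_energy_csv(config$energies))
    n_found <- nrow(ens)

    stage <- "window"
    inwin <- energy_window_filter(ens, window = config$window,
                                  energy_field = config$sp_field)
    n_window <- nrow(inwin)

    stage <- "dedup"
    pruned <- prune_duplicates(inwin, thr = config$thresholds,
                               energy_field = config$sp_field)
    uniq <- pruned$ensemble
    n_unique <- nrow(uniq)
    emit(function(x, p) utils::write.csv(x, p, row.names = FALSE),
         "dedup_report.csv", pruned$report)

    stage <- "weights"
    w <- boltzmann_weights(uniq, energy_field = config$weight_field,
                           temperature = config$temperature)
    signif_labels <- significant_conformers(w, cutoff = config$cutoff)
    n_signif <- length(signif_labels)
    emit(function(x, p) utils::write.csv(x, p, row.names = FALSE),
         "weights.csv", as.data.frame(w))
    w_avg <- w
    if (config$significant_only) {
      w_avg <- w[w$label %in% signif_labels, ]
      w_avg$weight <- w_avg$weight / sum(w_avg$weight)
      attr(w_avg, "energy_field") <- attr(w, "energy_field")
    }

    stage <- "spectra"
    tables <- lapply(w_avg$label, function(lab) {
      read_frequency_table(
        file.path(config$freq_dir, sprintf("freq_%s.tsv", lab)), "tsv",
        label = lab)
    })
    names(tables) <- w_avg$label
    sticks_ir <- lapply(tables, freq_sticks, modality = "IR")
    sticks_vcd <- lapply(tables, freq_sticks, modality = "VCD")
    spec_ir <- ensemble_spectrum(sticks_ir, w_avg, fwhm = config$fwhm)
    spec_vcd <- ensemble_spectrum(sticks_vcd, w_avg, fwhm = config$fwhm)
    emit(write_spectrum, "spectrum_ir.txt", spec_ir)
    emit(write_spectrum, "spectrum_vcd.txt", spec_vcd)
    stick_rows <- dplyr::bind_rows(lapply(names(tables), function(lab) {
      tibble::tibble(conformer = lab,
                     frequency = tables[[lab]]$frequency,
                     dipole_strength = tables[[lab]]$dipole_strength,
                     rotational_strength = tables[[lab]]$rotational_strength,
                     weight = w_avg$weight[match(lab, w_avg$label)])
    }))
    emit(function(x, p) utils::write.csv(x, p, row.names = FALSE),
         "sticks.csv", stick_rows)

    comparison <- NULL
    if (!is.null(config$exp_ir) && !is.null(config$exp_vcd)) {
      stage <- "compare"
      exp_ir <- read_experimental(config$exp_ir, "IR")
      exp_vcd <- read_experimental(config$exp_vcd, "VCD")
      comparison <- optimize_scaling(
        calc_ir = sticks_ir, calc_vcd = sticks_vcd, weights = w_avg,
        exp_ir = exp_ir, exp_vcd = exp_vcd, region = config$region,
        f_range = config$f_range, fwhm = config$fwhm)
      emit(function(x, p) utils::write.csv(x, p, row.names = FALSE),
           "scaling_scan.csv", comparison$scan)
      emit(function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE,
                                               digits = NA),
           "comparison.json",
           list(s_ir = comparison$s_ir, s_vcd = comparison$s_vcd,
                scaling_factor = comparison$scaling_factor,
                intensity_factor = comparison$intensity_factor,
                region = comparison$region))
    }

    stage <- "manifest"
    manifest <- list(
      parameters = list(
        window_kcal = config$window, sp_field = config$sp_field,
        weight_field = config$weight_field,
        temperature_K = config$temperature,
        energy_thr_kcal = config$thresholds$energy_thr,
        rmsd_thr_A = config$thresholds$rmsd_thr,
        rotconst_rel_thr = config$thresholds$rotconst_rel_thr,
        fwhm_cm = config$fwhm, region_cm = config$region,
        f_range = config$f_range, cutoff = config$cutoff,
        significant_only = config$significant_only),
      counts = list(found = n_found, within_window = n_window,
                    unique = n_unique, significant = n_signif),
      significant_labels = signif_labels,
      scaling_factor = if (!is.null(comparison)) comparison$scaling_factor,
      overlap = if (!is.null(comparison))
        list(ir = comparison$s_ir, vcd = comparison$s_vcd))
    emit(function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE,
                                             digits = NA, null = "null"),
         "manifest.json", manifest)

    list(manifest = manifest, weights = w,
         spectra = list(ir = spec_ir, vcd = spec_vcd),
         comparison = comparison)
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}
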