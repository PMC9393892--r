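# Seeded synthetic fixtures: toy ring-like conformer ensembles with planted
# duplicate groups, frequency tables with controllable signed band structure,
# and pseudo-experimental spectra with a planted frequency-scale distortion.
# Fixtures are geometric toys, not chemically valid peptides: every
# computation in the pipeline depends only on coordinates, energies,
# frequencies and strengths, none on chemical validity. Each generator runs
# in its own seeded RNG stream so adding one never perturbs another.

#' Specification for a synthetic fixture
#'
#' Defaults emulate the statistical structure of a small cyclic-peptide
#' study: a ring-like backbone, a handful of low-energy conformers spread
#' over a few kcal/mol, rotamer-like duplicates differing by sub-threshold
#' noise, a four-band signed amide-I pattern, and a frequency-scale
#' distortion typical of a hybrid functional (0.975).
#'
#' @param n_atoms Atoms in the toy ring.
#' @param n_conformers Number of genuinely distinct conformers.
#' @param n_duplicate_pairs Extra conformers planted as duplicates of
#'   distinct ones.
#' @param duplicate_noise Per-atom coordinate noise (Angstrom) for planted
#'   duplicates; must stay below `conformer_noise`.
#' @param conformer_noise Per-atom coordinate noise (Angstrom) separating
#'   distinct conformers.
#' @param energy_spread Spread of distinct-conformer energies, kcal/mol.
#' @param band_centers,band_signs Vibrational band centers (cm^-1) and VCD
#'   signs (+1/-1) shared by all conformers.
#' @param planted_scale Frequency-scale factor relating the calculated
#'   frequencies to the pseudo-experiment.
#' @param noise_sd Gaussian intensity noise in the pseudo-experiment, as a
#'   fraction of the maximum absolute intensity.
#' @param seed Integer seed; mandatory, all randomness is reproducible.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_atoms = 12, n_conformers = 5,
                         n_duplicate_pairs = 2,
                         duplicate_noise = 0.02, conformer_noise = 0.8,
                         energy_spread = 3.0,
                         band_centers = c(1673, 1668, 1650, 1643),
                         band_signs = c(-1, 1, 1, -1),
                         planted_scale = 0.975, noise_sd = 0, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (duplicate_noise >= conformer_noise)
    stop("duplicate_noise must be below conformer_noise", call. = FALSE)
  stopifnot(n_atoms >= 3, n_conformers >= 1, n_duplicate_pairs >= 0,
            length(band_centers) == length(band_signs),
            all(band_signs %in% c(-1, 1)), planted_scale > 0, noise_sd >= 0)
  structure(list(n_atoms = n_atoms, n_conformers = n_conformers,
                 n_duplicate_pairs = n_duplicate_pairs,
                 duplicate_noise = duplicate_noise,
                 conformer_noise = conformer_noise,
                 energy_spread = energy_spread,
                 band_centers = band_centers, band_signs = band_signs,
                 planted_scale = planted_scale, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# Evaluate fn under a derived seed without disturbing the caller's RNG.
with_stream <- function(seed, offset, fn) {
  withr::with_seed((seed + offset) %% .Machine$integer.max, fn())
}

random_rotation <- function() {
  qr_res <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_res)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

ring_geometry <- function(n_atoms, radius = 3) {
  th <- 2 * pi * (seq_len(n_atoms) - 1) / n_atoms
  cbind(radius * cos(th), radius * sin(th),
        0.4 * sin(3 * th))  # pucker so the ring is non-planar
}

#' Generate a toy ensemble with planted duplicate groups
#'
#' Distinct conformers are supra-threshold perturbations of a puckered
#' carbon ring with energies evenly spread over `energy_spread` (far apart
#' relative to the duplicate energy threshold). Each planted duplicate
#' copies a distinct conformer, applies sub-threshold coordinate noise plus
#' a random rigid motion and an energy jitter of at most half the energy
#' threshold; the noise is shrunk geometrically until all three duplicate
#' criteria hold with a safety margin, so the planted partition is exact by
#' construction. Gibbs and enthalpy fields carry small seeded
#' thermochemistry-like offsets from the electronic energy.
#'
#' @param spec A [fixture_spec()].
#' @param thr Thresholds the duplicates are planted against.
#' @return List with `ensemble` (a `vcd_ensemble`) and `groups`, a tibble
#'   mapping every label to its planted duplicate-group id.
#' @export
make_ensemble <- function(spec, thr = dedup_thresholds()) {
  if (spec$duplicate_noise >= thr$rmsd_thr)
    stop("contradictory spec: duplicate_noise at or above the RMSD threshold",
         call. = FALSE)
  with_stream(spec$seed, 1L, function() {
    base <- ring_geometry(spec$n_atoms)
    atoms <- rep("C", spec$n_atoms)
    n <- spec$n_conformers
    de <- if (n == 1) 0 else (seq_len(n) - 1) / (n - 1) * spec$energy_spread
    e0 <- -100.0
    distinct <- vector("list", n)
    for (k in seq_len(n)) {
      pert <- base + matrix(stats::rnorm(3 * spec$n_atoms,
                                         sd = spec$conformer_noise),
                            ncol = 3)
      e <- e0 + de[k] / .const$hartree_kcal
      gcorr <- 0.08 + stats::rnorm(1, sd = 0.3 / .const$hartree_kcal)
      distinct[[k]] <- conformer(atoms, pert, label = sprintf("c%02d", k),
                                 electronic = e, enthalpy = e + 0.05,
                                 gibbs = e + gcorr)
    }
    dup_of <- if (spec$n_duplicate_pairs > 0)
      sample(seq_len(n), spec$n_duplicate_pairs, replace = n < spec$n_duplicate_pairs)
    else integer(0)
    dups <- vector("list", length(dup_of))
    for (d in seq_along(dup_of)) {
      src <- distinct[[dup_of[d]]]
      noise <- spec$duplicate_noise
      repeat {
        cand_xyz <- (src$coords[[1]] +
          matrix(stats::rnorm(3 * spec$n_atoms, sd = noise), ncol = 3)) %*%
          random_rotation()
        cand_xyz <- sweep(cand_xyz, 2, stats::runif(3, -5, 5), `+`)
        ejit <- stats::runif(1, -0.5, 0.5) * thr$energy_thr /
          .const$hartree_kcal
        cand <- conformer(src$atoms[[1]], cand_xyz,
                          label = sprintf("d%02d", d),
                          electronic = src$electronic + ejit,
                          enthalpy = src$enthalpy + ejit,
                          gibbs = src$gibbs + ejit)
        m <- is_duplicate(src, cand, thr = thr)
        if (m$duplicate && m$rmsd_A <= 0.8 * thr$rmsd_thr &&
            m$db_rel <= 0.8 * thr$rotconst_rel_thr) break
        noise <- noise / 2
      }
      dups[[d]] <- cand
    }
    ens <- do.call(bind_conformers, c(distinct, dups))
    groups <- tibble::tibble(
      label = ens$label,
      group = c(seq_len(n), dup_of))
    list(ensemble = ens, groups = groups)
  })
}

#' Generate per-conformer frequency tables
#'
#' Each conformer receives one vibrational mode per entry of
#' `band_centers`, jittered by a small per-conformer shift (sd 1.5 cm^-1).
#' VCD rotational strengths carry `band_signs` with seeded random
#' magnitudes; IR dipole strengths are positive. Passing the printed band
#' centers and signs of an assigned experimental table yields fixtures with
#' that table's sign pattern.
#'
#' @param spec A [fixture_spec()].
#' @param ensemble The ensemble the tables belong to.
#' @return Named list of `vcd_freqtable`, one per conformer label.
#' @export
make_frequency_tables <- function(spec, ensemble) {
  with_stream(spec$seed, 2L, function() {
    out <- lapply(ensemble$label, function(lab) {
      freq <- spec$band_centers +
        stats::rnorm(length(spec$band_centers), sd = 1.5)
      ord <- order(freq)  # signs stay attached to their bands
      tab <- tibble::tibble(
        mode = seq_along(freq),
        frequency = freq[ord],
        dipole_strength = stats::runif(length(freq), 50, 200)[ord],
        rotational_strength = (spec$band_signs *
                                 stats::runif(length(freq), 40, 120))[ord])
      attr(tab, "label") <- lab
      class(tab) <- c("vcd_freqtable", class(tab))
      tab
    })
    stats::setNames(out, ensemble$label)
  })
}

#' Generate pseudo-experimental spectra with a planted scale distortion
#'
#' Builds the Boltzmann-weighted ensemble IR and VCD spectra from the
#' frequency tables, multiplies the frequency axis by `planted_scale`
#' (emulating the systematic harmonic-frequency error the scaling search
#' must recover), and adds seeded Gaussian intensity noise of standard
#' deviation `noise_sd * max(|I|)` per modality.
#'
#' @param tables Named list of `vcd_freqtable` from
#'   [make_frequency_tables()].
#' @param weights A `vcd_weights` for the same labels.
#' @param spec A [fixture_spec()].
#' @param fwhm Lorentzian width, cm^-1.
#' @return List with `ir` and `vcd` `vcd_spectrum` objects.
#' @export
make_pseudo_experiment <- function(tables, weights, spec, fwhm = 10) {
  with_stream(spec$seed, 3L, function() {
    build <- function(modality) {
      sticks <- lapply(tables, freq_sticks, modality = modality)
      sticks <- lapply(sticks, scale_frequencies, f = spec$planted_scale)
      s <- ensemble_spectrum(sticks, weights, fwhm = fwhm)
      if (spec$noise_sd > 0)
        s$intensity <- s$intensity +
          stats::rnorm(length(s$intensity),
                       sd = spec$noise_sd * max(abs(s$intensity)))
      s
    }
    list(ir = build("IR"), vcd = build("VCD"))
  })
}

#' Write a complete fixture directory
#'
#' Materializes a fixture on disk in the pipeline's interchange formats:
#' `ensemble.xyz` (multi-XYZ), `energies.csv`, one `freq_<label>.tsv` per
#' conformer, `exp_ir.txt` / `exp_vcd.txt` two-column spectra, and
#' `ground_truth.json` recording the planted duplicate partition and scale
#' factor. Identical specs produce byte-identical files.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @param fwhm Lorentzian width for the pseudo-experiment.
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(spec, dir, fwhm = 10) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fx <- make_ensemble(spec)
  ens <- fx$ensemble
  write_multixyz(ens, file.path(dir, "ensemble.xyz"))
  utils::write.csv(
    data.frame(label = ens$label,
               electronic = sprintf("%.10f", ens$electronic),
               enthalpy = sprintf("%.10f", ens$enthalpy),
               gibbs = sprintf("%.10f", ens$gibbs)),
    file.path(dir, "energies.csv"), row.names = FALSE, quote = FALSE)
  tables <- make_frequency_tables(spec, ens)
  for (lab in names(tables))
    write_frequency_table(tables[[lab]],
                          file.path(dir, sprintf("freq_%s.tsv", lab)))
  w <- boltzmann_weights(ens, "gibbs")
  pexp <- make_pseudo_experiment(tables, w, spec, fwhm = fwhm)
  write_spectrum(pexp$ir, file.path(dir, "exp_ir.txt"))
  write_spectrum(pexp$vcd, file.path(dir, "exp_vcd.txt"))
  jsonlite::write_json(
    list(seed = spec$seed, planted_scale = spec$planted_scale,
         groups = fx$groups, n_unique = spec$n_conformers),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
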