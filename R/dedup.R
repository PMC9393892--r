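# Duplicate detection by the three-criterion test used in conformer
# sampling workflows: total energy, optimal-superposition RMSD of Cartesian
# coordinates, and the relative difference in rotational constants.

#' Duplicate-detection thresholds
#'
#' The three criteria are compared against these thresholds. Defaults follow
#' the documented defaults of the CREST conformer sampling tool, whose
#' criteria the post-optimization duplicate removal reuses: 0.05 kcal/mol in
#' energy, 0.125 Angstrom in superposition RMSD, and 1% relative difference
#' in any rotational constant.
#'
#' @param energy_thr Energy difference threshold, kcal/mol.
#' @param rmsd_thr Kabsch RMSD threshold, Angstrom.
#' @param rotconst_rel_thr Relative rotational-constant difference threshold
#'   (dimensionless fraction).
#' @return A named list of thresholds.
#' @export
dedup_thresholds <- function(energy_thr = 0.05, rmsd_thr = 0.125,
                             rotconst_rel_thr = 0.01) {
  stopifnot(energy_thr > 0, rmsd_thr > 0, rotconst_rel_thr > 0)
  list(energy_thr = energy_thr, rmsd_thr = rmsd_thr,
       rotconst_rel_thr = rotconst_rel_thr)
}

#' Minimum RMSD under optimal rigid superposition (Kabsch)
#'
#' Centers both coordinate sets, finds the rotation minimizing the
#' root-mean-square deviation via the Kabsch singular-value-decomposition
#' algorithm (with the determinant correction that excludes reflections),
#' and returns the minimized RMSD. Atom order is treated as fixed; no
#' permutation search is performed.
#'
#' @param a,b Single conformers with identical atom identity.
#' @param mass_weighted If `TRUE`, atoms are weighted by their masses in both
#'   the centering and the deviation; default `FALSE` (plain Cartesian RMSD).
#' @return RMSD in Angstrom (non-negative; symmetric in its arguments).
#' @export
kabsch_rmsd <- function(a, b, mass_weighted = FALSE) {
  a <- as_conf(a); b <- as_conf(b)
  if (!same_identity(a, b))
    stop("incompatible structures: atom identities differ", call. = FALSE)
  w <- if (mass_weighted) element_mass(a$atoms) else rep(1, length(a$atoms))
  w <- w / sum(w)
  pa <- sweep(a$coords, 2, colSums(a$coords * w))
  pb <- sweep(b$coords, 2, colSums(b$coords * w))
  h <- t(pa * w) %*% pb
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  diffs <- pb %*% rot - pa
  sqrt(sum(w * rowSums(diffs^2)))
}

#' Rotational constants of a conformer
#'
#' Principal moments of inertia about the center of mass (most-abundant
#' isotope masses), converted to rotational constants `B = h / (8 pi^2 c I)`
#' in cm^-1 and sorted descending (A >= B >= C). For linear molecules the
#' smallest principal moment vanishes; any moment below `1e-10` amu Angstrom^2
#' is treated as exactly zero and its constant reported as `Inf` (callers
#' comparing constants should drop non-finite entries).
#'
#' @param conf A single conformer.
#' @return Numeric length-3 vector (cm^-1), descending.
#' @export
rotational_constants <- function(conf) {
  conf <- as_conf(conf)
  m <- element_mass(conf$atoms)
  x <- sweep(conf$coords, 2, colSums(conf$coords * m) / sum(m))
  r2 <- rowSums(x^2)
  ixx <- sum(m * (r2 - x[, 1]^2))
  iyy <- sum(m * (r2 - x[, 2]^2))
  izz <- sum(m * (r2 - x[, 3]^2))
  ixy <- -sum(m * x[, 1] * x[, 2])
  ixz <- -sum(m * x[, 1] * x[, 3])
  iyz <- -sum(m * x[, 2] * x[, 3])
  itens <- matrix(c(ixx, ixy, ixz, ixy, iyy, iyz, ixz, iyz, izz), 3, 3)
  mom <- sort(eigen(itens, symmetric = TRUE, only.values = TRUE)$values)
  if (all(mom < 1e-10)) stop("degenerate geometry: all atoms coincident",
                             call. = FALSE)
  mom[mom < 1e-10] <- 0
  consts <- ifelse(mom == 0, Inf, .const$rotconst_amuA2 / mom)
  sort(consts, decreasing = TRUE)
}

#' Test whether two conformers are duplicates
#'
#' Two conformers are duplicates when all three criteria hold simultaneously:
#' the selected energies differ by at most `energy_thr`, the Kabsch RMSD is
#' at most `rmsd_thr`, and the largest relative difference over the (finite)
#' rotational constants, `|B_a - B_b| / mean(B_a, B_b)`, is at most
#' `rotconst_rel_thr`.
#'
#' @param a,b Single conformers carrying the selected energy field.
#' @param thr Thresholds from [dedup_thresholds()].
#' @param energy_field One of `"electronic"`, `"enthalpy"`, `"gibbs"`.
#' @param mass_weighted Passed to [kabsch_rmsd()].
#' @return One-row tibble: `duplicate` (lgl), `de_kcal`, `rmsd_A`, `db_rel`.
#' @export
is_duplicate <- function(a, b, thr = dedup_thresholds(),
                         energy_field = "electronic", mass_weighted = FALSE) {
  energy_field <- match.arg(energy_field, c("electronic", "enthalpy", "gibbs"))
  ea <- if (is.data.frame(a)) a[[energy_field]][[1]] else a[[energy_field]]
  eb <- if (is.data.frame(b)) b[[energy_field]][[1]] else b[[energy_field]]
  if (is.null(ea) || is.null(eb) || !is.finite(ea) || !is.finite(eb))
    stop("energy unavailable: field '", energy_field, "' missing", call. = FALSE)
  de <- abs(ea - eb) * .const$hartree_kcal
  rmsd <- kabsch_rmsd(a, b, mass_weighted = mass_weighted)
  ba <- rotational_constants(a)
  bb <- rotational_constants(b)
  fin <- is.finite(ba) & is.finite(bb)
  db <- if (any(fin)) max(abs(ba[fin] - bb[fin]) / ((ba[fin] + bb[fin]) / 2))
        else 0
  tibble::tibble(
    duplicate = de <= thr$energy_thr && rmsd <= thr$rmsd_thr &&
      db <= thr$rotconst_rel_thr,
    de_kcal = de, rmsd_A = rmsd, db_rel = db
  )
}

#' Remove duplicate conformers from an ensemble
#'
#' Greedy sweep in ascending order of the selected energy: each conformer is
#' kept unless it is a duplicate of an already-kept one, so the lowest-energy
#' representative of every duplicate group survives. The sweep is
#' deterministic for a fixed input (ties in energy are broken by input
#' order) and idempotent: pruning an already-pruned ensemble removes
#' nothing.
#'
#' @inheritParams is_duplicate
#' @param ensemble A validated `vcd_ensemble`.
#' @return A list with `ensemble` (kept conformers, ascending energy) and
#'   `report`, a tibble with one row per input conformer: `label`, `kept`
#'   (lgl), `match` (label of the kept duplicate, `NA` for kept rows),
#'   `de_kcal`, `rmsd_A`, `db_rel` (metrics against the match).
#' @export
prune_duplicates <- function(ensemble, thr = dedup_thresholds(),
                             energy_field = "electronic",
                             mass_weighted = FALSE) {
  ensemble <- validate_ensemble(ensemble)
  e <- ensemble[[energy_field]]
  if (any(!is.finite(e)))
    stop("energy unavailable: field '", energy_field,
         "' missing for conformer(s) ",
         paste(ensemble$label[!is.finite(e)], collapse = ", "), call. = FALSE)
  ord <- order(e)
  kept_idx <- integer(0)
  rep_rows <- vector("list", nrow(ensemble))
  for (k in ord) {
    verdict <- NULL
    for (ki in kept_idx) {
      m <- is_duplicate(ensemble[ki, ], ensemble[k, ], thr = thr,
                        energy_field = energy_field,
                        mass_weighted = mass_weighted)
      if (m$duplicate) { verdict <- list(match = ki, metrics = m); break }
    }
    if (is.null(verdict)) {
      kept_idx <- c(kept_idx, k)
      rep_rows[[k]] <- tibble::tibble(
        label = ensemble$label[k], kept = TRUE, match = NA_character_,
        de_kcal = NA_real_, rmsd_A = NA_real_, db_rel = NA_real_)
    } else {
      rep_rows[[k]] <- tibble::tibble(
        label = ensemble$label[k], kept = FALSE,
        match = ensemble$label[verdict$match],
        de_kcal = verdict$metrics$de_kcal,
        rmsd_A = verdict$metrics$rmsd_A,
        db_rel = verdict$metrics$db_rel)
    }
  }
  pruned <- ensemble[kept_idx, ]
  class(pruned) <- unique(c("vcd_ensemble", class(pruned)))
  list(ensemble = pruned, report = dplyr::bind_rows(rep_rows[ord]))
}
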