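# Conformer ensembles are tibbles with one row per conformer:
#   label (chr), atoms (list of chr), coords (list of N x 3 matrices, Angstrom),
#   electronic / enthalpy / gibbs (dbl, Hartree, NA when absent).
# List-columns keep the per-conformer geometry next to its energy record so
# the whole pipeline chains with ordinary dplyr verbs.

#' Construct a single-conformer record
#'
#' @param atoms Character vector of element symbols.
#' @param coords Numeric N x 3 matrix of Cartesian coordinates in Angstrom
#'   (one row per atom).
#' @param label Conformer identifier; free text, unique within an ensemble.
#' @param electronic,enthalpy,gibbs Energies in Hartree; `NA` when not
#'   available. At least one must be finite for energy-based operations.
#'
#' @return A one-row tibble of class `vcd_ensemble`.
#' @examples
#' conformer(c("O", "H", "H"),
#'           rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)),
#'           label = "w1", electronic = -76.4)
#' @export
conformer <- function(atoms, coords, label = "1",
                      electronic = NA_real_, enthalpy = NA_real_,
                      gibbs = NA_real_) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must have 3 columns", call. = FALSE)
  if (length(atoms) != nrow(coords))
    stop("coords must have exactly one row per atom", call. = FALSE)
  if (length(atoms) < 2L) stop("a conformer needs at least 2 atoms", call. = FALSE)
  bad <- !is_valid_element(atoms)
  if (any(bad))
    stop("unknown element symbol(s): ", paste(unique(atoms[bad]), collapse = ", "),
         call. = FALSE)
  dimnames(coords) <- NULL
  out <- tibble::tibble(
    label = as.character(label),
    atoms = list(as.character(atoms)),
    coords = list(coords),
    electronic = as.numeric(electronic),
    enthalpy = as.numeric(enthalpy),
    gibbs = as.numeric(gibbs)
  )
  class(out) <- c("vcd_ensemble", class(out))
  out
}

#' Combine conformer records into an ensemble
#'
#' Rows are stacked in the order given; the result is validated so that all
#' conformers share the same atom identity (element, count, order) and labels
#' are unique.
#'
#' @param ... One-row (or multi-row) `vcd_ensemble` tibbles.
#' @return A validated `vcd_ensemble` tibble.
#' @seealso [validate_ensemble()]
#' @export
bind_conformers <- function(...) {
  out <- dplyr::bind_rows(...)
  class(out) <- unique(c("vcd_ensemble", class(out)))
  validate_ensemble(out)
}

#' Validate an ensemble's invariants
#'
#' Checks that the ensemble is non-empty, that every conformer has the same
#' atom identity (same elements in the same order), and that labels are
#' unique. Returns the input unchanged when all invariants hold, so the
#' function is idempotent and safe to call defensively inside pipelines.
#'
#' @param ensemble A `vcd_ensemble` tibble.
#' @return The ensemble, unchanged.
#' @export
validate_ensemble <- function(ensemble) {
  if (!is.data.frame(ensemble) ||
      !all(c("label", "atoms", "coords") %in% names(ensemble)))
    stop("not an ensemble: need columns label, atoms, coords", call. = FALSE)
  if (nrow(ensemble) == 0L) stop("empty ensemble", call. = FALSE)
  ident <- ensemble$atoms[[1]]
  same <- vapply(ensemble$atoms, identical, logical(1), y = ident)
  if (!all(same))
    stop("heterogeneous ensemble: conformer(s) ",
         paste(ensemble$label[!same], collapse = ", "),
         " do not match the shared atom identity", call. = FALSE)
  nat <- vapply(ensemble$coords, nrow, integer(1))
  if (!all(nat == length(ident)))
    stop("heterogeneous ensemble: coordinate row counts differ", call. = FALSE)
  if (anyDuplicated(ensemble$label))
    stop("label collision: ",
         paste(unique(ensemble$label[duplicated(ensemble$label)]),
               collapse = ", "), call. = FALSE)
  ensemble
}

# Accept either a one-row ensemble tibble or a bare list(atoms=, coords=).
as_conf <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L)
      stop("expected a single conformer (one-row ensemble)", call. = FALSE)
    list(atoms = x$atoms[[1]], coords = x$coords[[1]],
         label = x$label[[1]])
  } else if (is.list(x) && all(c("atoms", "coords") %in% names(x))) {
    x
  } else {
    stop("not a conformer", call. = FALSE)
  }
}

same_identity <- function(a, b) identical(a$atoms, b$atoms)

#' Center of geometry of a conformer
#'
#' Arithmetic (unweighted) mean of the atomic coordinates.
#'
#' @param conf A single conformer: a one-row `vcd_ensemble` tibble or a list
#'   with `atoms` and `coords`.
#' @return Numeric length-3 vector in Angstrom.
#' @export
center_of_geometry <- function(conf) {
  conf <- as_conf(conf)
  colMeans(conf$coords)
}

#' Genetic crossing of two conformers onto a reference
#'
#' Generates a candidate structure by adding the coordinate difference of two
#' conformers to a reference geometry: `R_new = R_ref + (R_i - R_j)`. This is
#' the Cartesian form of the genetic-crossing step used by conformational
#' sampling workflows to propose new conformers from pairs of known ones;
#' the reference is conventionally the lowest-energy conformer. The returned
#' record carries no energies (the new structure is unoptimized).
#'
#' @param ref,i,j Single conformers sharing the same atom identity.
#' @param label Label for the generated conformer.
#' @return A one-row `vcd_ensemble` tibble.
#' @export
genetic_cross <- function(ref, i, j, label = "gc") {
  ref <- as_conf(ref); i <- as_conf(i); j <- as_conf(j)
  if (!same_identity(ref, i) || !same_identity(ref, j))
    stop("incompatible structures: atom identities differ", call. = FALSE)
  conformer(ref$atoms, ref$coords + (i$coords - j$coords), label = label)
}
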