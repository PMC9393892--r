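# Readers and writers for the interchange formats of the pipeline:
# multi-structure XYZ ensembles, per-conformer energy CSVs, frequency tables
# (a tab-separated dialect plus a parser for the common frequency-job log
# layout), and two-column experimental spectra. All readers reject malformed
# records rather than silently coercing; writers round-trip at full printed
# precision. No multi-frame XYZ reader with energy comments exists in the
# installed toolchain, so the parser is implemented here.

#' Read a multi-structure XYZ file into an ensemble
#'
#' Parses concatenated XYZ blocks (atom count line, comment line, atom
#' lines). When the comment line contains a numeric token it is stored as
#' the conformer's electronic energy in Hartree (the convention of conformer
#' sampling tools). Labels default to the 1-based block position unless the
#' comment carries a `label=<x>` token.
#'
#' @param path Path to the file.
#' @return A validated `vcd_ensemble`.
#' @export
read_multixyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  # drop trailing blank lines only; blanks inside a block are malformed
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  rows <- list()
  i <- 1L; blk <- 0L
  while (i <= length(lines)) {
    blk <- blk + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 2L)
      stop("parse error at block ", blk, ": bad atom count line", call. = FALSE)
    if (i + 1L + nat > length(lines))
      stop("parse error at block ", blk, ": truncated block", call. = FALSE)
    comment <- lines[i + 1L]
    body <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(body), "\\s+")
    if (any(lengths(toks) < 4L))
      stop("parse error at block ", blk, ": bad atom line", call. = FALSE)
    atoms <- vapply(toks, `[[`, character(1), 1L)
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    if (anyNA(xyz))
      stop("parse error at block ", blk, ": non-numeric coordinate",
           call. = FALSE)
    energy <- NA_real_
    ctoks <- strsplit(trimws(comment), "\\s+")[[1]]
    num <- suppressWarnings(as.numeric(ctoks))
    if (any(!is.na(num))) energy <- num[which(!is.na(num))[1]]
    lab <- sub("^label=", "", grep("^label=", ctoks, value = TRUE))
    if (!length(lab)) lab <- as.character(blk)
    rows[[blk]] <- conformer(atoms, xyz, label = lab[1], electronic = energy)
    i <- i + 2L + nat
  }
  if (!length(rows)) stop("empty ensemble", call. = FALSE)
  do.call(bind_conformers, rows)
}

#' Write an ensemble as a multi-structure XYZ file
#'
#' The comment line of each block carries the electronic energy (when
#' finite, `%.10f` Hartree) and a `label=` token, so
#' [read_multixyz()] round-trips labels and energies.
#'
#' @param ensemble A `vcd_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multixyz <- function(ensemble, path) {
  validate_ensemble(ensemble)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(ensemble))) {
    atoms <- ensemble$atoms[[k]]
    xyz <- ensemble$coords[[k]]
    e <- ensemble$electronic[k]
    comment <- paste0(if (is.finite(e)) sprintf("%.10f ", e),
                      "label=", ensemble$label[k])
    writeLines(c(length(atoms), comment,
                 sprintf("%-3s %16.8f %16.8f %16.8f",
                         atoms, xyz[, 1], xyz[, 2], xyz[, 3])), con)
  }
  invisible(path)
}

#' Read a per-conformer energy table
#'
#' CSV with columns `label` and any of `electronic`, `enthalpy`, `gibbs`
#' (Hartree). Used to attach DFT energies and thermochemistry to an
#' ensemble parsed from geometry files.
#'
#' @param path Path to the CSV.
#' @return Tibble with one row per conformer.
#' @export
read_energy_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"label" %in% names(df)) stop("energy CSV needs a 'label' column",
                                    call. = FALSE)
  df$label <- as.character(df$label)
  for (f in c("electronic", "enthalpy", "gibbs"))
    if (!f %in% names(df)) df[[f]] <- NA_real_
  tibble::as_tibble(df[c("label", "electronic", "enthalpy", "gibbs")])
}

#' Attach energies from a table to an ensemble
#'
#' Values from the table override those parsed from geometry comments (a
#' warning notes any conflict in the electronic energy).
#'
#' @param ensemble A `vcd_ensemble`.
#' @param energies Tibble from [read_energy_csv()].
#' @return The ensemble with energy columns filled.
#' @export
attach_energies <- function(ensemble, energies) {
  idx <- match(ensemble$label, energies$label)
  if (anyNA(idx))
    stop("energy table missing conformer(s): ",
         paste(ensemble$label[is.na(idx)], collapse = ", "), call. = FALSE)
  for (f in c("electronic", "enthalpy", "gibbs")) {
    new <- energies[[f]][idx]
    if (f == "electronic") {
      clash <- is.finite(ensemble$electronic) & is.finite(new) &
        abs(ensemble$electronic - new) > 1e-10
      if (any(clash))
        warning("electronic energies in table override XYZ comments for: ",
                paste(ensemble$label[clash], collapse = ", "), call. = FALSE)
    }
    ensemble[[f]] <- ifelse(is.finite(new), new, ensemble[[f]])
  }
  ensemble
}

#' Read a per-conformer frequency table
#'
#' Two dialects:
#' \describe{
#'   \item{`tsv`}{Tab-separated with header
#'     `mode  frequency  dipole_strength  rotational_strength`
#'     (frequencies in cm^-1, dipole strengths in 10^-40 esu^2 cm^2,
#'     rotational strengths in 10^-44 esu^2 cm^2).}
#'   \item{`qm_log`}{The common frequency-job text-log layout with
#'     `Frequencies --`, `Dip. str.   --` and `Rot. str.   --` lines,
#'     three modes per block.}
#' }
#' A negative frequency (the printed convention for an imaginary mode)
#' signals a non-minimum structure and is rejected: the averaging protocol
#' requires true minima. Missing rotational strengths are an error unless
#' `ir_only = TRUE`.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"qm_log"`.
#' @param label Conformer label to attach (default: file name without
#'   extension).
#' @param ir_only Allow absent rotational strengths.
#' @return A `vcd_freqtable` tibble with columns `mode`, `frequency`,
#'   `dipole_strength`, `rotational_strength`; attribute `label`.
#' @export
read_frequency_table <- function(path, dialect = c("tsv", "qm_log"),
                                 label = NULL, ir_only = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  if (dialect == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("mode", "frequency", "dipole_strength")
    if (!all(need %in% names(df)))
      stop("frequency tsv must have columns mode, frequency, dipole_strength",
           call. = FALSE)
    if (!"rotational_strength" %in% names(df)) {
      if (!ir_only) stop("VCD data absent: no rotational_strength column",
                         call. = FALSE)
      df$rotational_strength <- NA_real_
    }
    tab <- tibble::as_tibble(df[c("mode", "frequency", "dipole_strength",
                                  "rotational_strength")])
  } else {
    lines <- readLines(path)
    grab <- function(pattern) {
      hits <- grep(pattern, lines, value = TRUE)
      unlist(lapply(hits, function(l) {
        as.numeric(strsplit(trimws(sub(".*--", "", l)), "\\s+")[[1]])
      }))
    }
    freq <- grab("^\\s*Frequencies\\s*--")
    dip <- grab("^\\s*Dip\\. str\\.\\s*--")
    rot <- grab("^\\s*Rot\\. str\\.\\s*--")
    if (!length(freq)) stop("no frequency blocks found", call. = FALSE)
    if (length(dip) != length(freq))
      stop("dipole strengths do not match frequencies", call. = FALSE)
    if (!length(rot)) {
      if (!ir_only) stop("VCD data absent: no 'Rot. str.' lines", call. = FALSE)
      rot <- rep(NA_real_, length(freq))
    } else if (length(rot) != length(freq)) {
      stop("rotational strengths do not match frequencies", call. = FALSE)
    }
    tab <- tibble::tibble(mode = seq_along(freq), frequency = freq,
                          dipole_strength = dip, rotational_strength = rot)
  }
  if (any(tab$frequency <= 0))
    stop("non-minimum structure: imaginary (negative) frequency present",
         call. = FALSE)
  if (is.unsorted(tab$mode) || anyDuplicated(tab$mode))
    stop("mode indices must be unique and ascending", call. = FALSE)
  attr(tab, "label") <- label
  class(tab) <- c("vcd_freqtable", class(tab))
  tab
}

#' Write a frequency table in the tsv dialect
#'
#' @param freqtable A `vcd_freqtable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(freqtable, path) {
  df <- as.data.frame(freqtable)[c("mode", "frequency", "dipole_strength",
                                   "rotational_strength")]
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the stick spectrum of one modality from a frequency table
#'
#' @param freqtable A `vcd_freqtable`.
#' @param modality `"IR"` (dipole strengths) or `"VCD"` (rotational
#'   strengths).
#' @return A `vcd_sticks` tibble.
#' @export
freq_sticks <- function(freqtable, modality = c("IR", "VCD")) {
  modality <- match.arg(modality)
  strength <- if (modality == "IR") freqtable$dipole_strength
              else freqtable$rotational_strength
  if (anyNA(strength)) stop("VCD data absent for this table", call. = FALSE)
  stick_spectrum(freqtable$frequency, strength, modality = modality,
                 label = attr(freqtable, "label"))
}

#' Read an experimental spectrum from two-column text
#'
#' Whitespace- or comma-separated numeric columns (wavenumber, intensity) in
#' either axis order; lines starting with `#` are ignored. The spectrum is
#' sorted ascending in wavenumber and resampled onto a uniform grid at the
#' median point spacing when the native grid is non-uniform.
#'
#' @param path Path to the file.
#' @param modality `"IR"` or `"VCD"`.
#' @return A `vcd_spectrum`.
#' @export
read_experimental <- function(path, modality = c("IR", "VCD")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  toks <- strsplit(trimws(gsub(",", " ", lines)), "\\s+")
  if (any(lengths(toks) < 2L))
    stop("malformed spectrum line", call. = FALSE)
  m <- t(vapply(toks, function(t) as.numeric(t[1:2]), numeric(2)))
  if (anyNA(m)) stop("non-numeric spectrum value", call. = FALSE)
  if (nrow(m) < 8L) stop("insufficient spectrum: fewer than 8 points",
                         call. = FALSE)
  ord <- order(m[, 1])
  nu <- m[ord, 1]; iy <- m[ord, 2]
  steps <- diff(nu)
  if (diff(range(steps)) > 1e-9) {
    grid <- seq(min(nu), max(nu), by = stats::median(steps))
    iy <- stats::approx(nu, iy, xout = grid)$y
    nu <- grid
  }
  continuous_spectrum(nu, iy, modality = modality)
}

#' Write a continuous spectrum as two-column text
#'
#' @param spec A `vcd_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  writeLines(sprintf("%.4f %.10e", spec$wavenumber, spec$intensity), path)
  invisible(path)
}
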