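# Shared toy builders and independent oracles used across test files.

toy_conformer <- function(xyz, atoms = rep("C", nrow(xyz)), label = "t",
                          electronic = -1) {
  conformer(atoms, xyz, label = label, electronic = electronic)
}

random_conformer <- function(n = 5, label = "r", electronic = -1) {
  toy_conformer(matrix(stats::rnorm(3 * n), ncol = 3), label = label,
                electronic = electronic)
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

euler_rotation <- function(a, b, c) {
  rx <- matrix(c(1, 0, 0, 0, cos(b), sin(b), 0, -sin(b), cos(b)), 3, 3)
  rotation_z(a) %*% rx %*% rotation_z(c)
}

# Independent RMSD oracle: dense Euler-angle grid followed by Nelder-Mead
# refinement of the best grid point. Never touches the SVD code path.
brute_force_rmsd <- function(a, b, grid_step = pi / 9) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  rmsd_at <- function(ang) {
    r <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((b %*% r - a)^2)))
  }
  angs <- seq(0, 2 * pi - 1e-9, by = grid_step)
  best <- Inf; best_ang <- c(0, 0, 0)
  for (x in angs) for (y in seq(0, pi, by = grid_step)) for (z in angs) {
    v <- rmsd_at(c(x, y, z))
    if (v < best) { best <- v; best_ang <- c(x, y, z) }
  }
  opt <- stats::optim(best_ang, rmsd_at, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# Connected components of the pairwise duplicate graph (union-find).
duplicate_components <- function(ensemble, thr = dedup_thresholds(),
                                 energy_field = "electronic") {
  n <- nrow(ensemble)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (is_duplicate(ensemble[i, ], ensemble[j, ], thr = thr,
                     energy_field = energy_field)$duplicate) {
      parent[find(j)] <- find(i)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Minimal frequency-job log fixture in the 'Frequencies -- / Dip. str. --'
# text layout, three modes per block.
write_qm_log <- function(path, freq, dip, rot = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(" Harmonic frequencies (cm**-1), dipole strengths and", con)
  for (i in seq(1, length(freq), by = 3)) {
    idx <- i:min(i + 2, length(freq))
    fmt <- function(x) paste(sprintf("%12.4f", x), collapse = "")
    writeLines(sprintf(" Frequencies --%s", fmt(freq[idx])), con)
    writeLines(sprintf(" Dip. str.   --%s", fmt(dip[idx])), con)
    if (!is.null(rot))
      writeLines(sprintf(" Rot. str.   --%s", fmt(rot[idx])), con)
  }
  path
}
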