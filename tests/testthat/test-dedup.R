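test_that("kabsch_rmsd is zero under rigid motion and symmetric", {
  set.seed(21)
  a <- random_conformer(7, "a")
  expect_equal(kabsch_rmsd(a, a), 0)

  moved <- toy_conformer(sweep(a$coords[[1]] %*% rotation_z(pi / 2),
                               2, c(5, 5, 5), `+`), label = "b")
  expect_equal(kabsch_rmsd(a, moved), 0, tolerance = 1e-10)

  b <- random_conformer(7, "b")
  expect_equal(kabsch_rmsd(a, b), kabsch_rmsd(b, a))
  # invariance under independent rigid motions of both arguments
  a2 <- toy_conformer(sweep(a$coords[[1]] %*% rotation_z(1.1), 2, 3, `+`))
  b2 <- toy_conformer(sweep(b$coords[[1]] %*% rotation_z(-0.4), 2, -2, `+`))
  expect_equal(kabsch_rmsd(a2, b2), kabsch_rmsd(a, b), tolerance = 1e-10)
})

test_that("kabsch_rmsd agrees with a brute-force rotation-grid oracle", {
  set.seed(22)
  for (k in 1:4) {
    a <- matrix(stats::rnorm(12), ncol = 3)
    b <- matrix(stats::rnorm(12), ncol = 3)
    expect_equal(kabsch_rmsd(toy_conformer(a), toy_conformer(b)),
                 brute_force_rmsd(a, b), tolerance = 1e-3)
  }
})

test_that("rotational constants match the diatomic rigid rotor", {
  r <- 0.74  # Angstrom
  h2 <- toy_conformer(rbind(c(-r / 2, 0, 0), c(r / 2, 0, 0)),
                      atoms = c("H", "H"))
  m <- atomic_masses()[["H"]]
  b_expected <- 16.8576304 / (m * r^2 / 2)
  consts <- rotational_constants(h2)
  expect_equal(consts[2], b_expected, tolerance = 1e-6)
  expect_equal(consts[3], b_expected, tolerance = 1e-6)
  expect_true(is.infinite(consts[1]))  # linear: zero moment along the axis
})

test_that("rotational constants match an explicit inertia tensor", {
  # bent symmetric triatomic placed with principal axes on x/y/z, so the
  # tensor is diagonal and the eigenvalues can be written down directly
  mo <- atomic_masses()[["O"]]; mh <- atomic_masses()[["H"]]
  x <- 0.76; y <- 0.59
  ycom <- 2 * mh * y / (mo + 2 * mh)
  xyz <- rbind(c(0, -ycom, 0), c(x, y - ycom, 0), c(-x, y - ycom, 0))
  w <- toy_conformer(xyz, atoms = c("O", "H", "H"))
  ixx <- mo * ycom^2 + 2 * mh * (y - ycom)^2
  iyy <- 2 * mh * x^2
  izz <- ixx + iyy  # planar
  expected <- sort(16.8576304 / c(ixx, iyy, izz), decreasing = TRUE)
  expect_equal(rotational_constants(w), expected, tolerance = 1e-10)
})

test_that("rotational constants are invariant under rigid motion", {
  set.seed(23)
  a <- random_conformer(6)
  moved <- toy_conformer(sweep(a$coords[[1]] %*% rotation_z(0.9),
                               2, c(-3, 1, 7), `+`))
  expect_equal(rotational_constants(a), rotational_constants(moved),
               tolerance = 1e-9)
  expect_true(all(rotational_constants(a) > 0))
})

test_that("is_duplicate requires all three criteria simultaneously", {
  set.seed(24)
  a <- random_conformer(6, "a", electronic = -100)
  copy <- toy_conformer(a$coords[[1]], label = "b", electronic = -100)
  v <- is_duplicate(a, copy)
  expect_true(v$duplicate)
  expect_equal(c(v$de_kcal, v$rmsd_A, v$db_rel), c(0, 0, 0))

  # identical geometry, energy shifted +5 kcal/mol: energy criterion fails
  far <- toy_conformer(a$coords[[1]], label = "c",
                       electronic = -100 + 5 / 627.509474)
  expect_false(is_duplicate(a, far)$duplicate)

  # straddle exactly one threshold of three: still not a duplicate
  thr <- dedup_thresholds()
  near_e <- toy_conformer(a$coords[[1]], label = "d",
                          electronic = -100 + 1.5 * thr$energy_thr / 627.509474)
  m <- is_duplicate(a, near_e, thr)
  expect_false(m$duplicate)
  expect_true(m$rmsd_A <= thr$rmsd_thr && m$db_rel <= thr$rotconst_rel_thr)

  noe <- toy_conformer(a$coords[[1]], label = "e", electronic = NA)
  expect_error(is_duplicate(a, noe), "energy unavailable")
})

test_that("prune_duplicates keeps one representative per planted group", {
  spec <- fixture_spec(n_conformers = 4, n_duplicate_pairs = 2, seed = 77)
  fx <- make_ensemble(spec)
  res <- prune_duplicates(fx$ensemble)
  expect_equal(nrow(res$ensemble), 4)
  expect_equal(nrow(res$report), nrow(fx$ensemble))
  expect_setequal(c(res$report$label[res$report$kept],
                    res$report$label[!res$report$kept]), fx$ensemble$label)
  # removed conformers match a kept member of their own planted group
  grp <- setNames(fx$groups$group, fx$groups$label)
  removed <- res$report[!res$report$kept, ]
  expect_equal(unname(grp[removed$label]), unname(grp[removed$match]))
  # kept set sorted ascending in energy
  expect_false(is.unsorted(res$ensemble$electronic))
})

test_that("prune_duplicates is idempotent and stable to injected copies", {
  spec <- fixture_spec(n_conformers = 5, n_duplicate_pairs = 2, seed = 78)
  ens <- make_ensemble(spec)$ensemble
  once <- prune_duplicates(ens)
  twice <- prune_duplicates(once$ensemble)
  expect_equal(twice$ensemble$label, once$ensemble$label)
  expect_equal(sum(!twice$report$kept), 0)

  # an exact copy of a kept conformer never changes the kept set
  copy <- once$ensemble[1, ]
  copy$label <- "copy"
  withcopy <- prune_duplicates(bind_conformers(once$ensemble, copy))
  expect_setequal(withcopy$ensemble$label, once$ensemble$label)
})

test_that("kept count equals the components of the brute-force duplicate graph", {
  for (s in c(101, 102, 103)) {
    spec <- fixture_spec(n_conformers = 4, n_duplicate_pairs = 3, seed = s)
    ens <- make_ensemble(spec)$ensemble
    comp <- duplicate_components(ens)
    res <- prune_duplicates(ens)
    expect_equal(nrow(res$ensemble), length(unique(comp)))
  }
})
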