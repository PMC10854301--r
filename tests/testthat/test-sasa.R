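test_that("the sphere lattice is unit-norm, balanced and quasi-uniform", {
  expect_equal(sqrt(sum(sphere_points(1)^2)), 1, tolerance = 1e-12)
  expect_error(sphere_points(0), ">= 1")
  p <- sphere_points(960)
  expect_equal(unname(sqrt(rowSums(p^2))), rep(1, 960), tolerance = 1e-12)
  expect_lt(sqrt(sum(colMeans(p)^2)), 0.01)
  # nearest-neighbour spacing varies by < 3x across points
  nn <- apply(as.matrix(dist(p)) + diag(Inf, 960), 1, min)
  expect_lt(max(nn) / min(nn), 3)
})

test_that("an isolated atom has the analytic sphere area", {
  s <- atoms_structure(c(0, 0, 0))
  a <- atom_sasa(s)$per_atom
  expect_equal(a, 4 * pi * 3.1^2, tolerance = 5e-3)
  # two atoms far apart do not occlude each other
  s2 <- atoms_structure(rbind(c(0, 0, 0), c(100, 0, 0)))
  expect_equal(atom_sasa(s2)$per_atom, rep(4 * pi * 3.1^2, 2),
               tolerance = 5e-3)
})

test_that("two overlapping spheres match the spherical-cap closed form", {
  for (d in c(2, 3, 4)) {
    s <- atoms_structure(rbind(c(0, 0, 0), c(d, 0, 0)))
    a <- atom_sasa(s)$per_atom
    expected <- two_sphere_area(3.1, d)
    expect_equal(a[1], expected, tolerance = 0.01)
    expect_equal(a[2], expected, tolerance = 0.01)
  }
})

test_that("cell-list neighbour search equals the all-pairs scan exactly", {
  for (seed in c(3, 7)) {
    cl <- make_random_cluster(25, sd = 4, seed = seed)
    expect_identical(atom_sasa(cl, method = "cells")$per_atom,
                     atom_sasa(cl, method = "allpairs")$per_atom)
  }
})

test_that("per-residue SASA sums atoms and normalises to the reference", {
  h <- make_helix(3)
  res <- calc_sasa(h)
  pr <- res$per_residue
  keys <- atom_residue_keys(h)
  for (i in seq_len(nrow(pr))) {
    expect_equal(pr$abs[i],
                 sum(res$per_atom[keys == pr$key[i]], na.rm = TRUE))
  }
  # middle residue of a tripeptide-like context stays within the
  # plausible bound of the Gly-X-Gly-style reference maximum
  expect_lte(pr$rel[2], 110)
  expect_false(any(pr$nonstandard))
  # nonstandard residues are flagged, not dropped
  cage <- residue_sasa(atom_sasa(make_sphere_cage(8, 20)))
  expect_true(all(cage$per_residue$nonstandard))
  expect_true(all(is.na(cage$per_residue$rel)))
})

test_that("excluded atoms contribute zero and excluded residues read zero", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "HETATM    2  O   HOH B   1      50.000   0.000   0.000  1.00  0.00           O",
    "END"), path)
  s <- read_structure(path)
  res <- residue_sasa(atom_sasa(s))
  expect_true(is.na(res$per_atom[2]))       # hetero excluded by default
  expect_equal(res$per_residue$abs[res$per_residue$chain == "B"], 0)
  # flag flips inclusion
  res2 <- atom_sasa(s, sasa_params(include_hetero = TRUE))
  expect_false(is.na(res2$per_atom[2]))
})

test_that("the Monte-Carlo oracle is seeded, unbiased and agrees with the lattice", {
  s <- atoms_structure(c(0, 0, 0))
  mc <- mc_sasa(s, n_samples = 1e5, seed = 1)
  expect_equal(mc$area, 4 * pi * 3.1^2, tolerance = 0.01)
  expect_identical(mc, mc_sasa(s, n_samples = 1e5, seed = 1))
  cl <- make_random_cluster(20, sd = 3, seed = 7)
  sr <- atom_sasa(cl)$per_atom
  mc2 <- mc_sasa(cl, n_samples = 2e4, seed = 11)
  # combined standard error: MC se plus a binomial bound on the
  # 960-point lattice sampling error
  se_sr <- 4 * pi * 3.1^2 * sqrt(0.25 / 960)
  comb <- sqrt(mc2$se^2 + se_sr^2)
  expect_true(all(abs(sr - mc2$area) <= 3 * comb))
})

test_that("adding an atom never increases any existing atom's SASA", {
  for (seed in c(1, 5, 9)) {
    cl <- make_random_cluster(15, sd = 3, seed = seed)
    base <- atom_sasa(cl)$per_atom
    set.seed(seed + 100)
    extra <- rbind(cl$atom[, c("x", "y", "z")], rnorm(3, sd = 3))
    grown <- atoms_structure(as.matrix(extra))
    aug <- atom_sasa(grown)$per_atom
    expect_true(all(aug[seq_along(base)] <= base + 1e-9))
  }
})

test_that("complex SASA is subadditive over its chains", {
  d <- make_helix_dimer(n_res_a = 10, n_res_b = 10)
  whole <- sum(atom_sasa(d)$per_atom, na.rm = TRUE)
  a <- sum(atom_sasa(select_structure(d, "chain A"))$per_atom, na.rm = TRUE)
  b <- sum(atom_sasa(select_structure(d, "chain B"))$per_atom, na.rm = TRUE)
  expect_lte(whole, a + b + 1e-6)
  # far-apart chains are exactly additive
  far <- make_helix_dimer(n_res_a = 6, n_res_b = 6, separation = 50)
  wf <- sum(atom_sasa(far)$per_atom, na.rm = TRUE)
  af <- sum(atom_sasa(select_structure(far, "chain A"))$per_atom, na.rm = TRUE)
  bf <- sum(atom_sasa(select_structure(far, "chain B"))$per_atom, na.rm = TRUE)
  expect_equal(wf, af + bf, tolerance = 1e-9)
})

test_that("doubling the point count moves total SASA by less than 0.5%", {
  h <- make_helix(12)
  t1 <- sum(atom_sasa(h, sasa_params(n_points = 960))$per_atom)
  t2 <- sum(atom_sasa(h, sasa_params(n_points = 1920))$per_atom)
  expect_lt(abs(t2 - t1) / t2, 0.005)
})

test_that("SASA is invariant under rigid-body transforms", {
  h <- make_helix(12)
  a0 <- atom_sasa(h)$per_atom
  t0 <- sum(a0)
  for (seed in c(2, 4)) {
    hr <- apply_transform(h, random_rotation(seed), c(5, -3, 2))
    a1 <- atom_sasa(hr)$per_atom
    # the fixed point lattice makes individual atoms orientation
    # sensitive at the ~1/n_points level; totals cancel much further
    expect_lt(abs(sum(a1) - t0) / t0, 0.005)
    expect_lt(max(abs(a1 - a0)) / (4 * pi * 3.1^2), 0.01)
  }
})

test_that("SASA results serialise with full per-atom detail", {
  res <- calc_sasa(make_helix(4))
  path <- tempfile(fileext = ".json")
  write_sasa_json(res, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(back$per_atom), nrow(res$structure$atom))
  expect_equal(back$params$probe_radius, 1.4)
  expect_equal(back$per_residue$abs, res$per_residue$abs, tolerance = 1e-4)
  tsv <- tempfile(fileext = ".tsv")
  write_sasa_tsv(res, tsv)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$abs_A2, res$per_residue$abs, tolerance = 1e-3)
})
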