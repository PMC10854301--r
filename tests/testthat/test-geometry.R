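test_that("CA distances are Euclidean and errors name the residue", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       0.000   0.000   5.000  1.00  0.00           C",
    "ATOM      3  CB  ALA A   3       1.000   0.000   0.000  1.00  0.00           C",
    "END"), path)
  s <- read_structure(path)
  expect_equal(ca_distance(s, residue_ref("A", 1), residue_ref("A", 2)), 5.0)
  expect_equal(ca_distance(s, residue_ref("A", 1), residue_ref("A", 1)), 0.0)
  expect_error(ca_distance(s, residue_ref("A", 1), residue_ref("A", 3)),
               "A3.*no CA")
  h <- make_helix(12)
  ca <- coords(h)[h$atom$elety == "CA", ]
  expect_equal(ca_distance(h, residue_ref("A", 2), residue_ref("A", 9)),
               sqrt(sum((ca[2, ] - ca[9, ])^2)))
})

test_that("contacts use a strict cutoff", {
  s <- atoms_structure(rbind(c(0, 0, 0), c(3.9, 0, 0), c(8.0, 0, 0)))
  cl <- contacts(s, "resno 1", "resno 2-3")
  expect_equal(nrow(cl$atoms), 1L)
  expect_equal(cl$atoms$dist, 3.9)
  s2 <- atoms_structure(rbind(c(0, 0, 0), c(4.1, 0, 0)))
  expect_equal(nrow(contacts(s2, "resno 1", "resno 2")$atoms), 0L)
  expect_equal(nrow(contacts(s2, "resno 1", "resno 2",
                             contact_params(cutoff = 4.2))$atoms), 1L)
  expect_error(contacts(s, "resno 1-2", "resno 2-3"), "overlap")
})

test_that("contacts equal the all-pairs brute-force scan on random clouds", {
  for (seed in c(3, 13)) {
    a <- make_random_cluster(50, sd = 6, seed = seed, chain = "A")
    b <- make_random_cluster(50, sd = 6, seed = seed + 1, chain = "B")
    b$atom$x <- b$atom$x + 4
    comb <- structure3d(rbind(a$atom, b$atom), id = "cloud")
    comb$atom$eleno <- seq_len(nrow(comb$atom))
    cl <- contacts(comb, "chain A", "chain B")
    oracle <- brute_contacts(coords(a), coords(b), 4.0)
    expect_equal(nrow(cl$atoms), nrow(oracle))
    expect_equal(sort(cl$atoms$dist), sort(oracle[, 3]), tolerance = 1e-9)
    # symmetry under selection swap
    cl2 <- contacts(comb, "chain B", "chain A")
    expect_equal(sort(cl2$atoms$dist), sort(cl$atoms$dist))
  }
})

# Ser-like donor and Arg-like acceptor with controlled geometry: OG at
# origin with antecedent CB; partner N placed at the given distance,
# with both antecedent angles near 150 degrees.
hbond_fixture <- function(d) {
  atoms <- data.frame(
    type = "ATOM", eleno = 1:4,
    elety = c("CB", "OG", "NH1", "CZ"), alt = "",
    resid = c("SER", "SER", "ARG", "ARG"), chain = c("A", "A", "B", "B"),
    resno = c(1L, 1L, 2L, 2L), insert = "",
    x = c(-1.43, 0, d, d + 1.33 * cos(pi / 6)),
    y = c(-0.5, 0, 0, 1.33 * sin(pi / 6)),
    z = 0, o = 1, b = 0, elem = c("C", "O", "N", "C"),
    stringsAsFactors = FALSE)
  structure3d(atoms, id = "hbond-fixture")
}

test_that("hydrogen bonds require distance and antecedent angle", {
  hb <- hydrogen_bonds(hbond_fixture(2.9), "chain A", "chain B")
  expect_equal(nrow(hb$atoms), 1L)
  expect_equal(hb$atoms$dist, 2.9)
  expect_equal(hb$atoms$elety_a, "OG")
  # beyond the distance criterion no bond is called
  expect_equal(nrow(hydrogen_bonds(hbond_fixture(4.2), "chain A",
                                   "chain B")$atoms), 0L)
  # an impossible criterion yields nothing anywhere
  expect_equal(nrow(hydrogen_bonds(hbond_fixture(2.9), "chain A", "chain B",
                                   hbond_criteria(max_distance = 0.5))$atoms),
               0L)
  # a failing antecedent angle suppresses the bond: bend CB behind OG
  bent <- hbond_fixture(2.9)
  bent$atom$x[1] <- 1.0; bent$atom$y[1] <- -1.0
  expect_equal(nrow(hydrogen_bonds(bent, "chain A", "chain B")$atoms), 0L)
})

test_that("Kabsch superposition recovers rigid transforms", {
  h <- make_helix(10)
  R <- random_rotation(21)
  moved <- apply_transform(h, R, c(3, -7, 1))
  fit <- superpose(h, moved)
  expect_lt(fit$rmsd, 1e-6)
  # applying the transform and refitting reproduces the rmsd
  back <- apply_transform(h, fit$rotation, fit$translation)
  expect_equal(sqrt(mean(rowSums((coords(back) - coords(moved))^2))),
               fit$rmsd, tolerance = 1e-6)
  refit <- superpose(back, moved)
  expect_lt(refit$rmsd, 1e-6)
})

test_that("a single 1 A displacement gives rmsd 1/sqrt(n)", {
  ca <- make_helix(16)
  ca <- select_structure(ca, "name CA")
  shifted <- ca
  shifted$atom$x[5] <- shifted$atom$x[5] + 1.0
  n <- nrow(ca$atom)
  fit <- superpose(ca, shifted)
  # 1/sqrt(n) is the un-superposed value; the minimized rmsd re-centres
  # the displacement, giving sqrt((n-1)/n)/sqrt(n), with the optimal
  # rotation shaving off slightly more
  expect_lte(fit$rmsd, 1 / sqrt(n) + 1e-9)
  expect_equal(fit$rmsd, sqrt((n - 1) / n) / sqrt(n), tolerance = 0.03)
  expect_equal(fit$rmsd, quaternion_superpose(coords(ca), coords(shifted)),
               tolerance = 1e-8)
})

test_that("Kabsch agrees with the quaternion oracle on random point sets", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    P <- matrix(rnorm(30), 10)
    Q <- matrix(rnorm(30), 10)
    expect_equal(superpose(P, Q)$rmsd, quaternion_superpose(P, Q),
                 tolerance = 1e-8)
  }
})

test_that("degenerate superposition inputs are rejected", {
  P <- matrix(rnorm(6), 2)
  expect_error(superpose(P, P), "3 atom pairs")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("proline pucker calls follow the Cgamma convention", {
  expect_equal(proline_pucker(make_proline_ring("endo", 0.3),
                              residue_ref("A", 1))$state, "endo")
  expect_equal(proline_pucker(make_proline_ring("exo", 0.3),
                              residue_ref("A", 1))$state, "exo")
  expect_equal(proline_pucker(make_proline_ring("endo", 0.02),
                              residue_ref("A", 1))$state, "planar")
  # threshold is configurable
  expect_equal(proline_pucker(make_proline_ring("endo", 0.3),
                              residue_ref("A", 1),
                              planarity_threshold = 0.5)$state, "planar")
  # missing ring atoms are named
  p <- make_proline_ring("endo", 0.3)
  p$atom <- p$atom[p$atom$elety != "CG", ]
  expect_error(proline_pucker(p, residue_ref("A", 1)), "CG")
  expect_error(proline_pucker(make_helix(3), residue_ref("A", 1)),
               "not a proline")
})

test_that("geometry is invariant under rigid transforms", {
  for (seed in c(6, 8)) {
    R <- random_rotation(seed)
    tr <- c(2, 5, -4)
    d <- make_helix_dimer(n_res_a = 8, n_res_b = 8)
    dr <- apply_transform(d, R, tr)
    c1 <- contacts(d, "chain A", "chain B")
    c2 <- contacts(dr, "chain A", "chain B")
    expect_equal(c1$atoms$dist, c2$atoms$dist, tolerance = 1e-9)
    expect_equal(c1$residue_pairs, c2$residue_pairs)
    expect_equal(ca_distance(d, residue_ref("A", 2), residue_ref("B", 5)),
                 ca_distance(dr, residue_ref("A", 2), residue_ref("B", 5)),
                 tolerance = 1e-9)
    p <- make_proline_ring("exo", 0.25)
    pr <- apply_transform(p, R, tr)
    expect_equal(proline_pucker(pr, residue_ref("A", 1))$state, "exo")
  }
})
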