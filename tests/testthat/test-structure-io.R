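test_that("a handcrafted PDB loads with all fields", {
  path <- write_mini_pdb(tempfile(fileext = ".pdb"))
  s <- read_structure(path)
  expect_s3_class(s, "structure3d")
  expect_equal(nrow(s$atom), 3L)
  expect_equal(nrow(residue_table(s)), 1L)
  expect_equal(s$atom$elety, c("N", "CA", "C"))
  expect_equal(s$atom$elem, c("N", "C", "C"))
  expect_equal(s$atom$x[1], 11.104)
  expect_equal(s$atom$b, c(10, 11, 12))
})

test_that("alt-loc groups keep the highest-occupancy conformer, ties first in file", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1       2.000   0.000   0.000  0.40  0.00           C",
    "ATOM      4  CB AALA A   1       3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      5  CB BALA A   1       4.000   0.000   0.000  0.50  0.00           C",
    "END"), path)
  s <- read_structure(path)
  expect_equal(nrow(s$atom), 3L)
  # CA: A wins on occupancy; CB: tie broken by file order (A first)
  expect_equal(s$atom$x[s$atom$elety == "CA"], 1.0)
  expect_equal(s$atom$x[s$atom$elety == "CB"], 3.0)
})

test_that("HETATM records load flagged and hydrogens are retained", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  H   ALA A   1       0.500   0.500   0.000  1.00  0.00           H",
    "HETATM    3  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
    "END"), path)
  s <- read_structure(path)
  expect_equal(s$atom$type, c("ATOM", "ATOM", "HETATM"))
  expect_true("H" %in% s$atom$elem)
})

test_that("unreadable or empty files raise parse errors", {
  expect_error(read_structure(tempfile()), "not found")
  empty <- tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(read_structure(empty))
})

test_that("the same model written as PDB and mmCIF reads back identically", {
  h <- make_helix(6)
  p1 <- tempfile(fileext = ".pdb"); p2 <- tempfile(fileext = ".cif")
  write_pdb(h, p1)
  write_mmcif(h, p2)
  s1 <- read_structure(p1)
  s2 <- read_structure(p2)
  for (col in c("type", "elety", "resid", "chain", "resno", "elem"))
    expect_equal(s1$atom[[col]], s2$atom[[col]], info = col)
  expect_equal(coords(s1), coords(s2), tolerance = 1e-6)
  expect_equal(nrow(residue_table(s1)), nrow(residue_table(s2)))
})

test_that("read-write-read round trip is idempotent to PDB precision", {
  h <- make_helix(8)
  p1 <- tempfile(fileext = ".pdb")
  write_pdb(h, p1)
  s1 <- read_structure(p1)
  p2 <- tempfile(fileext = ".pdb")
  write_pdb(s1, p2)
  s2 <- read_structure(p2)
  expect_equal(coords(s1), coords(s2), tolerance = 1e-9)
  expect_lt(max(abs(coords(s1) - coords(h))), 1e-3 + 1e-9)
})

test_that("write_annotated encodes per-residue values in the B-factor column", {
  h <- make_helix(4)
  rt <- residue_table(h)
  vals <- c(12.5, 3.25)
  names(vals) <- rt$key[1:2]
  path <- tempfile(fileext = ".pdb")
  write_annotated(h, vals, path, sentinel = -1)
  s <- read_structure(path)
  b <- s$atom$b[s$atom$resno == 1]
  expect_true(all(b == 12.5))
  expect_true(all(s$atom$b[s$atom$resno == 2] == 3.25))
  expect_true(all(s$atom$b[s$atom$resno %in% 3:4] == -1))
  # empty map -> all sentinels
  write_annotated(h, numeric(0), path, sentinel = -2)
  expect_true(all(read_structure(path)$atom$b == -2))
  # column overflow is an error, not silent truncation
  big <- stats::setNames(12345.6, rt$key[1])
  expect_error(write_annotated(h, big, path), "range")
  expect_error(write_annotated(h, stats::setNames(NaN, rt$key[1]), path),
               "finite")
})

test_that("the selection grammar selects chains, ranges and atom names", {
  d <- make_helix_dimer(n_res_a = 20, n_res_b = 10)
  sel <- select_structure(d, "chain A and resno 5-15")
  expect_equal(nrow(residue_table(sel)), 11L)
  expect_true(all(sel$atom$chain == "A"))
  expect_equal(select_structure(d, "all")$atom, d$atom)
  ca <- select_structure(d, "name CA")
  expect_equal(nrow(ca$atom), nrow(residue_table(d)))
  expect_equal(nrow(select_structure(d, "resno 1,3,5 and chain B")$atom), 15L)
  expect_equal(nrow(select_structure(d, "chain Q")$atom), 0L)
})

test_that("malformed selections report a syntax error with position", {
  h <- make_helix(4)
  expect_error(select_structure(h, "chian A"), "position 1")
  expect_error(select_structure(h, "chain A and resno x-3"), "position")
  expect_error(select_structure(h, "chain A and "), "empty clause")
  expect_error(select_structure(h, "resno 9-3"), "bad range")
})

test_that("incomplete residues are detected by heavy-atom count", {
  h <- make_helix(5)
  inc <- incomplete_residues(h)
  expect_true(all(!inc$incomplete))
  # drop one side-chain atom
  h2 <- h
  h2$atom <- h2$atom[!(h2$atom$resno == 3 & h2$atom$elety == "CB"), ]
  inc2 <- incomplete_residues(h2)
  expect_equal(inc2$incomplete, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  # nonstandard residues are flagged NA, not guessed
  cage <- make_sphere_cage(8, 20)
  expect_true(all(is.na(incomplete_residues(cage)$incomplete)))
})

test_that("radii lookup is total: override, element, then default", {
  s <- atoms_structure(rbind(c(0, 0, 0), c(5, 0, 0)), elem = c("C", "XX"))
  r0 <- atom_radii(s)
  expect_equal(r0, c(1.70, 1.70))  # unknown element falls to default
  rs <- radii_set("custom", c(C = 2.0), default = 1.0,
                  overrides = data.frame(resid = "DUM", elety = "C",
                                         radius = 0.5))
  expect_equal(atom_radii(s, rs), c(0.5, 1.0))
  expect_error(radii_set("bad", c(C = -1)), "> 0")
})
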