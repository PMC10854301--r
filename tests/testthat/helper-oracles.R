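# Independent oracles and small fixture builders used across the suite.

# Closed-form area of one sphere of radius R partially buried by an
# identical sphere at centre distance d (spherical-cap formula).
two_sphere_area <- function(R, d) {
  if (d >= 2 * R) return(4 * pi * R^2)
  4 * pi * R^2 - 2 * pi * R * (R - d / 2)
}

# Horn's quaternion absolute-orientation method: an independent
# superposition oracle (the package uses Kabsch/SVD).
quaternion_superpose <- function(P, Q) {
  cP <- colMeans(P); cQ <- colMeans(Q)
  P0 <- sweep(P, 2, cP); Q0 <- sweep(Q, 2, cQ)
  S <- t(P0) %*% Q0
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[1, 3] + S[3, 1]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  moved <- P0 %*% t(R)
  sqrt(mean(rowSums((moved - Q0)^2)))
}

# All-pairs brute-force contact scan (the package's contacts() must
# reproduce this exactly).
brute_contacts <- function(xyz_a, xyz_b, cutoff) {
  hits <- list(); n <- 0L
  for (i in seq_len(nrow(xyz_a))) {
    for (j in seq_len(nrow(xyz_b))) {
      d <- sqrt(sum((xyz_a[i, ] - xyz_b[j, ])^2))
      if (d < cutoff) { n <- n + 1L; hits[[n]] <- c(i, j, d) }
    }
  }
  if (n == 0L) return(matrix(numeric(0), ncol = 3))
  do.call(rbind, hits)
}

# Deterministic random rotation matrix.
random_rotation <- function(seed) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3)
  qr_d <- qr(M)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Residues of chain_a farther than `cutoff` from every chain_b atom.
far_residue_keys <- function(struc, chain_a = "A", chain_b = "B",
                             cutoff = 15) {
  at <- struc$atom
  xyz <- coords(struc)
  ib <- which(at$chain == chain_b)
  rt <- residue_table(struc)
  rt <- rt[rt$chain == chain_a, ]
  keep <- vapply(rt$key, function(k) {
    ia <- which(at$chain == chain_a &
                  paste0(at$chain, "|", at$resno, "|", at$insert) == k)
    all(vapply(ia, function(i)
      min(sqrt((xyz[ib, 1] - xyz[i, 1])^2 + (xyz[ib, 2] - xyz[i, 2])^2 +
                 (xyz[ib, 3] - xyz[i, 3])^2)) > cutoff, logical(1)))
  }, logical(1))
  rt$key[keep]
}

# A tiny handcrafted PDB text (3 atoms, 1 residue).
write_mini_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00 11.00           C",
    "ATOM      3  C   ALA A   1      12.685   7.182  -5.055  1.00 12.00           C",
    "END"), path)
  path
}

# Single free-standing atoms at given coordinates (one residue each).
atoms_structure <- function(xyz, elem = "C", elety = elem, chain = "A") {
  xyz <- matrix(xyz, ncol = 3)
  structure3d(data.frame(
    type = "ATOM", eleno = seq_len(nrow(xyz)), elety = elety, alt = "",
    resid = "DUM", chain = chain, resno = seq_len(nrow(xyz)), insert = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = 0, elem = elem,
    stringsAsFactors = FALSE), id = "atoms")
}
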