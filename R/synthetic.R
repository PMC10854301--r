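#' Synthetic structure generators
#'
#' Deterministic geometric fixtures standing in for experimental
#' coordinates: ideal helices, helix dimers, tight/expanded
#' ("closed/open") complex pairs, sphere cages enclosing a void,
#' packed and random atom clusters, and proline rings with controlled
#' pucker.  Every generator is seed-deterministic and echoes its
#' parameters in a `"generator"` attribute.  Fixtures are geometric,
#' not biological: they validate the pipeline, not any particular
#' protein.
#'
#' @name synthetic
NULL

new_atoms <- function(elety, resid, chain, resno, xyz, type = "ATOM",
                      elem = NULL) {
  if (is.null(elem)) elem <- substr(gsub("^[0-9]+", "", elety), 1L, 1L)
  data.frame(type = type, eleno = seq_along(elety), elety = elety,
             alt = "", resid = resid, chain = chain, resno = resno,
             insert = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             o = 1, b = 0, elem = elem, stringsAsFactors = FALSE)
}

with_generator <- function(struc, params) {
  attr(struc, "generator") <- params
  struc
}

# Natural-extension reference frame: place atom D bonded to C with the
# given bond length, angle B-C-D (deg) and torsion A-B-C-D (deg).
nerf_place <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + cbind(bc, m, n) %*% d2
}

#' Ideal poly-alanine helix
#'
#' Builds an N/CA/C/O/CB backbone with standard bond lengths and
#' angles at the given backbone dihedrals (alpha-helical by default:
#' phi -57, psi -47 degrees, omega 180).  The helix is positioned with
#' its axis along z and centroid at the origin.  The ideal alpha-helix
#' has a rise of about 1.5 Angstrom per residue and a CA(i)-CA(i+4)
#' distance of about 6.2 Angstrom.
#'
#' @param n_res number of residues (>= 2).
#' @param phi,psi backbone dihedrals in degrees.
#' @param chain chain identifier.
#' @param start_resno first residue number.
#' @return a [structure3d] of `n_res` ALA residues.
#' @export
make_helix <- function(n_res, phi = -57, psi = -47, chain = "A",
                       start_resno = 1L) {
  if (n_res < 2) stop("n_res must be >= 2")
  bN_CA <- 1.458; bCA_C <- 1.525; bC_N <- 1.329; bC_O <- 1.231; bCA_CB <- 1.521
  aN_CA_C <- 111.2; aCA_C_N <- 116.2; aC_N_CA <- 121.7; aCA_C_O <- 120.8
  N <- matrix(0, n_res, 3); CA <- N; C <- N; O <- N; CB <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(bN_CA, 0, 0)
  C[1, ] <- CA[1, ] + bCA_C * c(-cos(aN_CA_C * pi / 180),
                                sin(aN_CA_C * pi / 180), 0)
  for (i in 2:n_res) {
    N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ], bC_N, aCA_C_N, psi)
    CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ], bN_CA, aC_N_CA, 180)
    C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ], bCA_C, aN_CA_C, phi)
  }
  for (i in 1:n_res) {
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], bC_O, aCA_C_O, psi + 180)
    u1 <- N[i, ] - CA[i, ]; u1 <- u1 / sqrt(sum(u1^2))
    u2 <- C[i, ] - CA[i, ]; u2 <- u2 / sqrt(sum(u2^2))
    bis <- -(u1 + u2); bis <- bis / sqrt(sum(bis^2))
    pp <- c(u1[2] * u2[3] - u1[3] * u2[2],
            u1[3] * u2[1] - u1[1] * u2[3],
            u1[1] * u2[2] - u1[2] * u2[1])
    pp <- pp / sqrt(sum(pp^2))
    dir <- cos(0.96) * bis + sin(0.96) * pp   # ~55 deg off the bisector
    CB[i, ] <- CA[i, ] + bCA_CB * dir
  }
  nm <- c("N", "CA", "C", "O", "CB")
  xyz <- do.call(rbind, lapply(1:n_res, function(i)
    rbind(N[i, ], CA[i, ], C[i, ], O[i, ], CB[i, ])))
  atoms <- new_atoms(elety = rep(nm, n_res), resid = "ALA", chain = chain,
                     resno = rep(start_resno + (1:n_res) - 1L, each = 5L),
                     xyz = xyz)
  struc <- align_axis_z(structure3d(atoms, id = sprintf("helix-%d", n_res)))
  with_generator(struc, list(kind = "ideal_helix", n_res = n_res,
                             phi = phi, psi = psi))
}

# Rotate so the principal axis of the CA trace is +z, centroid at origin.
align_axis_z <- function(struc) {
  xyz <- coords(struc)
  ca <- xyz[struc$atom$elety == "CA", , drop = FALSE]
  if (nrow(ca) < 2) ca <- xyz
  ctr <- colMeans(ca)
  v <- eigen(crossprod(sweep(ca, 2, ctr)), symmetric = TRUE)$vectors
  R <- cbind(v[, 2], v[, 3], v[, 1])   # PC1 -> z
  if (det(R) < 0) R[, 1] <- -R[, 1]
  if (sum(diff(sweep(ca, 2, ctr) %*% R[, 3])) < 0) {  # N-to-C along +z
    R[, 3] <- -R[, 3]; R[, 1] <- -R[, 1]
  }
  out <- sweep(coords(struc), 2, ctr) %*% R
  struc$atom$x <- out[, 1]; struc$atom$y <- out[, 2]; struc$atom$z <- out[, 3]
  struc
}

#' Two-helix dimer
#'
#' Chain A is an ideal helix along z; chain B is a second helix offset
#' by `separation` along x (axis-to-axis) and by `z_offset` along z.
#' At the default 10 Angstrom separation the two surfaces are in van
#' der Waals contact, emulating a tightly packed subunit interface.
#' With `caps = TRUE`, plates of atoms (chain X) close the inter-helix
#' groove at both z ends, turning it into an enclosed inter-chain
#' void.
#'
#' @param n_res_a,n_res_b residues per helix.
#' @param separation axis-to-axis distance, Angstrom.
#' @param z_offset z shift of chain B (default centres both).
#' @param caps add end plates (default `FALSE`).
#' @return a [structure3d] with chains A, B (and X when capped).
#' @export
make_helix_dimer <- function(n_res_a = 16, n_res_b = n_res_a,
                             separation = 10, z_offset = 0, caps = FALSE) {
  ha <- make_helix(n_res_a, chain = "A")
  hb <- make_helix(n_res_b, chain = "B")
  hb$atom$x <- hb$atom$x + separation
  hb$atom$z <- hb$atom$z + z_offset
  atoms <- rbind(ha$atom, hb$atom)
  if (caps) {
    zr <- range(atoms$z)
    gx <- seq(-2, separation + 2, by = 2)
    gy <- seq(-4, 4, by = 2)
    plate <- expand.grid(x = gx, y = gy)
    cap <- do.call(rbind, lapply(c(zr[1] - 2.5, zr[2] + 2.5), function(zc)
      cbind(plate$x, plate$y, zc)))
    atoms <- rbind(atoms,
                   new_atoms(elety = "C", resid = "CAP", chain = "X",
                             resno = seq_len(nrow(cap)), xyz = cap))
  }
  atoms$eleno <- seq_len(nrow(atoms))
  struc <- structure3d(atoms, id = sprintf("helix-dimer-%d-%d", n_res_a, n_res_b))
  with_generator(struc, list(kind = "helix_dimer", n_res_a = n_res_a,
                             n_res_b = n_res_b, separation = separation,
                             z_offset = z_offset, caps = caps))
}

#' Helix-in-socket complex with a fully releasable interface
#'
#' Chain A is an ideal helix along z; chain B is a concave two-layer
#' shell ("socket") capping the helix +z end.  The shell is an offset
#' surface of the helix top: along every direction within `cone_deg`
#' of +z the inner layer sits at `contact_dist` from the nearest A
#' atom, and at `loose_dist` further out, down to `max_ang` from the
#' axis.  Two atoms occlude one another's solvent shells only while
#' their centres are within r1 + r2 + 2 * probe (about 6.2 Angstrom
#' for carbon and water); displacing chain B by `d` along +z moves a
#' pair at distance D and angle theta from the axis to
#' `sqrt(D^2 + d^2 + 2 D d cos(theta))`.  The shell geometry is chosen
#' so that every inter-chain pair inside the occlusion horizon leaves
#' it after a 3 Angstrom displacement: the opening motion fully
#' disengages the interface instead of merely stretching it, which is
#' the signature a differential SASA analysis is meant to detect.
#'
#' Below the shell rim a cylindrical sleeve (still chain B) hugs the
#' helix flank at `sleeve_radius`.  The sleeve slides *along* the
#' flank when chain B lifts, so its occlusion of the flank is
#' essentially constant (no SASA signal), but it keeps the chamber
#' between the helix top and the cap sealed against the bulk-solvent
#' probe at every opening distance, so the enclosed inter-chain void
#' grows monotonically with the separation.  Shell and sleeve atoms
#' are grouped four-at-a-time into pseudo-glycine residues so the
#' relative-SASA machinery treats them like protein.
#'
#' @param n_res chain A helix length.
#' @param contact_dist inner-shell offset over the polar cone,
#'   Angstrom (within the 5 Angstrom interface cutoff).
#' @param loose_dist shell offset outside the cone, Angstrom.
#' @param cone_deg polar angle of the close-contact cone, degrees.
#' @param max_ang maximum polar angle of the shell, degrees.
#' @param center_drop how far below the top-two-residue centroid the
#'   shell centre sits, Angstrom; lowering it lets the skirt wrap the
#'   second-from-top residue while keeping every inter-chain pair at
#'   or above the horizontal (so the release inequality holds).
#' @param n_dirs sphere-lattice size controlling shell atom density.
#' @param sleeve_len length of the cylindrical sleeve below the rim,
#'   Angstrom (0 disables it).
#' @param sleeve_radius sleeve radius from the helix axis, Angstrom
#'   (comfortably outside the 5 Angstrom interface cutoff from the
#'   flank atoms).
#' @param chamber lifts the whole socket by this many Angstrom,
#'   creating a sealed solvent-size chamber between the helix top and
#'   the cap even in the closed state.  With `chamber = 0` (default)
#'   the cap engages the helix at `contact_dist` (the differential
#'   SASA study); with a positive chamber (e.g. 6) the enclosed
#'   inter-chain void exists at every separation and grows with it
#'   (the cavity monotonicity study).
#' @return a [structure3d] with chains A (helix) and B (socket).
#' @export
make_socket_complex <- function(n_res = 40, contact_dist = 4.6,
                                loose_dist = 5.6, cone_deg = 35,
                                max_ang = 88, center_drop = 4,
                                n_dirs = 300, sleeve_len = 9,
                                sleeve_radius = 9, chamber = 0) {
  helix <- make_helix(n_res, chain = "A")
  xyz <- coords(helix)
  # shell centre: centroid of the top two residues
  top <- helix$atom$resno >= n_res - 1L
  c0 <- colMeans(xyz[top, , drop = FALSE]) - c(0, 0, center_drop)
  dirs <- sphere_points(n_dirs)
  dirs <- dirs[dirs[, 3] >= cos(max_ang * pi / 180), , drop = FALSE]
  near <- xyz[xyz[, 3] > c0[3] - 12, , drop = FALSE]  # atoms the shell can see
  offset_point <- function(u, target) {
    rel <- sweep(near, 2, c0)
    proj <- rel %*% u
    perp2 <- rowSums(rel^2) - proj^2
    ok <- perp2 < target^2
    if (!any(ok)) return(NULL)
    t <- max(proj[ok] + sqrt(target^2 - perp2[ok]))
    c0 + t * u
  }
  layer <- function(extra) {
    pts <- lapply(seq_len(nrow(dirs)), function(k) {
      u <- dirs[k, ]
      ang <- acos(u[3]) * 180 / pi
      target <- if (ang <= cone_deg) contact_dist else loose_dist
      b <- offset_point(u, target)
      if (is.null(b)) NULL else b + extra * u
    })
    do.call(rbind, pts)
  }
  shell <- rbind(layer(0), layer(2.2))
  if (sleeve_len > 0) {
    # rings from just above the skirt rim downward along the flank
    zs <- seq(c0[3] + 1, c0[3] + 1 - sleeve_len, by = -2)
    n_ring <- max(8L, round(2 * pi * sleeve_radius / 2.2))
    ang <- 2 * pi * (seq_len(n_ring) - 1L) / n_ring
    sleeve <- do.call(rbind, lapply(zs, function(z)
      cbind(sleeve_radius * cos(ang), sleeve_radius * sin(ang), z)))
    shell <- rbind(shell, sleeve)
  }
  # constructive guarantee: any shell atom engaging a helix atom inside
  # the 5 A interface cutoff must fully leave the occlusion horizon
  # after a 3 A lift (with margin for the centroid-axis tilt)
  keep <- vapply(seq_len(nrow(shell)), function(k) {
    dd <- sqrt(rowSums(sweep(xyz, 2, shell[k, ])^2))
    eng <- dd < 5
    if (!any(eng)) return(TRUE)
    lifted <- shell[k, ] + c(0, 0, 3)
    all(sqrt(rowSums(sweep(xyz[eng, , drop = FALSE], 2, lifted)^2)) >= 6.35)
  }, logical(1))
  shell <- shell[keep, , drop = FALSE]
  if (chamber > 0) shell[, 3] <- shell[, 3] + chamber
  # group shell atoms into 4-atom pseudo-glycines, layer by layer
  n_res_b <- floor(nrow(shell) / 4)
  shell <- shell[seq_len(4 * n_res_b), , drop = FALSE]
  atoms_b <- new_atoms(elety = rep(c("N", "CA", "C", "O"), n_res_b),
                       resid = "GLY", chain = "B",
                       resno = rep(seq_len(n_res_b), each = 4L),
                       xyz = shell)
  atoms <- rbind(helix$atom, atoms_b)
  atoms$eleno <- seq_len(nrow(atoms))
  struc <- structure3d(atoms, id = sprintf("socket-complex-%d", n_res))
  with_generator(struc, list(kind = "socket_complex", n_res = n_res,
                             contact_dist = contact_dist,
                             loose_dist = loose_dist, cone_deg = cone_deg,
                             max_ang = max_ang, center_drop = center_drop,
                             n_dirs = n_dirs, sleeve_len = sleeve_len,
                             sleeve_radius = sleeve_radius,
                             chamber = chamber))
}

#' Tight/expanded ("closed/open") complex pair
#'
#' The closed structure is the base complex; the open structure is the
#' same complex with one chain rigidly translated by `d` Angstrom
#' along the axis joining the two chain centroids, opening the
#' interface while keeping sequences, numbering and atom order
#' identical.  This emulates a pair of complexes that differ by a
#' looser subunit interface.
#'
#' @param base a multi-chain [structure3d] (default: the
#'   [make_socket_complex()] helix-in-socket complex, whose interface
#'   is fully disengaged by the opening displacement and whose long
#'   helix provides residues far from the interface).
#' @param d separation increment, Angstrom (>= 0).
#' @param move_chain chain translated in the open copy (default "B").
#' @param ref_chain chain defining the other end of the centroid axis.
#' @return list with elements `closed` and `open`.
#' @export
make_open_closed_pair <- function(base = make_socket_complex(),
                                  d = 3, move_chain = "B", ref_chain = "A") {
  if (d < 0) stop("d must be >= 0")
  at <- base$atom
  if (!all(c(move_chain, ref_chain) %in% at$chain))
    stop("base structure lacks chain ", move_chain, " or ", ref_chain)
  ca <- colMeans(as.matrix(at[at$chain == ref_chain, c("x", "y", "z")]))
  cb <- colMeans(as.matrix(at[at$chain == move_chain, c("x", "y", "z")]))
  axis <- cb - ca
  axis <- axis / sqrt(sum(axis^2))
  open <- base
  mv <- open$atom$chain == move_chain
  open$atom$x[mv] <- open$atom$x[mv] + d * axis[1]
  open$atom$y[mv] <- open$atom$y[mv] + d * axis[2]
  open$atom$z[mv] <- open$atom$z[mv] + d * axis[3]
  open$id <- paste0(base$id, "-open-d", d)
  closed <- base
  closed$id <- paste0(base$id, "-closed")
  list(closed = with_generator(closed, list(kind = "open_closed_pair",
                                            role = "closed", d = d)),
       open = with_generator(open, list(kind = "open_closed_pair",
                                        role = "open", d = d)))
}

#' Interface residues of a two-chain complex
#'
#' The residues (of both chains) having any atom within `cutoff` of
#' the partner chain.  This is the definition used by the pipeline
#' recovery tests: interface membership is always evaluated on the
#' closed structure.
#'
#' @param struc a [structure3d].
#' @param chain_a,chain_b the two chains.
#' @param cutoff Angstrom (default 5).
#' @return data.frame of residues (chain, resno, insert, resid, key).
#' @export
interface_residues <- function(struc, chain_a = "A", chain_b = "B",
                               cutoff = 5) {
  at <- struc$atom
  ia <- which(at$chain == chain_a)
  ib <- which(at$chain == chain_b)
  xyz <- coords(struc)
  keys <- atom_residue_keys(struc)
  touch <- character(0)
  for (i in ia) {
    d2 <- (xyz[ib, 1] - xyz[i, 1])^2 + (xyz[ib, 2] - xyz[i, 2])^2 +
      (xyz[ib, 3] - xyz[i, 3])^2
    if (any(d2 < cutoff^2)) touch <- c(touch, keys[i], keys[ib[d2 < cutoff^2]])
  }
  rt <- residue_table(struc)
  rt[rt$key %in% unique(touch), , drop = FALSE]
}

#' Spherical cage of atoms enclosing a void
#'
#' Atoms are placed quasi-uniformly (golden-spiral lattice) on a
#' sphere; with enough atoms the gaps between neighbouring atoms are
#' too narrow for the solvent probe and the interior becomes an
#' enclosed cavity of analytically known size.  `open_angle > 0`
#' removes the polar cap of atoms around +z, opening a mouth.  The
#' maximal inter-atom gap is reported so callers can check
#' probe-tightness; a cage whose estimated hole radius exceeds
#' `probe_radius` carries a `leaky = TRUE` flag (a warning field, not
#' a failure).
#'
#' @param radius sphere radius, Angstrom.
#' @param n_atoms number of atoms (>= 12).
#' @param open_angle polar angle (degrees) of the removed cap.
#' @param probe_radius probe used for the leak check.
#' @return a [structure3d]; attributes `max_gap` (largest
#'   nearest-neighbour distance), `hole_radius` (estimated largest
#'   inter-atom hole radius) and `leaky`.
#' @export
make_sphere_cage <- function(radius = 8, n_atoms = 60, open_angle = 0,
                             probe_radius = 1.4) {
  if (n_atoms < 12) stop("n_atoms must be >= 12")
  pts <- sphere_points(n_atoms) * radius
  if (open_angle > 0) {
    polar <- acos(pts[, 3] / radius) * 180 / pi
    pts <- pts[polar > open_angle, , drop = FALSE]
  }
  nn <- apply(as.matrix(stats::dist(pts)) + diag(Inf, nrow(pts)), 1, min)
  max_gap <- max(nn)
  r_atom <- default_radii()$elements[["C"]]
  hole_radius <- max_gap / sqrt(3) - r_atom   # circumradius of the widest
  struc <- structure3d(                       # triangular hole, heuristically
    new_atoms(elety = "C", resid = "CAG", chain = "A",
              resno = seq_len(nrow(pts)), xyz = pts),
    id = sprintf("sphere-cage-r%g-n%d", radius, n_atoms))
  attr(struc, "max_gap") <- max_gap
  attr(struc, "hole_radius") <- hole_radius
  attr(struc, "leaky") <- hole_radius > probe_radius
  with_generator(struc, list(kind = "sphere_cage", radius = radius,
                             n_atoms = n_atoms, open_angle = open_angle))
}

#' Packed atom cluster (no interior void)
#'
#' Carbon atoms on a cubic lattice filled from the centre outward:
#' a solid cluster whose interstices are too small for the probe, so
#' cavity detection must find nothing.
#'
#' @param n_atoms number of atoms.
#' @param spacing lattice spacing, Angstrom (default 2: below twice
#'   the carbon van der Waals radius, so neighbouring spheres overlap).
#' @return a [structure3d].
#' @export
make_sphere_cluster <- function(n_atoms = 30, spacing = 2.0) {
  k <- ceiling((n_atoms^(1 / 3) - 1) / 2) + 1L
  g <- expand.grid(x = -k:k, y = -k:k, z = -k:k) * spacing
  g <- g[order(g$x^2 + g$y^2 + g$z^2, g$x, g$y, g$z), ][seq_len(n_atoms), ]
  struc <- structure3d(
    new_atoms(elety = "C", resid = "DUM", chain = "A",
              resno = seq_len(n_atoms), xyz = as.matrix(g)),
    id = sprintf("cluster-%d", n_atoms))
  with_generator(struc, list(kind = "sphere_cluster", n_atoms = n_atoms,
                             spacing = spacing))
}

#' Random atom cluster
#'
#' Seeded Gaussian cloud of carbon atoms, used for oracle-equivalence
#' and property tests (burial monotonicity, contact brute-force
#' checks).  Same seed, same coordinates.
#'
#' @param n_atoms number of atoms.
#' @param sd standard deviation of the Gaussian cloud, Angstrom.
#' @param seed RNG seed.
#' @param chain chain identifier.
#' @return a [structure3d].
#' @export
make_random_cluster <- function(n_atoms = 20, sd = 3, seed = 1, chain = "A") {
  set.seed(seed)
  xyz <- matrix(stats::rnorm(3 * n_atoms, sd = sd), ncol = 3)
  struc <- structure3d(
    new_atoms(elety = "C", resid = "DUM", chain = chain,
              resno = seq_len(n_atoms), xyz = xyz),
    id = sprintf("random-cluster-%d-seed%d", n_atoms, seed))
  with_generator(struc, list(kind = "random_cluster", n_atoms = n_atoms,
                             sd = sd, seed = seed))
}

#' Proline residue with controlled ring pucker
#'
#' A single PRO residue whose ring atoms are placed so that N, CA, CB
#' and CD are exactly coplanar and CG is displaced by `amplitude`
#' Angstrom from that plane - on the same side as the backbone
#' carbonyl carbon for `"endo"`, the opposite side for `"exo"`.
#' With amplitude below the planarity threshold the ring is planar.
#'
#' @param pucker `"endo"` or `"exo"`.
#' @param amplitude CG out-of-plane displacement, Angstrom (>= 0).
#' @param chain,resno residue identity.
#' @return a [structure3d] with one PRO residue (N, CA, C, O, CB, CG, CD).
#' @export
make_proline_ring <- function(pucker = c("endo", "exo"), amplitude = 0.3,
                              chain = "A", resno = 1L) {
  pucker <- match.arg(pucker)
  if (amplitude < 0) stop("amplitude must be >= 0")
  rad <- 1.5 / (2 * sin(pi / 5))       # pentagon circumradius, side 1.5
  ang <- (90 - 72 * (0:4)) * pi / 180  # N, CA, CB, CG, CD around the ring
  ring <- cbind(rad * cos(ang), rad * sin(ang), 0)
  rownames(ring) <- c("N", "CA", "CB", "CG", "CD")
  cz <- 0.5                            # carbonyl C sits above the plane
  cg_z <- if (pucker == "endo") amplitude else -amplitude
  ring["CG", 3] <- cg_z
  ca <- ring["CA", ]
  cdir <- c(ca[1], ca[2], 0) / sqrt(sum(ca[1:2]^2))
  Cp <- c(ca[1:2] + 1.42 * cdir[1:2], cz)
  Op <- c(Cp[1:2] + 1.18 * cdir[1:2], cz + 0.35)
  xyz <- rbind(ring["N", ], ring["CA", ], Cp, Op,
               ring["CB", ], ring["CG", ], ring["CD", ])
  struc <- structure3d(
    new_atoms(elety = c("N", "CA", "C", "O", "CB", "CG", "CD"),
              resid = "PRO", chain = chain, resno = resno, xyz = xyz),
    id = sprintf("proline-%s-%.2f", pucker, amplitude))
  with_generator(struc, list(kind = "proline_ring", pucker = pucker,
                             amplitude = amplitude))
}
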