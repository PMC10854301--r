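#' C-alpha to C-alpha distance
#'
#' Euclidean distance in Angstrom between the CA atoms of two residues
#' (e.g. K227 in TM6 to R293 in H8, or the Q35-Y339 HN-H4 axis of a
#' G alpha subunit).
#'
#' @param struc a [structure3d].
#' @param a,b [residue_ref()] objects.
#' @return distance in Angstrom.
#' @export
ca_distance <- function(struc, a, b) {
  pa <- ca_coord(struc, a)
  pb <- ca_coord(struc, b)
  sqrt(sum((pa - pb)^2))
}

ca_coord <- function(struc, ref) {
  idx <- residue_atom_idx(struc, ref)
  ca <- idx[struc$atom$elety[idx] == "CA"]
  if (!length(ca))
    stop("residue ", format(ref), " has no CA atom in '", struc$id, "'")
  unlist(struc$atom[ca[1], c("x", "y", "z")], use.names = FALSE)
}

#' Contact parameters
#' @param cutoff contact distance cutoff in Angstrom; pairs strictly
#'   below it count (default 4.0).
#' @param heavy_atoms_only ignore hydrogens (default `TRUE`).
#' @return object of class `contact_params`.
#' @export
contact_params <- function(cutoff = 4.0, heavy_atoms_only = TRUE) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  structure(list(cutoff = cutoff, heavy_atoms_only = heavy_atoms_only),
            class = "contact_params")
}

#' Inter-selection atomic contacts
#'
#' All and only atom pairs, one from each selection, with distance
#' strictly below the cutoff.  Selections must not overlap.  Output is
#' deterministic (selection-a atom order, then selection-b), with a
#' deduplicated residue-pair summary.
#'
#' @param struc a [structure3d].
#' @param sel_a,sel_b selection strings (see [select_structure()]) or
#'   integer atom-index vectors.
#' @param params a [contact_params()].
#' @return object of class `contact_list`: `atoms` data.frame (atom
#'   identities and distance), `residue_pairs` data.frame, `params`.
#' @export
contacts <- function(struc, sel_a, sel_b, params = contact_params()) {
  ia <- as_atom_idx(struc, sel_a)
  ib <- as_atom_idx(struc, sel_b)
  if (length(intersect(ia, ib)))
    stop("selections overlap (", length(intersect(ia, ib)), " shared atoms)")
  if (params$heavy_atoms_only) {
    ia <- ia[struc$atom$elem[ia] != "H"]
    ib <- ib[struc$atom$elem[ib] != "H"]
  }
  at <- struc$atom
  rows <- list(); n <- 0L
  xyzb <- as.matrix(at[ib, c("x", "y", "z"), drop = FALSE])
  for (i in ia) {
    d <- sqrt((xyzb[, 1] - at$x[i])^2 + (xyzb[, 2] - at$y[i])^2 +
                (xyzb[, 3] - at$z[i])^2)
    hit <- which(d < params$cutoff)
    if (length(hit)) {
      n <- n + 1L
      rows[[n]] <- data.frame(idx_a = i, idx_b = ib[hit], dist = d[hit])
    }
  }
  pairs <- if (n) do.call(rbind, rows) else
    data.frame(idx_a = integer(), idx_b = integer(), dist = numeric())
  atoms <- data.frame(
    chain_a = at$chain[pairs$idx_a], resno_a = at$resno[pairs$idx_a],
    resid_a = at$resid[pairs$idx_a], elety_a = at$elety[pairs$idx_a],
    chain_b = at$chain[pairs$idx_b], resno_b = at$resno[pairs$idx_b],
    resid_b = at$resid[pairs$idx_b], elety_b = at$elety[pairs$idx_b],
    dist = pairs$dist, stringsAsFactors = FALSE)
  rp <- unique(atoms[, c("chain_a", "resno_a", "resid_a",
                         "chain_b", "resno_b", "resid_b")])
  rownames(rp) <- NULL
  structure(list(atoms = atoms, residue_pairs = rp, params = params,
                 structure_id = struc$id),
            class = "contact_list")
}

as_atom_idx <- function(struc, sel) {
  if (is.character(sel)) select_atom_idx(struc, sel)
  else as.integer(sel)
}

#' @export
print.contact_list <- function(x, ...) {
  cat(sprintf("contact_list: %d atom pairs, %d residue pairs (cutoff %.2f A)\n",
              nrow(x$atoms), nrow(x$residue_pairs), x$params$cutoff))
  invisible(x)
}

#' Hydrogen-bond criteria
#'
#' Hydrogen-free geometric criteria suited to experimental models that
#' lack hydrogens: donor-acceptor heavy-atom distance, plus (when an
#' antecedent atom is identifiable) a minimum antecedent-donor-acceptor
#' angle.
#'
#' @param max_distance donor-acceptor maximum distance, Angstrom
#'   (default 3.5).
#' @param min_angle minimum antecedent-donor-acceptor angle, degrees
#'   (default 90).
#' @param donor_elements,acceptor_elements element sets.
#' @return object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_distance = 3.5, min_angle = 90,
                           donor_elements = c("N", "O", "S"),
                           acceptor_elements = c("N", "O", "S")) {
  if (max_distance <= 0) stop("max_distance must be > 0")
  if (min_angle < 0 || min_angle > 180) stop("min_angle must be in [0, 180]")
  structure(list(max_distance = max_distance, min_angle = min_angle,
                 donor_elements = donor_elements,
                 acceptor_elements = acceptor_elements),
            class = "hbond_criteria")
}

#' Hydrogen bonds between two selections
#'
#' Candidate donor/acceptor atoms are identified by element.  A pair
#' (one atom from each selection, different residues) is a bond when
#' the heavy-atom distance is within `max_distance` and, for each atom
#' whose covalent antecedent can be found (nearest heavy atom within
#' 1.8 Angstrom), the antecedent-atom-partner angle is at least
#' `min_angle`.  Criteria are echoed in the output.
#'
#' @inheritParams contacts
#' @param criteria a [hbond_criteria()].
#' @return a `contact_list` whose `atoms` rows carry the bond distance;
#'   `criteria` echoed.
#' @export
hydrogen_bonds <- function(struc, sel_a, sel_b, criteria = hbond_criteria()) {
  ia <- as_atom_idx(struc, sel_a)
  ib <- as_atom_idx(struc, sel_b)
  at <- struc$atom
  el <- at$elem
  ia <- ia[el[ia] %in% union(criteria$donor_elements, criteria$acceptor_elements)]
  ib <- ib[el[ib] %in% union(criteria$donor_elements, criteria$acceptor_elements)]
  rows <- list(); n <- 0L
  xyz <- coords(struc)
  keys <- atom_residue_keys(struc)
  for (i in ia) {
    for (j in ib) {
      if (keys[i] == keys[j]) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d > criteria$max_distance || d < 2.0) next
      # donor/acceptor roles are ambiguous without hydrogens: require
      # the angle criterion on both ends where computable
      if (!angle_ok(struc, xyz, keys, i, j, criteria$min_angle)) next
      if (!angle_ok(struc, xyz, keys, j, i, criteria$min_angle)) next
      n <- n + 1L
      rows[[n]] <- data.frame(idx_a = i, idx_b = j, dist = d)
    }
  }
  pairs <- if (n) do.call(rbind, rows) else
    data.frame(idx_a = integer(), idx_b = integer(), dist = numeric())
  atoms <- data.frame(
    chain_a = at$chain[pairs$idx_a], resno_a = at$resno[pairs$idx_a],
    resid_a = at$resid[pairs$idx_a], elety_a = at$elety[pairs$idx_a],
    chain_b = at$chain[pairs$idx_b], resno_b = at$resno[pairs$idx_b],
    resid_b = at$resid[pairs$idx_b], elety_b = at$elety[pairs$idx_b],
    dist = pairs$dist, stringsAsFactors = FALSE)
  rp <- unique(atoms[, c("chain_a", "resno_a", "resid_a",
                         "chain_b", "resno_b", "resid_b")])
  rownames(rp) <- NULL
  structure(list(atoms = atoms, residue_pairs = rp, criteria = criteria,
                 params = contact_params(cutoff = criteria$max_distance),
                 structure_id = struc$id, bond_type = "hydrogen-bond"),
            class = "contact_list")
}

angle_ok <- function(struc, xyz, keys, i, partner, min_angle) {
  same_res <- which(keys == keys[i] & struc$atom$elem != "H")
  same_res <- setdiff(same_res, i)
  if (!length(same_res)) return(TRUE)
  d <- sqrt((xyz[same_res, 1] - xyz[i, 1])^2 +
              (xyz[same_res, 2] - xyz[i, 2])^2 +
              (xyz[same_res, 3] - xyz[i, 3])^2)
  ante <- same_res[d < 1.8]
  if (!length(ante)) return(TRUE)
  ante <- ante[which.min(d[d < 1.8])]
  v1 <- xyz[ante, ] - xyz[i, ]
  v2 <- xyz[partner, ] - xyz[i, ]
  ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                             (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
  ang >= min_angle
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rotation and translation minimising the RMSD between
#' paired atoms (typically CA atoms of corresponding residues, e.g. a
#' TM6 or Ras-domain alignment).  Requires at least three
#' non-collinear pairs.
#'
#' @param mobile,target n x 3 coordinate matrices of paired atoms, or
#'   [structure3d] objects together with `sel_mobile`/`sel_target`
#'   selections resolving to equal-length atom sets.
#' @param sel_mobile,sel_target optional selection strings.
#' @return list with `rotation` (3 x 3), `translation` (length 3;
#'   transformed x = R x + t), `rmsd` and `n`.
#' @export
superpose <- function(mobile, target, sel_mobile = NULL, sel_target = NULL) {
  P <- superpose_coords(mobile, sel_mobile)
  Q <- superpose_coords(target, sel_target)
  if (!all(dim(P) == dim(Q))) stop("paired coordinate sets differ in size")
  n <- nrow(P)
  if (n < 3L) stop("need at least 3 atom pairs")
  cP <- colMeans(P); cQ <- colMeans(Q)
  P0 <- sweep(P, 2, cP); Q0 <- sweep(Q, 2, cQ)
  if (any(svd(P0)$d[2] < 1e-8)) stop("atom pairs are collinear")
  H <- t(P0) %*% Q0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- P0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q0)^2)))
  list(rotation = R, translation = as.vector(cQ - R %*% cP),
       rmsd = rmsd, n = n)
}

superpose_coords <- function(x, sel) {
  if (inherits(x, "structure3d")) {
    if (!is.null(sel)) x <- select_structure(x, sel, allow_empty = FALSE)
    coords(x)
  } else as.matrix(x)
}

#' Apply a rigid transform to a structure
#'
#' @param struc a [structure3d].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector.
#' @return the transformed [structure3d].
#' @export
apply_transform <- function(struc, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- coords(struc) %*% t(rotation)
  xyz <- sweep(xyz, 2, -as.numeric(translation))
  struc$atom$x <- xyz[, 1]; struc$atom$y <- xyz[, 2]; struc$atom$z <- xyz[, 3]
  struc
}

#' Proline ring pucker (endo/exo) classification
#'
#' Fits a least-squares plane through the ring atoms N, CA, CB and CD
#' and measures the signed displacement of CG and of the backbone
#' carbonyl carbon C from that plane.  By the standard Cgamma-endo /
#' Cgamma-exo convention, the ring is *endo* when CG puckers to the
#' same side as the carbonyl carbon, *exo* when it puckers to the
#' opposite side, and *planar* when |CG displacement| is below the
#' planarity threshold.
#'
#' @param struc a [structure3d].
#' @param residue a [residue_ref()]; must be a proline with N, CA, CB,
#'   CG, CD and C present.
#' @param planarity_threshold Angstrom (default 0.1).
#' @return object of class `pucker_call`: `state` ("endo", "exo" or
#'   "planar"), `cgamma_displacement`, `carbonyl_displacement`
#'   (signed, Angstrom), `residue`.
#' @export
proline_pucker <- function(struc, residue, planarity_threshold = 0.1) {
  idx <- residue_atom_idx(struc, residue)
  if (!length(idx)) stop("residue ", format(residue), " not found")
  if (!all(struc$atom$resid[idx] == "PRO"))
    stop("residue ", format(residue), " is not a proline")
  get <- function(name) {
    k <- idx[struc$atom$elety[idx] == name]
    if (!length(k)) stop("proline ", format(residue),
                         " is missing ring atom ", name)
    unlist(struc$atom[k[1], c("x", "y", "z")], use.names = FALSE)
  }
  plane_pts <- rbind(get("N"), get("CA"), get("CB"), get("CD"))
  ctr <- colMeans(plane_pts)
  normal <- svd(sweep(plane_pts, 2, ctr))$v[, 3]
  d_cg <- sum((get("CG") - ctr) * normal)
  d_c <- sum((get("C") - ctr) * normal)
  state <- if (abs(d_cg) < planarity_threshold) "planar"
  else if (sign(d_cg) == sign(d_c)) "endo" else "exo"
  structure(list(residue = residue, state = state,
                 cgamma_displacement = d_cg, carbonyl_displacement = d_c,
                 planarity_threshold = planarity_threshold),
            class = "pucker_call")
}

#' @export
print.pucker_call <- function(x, ...) {
  cat(sprintf("proline %s: %s (Cgamma %+.3f A, C' %+.3f A from ring plane)\n",
              format(x$residue), x$state, x$cgamma_displacement,
              x$carbonyl_displacement))
  invisible(x)
}
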