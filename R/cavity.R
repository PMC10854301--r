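#' Cavity detection parameters
#'
#' The two-probe grid definition used for interior voids: the solvent
#' probe (`probe_radius`) defines the solvent-excluded envelope, the
#' *detection radius* (`detection_multiplier * probe_radius`, default
#' 3 solvent radii) is the size of the bulk-solvent probe - empty
#' space is bulk only where a sphere of that radius can reach from
#' outside - and the *cutoff radius* (`cutoff_multiplier *
#' probe_radius`, default 4 solvent radii) limits how wide a
#' boundary-connected void may be before it is considered open solvent
#' rather than a cavity.
#'
#' @param grid_spacing grid step, Angstrom (default 0.5).
#' @param probe_radius solvent probe radius, Angstrom (default 1.4).
#' @param detection_multiplier bulk-probe size in solvent radii
#'   (default 3).
#' @param cutoff_multiplier mouth-width limit in solvent radii
#'   (default 4).
#' @param min_volume discard components below this volume, Angstrom^3
#'   (default 5; suppresses single-voxel noise).
#' @param connectivity flood-fill connectivity, 6 (default) or 26.
#' @param lining_distance residues with an atom within this distance
#'   of a cavity voxel line the cavity (default 5 Angstrom).
#' @param max_grid_points error budget for the grid (default 2e7).
#' @param radii a `radii_set`.
#' @param include_hetero occlude with HETATM atoms too (default `TRUE`;
#'   waters named HOH are always ignored).
#' @return object of class `cavity_params`.
#' @export
cavity_params <- function(grid_spacing = 0.5, probe_radius = 1.4,
                          detection_multiplier = 3, cutoff_multiplier = 4,
                          min_volume = 5, connectivity = 6,
                          lining_distance = 5, max_grid_points = 2e7,
                          radii = default_radii(), include_hetero = TRUE) {
  if (grid_spacing <= 0) stop("grid_spacing must be > 0")
  if (detection_multiplier < 1 || cutoff_multiplier < 1)
    stop("multipliers must be >= 1")
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  structure(list(grid_spacing = grid_spacing, probe_radius = probe_radius,
                 detection_multiplier = detection_multiplier,
                 cutoff_multiplier = cutoff_multiplier,
                 min_volume = min_volume, connectivity = connectivity,
                 lining_distance = lining_distance,
                 max_grid_points = max_grid_points, radii = radii,
                 include_hetero = include_hetero),
            class = "cavity_params")
}

#' Detect interior cavities and deep pockets
#'
#' Grid algorithm: (1) a grid covers the structure's bounding box with
#' a margin wide enough that the box faces are bulk solvent; (2) each
#' grid point's *clearance* is its distance to the solvent-excluded
#' envelope (atom van der Waals radius + probe), so a point is EMPTY
#' iff its clearance is positive; (3) bulk solvent is found by
#' flood-filling from the box faces through points where a sphere of
#' the detection radius fits (clearance >= detection radius), then
#' sweeping that sphere over the reached positions; (4) EMPTY points
#' not swept by the bulk probe, morphologically opened with the
#' solvent probe (a cavity must be able to host a full solvent
#' sphere; thinner slivers are sub-probe surface texture, not void),
#' form the cavity/pocket components; (5) components smaller than
#' `min_volume`, and boundary-connected components whose largest
#' inscribed empty sphere at the mouth exceeds the cutoff radius (a
#' mouth wider than the cutoff: open solvent), are discarded.  Volume
#' is voxel count times spacing cubed.
#'
#' @param struc a [structure3d].
#' @param params a [cavity_params()].
#' @return object of class `cavity_report`: `cavities` (list of
#'   components with `volume`, `centroid`, `bbox`, `max_clearance`,
#'   `boundary_connected`, `lining` residue data.frame),
#'   `total_volume`, `params`.
#' @export
detect_cavities <- function(struc, params = cavity_params()) {
  stopifnot(inherits(struc, "structure3d"), inherits(params, "cavity_params"))
  g <- cavity_grid(struc, params)
  comp <- cavity_components(g, params)
  lining <- lapply(comp, function(cc)
    lining_residues(struc, g, cc$voxels, params))
  cavities <- mapply(function(cc, ln) { cc$lining <- ln; cc },
                     comp, lining, SIMPLIFY = FALSE)
  structure(list(cavities = cavities,
                 total_volume = sum(vapply(cavities, `[[`, 0, "volume")),
                 params = params, structure_id = struc$id,
                 grid_dim = g$dim),
            class = "cavity_report")
}

# Build the clearance field and bulk/cavity masks.
cavity_grid <- function(struc, params) {
  at <- struc$atom
  keep <- at$elem != "H" & at$resid != "HOH"
  if (!params$include_hetero) keep <- keep & at$type != "HETATM"
  if (!any(keep)) stop("no occluding atoms in structure")
  xyz <- as.matrix(at[keep, c("x", "y", "z")])
  r <- atom_radii(struc, params$radii)[keep] + params$probe_radius
  sp <- params$grid_spacing
  rdet <- params$detection_multiplier * params$probe_radius
  rcut <- params$cutoff_multiplier * params$probe_radius
  cmax <- max(rdet, rcut) + sp
  pad <- rdet + max(r) + 2 * sp
  ax <- lapply(1:3, function(k)
    seq(min(xyz[, k]) - pad, max(xyz[, k]) + pad + sp, by = sp))
  dims <- vapply(ax, length, 0L)
  if (prod(dims) > params$max_grid_points)
    stop("grid of ", prod(dims), " points exceeds the budget of ",
         format(params$max_grid_points, scientific = FALSE),
         "; use a coarser grid_spacing")
  C <- array(cmax, dim = dims)
  upd <- ceiling((max(r) + cmax) / sp)
  for (i in seq_len(nrow(xyz))) {
    ctr <- xyz[i, ]
    rng <- lapply(1:3, function(k) {
      j0 <- findInterval(ctr[k], ax[[k]])
      max(1L, j0 - upd):min(dims[k], j0 + upd)
    })
    dx2 <- (ax[[1]][rng[[1]]] - ctr[1])^2
    dy2 <- (ax[[2]][rng[[2]]] - ctr[2])^2
    dz2 <- (ax[[3]][rng[[3]]] - ctr[3])^2
    loc <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+")) - r[i]
    C[rng[[1]], rng[[2]], rng[[3]]] <-
      pmin(C[rng[[1]], rng[[2]], rng[[3]]], loc)
  }
  empty <- C > 0
  passable <- C >= rdet
  core <- flood_from_faces(passable, dims, params$connectivity)
  bulk <- empty & dilate_ball(core, dims, rdet / sp)
  # raw void: small-probe-accessible space the bulk probe cannot sweep
  cav_raw <- empty & !bulk
  # open with the solvent probe: a cavity is where a full solvent
  # sphere can sit; sub-probe slivers are surface texture, not void
  open_core <- cav_raw & (C >= params$probe_radius)
  cav <- cav_raw & dilate_ball(open_core, dims, params$probe_radius / sp)
  list(axes = ax, dim = dims, clearance = C, empty = empty,
       bulk = bulk, cav = cav, rdet = rdet, rcut = rcut)
}

# 6/26-connected flood fill restricted to `passable`, seeded from all
# passable voxels on the six box faces.  Index-based BFS.
flood_from_faces <- function(passable, dims, connectivity = 6) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  n <- nx * ny * nz
  offs <- neighbor_offsets(dims, connectivity)
  face <- face_indices(dims)
  visited <- logical(n)
  frontier <- face[passable[face]]
  visited[frontier] <- TRUE
  while (length(frontier)) {
    nxt <- integer(0)
    for (k in seq_len(nrow(offs))) {
      cand <- frontier + offs$off[k]
      ok <- offs$valid[[k]](frontier)
      cand <- cand[ok]
      cand <- cand[passable[cand] & !visited[cand]]
      if (length(cand)) {
        visited[cand] <- TRUE
        nxt <- c(nxt, cand)
      }
    }
    frontier <- nxt
  }
  array(visited, dim = dims)
}

neighbor_offsets <- function(dims, connectivity) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  xi <- function(idx) (idx - 1L) %% nx + 1L
  yi <- function(idx) ((idx - 1L) %/% nx) %% ny + 1L
  zi <- function(idx) (idx - 1L) %/% (nx * ny) + 1L
  steps <- if (connectivity == 6)
    expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)[c(5, 11, 13, 15, 17, 23), ]
  else expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)[-14, ]
  off <- steps$dx + nx * steps$dy + nx * ny * steps$dz
  valid <- lapply(seq_len(nrow(steps)), function(k) {
    dx <- steps$dx[k]; dy <- steps$dy[k]; dz <- steps$dz[k]
    function(idx) {
      ok <- rep(TRUE, length(idx))
      if (dx == 1) ok <- ok & xi(idx) < nx else if (dx == -1) ok <- ok & xi(idx) > 1
      if (dy == 1) ok <- ok & yi(idx) < ny else if (dy == -1) ok <- ok & yi(idx) > 1
      if (dz == 1) ok <- ok & zi(idx) < nz else if (dz == -1) ok <- ok & zi(idx) > 1
      ok
    }
  })
  data.frame(off = off)[, , drop = FALSE] -> d
  d$valid <- valid
  d
}

face_indices <- function(dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  idx <- function(i, j, k) i + nx * (j - 1L) + nx * ny * (k - 1L)
  unique(c(
    as.vector(outer(idx(1L, 1:ny, 1), nx * ny * (0:(nz - 1L)), "+")),
    as.vector(outer(idx(nx, 1:ny, 1), nx * ny * (0:(nz - 1L)), "+")),
    as.vector(outer(idx(1:nx, 1, 1), nx * ny * (0:(nz - 1L)), "+")),
    as.vector(outer(idx(1:nx, ny, 1), nx * ny * (0:(nz - 1L)), "+")),
    as.vector(outer(idx(1:nx, 1, 1), nx * (0:(ny - 1L)), "+")),
    idx(rep(1:nx, ny), rep(1:ny, each = nx), nz)
  ))
}

# Morphological dilation by a Euclidean ball (radius in voxels), via
# FFT convolution with a spherical kernel.  The kernel includes voxels
# whose centre lies within radius + half a voxel (midpoint
# rasterisation; an exact-radius kernel systematically under-covers on
# coarse grids).  The grid margin exceeds the ball radius, so circular
# wrap-around cannot reach any voxel that matters.
dilate_ball <- function(mask, dims, radius_vox) {
  kr <- ceiling(radius_vox + 0.5)
  o <- -kr:kr
  grid <- expand.grid(x = o, y = o, z = o)
  grid <- grid[grid$x^2 + grid$y^2 + grid$z^2 <= (radius_vox + 0.5)^2, ]
  kern <- array(0, dim = dims)
  kern[cbind(grid$x %% dims[1] + 1L, grid$y %% dims[2] + 1L,
             grid$z %% dims[3] + 1L)] <- 1
  conv <- Re(stats::fft(stats::fft(array(as.numeric(mask), dim = dims)) *
                          stats::fft(kern), inverse = TRUE)) / prod(dims)
  array(conv > 0.5, dim = dims)
}

# Label connected cavity components and apply the volume and
# mouth-width filters.
cavity_components <- function(g, params) {
  dims <- g$dim
  sp <- params$grid_spacing
  cav <- g$cav
  offs <- neighbor_offsets(dims, params$connectivity)
  remaining <- which(cav)
  comp <- list()
  seen <- logical(prod(dims))
  for (start in remaining) {
    if (seen[start]) next
    members <- integer(0)
    frontier <- start
    seen[start] <- TRUE
    while (length(frontier)) {
      members <- c(members, frontier)
      nxt <- integer(0)
      for (k in seq_len(nrow(offs))) {
        cand <- frontier + offs$off[k]
        cand <- cand[offs$valid[[k]](frontier)]
        cand <- cand[cav[cand] & !seen[cand]]
        if (length(cand)) { seen[cand] <- TRUE; nxt <- c(nxt, cand) }
      }
      frontier <- nxt
    }
    vol <- length(members) * sp^3
    if (vol < params$min_volume) next
    # mouth voxels: component voxels adjacent to swept bulk solvent
    mouth <- integer(0)
    for (k in seq_len(nrow(offs))) {
      cand <- members + offs$off[k]
      src <- members[offs$valid[[k]](members)]
      cand <- cand[offs$valid[[k]](members)]
      mouth <- c(mouth, src[g$bulk[cand]])
    }
    mouth <- unique(mouth)
    touches <- length(mouth) > 0L
    maxcl <- max(g$clearance[members])
    # a mouth wider than the cutoff radius is open solvent, not a cavity
    if (touches && max(g$clearance[mouth]) > g$rcut) next
    xyzv <- voxel_coords(g, members)
    comp[[length(comp) + 1L]] <- list(
      voxels = members, voxel_xyz = xyzv, n_voxels = length(members),
      volume = vol, centroid = colMeans(xyzv),
      bbox = rbind(min = apply(xyzv, 2, min), max = apply(xyzv, 2, max)),
      max_clearance = maxcl, boundary_connected = touches)
  }
  comp
}

voxel_coords <- function(g, idx) {
  dims <- g$dim
  i <- (idx - 1L) %% dims[1] + 1L
  j <- ((idx - 1L) %/% dims[1]) %% dims[2] + 1L
  k <- (idx - 1L) %/% (dims[1] * dims[2]) + 1L
  cbind(x = g$axes[[1]][i], y = g$axes[[2]][j], z = g$axes[[3]][k])
}

lining_residues <- function(struc, g, voxels, params) {
  at <- struc$atom
  keep <- which(at$elem != "H")
  xyzv <- voxel_coords(g, voxels)
  d2max <- params$lining_distance^2
  near <- logical(length(keep))
  for (n in seq_along(keep)) {
    i <- keep[n]
    d2 <- (xyzv[, 1] - at$x[i])^2 + (xyzv[, 2] - at$y[i])^2 +
      (xyzv[, 3] - at$z[i])^2
    near[n] <- any(d2 <= d2max)
  }
  idx <- keep[near]
  rt <- data.frame(chain = at$chain[idx], resno = at$resno[idx],
                   insert = at$insert[idx], resid = at$resid[idx],
                   stringsAsFactors = FALSE)
  rt <- unique(rt)
  rt$key <- residue_key(rt$chain, rt$resno, rt$insert)
  rownames(rt) <- NULL
  rt
}

#' @export
print.cavity_report <- function(x, ...) {
  cat(sprintf("cavity_report for '%s': %d cavities, total %.1f A^3\n",
              x$structure_id, length(x$cavities), x$total_volume))
  for (i in seq_along(x$cavities)) {
    cc <- x$cavities[[i]]
    cat(sprintf("  [%d] %.1f A^3 at (%.1f, %.1f, %.1f), %d lining residues%s\n",
                i, cc$volume, cc$centroid[1], cc$centroid[2], cc$centroid[3],
                nrow(cc$lining),
                if (cc$boundary_connected) " (pocket)" else ""))
  }
  invisible(x)
}

#' Cavities between two subunits
#'
#' Restricts a cavity report to components lined by residues of both
#' selections, supporting between-subunit comparisons such as the
#' receptor/G-protein or G-alpha/G-beta interfaces.
#'
#' @param struc a [structure3d].
#' @param sel_a,sel_b selection strings or atom index vectors.
#' @param params a [cavity_params()].
#' @param report optionally, a precomputed [detect_cavities()] report
#'   for `struc` (avoids recomputing the grid).
#' @return a `cavity_report` containing only inter-selection cavities.
#' @export
cavity_between <- function(struc, sel_a, sel_b, params = cavity_params(),
                           report = NULL) {
  if (is.null(report)) report <- detect_cavities(struc, params)
  keys_a <- unique(atom_residue_keys(struc)[as_atom_idx(struc, sel_a)])
  keys_b <- unique(atom_residue_keys(struc)[as_atom_idx(struc, sel_b)])
  keep <- vapply(report$cavities, function(cc) {
    any(cc$lining$key %in% keys_a) && any(cc$lining$key %in% keys_b)
  }, logical(1))
  out <- report
  out$cavities <- report$cavities[keep]
  out$total_volume <- sum(vapply(out$cavities, `[[`, 0, "volume"))
  out
}

#' Dump cavity voxels as a pseudo-atom PDB point cloud
#'
#' One HETATM pseudo-atom per cavity grid point (element X, residue
#' CAV, one residue number per cavity), for visual inspection of the
#' detected voids alongside the structure.
#'
#' @param report a `cavity_report`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_cavity_pdb <- function(report, path) {
  stopifnot(inherits(report, "cavity_report"))
  xyz <- do.call(rbind, lapply(report$cavities, `[[`, "voxel_xyz"))
  if (is.null(xyz) || nrow(xyz) == 0L) {
    writeLines("END", path)
    return(invisible(path))
  }
  n_per <- vapply(report$cavities, `[[`, 0L, "n_voxels")
  atoms <- data.frame(
    type = "HETATM", eleno = seq_len(nrow(xyz)), elety = "X", alt = "",
    resid = "CAV", chain = "C", resno = rep(seq_along(n_per), n_per),
    insert = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    o = 1, b = 0, elem = "X", stringsAsFactors = FALSE)
  write_pdb(structure3d(atoms, id = "cavity-voxels"), path)
}

#' Write a cavity report as JSON
#' @param report a `cavity_report`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_cavity_json <- function(report, path) {
  stopifnot(inherits(report, "cavity_report"))
  p <- report$params
  out <- list(
    structure = report$structure_id,
    params = list(grid_spacing = p$grid_spacing,
                  probe_radius = p$probe_radius,
                  detection_multiplier = p$detection_multiplier,
                  cutoff_multiplier = p$cutoff_multiplier,
                  min_volume = p$min_volume, connectivity = p$connectivity,
                  radii_set = p$radii$name),
    total_volume = round(report$total_volume, 3),
    cavities = lapply(report$cavities, function(cc) list(
      volume = round(cc$volume, 3),
      centroid = round(unname(cc$centroid), 3),
      max_clearance = round(cc$max_clearance, 3),
      boundary_connected = cc$boundary_connected,
      lining = cc$lining[, c("chain", "resno", "resid")])))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
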