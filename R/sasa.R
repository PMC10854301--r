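#' Quasi-uniform points on the unit sphere
#'
#' Golden-spiral (Fibonacci) lattice: deterministic for a given `n`,
#' with near-uniform spacing.  These are the sample directions used by
#' the Shrake-Rupley SASA calculation.
#'
#' @param n number of points (>= 1).
#' @return `n` x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  i <- seq_len(n) - 1L
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))          # golden angle
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' SASA parameters
#'
#' @param probe_radius probe (water) radius in Angstrom; 1.4 by default.
#' @param n_points Shrake-Rupley sample points per atom (default 960).
#' @param radii the `radii_set` to use.
#' @param include_hetero include HETATM atoms (waters, ligands) as
#'   targets and occluders (default `FALSE`).
#' @param include_hydrogens include hydrogen atoms (default `FALSE`;
#'   experimental structures usually lack them).
#' @return object of class `sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4, n_points = 960,
                        radii = default_radii(),
                        include_hetero = FALSE, include_hydrogens = FALSE) {
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  if (n_points < 1) stop("n_points must be >= 1")
  stopifnot(inherits(radii, "radii_set"))
  structure(list(probe_radius = probe_radius, n_points = as.integer(n_points),
                 radii = radii, include_hetero = include_hetero,
                 include_hydrogens = include_hydrogens),
            class = "sasa_params")
}

sasa_params_signature <- function(p) {
  sprintf("probe=%.3f points=%d radii=%s het=%s hyd=%s",
          p$probe_radius, p$n_points, p$radii$name,
          p$include_hetero, p$include_hydrogens)
}

sasa_atom_mask <- function(struc, params) {
  at <- struc$atom
  keep <- rep(TRUE, nrow(at))
  if (!params$include_hetero) keep <- keep & at$type != "HETATM"
  if (!params$include_hydrogens) keep <- keep & at$elem != "H"
  keep
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' For each included atom of radius `r`, `n_points` sample points are
#' placed on the expanded sphere of radius `R = r + probe`; a point is
#' accessible iff it lies outside every other included atom's expanded
#' sphere, and the atom's SASA is `4*pi*R^2` times the accessible
#' fraction.  Neighbour search uses spatial binning with cell size
#' `2 * max(R)`; its output is contractually identical to the all-pairs
#' scan (`method = "allpairs"`), which is kept for verification.
#'
#' @param struc a [structure3d].
#' @param params a [sasa_params()].
#' @param method `"cells"` (default) or `"allpairs"`.
#' @return object of class `sasa_result` with elements `per_atom`
#'   (numeric, NA for excluded atoms), `structure`, `params`, `mask`.
#' @export
atom_sasa <- function(struc, params = sasa_params(),
                      method = c("cells", "allpairs")) {
  method <- match.arg(method)
  stopifnot(inherits(struc, "structure3d"), inherits(params, "sasa_params"))
  mask <- sasa_atom_mask(struc, params)
  xyz <- coords(struc)
  r <- atom_radii(struc, params$radii)
  per_atom <- rep(NA_real_, nrow(xyz))
  idx <- which(mask)
  if (length(idx)) {
    per_atom[idx] <- shrake_rupley(xyz[idx, , drop = FALSE], r[idx],
                                   params$probe_radius, params$n_points,
                                   method)
  }
  structure(list(per_atom = per_atom, structure = struc, params = params,
                 mask = mask, per_residue = NULL, reference_table = NULL),
            class = "sasa_result")
}

shrake_rupley <- function(xyz, r, probe, n_points, method = "cells") {
  n <- nrow(xyz)
  R <- r + probe
  pts <- sphere_points(n_points)
  area <- numeric(n)
  nb <- if (method == "cells" && n > 1)
    cell_neighbors(xyz, 2 * max(R)) else NULL
  for (i in seq_len(n)) {
    cand <- if (is.null(nb)) seq_len(n)[-i] else setdiff(nb[[i]], i)
    if (length(cand)) {
      d2 <- (xyz[cand, 1] - xyz[i, 1])^2 + (xyz[cand, 2] - xyz[i, 2])^2 +
        (xyz[cand, 3] - xyz[i, 3])^2
      cand <- cand[d2 < (R[i] + R[cand])^2]
    }
    if (!length(cand)) { area[i] <- 4 * pi * R[i]^2; next }
    px <- pts[, 1] * R[i] + xyz[i, 1]
    py <- pts[, 2] * R[i] + xyz[i, 2]
    pz <- pts[, 3] * R[i] + xyz[i, 3]
    acc <- rep(TRUE, n_points)
    for (j in cand) {
      sel <- which(acc)
      if (!length(sel)) break
      d2 <- (px[sel] - xyz[j, 1])^2 + (py[sel] - xyz[j, 2])^2 +
        (pz[sel] - xyz[j, 3])^2
      acc[sel[d2 <= R[j]^2]] <- FALSE
    }
    area[i] <- 4 * pi * R[i]^2 * sum(acc) / n_points
  }
  area
}

# Spatial binning: for each atom, the candidate atoms from the 27
# surrounding cells.  Cell size must be >= the largest pair cutoff so
# that the result matches the all-pairs scan exactly.
cell_neighbors <- function(xyz, cell) {
  ix <- floor(xyz[, 1] / cell); iy <- floor(xyz[, 2] / cell)
  iz <- floor(xyz[, 3] / cell)
  key <- paste(ix, iy, iz)
  cells <- split(seq_len(nrow(xyz)), key)
  lookup <- function(cx, cy, cz) cells[[paste(cx, cy, cz)]]
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  lapply(seq_len(nrow(xyz)), function(i) {
    out <- integer(0)
    for (k in seq_len(27)) {
      hit <- lookup(ix[i] + off$dx[k], iy[i] + off$dy[k], iz[i] + off$dz[k])
      if (!is.null(hit)) out <- c(out, hit)
    }
    out
  })
}

#' Aggregate SASA per residue and normalise to a reference maximum
#'
#' Per-residue absolute SASA is the sum over the residue's included
#' atoms.  Relative SASA ("percent ratio") is `100 * abs / reference`,
#' where the reference is a tabulated per-residue-type maximum SASA in
#' an extended Gly-X-Gly context; residue types missing from the table
#' are flagged (`nonstandard`), never silently dropped.
#'
#' @param result a `sasa_result` from [atom_sasa()].
#' @param reference_table name of the shipped reference table (see
#'   [max_sasa_reference()]).
#' @return the `sasa_result` with `per_residue` (data.frame: residue
#'   identity, `abs` Angstrom^2, `rel` percent, `nonstandard` flag) and
#'   `reference_table` filled.
#' @export
residue_sasa <- function(result, reference_table = "tien2013") {
  stopifnot(inherits(result, "sasa_result"))
  struc <- result$structure
  rt <- residue_table(struc)
  keys <- atom_residue_keys(struc)
  a <- result$per_atom
  a[is.na(a)] <- 0
  sums <- tapply(a, factor(keys, levels = rt$key), sum)
  rt$abs <- as.numeric(sums)
  rt$abs[is.na(rt$abs)] <- 0
  ref <- max_sasa_reference(reference_table)
  refv <- unname(ref[rt$resid])
  rt$rel <- 100 * rt$abs / refv
  rt$nonstandard <- is.na(refv)
  result$per_residue <- rt
  result$reference_table <- reference_table
  result
}

#' Compute per-atom and per-residue SASA in one call
#' @inheritParams atom_sasa
#' @inheritParams residue_sasa
#' @return a complete `sasa_result`.
#' @export
calc_sasa <- function(struc, params = sasa_params(),
                      reference_table = "tien2013") {
  residue_sasa(atom_sasa(struc, params), reference_table)
}

#' Tabulated maximum per-residue SASA
#'
#' Theoretical maximum solvent accessibilities of residue X in an
#' extended Gly-X-Gly tripeptide (Tien et al. 2013, "theoretical"
#' column), shipped as plain text under `extdata`.  The table name is
#' recorded in every result that uses it.
#'
#' @param name table name (currently `"tien2013"`).
#' @return named numeric vector, Angstrom^2 per 3-letter residue code.
#' @export
max_sasa_reference <- function(name = "tien2013") {
  path <- system.file("extdata", paste0("max_sasa_", name, ".tsv"),
                      package = "strucdiff")
  if (path == "") stop("unknown reference table: ", name)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  stats::setNames(tab$max_sasa, tab$resid)
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("sasa_result for '%s' (%s)\n", x$structure$id,
              sasa_params_signature(x$params)))
  cat(sprintf("  total SASA: %.1f A^2 over %d atoms\n",
              sum(x$per_atom, na.rm = TRUE), sum(x$mask)))
  if (!is.null(x$per_residue))
    cat(sprintf("  per-residue: %d residues, reference '%s'\n",
                nrow(x$per_residue), x$reference_table))
  invisible(x)
}

#' Monte-Carlo SASA oracle
#'
#' Independent estimate of per-atom SASA by uniform random sampling on
#' each expanded sphere, with a per-atom standard error.  Used to
#' cross-check the deterministic Shrake-Rupley lattice; identical
#' seeds give bit-identical results.
#'
#' @param struc a [structure3d].
#' @param params a [sasa_params()] (the `n_points` field is ignored).
#' @param n_samples random samples per atom.
#' @param seed RNG seed.
#' @return data.frame with `area` and `se` per included atom (NA rows
#'   for excluded atoms).
#' @export
mc_sasa <- function(struc, params = sasa_params(), n_samples = 10000,
                    seed = 1) {
  stopifnot(inherits(struc, "structure3d"))
  mask <- sasa_atom_mask(struc, params)
  xyz <- coords(struc)[mask, , drop = FALSE]
  r <- atom_radii(struc, params$radii)[mask]
  R <- r + params$probe_radius
  n <- nrow(xyz)
  area <- se <- rep(NA_real_, length(mask))
  set.seed(seed)
  ai <- which(mask)
  for (k in seq_len(n)) {
    z <- stats::runif(n_samples, -1, 1)
    t <- stats::runif(n_samples, 0, 2 * pi)
    rho <- sqrt(1 - z^2)
    px <- (rho * cos(t)) * R[k] + xyz[k, 1]
    py <- (rho * sin(t)) * R[k] + xyz[k, 2]
    pz <- z * R[k] + xyz[k, 3]
    acc <- rep(TRUE, n_samples)
    for (j in seq_len(n)) {
      if (j == k) next
      d2c <- (xyz[j, 1] - xyz[k, 1])^2 + (xyz[j, 2] - xyz[k, 2])^2 +
        (xyz[j, 3] - xyz[k, 3])^2
      if (d2c >= (R[j] + R[k])^2) next
      sel <- which(acc)
      if (!length(sel)) break
      d2 <- (px[sel] - xyz[j, 1])^2 + (py[sel] - xyz[j, 2])^2 +
        (pz[sel] - xyz[j, 3])^2
      acc[sel[d2 <= R[j]^2]] <- FALSE
    }
    p <- sum(acc) / n_samples
    area[ai[k]] <- 4 * pi * R[k]^2 * p
    se[ai[k]] <- 4 * pi * R[k]^2 * sqrt(p * (1 - p) / n_samples)
  }
  data.frame(area = area, se = se)
}

#' Write a SASA result as JSON with full per-atom detail
#'
#' @param result a `sasa_result`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_sasa_json <- function(result, path) {
  stopifnot(inherits(result, "sasa_result"))
  at <- result$structure$atom
  out <- list(
    structure = result$structure$id,
    params = list(probe_radius = result$params$probe_radius,
                  n_points = result$params$n_points,
                  radii_set = result$params$radii$name,
                  include_hetero = result$params$include_hetero,
                  include_hydrogens = result$params$include_hydrogens),
    reference_table = result$reference_table,
    per_atom = data.frame(chain = at$chain, resno = at$resno,
                          resid = at$resid, elety = at$elety,
                          area = round(result$per_atom, 4)),
    per_residue = if (!is.null(result$per_residue))
      result$per_residue[, c("chain", "resno", "insert", "resid", "abs",
                             "rel", "nonstandard")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write a per-residue SASA table as TSV
#'
#' One row per residue: chain, residue number, insertion code, residue
#' name, absolute SASA, relative SASA and the nonstandard flag.
#'
#' @param result a `sasa_result` with per-residue values.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_sasa_tsv <- function(result, path) {
  stopifnot(inherits(result, "sasa_result"), !is.null(result$per_residue))
  pr <- result$per_residue
  out <- data.frame(chain = pr$chain, resno = pr$resno, insert = pr$insert,
                    resid = pr$resid, abs_A2 = sprintf("%.3f", pr$abs),
                    rel_pct = ifelse(is.na(pr$rel), "NA",
                                     sprintf("%.3f", pr$rel)),
                    nonstandard = pr$nonstandard)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
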