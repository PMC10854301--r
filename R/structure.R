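#' Structure object
#'
#' The atom/residue model consumed by every analysis function.  Atoms
#' live in a single data.frame in file order; residues are identified
#' by the triple (chain, residue number, insertion code) which must be
#' unique within a structure.  Author (file) numbering is authoritative;
#' generic labels (e.g. Ballesteros-Weinstein "7.50" or CGN "G.HN.52")
#' may be attached as annotations but are never parsed for geometry.
#'
#' @param atom data.frame with columns `type` ("ATOM"/"HETATM"),
#'   `eleno`, `elety` (atom name), `alt`, `resid` (3-letter residue
#'   name), `chain`, `resno`, `insert`, `x`, `y`, `z`, `o` (occupancy),
#'   `b` (B-factor), `elem` (element symbol).
#' @param id label for the structure.
#' @return object of class `structure3d`.
#' @export
structure3d <- function(atom, id = "structure") {
  need <- c("type", "eleno", "elety", "alt", "resid", "chain", "resno",
            "insert", "x", "y", "z", "o", "b", "elem")
  miss <- setdiff(need, names(atom))
  if (length(miss)) stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atom) == 0L) stop("empty model: structure has no atoms")
  xyz <- as.matrix(atom[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  o <- atom$o
  o[is.na(o)] <- 1
  if (any(o < 0 | o > 1)) stop("occupancy outside [0, 1]")
  atom$o <- o
  atom$alt[is.na(atom$alt)] <- ""
  atom$insert[is.na(atom$insert)] <- ""
  atom$chain[is.na(atom$chain)] <- ""
  atom$b[is.na(atom$b)] <- 0
  rownames(atom) <- NULL
  structure(list(id = id, atom = atom), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("structure3d '%s': %d atoms, %d residues, chains [%s]\n",
              x$id, nrow(x$atom), nrow(rt),
              paste(unique(rt$chain), collapse = " ")))
  invisible(x)
}

#' Atom coordinates as a matrix
#' @param struc a structure3d.
#' @return n x 3 numeric matrix.
#' @export
coords <- function(struc) {
  as.matrix(struc$atom[, c("x", "y", "z")])
}

residue_key <- function(chain, resno, insert) {
  paste0(chain, "|", resno, "|", ifelse(is.na(insert) | insert == " ", "", insert))
}

#' Residue table
#'
#' One row per residue in file order: chain, resno, insert, resid and
#' the internal key used to join per-residue results.
#'
#' @param struc a structure3d.
#' @return data.frame with columns `chain`, `resno`, `insert`, `resid`, `key`.
#' @export
residue_table <- function(struc) {
  at <- struc$atom
  key <- residue_key(at$chain, at$resno, at$insert)
  keep <- !duplicated(key)
  out <- data.frame(chain = at$chain[keep], resno = at$resno[keep],
                    insert = at$insert[keep], resid = at$resid[keep],
                    key = key[keep], stringsAsFactors = FALSE)
  dupname <- tapply(at$resid[keep], out$key, length)
  rownames(out) <- NULL
  out
}

atom_residue_keys <- function(struc) {
  residue_key(struc$atom$chain, struc$atom$resno, struc$atom$insert)
}

#' Reference a residue
#'
#' Constructs the (chain, resno, insert) triple used to address a
#' residue in measurement functions.
#'
#' @param chain chain identifier.
#' @param resno author residue number.
#' @param insert insertion code ("" if none).
#' @param generic_label optional scheme-qualified label (annotation only).
#' @return object of class `residue_ref`.
#' @export
residue_ref <- function(chain, resno, insert = "", generic_label = NULL) {
  structure(list(chain = as.character(chain), resno = as.integer(resno),
                 insert = as.character(insert), generic_label = generic_label),
            class = "residue_ref")
}

#' @export
format.residue_ref <- function(x, ...) {
  lab <- if (is.null(x$generic_label)) "" else paste0(" (", x$generic_label, ")")
  sprintf("%s%d%s%s", x$chain, x$resno, x$insert, lab)
}

#' @export
print.residue_ref <- function(x, ...) {
  cat("residue", format(x), "\n"); invisible(x)
}

residue_atom_idx <- function(struc, ref) {
  at <- struc$atom
  which(at$chain == ref$chain & at$resno == ref$resno &
          (at$insert == ref$insert | (ref$insert == "" & at$insert == " ")))
}

# Expected heavy-atom counts for the 20 standard residues (no OXT).
heavy_atom_counts <- function() {
  c(ALA = 5, ARG = 11, ASN = 8, ASP = 8, CYS = 6, GLN = 9, GLU = 9,
    GLY = 4, HIS = 10, ILE = 8, LEU = 8, LYS = 9, MET = 8, PHE = 11,
    PRO = 7, SER = 6, THR = 7, TRP = 14, TYR = 12, VAL = 7)
}

#' Detect incomplete residues
#'
#' Compares the observed heavy-atom count of every standard residue
#' against the expected count for its type (terminal OXT ignored).
#' Structure repair is deliberately out of scope: incomplete residues
#' are reported so that differential analysis can exclude them, since a
#' partial-side-chain SASA would bias the ratio for that residue.
#'
#' @param struc a structure3d.
#' @return data.frame of residues with `n_heavy` observed, `n_expected`,
#'   and logical `incomplete`; nonstandard residue types get
#'   `n_expected = NA` and `incomplete = NA`.
#' @export
incomplete_residues <- function(struc) {
  at <- struc$atom
  heavy <- at$elem != "H" & at$elety != "OXT"
  keys <- atom_residue_keys(struc)
  rt <- residue_table(struc)
  cnt <- table(keys[heavy])
  rt$n_heavy <- as.integer(cnt[rt$key])
  rt$n_heavy[is.na(rt$n_heavy)] <- 0L
  exp <- heavy_atom_counts()
  rt$n_expected <- unname(exp[rt$resid])
  rt$incomplete <- rt$n_heavy < rt$n_expected
  rt
}
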