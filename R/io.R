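#' Read a macromolecular coordinate file
#'
#' Reads PDB (fixed-column) or mmCIF files into a [structure3d].
#' Parsing is delegated to bio3d (`read.pdb` / `read.cif`); this
#' wrapper then applies the package's deterministic normalisation
#' rules:
#'
#' * only model 1 of a multi-model file is used;
#' * HETATM records are loaded but flagged (`type == "HETATM"`);
#' * for alternate-location groups only the highest-occupancy conformer
#'   is retained, ties broken by file order;
#' * hydrogens are retained in the model (SASA excludes them by
#'   default via its own flag);
#' * missing element symbols are derived from the atom name.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by file extension,
#'   `.cif`/`.mmcif` -> mmCIF, else PDB).
#' @param id structure id (defaults to the file name without extension).
#' @return a [structure3d].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") {
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE))
    } else {
      suppressWarnings(bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE))
    },
    error = function(e) stop("cannot parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("empty model in ", path)
  atom <- data.frame(
    type = at$type, eleno = at$eleno, elety = at$elety,
    alt = ifelse(is.na(at$alt), "", at$alt),
    resid = at$resid, chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    elem = if ("elesy" %in% names(at)) at$elesy else NA_character_,
    stringsAsFactors = FALSE
  )
  noel <- is.na(atom$elem) | atom$elem == ""
  atom$elem[noel] <- guess_element(atom$elety[noel])
  atom <- resolve_altlocs(atom)
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  structure3d(atom, id = id)
}

# Highest occupancy wins within an alt-loc group; ties -> first in file.
resolve_altlocs <- function(atom) {
  grp <- paste(atom$chain, atom$resno, atom$insert, atom$resid, atom$elety)
  has_alt <- atom$alt != ""
  if (!any(has_alt)) return(atom)
  keep <- rep(TRUE, nrow(atom))
  for (g in unique(grp[has_alt])) {
    i <- which(grp == g)
    if (length(i) < 2L) next
    best <- i[which.max(atom$o[i])]   # which.max is first-wins on ties
    keep[setdiff(i, best)] <- FALSE
  }
  atom[keep, , drop = FALSE]
}

guess_element <- function(elety) {
  two <- c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "CA", "CU", "NI", "SE")
  nm <- toupper(trimws(elety))
  el <- substr(nm, 1L, 1L)
  # names like "1HB" start with a digit
  digit <- grepl("^[0-9]", nm)
  el[digit] <- substr(sub("^[0-9]+", "", nm[digit]), 1L, 1L)
  first2 <- substr(nm, 1L, 2L)
  # a two-letter element only when the name itself is that element (ions)
  el[first2 %in% two & nchar(nm) == 2L] <- first2[first2 %in% two & nchar(nm) == 2L]
  el
}

#' Write a structure as PDB
#'
#' @param struc a [structure3d].
#' @param path output file.
#' @param b optional replacement B-factor vector (one per atom).
#' @return invisibly, `path`.
#' @export
write_pdb <- function(struc, path, b = NULL) {
  at <- struc$atom
  if (is.null(b)) b <- at$b
  if (length(b) != nrow(at)) stop("b must have one value per atom")
  if (any(b <= -10 | b >= 1000))
    stop("B-factor value outside PDB column range [-9.99, 999.99]: ",
         paste(format(b[b <= -10 | b >= 1000]), collapse = ", "))
  bio3d::write.pdb(file = path,
                   type = at$type, eleno = at$eleno, elety = at$elety,
                   resid = at$resid, chain = at$chain, resno = at$resno,
                   insert = ifelse(at$insert == "", NA, at$insert),
                   xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                   o = at$o, b = b, elesy = at$elem)
  invisible(path)
}

#' Write a structure as mmCIF
#'
#' Emits a minimal `atom_site` loop (group, id, element, atom name,
#' alt, residue, chain, seq id, insertion code, coordinates, occupancy,
#' B, author fields, model number).  No R package on this system writes
#' mmCIF, so the writer is implemented here; the file reads back with
#' [read_structure()].
#'
#' @param struc a [structure3d].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_mmcif <- function(struc, path) {
  at <- struc$atom
  q <- function(x) ifelse(is.na(x) | x == "", "?", as.character(x))
  lines <- c(
    paste0("data_", gsub("[^A-Za-z0-9_-]", "_", struc$id)),
    "loop_",
    paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id",
             "label_alt_id", "label_comp_id", "label_asym_id",
             "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
             "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
             "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
             "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")),
    sprintf("%s %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
            at$type, at$eleno, q(at$elem), at$elety,
            ifelse(at$alt == "", ".", at$alt), at$resid,
            q(at$chain), at$resno, q(at$insert),
            at$x, at$y, at$z, at$o, at$b,
            at$resno, at$resid, q(at$chain), at$elety),
    "#"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a PDB with per-residue values encoded in the B-factor column
#'
#' Supports sphere/colour visualisation of per-residue quantities
#' (e.g. SASA fold bins): every atom of a residue gets the residue's
#' mapped value; residues absent from the map get `sentinel`.  Values
#' overflowing the fixed-width PDB B-factor column are an error, never
#' silently truncated.
#'
#' @param struc a [structure3d].
#' @param per_residue_values named numeric vector keyed by residue key
#'   (see [residue_table()]`$key`), or a data.frame with columns
#'   `chain`, `resno`, `insert` (optional), `value`.
#' @param path output file.
#' @param sentinel value for unmapped residues (default -1).
#' @return invisibly, `path`.
#' @export
write_annotated <- function(struc, per_residue_values, path, sentinel = -1) {
  if (is.data.frame(per_residue_values)) {
    ins <- if ("insert" %in% names(per_residue_values))
      per_residue_values$insert else ""
    v <- per_residue_values$value
    names(v) <- residue_key(per_residue_values$chain,
                            per_residue_values$resno, ins)
    per_residue_values <- v
  }
  if (length(per_residue_values) && any(!is.finite(per_residue_values)))
    stop("per-residue values must be finite (use the sentinel for 'excluded')")
  keys <- atom_residue_keys(struc)
  b <- unname(per_residue_values[keys])
  b[is.na(b)] <- sentinel
  write_pdb(struc, path, b = b)
}
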