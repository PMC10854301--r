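#' Select a sub-structure
#'
#' Evaluates a small selection expression against a structure and
#' returns the matching atoms as a new [structure3d], preserving file
#' order.  The grammar is a conjunction of clauses joined by `and`:
#'
#' * `all` - every atom
#' * `protein` - ATOM records only
#' * `hetero` - HETATM records only
#' * `chain A` / `chain A,B` - chain identifiers
#' * `resno 225-235` / `resno 5,9,20-30` - author residue numbers
#' * `name CA` / `name CA,CB` - atom names
#' * `elem C,N` - element symbols
#' * `resid PRO` - residue type names
#'
#' e.g. `"chain R and resno 225-235 and name CA"`.  An empty selection
#' result is allowed; a malformed expression is a syntax error that
#' reports the clause position.
#'
#' @param struc a [structure3d].
#' @param selection selection string.
#' @param allow_empty if `FALSE`, an empty result is an error.
#' @return a [structure3d] with the selected atoms (may have 0 rows
#'   only when `allow_empty`; a 0-atom selection is returned as an
#'   object with an empty atom table kept out of `structure3d()`'s
#'   non-empty invariant).
#' @export
select_structure <- function(struc, selection, allow_empty = TRUE) {
  idx <- select_atom_idx(struc, selection)
  sub_structure(struc, idx,
                id = paste0(struc$id, " [", selection, "]"),
                allow_empty = allow_empty)
}

#' Atom indices matching a selection
#' @inheritParams select_structure
#' @return integer vector of atom row indices.
#' @export
select_atom_idx <- function(struc, selection) {
  stopifnot(is.character(selection), length(selection) == 1L)
  at <- struc$atom
  keep <- rep(TRUE, nrow(at))
  # split on the keyword 'and', tracking character offsets for errors
  clauses <- strsplit(selection, "\\band\\b")[[1]]
  pos <- 1L
  for (cl in clauses) {
    cl_trim <- trimws(cl)
    if (cl_trim == "")
      stop("selection syntax error at position ", pos, ": empty clause")
    keep <- keep & eval_clause(cl_trim, at, pos)
    pos <- pos + nchar(cl) + 3L
  }
  which(keep)
}

eval_clause <- function(clause, at, pos) {
  toks <- strsplit(clause, "[[:space:]]+")[[1]]
  kw <- tolower(toks[1])
  arg <- if (length(toks) > 1) paste(toks[-1], collapse = "") else NULL
  bad <- function(msg) stop("selection syntax error at position ", pos,
                            " ('", clause, "'): ", msg, call. = FALSE)
  switch(kw,
    all = { if (!is.null(arg)) bad("'all' takes no argument"); rep(TRUE, nrow(at)) },
    protein = { if (!is.null(arg)) bad("'protein' takes no argument"); at$type == "ATOM" },
    hetero = { if (!is.null(arg)) bad("'hetero' takes no argument"); at$type == "HETATM" },
    chain = { if (is.null(arg)) bad("'chain' needs an argument")
              at$chain %in% strsplit(arg, ",")[[1]] },
    name = { if (is.null(arg)) bad("'name' needs an argument")
             at$elety %in% strsplit(arg, ",")[[1]] },
    elem = { if (is.null(arg)) bad("'elem' needs an argument")
             at$elem %in% toupper(strsplit(arg, ",")[[1]]) },
    resid = { if (is.null(arg)) bad("'resid' needs an argument")
              at$resid %in% toupper(strsplit(arg, ",")[[1]]) },
    resno = { if (is.null(arg)) bad("'resno' needs an argument")
              at$resno %in% parse_ranges(arg, bad) },
    bad(paste0("unknown keyword '", kw, "'"))
  )
}

parse_ranges <- function(arg, bad) {
  out <- integer(0)
  for (part in strsplit(arg, ",")[[1]]) {
    if (grepl("^-?[0-9]+--?[0-9]+$", part) || grepl("^-?[0-9]+-[0-9]+$", part)) {
      m <- regmatches(part, regexec("^(-?[0-9]+)-(-?[0-9]+)$", part))[[1]]
      lo <- as.integer(m[2]); hi <- as.integer(m[3])
      if (is.na(lo) || is.na(hi) || lo > hi) bad(paste0("bad range '", part, "'"))
      out <- c(out, lo:hi)
    } else if (grepl("^-?[0-9]+$", part)) {
      out <- c(out, as.integer(part))
    } else bad(paste0("bad residue number '", part, "'"))
  }
  out
}

sub_structure <- function(struc, idx, id = struc$id, allow_empty = TRUE) {
  if (length(idx) == 0L) {
    if (!allow_empty) stop("selection matches no atoms in '", struc$id, "'")
    out <- struc
    out$id <- id
    out$atom <- struc$atom[0, , drop = FALSE]
    return(out)
  }
  structure3d(struc$atom[sort(idx), , drop = FALSE], id = id)
}
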