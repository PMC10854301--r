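#' Differential SASA parameters
#'
#' @param exclusion_delta residues whose SASA difference between the
#'   two structures is below this value are excluded from
#'   classification.  Default 2.5; in the default `relative_percent`
#'   mode this is 2.5 percentage points of relative SASA.
#' @param ratio_mode `"relative_percent"` (ratio and delta on the
#'   percent-of-reference scale) or `"absolute"` (Angstrom^2).
#' @param epsilon_area floor applied to both ratio operands (0.1
#'   percentage points / 0.1 Angstrom^2 by default) so buried residues
#'   never produce unbounded fold changes; pairs where both values are
#'   below the floor are excluded as "both-buried".
#' @return object of class `diff_params`.
#' @export
diff_params <- function(exclusion_delta = 2.5,
                        ratio_mode = c("relative_percent", "absolute"),
                        epsilon_area = 0.1) {
  ratio_mode <- match.arg(ratio_mode)
  if (exclusion_delta < 0) stop("exclusion_delta must be >= 0")
  if (epsilon_area <= 0) stop("epsilon_area must be > 0")
  structure(list(exclusion_delta = exclusion_delta, ratio_mode = ratio_mode,
                 epsilon_area = epsilon_area), class = "diff_params")
}

#' Fold-change classification scheme
#'
#' Bins on the fold-ratio axis partition (0, Inf): `>50x`, `10-50x`
#' and `3-10x` greater; below 3-fold either way neutral; and the
#' mirrored `3-10x`, `10-50x`, `>50x` smaller bins.  Edges are
#' half-open `[low, high)` on the greater side and mirrored by
#' reciprocal (`(1/high, 1/low]`) on the smaller side, so a ratio of
#' exactly 3 is "3-10x greater" and exactly 1/3 is "3-10x smaller".
#' Each bin carries a colour label for sphere/surface rendering.
#'
#' @param edges increasing fold-change bin edges (default `c(3, 10, 50)`).
#' @param colors seven colours: greater bins from largest fold down,
#'   neutral, then smaller bins from 3-10x out.
#' @return object of class `classification_scheme`.
#' @export
classification_scheme <- function(edges = c(3, 10, 50),
                                  colors = c("red", "orange", "yellow",
                                             "grey", "lightgreen", "cyan",
                                             "darkblue")) {
  stopifnot(length(edges) == 3L, all(diff(edges) > 0), all(edges > 1))
  stopifnot(length(colors) == 7L)
  labels <- c(paste0(">", edges[3], "x greater"),
              paste0(edges[2], "-", edges[3], "x greater"),
              paste0(edges[1], "-", edges[2], "x greater"),
              "neutral",
              paste0(edges[1], "-", edges[2], "x smaller"),
              paste0(edges[2], "-", edges[3], "x smaller"),
              paste0(">", edges[3], "x smaller"))
  structure(list(edges = edges, labels = labels,
                 colors = stats::setNames(colors, labels)),
            class = "classification_scheme")
}

#' Classify fold ratios into bins
#'
#' @param ratio numeric vector of fold ratios (> 0).
#' @param scheme a [classification_scheme()].
#' @return character vector of bin labels.
#' @export
classify_ratio <- function(ratio, scheme = classification_scheme()) {
  e <- scheme$edges; L <- scheme$labels
  out <- rep(L[4], length(ratio))
  out[ratio >= e[1]] <- L[3]
  out[ratio >= e[2]] <- L[2]
  out[ratio >= e[3]] <- L[1]
  out[ratio <= 1 / e[1]] <- L[5]
  out[ratio <= 1 / e[2]] <- L[6]
  out[ratio <= 1 / e[3]] <- L[7]
  out[!is.finite(ratio)] <- NA_character_
  out
}

#' Differential per-residue SASA ratio table
#'
#' For every paired residue, computes the SASA difference
#' `delta = |value_a - value_b|` and fold ratio
#' `max(value_a, eps) / max(value_b, eps)`, applies the exclusion
#' rules, and classifies the surviving rows into fold bins.  Exclusion
#' reasons, in order of precedence:
#'
#' * `incomplete-residue` - either partner is missing heavy atoms
#'   (when `exclude_incomplete`);
#' * `both-buried` - both values below the epsilon floor;
#' * `small-delta` - `delta < exclusion_delta`.
#'
#' Both SASA results must have been computed with identical parameters
#' unless `allow_param_mismatch` is set, in which case a warning is
#' issued.  Row order follows structure `a`'s residue order.
#'
#' @param sasa_a,sasa_b complete `sasa_result` objects (see
#'   [calc_sasa()]); `a` is the numerator.
#' @param corr a [align_residues()] correspondence.
#' @param params a [diff_params()].
#' @param scheme a [classification_scheme()].
#' @param exclude_incomplete exclude residues flagged by
#'   [incomplete_residues()] (default `TRUE`).
#' @param allow_param_mismatch permit differing SASA parameters.
#' @return object of class `diff_table`: data.frame `rows` plus the
#'   parameter echo.
#' @export
sasa_ratio_table <- function(sasa_a, sasa_b, corr,
                             params = diff_params(),
                             scheme = classification_scheme(),
                             exclude_incomplete = TRUE,
                             allow_param_mismatch = FALSE) {
  stopifnot(inherits(sasa_a, "sasa_result"), inherits(sasa_b, "sasa_result"),
            inherits(corr, "residue_correspondence"))
  if (is.null(sasa_a$per_residue) || is.null(sasa_b$per_residue))
    stop("sasa results must include per-residue values (see residue_sasa)")
  siga <- sasa_params_signature(sasa_a$params)
  sigb <- sasa_params_signature(sasa_b$params)
  if (siga != sigb) {
    if (!allow_param_mismatch)
      stop("SASA parameter mismatch between inputs:\n  a: ", siga,
           "\n  b: ", sigb)
    warning("comparing SASA results computed with different parameters")
  }
  pra <- sasa_a$per_residue; prb <- sasa_b$per_residue
  missing_a <- setdiff(corr$pairs$key_a, pra$key)
  missing_b <- setdiff(corr$pairs$key_b, prb$key)
  if (length(missing_a) || length(missing_b))
    stop("correspondence references residues absent from SASA results: ",
         paste(c(missing_a, missing_b), collapse = ", "))
  col <- if (params$ratio_mode == "relative_percent") "rel" else "abs"
  ia <- match(corr$pairs$key_a, pra$key)
  ib <- match(corr$pairs$key_b, prb$key)
  va <- pra[[col]][ia]
  vb <- prb[[col]][ib]
  eps <- params$epsilon_area
  rows <- corr$pairs
  rows$value_a <- va
  rows$value_b <- vb
  rows$delta <- abs(va - vb)
  rows$ratio <- pmax(va, eps) / pmax(vb, eps)
  rows$excluded <- FALSE
  rows$reason <- ""
  if (exclude_incomplete) {
    inc_a <- incomplete_residues(sasa_a$structure)
    inc_b <- incomplete_residues(sasa_b$structure)
    bad <- (inc_a$incomplete[match(rows$key_a, inc_a$key)] %in% TRUE) |
      (inc_b$incomplete[match(rows$key_b, inc_b$key)] %in% TRUE)
    rows$excluded[bad] <- TRUE
    rows$reason[bad] <- "incomplete-residue"
  }
  nonstd <- is.na(va) | is.na(vb)
  mark <- nonstd & !rows$excluded
  rows$excluded[mark] <- TRUE
  rows$reason[mark] <- "no-reference"
  buried <- !rows$excluded & !nonstd & va < eps & vb < eps
  rows$excluded[buried] <- TRUE
  rows$reason[buried] <- "both-buried"
  small <- !rows$excluded & !nonstd & rows$delta < params$exclusion_delta
  rows$excluded[small] <- TRUE
  rows$reason[small] <- "small-delta"
  rows$bin <- NA_character_
  ok <- !rows$excluded
  rows$bin[ok] <- classify_ratio(rows$ratio[ok], scheme)
  structure(list(rows = rows, params = params, scheme = scheme,
                 sasa_params = sasa_a$params,
                 reference_table = sasa_a$reference_table),
            class = "diff_table")
}

#' @export
print.diff_table <- function(x, ...) {
  r <- x$rows
  cat(sprintf("diff_table: %d residue pairs (%d excluded)\n",
              nrow(r), sum(r$excluded)))
  if (any(!r$excluded)) {
    print(table(bin = r$bin[!r$excluded]))
  }
  invisible(x)
}

#' Per-bin counts of a differential table
#' @param table a `diff_table`.
#' @return named integer vector over all bins of the scheme, plus
#'   `excluded`.
#' @export
bin_counts <- function(table) {
  stopifnot(inherits(table, "diff_table"))
  r <- table$rows
  cnt <- vapply(table$scheme$labels,
                function(l) sum(r$bin %in% l), integer(1))
  c(cnt, excluded = sum(r$excluded))
}

#' Restrict a differential table to interface residues
#'
#' Subsets the table to residue pairs whose `a`- or `b`-side residue is
#' in the given contact set (e.g. residues with inter-subunit contacts
#' from [contacts()]), keeping row order; a per-bin summary is attached.
#'
#' @param table a `diff_table`.
#' @param contact_residues data.frame with `chain`, `resno` and
#'   optionally `insert` columns, or a character vector of residue keys.
#' @param side `"a"`, `"b"` or `"either"`: which structure's residue
#'   identity the contact set refers to.
#' @return a `diff_table` restricted to contact residues, with a
#'   `summary` element of per-bin counts.
#' @export
interface_diff <- function(table, contact_residues, side = c("b", "a", "either")) {
  stopifnot(inherits(table, "diff_table"))
  side <- match.arg(side)
  keys <- contact_keys(contact_residues)
  if (!length(keys)) warning("empty contact set: interface table is empty")
  r <- table$rows
  keep <- switch(side,
                 a = r$key_a %in% keys,
                 b = r$key_b %in% keys,
                 either = r$key_a %in% keys | r$key_b %in% keys)
  out <- table
  out$rows <- r[keep, , drop = FALSE]
  out$summary <- bin_counts(out)
  out
}

contact_keys <- function(contact_residues) {
  if (is.character(contact_residues)) return(unique(contact_residues))
  stopifnot(is.data.frame(contact_residues))
  ins <- if ("insert" %in% names(contact_residues))
    contact_residues$insert else ""
  unique(residue_key(contact_residues$chain, contact_residues$resno, ins))
}

#' Write a differential table as TSV
#'
#' @param table a `diff_table`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_diff_tsv <- function(table, path) {
  stopifnot(inherits(table, "diff_table"))
  r <- table$rows
  out <- data.frame(
    chain_a = r$chain_a, resno_a = r$resno_a, resid_a = r$resid_a,
    chain_b = r$chain_b, resno_b = r$resno_b, resid_b = r$resid_b,
    value_a = sprintf("%.3f", r$value_a), value_b = sprintf("%.3f", r$value_b),
    delta = sprintf("%.3f", r$delta), ratio = sprintf("%.4f", r$ratio),
    excluded = r$excluded, reason = r$reason,
    bin = ifelse(is.na(r$bin), "", r$bin))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Emit a colouring script for a differential table
#'
#' Writes plain rendering commands (one per classified residue) keyed
#' by the scheme's bin-to-colour map, in PyMOL `color` syntax, for
#' sphere/surface visualisation of the fold bins.
#'
#' @param table a `diff_table`.
#' @param path output file.
#' @param side colour residues of structure `"a"` or `"b"`.
#' @return invisibly, `path`.
#' @export
write_color_script <- function(table, path, side = c("a", "b")) {
  side <- match.arg(side)
  r <- table$rows[!table$rows$excluded, , drop = FALSE]
  chain <- r[[paste0("chain_", side)]]
  resno <- r[[paste0("resno_", side)]]
  col <- unname(table$scheme$colors[r$bin])
  lines <- c("# residue colouring by SASA fold-change bin",
             sprintf("color %s, chain %s and resi %d", col, chain, resno))
  writeLines(lines, path)
  invisible(path)
}
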