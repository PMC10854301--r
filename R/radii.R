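#' Van der Waals radii sets
#'
#' A radii set maps chemical elements (and optionally specific
#' residue/atom-name combinations) to van der Waals radii in Angstrom.
#' Lookup is total: a per-(residue, atom-name) override wins over the
#' per-element radius, which wins over the default radius used for
#' unknown elements.  Every SASA and cavity result records the name of
#' the radii set it was computed with, because absolute areas and
#' volumes depend on it.
#'
#' @param name label for the set, recorded in downstream results.
#' @param elements named numeric vector of per-element radii (Angstrom).
#' @param overrides data.frame with columns `resid`, `elety`, `radius`
#'   giving per-(residue, atom-name) radii, or `NULL`.
#' @param default radius (Angstrom) assigned to elements absent from
#'   `elements`.
#' @return an object of class `radii_set`.
#' @export
radii_set <- function(name, elements, overrides = NULL, default = 1.70) {
  stopifnot(is.character(name), length(name) == 1L)
  stopifnot(is.numeric(elements), !is.null(names(elements)))
  if (any(elements <= 0) || default <= 0)
    stop("all radii must be > 0")
  if (!is.null(overrides)) {
    stopifnot(is.data.frame(overrides),
              all(c("resid", "elety", "radius") %in% names(overrides)))
    if (any(overrides$radius <= 0)) stop("all radii must be > 0")
  }
  structure(list(name = name, elements = elements,
                 overrides = overrides, default = default),
            class = "radii_set")
}

#' Default van der Waals radii
#'
#' The set used when none is given: C 1.70, N 1.55, O 1.52, S 1.80,
#' P 1.80, H 1.20 Angstrom, with 1.70 for any other element.
#'
#' @return a `radii_set`.
#' @export
default_radii <- function() {
  radii_set("default-1.70",
            c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20),
            default = 1.70)
}

#' Look up per-atom radii for a structure
#'
#' @param struc a [structure3d] object.
#' @param radii a `radii_set` (default [default_radii()]).
#' @return numeric vector of radii, one per atom row.
#' @export
atom_radii <- function(struc, radii = default_radii()) {
  stopifnot(inherits(radii, "radii_set"))
  at <- struc$atom
  r <- unname(radii$elements[at$elem])
  r[is.na(r)] <- radii$default
  if (!is.null(radii$overrides) && nrow(radii$overrides)) {
    ov <- radii$overrides
    key <- paste(at$resid, at$elety)
    okey <- paste(ov$resid, ov$elety)
    hit <- match(key, okey)
    r[!is.na(hit)] <- ov$radius[hit[!is.na(hit)]]
  }
  r
}

#' @export
print.radii_set <- function(x, ...) {
  cat("radii_set:", x$name, "\n")
  cat("  elements:",
      paste(sprintf("%s=%.2f", names(x$elements), x$elements), collapse = " "),
      "\n  default:", sprintf("%.2f", x$default), "\n")
  if (!is.null(x$overrides) && nrow(x$overrides))
    cat("  overrides:", nrow(x$overrides), "\n")
  invisible(x)
}
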