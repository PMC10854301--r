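#' Global sequence alignment (Needleman-Wunsch)
#'
#' Minimal global aligner used to pair analogous residues between two
#' structures.  Scoring is fixed and documented: identity +1,
#' mismatch -1, gap -2 (linear).  Traceback ties are broken
#' deterministically toward the upper-left path: diagonal first, then
#' a gap in the second sequence, then a gap in the first.
#'
#' @param a,b character vectors of single-letter codes.
#' @return list with `ai`, `bi` (aligned index vectors, NA at gaps)
#'   and `score`.
#' @export
nw_align <- function(a, b) {
  n <- length(a); m <- length(b)
  gap <- -2L
  S <- matrix(0L, n + 1L, m + 1L)
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(a[i] == b, 1L, -1L)
    for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + sub[j],
                               S[i, j + 1L] + gap,
                               S[i + 1L, j] + gap)
    }
  }
  ai <- bi <- integer(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] == S[i, j] + (if (a[i] == b[j]) 1L else -1L)) {
      ai <- c(i, ai); bi <- c(j, bi); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      ai <- c(i, ai); bi <- c(NA, bi); i <- i - 1L
    } else {
      ai <- c(NA, ai); bi <- c(j, bi); j <- j - 1L
    }
  }
  list(ai = ai, bi = bi, score = S[n + 1L, m + 1L])
}

#' Pair analogous residues between two structures
#'
#' Aligns the one-letter sequences of each configured chain pair with
#' [nw_align()] and returns the order-preserving residue
#' correspondence.  Identical sequences map one-to-one regardless of
#' author-numbering offsets; alignment gaps go to the unpaired lists.
#'
#' @param struct_a,struct_b [structure3d] objects.
#' @param chain_pairs two-column matrix or data.frame (chain in `a`,
#'   chain in `b`), or a named character vector `c(A = "B", ...)`.
#' @return object of class `residue_correspondence`: `pairs`
#'   (data.frame of paired residue identities and keys), `unpaired_a`,
#'   `unpaired_b`, `chain_pairs`.
#' @export
align_residues <- function(struct_a, struct_b, chain_pairs) {
  cp <- normalize_chain_pairs(chain_pairs)
  rta <- residue_table(struct_a)
  rtb <- residue_table(struct_b)
  for (k in seq_len(nrow(cp))) {
    if (!cp$a[k] %in% rta$chain)
      stop("chain '", cp$a[k], "' not present in structure '", struct_a$id, "'")
    if (!cp$b[k] %in% rtb$chain)
      stop("chain '", cp$b[k], "' not present in structure '", struct_b$id, "'")
  }
  pairs <- list(); un_a <- list(); un_b <- list()
  for (k in seq_len(nrow(cp))) {
    sa <- rta[rta$chain == cp$a[k], , drop = FALSE]
    sb <- rtb[rtb$chain == cp$b[k], , drop = FALSE]
    if (nrow(sa) == 0L || nrow(sb) == 0L) {
      un_a[[k]] <- sa; un_b[[k]] <- sb
      next
    }
    al <- nw_align(one_letter(sa$resid), one_letter(sb$resid))
    hit <- !is.na(al$ai) & !is.na(al$bi)
    pa <- sa[al$ai[hit], , drop = FALSE]
    pb <- sb[al$bi[hit], , drop = FALSE]
    names(pa) <- paste0(names(pa), "_a")
    names(pb) <- paste0(names(pb), "_b")
    pairs[[k]] <- cbind(pa, pb)
    un_a[[k]] <- sa[setdiff(seq_len(nrow(sa)), al$ai[hit]), , drop = FALSE]
    un_b[[k]] <- sb[setdiff(seq_len(nrow(sb)), al$bi[hit]), , drop = FALSE]
  }
  out <- list(chain_pairs = cp,
              pairs = do.call(rbind, c(pairs, list(NULL))),
              unpaired_a = do.call(rbind, c(un_a, list(NULL))),
              unpaired_b = do.call(rbind, c(un_b, list(NULL))))
  if (is.null(out$pairs)) out$pairs <- empty_pairs_df()
  class(out) <- "residue_correspondence"
  out
}

empty_pairs_df <- function() {
  data.frame(chain_a = character(), resno_a = integer(),
             insert_a = character(), resid_a = character(),
             key_a = character(), chain_b = character(),
             resno_b = integer(), insert_b = character(),
             resid_b = character(), key_b = character(),
             stringsAsFactors = FALSE)
}

normalize_chain_pairs <- function(chain_pairs) {
  if (is.list(chain_pairs) && !is.data.frame(chain_pairs))
    chain_pairs <- unlist(chain_pairs)
  if (is.matrix(chain_pairs) || is.data.frame(chain_pairs)) {
    cp <- as.data.frame(chain_pairs, stringsAsFactors = FALSE)
    names(cp) <- c("a", "b")
  } else if (!is.null(names(chain_pairs))) {
    cp <- data.frame(a = names(chain_pairs), b = unname(chain_pairs),
                     stringsAsFactors = FALSE)
  } else stop("chain_pairs must be a 2-column table or a named vector")
  cp$a <- as.character(cp$a); cp$b <- as.character(cp$b)
  cp
}

one_letter <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(resid))
  out[is.na(out)] <- "X"
  out
}

#' @export
print.residue_correspondence <- function(x, ...) {
  cat(sprintf("residue_correspondence: %d pairs, %d unpaired (a), %d unpaired (b)\n",
              nrow(x$pairs),
              if (is.null(x$unpaired_a)) 0L else nrow(x$unpaired_a),
              if (is.null(x$unpaired_b)) 0L else nrow(x$unpaired_b)))
  invisible(x)
}
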