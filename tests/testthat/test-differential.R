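# Build a pair of sasa_result stubs over simple helices so exclusion
# and binning logic can be exercised with hand-set relative values.
mock_pair <- function(rel_a, rel_b) {
  n <- length(rel_a)
  a <- calc_sasa(make_helix(n))
  b <- calc_sasa(make_helix(n))
  a$per_residue$rel <- rel_a
  b$per_residue$rel <- rel_b
  corr <- align_residues(a$structure, b$structure, c(A = "A"))
  list(a = a, b = b, corr = corr)
}

test_that("global alignment pairs identical chains despite numbering offsets", {
  a <- make_helix(50)
  b <- make_helix(50, start_resno = 11L)
  corr <- align_residues(a, b, c(A = "A"))
  expect_equal(nrow(corr$pairs), 50L)
  expect_equal(nrow(corr$unpaired_a), 0L)
  expect_equal(corr$pairs$resno_b, corr$pairs$resno_a + 10L)
})

test_that("deletions go to the unpaired lists", {
  a <- make_helix(50)
  b <- make_helix(50)
  b$atom <- b$atom[!(b$atom$resno %in% 5:7), ]
  corr <- align_residues(a, b, c(A = "A"))
  expect_equal(nrow(corr$pairs), 47L)
  expect_equal(nrow(corr$unpaired_a), 3L)
  expect_equal(nrow(corr$unpaired_b), 0L)
  expect_error(align_residues(a, b, c(Q = "A")), "chain 'Q'")
})

test_that("alignment scores agree with an independent aligner", {
  skip_if_not_installed("Biostrings")
  set.seed(42)
  for (k in 1:3) {
    sa <- paste(sample(c("A", "G", "L", "S"), 30, replace = TRUE), collapse = "")
    sb <- paste(sample(c("A", "G", "L", "S"), 25, replace = TRUE), collapse = "")
    ours <- nw_align(strsplit(sa, "")[[1]], strsplit(sb, "")[[1]])$score
    mat <- matrix(-1L, 4, 4, dimnames = list(c("A", "G", "L", "S"),
                                             c("A", "G", "L", "S")))
    diag(mat) <- 1L
    ref <- Biostrings::pairwiseAlignment(
      sa, sb, type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2, scoreOnly = TRUE)
    expect_equal(ours, ref)
  }
})

test_that("the exclusion rule and fold bins follow the documented conventions", {
  m <- mock_pair(c(50.0, 30.0, 20.0, 0.4, 10.0),
                 c(48.0, 30.0,  4.0, 24.0, 0.05))
  dt <- sasa_ratio_table(m$a, m$b, m$corr)
  r <- dt$rows
  # delta 2.0 < 2.5 -> excluded
  expect_true(r$excluded[1]); expect_equal(r$reason[1], "small-delta")
  # identical values -> delta 0 -> excluded
  expect_true(r$excluded[2])
  # 20 vs 4: delta 16, ratio 5 -> 3-10x greater (yellow)
  expect_false(r$excluded[3])
  expect_equal(r$ratio[3], 5)
  expect_equal(r$bin[3], "3-10x greater")
  expect_equal(unname(dt$scheme$colors[r$bin[3]]), "yellow")
  # 0.4 vs 24: ratio 1/60 -> >50x smaller
  expect_equal(r$bin[4], ">50x smaller")
  # denominator floored at epsilon: 10 vs 0.05 -> ratio 100, not 200
  expect_equal(r$ratio[5], 100)
  expect_equal(r$bin[5], ">50x greater")
})

test_that("both-buried pairs are excluded with a reason, never binned", {
  m <- mock_pair(c(0.05, 40), c(0.01, 10))
  dt <- sasa_ratio_table(m$a, m$b, m$corr)
  expect_equal(dt$rows$reason[1], "both-buried")
  expect_true(is.na(dt$rows$bin[1]))
  expect_equal(dt$rows$bin[2], "3-10x greater")
})

test_that("incomplete residues are excluded from classification by default", {
  a <- calc_sasa(make_helix(4))
  b0 <- make_helix(4)
  b0$atom <- b0$atom[!(b0$atom$resno == 2 & b0$atom$elety == "CB"), ]
  b <- calc_sasa(b0)
  corr <- align_residues(a$structure, b0, c(A = "A"))
  dt <- sasa_ratio_table(a, b, corr)
  expect_equal(dt$rows$reason[2], "incomplete-residue")
  dt2 <- sasa_ratio_table(a, b, corr, exclude_incomplete = FALSE)
  expect_false(dt2$rows$reason[2] == "incomplete-residue")
})

test_that("mismatched SASA parameters are rejected unless overridden", {
  a <- calc_sasa(make_helix(3), sasa_params(n_points = 960))
  b <- calc_sasa(make_helix(3), sasa_params(n_points = 480))
  corr <- align_residues(a$structure, b$structure, c(A = "A"))
  expect_error(sasa_ratio_table(a, b, corr), "mismatch")
  expect_warning(sasa_ratio_table(a, b, corr, allow_param_mismatch = TRUE),
                 "different parameters")
})

test_that("the bins partition (0, Inf) with half-open reciprocal edges", {
  ratios <- c(10^seq(-3, 3, length.out = 2001),
              1 / 50, 1 / 10, 1 / 3, 1, 3, 10, 50)
  bins <- classify_ratio(ratios)
  expect_false(any(is.na(bins)))        # no gaps, one bin per ratio
  # bins change monotonically along the ratio axis (no overlap/interleave)
  ord <- match(bins[order(ratios)], rev(classification_scheme()$labels))
  expect_true(all(diff(ord) >= 0))
  expect_equal(classify_ratio(3), "3-10x greater")
  expect_equal(classify_ratio(10), "10-50x greater")
  expect_equal(classify_ratio(50), ">50x greater")
  expect_equal(classify_ratio(1 / 3), "3-10x smaller")
  expect_equal(classify_ratio(1 / 10), "10-50x smaller")
  expect_equal(classify_ratio(1 / 50), ">50x smaller")
  expect_equal(classify_ratio(2.999), "neutral")
  expect_equal(classify_ratio(1 / 2.999), "neutral")
})

test_that("swapping the structures mirrors every bin and inverts every ratio", {
  pair <- make_open_closed_pair(d = 3)
  sa <- calc_sasa(pair$open); sb <- calc_sasa(pair$closed)
  corr_ab <- align_residues(pair$open, pair$closed, c(A = "A", B = "B"))
  corr_ba <- align_residues(pair$closed, pair$open, c(A = "A", B = "B"))
  dt <- sasa_ratio_table(sa, sb, corr_ab)
  ds <- sasa_ratio_table(sb, sa, corr_ba)
  expect_equal(ds$rows$ratio, 1 / dt$rows$ratio, tolerance = 1e-12)
  expect_equal(ds$rows$excluded, dt$rows$excluded)
  mirror <- function(bin) {
    out <- bin
    out[grepl("greater", bin)] <- sub("greater", "smaller", bin[grepl("greater", bin)])
    out[grepl("smaller", bin)] <- sub("smaller", "greater", bin[grepl("smaller", bin)])
    out
  }
  expect_equal(ds$rows$bin, mirror(dt$rows$bin))
})

test_that("the pipeline recovers the opened interface on the synthetic pair", {
  pair <- make_open_closed_pair(d = 3)
  sa <- calc_sasa(pair$open); sb <- calc_sasa(pair$closed)
  corr <- align_residues(pair$open, pair$closed, c(A = "A", B = "B"))
  dt <- sasa_ratio_table(sa, sb, corr)
  r <- dt$rows
  ifr <- interface_residues(pair$closed)
  expect_gt(nrow(ifr), 5)
  ri <- r[r$key_a %in% ifr$key, ]
  # every classified interface residue with delta >= 2.5 is "greater"
  strong <- ri[!ri$excluded & ri$delta >= 2.5, ]
  expect_gt(nrow(strong), 0)
  expect_true(all(grepl("greater", strong$bin)))
  # residues far from the interface are excluded or neutral
  far_keys <- far_residue_keys(pair$closed)
  rf <- r[r$key_a %in% far_keys, ]
  expect_gt(nrow(rf), 5)
  expect_gte(mean(rf$excluded | rf$bin %in% "neutral"), 0.95)
  # interface residues are enriched in "greater" bins
  is_if <- r$key_a %in% ifr$key
  greater <- grepl("greater", r$bin) & !r$excluded
  tab <- matrix(c(sum(greater & is_if), sum(!greater & is_if),
                  sum(greater & !is_if), sum(!greater & !is_if)), 2)
  # exact one-sided test of greater-bin enrichment at the interface
  ft <- stats::fisher.test(tab, alternative = "greater")
  expect_lt(ft$p.value, 0.01)
})

test_that("interface_diff subsets to contact residues with per-bin counts", {
  m <- mock_pair(c(50, 20, 40, 5), c(5, 4, 39, 30))
  dt <- sasa_ratio_table(m$a, m$b, m$corr)
  rt <- residue_table(m$a$structure)
  sel <- rt[c(1, 2), c("chain", "resno", "insert")]
  sub <- interface_diff(dt, sel, side = "a")
  expect_equal(nrow(sub$rows), 2L)
  expect_named(sub$summary)
  expect_equal(sum(sub$summary[grepl("greater", names(sub$summary))]), 2L)
  expect_warning(interface_diff(dt, character(0)), "empty contact set")
  expect_equal(suppressWarnings(nrow(interface_diff(dt, character(0))$rows)), 0L)
})
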