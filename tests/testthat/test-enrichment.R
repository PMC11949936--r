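test_that("CPM columns sum to the scale and zeros stay zero", {
  m <- matrix(c(1L, 1L, 2L, 0L, 5L, 5L), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  norm <- normalize_cpm(m)
  expect_equal(unname(norm[, 1]), c(250000, 250000, 500000))
  expect_equal(unname(colSums(norm)), c(1e6, 1e6))
  expect_equal(norm[1, 2], 0)
  # a column already at scale is a fixed point
  fp <- matrix(c(4e5, 6e5), 2, 1, dimnames = list(c("g1", "g2"), "a"))
  expect_equal(normalize_cpm(fp), fp)
  # random matrices: every column sums to scale
  set.seed(5)
  r <- matrix(rpois(60, 30), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  expect_equal(unname(colSums(normalize_cpm(r, 7e3))), rep(7e3, 6),
               tolerance = 1e-9)
  bad <- matrix(c(1L, 0L), 1, 2, dimnames = list("g1", c("ok", "empty")))
  expect_error(normalize_cpm(bad), "empty")
})

test_that("a flat guide has zero fold change, zero score, no hit", {
  norm <- toy_norm(matrix(100, 1, 3), matrix(100, 1, 3))
  tbl <- guide_statistics(norm, toy_norm_sheet())
  expect_equal(tbl$log2fc, 0)
  expect_equal(tbl$score, 0)
  expect_false(tbl$is_hit)
  expect_equal(tbl$p_value, 1)  # degenerate equal means
})

test_that("fold change is computed from condition medians with pseudocount", {
  norm <- toy_norm(matrix(c(600, 700, 800), 1), matrix(c(90, 100, 110), 1))
  tbl <- guide_statistics(norm, toy_norm_sheet())
  expect_equal(tbl$median_sorted, 700)
  expect_equal(tbl$median_baseline, 100)
  expect_equal(tbl$log2fc, log2(701 / 101))
  expect_equal(tbl$log2fc, 2.795, tolerance = 1e-3)
})

test_that("the ratio-median alternative uses per-replicate ratios", {
  sorted <- matrix(c(200, 400, 800), 1)
  baseline <- matrix(c(100, 100, 100), 1)
  norm <- toy_norm(sorted, baseline)
  p <- enrichment_params(fc_method = "ratio-median")
  tbl <- guide_statistics(norm, toy_norm_sheet(), params = p)
  expect_equal(tbl$log2fc, median(log2((sorted + 1) / (baseline + 1))))
})

test_that("Welch one-sided p-values match the reference t-test to 1e-9", {
  # a small fixed case first
  xs <- c(30, 40, 50)
  xb <- c(10, 12, 8)
  norm <- toy_norm(matrix(xs, 1), matrix(xb, 1))
  p <- enrichment_params(test_scale = "cpm")
  tbl <- guide_statistics(norm, toy_norm_sheet(), params = p)
  want <- t.test(xs, xb, alternative = "greater", var.equal = FALSE)$p.value
  expect_equal(tbl$p_value, want, tolerance = 1e-9)

  # random guides, both test scales, against stats::t.test row by row
  set.seed(77)
  ns <- matrix(rpois(400, 60), 100, 4)
  nb <- matrix(rpois(400, 50), 100, 4)
  norm <- toy_norm(ns, nb)
  sheet <- toy_norm_sheet(4, 4)
  for (scale in c("cpm", "log2")) {
    prm <- enrichment_params(test_scale = scale)
    tbl <- guide_statistics(norm, sheet, params = prm)
    tr <- if (scale == "log2") function(x) log2(x + 1) else identity
    want <- vapply(seq_len(100), function(i) {
      t.test(tr(ns[i, ]), tr(nb[i, ]), alternative = "greater",
             var.equal = FALSE)$p.value
    }, numeric(1))
    expect_equal(tbl$p_value, want, tolerance = 1e-9)
  }
})

test_that("degenerate variance rows get a total ordering, never an error", {
  norm <- toy_norm(matrix(rep(c(50, 10, 10), each = 3), 3, byrow = TRUE),
                   matrix(rep(c(10, 50, 10), each = 3), 3, byrow = TRUE))
  tbl <- guide_statistics(norm, toy_norm_sheet(),
                          params = enrichment_params(test_scale = "cpm"))
  expect_equal(tbl$p_value, c(.Machine$double.xmin, 1, 1))
  expect_true(all(is.finite(tbl$score)))
})

test_that("hit calls use strict thresholds on both axes", {
  tbl <- data.frame(guide_id = paste0("g", 1:4),
                    log2fc = c(1.6, 1.5, 3.0, 1.6),
                    p_value = c(0.01, 0.01, 0.02, 0.01),
                    exonic = c(FALSE, FALSE, FALSE, TRUE))
  out <- call_hits(tbl, enrichment_params())
  expect_equal(out$is_hit, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(out$volcano_class,
               c("enriched-non-exonic", "non-exonic", "non-exonic",
                 "exonic"))
})

test_that("score is -log10(p) * log2fc with matching sign and monotonicity", {
  set.seed(9)
  ns <- matrix(rpois(300, 80), 100, 3)
  nb <- matrix(rpois(300, 80), 100, 3)
  tbl <- guide_statistics(toy_norm(ns, nb), toy_norm_sheet())
  expect_equal(tbl$score, -log10(tbl$p_value) * tbl$log2fc)
  expect_true(all(sign(tbl$score) == sign(tbl$log2fc) |
                    tbl$score == 0))
  # monotone in log2fc at fixed p, decreasing in p at fixed positive log2fc
  expect_true(all(diff(-log10(c(0.5, 0.1, 0.01)) * 2) > 0))
  expect_equal(order(-log10(0.01) * c(1, 2, 3)),
               1:3)
})

test_that("swapping condition labels negates every log2fc", {
  set.seed(13)
  ns <- matrix(rpois(150, 120), 50, 3)
  nb <- matrix(rpois(150, 40), 50, 3)
  norm <- toy_norm(ns, nb)
  sheet <- toy_norm_sheet()
  fwd <- guide_statistics(norm, sheet)
  swapped <- sheet
  swapped$condition <- ifelse(sheet$condition == "sorted", "baseline",
                              "sorted")
  rev <- guide_statistics(norm, sample_sheet(as.data.frame(swapped)))
  expect_equal(rev$log2fc, -fwd$log2fc)
})

test_that("guide_statistics carries library annotation and checks inputs", {
  lib <- toy_library()
  norm <- toy_norm(matrix(rpois(12, 50), 4, 3),
                   matrix(rpois(12, 50), 4, 3),
                   ids = guides(lib)$guide_id)
  tbl <- guide_statistics(norm, toy_norm_sheet(), lib)
  expect_equal(tbl$cut_site, guides(lib)$cut_site)
  expect_equal(tbl$exonic, guides(lib)$exonic)
  # fewer than 2 replicates per condition is an error
  expect_error(guide_statistics(norm[, c(1, 4), drop = FALSE],
                                toy_norm_sheet(1, 1)),
               "2 replicates")
})

test_that("score_track writes one sorted 1-bp interval per guide", {
  lib <- toy_library()
  tbl <- data.frame(guide_id = guides(lib)$guide_id,
                    chrom = guides(lib)$chrom,
                    cut_site = guides(lib)$cut_site,
                    score = c(4.2, 0, -1.5, 2.25))
  p <- tempfile(fileext = ".bedgraph")
  score_track(tbl[c(3, 1, 2, 4), ], p)   # shuffled input
  back <- read_bedgraph(p)
  expect_equal(back$start, sort(guides(lib)$cut_site))
  expect_equal(back$end, back$start + 1)
  # zero scores are kept
  expect_true(0 %in% back$value)
  # empty table -> header-only track
  score_track(tbl[0, ], p)
  expect_equal(nrow(read_bedgraph(p)), 0)
  # duplicate cut sites are shifted to the next free base, stably
  dup <- tbl
  dup$cut_site <- c(117L, 117L, 117L, 200L)
  expect_message(score_track(dup, p), "shares cut site")
  back <- read_bedgraph(p)
  expect_equal(back$start, c(117, 118, 119, 200))
  expect_equal(back$value[1:3], dup$score[1:3])
})

test_that("volcano summary counts classes and orders hits by score", {
  tbl <- data.frame(guide_id = sprintf("g%02d", 1:10),
                    log2fc = c(rep(0.1, 6), 2, 2, 3, 0.2),
                    p_value = c(rep(0.5, 6), 1e-3, 1e-3, 1e-4, 0.9),
                    exonic = c(rep(FALSE, 9), TRUE))
  tbl <- call_hits(tbl, enrichment_params())
  tbl$score <- -log10(tbl$p_value) * tbl$log2fc
  vs <- volcano_summary(tbl)
  expect_equal(sum(vs$class_counts), 10)
  expect_equal(unname(vs$class_counts["exonic"]), 1)
  expect_equal(vs$n_hits, 3)
  expect_equal(vs$hits$guide_id, c("g09", "g07", "g08"))  # tie: g07 < g08
  # all-exonic table has no enriched-non-exonic guides
  allex <- tbl
  allex$exonic <- TRUE
  allex <- call_hits(allex, enrichment_params())
  expect_equal(unname(volcano_summary(allex)$class_counts[
    "enriched-non-exonic"]), 0)
})
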