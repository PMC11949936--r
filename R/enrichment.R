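#' Enrichment analysis parameters
#'
#' Defaults follow the screen's published cut-offs: a guide is a hit when its
#' log2 fold enrichment exceeds 1.5 and its one-sided p-value is below 0.02
#' (both strict).
#'
#' @param pseudocount Positive value added to both condition medians before
#'   the ratio (and to CPM values before the log transform used by the
#'   t-test). Guards against zero baselines. Default 1 (normalized units).
#' @param lfc_threshold Hit threshold on log2 fold change (strict `>`).
#' @param p_threshold Hit threshold on the raw one-sided p-value
#'   (strict `<`); no multiple-testing correction is applied to hit calls,
#'   though a BH-adjusted column is reported.
#' @param scale Normalization scale: reads per million.
#' @param fc_method `"median-ratio"` (default): fold change of condition
#'   medians; `"ratio-median"`: median of per-replicate ratios (replicates
#'   paired by order).
#' @param test_scale Scale on which the Welch t-test is computed:
#'   `"log2"` (default, `log2(CPM + pseudocount)`; variance-stabilizing for
#'   overdispersed counts) or `"cpm"` (raw normalized counts).
#' @return List of class `"enrichment_params"`.
#' @export
enrichment_params <- function(pseudocount = 1, lfc_threshold = 1.5,
                              p_threshold = 0.02, scale = 1e6,
                              fc_method = c("median-ratio", "ratio-median"),
                              test_scale = c("log2", "cpm")) {
  stopifnot(pseudocount > 0, lfc_threshold > 0,
            p_threshold > 0, p_threshold < 1, scale > 0)
  structure(list(pseudocount = pseudocount, lfc_threshold = lfc_threshold,
                 p_threshold = p_threshold, normalization = "cpm",
                 scale = scale, fc_method = match.arg(fc_method),
                 test_scale = match.arg(test_scale)),
            class = "enrichment_params")
}

#' Counts-per-million normalization
#'
#' Scales every sample column so it sums to `scale` (default one million):
#' the minimal depth correction before comparing guide abundances across
#' samples. Zero counts stay zero.
#'
#' @param cm A `count_matrix`, or a plain numeric matrix.
#' @param scale Target column sum.
#' @return Numeric matrix of normalized counts (same dimnames).
#' @export
normalize_cpm <- function(cm, scale = 1e6) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  stopifnot(is.matrix(counts))
  depth <- colSums(counts)
  if (any(depth == 0)) {
    stop("cannot normalize sample with zero assigned reads: ",
         paste(colnames(counts)[depth == 0], collapse = ", "),
         call. = FALSE)
  }
  sweep(counts, 2L, depth / scale, "/")
}

# Vectorized one-sided Welch t-test over rows: H1 is mean(sorted) >
# mean(baseline). Rows where both groups have zero variance get p = 1 when
# the sorted mean does not exceed the baseline mean and the smallest positive
# double otherwise, so every row has a defined p-value.
welch_one_sided <- function(x_sorted, x_baseline) {
  n1 <- ncol(x_sorted)
  n2 <- ncol(x_baseline)
  m1 <- rowMeans(x_sorted)
  m2 <- rowMeans(x_baseline)
  v1 <- rowSums((x_sorted - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x_baseline - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- stats::pt((m1 - m2) / sqrt(se2), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  p[degenerate & m1 > m2] <- .Machine$double.xmin
  p[degenerate & m1 <= m2] <- 1
  p
}

#' Per-guide enrichment statistics
#'
#' Computes, for every guide, the replicate medians of normalized counts in
#' the sorted and baseline conditions, the log2 fold enrichment
#' `log2((median_sorted + pc) / (median_baseline + pc))`, a one-sided Welch
#' two-sample t-test of sorted > baseline across replicates, and the
#' composite volcano score `-log10(p) * log2fc`. Hit calls and volcano
#' classes are then set by [call_hits()].
#'
#' @param norm Normalized count matrix from [normalize_cpm()] (guides x
#'   samples).
#' @param sheet The [sample_sheet()] describing the columns of `norm`.
#' @param lib Optional `guide_library`; carries `chrom`, `cut_site` and
#'   `exonic` into the result.
#' @param params [enrichment_params()].
#' @return Data frame of class `"enrichment_table"` with columns `guide_id,
#'   median_sorted, median_baseline, log2fc, p_value, p_adjust, score,
#'   volcano_class, is_hit, chrom, cut_site, exonic`.
#' @export
guide_statistics <- function(norm, sheet, lib = NULL,
                             params = enrichment_params()) {
  stopifnot(is.matrix(norm), inherits(sheet, "sample_sheet"),
            inherits(params, "enrichment_params"))
  if (!identical(colnames(norm), sheet$sample_id)) {
    norm <- norm[, sheet$sample_id, drop = FALSE]
  }
  s_cols <- sheet$condition == "sorted"
  b_cols <- sheet$condition == "baseline"
  if (sum(s_cols) < 2L || sum(b_cols) < 2L) {
    stop("need at least 2 replicates per condition for the t-test",
         call. = FALSE)
  }
  xs <- norm[, s_cols, drop = FALSE]
  xb <- norm[, b_cols, drop = FALSE]
  pc <- params$pseudocount
  med_s <- apply(xs, 1L, stats::median)
  med_b <- apply(xb, 1L, stats::median)
  log2fc <- switch(params$fc_method,
    "median-ratio" = log2((med_s + pc) / (med_b + pc)),
    "ratio-median" = {
      k <- min(ncol(xs), ncol(xb))
      ratios <- log2((xs[, seq_len(k), drop = FALSE] + pc) /
                     (xb[, seq_len(k), drop = FALSE] + pc))
      apply(ratios, 1L, stats::median)
    })
  p <- switch(params$test_scale,
    log2 = welch_one_sided(log2(xs + pc), log2(xb + pc)),
    cpm = welch_one_sided(xs, xb))
  tbl <- data.frame(
    guide_id = rownames(norm),
    median_sorted = med_s,
    median_baseline = med_b,
    log2fc = log2fc,
    p_value = p,
    p_adjust = stats::p.adjust(p, method = "BH"),
    score = -log10(p) * log2fc,
    volcano_class = NA_character_,
    is_hit = NA,
    chrom = NA_character_,
    cut_site = NA_integer_,
    exonic = FALSE,
    stringsAsFactors = FALSE)
  if (!is.null(lib)) {
    stopifnot(inherits(lib, "guide_library"))
    idx <- match(tbl$guide_id, lib$guides$guide_id)
    if (anyNA(idx)) {
      stop("guide(s) in the count matrix absent from the library: ",
           tbl$guide_id[is.na(idx)][1L], call. = FALSE)
    }
    tbl$chrom <- lib$guides$chrom[idx]
    tbl$cut_site <- lib$guides$cut_site[idx]
    tbl$exonic <- lib$guides$exonic[idx]
  }
  rownames(tbl) <- NULL
  tbl <- call_hits(tbl, params)
  structure(tbl, class = c("enrichment_table", "data.frame"),
            params = params)
}

#' Call hits and assign volcano classes
#'
#' A hit exceeds both cut-offs strictly: `log2fc > lfc_threshold` and
#' `p_value < p_threshold`. Volcano classes: `"exonic"` (knockout-like
#' positive controls), `"enriched-non-exonic"` (hits outside exons — the
#' regulatory-element candidates), `"non-exonic"` (everything else).
#'
#' @param tbl An `enrichment_table` (or data frame with the same columns).
#' @param params [enrichment_params()].
#' @return The table with `is_hit` and `volcano_class` set.
#' @export
call_hits <- function(tbl, params = enrichment_params()) {
  stopifnot(all(c("log2fc", "p_value", "exonic") %in% names(tbl)))
  tbl$is_hit <- tbl$log2fc > params$lfc_threshold &
    tbl$p_value < params$p_threshold
  tbl$volcano_class <- ifelse(tbl$exonic, "exonic",
                              ifelse(tbl$is_hit, "enriched-non-exonic",
                                     "non-exonic"))
  tbl
}

#' Write the per-guide score track
#'
#' Emits the volcano score of each guide at its 1-bp cut-site interval
#' `[cut_site, cut_site + 1)` as bedGraph, for genome-browser display of
#' enrichment peaks. Guides sharing a cut site (a plus/minus pair can cleave
#' the same bond) are shifted, in stable table order, to the next free 1-bp
#' slot; each shift is reported via `message()`.
#'
#' @param tbl An `enrichment_table` with `chrom` and `cut_site` set.
#' @param path Output bedGraph path.
#' @return Invisibly, `path`.
#' @export
score_track <- function(tbl, path) {
  stopifnot(all(c("chrom", "cut_site", "score") %in% names(tbl)))
  if (nrow(tbl) > 0L && anyNA(tbl$cut_site)) {
    stop("cut_site missing; run guide_statistics() with a library",
         call. = FALSE)
  }
  pos <- tbl$cut_site
  if (nrow(tbl) > 0L) {
    taken <- new.env(parent = emptyenv())
    for (i in seq_along(pos)) {
      key <- paste0(tbl$chrom[i], ":", pos[i])
      while (!is.null(taken[[key]])) {
        pos[i] <- pos[i] + 1L
        key <- paste0(tbl$chrom[i], ":", pos[i])
      }
      if (pos[i] != tbl$cut_site[i]) {
        message("score_track: guide ", tbl$guide_id[i],
                " shares cut site ", tbl$cut_site[i], "; shifted to ",
                pos[i])
      }
      taken[[key]] <- TRUE
    }
  }
  rec <- data.frame(chrom = tbl$chrom, start = pos, end = pos + 1L,
                    value = tbl$score, stringsAsFactors = FALSE)
  write_bedgraph(rec, path, track_name = "sgRNA_score")
}

#' Summarize volcano classes and hits
#'
#' @param tbl An `enrichment_table`.
#' @return List with `class_counts` (named integer vector over the three
#'   volcano classes, summing to the number of guides), `n_hits`, and `hits`
#'   (hit rows sorted by descending score, ties broken by guide_id).
#' @export
volcano_summary <- function(tbl) {
  stopifnot(all(c("volcano_class", "is_hit", "score") %in% names(tbl)))
  classes <- c("non-exonic", "exonic", "enriched-non-exonic")
  counts <- stats::setNames(
    vapply(classes, function(cl) sum(tbl$volcano_class == cl), integer(1)),
    classes)
  hits <- tbl[tbl$is_hit, , drop = FALSE]
  hits <- hits[order(-hits$score, hits$guide_id), , drop = FALSE]
  rownames(hits) <- NULL
  list(class_counts = counts, n_hits = nrow(hits), hits = hits)
}

#' Write / read an enrichment table CSV
#'
#' Column order is fixed: `guide_id, median_sorted, median_baseline, log2fc,
#' p_value, score, volcano_class, is_hit, chrom, cut_site, exonic`
#' (plus `p_adjust`).
#'
#' @param tbl An `enrichment_table`.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_enrichment <- function(tbl, path) {
  cols <- c("guide_id", "median_sorted", "median_baseline", "log2fc",
            "p_value", "score", "volcano_class", "is_hit", "chrom",
            "cut_site", "exonic", "p_adjust")
  cols <- intersect(cols, names(tbl))
  utils::write.csv(as.data.frame(tbl)[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
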