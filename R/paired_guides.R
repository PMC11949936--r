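#' Predict the excision produced by a guide pair
#'
#' With two guides on the same chromosome, simultaneous blunt Cas9 cuts
#' followed by religation of the outer ends delete the fragment between the
#' two cleaved bonds. The predicted size is the coordinate difference of the
#' cut bonds (cut-to-cut distance); the prediction is symmetric in the pair
#' and independent of either guide's strand.
#'
#' @param lib A `guide_library`.
#' @param id_a,id_b Guide ids present in the library.
#' @return List of class `"excision_prediction"` with `guide_a`, `guide_b`,
#'   `chrom`, `start`, `end` (the deleted span, 0-based half-open; empty when
#'   the cut sites coincide) and `size` (bp).
#' @examples
#' lib <- scan_protospacers(c(s = strrep("ACGTG", 40)),
#'                          genomic_interval("s", 0, 200))
#' ids <- guides(lib)$guide_id[1:2]
#' predict_excision(lib, ids[1], ids[2])
#' @export
predict_excision <- function(lib, id_a, id_b) {
  stopifnot(inherits(lib, "guide_library"))
  df <- lib$guides
  ia <- match(id_a, df$guide_id)
  ib <- match(id_b, df$guide_id)
  if (is.na(ia)) stop("unknown guide id: ", id_a, call. = FALSE)
  if (is.na(ib)) stop("unknown guide id: ", id_b, call. = FALSE)
  if (df$chrom[ia] != df$chrom[ib]) {
    stop("guides ", id_a, " and ", id_b, " lie on different chromosomes (",
         df$chrom[ia], " vs ", df$chrom[ib], ")", call. = FALSE)
  }
  cuts <- sort(c(df$cut_site[ia], df$cut_site[ib]))
  structure(list(guide_a = id_a, guide_b = id_b, chrom = df$chrom[ia],
                 start = cuts[1L], end = cuts[2L],
                 size = cuts[2L] - cuts[1L]),
            class = "excision_prediction")
}

#' @export
print.excision_prediction <- function(x, ...) {
  cat(sprintf("<excision_prediction> %s + %s: %d bp (%s:[%d,%d))\n",
              x$guide_a, x$guide_b, x$size, x$chrom, x$start, x$end))
  invisible(x)
}

#' Tabulate excision predictions for a list of guide pairs
#'
#' @param lib A `guide_library`.
#' @param pairs Data frame with columns `guide_a`, `guide_b` (one row per
#'   pair; duplicates are kept).
#' @param path Optional CSV output path.
#' @return Data frame with one row per pair: `guide_a, guide_b, chrom,
#'   start, end, size`.
#' @export
excision_report <- function(lib, pairs, path = NULL) {
  stopifnot(is.data.frame(pairs),
            all(c("guide_a", "guide_b") %in% names(pairs)))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- predict_excision(lib, pairs$guide_a[i], pairs$guide_b[i])
    data.frame(guide_a = p$guide_a, guide_b = p$guide_b, chrom = p$chrom,
               start = p$start, end = p$end, size = p$size,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else {
    data.frame(guide_a = character(), guide_b = character(),
               chrom = character(), start = integer(), end = integer(),
               size = integer(), stringsAsFactors = FALSE)
  }
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  out
}
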