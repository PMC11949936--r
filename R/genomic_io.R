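#' Genomic interval (0-based, half-open)
#'
#' All coordinates inside the package are 0-based half-open: `start` is the
#' 0-based position of the first base, `end` is one past the last base, so
#' `end - start` is the interval length in bp. Coordinates printed by genome
#' browsers are 1-based inclusive; convert those with
#' [interval_from_1based()] at the boundary, never mix conventions internally.
#'
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start (bp).
#' @param end 0-based exclusive end (bp); must satisfy `0 <= start < end`.
#' @return An object of class `"genomic_interval"`.
#' @examples
#' gi <- genomic_interval("chr14", 22541008, 22564966)
#' interval_length(gi)
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end) {
    stop("invalid genomic interval ", chrom, ":[", start, ",", end,
         "): need 0 <= start < end", call. = FALSE)
  }
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @rdname genomic_interval
#' @param x A `genomic_interval`.
#' @export
interval_length <- function(x) {
  stopifnot(inherits(x, "genomic_interval"))
  x$end - x$start
}

#' Convert 1-based inclusive coordinates to an internal interval
#'
#' Genome browsers print 1-based inclusive coordinates
#' (e.g. chr14:22,541,009-22,564,966). The conversion to the internal 0-based
#' half-open convention is `start - 1`, `end` unchanged.
#'
#' @param chrom Chromosome name.
#' @param start_1based,end_1based 1-based inclusive boundary coordinates.
#' @return A [genomic_interval()].
#' @export
interval_from_1based <- function(chrom, start_1based, end_1based) {
  genomic_interval(chrom, as.numeric(start_1based) - 1, end_1based)
}

#' Parse a region string like "chr14:22,541,009-22,564,966"
#'
#' Coordinates are taken as 1-based inclusive (browser convention) and
#' converted internally; thousands separators are stripped.
#'
#' @param region Region string `chrom:start-end`.
#' @return A [genomic_interval()].
#' @export
parse_region <- function(region) {
  stopifnot(is.character(region), length(region) == 1L)
  s <- gsub(",", "", region, fixed = TRUE)
  m <- regmatches(s, regexec("^([^:]+):([0-9]+)-([0-9]+)$", s))[[1]]
  if (length(m) != 4L) {
    stop("cannot parse region '", region, "'; expected chrom:start-end",
         call. = FALSE)
  }
  interval_from_1based(m[2], as.numeric(m[3]), as.numeric(m[4]))
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<genomic_interval> %s:[%d,%d) (%d bp)\n",
              x$chrom, x$start, x$end, interval_length(x)))
  invisible(x)
}

#' Do two intervals overlap?
#'
#' Half-open semantics: intervals sharing only a boundary do not overlap.
#'
#' @param a,b `genomic_interval` objects.
#' @return `TRUE` iff on the same chromosome and `a$start < b$end` and
#'   `b$start < a$end`.
#' @export
interval_overlaps <- function(a, b) {
  stopifnot(inherits(a, "genomic_interval"), inherits(b, "genomic_interval"))
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

#' Build a feature annotation table
#'
#' A feature annotation is a data frame of labelled intervals (columns
#' `chrom`, `start`, `end`, `label`; 0-based half-open), sorted by
#' `(chrom, start, end)`. Overlapping intervals are permitted.
#'
#' @param chrom,start,end Parallel vectors of interval coordinates.
#' @param label Feature labels (default `"exon"`), recycled.
#' @param source Provenance string stored as an attribute
#'   (a file path, or `"synthetic"`).
#' @return A data frame of class `"feature_annotation"`.
#' @export
feature_annotation <- function(chrom = character(), start = integer(),
                               end = integer(), label = "exon",
                               source = "synthetic") {
  n <- length(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  stopifnot(length(start) == n, length(end) == n)
  if (n > 0L && any(start < 0L | start >= end)) {
    bad <- which(start < 0L | start >= end)[1L]
    stop("invalid feature interval ", chrom[bad], ":[", start[bad], ",",
         end[bad], ")", call. = FALSE)
  }
  ann <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    label = rep_len(as.character(label), n),
                    stringsAsFactors = FALSE)
  ann <- ann[order(ann$chrom, ann$start, ann$end), , drop = FALSE]
  rownames(ann) <- NULL
  structure(ann, source = source,
            class = c("feature_annotation", "data.frame"))
}

#' Read a genome FASTA file
#'
#' Sequences are upper-cased; only the unambiguous DNA alphabet plus `N` is
#' accepted. N-containing stretches are tolerated here but no protospacer
#' containing an `N` is ever emitted by the library designer.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) {
      stop("FASTA format error in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  if (length(set) == 0L) {
    stop("FASTA format error in '", path, "': no sequence records",
         call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(names(seqs))) || anyDuplicated(names(seqs))) {
    stop("FASTA format error in '", path,
         "': empty or duplicated sequence names", call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("FASTA format error in '", path, "': sequence '",
         names(seqs)[bad][1L],
         "' contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a BED3/BED4 feature file
#'
#' BED is 0-based half-open; column 4, when present, is used as the feature
#' label (default `"exon"` otherwise). Rows are validated (`start < end`)
#' and sorted.
#'
#' @param path Path to a BED file.
#' @param default_label Label used when the file has no name column.
#' @return A [feature_annotation()].
#' @export
read_bed <- function(path, default_label = "exon") {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, comment.char = "#",
                      quote = ""),
    error = function(e) {
      stop("BED format error in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  if (ncol(tab) < 3L) {
    stop("BED format error in '", path, "': fewer than 3 columns",
         call. = FALSE)
  }
  start <- suppressWarnings(as.integer(tab[[2]]))
  end <- suppressWarnings(as.integer(tab[[3]]))
  if (anyNA(start) || anyNA(end)) {
    stop("BED format error in '", path, "': non-integer coordinates",
         call. = FALSE)
  }
  if (any(start >= end)) {
    bad <- which(start >= end)[1L]
    stop("BED format error in '", path, "', line ", bad, ": start (",
         start[bad], ") >= end (", end[bad], ")", call. = FALSE)
  }
  label <- if (ncol(tab) >= 4L) as.character(tab[[4]]) else default_label
  feature_annotation(tab[[1]], start, end, label, source = path)
}

#' Write a feature annotation as BED4
#'
#' @param ann A [feature_annotation()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(ann, path) {
  stopifnot(inherits(ann, "feature_annotation"))
  df <- as.data.frame(ann)[, c("chrom", "start", "end", "label")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# bedGraph values carry 6 significant digits so a write/read round trip is
# exact to that precision.
format_bedgraph_value <- function(x) {
  sprintf("%.6g", x)
}

#' Write a bedGraph score track
#'
#' Records are sorted by `(chrom, start, end)`; overlapping intervals are an
#' error (a bedGraph track assigns one value per position). Values are
#' written with 6 significant digits.
#'
#' @param records Data frame with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open intervals).
#' @param path Output path.
#' @param track_name Name written in the track header line.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(records, path, track_name = "tilescreen") {
  stopifnot(is.data.frame(records),
            all(c("chrom", "start", "end", "value") %in% names(records)))
  rec <- records[order(records$chrom, records$start, records$end), ,
                 drop = FALSE]
  if (nrow(rec) > 1L) {
    same <- rec$chrom[-1L] == rec$chrom[-nrow(rec)]
    clash <- same & (rec$start[-1L] < rec$end[-nrow(rec)])
    if (any(clash)) {
      i <- which(clash)[1L]
      stop("overlapping bedGraph intervals: ", rec$chrom[i], ":[",
           rec$start[i], ",", rec$end[i], ") and ", rec$chrom[i + 1L], ":[",
           rec$start[i + 1L], ",", rec$end[i + 1L], ")", call. = FALSE)
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s"', track_name), con)
  if (nrow(rec) > 0L) {
    writeLines(paste(rec$chrom, rec$start, rec$end,
                     format_bedgraph_value(rec$value), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a bedGraph track written by [write_bedgraph()]
#'
#' @param path Path to a bedGraph file.
#' @return Data frame with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 4L)) {
    stop("bedGraph format error in '", path, "': expected 4 columns",
         call. = FALSE)
  }
  m <- do.call(rbind, parts)
  data.frame(chrom = m[, 1], start = as.integer(m[, 2]),
             end = as.integer(m[, 3]), value = as.numeric(m[, 4]),
             stringsAsFactors = FALSE)
}
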