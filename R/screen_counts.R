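#' Build or read a screen sample sheet
#'
#' A sample sheet maps sequencing files to screen conditions. Required
#' columns: `sample_id` (unique), `condition` (`"sorted"` for the selected
#' expression-negative population, `"baseline"` for the untreated library
#' control), `replicate` (integer). Optional: `fastq_r1`, `fastq_r2`.
#'
#' @param df Data frame with the columns above.
#' @return Validated data frame of class `"sample_sheet"`.
#' @export
sample_sheet <- function(df) {
  required <- c("sample_id", "condition", "replicate")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("sample sheet: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  df$condition <- as.character(df$condition)
  df$replicate <- as.integer(df$replicate)
  if (anyDuplicated(df$sample_id)) {
    stop("sample sheet: duplicated sample_id", call. = FALSE)
  }
  if (any(!df$condition %in% c("sorted", "baseline"))) {
    stop("sample sheet: condition must be 'sorted' or 'baseline'",
         call. = FALSE)
  }
  if (!all(c("sorted", "baseline") %in% df$condition)) {
    stop("sample sheet: need at least one replicate per condition",
         call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, class = c("sample_sheet", "data.frame"))
}

#' @rdname sample_sheet
#' @param path CSV path with header
#'   `sample_id,condition,replicate,fastq_r1[,fastq_r2]`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path,
                               call. = FALSE)
  sample_sheet(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Extract guide spacers from reads by anchor matching
#'
#' Returns the `spacer_len` bases immediately following the first occurrence
#' of `anchor5`, provided `anchor3` (when non-empty) follows immediately
#' after them; `NA` otherwise. This reimplements, for a fixed amplicon
#' layout, the role of an adapter trimmer: the anchors are the constant
#' vector context flanking the variable spacer.
#'
#' @param reads Character vector of read sequences.
#' @param anchor5 Constant sequence 5' of the spacer (non-empty).
#' @param anchor3 Constant sequence 3' of the spacer; `""` disables the
#'   3' check.
#' @param spacer_len Spacer length (default 20).
#' @return Character vector: extracted spacer or `NA` per read.
#' @export
extract_spacer <- function(reads, anchor5, anchor3 = "", spacer_len = 20L) {
  stopifnot(is.character(anchor5), nzchar(anchor5))
  if (length(reads) == 0L) return(character())
  pos <- regexpr(anchor5, reads, fixed = TRUE)
  sp_start <- pos + nchar(anchor5)
  sp_end <- sp_start + spacer_len - 1L
  out <- substr(reads, sp_start, sp_end)
  ok <- pos > 0L & nchar(out) == spacer_len
  if (nzchar(anchor3)) {
    a3 <- substr(reads, sp_end + 1L, sp_end + nchar(anchor3))
    ok <- ok & a3 == anchor3
  }
  out[!ok] <- NA_character_
  out
}

# Minimal 4-line FASTQ reader returning the sequence lines; errors carry the
# file and the index of the offending record.
read_fastq_sequences <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0L) return(character())
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ format error in '", path, "': truncated record ",
         length(lines) %/% 4L + 1L, call. = FALSE)
  }
  heads <- lines[seq(1L, length(lines), by = 4L)]
  seps <- lines[seq(3L, length(lines), by = 4L)]
  bad <- !startsWith(heads, "@")
  if (any(bad)) {
    stop("FASTQ format error in '", path, "', record ", which(bad)[1L],
         ": header does not start with '@'", call. = FALSE)
  }
  bad <- !startsWith(seps, "+")
  if (any(bad)) {
    stop("FASTQ format error in '", path, "', record ", which(bad)[1L],
         ": separator line does not start with '+'", call. = FALSE)
  }
  toupper(lines[seq(2L, length(lines), by = 4L)])
}

# Map spacers to guide indices. Exact dictionary matches always win; with
# max_mismatches = 1 a non-exact spacer is rescued when it lies within
# Hamming distance 1 of exactly one guide, and stays unassigned when that
# neighbour is ambiguous.
spacer_matcher <- function(spacers, max_mismatches = 0L) {
  exact <- seq_along(spacers)
  names(exact) <- spacers
  if (max_mismatches == 0L) {
    return(function(x) unname(exact[x]))
  }
  if (max_mismatches != 1L) {
    stop("max_mismatches must be 0 or 1", call. = FALSE)
  }
  len <- nchar(spacers[1L])
  variants <- character(0)
  origin <- integer(0)
  for (pos in seq_len(len)) {
    for (base in c("A", "C", "G", "T")) {
      v <- spacers
      substr(v, pos, pos) <- base
      variants <- c(variants, v)
      origin <- c(origin, seq_along(spacers))
    }
  }
  keep <- !duplicated(paste0(variants, "#", origin))
  variants <- variants[keep]
  origin <- origin[keep]
  dup <- variants %in% variants[duplicated(variants)]
  amb <- unique(variants[dup])
  map <- origin[!dup]
  names(map) <- variants[!dup]
  function(x) {
    hit <- unname(exact[x])
    miss <- which(is.na(hit) & !is.na(x))
    if (length(miss) > 0L) {
      rescue <- unname(map[x[miss]])
      rescue[x[miss] %in% amb] <- NA_integer_
      hit[miss] <- rescue
    }
    hit
  }
}

#' Count guide spacers per sample
#'
#' Reads each sample's FASTQ, extracts spacers between the anchors with
#' [extract_spacer()], and tallies them against the library. Each read is
#' assigned to at most one guide; reads matching no guide are tallied as
#' unassigned. In paired-end mode the spacer is taken from R1; when R1 yields
#' none, the reverse-complemented R2 is tried. Counting is independent of
#' read order.
#'
#' @param sheet A [sample_sheet()] with `fastq_r1` (and optionally
#'   `fastq_r2`) paths.
#' @param lib A `guide_library` with unique spacers.
#' @param anchor5,anchor3 Constant anchor sequences flanking the spacer.
#' @param max_mismatches 0 (exact spacer match, default) or 1 (rescue reads
#'   whose spacer is within Hamming distance 1 of a unique library entry).
#' @return A `count_matrix`: integer matrix guides x samples plus per-sample
#'   unassigned and total read tallies.
#' @export
count_guides <- function(sheet, lib, anchor5, anchor3 = "",
                         max_mismatches = 0L) {
  stopifnot(inherits(sheet, "sample_sheet"), inherits(lib, "guide_library"))
  if (!"fastq_r1" %in% names(sheet)) {
    stop("sample sheet has no fastq_r1 column", call. = FALSE)
  }
  gdf <- lib$guides
  if (anyDuplicated(gdf$spacer)) {
    stop("library spacers must be unique for counting; run ",
         "apply_design_filters() with dedupe on", call. = FALSE)
  }
  match_fun <- spacer_matcher(gdf$spacer, max_mismatches)
  n_guides <- nrow(gdf)
  counts <- matrix(0L, nrow = n_guides, ncol = nrow(sheet),
                   dimnames = list(gdf$guide_id, sheet$sample_id))
  unassigned <- stats::setNames(integer(nrow(sheet)), sheet$sample_id)
  total <- unassigned
  has_r2 <- "fastq_r2" %in% names(sheet)
  for (j in seq_len(nrow(sheet))) {
    r1 <- read_fastq_sequences(sheet$fastq_r1[j])
    spac <- extract_spacer(r1, anchor5, anchor3)
    if (has_r2 && !is.na(sheet$fastq_r2[j]) && nzchar(sheet$fastq_r2[j])) {
      r2 <- read_fastq_sequences(sheet$fastq_r2[j])
      if (length(r2) != length(r1)) {
        stop("FASTQ pairing error for sample '", sheet$sample_id[j],
             "': R1 has ", length(r1), " reads, R2 has ", length(r2),
             call. = FALSE)
      }
      retry <- which(is.na(spac))
      if (length(retry) > 0L) {
        spac[retry] <- extract_spacer(reverse_complement(r2[retry]),
                                      anchor5, anchor3)
      }
    }
    idx <- match_fun(spac)
    idx <- idx[!is.na(idx)]
    tab <- tabulate(idx, nbins = n_guides)
    counts[, j] <- tab
    total[j] <- length(r1)
    unassigned[j] <- length(r1) - sum(tab)
  }
  new_count_matrix(counts, sheet, unassigned, total)
}

new_count_matrix <- function(counts, sheet, unassigned, total) {
  stopifnot(is.matrix(counts), nrow(sheet) == ncol(counts))
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, samples = sheet,
                 unassigned = unassigned, total = total),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d guides x %d samples; %s assigned reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Write / read a guide count matrix CSV
#'
#' Guides are rows, samples columns; per-sample unassigned-read tallies are
#' stored in a final `__unassigned__` row so a write/read round trip is the
#' identity.
#'
#' @param cm A `count_matrix`.
#' @param path CSV path.
#' @param sheet Optional [sample_sheet()]; when given, `read_counts()`
#'   requires the CSV's sample columns to match it exactly.
#' @return `write_counts()`: invisibly, `path`; `read_counts()`: a
#'   `count_matrix`.
#' @export
write_counts <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(guide_id = c(rownames(cm$counts), "__unassigned__"),
                   rbind(cm$counts, cm$unassigned),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path, sheet = NULL) {
  if (!file.exists(path)) stop("counts file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "guide_id" || ncol(df) < 2L) {
    stop("counts format error in '", path,
         "': first column must be guide_id", call. = FALSE)
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals) || any(vals != round(vals))) {
    stop("counts format error in '", path, "': non-integer cell",
         call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("counts format error in '", path, "': negative count", call. = FALSE)
  }
  storage.mode(vals) <- "integer"
  rownames(vals) <- df$guide_id
  un_row <- which(df$guide_id == "__unassigned__")
  if (length(un_row) == 1L) {
    unassigned <- vals[un_row, ]
    vals <- vals[-un_row, , drop = FALSE]
  } else {
    unassigned <- stats::setNames(integer(ncol(vals)), colnames(vals))
  }
  if (is.null(sheet)) {
    # placeholder sheet (conditions guessed from column names, unvalidated);
    # pass a real sample sheet for downstream statistics
    sheet <- structure(data.frame(
      sample_id = colnames(vals),
      condition = ifelse(grepl("sorted", colnames(vals)), "sorted",
                         "baseline"),
      replicate = seq_len(ncol(vals)), stringsAsFactors = FALSE),
      class = c("sample_sheet", "data.frame"))
  } else {
    if (!identical(sort(colnames(vals)), sort(sheet$sample_id))) {
      stop("counts format error in '", path,
           "': sample columns do not match the sample sheet", call. = FALSE)
    }
    vals <- vals[, sheet$sample_id, drop = FALSE]
    unassigned <- unassigned[sheet$sample_id]
  }
  new_count_matrix(vals, sheet, unassigned,
                   colSums(vals) + unassigned)
}
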