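#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

new_guide_library <- function(guides, target_interval, design_params,
                              filter_report = NULL) {
  structure(list(guides = guides, target_interval = target_interval,
                 design_params = design_params,
                 filter_report = filter_report),
            class = "guide_library")
}

#' @export
print.guide_library <- function(x, ...) {
  ti <- x$target_interval
  cat(sprintf("<guide_library> %d sgRNAs over %s:[%d,%d)\n",
              nrow(x$guides), ti$chrom, ti$start, ti$end))
  if (!is.null(x$filter_report)) {
    for (i in seq_len(nrow(x$filter_report))) {
      cat(sprintf("  filter %-12s removed %d\n", x$filter_report$rule[i],
                  x$filter_report$removed[i]))
    }
  }
  invisible(x)
}

#' Guide table of a library
#'
#' @param lib A `guide_library`.
#' @return The per-guide data frame (one row per sgRNA).
#' @export
guides <- function(lib) {
  stopifnot(inherits(lib, "guide_library"))
  lib$guides
}

guide_columns <- c("guide_id", "spacer", "pam", "chrom", "spacer_start",
                   "spacer_end", "strand", "cut_site", "exonic")

validate_guide_table <- function(df, where = "guide table") {
  missing <- setdiff(guide_columns, names(df))
  if (length(missing) > 0L) {
    stop(where, ": missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$guide_id)) {
    stop(where, ": duplicated guide_id", call. = FALSE)
  }
  if (nrow(df) == 0L) return(invisible(df))
  if (any(nchar(df$spacer) != 20L)) {
    stop(where, ": spacer length != 20 for guide ",
         df$guide_id[nchar(df$spacer) != 20L][1L], call. = FALSE)
  }
  if (any(!grepl("^[ACGTN]GG$", df$pam))) {
    stop(where, ": PAM not matching NGG for guide ",
         df$guide_id[!grepl("^[ACGTN]GG$", df$pam)][1L], call. = FALSE)
  }
  if (any(!df$strand %in% c("+", "-"))) {
    stop(where, ": strand must be '+' or '-'", call. = FALSE)
  }
  if (any(df$spacer_end - df$spacer_start != 20L)) {
    stop(where, ": protospacer span must be 20 bp", call. = FALSE)
  }
  expected_cut <- ifelse(df$strand == "+", df$spacer_start + 17L,
                         df$spacer_start + 3L)
  if (any(df$cut_site != expected_cut)) {
    stop(where, ": cut_site inconsistent with strand convention for guide ",
         df$guide_id[df$cut_site != expected_cut][1L], call. = FALSE)
  }
  invisible(df)
}

#' Enumerate every SpCas9 protospacer in a target interval
#'
#' Scans both strands of the target interval for 20-nt spacers followed by an
#' NGG PAM (SpCas9). A protospacer is reported only if the full 23 bp
#' (spacer + PAM) fits inside the interval; spacers containing `N` are
#' dropped. The predicted cut site is the 0-based coordinate of the bond
#' cleaved by the blunt SpCas9 cut, 3 bp 5' of the PAM: `spacer_start + 17`
#' on the plus strand, `spacer_start + 3` on the minus strand. Guides are
#' sorted by cut site (ties: plus strand first) and assigned zero-padded ids.
#'
#' @param sequence Named character vector of chromosome sequences (as from
#'   [read_fasta()]), or a single unnamed sequence taken to be the interval's
#'   chromosome starting at coordinate 0.
#' @param interval [genomic_interval()] to scan; coordinates are relative to
#'   the start of the chromosome sequence.
#' @param id_prefix Prefix for guide ids (default `"sg"` gives `sg-0001`...).
#' @return A `guide_library`.
#' @examples
#' lib <- scan_protospacers(
#'   c(chrA = "AAAAAAAAAAAAAAAAAAAAAGGA"),
#'   genomic_interval("chrA", 0, 24))
#' guides(lib)
#' @export
scan_protospacers <- function(sequence, interval, id_prefix = "sg") {
  stopifnot(inherits(interval, "genomic_interval"))
  if (is.null(names(sequence))) {
    if (length(sequence) != 1L) {
      stop("unnamed 'sequence' must be a single string", call. = FALSE)
    }
    chrom_seq <- sequence[[1L]]
  } else {
    if (!interval$chrom %in% names(sequence)) {
      stop("chromosome '", interval$chrom, "' not present in sequence set",
           call. = FALSE)
    }
    chrom_seq <- sequence[[interval$chrom]]
  }
  if (interval$end > nchar(chrom_seq)) {
    stop("interval ", interval$chrom, ":[", interval$start, ",",
         interval$end, ") extends past sequence end (",
         nchar(chrom_seq), " bp)", call. = FALSE)
  }
  if (interval_length(interval) < 23L) {
    stop("interval too short to hold a 23-bp protospacer+PAM", call. = FALSE)
  }
  local <- toupper(substr(chrom_seq, interval$start + 1L, interval$end))
  L <- nchar(local)
  ch <- strsplit(local, "", fixed = TRUE)[[1L]]
  gg <- which(ch[-L] == "G" & ch[-1L] == "G")      # 'GG' starting here
  cc <- which(ch[-L] == "C" & ch[-1L] == "C")      # 'CC' starting here

  # plus strand: spacer [i, i+19], PAM [i+20, i+22] with GG at i+21
  i_plus <- gg - 21L
  i_plus <- i_plus[i_plus >= 1L & i_plus + 22L <= L]
  # minus strand: plus-strand layout CCN + 20 nt; CC at q, spacer [q+3, q+22]
  q_minus <- cc
  q_minus <- q_minus[q_minus + 22L <= L]

  sub <- function(first, last) {
    if (length(first) == 0L) character() else substring(local, first, last)
  }
  plus <- data.frame(
    spacer = sub(i_plus, i_plus + 19L),
    pam = sub(i_plus + 20L, i_plus + 22L),
    spacer_start = interval$start + i_plus - 1L,
    strand = rep("+", length(i_plus)),
    stringsAsFactors = FALSE)
  minus <- data.frame(
    spacer = reverse_complement(sub(q_minus + 3L, q_minus + 22L)),
    pam = reverse_complement(sub(q_minus, q_minus + 2L)),
    spacer_start = interval$start + q_minus + 2L,
    strand = rep("-", length(q_minus)),
    stringsAsFactors = FALSE)
  df <- rbind(plus, minus)
  keep <- !grepl("N", df$spacer, fixed = TRUE)
  df <- df[keep, , drop = FALSE]
  df$chrom <- rep_len(interval$chrom, nrow(df))
  df$spacer_end <- df$spacer_start + 20L
  df$cut_site <- ifelse(df$strand == "+", df$spacer_start + 17L,
                        df$spacer_start + 3L)
  df$exonic <- rep_len(FALSE, nrow(df))
  ord <- order(df$cut_site, df$strand, df$spacer_start)
  df <- df[ord, , drop = FALSE]
  width <- max(4L, nchar(nrow(df)))
  df$guide_id <- if (nrow(df) > 0L) {
    sprintf("%s-%0*d", id_prefix, width, seq_len(nrow(df)))
  } else character()
  df <- df[, guide_columns]
  rownames(df) <- NULL
  validate_guide_table(df, "scan_protospacers")
  new_guide_library(df, interval,
                    list(spacer_length = 20L, pam = "NGG",
                         id_prefix = id_prefix, filters = "none"))
}

#' Design-filter rule set
#'
#' @param dedupe Drop guides whose spacer occurs more than once, keeping the
#'   first by coordinate order (duplicated spacers cannot be counted
#'   separately). Default on.
#' @param polyt Drop spacers containing `TTTT`, a U6 Pol III terminator that
#'   truncates the transcribed guide. Default on.
#' @param gc_min,gc_max Optional GC-content bounds (fractions in \[0,1\]);
#'   `NULL` disables the bound.
#' @return A named list of rules for [apply_design_filters()].
#' @export
design_rules <- function(dedupe = TRUE, polyt = TRUE, gc_min = NULL,
                         gc_max = NULL) {
  list(dedupe = dedupe, polyt = polyt, gc_min = gc_min, gc_max = gc_max)
}

gc_fraction <- function(spacer) {
  (nchar(spacer) - nchar(gsub("[GC]", "", spacer))) / nchar(spacer)
}

#' Apply design filters to a guide library
#'
#' Surviving guides keep their original ids; a per-rule removal report is
#' attached to the returned library (`$filter_report`).
#'
#' @param lib A `guide_library`.
#' @param rules A rule set from [design_rules()] (or a named list with a
#'   subset of its names). Unknown rule names are an error.
#' @return Filtered `guide_library`.
#' @export
apply_design_filters <- function(lib, rules = design_rules()) {
  stopifnot(inherits(lib, "guide_library"))
  known <- names(design_rules())
  unknown <- setdiff(names(rules), known)
  if (length(unknown) > 0L) {
    stop("unknown design filter rule(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  full <- design_rules(dedupe = FALSE, polyt = FALSE)
  full[names(rules)] <- rules
  df <- lib$guides
  report <- data.frame(rule = character(), removed = integer(),
                       stringsAsFactors = FALSE)
  note <- function(rule, n) rbind(report, data.frame(rule = rule, removed = n))
  if (isTRUE(full$dedupe)) {
    drop <- duplicated(df$spacer)
    report <- note("dedupe", sum(drop))
    df <- df[!drop, , drop = FALSE]
  }
  if (isTRUE(full$polyt)) {
    drop <- grepl("TTTT", df$spacer, fixed = TRUE)
    report <- note("polyt", sum(drop))
    df <- df[!drop, , drop = FALSE]
  }
  if (!is.null(full$gc_min) || !is.null(full$gc_max)) {
    gc <- gc_fraction(df$spacer)
    lo <- if (is.null(full$gc_min)) 0 else full$gc_min
    hi <- if (is.null(full$gc_max)) 1 else full$gc_max
    drop <- gc < lo | gc > hi
    report <- note("gc_bounds", sum(drop))
    df <- df[!drop, , drop = FALSE]
  }
  rownames(df) <- NULL
  params <- lib$design_params
  params$filters <- report
  new_guide_library(df, lib$target_interval, params, filter_report = report)
}

#' Label guides as exonic
#'
#' A guide is exonic iff its cut window `[cut_site - 3, cut_site + 3)`
#' overlaps any annotated feature interval on the same chromosome. Exonic
#' guides act as knockout positive controls in an expression screen; enriched
#' non-exonic guides are the regulatory-element candidates.
#'
#' @param lib A `guide_library`.
#' @param ann A [feature_annotation()] (typically exons). An empty annotation
#'   labels every guide non-exonic.
#' @return The library with the `exonic` column set.
#' @export
annotate_exonic <- function(lib, ann) {
  stopifnot(inherits(lib, "guide_library"),
            inherits(ann, "feature_annotation"))
  df <- lib$guides
  df$exonic <- FALSE
  if (nrow(df) > 0L && nrow(ann) > 0L) {
    for (chr in unique(df$chrom)) {
      sel_g <- df$chrom == chr
      sel_a <- ann$chrom == chr
      if (!any(sel_a)) next
      # IRanges is 1-based closed: [start+1, end]
      q <- IRanges::IRanges(start = df$cut_site[sel_g] - 3L + 1L,
                            end = df$cut_site[sel_g] + 3L)
      s <- IRanges::IRanges(start = ann$start[sel_a] + 1L,
                            end = ann$end[sel_a])
      df$exonic[sel_g] <- IRanges::overlapsAny(q, s)
    }
  }
  lib$guides <- df
  lib
}

#' Write / read a guide library CSV
#'
#' The CSV carries the columns `guide_id, spacer, pam, chrom, spacer_start,
#' spacer_end, strand, cut_site, exonic` plus a `#target_interval=` comment
#' line, so that a write/read round trip is the identity.
#'
#' @param lib A `guide_library`.
#' @param path CSV path.
#' @return `write_library()`: invisibly, `path`. `read_library()`: a
#'   validated `guide_library`.
#' @export
write_library <- function(lib, path) {
  stopifnot(inherits(lib, "guide_library"))
  ti <- lib$target_interval
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#target_interval=%s:%d:%d", ti$chrom, ti$start, ti$end),
             con)
  utils::write.csv(lib$guides, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  if (!file.exists(path)) stop("library file not found: ", path,
                               call. = FALSE)
  first <- readLines(path, n = 1L)
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) {
      stop("library format error in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  df$exonic <- as.logical(df$exonic)
  validate_guide_table(df, paste0("library file '", path, "'"))
  df <- df[, guide_columns]
  m <- regmatches(first,
                  regexec("^#target_interval=([^:]+):([0-9]+):([0-9]+)$",
                          first))[[1L]]
  ti <- if (length(m) == 4L) {
    genomic_interval(m[2], as.integer(m[3]), as.integer(m[4]))
  } else {
    genomic_interval(df$chrom[1L], min(df$spacer_start), max(df$spacer_end))
  }
  new_guide_library(df, ti, list(spacer_length = 20L, pam = "NGG",
                                 source = path))
}
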