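# Shared fixtures and independent oracles. The oracles deliberately avoid
# every package code path they are used to check.

# Independent reverse complement (character-by-character).
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Brute-force protospacer scan: test every 23-bp window offset on each
# strand directly (window extraction + PAM check per offset, own reverse
# complement; shares no code with the scanner it checks).
oracle_scan <- function(seq, start0, end0) {
  local <- substr(seq, start0 + 1L, end0)
  L <- nchar(local)
  empty <- data.frame(spacer = character(), strand = character(),
                      spacer_start = integer(), cut_site = integer(),
                      stringsAsFactors = FALSE)
  if (L < 23L) return(empty)
  i <- seq_len(L - 22L)
  win <- substring(local, i, i + 22L)
  plus_ok <- substring(win, 22L, 23L) == "GG" &
    !grepl("N", substring(win, 1L, 20L))
  rwin <- oracle_revcomp(win)
  minus_ok <- substring(rwin, 22L, 23L) == "GG" &
    !grepl("N", substring(rwin, 1L, 20L))
  out <- rbind(
    data.frame(spacer = substring(win[plus_ok], 1L, 20L), strand = "+",
               spacer_start = start0 + i[plus_ok] - 1L,
               cut_site = start0 + i[plus_ok] - 1L + 17L,
               stringsAsFactors = FALSE),
    data.frame(spacer = substring(rwin[minus_ok], 1L, 20L), strand = "-",
               spacer_start = start0 + i[minus_ok] + 2L,
               cut_site = start0 + i[minus_ok] + 2L + 3L,
               stringsAsFactors = FALSE))
  if (nrow(out) == 0L) return(empty)
  out[order(out$cut_site, out$strand, out$spacer_start), , drop = FALSE]
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A hand-built 4-guide library on one chromosome, via the public CSV reader
# so it passes the same validation as user input.
toy_library <- function() {
  spacers <- c("ACGTACGTACGTACGTACGT", "TGCATGCATGCATGCATGCA",
               "AAAACCCCGGGGTTTACGTA", "GATTACAGATTACAGATTAC")
  df <- data.frame(
    guide_id = paste0("sg-", 1:4),
    spacer = spacers,
    pam = c("AGG", "TGG", "CGG", "GGG"),
    chrom = "chrT",
    spacer_start = c(100L, 200L, 350L, 1000L),
    spacer_end = c(120L, 220L, 370L, 1020L),
    strand = c("+", "-", "+", "-"),
    cut_site = c(117L, 203L, 367L, 1003L),
    exonic = c(FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  writeLines(c("#target_interval=chrT:0:2000",
               paste(colnames(df), collapse = ",")), path)
  write.table(df, path, sep = ",", append = TRUE, col.names = FALSE,
              row.names = FALSE, quote = FALSE)
  read_library(path)
}

# Write a FASTQ file from read sequences (constant quality).
write_fastq_fixture <- function(reads, path, ids = NULL) {
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  if (length(reads) == 0L) {
    writeLines(character(), path)
  } else {
    writeLines(c(rbind(paste0("@", ids), reads, "+",
                       strrep("I", nchar(reads)))), path)
  }
  path
}

toy_sheet <- function(r1, r2 = NULL,
                      condition = rep(c("sorted", "baseline"),
                                      length.out = length(r1))) {
  df <- data.frame(sample_id = paste0("s", seq_along(r1)),
                   condition = condition,
                   replicate = seq_along(r1),
                   fastq_r1 = r1, stringsAsFactors = FALSE)
  if (!is.null(r2)) df$fastq_r2 <- r2
  sample_sheet(df)
}

# Small normalized matrix with explicit sorted/baseline columns.
toy_norm <- function(sorted, baseline, ids = NULL) {
  stopifnot(is.matrix(sorted), is.matrix(baseline))
  m <- cbind(sorted, baseline)
  colnames(m) <- c(paste0("sorted_", seq_len(ncol(sorted))),
                   paste0("baseline_", seq_len(ncol(baseline))))
  rownames(m) <- if (is.null(ids)) paste0("g", seq_len(nrow(m))) else ids
  m
}

toy_norm_sheet <- function(n_sorted = 3L, n_baseline = 3L) {
  sample_sheet(data.frame(
    sample_id = c(paste0("sorted_", seq_len(n_sorted)),
                  paste0("baseline_", seq_len(n_baseline))),
    condition = rep(c("sorted", "baseline"), c(n_sorted, n_baseline)),
    replicate = c(seq_len(n_sorted), seq_len(n_baseline)),
    stringsAsFactors = FALSE))
}
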