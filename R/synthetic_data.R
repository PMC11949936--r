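# Run code under a temporary RNG state so simulators are deterministic per
# seed without clobbering the caller's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Default sequencing-anchor context for simulated reads
#'
#' Constant vector sequences flanking the variable spacer in the sgRNA
#' expression cassette, used as synthetic-fixture defaults: the 3' end of a
#' U6 promoter ending in the `G` most spacers start from, and the first bases
#' of the guide scaffold. Real amplicons should override these with the
#' vector's actual context.
#'
#' @return List with `anchor5` and `anchor3`.
#' @export
default_anchors <- function() {
  list(anchor5 = "GGAAAGGACGAAACACCG", anchor3 = "GTTTTAGAGCTAGAAATAGC")
}

#' Simulation parameters for a synthetic tiling screen
#'
#' Defaults mirror the screened study design: a ~24-kb window, triplicate
#' sorted vs. triplicate baseline samples at 200-fold library coverage, six
#' truly enriched non-exonic guides, and exon blocks whose guides enrich like
#' knockouts (positive controls).
#'
#' @param seed Integer seed; every draw in every simulator derives from it.
#' @param region_length Length of the simulated window (bp).
#' @param gc_content GC fraction of the simulated DNA (human-like 0.41).
#' @param n_true_hits Number of truly enriched non-exonic guides.
#' @param hit_fold_enrichment Mean fold enrichment of true hits (and of
#'   exon-window guides) in the sorted condition.
#' @param exon_intervals Data frame `start,end` (0-based half-open, relative
#'   to the region) of synthetic exon blocks, or `NULL` for the default four
#'   blocks sized like the constant-region exons of a TCR locus.
#' @param replicates Replicates per condition.
#' @param mean_coverage Mean reads per guide per sample.
#' @param dispersion Negative-binomial size parameter of count noise
#'   (larger = closer to Poisson).
#' @param read_error_rate Per-base substitution rate in simulated reads.
#' @return List of class `"screen_sim_params"`.
#' @export
screen_sim_params <- function(seed = 1L, region_length = 24000L,
                              gc_content = 0.41, n_true_hits = 6L,
                              hit_fold_enrichment = 8,
                              exon_intervals = NULL, replicates = 3L,
                              mean_coverage = 200, dispersion = 10,
                              read_error_rate = 0) {
  stopifnot(region_length >= 1000L, gc_content >= 0, gc_content <= 1,
            n_true_hits >= 0L, hit_fold_enrichment > 0, replicates >= 1L,
            mean_coverage > 0, dispersion > 0, read_error_rate >= 0,
            read_error_rate < 1)
  if (is.null(exon_intervals)) {
    starts <- floor(region_length * c(0.27, 0.30, 0.33, 0.36))
    widths <- c(274L, 108L, 144L, 30L)
    exon_intervals <- data.frame(start = starts,
                                 end = pmin(starts + widths, region_length))
  }
  structure(list(seed = as.integer(seed), region_length = region_length,
                 gc_content = gc_content, n_true_hits = n_true_hits,
                 hit_fold_enrichment = hit_fold_enrichment,
                 exon_intervals = exon_intervals, replicates = replicates,
                 mean_coverage = mean_coverage, dispersion = dispersion,
                 read_error_rate = read_error_rate),
            class = "screen_sim_params")
}

random_dna <- function(n, gc = 0.41) {
  if (n == 0L) return("")
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE,
                                             prob = probs)])
}

#' Simulate a target region and its exon annotation
#'
#' Generates i.i.d. DNA at the requested GC content over a single synthetic
#' chromosome `"chrSim"`, with the parameterized exon blocks recorded as a
#' feature annotation. Deterministic per seed.
#'
#' @param params [screen_sim_params()].
#' @return List with `sequence` (named character vector), `interval`
#'   (the full region as a [genomic_interval()]) and `annotation`
#'   (a [feature_annotation()]).
#' @export
simulate_region <- function(params = screen_sim_params()) {
  stopifnot(inherits(params, "screen_sim_params"))
  seq <- with_seed(params$seed + 1L,
                   random_dna(params$region_length, params$gc_content))
  ann <- feature_annotation(rep("chrSim", nrow(params$exon_intervals)),
                            params$exon_intervals$start,
                            params$exon_intervals$end,
                            label = "exon", source = "synthetic")
  list(sequence = c(chrSim = seq),
       interval = genomic_interval("chrSim", 0L, params$region_length),
       annotation = ann)
}

#' Simulate a screen count matrix with known ground truth
#'
#' Baseline abundances are drawn log-normal (sdlog 0.5) and scaled to the
#' mean coverage; replicate counts are negative binomial around them.
#' Sorted-condition means are multiplied by `hit_fold_enrichment` for
#' `n_true_hits` randomly chosen non-exonic guides (the planted regulatory
#' hits) and for every exonic guide (knockout mimics — the screen cannot
#' distinguish mechanism, only enrichment); each sorted column is then
#' rescaled to the column target depth, as sorting and resequencing fix the
#' depth, not the composition.
#'
#' @param lib A `guide_library` (run [annotate_exonic()] first if exonic
#'   guides should behave as positive controls).
#' @param params [screen_sim_params()].
#' @return List with `counts` (a `count_matrix`) and `truth` (a
#'   `screen_sim_truth`: per-guide baseline abundance, fold enrichment,
#'   `is_true_hit`, plus the vector of planted hit ids).
#' @export
simulate_counts <- function(lib, params = screen_sim_params()) {
  stopifnot(inherits(lib, "guide_library"),
            inherits(params, "screen_sim_params"))
  gdf <- lib$guides
  n <- nrow(gdf)
  if (n == 0L) stop("library is empty", call. = FALSE)
  non_exonic <- which(!gdf$exonic)
  if (params$n_true_hits > length(non_exonic)) {
    stop("n_true_hits (", params$n_true_hits,
         ") exceeds the number of non-exonic guides (", length(non_exonic),
         ")", call. = FALSE)
  }
  reps <- params$replicates
  out <- with_seed(params$seed + 2L, {
    abundance <- stats::rlnorm(n, meanlog = 0, sdlog = 0.5)
    abundance <- abundance / mean(abundance) * params$mean_coverage
    hits <- sort(sample(non_exonic, params$n_true_hits))
    fold <- rep(1, n)
    fold[hits] <- params$hit_fold_enrichment
    fold[gdf$exonic] <- params$hit_fold_enrichment
    mu_sorted <- abundance * fold
    baseline <- matrix(stats::rnbinom(n * reps, mu = abundance,
                                      size = params$dispersion), n, reps)
    sorted <- matrix(stats::rnbinom(n * reps, mu = mu_sorted,
                                    size = params$dispersion), n, reps)
    target_depth <- params$mean_coverage * n
    depth <- colSums(sorted)
    depth[depth == 0] <- 1
    sorted <- round(sweep(sorted, 2L, depth / target_depth, "/"))
    list(abundance = abundance, hits = hits, fold = fold,
         baseline = baseline, sorted = sorted)
  })
  sheet <- sample_sheet(data.frame(
    sample_id = c(paste0("sorted_", seq_len(reps)),
                  paste0("baseline_", seq_len(reps))),
    condition = rep(c("sorted", "baseline"), each = reps),
    replicate = rep(seq_len(reps), 2L), stringsAsFactors = FALSE))
  counts <- cbind(out$sorted, out$baseline)
  dimnames(counts) <- list(gdf$guide_id, sheet$sample_id)
  cm <- new_count_matrix(counts, sheet,
                         stats::setNames(integer(2L * reps),
                                         sheet$sample_id),
                         colSums(counts))
  truth <- structure(list(
    per_guide = data.frame(guide_id = gdf$guide_id,
                           baseline_abundance = out$abundance,
                           fold_enrichment = out$fold,
                           exonic = gdf$exonic,
                           is_true_hit = seq_len(n) %in% out$hits,
                           stringsAsFactors = FALSE),
    enriched_guide_ids = gdf$guide_id[out$hits],
    hit_fold_enrichment = params$hit_fold_enrichment),
    class = "screen_sim_truth")
  list(counts = cm, truth = truth)
}

# Substitute bases at rate `rate` in a character vector of reads.
inject_read_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  len <- nchar(reads[1L])
  n_err <- stats::rbinom(length(reads), len, rate)
  for (i in which(n_err > 0L)) {
    pos <- sample.int(len, n_err[i])
    for (p in pos) {
      cur <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur),
                                       1L)
    }
  }
  reads
}

#' Simulate screen FASTQ files from a count matrix
#'
#' Emits one read per count unit: the `anchor5 + spacer + anchor3` construct
#' embedded at a random offset in random stuffer sequence, padded to the
#' read length. Records are shuffled so counting cannot rely on order.
#' Optionally writes an R2 mate (the reverse complement of R1, as for a
#' short amplicon read from both ends).
#'
#' @param cm A `count_matrix` (e.g. from [simulate_counts()]).
#' @param lib The `guide_library` the counts refer to.
#' @param dir Output directory (created if needed).
#' @param anchors List with `anchor5`, `anchor3` ([default_anchors()]).
#' @param params [screen_sim_params()] (seed and `read_error_rate` used).
#' @param read_length Read length in bp (250, as for 250-bp paired-end
#'   amplicon sequencing).
#' @param paired Also write R2 files.
#' @return A [sample_sheet()] with `fastq_r1` (and `fastq_r2`) columns.
#' @export
simulate_fastq <- function(cm, lib, dir, anchors = default_anchors(),
                           params = screen_sim_params(),
                           read_length = 250L, paired = FALSE) {
  stopifnot(inherits(cm, "count_matrix"), inherits(lib, "guide_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gdf <- lib$guides
  stopifnot(identical(rownames(cm$counts), gdf$guide_id))
  construct <- paste0(anchors$anchor5, gdf$spacer, anchors$anchor3)
  clen <- nchar(construct[1L])
  if (clen > read_length) {
    stop("anchor5 + spacer + anchor3 (", clen,
         " bp) exceeds the read length", call. = FALSE)
  }
  sheet <- cm$samples
  r1_paths <- character(nrow(sheet))
  r2_paths <- character(nrow(sheet))
  for (j in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[j]
    r1_paths[j] <- file.path(dir, paste0(sid, "_R1.fastq"))
    r2_paths[j] <- file.path(dir, paste0(sid, "_R2.fastq"))
    with_seed(params$seed + 100L + j, {
      nj <- cm$counts[, j]
      n_reads <- sum(nj)
      if (n_reads == 0L) {
        writeLines(character(), r1_paths[j])
        if (paired) writeLines(character(), r2_paths[j])
      } else {
        cons <- rep.int(construct, nj)
        big <- random_dna(n_reads * read_length, 0.5)
        reads <- substring(big, (seq_len(n_reads) - 1L) * read_length + 1L,
                           seq_len(n_reads) * read_length)
        offset <- sample.int(read_length - clen + 1L, n_reads,
                             replace = TRUE)
        substr(reads, offset, offset + clen - 1L) <- cons
        reads <- inject_read_errors(reads, params$read_error_rate)
        ord <- sample.int(n_reads)
        reads <- reads[ord]
        heads <- paste0("@", sid, ":", seq_len(n_reads))
        qual <- strrep("I", read_length)
        writeLines(rbind(heads, reads, "+", qual), r1_paths[j])
        if (paired) {
          writeLines(rbind(heads, reverse_complement(reads), "+", qual),
                     r2_paths[j])
        }
      }
    })
  }
  df <- as.data.frame(sheet)
  df$fastq_r1 <- r1_paths
  if (paired) df$fastq_r2 <- r2_paths
  sample_sheet(df)
}

#' Simulate a delta-delta-Ct qPCR experiment
#'
#' Generates per-donor treated and control measurements whose true relative
#' expression is `true_fold`: treated delta-Ct values sit `-log2(true_fold)`
#' cycles away from the control delta-Ct, with Gaussian noise on the Ct
#' scale.
#'
#' @param true_fold True fold change of the target in treated vs. control.
#' @param n_donors Biological replicates per group.
#' @param noise_sd_ct SD of the Ct noise (cycles).
#' @param seed Integer seed.
#' @param base_dct,reference_ct Baseline delta-Ct of the control group and
#'   the reference-gene Ct used to lay out the table.
#' @return Data frame `sample, group, target_ct, reference_ct` suitable for
#'   [summarize_ddct()] (control group label `"control"`).
#' @export
simulate_qpcr <- function(true_fold, n_donors = 3L, noise_sd_ct = 0.3,
                          seed = 1L, base_dct = 5, reference_ct = 20) {
  stopifnot(true_fold > 0, n_donors >= 1L, noise_sd_ct >= 0)
  with_seed(seed + 3L, {
    ctrl_dct <- base_dct + stats::rnorm(n_donors, 0, noise_sd_ct)
    trt_dct <- base_dct - log2(true_fold) +
      stats::rnorm(n_donors, 0, noise_sd_ct)
    data.frame(
      sample = c(paste0("donor", seq_len(n_donors), "_control"),
                 paste0("donor", seq_len(n_donors), "_treated")),
      group = rep(c("control", "treated"), each = n_donors),
      target_ct = reference_ct + c(ctrl_dct, trt_dct),
      reference_ct = reference_ct,
      stringsAsFactors = FALSE)
  })
}

#' Simulate a complete screen input set on disk
#'
#' Convenience wrapper chaining [simulate_region()], [scan_protospacers()],
#' [apply_design_filters()], [annotate_exonic()], [simulate_counts()] and
#' [simulate_fastq()], writing `region.fasta`, `exons.bed`, `library.csv`,
#' `counts.csv`, `samples.csv`, per-sample FASTQ and `truth.json` under
#' `dir`.
#'
#' @param params [screen_sim_params()].
#' @param dir Output directory.
#' @param anchors List with `anchor5`, `anchor3`.
#' @param fastq Also write FASTQ reads (the slowest artifact).
#' @return Invisibly, a list with `lib`, `counts`, `truth`, `sheet` and the
#'   output paths.
#' @export
simulate_screen <- function(params = screen_sim_params(), dir,
                            anchors = default_anchors(), fastq = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  region <- simulate_region(params)
  write_fasta(region$sequence, file.path(dir, "region.fasta"))
  write_bed(region$annotation, file.path(dir, "exons.bed"))
  lib <- scan_protospacers(region$sequence, region$interval)
  lib <- apply_design_filters(lib)
  lib <- annotate_exonic(lib, region$annotation)
  write_library(lib, file.path(dir, "library.csv"))
  sim <- simulate_counts(lib, params)
  write_counts(sim$counts, file.path(dir, "counts.csv"))
  sheet <- sim$counts$samples
  if (fastq) {
    sheet <- simulate_fastq(sim$counts, lib, dir, anchors, params)
  }
  utils::write.csv(as.data.frame(sheet), file.path(dir, "samples.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(enriched_guide_ids = sim$truth$enriched_guide_ids,
         hit_fold_enrichment = sim$truth$hit_fold_enrichment,
         per_guide = sim$truth$per_guide),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(lib = lib, counts = sim$counts, truth = sim$truth,
                 sheet = sheet, dir = dir))
}
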