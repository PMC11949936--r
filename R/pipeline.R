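#' Pipeline run configuration
#'
#' Declarative configuration for [run_pipeline()]. Exactly one guide source
#' (`library_csv`, or `fasta` + `region` to design one) and one count source
#' (`counts_csv`, or `samples_csv` with FASTQ paths to count reads) must be
#' given. Unknown keys are rejected so a typo cannot silently disable a
#' stage.
#'
#' @param out_dir Output directory for `enrichment.csv`, `scores.bedgraph`
#'   and `summary.json`.
#' @param library_csv Existing guide library CSV (from [write_library()]).
#' @param fasta,region Genome FASTA and 1-based region string
#'   (`chr:start-end`) to design the library from.
#' @param exons_bed Optional BED of exons for exonic labelling.
#' @param counts_csv Existing count matrix CSV.
#' @param samples_csv Sample sheet CSV with `fastq_r1` (and `fastq_r2`)
#'   columns for counting reads.
#' @param anchor5,anchor3 Spacer anchors used when counting from FASTQ.
#' @param max_mismatches Spacer matching tolerance (0 or 1).
#' @param params [enrichment_params()].
#' @param verbose Log stage progress via `message()`.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(out_dir, library_csv = NULL, fasta = NULL,
                       region = NULL, exons_bed = NULL, counts_csv = NULL,
                       samples_csv = NULL,
                       anchor5 = default_anchors()$anchor5,
                       anchor3 = default_anchors()$anchor3,
                       max_mismatches = 0L, params = enrichment_params(),
                       verbose = TRUE) {
  cfg <- list(out_dir = out_dir, library_csv = library_csv, fasta = fasta,
              region = region, exons_bed = exons_bed,
              counts_csv = counts_csv, samples_csv = samples_csv,
              anchor5 = anchor5, anchor3 = anchor3,
              max_mismatches = as.integer(max_mismatches), params = params,
              verbose = isTRUE(verbose))
  if (is.null(cfg$library_csv) && (is.null(cfg$fasta) || is.null(cfg$region))) {
    stop("config: need either library_csv or fasta + region", call. = FALSE)
  }
  if (is.null(cfg$counts_csv) && is.null(cfg$samples_csv)) {
    stop("config: need either counts_csv or samples_csv", call. = FALSE)
  }
  stopifnot(inherits(cfg$params, "enrichment_params"))
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML-like `key: value` config file; keys are the arguments of
#'   `run_config()` (thresholds given as `pseudocount`, `lfc_threshold`,
#'   `p_threshold`).
#' @param overrides Named list applied over the file's values.
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  lines <- grep("^\\s*(#|$)", readLines(path), value = TRUE, invert = TRUE)
  m <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*?)\\s*$",
                                 lines))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("config parse error at line: ", lines[bad][1L], call. = FALSE)
  }
  vals <- stats::setNames(lapply(m, `[`, 3L), vapply(m, `[`, "", 2L))
  vals[names(overrides)] <- overrides
  param_keys <- c("pseudocount", "lfc_threshold", "p_threshold",
                  "fc_method", "test_scale")
  known <- c(setdiff(names(formals(run_config)), "params"), param_keys)
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("config: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  pargs <- vals[intersect(param_keys, names(vals))]
  for (k in c("pseudocount", "lfc_threshold", "p_threshold")) {
    if (k %in% names(pargs)) pargs[[k]] <- as.numeric(pargs[[k]])
  }
  cargs <- vals[setdiff(names(vals), param_keys)]
  if ("max_mismatches" %in% names(cargs)) {
    cargs$max_mismatches <- as.integer(cargs$max_mismatches)
  }
  if ("verbose" %in% names(cargs)) {
    cargs$verbose <- tolower(cargs$verbose) %in% c("true", "yes", "1")
  }
  cargs$params <- do.call(enrichment_params, pargs)
  do.call(run_config, cargs)
}

stage <- function(name, verbose, expr) {
  if (verbose) message("[", name, "] starting")
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the screen analysis pipeline
#'
#' Chains library design (or loading), guide counting (or count loading),
#' CPM normalization, enrichment statistics, hit calling, and report
#' writing. Outputs under `out_dir`: `enrichment.csv` (full per-guide
#' table), `scores.bedgraph` (score at each cut site) and `summary.json`
#' (thresholds used, volcano class counts, hit list). Deterministic: a rerun
#' with the same config reproduces the CSV byte for byte.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `lib`, `counts`, `table`, `summary` and
#'   output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  v <- config$verbose
  lib <- stage("design", v, {
    if (!is.null(config$library_csv)) {
      lib <- read_library(config$library_csv)
      if (v) message("[design] loaded ", nrow(guides(lib)), " guides from ",
                     config$library_csv)
      lib
    } else {
      genome <- read_fasta(config$fasta)
      lib <- scan_protospacers(genome, parse_region(config$region))
      lib <- apply_design_filters(lib)
      if (v) message("[design] designed ", nrow(guides(lib)), " guides")
      lib
    }
  })
  if (!is.null(config$exons_bed)) {
    lib <- stage("annotate", v, annotate_exonic(lib, read_bed(config$exons_bed)))
  }
  cm <- stage("count", v, {
    if (!is.null(config$counts_csv)) {
      sheet <- if (!is.null(config$samples_csv)) {
        read_sample_sheet(config$samples_csv)
      } else NULL
      read_counts(config$counts_csv, sheet)
    } else {
      sheet <- read_sample_sheet(config$samples_csv)
      count_guides(sheet, lib, config$anchor5, config$anchor3,
                   config$max_mismatches)
    }
  })
  if (v) {
    message("[count] ", nrow(cm$counts), " guides x ", ncol(cm$counts),
            " samples, ", sum(cm$counts), " assigned / ",
            sum(cm$unassigned), " unassigned reads")
  }
  tbl <- stage("score", v, {
    norm <- normalize_cpm(cm, config$params$scale)
    guide_statistics(norm, cm$samples, lib, config$params)
  })
  if (v) {
    message("[score] thresholds: log2fc > ", config$params$lfc_threshold,
            ", p < ", config$params$p_threshold, " (",
            config$params$fc_method, ", t-test on ",
            config$params$test_scale, " scale)")
  }
  out <- stage("report", v, {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    enrichment_csv <- file.path(config$out_dir, "enrichment.csv")
    track <- file.path(config$out_dir, "scores.bedgraph")
    summary_json <- file.path(config$out_dir, "summary.json")
    write_enrichment(tbl, enrichment_csv)
    score_track(tbl, track)
    vs <- volcano_summary(tbl)
    summary <- list(
      n_guides = nrow(tbl),
      thresholds = list(lfc = config$params$lfc_threshold,
                        p = config$params$p_threshold,
                        pseudocount = config$params$pseudocount,
                        fc_method = config$params$fc_method,
                        test_scale = config$params$test_scale),
      class_counts = as.list(vs$class_counts),
      n_hits = vs$n_hits,
      hits = vs$hits[, c("guide_id", "log2fc", "p_value", "score",
                         "volcano_class")])
    jsonlite::write_json(summary, summary_json, auto_unbox = TRUE,
                         digits = NA)
    list(enrichment_csv = enrichment_csv, track = track,
         summary_json = summary_json, summary = summary)
  })
  if (v) message("[report] ", out$summary$n_hits, " hits; outputs in ",
                 config$out_dir)
  invisible(list(lib = lib, counts = cm, table = tbl,
                 summary = out$summary, paths = out[1:3]))
}
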