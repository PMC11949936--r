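test_that("region simulation is deterministic and respects GC settings", {
  p <- screen_sim_params(seed = 4, region_length = 5000)
  r1 <- simulate_region(p)
  r2 <- simulate_region(p)
  expect_identical(r1$sequence, r2$sequence)
  expect_identical(as.data.frame(r1$annotation), as.data.frame(r2$annotation))
  expect_equal(nchar(r1$sequence[["chrSim"]]), 5000)

  # gc_content = 0 -> A/T only
  at <- simulate_region(screen_sim_params(seed = 4, region_length = 1000,
                                          gc_content = 0))
  expect_false(grepl("[GC]", at$sequence[["chrSim"]]))

  # observed GC within 3 binomial SD of the target at L = 24,000
  full <- simulate_region(screen_sim_params(seed = 8))
  s <- full$sequence[["chrSim"]]
  gc <- nchar(gsub("[AT]", "", s)) / nchar(s)
  expect_lt(abs(gc - 0.41), 3 * sqrt(0.41 * 0.59 / 24000))
})

test_that("different seeds give different sequences", {
  a <- simulate_region(screen_sim_params(seed = 1, region_length = 1000))
  b <- simulate_region(screen_sim_params(seed = 2, region_length = 1000))
  expect_false(identical(a$sequence, b$sequence))
})

test_that("count simulation is seeded, labelled, and truth-complete", {
  p <- screen_sim_params(seed = 6, region_length = 4000, n_true_hits = 3,
                         mean_coverage = 50)
  reg <- simulate_region(p)
  lib <- annotate_exonic(apply_design_filters(
    scan_protospacers(reg$sequence, reg$interval)), reg$annotation)
  s1 <- simulate_counts(lib, p)
  s2 <- simulate_counts(lib, p)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$truth$enriched_guide_ids, s2$truth$enriched_guide_ids)
  # truth covers every guide exactly once
  expect_setequal(s1$truth$per_guide$guide_id, guides(lib)$guide_id)
  expect_equal(sum(s1$truth$per_guide$is_true_hit), 3)
  # planted hits are non-exonic and enriched at the configured fold
  tr <- s1$truth$per_guide
  expect_false(any(tr$exonic[tr$is_true_hit]))
  expect_equal(unique(tr$fold_enrichment[tr$is_true_hit | tr$exonic]),
               p$hit_fold_enrichment)
  expect_equal(unique(tr$fold_enrichment[!tr$is_true_hit & !tr$exonic]), 1)
  # 3 + 3 design with the expected conditions
  expect_equal(sum(s1$counts$samples$condition == "sorted"), 3)
  expect_equal(sum(s1$counts$samples$condition == "baseline"), 3)
  # impossible hit budget is a config error
  expect_error(simulate_counts(lib, screen_sim_params(
    seed = 1, region_length = 4000, n_true_hits = nrow(guides(lib)) + 1)),
    "exceeds")
})

test_that("with no planted effects the two conditions are exchangeable", {
  p <- screen_sim_params(seed = 10, region_length = 6000, n_true_hits = 0,
                         exon_intervals = data.frame(start = integer(),
                                                     end = integer()),
                         mean_coverage = 100)
  reg <- simulate_region(p)
  lib <- apply_design_filters(scan_protospacers(reg$sequence, reg$interval))
  sim <- simulate_counts(lib, p)
  tbl <- guide_statistics(normalize_cpm(sim$counts), sim$counts$samples, lib)
  # hit fraction stays near the nominal test size, far from enrichment
  expect_lt(mean(tbl$is_hit), 0.03)
  expect_lt(abs(mean(tbl$log2fc)), 0.1)
})

test_that("large dispersion approaches Poisson noise (var/mean -> 1)", {
  p <- screen_sim_params(seed = 12, region_length = 2000, n_true_hits = 0,
                         exon_intervals = data.frame(start = integer(),
                                                     end = integer()),
                         replicates = 60, mean_coverage = 100,
                         dispersion = 1e6)
  reg <- simulate_region(p)
  lib <- apply_design_filters(scan_protospacers(reg$sequence, reg$interval))
  sim <- simulate_counts(lib, p)
  base <- sim$counts$counts[, sim$counts$samples$condition == "baseline"]
  vm <- apply(base, 1, var) / rowMeans(base)
  expect_equal(mean(vm[is.finite(vm)]), 1, tolerance = 0.05)
})

test_that("error-free FASTQ round-trips the generating counts exactly", {
  p <- screen_sim_params(seed = 14, region_length = 3000, n_true_hits = 2,
                         mean_coverage = 20)
  reg <- simulate_region(p)
  lib <- annotate_exonic(apply_design_filters(
    scan_protospacers(reg$sequence, reg$interval)), reg$annotation)
  sim <- simulate_counts(lib, p)
  dir <- file.path(tempdir(), "fq_small")
  on.exit(unlink(dir, recursive = TRUE))
  sheet <- simulate_fastq(sim$counts, lib, dir, params = p)
  a <- default_anchors()
  cm <- count_guides(sheet, lib, a$anchor5, a$anchor3)
  expect_identical(cm$counts, sim$counts$counts)
  expect_equal(sum(cm$unassigned), 0)
})

test_that("paired FASTQ mates rescue reads whose R1 spacer is destroyed", {
  p <- screen_sim_params(seed = 15, region_length = 3000, n_true_hits = 0,
                         mean_coverage = 10)
  reg <- simulate_region(p)
  lib <- annotate_exonic(apply_design_filters(
    scan_protospacers(reg$sequence, reg$interval)), reg$annotation)
  sim <- simulate_counts(lib, p)
  dir <- file.path(tempdir(), "fq_paired")
  on.exit(unlink(dir, recursive = TRUE))
  sheet <- simulate_fastq(sim$counts, lib, dir, params = p, paired = TRUE)
  # wreck every R1: reads become all-A, so only R2 can place the spacer
  for (f in sheet$fastq_r1) {
    lines <- readLines(f)
    idx <- seq(2, length(lines), by = 4)
    lines[idx] <- strrep("A", 250)
    writeLines(lines, f)
  }
  a <- default_anchors()
  cm <- count_guides(sheet, lib, a$anchor5, a$anchor3)
  expect_identical(cm$counts, sim$counts$counts)
})

test_that("read errors degrade recovery and raise unassigned reads", {
  p <- screen_sim_params(seed = 16, region_length = 3000, n_true_hits = 0,
                         mean_coverage = 10, read_error_rate = 0.25)
  reg <- simulate_region(p)
  lib <- annotate_exonic(apply_design_filters(
    scan_protospacers(reg$sequence, reg$interval)), reg$annotation)
  sim <- simulate_counts(lib, p)
  dir <- file.path(tempdir(), "fq_err")
  on.exit(unlink(dir, recursive = TRUE))
  sheet <- simulate_fastq(sim$counts, lib, dir, params = p)
  a <- default_anchors()
  cm <- count_guides(sheet, lib, a$anchor5, a$anchor3)
  expect_lt(sum(cm$counts), sum(sim$counts$counts))
  expect_gt(sum(cm$unassigned), 0)
  # conservation still holds under corruption
  expect_equal(unname(colSums(cm$counts) + cm$unassigned),
               unname(cm$total))
})

test_that("an all-zero count matrix yields empty FASTQ files", {
  lib <- toy_library()
  sheet <- sample_sheet(data.frame(sample_id = c("s1", "s2"),
                                   condition = c("sorted", "baseline"),
                                   replicate = 1))
  zero <- matrix(0L, 4, 2, dimnames = list(guides(lib)$guide_id,
                                           sheet$sample_id))
  cm <- tilescreen:::new_count_matrix(zero, sheet,
                                      c(s1 = 0L, s2 = 0L),
                                      c(s1 = 0L, s2 = 0L))
  dir <- file.path(tempdir(), "fq_zero")
  on.exit(unlink(dir, recursive = TRUE))
  out <- simulate_fastq(cm, lib, dir, params = screen_sim_params(seed = 1))
  expect_true(all(file.exists(out$fastq_r1)))
  expect_equal(unname(vapply(out$fastq_r1,
                             function(f) length(readLines(f)), 1L)),
               c(0L, 0L))
})

test_that("qPCR simulation recovers the true fold change", {
  # zero noise -> exact recovery
  tab <- simulate_qpcr(true_fold = 0.25, n_donors = 3, noise_sd_ct = 0,
                       seed = 1)
  g <- summarize_ddct(tab, "control")$groups
  expect_equal(g$mean_fold[g$group == "treated"], 0.25)

  # null fold centers on 1 and noisy estimates stay near the truth
  ests <- vapply(1:60, function(s) {
    tab <- simulate_qpcr(true_fold = 1, n_donors = 3, noise_sd_ct = 0.3,
                         seed = s)
    g <- summarize_ddct(tab, "control")$groups
    g$mean_fold[g$group == "treated"]
  }, numeric(1))
  expect_equal(mean(ests), 1, tolerance = 0.1)

  # deterministic per seed
  expect_identical(simulate_qpcr(2, seed = 5), simulate_qpcr(2, seed = 5))
})
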