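test_that("the same seed reproduces the cohort byte for byte", {
  cfg <- small_sim_config(samples_per_type = c(HGG = 4, LGAT = 3))
  a <- simulate_cohort(cfg, seed = 11)
  b <- simulate_cohort(cfg, seed = 11)
  expect_identical(a$truth, b$truth)
  expect_identical(as.data.frame(a$callsets), as.data.frame(b$callsets))
  expect_identical(a$cnv, b$cnv)
  expect_identical(a$samples, b$samples)
  c2 <- simulate_cohort(cfg, seed = 12)
  expect_false(identical(a$truth, c2$truth))
})

test_that("growing the cohort does not perturb earlier samples", {
  small <- small_sim_config(samples_per_type = c(HGG = 3))
  big <- small_sim_config(samples_per_type = c(HGG = 6))
  a <- simulate_cohort(small, seed = 5)
  b <- simulate_cohort(big, seed = 5)
  first <- b$truth[b$truth$sample_id %in% a$truth$sample_id, ]
  rownames(first) <- NULL
  expect_identical(a$truth, first)
})

test_that("perfect callers reproduce the truth identically in all three callsets", {
  cfg <- small_sim_config(
    samples_per_type = c(HGG = 5),
    callers = list(
      meerkat = list(sensitivity = 1, jitter_sd = 0, fp_rate = 0,
                     support_mean = 10, reports_homology = TRUE),
      manta = list(sensitivity = 1, jitter_sd = 0, fp_rate = 0,
                   support_mean = 10, reports_homology = TRUE),
      delly = list(sensitivity = 1, jitter_sd = 0, fp_rate = 0,
                   support_mean = 10, reports_homology = TRUE)))
  co <- simulate_cohort(cfg, seed = 21)
  key <- function(df) sort(paste(df$sample_id, df$chrom1, df$pos1, df$chrom2,
                                 df$pos2, df$svtype))
  tk <- key(co$truth)
  for (caller in c("meerkat", "manta", "delly")) {
    expect_equal(key(co$callsets[co$callsets$caller == caller, ]), tk)
  }
})

test_that("caller-specific false positives never survive consensus", {
  cfg <- small_sim_config(
    samples_per_type = c(HGG = 6, Medulloblastoma = 4),
    callers = list(
      meerkat = list(sensitivity = 1, jitter_sd = 0, fp_rate = 0.5,
                     support_mean = 10, reports_homology = TRUE),
      manta = list(sensitivity = 1, jitter_sd = 0, fp_rate = 0.5,
                   support_mean = 10, reports_homology = TRUE),
      delly = list(sensitivity = 1, jitter_sd = 0, fp_rate = 0.5,
                   support_mean = 10, reports_homology = FALSE)))
  co <- simulate_cohort(cfg, seed = 31)
  cons <- sv_consensus(co$callsets, co$genome, co$cnv)
  m <- match_to_truth(cons, co$truth, tol = 0)
  expect_true(all(!is.na(m)))                       # precision 1.0
  expect_equal(length(unique(m)), nrow(co$truth))   # full recall at sens 1
})

test_that("consensus recall tracks the at-least-two-callers binomial expectation", {
  cfg <- small_sim_config(samples_per_type = c(HGG = 25, Medulloblastoma = 15))
  co <- simulate_cohort(cfg, seed = 41)
  cons <- sv_consensus(co$callsets, co$genome, co$cnv)
  m <- match_to_truth(cons, co$truth)
  expect_equal(mean(!is.na(m)), 1.0)  # precision
  sens <- vapply(cfg$callers, `[[`, numeric(1), "sensitivity")
  p2 <- sum(sens[1] * sens[2] * (1 - sens[3]),
            sens[1] * sens[3] * (1 - sens[2]),
            sens[2] * sens[3] * (1 - sens[1]),
            prod(sens))
  recall <- length(unique(stats::na.omit(m))) / nrow(co$truth)
  se <- sqrt(p2 * (1 - p2) / nrow(co$truth))
  # within sampling error (plus a small allowance for the Delly short-SV
  # support filter, which the expectation ignores)
  expect_lt(abs(recall - p2), 4 * se + 0.02)
})

test_that("large copy-altering SVs leave CNV breakpoints within the configured jitter", {
  cfg <- small_sim_config(samples_per_type = c(HGG = 10))
  co <- simulate_cohort(cfg, seed = 51)
  big <- co$truth[co$truth$svtype %in% c("DEL", "DUP") &
                    co$truth$chrom1 == co$truth$chrom2 &
                    abs(co$truth$pos2 - co$truth$pos1) >= cfg$cnv_resolution &
                    !grepl("clustered|tic", co$truth$process), ]
  bp <- svsig:::cnv_breakpoints(co$cnv)
  max_jitter <- 400 + 1  # boundary jitter is clamped in the generator
  for (i in seq_len(nrow(big))) {
    for (end in 1:2) {
      pos <- if (end == 1) big$pos1[i] else big$pos2[i]
      chrom <- if (end == 1) big$chrom1[i] else big$chrom2[i]
      cand <- bp$pos[bp$sample_id == big$sample_id[i] & bp$chrom == chrom]
      expect_lte(min(abs(cand - pos)), max_jitter)
    }
  }
})

test_that("null feature tracks are independent of breakpoints; planting flips track 1", {
  cfg <- small_sim_config(n_feature_tracks = 5)
  g <- svsig:::with_seed(1, svsig:::simulate_genome(cfg))
  tr <- simulate_null_features(cfg, g, seed = 7)
  expect_length(tr, 5)
  expect_identical(simulate_null_features(cfg, g, seed = 7)$track01$data,
                   tr$track01$data)
  none <- simulate_null_features(small_sim_config(n_feature_tracks = 0), g, 7)
  expect_length(none, 0)
})

test_that("infeasible event spans are rejected", {
  cfg <- small_sim_config(chrom_lengths = c(chr1 = 25e6),
                          clustered_span = c(30e6, 40e6),
                          samples_per_type = c(HGG = 1))
  expect_error(simulate_cohort(cfg, seed = 1), "exceeds")
  expect_error(simulation_config(callers = list(
    meerkat = list(sensitivity = 1.4, jitter_sd = 0, fp_rate = 0,
                   support_mean = 5, reports_homology = TRUE))),
    "sensitivity")
})

test_that("written cohorts are read back by the io layer", {
  cfg <- small_sim_config(samples_per_type = c(HGG = 3))
  co <- simulate_cohort(cfg, seed = 61)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- do.call(rbind, lapply(c("meerkat", "manta", "delly"), function(cl)
    read_sv_callset(file.path(dir, paste0(cl, ".bedpe")), cl, genome = co$genome)))
  expect_equal(nrow(back), nrow(co$callsets))
  cnv <- read_cnv_segments(file.path(dir, "cnv_segments.tsv"), co$genome)
  expect_equal(nrow(cnv), nrow(co$cnv))
  sheet <- read_sample_sheet(file.path(dir, "samples.tsv"))
  expect_equal(sheet$sample_id, co$samples$sample_id)
})
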