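test_that("hotspot counts deduplicate samples within bins", {
  g <- toy_genome()
  svs <- mk_calls(
    # S1: three same-signature breakpoint pairs in the first 1 Mb bin of chr1
    mk_call("chr1", 1e5, "chr1", 2e5, "DEL", sample_id = "S1"),
    mk_call("chr1", 3e5, "chr1", 4e5, "DEL", sample_id = "S1"),
    mk_call("chr1", 5e5, "chr1", 6e5, "DEL", sample_id = "S1"),
    # S2: one breakpoint pair in the same bin
    mk_call("chr1", 7e5, "chr1", 7.5e5, "DEL", sample_id = "S2"))
  svs$signature <- c("Del0", "Del0", "Del0", "Del0")
  hs <- hotspot_counts(svs, g, bin_size = 1e6)
  bin1 <- hs[hs$chrom == "chr1" & hs$start == 1 & hs$signature == "Del0", ]
  expect_equal(bin1$n_samples, 2)  # S1 counted once despite 6 breakpoints

  # different signatures are tracked separately and both count the sample
  svs2 <- svs
  svs2$signature <- c("Del0", "TD", "Del0", "Del0")
  hs2 <- hotspot_counts(svs2, g, bin_size = 1e6)
  expect_equal(hs2$n_samples[hs2$signature == "Del0" & hs2$start == 1 &
                               hs2$chrom == "chr1"], 2)
  expect_equal(hs2$n_samples[hs2$signature == "TD" & hs2$start == 1 &
                               hs2$chrom == "chr1"], 1)

  # bins tile from 1 and keep the final partial bin
  chr3 <- hs[hs$chrom == "chr3" & hs$signature == "Del0", ]
  expect_equal(chr3$start[1], 1)
  expect_equal(chr3$end[nrow(chr3)], 6e6)
  # per-bin count never exceeds the number of samples
  expect_true(all(hs$n_samples <= 2))
})

test_that("Fisher tests match exhaustive hypergeometric enumeration", {
  tab <- matrix(c(5, 5, 0, 10), 2, byrow = TRUE)
  expect_equal(fisher.test(tab)$p.value, oracle_fisher_p(tab), tolerance = 1e-9)
  expect_equal(round(fisher.test(tab)$p.value, 4), 0.0325)

  expect_equal(fisher.test(matrix(c(5, 5, 5, 5), 2))$p.value, 1)

  with_seed_local(3, {
    for (i in 1:60) {
      n <- sample(6:40, 1)
      cells <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.1, 1)))
      tab <- matrix(cells, 2)
      expect_equal(fisher.test(tab)$p.value, oracle_fisher_p(tab),
                   tolerance = 1e-9)
    }
  })
})

test_that("mutation association applies the frequency and hypermutation filters", {
  with_seed_local(8, {
    n <- 60
    samples <- data.frame(
      sample_id = sprintf("S%02d", 1:n), tumor_type = "HGG",
      sex = "female", hypermutated = c(TRUE, rep(FALSE, n - 1)),
      survival_time = NA, survival_event = "unknown",
      mutations = "", stringsAsFactors = FALSE)
    present <- matrix(FALSE, n, 1, dimnames = list(samples$sample_id, "Del2"))
    present[2:21, 1] <- TRUE
    # TP53 mutations concentrated in signature carriers; RARE mutated once (<5%)
    mut <- rep("", n)
    mut[2:13] <- "TP53:missense"
    mut[30] <- "RARE:missense"
    mut[1] <- "TP53:missense"  # hypermutated sample, must be excluded
    samples$mutations <- mut
    res <- mutation_association(samples, present, min_freq = 0.05)
    expect_true("TP53" %in% res$gene)
    expect_false("RARE" %in% res$gene)
    tp53 <- res[res$gene == "TP53", ]
    expect_equal(tp53$sig_mut + tp53$sig_nomut + tp53$nosig_mut + tp53$nosig_nomut,
                 n - 1L)  # hypermutated excluded from the margins
    expect_lt(tp53$p, 0.01)
    # the association is recovered as significant after BH
    expect_true(tp53$significant)
  })
})

test_that("homology spectra bin insertions and microhomology as documented", {
  svs <- mk_calls(
    mk_call("chr1", 1e5, "chr1", 2e5, "DEL", homology_len = 0, insertion_len = 0),
    mk_call("chr1", 3e5, "chr1", 4e5, "DEL", homology_len = 0, insertion_len = 15),
    mk_call("chr1", 5e5, "chr1", 6e5, "DEL", homology_len = 2, insertion_len = 0),
    mk_call("chr1", 7e5, "chr1", 8e5, "DEL", homology_len = 7, insertion_len = 0),
    mk_call("chr1", 9e5, "chr1", 9.5e5, "DEL", homology_len = 0, insertion_len = 4),
    mk_call("chr1", 9.6e5, "chr1", 9.7e5, "DEL"))  # unknown: excluded
  svs$signature <- "Del0"
  sp <- homology_spectrum(svs)
  counts <- stats::setNames(sp$count, sp$category)
  expect_equal(unname(counts["blunt"]), 1)
  expect_equal(unname(counts["insertion_gt10bp"]), 1)
  expect_equal(unname(counts["insertion_1_10bp"]), 1)
  expect_equal(unname(counts["microhomology_2bp"]), 1)
  expect_equal(unname(counts["microhomology_5plus"]), 1)
  expect_equal(sum(sp$count), 5)  # unknown homology excluded
})

test_that("log-rank statistics match the closed-form oracle", {
  # identical groups: statistic 0, p = 1
  samples <- data.frame(
    sample_id = paste0("S", 1:6), tumor_type = "HGG", sex = "male",
    hypermutated = FALSE,
    survival_time = c(100, 200, 300, 100, 200, 300),
    survival_event = "death", mutations = "")
  pres <- matrix(rep(c(TRUE, FALSE), each = 3), 6, 1,
                 dimnames = list(samples$sample_id, "Del2"))
  res <- survival_stratification(samples, pres, "simple")
  expect_equal(res$chisq, 0, tolerance = 1e-9)
  expect_equal(res$p, 1, tolerance = 1e-9)

  # separated groups: match the O-E / V hand computation
  samples$survival_time <- c(1, 2, 3, 10, 20, 30)
  res2 <- survival_stratification(samples, pres, "simple")
  oracle <- oracle_logrank_chisq(samples$survival_time,
                                 rep(1, 6), pres[, 1])
  expect_equal(res2$chisq, oracle, tolerance = 1e-9)

  with_seed_local(21, {
    for (i in 1:20) {
      n <- 24
      time <- sample(1:50, n, TRUE)
      event <- rbinom(n, 1, 0.8)
      grp <- rbinom(n, 1, 0.5) == 1
      if (all(grp) || !any(grp)) next
      s <- data.frame(sample_id = paste0("X", 1:n), tumor_type = "HGG",
                      sex = "male", hypermutated = FALSE,
                      survival_time = time,
                      survival_event = ifelse(event == 1, "death", "censored"),
                      mutations = "")
      p <- matrix(grp, n, 1, dimnames = list(s$sample_id, "Del2"))
      got <- survival_stratification(s, p, "simple")
      want <- oracle_logrank_chisq(time, event, grp)
      expect_equal(got$chisq, want, tolerance = 1e-8)
    }
  })
})

test_that("clustered survival grouping builds single/Mixed/None strata", {
  with_seed_local(12, {
    n <- 40
    samples <- data.frame(
      sample_id = sprintf("C%02d", 1:n), tumor_type = "HGG", sex = "male",
      hypermutated = FALSE,
      survival_time = sample(100:2000, n),
      survival_event = sample(c("death", "censored"), n, TRUE),
      mutations = "")
    pres <- matrix(FALSE, n, 2,
                   dimnames = list(samples$sample_id, c("ecDNA", "Large loss")))
    pres[1:8, 1] <- TRUE          # ecDNA only
    pres[9:14, 2] <- TRUE         # Large loss only
    pres[15:18, ] <- TRUE         # Mixed
    res <- survival_stratification(samples, pres, "clustered")
    expect_equal(res$signature, "clustered_complex")
    expect_equal(res$df, 3)       # ecDNA, Large loss, Mixed, None
    expect_true(res$p >= 0 && res$p <= 1)
  })
})

test_that("survival effects are detectable at the simulated hazard ratio", {
  hits <- 0
  for (rep in 1:20) {
    with_seed_local(300 + rep, {
      n <- 200
      carrier <- rep(c(TRUE, FALSE), each = n / 2)
      hazard <- ifelse(carrier, 3 / 1500, 1 / 1500)
      t_event <- rexp(n, hazard)
      t_cens <- runif(n, 500, 3000)
      s <- data.frame(sample_id = paste0("P", 1:n), tumor_type = "HGG",
                      sex = "male", hypermutated = FALSE,
                      survival_time = pmin(t_event, t_cens),
                      survival_event = ifelse(t_event <= t_cens, "death", "censored"),
                      mutations = "")
      p <- matrix(carrier, n, 1, dimnames = list(s$sample_id, "Del2"))
      res <- survival_stratification(s, p, "simple")
      if (res$p < 0.05) hits <- hits + 1
    })
  }
  expect_gte(hits, 18)  # >= 90% power
})

test_that("cohort summary reproduces printed-count arithmetic and handles empty cohorts", {
  expect_equal(pct(7601, 13199), 57.6)
  expect_equal(pct(552, 744), 74.2)
  expect_equal(pct(13, 70), 18.6)
  expect_equal(pct(13, 23, digits = 0), 57)
  expect_equal(pct(2377, 13199), 18.0)
  expect_equal(pct(3221, 13199), 24.4)
  expect_equal(pct(108, 744), 14.5)
  expect_equal(pct(150, 744), 20.2)

  empty_samples <- data.frame(sample_id = character(), tumor_type = character(),
                              sex = character(), hypermutated = logical(),
                              survival_time = numeric(),
                              survival_event = character(),
                              mutations = character())
  svs <- empty_sv_calls <- svsig:::empty_sv_calls()
  svs$event_class <- character(0)
  out <- cohort_summary(svs, NULL, empty_samples)
  expect_equal(out$overall$n_sv, 0)
  expect_equal(out$overall$pct_clustered, 0)  # no division by zero
})

test_that("a labeled synthetic cohort summarizes consistently", {
  g <- toy_genome()
  svs <- mk_calls(
    mk_call("chr1", 1e5, "chr1", 2e5, "DEL", sample_id = "S1"),
    mk_call("chr1", 3e5, "chr1", 4e5, "DEL", sample_id = "S1"),
    mk_call("chr2", 1e5, "chr2", 2e5, "DUP", sample_id = "S2"))
  svs$event_class <- c("clustered_complex", "simple", "simple")
  samples <- data.frame(sample_id = c("S1", "S2", "S3"),
                        tumor_type = c("HGG", "HGG", "LGAT"),
                        sex = "male", hypermutated = FALSE,
                        survival_time = NA, survival_event = "unknown",
                        mutations = "")
  out <- cohort_summary(svs, NULL, samples)
  expect_equal(out$overall$n_sv, 3)
  expect_equal(out$overall$pct_clustered, pct(1, 3))
  expect_equal(out$overall$n_samples_no_complex, 2)
  expect_equal(out$by_type$n_sv[out$by_type$tumor_type == "HGG"], 3)
})
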