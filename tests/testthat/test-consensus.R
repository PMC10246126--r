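test_that("the short-SV support filter applies to Delly only", {
  cfg <- consensus_config()
  g <- toy_genome()
  calls <- mk_calls(
    mk_call("chr1", 1000, "chr1", 1400, "DEL", caller = "delly",
            split_reads = 1, read_pairs = 2),                    # 3 < 4, short
    mk_call("chr1", 5000, "chr1", 5400, "DEL", caller = "delly",
            split_reads = 2, read_pairs = 2),                    # 4 >= 4
    mk_call("chr1", 9000, "chr1", 9400, "DEL", caller = "manta",
            split_reads = 0, read_pairs = 1),                    # exempt caller
    mk_call("chr1", 20000, "chr1", 20700, "DEL", caller = "delly",
            split_reads = 1, read_pairs = 1))                    # 700 bp, not short
  out <- prefilter_calls(calls, cfg, g)
  expect_equal(out$pos1, c(5000, 9000, 20000))
})

test_that("calls touching non-canonical chromosomes are removed", {
  cfg <- consensus_config()
  df <- rbind(mk_call("chr1", 1000, "chr1", 2000, "DEL"),
              mk_call("chrM", 100, "chrM", 900, "DEL"))
  calls <- sv_calls(df)
  out <- prefilter_calls(calls, cfg)
  expect_equal(out$chrom1, "chr1")
})

test_that("cross-caller matching honors the 10 bp / same-orientation predicate", {
  cfg <- consensus_config()
  # exact agreement between two callers
  out <- match_calls(mk_calls(
    mk_call("chr1", 1e5, "chr1", 2e5, "DEL", caller = "manta"),
    mk_call("chr1", 1e5, "chr1", 2e5, "DEL", caller = "delly")), cfg)
  expect_equal(nrow(out), 1)
  expect_equal(out$callers, "delly,manta")

  # 10 bp apart on both ends matches; 11 bp does not
  m10 <- match_calls(mk_calls(
    mk_call("chr1", 1e5, "chr1", 2e5, "DEL", caller = "manta"),
    mk_call("chr1", 1e5 + 10, "chr1", 2e5 + 10, "DEL", caller = "meerkat")), cfg)
  expect_equal(nrow(m10), 1)
  m11 <- match_calls(mk_calls(
    mk_call("chr1", 1e5, "chr1", 2e5, "DEL", caller = "manta"),
    mk_call("chr1", 1e5 + 11, "chr1", 2e5 + 11, "DEL", caller = "meerkat")), cfg)
  expect_equal(nrow(m11), 0)

  # same positions, different orientation pair: no match
  inv <- match_calls(mk_calls(
    mk_call("chr1", 1e5, "chr1", 2e5, "h2hINV", caller = "manta"),
    mk_call("chr1", 1e5, "chr1", 2e5, "t2tINV", caller = "meerkat")), cfg)
  expect_equal(nrow(inv), 0)

  # all three callers agree
  m3 <- match_calls(mk_calls(
    mk_call("chr1", 1e5, "chr1", 2e5, "DEL", caller = "manta"),
    mk_call("chr1", 1e5 + 3, "chr1", 2e5 - 2, "DEL", caller = "meerkat"),
    mk_call("chr1", 1e5 - 1, "chr1", 2e5 + 4, "DEL", caller = "delly")), cfg)
  expect_equal(m3$n_callers, 3)
})

test_that("within-caller duplicates collapse to the higher-support call", {
  cfg <- consensus_config()
  out <- match_calls(mk_calls(
    mk_call("chr1", 1e5, "chr1", 2e5, "DEL", caller = "manta", split_reads = 2),
    mk_call("chr1", 1e5 + 1, "chr1", 2e5, "DEL", caller = "manta", split_reads = 30),
    mk_call("chr1", 1e5, "chr1", 2e5, "DEL", caller = "delly", split_reads = 5)), cfg)
  expect_equal(nrow(out), 1)
  expect_equal(out$split_reads, 30)  # representative = highest support
  members <- attr(out, "members")
  expect_equal(nrow(members), 2)
})

test_that("graph matching equals the exhaustive union-find oracle on fuzzed callsets", {
  cfg <- consensus_config()
  for (seed in 1:120) {
    calls <- fuzz_callset(n = sample(5:50, 1), seed = seed)
    calls <- svsig:::collapse_within_caller(calls, cfg)
    got <- match_calls(calls, cfg)
    want <- oracle_consensus_groups(calls)
    expect_equal(nrow(got), length(want), info = paste("seed", seed))
    if (length(want)) {
      want_sets <- sort(unname(vapply(want, function(g)
        paste(sort(unique(calls$caller[g])), collapse = ","), "")))
      expect_equal(sort(got$callers), want_sets, info = paste("seed", seed))
    }
  }
})

test_that("enlarging the match distance never reduces consensus yield", {
  for (seed in 1:25) {
    calls <- fuzz_callset(n = 40, seed = seed + 500)
    n_prev <- -1
    for (d in c(5, 10, 25, 50)) {
      n <- nrow(match_calls(calls, consensus_config(match_distance = d)))
      expect_gte(n, n_prev)
      n_prev <- n
    }
  }
})

test_that("cDNA-artifact deletions at exon-intron boundaries of one gene are removed", {
  g <- toy_genome()
  cfg <- consensus_config()
  # GENEA exon1 ends 100200, exon2 starts 101000: intron-spanning deletion
  del_intron <- mk_calls(mk_call("chr1", 100200, "chr1", 101000, "DEL"))
  expect_equal(nrow(filter_cdna_artifacts(del_intron, g, cfg)), 0)

  # breakends 3 bp off are still removed; 4 bp off are kept
  del3 <- mk_calls(mk_call("chr1", 100200 - 3, "chr1", 101000 + 3, "DEL"))
  expect_equal(nrow(filter_cdna_artifacts(del3, g, cfg)), 0)
  del4 <- mk_calls(mk_call("chr1", 100200 - 4, "chr1", 101000, "DEL"))
  expect_equal(nrow(filter_cdna_artifacts(del4, g, cfg)), 1)

  # boundaries of two different genes: kept
  del_cross <- mk_calls(mk_call("chr1", 100200, "chr1", 300400, "DEL"))
  expect_equal(nrow(filter_cdna_artifacts(del_cross, g, cfg)), 1)

  # non-DEL types untouched even at boundaries
  dup <- mk_calls(mk_call("chr1", 100200, "chr1", 101000, "DUP"))
  expect_equal(nrow(filter_cdna_artifacts(dup, g, cfg)), 1)
})

test_that("CNV validation flags SVs with both breakends under 1 kb from CNV breakpoints", {
  cfg <- consensus_config()
  cnv <- data.frame(sample_id = "S1", chrom = "chr1",
                    start = c(1, 1e6), end = c(1e6 - 1, 2e6),
                    copy_number = c(2, 1))
  # breakpoints at 1, 1e6-1, 2e6
  svs <- mk_calls(
    mk_call("chr1", 1e6 - 1 - 500, "chr1", 2e6 + 700, "DEL"),   # 500 & 700 bp
    mk_call("chr1", 1e6 - 1, "chr1", 2e6, "DEL"),               # exact: distance 0
    mk_call("chr1", 1e6 - 1 - 500, "chr1", 2e6 + 2000, "DEL"))  # one end 2 kb away
  out <- cnv_validate(svs, cnv, cfg)
  expect_equal(out$cnv_validated, c(TRUE, TRUE, FALSE))

  # exactly 1 kb is NOT validated (strict inequality)
  at_1kb <- mk_calls(mk_call("chr1", 1e6 - 1 - 1000, "chr1", 2e6, "DEL"))
  expect_false(cnv_validate(at_1kb, cnv, cfg)$cnv_validated)

  # missing CNV data: flag FALSE with a warning
  other <- mk_calls(mk_call("chr1", 5e5, "chr1", 6e5, "DEL", sample_id = "S9"))
  expect_warning(out2 <- cnv_validate(other, cnv, cfg), "no CNV data")
  expect_false(out2$cnv_validated)
})
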