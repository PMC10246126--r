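# toy constructors for event tests

interleaved_cluster <- function(n = 12, chrom = "chr1", lo = 3e6, hi = 8e6,
                                sample_id = "S1", seed = 4) {
  with_seed_local(seed, {
    do.call(rbind, lapply(seq_len(n), function(i) {
      p <- sort(sample(seq(lo, hi), 2))
      tp <- sample(c("DEL", "DUP", "h2hINV", "t2tINV"), 1)
      mk_call(chrom, p[1], chrom, p[2], tp, sample_id = sample_id)
    }))
  })
}

test_that("interleaved clusters group into one event and distal junctions stay apart", {
  g <- toy_genome()
  svs <- sv_calls(rbind(interleaved_cluster(12),
                        mk_call("chr3", 1e5, "chr3", 2e5, "DEL")), g)
  membership <- cluster_events(svs, g)
  expect_equal(length(unique(membership)), 2)
  sizes <- sort(table(membership))
  expect_equal(as.integer(sizes), c(1L, 12L))

  # single junction in an otherwise empty genome: one singleton event
  single <- mk_calls(mk_call("chr1", 1e6, "chr1", 2e6, "DEL"))
  expect_equal(cluster_events(single, g), 1L)

  # reciprocal translocation partners at the same loci group together
  pair <- mk_calls(
    mk_call("chr1", 1e6, "chr2", 3e6, "TRA", strand1 = "+", strand2 = "-"),
    mk_call("chr1", 1e6 + 50, "chr2", 3e6 + 60, "TRA", strand1 = "-", strand2 = "+"))
  expect_equal(length(unique(cluster_events(pair, g))), 1)
})

test_that("every junction lands in exactly one event and counts are conserved", {
  g <- toy_genome()
  for (seed in 1:10) {
    svs <- sv_calls(rbind(interleaved_cluster(10, seed = seed),
                          interleaved_cluster(7, chrom = "chr2", lo = 1e6,
                                              hi = 4e6, seed = seed + 50),
                          mk_call("chr3", 1e5, "chr3", 2e5, "DEL"),
                          mk_call("chr3", 4e6, "chr3", 5.5e6, "DUP")), g)
    res <- classify_events(svs, NULL, g,
                           event_config(missing_cnv_label = "Hourglass"))
    expect_false(any(is.na(res$svs$event_id)))
    expect_equal(sum(res$events$n_junctions), nrow(svs))
    expect_equal(length(unique(res$svs$event_id)), nrow(res$events))
  }
})

oscillating_cnv <- function(chrom = "chr1", lo = 3e6, hi = 8e6,
                            states = c(2, 1), n_seg = 10, sample_id = "S1",
                            L = 10e6, terminal_loss = FALSE) {
  bp <- round(seq(lo, hi, length.out = n_seg + 1))
  body <- data.frame(sample_id = sample_id, chrom = chrom,
                     start = bp[-length(bp)] + 1, end = bp[-1],
                     copy_number = rep(states, length.out = n_seg))
  head <- data.frame(sample_id = sample_id, chrom = chrom, start = 1,
                     end = bp[1], copy_number = 2)
  tail <- data.frame(sample_id = sample_id, chrom = chrom, start = bp[n_seg + 1] + 1,
                     end = L, copy_number = if (terminal_loss) 1 else 2)
  rbind(head, body, tail)
}

test_that("clustered labels follow the documented copy-number decision tree", {
  g <- toy_genome()
  cfg <- event_config()
  svs <- sv_calls(interleaved_cluster(10, lo = 3e6, hi = 8e6), g)
  idx <- seq_len(nrow(svs))

  # two-state oscillation without telomere loss: Micronuclei
  cnv_osc <- oscillating_cnv()
  expect_equal(classify_clustered(svs, idx, cnv_osc, g, cfg), "Micronuclei")

  # same oscillation with the terminal segment lost: Chr bridge
  cnv_tel <- oscillating_cnv(terminal_loss = TRUE)
  expect_equal(classify_clustered(svs, idx, cnv_tel, g, cfg), "Chr bridge")

  # majority of a large footprint lost: Large loss (the footprint threshold
  # is config data; the toy genome tops out under 10 Mb)
  cfg_large <- event_config(large_footprint = 4e6)
  big <- sv_calls(interleaved_cluster(10, chrom = "chr1", lo = 1e5, hi = 9.9e6,
                                      seed = 9), g)
  cnv_loss <- data.frame(sample_id = "S1", chrom = "chr1",
                         start = c(1, 2e6), end = c(2e6 - 1, 10e6),
                         copy_number = c(2, 1))
  expect_equal(classify_clustered(big, seq_len(nrow(big)), cnv_loss, g, cfg_large),
               "Large loss")
  cnv_gain <- cnv_loss; cnv_gain$copy_number <- c(2, 3)
  expect_equal(classify_clustered(big, seq_len(nrow(big)), cnv_gain, g, cfg_large),
               "Large gain")

  # concentrated breakpoints, little loss: Hourglass
  cnv_flat <- data.frame(sample_id = "S1", chrom = "chr1",
                         start = c(1, 5e6), end = c(5e6 - 1, 5.4e6),
                         copy_number = c(2, 1))
  cnv_flat <- rbind(cnv_flat, data.frame(sample_id = "S1", chrom = "chr1",
                                         start = 5.4e6 + 1, end = 10e6,
                                         copy_number = 2))
  expect_equal(classify_clustered(svs, idx, cnv_flat, g, cfg), "Hourglass")

  # missing CNV: configured fallback label with a warning
  expect_warning(lab <- classify_clustered(svs, idx, NULL, g, cfg), "no CNV")
  expect_equal(lab, "Hourglass")
})

test_that("amplified circularizable junction sets are labeled ecDNA", {
  g <- toy_genome()
  cfg <- event_config()
  # three amplified segments chained into a closed cycle on chr1
  segs <- rbind(c(3.0e6, 3.4e6), c(4.0e6, 4.5e6), c(5.2e6, 5.8e6))
  juncs <- do.call(rbind, lapply(1:3, function(s) {
    nxt <- if (s == 3) 1 else s + 1
    tp <- if (segs[s, 2] <= segs[nxt, 1]) "DUP" else "DEL"
    mk_call("chr1", segs[s, 2], "chr1", segs[nxt, 1], tp,
            strand1 = "+", strand2 = "-")
  }))
  svs <- sv_calls(juncs, g)
  cnv <- data.frame(sample_id = "S1", chrom = "chr1",
                    start = c(1, segs[, 1]),
                    end = c(segs[1, 1] - 1, segs[, 2]),
                    copy_number = c(2, 20, 20, 20))
  cnv <- svsig:::validate_cnv_segments(cnv[order(cnv$start), ])
  expect_equal(classify_clustered(svs, 1:3, cnv, g, cfg), "ecDNA")

  # same junctions with diploid copy number are not ecDNA
  cnv2 <- cnv; cnv2$copy_number <- 2
  expect_false(classify_clustered(svs, 1:3, cnv2, g, cfg) == "ecDNA")
})

test_that("non-clustered junction patterns separate chromoplexy, TIC and unclear", {
  g <- toy_genome()
  cfg <- event_config()
  flat_cnv <- data.frame(sample_id = "S1",
                         chrom = c("chr1", "chr2", "chr3"),
                         start = 1, end = c(10e6, 8e6, 6e6), copy_number = 2)

  # balanced 3-chromosome cycle: chromoplexy
  loci <- c(2e6, 3e6, 1.5e6); chrs <- c("chr1", "chr2", "chr3")
  cp <- do.call(rbind, lapply(1:3, function(i) {
    j <- if (i == 3) 1 else i + 1
    mk_call(chrs[i], loci[i] + 100, chrs[j], loci[j], "TRA",
            strand1 = "-", strand2 = "+")
  }))
  svs <- sv_calls(cp, g)
  expect_equal(classify_nonclustered(svs, 1:3, flat_cnv, g, cfg), "chromoplexy")

  # 2-junction cycle bridged through a 50 kb gained segment: TIC
  tic <- rbind(
    mk_call("chr1", 2e6, "chr2", 3e6, "TRA", strand1 = "+", strand2 = "-"),
    mk_call("chr2", 3e6 + 5e4, "chr1", 2e6 + 80, "TRA",
            strand1 = "+", strand2 = "-"))
  tic_svs <- sv_calls(tic, g)
  gained <- rbind(flat_cnv[flat_cnv$chrom != "chr2", ],
                  data.frame(sample_id = "S1", chrom = "chr2",
                             start = c(1, 3e6, 3e6 + 5e4 + 1),
                             end = c(3e6 - 1, 3e6 + 5e4, 8e6),
                             copy_number = c(2, 3, 2)))
  expect_equal(classify_nonclustered(tic_svs, 1:2, gained, g, cfg),
               "templated_insertion_cycle")

  # junctions sharing no pairable ends: complex unclear
  far <- sv_calls(rbind(
    mk_call("chr1", 1e6, "chr1", 1.2e6, "DEL"),
    mk_call("chr1", 1.25e6, "chr1", 1.4e6, "DEL"),
    mk_call("chr1", 1.45e6, "chr1", 1.6e6, "DEL")), g)
  expect_equal(classify_nonclustered(far, 1:3, flat_cnv, g, cfg),
               "complex_unclear")
})
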