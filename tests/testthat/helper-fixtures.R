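# shared fixtures and independent oracles, built in code at test time

toy_genome <- function() {
  chroms <- data.frame(name = c("chr1", "chr2", "chr3"),
                       length = c(10e6, 8e6, 6e6))
  centromeres <- data.frame(chrom = chroms$name,
                            start = chroms$length / 2 - 5e4,
                            end = chroms$length / 2 + 5e4)
  telomeres <- data.frame(chrom = rep(chroms$name, 2),
                          pos = c(1, 1, 1, chroms$length))
  fragile <- data.frame(chrom = "chr1", start = 2e6, end = 2.1e6)
  genes <- data.frame(gene_id = c("GENEA", "GENEB"),
                      chrom = c("chr1", "chr1"),
                      strand = c("+", "-"))
  exons <- data.frame(
    gene_id = c("GENEA", "GENEA", "GENEA", "GENEB", "GENEB"),
    start = c(100000, 101000, 102000, 300000, 301500),
    end = c(100200, 101300, 102150, 300400, 301900))
  genome_model(chroms, centromeres, telomeres, fragile, genes, exons,
               braf_region = list(chrom = "chr2", start = 4e6, end = 7e6))
}

mk_call <- function(chrom1, pos1, chrom2, pos2, svtype,
                    caller = "manta", sample_id = "S1",
                    split_reads = 5, read_pairs = 5,
                    homology_len = NA, insertion_len = NA,
                    strand1 = NA, strand2 = NA) {
  data.frame(sample_id = sample_id, caller = caller,
             chrom1 = chrom1, pos1 = pos1, strand1 = strand1,
             chrom2 = chrom2, pos2 = pos2, strand2 = strand2,
             svtype = svtype, split_reads = split_reads,
             read_pairs = read_pairs, homology_len = homology_len,
             insertion_len = insertion_len, stringsAsFactors = FALSE)
}

mk_calls <- function(...) sv_calls(do.call(rbind, list(...)), toy_genome())

small_sim_config <- function(...) {
  args <- list(...)
  if (!"chrom_lengths" %in% names(args)) {
    args$chrom_lengths <- stats::setNames(c(60e6, 50e6, 40e6, 30e6),
                                          paste0("chr", 1:4))
  }
  do.call(simulation_config, args)
}

# ---- independent oracles -------------------------------------------------

# exhaustive consensus matching: all-pairs predicate + union-find, then
# component filtering by distinct-caller count
oracle_consensus_groups <- function(calls, match_distance = 10, min_callers = 2) {
  n <- nrow(calls)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    if (calls$caller[i] == calls$caller[j]) next
    ok <- calls$chrom1[i] == calls$chrom1[j] && calls$chrom2[i] == calls$chrom2[j] &&
      calls$strand1[i] == calls$strand1[j] && calls$strand2[i] == calls$strand2[j] &&
      abs(calls$pos1[i] - calls$pos1[j]) <= match_distance &&
      abs(calls$pos2[i] - calls$pos2[j]) <= match_distance
    if (ok) parent[find(i)] <- find(j)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)
  Filter(function(g) length(unique(calls$caller[g])) >= min_callers, groups)
}

# brute-force two-sample KS D: max ECDF difference over all pooled points
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# exhaustive two-sided Fisher p for a 2x2 table: sum of hypergeometric
# probabilities of all tables with probability <= that of the observed one
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# textbook two-group log-rank statistic: (sum(O-E))^2 / sum(V)
oracle_logrank_chisq <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- sort(unique(group))[1]
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}

# random fuzzed callset for consensus oracle comparisons
fuzz_callset <- function(n, seed) {
  with_seed_local(seed, {
    chroms <- sample(c("chr1", "chr2"), n, replace = TRUE)
    pos1 <- sample.int(1e6, n, replace = TRUE) + 1e4
    size <- sample.int(5e4, n, replace = TRUE) + 600
    # cluster some calls tightly so matches actually occur
    dup <- sample.int(n, size = ceiling(n / 2), replace = TRUE)
    idx <- sample.int(n, size = ceiling(n / 2))
    pos1[idx] <- pos1[dup] + sample(-15:15, length(idx), replace = TRUE)
    size[idx] <- size[dup] + sample(-15:15, length(idx), replace = TRUE)
    chroms[idx] <- chroms[dup]
    svtype <- sample(c("DEL", "DUP", "h2hINV", "t2tINV"), n, replace = TRUE)
    svtype[idx] <- svtype[dup]
    df <- data.frame(sample_id = "S1",
                     caller = sample(c("meerkat", "manta", "delly"), n, TRUE),
                     chrom1 = chroms, pos1 = pos1, strand1 = NA,
                     chrom2 = chroms, pos2 = pos1 + size, strand2 = NA,
                     svtype = svtype, split_reads = sample.int(20, n, TRUE),
                     read_pairs = sample.int(20, n, TRUE),
                     homology_len = NA, insertion_len = NA)
    sv_calls(df, toy_genome())
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# helper: planted signature matrix over the 49 subcategories
planted_signatures <- function(k = 9, seed = 99) {
  schema <- simple_sv_schema()
  with_seed_local(seed, {
    sigs <- signature_names()[seq_len(k)]
    W <- matrix(0, 49, k, dimnames = list(schema$subcategory, sigs))
    groups <- list(
      `Del0` = schema$subcategory[schema$signature == "Del0"],
      `Del1` = schema$subcategory[schema$signature == "Del1"],
      `Del2` = schema$subcategory[schema$signature == "Del2"],
      `TD` = setdiff(schema$subcategory[schema$signature == "TD"],
                     c("TD_1000000_1500000", "TD_1500000_2000000",
                       "TD_2000000_2500000")),
      `BRAF fusion` = c("TD_1000000_1500000", "TD_1500000_2000000",
                        "TD_2000000_2500000"),
      `Unbal inv` = schema$subcategory[schema$signature == "Unbal inv"],
      `Large mixed` = schema$subcategory[schema$signature == "Large mixed"],
      `Recip` = schema$subcategory[schema$signature == "Recip"],
      `Unbal tra` = schema$subcategory[schema$signature == "Unbal tra"])
    for (s in sigs) {
      w <- stats::runif(length(groups[[s]]), 0.5, 1.5)
      W[groups[[s]], s] <- w / sum(w)
    }
    W
  })
}

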