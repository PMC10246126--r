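# Genomic-feature enrichment testing: matched random SVs, breakpoint
# annotation, two-sided KS tests and BH FDR.

#' Generate matched random SVs for one observed SV
#'
#' Places `n` random SVs with the same chromosome(s), span and type as the
#' observed SV, positions uniform over feasible placements. For
#' translocations each breakend is redrawn uniformly on its own chromosome.
#'
#' @param sv one-row `sv_calls` data.frame.
#' @param genome `genome_model`.
#' @param n number of random SVs (default 4).
#' @param seed integer seed (deterministic placements).
#' @return `sv_calls` with `n` rows.
#' @export
generate_random_svs <- function(sv, genome, n = 4, seed = 1) {
  stopifnot(nrow(sv) == 1)
  with_seed(seed, {
    if (sv$chrom1 == sv$chrom2) {
      L <- chrom_length(genome, sv$chrom1)
      size <- abs(sv$pos2 - sv$pos1)
      if (size > L - 1) stopf("SV span %g exceeds chromosome %s length %g",
                              size, sv$chrom1, L)
      start <- floor(stats::runif(n, min = 1, max = L - size + 1))
      out <- sv[rep(1, n), , drop = FALSE]
      out$pos1 <- start
      out$pos2 <- start + size
    } else {
      L1 <- chrom_length(genome, sv$chrom1); L2 <- chrom_length(genome, sv$chrom2)
      out <- sv[rep(1, n), , drop = FALSE]
      out$pos1 <- floor(stats::runif(n, 1, L1 + 1))
      out$pos2 <- floor(stats::runif(n, 1, L2 + 1))
    }
    rownames(out) <- NULL
    class(out) <- c("sv_calls", "data.frame")
    out
  })
}

# matched random SVs for a whole table (per-row deterministic substreams)
generate_random_sv_table <- function(svs, genome, n = 4, seed = 1) {
  if (!nrow(svs)) return(svs)
  out <- lapply(seq_len(nrow(svs)), function(i)
    generate_random_svs(svs[i, , drop = FALSE], genome, n = n,
                        seed = substream_seed(seed, i)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate breakpoints with feature scores
#'
#' One score per breakend per feature: interval tracks give the
#' log-transformed distance (in the track's units; 0 inside an interval);
#' signal tracks give the annotated value at the position (0 where the track
#' has no value). GC content from a genome sequence, when available, is the
#' G+C fraction in a +/-50 bp window.
#'
#' @param breakends `data.frame(chrom, pos)` (see [sv_breakends()]).
#' @param tracks `feature_track_set`.
#' @param genome `genome_model` (bounds checking).
#' @return numeric matrix, breakends x features.
#' @export
annotate_breakpoints <- function(breakends, tracks, genome) {
  if (any(breakends$pos < 1 | breakends$pos > chrom_length(genome, breakends$chrom)))
    stopf("breakend outside chromosome bounds")
  scores <- vapply(tracks, function(t) {
    if (t$type == "interval") {
      d <- point_interval_distance(breakends$chrom, breakends$pos, t$data)
      d[is.infinite(d)] <- chrom_length(genome, breakends$chrom)[is.infinite(d)]
      du <- d / switch(t$units, kb = 1e3, Mb = 1e6, bp = 1,
                       stopf("unknown units '%s'", t$units))
      if (t$transform == "log") log(du + t$pseudocount) else du
    } else {
      annotate_signal(breakends, t$data)
    }
  }, numeric(nrow(breakends)))
  scores <- matrix(scores, nrow = nrow(breakends),
                   dimnames = list(NULL, names(tracks)))
  scores
}

# value of a step-function signal track at point positions (0 if uncovered)
annotate_signal <- function(breakends, data) {
  out <- numeric(nrow(breakends))
  for (chr in unique(breakends$chrom)) {
    qi <- which(breakends$chrom == chr)
    s <- data[data$chrom == chr, , drop = FALSE]
    if (!nrow(s)) next
    s <- s[order(s$start), , drop = FALSE]
    idx <- findInterval(breakends$pos[qi], s$start)
    val <- numeric(length(qi))
    cov <- idx >= 1
    cov[cov] <- breakends$pos[qi][cov] <= s$end[idx[cov]]
    val[cov] <- s$value[idx[cov]]
    out[qi] <- val
  }
  out
}

#' GC fraction around breakpoints
#'
#' @param breakends `data.frame(chrom, pos)`.
#' @param sequence named character vector of chromosome sequences.
#' @param flank window half-width in bp (default 50).
#' @return numeric vector of G+C fractions.
#' @export
gc_content <- function(breakends, sequence, flank = 50) {
  vapply(seq_len(nrow(breakends)), function(i) {
    s <- sequence[[breakends$chrom[i]]]
    lo <- max(1, breakends$pos[i] - flank)
    hi <- min(nchar(s), breakends$pos[i] + flank)
    win <- toupper(substr(s, lo, hi))
    n <- nchar(win)
    if (!n) return(NA_real_)
    gc <- n - nchar(gsub("[GC]", "", win))
    gc / n
  }, numeric(1))
}

#' Two-sided KS comparison of observed vs random breakpoint scores
#'
#' Scores are rescaled jointly to \[0, 1\] (min-max over the pooled sample)
#' and compared by a two-sided two-sample Kolmogorov-Smirnov test. Direction
#' is the sign of (median observed - median random). Constant pooled scores
#' give D = 0, p = 1.
#'
#' @param observed,random numeric score vectors.
#' @return list with `D`, `p`, `direction`, `n_observed`, `n_random`.
#' @export
ks_association_test <- function(observed, random) {
  stopifnot(length(observed) > 0, length(random) > 0)
  pool <- c(observed, random)
  rng <- range(pool)
  if (rng[2] - rng[1] < .Machine$double.eps) {
    return(list(D = 0, p = 1, direction = 0,
                n_observed = length(observed), n_random = length(random)))
  }
  obs <- (observed - rng[1]) / (rng[2] - rng[1])
  rnd <- (random - rng[1]) / (rng[2] - rng[1])
  kt <- suppressWarnings(stats::ks.test(obs, rnd, alternative = "two.sided"))
  list(D = unname(kt$statistic), p = kt$p.value,
       direction = sign(stats::median(obs) - stats::median(rnd)),
       n_observed = length(observed), n_random = length(random))
}

#' Benjamini-Hochberg correction over an association grid
#'
#' @param results data.frame with a `p` column (one row per
#'   signature x feature test).
#' @param q_cutoff FDR cutoff for the `significant` flag (default 0.1).
#' @return `results` with `q` and `significant` columns.
#' @export
fdr_correct <- function(results, q_cutoff = 0.1) {
  results$q <- stats::p.adjust(results$p, method = "BH")
  results$significant <- results$q < q_cutoff
  results
}

#' Signature x feature enrichment scan
#'
#' For each signature, pools its breakpoints across samples, generates
#' `n_random` matched random SVs per observed SV, annotates both sets over
#' all feature tracks, and runs the two-sided KS test per feature; BH FDR is
#' applied over the full signature x feature grid.
#'
#' @param svs labeled SVs (`sv_calls` rows with a `signature` column).
#' @param tracks `feature_track_set`.
#' @param genome `genome_model`.
#' @param n_random matched random SVs per observed SV (default 4).
#' @param seed integer seed for the randomization.
#' @param q_cutoff FDR cutoff (default 0.1).
#' @return long data.frame: `signature`, `feature`, `D`, `p`, `q`,
#'   `direction`, `significant`, `n_observed`, `n_random`.
#' @export
sv_feature_assoc <- function(svs, tracks, genome, n_random = 4, seed = 1,
                             q_cutoff = 0.1) {
  res <- list()
  for (sig in sort(unique(svs$signature))) {
    obs <- svs[svs$signature == sig, , drop = FALSE]
    rnd <- generate_random_sv_table(obs, genome, n = n_random,
                                    seed = substream_seed(seed, nchar(sig) + sum(utf8ToInt(sig))))
    obs_sc <- annotate_breakpoints(sv_breakends(obs)[, c("chrom", "pos")], tracks, genome)
    rnd_sc <- annotate_breakpoints(sv_breakends(rnd)[, c("chrom", "pos")], tracks, genome)
    for (feat in colnames(obs_sc)) {
      kt <- ks_association_test(obs_sc[, feat], rnd_sc[, feat])
      res[[length(res) + 1L]] <- data.frame(
        signature = sig, feature = feat, D = kt$D, p = kt$p,
        direction = kt$direction, n_observed = kt$n_observed,
        n_random = kt$n_random, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res) %||% data.frame(
    signature = character(), feature = character(), D = numeric(),
    p = numeric(), direction = numeric(), n_observed = integer(),
    n_random = integer())
  fdr_correct(out, q_cutoff)
}

#' Default 31-feature manifest skeleton
#'
#' Names and types of the default genomic-feature panel: GC content, seven
#' non-B DNA structure classes, eight repeat classes, centromere and telomere
#' distance (Mb), CpG islands, TAD boundaries, ten histone marks
#' (signal, -log10 p) and one replication-timing signal; 31 features in all.
#' Interval distances are log-transformed in the stated units.
#'
#' @return data.frame with `name`, `type`, `units` for the 31 features.
#' @export
default_feature_manifest <- function() {
  nonb <- c("A_phased_repeat", "direct_repeat", "G_quadruplex",
            "inverted_repeat", "mirror_repeat", "short_tandem_repeat",
            "Z_DNA_motif")
  repeats <- c("Alu", "L1", "L2", "LTR", "MIR", "simple_repeat",
               "DNA_transposon", "low_complexity")
  histones <- c("H3K4me1", "H3K9me3", "H3K36me3", "H3K4me3", "H3K27me3",
                "H3K9ac", "H3K4me2", "H3K79me2", "H3K27ac", "H4K20me1")
  rbind(
    data.frame(name = "GC_content", type = "signal", units = "bp"),
    data.frame(name = nonb, type = "interval", units = "kb"),
    data.frame(name = repeats, type = "interval", units = "kb"),
    data.frame(name = c("centromere", "telomere"), type = "interval", units = "Mb"),
    data.frame(name = "CpG_island", type = "interval", units = "kb"),
    data.frame(name = "TAD_boundary", type = "interval", units = "kb"),
    data.frame(name = histones, type = "signal", units = "bp"),
    data.frame(name = "replication_timing", type = "signal", units = "bp")
  )
}
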