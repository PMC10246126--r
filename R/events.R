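#' Event-classification configuration
#'
#' Parameters of the simplified event clustering and the rule-based complex
#' labels. The clustering links two junctions when the gap between their
#' footprints is improbably small under uniform placement (`p_cluster`,
#' Bonferroni-adjusted over junction pairs per sample). An event is
#' clustered-complex when it has at least `min_clustered_junctions` junctions
#' and its breakpoint density exceeds the sample background by
#' `density_factor`. The six-way clustered labels and the chromoplexy /
#' templated-insertion-cycle junction patterns are explicit decision rules,
#' documented surrogates for the published clustering tools.
#'
#' @param p_cluster footprint-gap probability threshold for linking.
#' @param min_clustered_junctions minimum junctions of a clustered event.
#' @param density_factor breakpoint-density enrichment over background.
#' @param pair_distance breakend pairing distance (bp) for chain/cycle
#'   detection and reciprocal pairs.
#' @param max_bridge maximal bridged-segment span (bp) for cycle detection.
#' @param amplification_threshold copy number calling an amplification.
#' @param loss_fraction,gain_fraction footprint fraction lost/gained for the
#'   Large loss / Large gain labels.
#' @param large_footprint minimal footprint span (bp) of Large loss/gain.
#' @param oscillation_fraction two-state segment share for oscillation.
#' @param minor_state_fraction minimal length-weighted share of the less
#'   common of the two dominant copy-number states for a footprint to count
#'   as oscillating (separates chromothripsis-like alternation from sporadic
#'   small losses).
#' @param telomere_window bp window at chromosome ends checked for
#'   telomere-loss evidence (Chr bridge vs Micronuclei split).
#' @param cn_baseline diploid baseline copy number.
#' @param cn_tol copy-number tolerance around the baseline.
#' @param missing_cnv_label clustered label used when no CNV data exist.
#' @return list of class `event_config`.
#' @export
event_config <- function(p_cluster = 1e-3,
                         min_clustered_junctions = 6,
                         density_factor = 5,
                         pair_distance = 1000,
                         max_bridge = 10e6,
                         amplification_threshold = 8,
                         loss_fraction = 0.5,
                         gain_fraction = 0.5,
                         large_footprint = 10e6,
                         oscillation_fraction = 0.7,
                         minor_state_fraction = 0.25,
                         telomere_window = 1e6,
                         cn_baseline = 2,
                         cn_tol = 0.3,
                         missing_cnv_label = "Hourglass") {
  structure(as.list(environment()), class = "event_config")
}

clustered_labels <- function() {
  c("ecDNA", "Micronuclei", "Chr bridge", "Large loss", "Large gain", "Hourglass")
}
nonclustered_labels <- function() {
  c("chromoplexy", "templated_insertion_cycle", "complex_unclear")
}

# footprint intervals of one junction: data.frame(chrom, start, end)
junction_footprints <- function(svs, i) {
  if (svs$chrom1[i] == svs$chrom2[i]) {
    data.frame(chrom = svs$chrom1[i],
               start = min(svs$pos1[i], svs$pos2[i]),
               end = max(svs$pos1[i], svs$pos2[i]))
  } else {
    data.frame(chrom = c(svs$chrom1[i], svs$chrom2[i]),
               start = c(svs$pos1[i], svs$pos2[i]),
               end = c(svs$pos1[i], svs$pos2[i]))
  }
}

# merged footprint of a junction set
event_footprint <- function(svs, idx) {
  fp <- do.call(rbind, lapply(idx, function(i) junction_footprints(svs, i)))
  gr <- GenomicRanges::reduce(iv_granges(fp))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Group one sample's junctions into candidate events
#'
#' Single-linkage agglomeration: two junctions are linked when, on some
#' shared chromosome, the gap between their footprints has probability below
#' the per-sample Bonferroni-adjusted `p_cluster` under uniform placement
#' (`p = 2 * gap / chromosome length`; overlapping footprints always link).
#' Connected components become events; isolated junctions are candidate
#' simple SVs.
#'
#' @param svs one sample's consensus `sv_calls`.
#' @param genome `genome_model`.
#' @param config [event_config()].
#' @return integer vector of event membership ids, one per junction row.
#' @export
cluster_events <- function(svs, genome, config = event_config()) {
  n <- nrow(svs)
  if (!n) return(integer())
  if (n == 1) return(1L)
  fps <- lapply(seq_len(n), function(i) junction_footprints(svs, i))
  alpha <- config$p_cluster / max(1, choose(n, 2))
  edges <- matrix(integer(), ncol = 2)
  # per-chromosome sweep over footprint intervals
  flat <- do.call(rbind, lapply(seq_len(n), function(i) cbind(fps[[i]], j = i)))
  ee <- list()
  for (chr in unique(flat$chrom)) {
    sub <- flat[flat$chrom == chr, , drop = FALSE]
    if (nrow(sub) < 2) next
    L <- chrom_length(genome, chr)
    gmax <- L * alpha / 2
    sub <- sub[order(sub$start), , drop = FALSE]
    for (a in seq_len(nrow(sub) - 1)) {
      b <- a + 1L
      while (b <= nrow(sub) && sub$start[b] - sub$end[a] <= gmax) {
        if (sub$j[a] != sub$j[b]) ee[[length(ee) + 1L]] <- c(sub$j[a], sub$j[b])
        b <- b + 1L
      }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(ee)) g <- igraph::add_edges(g, t(do.call(rbind, ee)))
  as.integer(igraph::components(g)$membership)
}

# --- breakend pairing / junction chain machinery -------------------------

# CN over an interval from a sample's CNV segments: length-weighted mean,
# NA when uncovered
interval_mean_cn <- function(cnv, chrom, start, end) {
  if (is.null(cnv) || !nrow(cnv)) return(NA_real_)
  s <- cnv[cnv$chrom == chrom & cnv$end >= start & cnv$start <= end, , drop = FALSE]
  if (!nrow(s)) return(NA_real_)
  w <- pmin(s$end, end) - pmax(s$start, start) + 1
  sum(s$copy_number * w) / sum(w)
}

# candidate pairing edges between breakends of different junctions in `idx`.
# Type "pair": opposite orientations within pair_distance (a balanced join).
# Type "bridge": facing breakends (left '-', right '+') spanning <= max_bridge
# whose intervening segment is copy-gained.
junction_chain_edges <- function(svs, idx, cnv, config,
                                 bridge_min_cn = NULL) {
  be <- sv_breakends(svs[idx, , drop = FALSE])
  be$junction <- idx[be$row]
  be$key <- paste0(be$row, ":", be$end)
  edges <- list()
  baseline <- config$cn_baseline
  min_gain <- bridge_min_cn %||% (baseline + config$cn_tol)
  for (chr in unique(be$chrom)) {
    sub <- be[be$chrom == chr, , drop = FALSE]
    if (nrow(sub) < 2) next
    for (a in seq_len(nrow(sub) - 1)) for (b in seq((a + 1), nrow(sub))) {
      if (sub$junction[a] == sub$junction[b]) next
      d <- abs(sub$pos[a] - sub$pos[b])
      if (sub$strand[a] != sub$strand[b] && d <= config$pair_distance) {
        edges[[length(edges) + 1L]] <- data.frame(
          a = sub$key[a], b = sub$key[b], ja = sub$junction[a], jb = sub$junction[b],
          type = "pair", dist = d, chrom = chr,
          pos_a = sub$pos[a], pos_b = sub$pos[b], stringsAsFactors = FALSE)
      } else if (d > config$pair_distance && d <= config$max_bridge) {
        left <- if (sub$pos[a] <= sub$pos[b]) a else b
        right <- if (left == a) b else a
        if (sub$strand[left] == "-" && sub$strand[right] == "+") {
          cn <- interval_mean_cn(cnv, chr, sub$pos[left], sub$pos[right])
          if (!is.na(cn) && cn >= min_gain) {
            edges[[length(edges) + 1L]] <- data.frame(
              a = sub$key[a], b = sub$key[b], ja = sub$junction[a], jb = sub$junction[b],
              type = "bridge", dist = d, chrom = chr,
              pos_a = sub$pos[a], pos_b = sub$pos[b], stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  do.call(rbind, edges) %||%
    data.frame(a = character(), b = character(), ja = integer(), jb = integer(),
               type = character(), dist = numeric(), chrom = character(),
               pos_a = numeric(), pos_b = numeric())
}

# greedy mutual matching of breakends (each used once): pair edges before
# bridges, closer first. Returns the accepted edge table.
match_chain_edges <- function(edges) {
  if (!nrow(edges)) return(edges)
  edges <- edges[order(edges$type != "pair", edges$dist), , drop = FALSE]
  used <- character()
  keep <- logical(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    if (edges$a[i] %in% used || edges$b[i] %in% used) next
    keep[i] <- TRUE
    used <- c(used, edges$a[i], edges$b[i])
  }
  edges[keep, , drop = FALSE]
}

# chain topology of a junction set: list(closed=, path=, n_edges=, chroms=,
# bridges=) given matched edges
chain_topology <- function(svs, idx, matched) {
  n <- length(idx)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(matched)) {
    g <- igraph::add_edges(g, rbind(match(matched$ja, idx), match(matched$jb, idx)))
  }
  deg <- igraph::degree(g)
  connected <- igraph::is_connected(g)
  m <- igraph::ecount(g)
  list(closed = connected && m == n && all(deg == 2),
       path = connected && m == n - 1 && all(deg <= 2) && n >= 2,
       n_edges = m,
       n_bridges = sum(matched$type == "bridge"),
       chroms = length(unique(c(svs$chrom1[idx], svs$chrom2[idx]))))
}

# is a junction set circularizable through pairs and (optionally amplified)
# bridges?
is_cyclic_junctions <- function(svs, idx, cnv, config, bridge_min_cn = NULL) {
  edges <- junction_chain_edges(svs, idx, cnv, config, bridge_min_cn)
  matched <- match_chain_edges(edges)
  chain_topology(svs, idx, matched)$closed
}

# reciprocal inversion / translocation partner test for a 2-junction set
is_reciprocal_pair <- function(svs, i, j, pair_distance) {
  ti <- svs$svtype[i]; tj <- svs$svtype[j]
  close1 <- abs(svs$pos1[i] - svs$pos1[j]) <= pair_distance
  close2 <- abs(svs$pos2[i] - svs$pos2[j]) <= pair_distance
  same_chrom <- svs$chrom1[i] == svs$chrom1[j] && svs$chrom2[i] == svs$chrom2[j]
  if (!same_chrom || !close1 || !close2) return(FALSE)
  if (setequal(c(ti, tj), c("h2hINV", "t2tINV"))) return(TRUE)
  if (ti == "TRA" && tj == "TRA") {
    return(svs$strand1[i] != svs$strand1[j] && svs$strand2[i] != svs$strand2[j])
  }
  FALSE
}

# copy-number summary of an event footprint
event_cn_summary <- function(footprint, cnv, config) {
  base <- config$cn_baseline; tol <- config$cn_tol
  if (is.null(cnv) || !nrow(cnv)) {
    return(list(frac_lost = NA_real_, frac_gained = NA_real_,
                max_cn = NA_real_, two_state_frac = NA_real_,
                n_states = NA_integer_, n_segments = 0L))
  }
  segs <- list()
  for (k in seq_len(nrow(footprint))) {
    s <- cnv[cnv$chrom == footprint$chrom[k] &
               cnv$end >= footprint$start[k] & cnv$start <= footprint$end[k], ,
             drop = FALSE]
    if (nrow(s)) {
      s$start <- pmax(s$start, footprint$start[k])
      s$end <- pmin(s$end, footprint$end[k])
      segs[[length(segs) + 1L]] <- s
    }
  }
  if (!length(segs)) {
    return(list(frac_lost = NA_real_, frac_gained = NA_real_,
                max_cn = NA_real_, two_state_frac = NA_real_,
                osc_frac = NA_real_, n_states = NA_integer_, n_segments = 0L))
  }
  s <- do.call(rbind, segs)
  s <- s[order(s$chrom, s$start), , drop = FALSE]
  w <- s$end - s$start + 1
  total <- sum(w)
  states <- round(s$copy_number * 2) / 2  # half-integer CN states
  tab <- sort(tapply(rep(1, length(states)), states, sum), decreasing = TRUE)
  two_state <- sum(tab[seq_len(min(2, length(tab)))]) / length(states)
  # genuine two-state oscillation devotes a substantial share of the
  # footprint to each of the two dominant states; sporadic small losses
  # (hourglass-like) leave the minor state with little territory
  w_by_state <- sort(tapply(w, states, sum), decreasing = TRUE)
  minor <- if (length(w_by_state) >= 2)
    w_by_state[2] / sum(w_by_state[1:2]) else 0
  list(frac_lost = sum(w[s$copy_number < base - tol]) / total,
       frac_gained = sum(w[s$copy_number > base + tol]) / total,
       max_cn = max(s$copy_number),
       two_state_frac = two_state,
       minor_state_frac = unname(minor),
       n_states = length(tab),
       n_segments = nrow(s))
}

# telomere-loss evidence: any footprint chromosome whose terminal window
# (either end) is copy-lost
has_telomere_loss <- function(footprint, cnv, genome, config) {
  if (is.null(cnv) || !nrow(cnv)) return(FALSE)
  for (chr in unique(footprint$chrom)) {
    L <- chrom_length(genome, chr)
    for (win in list(c(1, config$telomere_window),
                     c(L - config$telomere_window + 1, L))) {
      cn <- interval_mean_cn(cnv, chr, win[1], win[2])
      if (!is.na(cn) && cn < config$cn_baseline - config$cn_tol) return(TRUE)
    }
  }
  FALSE
}

#' Label a clustered-complex event
#'
#' Explicit decision tree over the event's copy-number footprint:
#' amplification at or above `amplification_threshold` on a circularizable
#' junction set gives "ecDNA"; a footprint of at least `large_footprint` with
#' at least half its length lost (gained) gives "Large loss" ("Large gain");
#' two-state copy-number oscillation over at least `oscillation_fraction` of
#' segments gives "Micronuclei", or "Chr bridge" with telomere-loss evidence;
#' everything else is "Hourglass". These rules are a documented surrogate for
#' the published clustering-based classifier, not a reproduction of it.
#'
#' @param svs sample's consensus `sv_calls`.
#' @param idx row indices of the event's member junctions.
#' @param cnv the sample's CNV segments (may be `NULL`).
#' @param genome `genome_model`.
#' @param config [event_config()].
#' @return one of `clustered_labels()`.
#' @export
classify_clustered <- function(svs, idx, cnv, genome, config = event_config()) {
  fp <- event_footprint(svs, idx)
  if (is.null(cnv) || !nrow(cnv)) {
    warnf("no CNV data for sample %s: clustered event labeled '%s'",
          svs$sample_id[idx[1]], config$missing_cnv_label)
    return(config$missing_cnv_label)
  }
  cs <- event_cn_summary(fp, cnv, config)
  fp_len <- sum(fp$end - fp$start + 1)
  if (!is.na(cs$max_cn) && cs$max_cn >= config$amplification_threshold &&
      is_cyclic_junctions(svs, idx, cnv, config,
                          bridge_min_cn = config$amplification_threshold)) {
    return("ecDNA")
  }
  if (!is.na(cs$frac_lost) && cs$frac_lost >= config$loss_fraction &&
      fp_len >= config$large_footprint) return("Large loss")
  if (!is.na(cs$frac_gained) && cs$frac_gained >= config$gain_fraction &&
      fp_len >= config$large_footprint) return("Large gain")
  if (!is.na(cs$two_state_frac) && cs$n_segments >= 3 && cs$n_states >= 2 &&
      cs$two_state_frac >= config$oscillation_fraction &&
      cs$minor_state_frac >= config$minor_state_fraction) {
    if (has_telomere_loss(fp, cnv, genome, config)) return("Chr bridge")
    return("Micronuclei")
  }
  "Hourglass"
}

#' Label a non-clustered multi-junction event
#'
#' Junction-pattern rules: a closed or near-closed chain of >= 3 junctions
#' across >= 2 chromosomes whose breakends pair head-to-tail through balanced
#' joins is "chromoplexy"; a closed junction cycle routed through at least one
#' copy-gained bridged segment is "templated_insertion_cycle"; anything else
#' is "complex_unclear".
#'
#' @inheritParams classify_clustered
#' @return one of `nonclustered_labels()`.
#' @export
classify_nonclustered <- function(svs, idx, cnv, genome, config = event_config()) {
  edges <- junction_chain_edges(svs, idx, cnv, config)
  matched <- match_chain_edges(edges)
  topo <- chain_topology(svs, idx, matched)
  if (topo$closed && topo$n_bridges > 0) return("templated_insertion_cycle")
  if ((topo$closed || topo$path) && length(idx) >= 3 && topo$chroms >= 2 &&
      topo$n_bridges == 0 && chain_joins_balanced(svs, matched, cnv, config)) {
    return("chromoplexy")
  }
  "complex_unclear"
}

# are all matched pair-joins copy-balanced? Checks the mean copy number in a
# 20 kb window around each join locus against the baseline; samples with no
# CNV data count as balanced.
chain_joins_balanced <- function(svs, matched, cnv, config, window = 10e3) {
  if (is.null(cnv) || !nrow(cnv) || !nrow(matched)) return(TRUE)
  pairs <- matched[matched$type == "pair", , drop = FALSE]
  if (!nrow(pairs)) return(TRUE)
  for (i in seq_len(nrow(pairs))) {
    mid <- (pairs$pos_a[i] + pairs$pos_b[i]) / 2
    cn <- interval_mean_cn(cnv, pairs$chrom[i], mid - window, mid + window)
    if (!is.na(cn) && abs(cn - config$cn_baseline) > config$cn_tol) return(FALSE)
  }
  TRUE
}

#' Partition consensus SVs into events and classify them
#'
#' Runs [cluster_events()] per sample, decides clustered vs non-clustered vs
#' simple, and assigns complex labels. Two-junction events forming reciprocal
#' inversion/translocation pairs are classed simple (they are consumed as one
#' reciprocal SV by the simple-SV catalog).
#'
#' @param svs consensus `sv_calls` for the cohort.
#' @param cnv_segments CNV segment table (all samples) or `NULL`.
#' @param genome `genome_model`.
#' @param config [event_config()].
#' @return list with `svs` (input plus `event_id`, `event_class`,
#'   `complex_label` columns) and `events` (one row per event with footprint
#'   span and copy-number summary).
#' @export
classify_events <- function(svs, cnv_segments, genome, config = event_config()) {
  svs$event_id <- NA_character_
  svs$event_class <- NA_character_
  svs$complex_label <- NA_character_
  events <- list()
  if (!nrow(svs)) {
    return(list(svs = svs, events = data.frame(
      event_id = character(), sample_id = character(), event_class = character(),
      complex_label = character(), n_junctions = integer(),
      footprint_bp = numeric(), frac_lost = numeric(), frac_gained = numeric(),
      max_cn = numeric(), two_state_frac = numeric())))
  }
  genome_len <- sum(genome$chromosomes$length)
  for (sample in unique(svs$sample_id)) {
    rows <- which(svs$sample_id == sample)
    sub <- svs[rows, , drop = FALSE]
    cnv <- if (!is.null(cnv_segments))
      cnv_segments[cnv_segments$sample_id == sample, , drop = FALSE] else NULL
    membership <- cluster_events(sub, genome, config)
    bg_density <- (2 * nrow(sub)) / genome_len
    for (ev in unique(membership)) {
      idx <- which(membership == ev)
      gidx <- rows[idx]
      eid <- sprintf("%s_ev%03d", sample, ev)
      fp <- event_footprint(sub, idx)
      fp_len <- sum(fp$end - fp$start + 1)
      density <- (2 * length(idx)) / max(fp_len, 1)
      if (length(idx) >= config$min_clustered_junctions &&
          density >= config$density_factor * bg_density) {
        cls <- "clustered_complex"
        lab <- classify_clustered(sub, idx, cnv, genome, config)
      } else if (length(idx) == 1) {
        cls <- "simple"; lab <- NA_character_
      } else if (length(idx) == 2 &&
                 is_reciprocal_pair(sub, idx[1], idx[2], config$pair_distance)) {
        cls <- "simple"; lab <- NA_character_
      } else {
        cls <- "nonclustered_complex"
        lab <- classify_nonclustered(sub, idx, cnv, genome, config)
      }
      svs$event_id[gidx] <- eid
      svs$event_class[gidx] <- cls
      svs$complex_label[gidx] <- lab
      cs <- event_cn_summary(fp, cnv, config)
      events[[length(events) + 1L]] <- data.frame(
        event_id = eid, sample_id = sample, event_class = cls,
        complex_label = lab, n_junctions = length(idx), footprint_bp = fp_len,
        frac_lost = cs$frac_lost, frac_gained = cs$frac_gained,
        max_cn = cs$max_cn, two_state_frac = cs$two_state_frac,
        stringsAsFactors = FALSE)
    }
  }
  list(svs = svs, events = do.call(rbind, events))
}
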