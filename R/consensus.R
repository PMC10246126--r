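#' Consensus-calling configuration
#'
#' Thresholds for merging per-caller callsets into high-confidence SVs.
#' Defaults follow the published filtering rules: breakends match within
#' 10 bp with identical orientations; at least 2 supporting callers; Delly
#' calls shorter than 500 bp need >= 4 combined read pairs + split reads;
#' cDNA-artifact deletions are dropped when both breakends sit within 3 bp of
#' exon-intron boundaries of one gene; an SV is CNV-validated when both
#' breakends are < 1 kb from the nearest CNV breakpoint.
#'
#' @param match_distance breakend matching tolerance in bp (<= comparison).
#' @param min_callers minimum distinct supporting callers.
#' @param delly_min_support minimum `split_reads + read_pairs` for short Delly
#'   calls.
#' @param delly_support_max_size span below which the Delly support filter
#'   applies (bp).
#' @param delly_caller caller id the support filter applies to.
#' @param exon_boundary_tolerance bp tolerance of the cDNA-artifact filter.
#' @param cnv_validation_distance bp distance for CNV validation (strict `<`).
#' @param canonical_only drop calls touching non-canonical chromosomes.
#' @param caller_priority caller order used to break representative-call ties.
#' @return list of class `consensus_config`.
#' @export
consensus_config <- function(match_distance = 10,
                             min_callers = 2,
                             delly_min_support = 4,
                             delly_support_max_size = 500,
                             delly_caller = "delly",
                             exon_boundary_tolerance = 3,
                             cnv_validation_distance = 1000,
                             canonical_only = TRUE,
                             caller_priority = c("meerkat", "manta", "delly")) {
  stopifnot(match_distance > 0, min_callers > 0, delly_min_support > 0,
            exon_boundary_tolerance > 0, cnv_validation_distance > 0)
  structure(list(match_distance = match_distance, min_callers = min_callers,
                 delly_min_support = delly_min_support,
                 delly_support_max_size = delly_support_max_size,
                 delly_caller = delly_caller,
                 exon_boundary_tolerance = exon_boundary_tolerance,
                 cnv_validation_distance = cnv_validation_distance,
                 canonical_only = canonical_only,
                 caller_priority = caller_priority),
            class = "consensus_config")
}

#' Pre-filter raw caller calls
#'
#' Applies the caller-level filters that precede matching: the Delly support
#' filter (short calls need >= `delly_min_support` combined read pairs and
#' split reads; other callers are exempt) and the canonical-chromosome filter.
#'
#' @param calls `sv_calls` data.frame (one or more callers).
#' @param config [consensus_config()].
#' @param genome optional `genome_model` (defines the canonical set; the
#'   built-in chr1-22/X/Y set is used without one).
#' @return filtered `sv_calls`.
#' @export
prefilter_calls <- function(calls, config = consensus_config(), genome = NULL) {
  if (!nrow(calls)) return(calls)
  keep <- rep(TRUE, nrow(calls))
  if (config$canonical_only) {
    canon <- if (!is.null(genome)) genome$chromosomes$name else canonical_chromosomes()
    keep <- keep & calls$chrom1 %in% canon & calls$chrom2 %in% canon
  }
  is_delly <- !is.na(calls$caller) & calls$caller == config$delly_caller
  span <- sv_size(calls)
  short <- !is.na(span) & span < config$delly_support_max_size
  support <- ifelse(is.na(calls$split_reads), 0, calls$split_reads) +
    ifelse(is.na(calls$read_pairs), 0, calls$read_pairs)
  keep <- keep & !(is_delly & short & support < config$delly_min_support)
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# TRUE where calls i and j satisfy the identity predicate: same chromosome
# pair, same orientation pair, and both positional differences <= match_distance
calls_match <- function(calls, i, j, match_distance) {
  calls$chrom1[i] == calls$chrom1[j] & calls$chrom2[i] == calls$chrom2[j] &
    calls$strand1[i] == calls$strand1[j] & calls$strand2[i] == calls$strand2[j] &
    abs(calls$pos1[i] - calls$pos1[j]) <= match_distance &
    abs(calls$pos2[i] - calls$pos2[j]) <= match_distance
}

# candidate pairs within tolerance on breakend 1, by sorted-position sweep
candidate_pairs <- function(calls, match_distance) {
  n <- nrow(calls)
  if (n < 2) return(cbind(i = integer(), j = integer()))
  key <- paste(calls$chrom1, calls$chrom2, calls$strand1, calls$strand2)
  res_i <- integer(); res_j <- integer()
  for (idx in split(seq_len(n), key)) {
    if (length(idx) < 2) next
    idx <- idx[order(calls$pos1[idx])]
    p <- calls$pos1[idx]
    for (a in seq_along(idx)[-length(idx)]) {
      b <- a + 1L
      while (b <= length(idx) && p[b] - p[a] <= match_distance) {
        res_i <- c(res_i, idx[a]); res_j <- c(res_j, idx[b])
        b <- b + 1L
      }
    }
  }
  cbind(i = res_i, j = res_j)
}

# collapse within-caller duplicates (same predicate), keeping higher support
collapse_within_caller <- function(calls, config) {
  if (nrow(calls) < 2) return(calls)
  drop <- rep(FALSE, nrow(calls))
  pairs <- candidate_pairs(calls, config$match_distance)
  if (nrow(pairs)) {
    same_caller <- calls$caller[pairs[, 1]] == calls$caller[pairs[, 2]]
    ok <- calls_match(calls, pairs[, 1], pairs[, 2], config$match_distance)
    pairs <- pairs[same_caller & ok, , drop = FALSE]
    if (nrow(pairs)) {
      support <- ifelse(is.na(calls$split_reads), 0, calls$split_reads) +
        ifelse(is.na(calls$read_pairs), 0, calls$read_pairs)
      g <- igraph::graph_from_edgelist(matrix(as.character(pairs), ncol = 2),
                                       directed = FALSE)
      comp <- igraph::components(g)
      for (members in split(as.integer(igraph::V(g)$name),
                            comp$membership)) {
        if (length(members) < 2) next
        keep_one <- members[which.max(support[members])]
        drop[setdiff(members, keep_one)] <- TRUE
      }
    }
  }
  out <- calls[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match calls across callers into consensus SVs
#'
#' Builds a graph over prefiltered calls of one sample with edges between
#' calls from different callers satisfying the matching predicate (same
#' chromosomes and orientations, both breakends within `match_distance`), and
#' takes connected components. Components with at least `min_callers` distinct
#' callers are emitted as consensus SVs; caller-specific components are
#' discarded. Within-caller duplicates are collapsed first (higher support
#' wins). The representative breakends come from the highest-support member
#' call, ties broken by caller priority then genome order.
#'
#' @param calls prefiltered `sv_calls` of a single sample.
#' @param config [consensus_config()].
#' @return consensus `sv_calls` with columns `callers` (comma-separated
#'   supporting caller set), `n_callers`, `cnv_validated` (initialized `NA`);
#'   matched member calls are attached as attribute `"members"`.
#' @export
match_calls <- function(calls, config = consensus_config()) {
  calls <- collapse_within_caller(calls, config)
  n <- nrow(calls)
  if (!n) {
    out <- calls
    out$callers <- character(0); out$n_callers <- integer(0)
    out$cnv_validated <- logical(0)
    return(out)
  }
  pairs <- candidate_pairs(calls, config$match_distance)
  if (nrow(pairs)) {
    cross <- calls$caller[pairs[, 1]] != calls$caller[pairs[, 2]]
    ok <- calls_match(calls, pairs[, 1], pairs[, 2], config$match_distance)
    pairs <- pairs[cross & ok, , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(pairs)) g <- igraph::add_edges(g, t(pairs))
  membership <- igraph::components(g)$membership

  support <- ifelse(is.na(calls$split_reads), 0, calls$split_reads) +
    ifelse(is.na(calls$read_pairs), 0, calls$read_pairs)
  prio <- match(calls$caller, config$caller_priority)
  prio[is.na(prio)] <- length(config$caller_priority) + 1L

  groups <- split(seq_len(n), membership)
  rows <- list(); members <- list()
  for (grp in groups) {
    caller_set <- sort(unique(calls$caller[grp]))
    if (length(caller_set) < config$min_callers) next
    ord <- grp[order(-support[grp], prio[grp], calls$pos1[grp], calls$pos2[grp])]
    rep_call <- calls[ord[1], , drop = FALSE]
    rep_call$callers <- paste(caller_set, collapse = ",")
    rep_call$n_callers <- length(caller_set)
    rep_call$cnv_validated <- NA
    rows[[length(rows) + 1L]] <- rep_call
    m <- calls[grp, , drop = FALSE]
    m$consensus_id <- length(rows)
    members[[length(members) + 1L]] <- m
  }
  if (!length(rows)) {
    out <- calls[0, , drop = FALSE]
    out$callers <- character(0); out$n_callers <- integer(0)
    out$cnv_validated <- logical(0)
    attr(out, "members") <- calls[0, , drop = FALSE]
    class(out) <- c("sv_calls", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  ord <- order(out$chrom1, out$pos1, out$chrom2, out$pos2)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "members") <- do.call(rbind, members)
  class(out) <- c("sv_calls", "data.frame")
  out
}

#' Remove cDNA-contamination deletion artifacts
#'
#' Deletions whose two breakends both lie within `exon_boundary_tolerance` bp
#' of exon-intron boundaries of the same gene are excluded; all other types
#' pass through.
#'
#' @param svs consensus `sv_calls`.
#' @param genome `genome_model` carrying gene/exon models.
#' @param config [consensus_config()].
#' @return filtered consensus table.
#' @export
filter_cdna_artifacts <- function(svs, genome, config = consensus_config()) {
  if (!nrow(svs)) return(svs)
  bounds <- exon_intron_boundaries(genome)
  if (!nrow(bounds)) return(svs)
  tol <- config$exon_boundary_tolerance
  genes <- genome$genes
  drop <- vapply(seq_len(nrow(svs)), function(i) {
    if (svs$svtype[i] != "DEL") return(FALSE)
    gchr <- genes$chrom[match(bounds$gene_id, genes$gene_id)]
    near1 <- bounds$gene_id[gchr == svs$chrom1[i] &
                              abs(bounds$pos - svs$pos1[i]) <= tol]
    if (!length(near1)) return(FALSE)
    near2 <- bounds$gene_id[gchr == svs$chrom2[i] &
                              abs(bounds$pos - svs$pos2[i]) <= tol]
    length(intersect(near1, near2)) > 0
  }, logical(1))
  out <- svs[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "members") <- attr(svs, "members")
  out
}

# CNV breakpoints per sample/chromosome: boundaries between adjacent segments
# with differing copy number, plus segment boundaries adjacent to uncovered
# regions. Returns data.frame(sample_id, chrom, pos).
cnv_breakpoints <- function(segments, tol = 1e-9) {
  if (!nrow(segments)) {
    return(data.frame(sample_id = character(), chrom = character(), pos = numeric()))
  }
  segments <- segments[order(segments$sample_id, segments$chrom, segments$start), ]
  out <- lapply(split(segments, paste(segments$sample_id, segments$chrom, sep = "\r")),
                function(s) {
    n <- nrow(s)
    pos <- numeric()
    # boundary with uncovered region before the first / after the last segment
    pos <- c(pos, s$start[1], s$end[n])
    if (n > 1) {
      adjacent <- s$start[-1] == s$end[-n] + 1
      differ <- abs(s$copy_number[-1] - s$copy_number[-n]) > tol
      # junction between consecutive covered segments with CN change,
      # or any gap in coverage
      take <- differ | !adjacent
      pos <- c(pos, s$end[-n][take], s$start[-1][take & !adjacent])
    }
    data.frame(sample_id = s$sample_id[1], chrom = s$chrom[1],
               pos = sort(unique(pos)), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag CNV-validated consensus SVs
#'
#' Sets `cnv_validated = TRUE` when both breakends lie strictly within
#' `cnv_validation_distance` of the nearest CNV breakpoint on their
#' chromosome. Annotation only; no records are removed. Samples without CNV
#' data get `FALSE` with a warning.
#'
#' @param svs consensus `sv_calls` (with `sample_id` set).
#' @param cnv_segments CNV segment data.frame (as [read_cnv_segments()]).
#' @param config [consensus_config()].
#' @return `svs` with the `cnv_validated` column filled.
#' @export
cnv_validate <- function(svs, cnv_segments, config = consensus_config()) {
  if (!nrow(svs)) { svs$cnv_validated <- logical(0); return(svs) }
  bp <- cnv_breakpoints(cnv_segments)
  maxd <- config$cnv_validation_distance
  nearest <- function(sample, chrom, pos) {
    cand <- bp$pos[bp$sample_id == sample & bp$chrom == chrom]
    if (!length(cand)) return(Inf)
    min(abs(cand - pos))
  }
  no_cnv <- setdiff(unique(svs$sample_id), unique(bp$sample_id))
  if (length(no_cnv)) warnf("no CNV data for sample(s) %s; cnv_validated set FALSE",
                            paste(no_cnv, collapse = ", "))
  svs$cnv_validated <- vapply(seq_len(nrow(svs)), function(i) {
    d1 <- nearest(svs$sample_id[i], svs$chrom1[i], svs$pos1[i])
    d2 <- nearest(svs$sample_id[i], svs$chrom2[i], svs$pos2[i])
    d1 < maxd && d2 < maxd
  }, logical(1))
  svs
}

#' Full consensus stage for one or more samples
#'
#' Runs prefilter, cross-caller matching, the cDNA-artifact filter and CNV
#' validation per sample, concatenating the results.
#'
#' @param calls `sv_calls` from all callers (with `sample_id` and `caller`).
#' @param genome `genome_model`.
#' @param cnv_segments optional CNV segment table for validation.
#' @param config [consensus_config()].
#' @return consensus `sv_calls` with `callers`, `n_callers`, `cnv_validated`.
#' @export
sv_consensus <- function(calls, genome, cnv_segments = NULL,
                         config = consensus_config()) {
  calls <- prefilter_calls(calls, config, genome)
  per_sample <- split(calls, calls$sample_id)
  res <- lapply(per_sample, function(cs) {
    cons <- match_calls(cs, config)
    filter_cdna_artifacts(cons, genome, config)
  })
  out <- do.call(rbind, res) %||% {
    z <- empty_sv_calls(); z$callers <- character(0)
    z$n_callers <- integer(0); z$cnv_validated <- logical(0); z
  }
  rownames(out) <- NULL
  if (!is.null(cnv_segments)) out <- cnv_validate(out, cnv_segments, config)
  else if (nrow(out)) out$cnv_validated <- NA
  class(out) <- c("sv_calls", "data.frame")
  out
}
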