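# Hotspot binning, mutation-signature association, breakpoint homology
# spectra, survival stratification and cohort summary statistics.

#' Per-signature hotspot tracks over 1 Mb bins
#'
#' Tiles each chromosome with non-overlapping bins starting at position 1
#' (the final partial bin is kept) and counts, per signature and bin, the
#' number of distinct samples with at least one breakpoint of that signature
#' in the bin; multiple breakpoints of one sample in one bin count once.
#'
#' @param svs labeled SVs (`sv_calls` rows with `signature` and `sample_id`).
#' @param genome `genome_model`.
#' @param bin_size bin width in bp (default 1e6).
#' @return data.frame: `signature`, `chrom`, `start`, `end`, `n_samples`.
#' @export
hotspot_counts <- function(svs, genome, bin_size = 1e6) {
  bins <- do.call(rbind, lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    L <- genome$chromosomes$length[i]
    start <- seq(1, L, by = bin_size)
    data.frame(chrom = genome$chromosomes$name[i], start = start,
               end = pmin(start + bin_size - 1, L), stringsAsFactors = FALSE)
  }))
  out <- list()
  be <- sv_breakends(svs)
  be$signature <- rep(svs$signature, 2L)
  be <- be[!is.na(be$signature), , drop = FALSE]
  for (sig in sort(unique(be$signature))) {
    sub <- be[be$signature == sig, , drop = FALSE]
    bin_idx <- paste(sub$chrom, (sub$pos - 1) %/% bin_size)
    key <- paste(sub$sample_id, bin_idx)
    uniq <- !duplicated(key)
    counts <- table(bin_idx[uniq])
    b <- bins
    b$signature <- sig
    b$n_samples <- as.integer(counts[paste(b$chrom, (b$start - 1) %/% bin_size)])
    b$n_samples[is.na(b$n_samples)] <- 0L
    out[[length(out) + 1L]] <- b[, c("signature", "chrom", "start", "end", "n_samples")]
  }
  do.call(rbind, out) %||% data.frame(signature = character(), chrom = character(),
                                      start = numeric(), end = numeric(),
                                      n_samples = integer())
}

#' Mutation-signature association tests
#'
#' Within each tumor type (hypermutated samples excluded first), tests each
#' protein-coding gene mutated in at least `min_freq` of the type's samples
#' against each signature's presence/absence with a two-sided Fisher exact
#' test on the 2x2 table; BH FDR over all tests.
#'
#' @param samples sample sheet (see [read_sample_sheet()]).
#' @param signature_presence logical matrix, samples x signatures
#'   (rownames = sample ids).
#' @param min_freq minimal within-type mutation frequency (default 0.05).
#' @param q_cutoff FDR cutoff (default 0.1).
#' @return data.frame: `tumor_type`, `gene`, `signature`, 2x2 cell counts,
#'   `p`, `q`, `significant`.
#' @export
mutation_association <- function(samples, signature_presence, min_freq = 0.05,
                                 q_cutoff = 0.1) {
  samples <- samples[!samples$hypermutated, , drop = FALSE]
  muts <- parse_mutations(samples)
  res <- list()
  for (tt in sort(unique(samples$tumor_type))) {
    ss <- samples[samples$tumor_type == tt, , drop = FALSE]
    if (nrow(ss) < 2) { warnf("tumor type %s has < 2 samples; skipped", tt); next }
    mt <- muts[muts$sample_id %in% ss$sample_id, , drop = FALSE]
    gene_freq <- table(unique(mt[, c("sample_id", "gene")])$gene) / nrow(ss)
    genes <- names(gene_freq)[gene_freq >= min_freq]
    sp <- signature_presence[rownames(signature_presence) %in% ss$sample_id, ,
                             drop = FALSE]
    for (gene in genes) {
      mutated <- ss$sample_id %in% mt$sample_id[mt$gene == gene]
      names(mutated) <- ss$sample_id
      for (sig in colnames(sp)) {
        present <- stats::setNames(rep(FALSE, nrow(ss)), ss$sample_id)
        present[rownames(sp)] <- sp[, sig]
        tab <- table(factor(present, levels = c(TRUE, FALSE)),
                     factor(mutated[names(present)], levels = c(TRUE, FALSE)))
        p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
        res[[length(res) + 1L]] <- data.frame(
          tumor_type = tt, gene = gene, signature = sig,
          sig_mut = tab[1, 1], sig_nomut = tab[1, 2],
          nosig_mut = tab[2, 1], nosig_nomut = tab[2, 2],
          p = p, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, res) %||% data.frame(
    tumor_type = character(), gene = character(), signature = character(),
    sig_mut = integer(), sig_nomut = integer(), nosig_mut = integer(),
    nosig_nomut = integer(), p = numeric())
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < q_cutoff
  rownames(out) <- NULL
  out
}

homology_categories <- function() {
  c("insertion_gt10bp", "insertion_1_10bp", "blunt", "microhomology_1bp",
    "microhomology_2bp", "microhomology_3bp", "microhomology_4bp",
    "microhomology_5plus")
}

#' Breakpoint homology/insertion spectra per signature
#'
#' Histograms each signature's SVs over the junction-sequence categories
#' (insertion > 10 bp, insertion 1-10 bp, blunt ends, 1/2/3/4 bp
#' microhomology, 5+ bp microhomology). Insertions take precedence over
#' homology; SVs with neither annotation known are excluded.
#'
#' @param svs labeled SVs with `homology_len`, `insertion_len`, `signature`.
#' @param by optional grouping column name (e.g. `"tumor_type"` after
#'   joining) for a per-group breakdown.
#' @return data.frame: `signature` (, `by` group), `category`, `count`.
#' @export
homology_spectrum <- function(svs, by = NULL) {
  known <- !(is.na(svs$homology_len) & is.na(svs$insertion_len))
  svs <- svs[known & !is.na(svs$signature), , drop = FALSE]
  ins <- ifelse(is.na(svs$insertion_len), 0, svs$insertion_len)
  hom <- ifelse(is.na(svs$homology_len), 0, svs$homology_len)
  cat <- ifelse(ins > 10, "insertion_gt10bp",
         ifelse(ins >= 1, "insertion_1_10bp",
         ifelse(hom == 0, "blunt",
         ifelse(hom >= 5, "microhomology_5plus",
                paste0("microhomology_", hom, "bp")))))
  cat <- factor(cat, levels = homology_categories())
  if (is.null(by)) {
    tab <- as.data.frame(table(signature = svs$signature, category = cat),
                         stringsAsFactors = FALSE)
  } else {
    tab <- as.data.frame(table(signature = svs$signature, group = svs[[by]],
                               category = cat), stringsAsFactors = FALSE)
  }
  names(tab)[names(tab) == "Freq"] <- "count"
  tab
}

#' Survival stratification by SV signature
#'
#' Within one tumor type: clustered-complex signatures are compared by a
#' multi-group log-rank test over the groups {each single signature, Mixed
#' (more than one signature), None}; simple signatures by two-group
#' presence/absence log-rank tests. Groups that would be empty are skipped
#' with a warning.
#'
#' @param samples sample sheet rows of one tumor type with `survival_time`
#'   and `survival_event`.
#' @param presence logical matrix samples x signatures (rownames = sample
#'   ids) of the signature family under test.
#' @param grouping `"clustered"` (single/Mixed/None multi-group) or
#'   `"simple"` (per-signature presence/absence).
#' @return data.frame: `signature` (or `"clustered_complex"` for the
#'   multi-group test), `chisq`, `df`, `p`, `n`.
#' @export
survival_stratification <- function(samples, presence,
                                    grouping = c("simple", "clustered")) {
  grouping <- match.arg(grouping)
  ok <- !is.na(samples$survival_time) & samples$survival_event %in%
    c("death", "censored")
  samples <- samples[ok, , drop = FALSE]
  surv_obj <- function(s) survival::Surv(s$survival_time,
                                         s$survival_event == "death")
  pres <- matrix(FALSE, nrow(samples), ncol(presence),
                 dimnames = list(samples$sample_id, colnames(presence)))
  common <- intersect(samples$sample_id, rownames(presence))
  pres[common, ] <- presence[common, , drop = FALSE]

  logrank <- function(time_event, group) {
    sd <- survival::survdiff(time_event ~ group)
    df <- length(unique(group)) - 1
    data.frame(chisq = sd$chisq, df = df,
               p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
               n = length(group))
  }

  if (grouping == "clustered") {
    n_sig <- rowSums(pres)
    group <- rep("None", nrow(samples))
    one <- which(n_sig == 1)
    group[one] <- colnames(pres)[apply(pres[one, , drop = FALSE], 1, which)]
    group[n_sig > 1] <- "Mixed"
    sizes <- table(group)
    if (length(sizes) < 2) {
      warnf("fewer than two survival groups; comparison skipped")
      return(data.frame(signature = character(), chisq = numeric(),
                        df = integer(), p = numeric(), n = integer()))
    }
    out <- logrank(surv_obj(samples), group)
    return(cbind(data.frame(signature = "clustered_complex"), out))
  }

  res <- list()
  for (sig in colnames(pres)) {
    g <- pres[, sig]
    if (all(g) || !any(g)) {
      warnf("signature %s: a presence/absence group is empty; skipped", sig)
      next
    }
    out <- logrank(surv_obj(samples), ifelse(g, "present", "absent"))
    res[[length(res) + 1L]] <- cbind(data.frame(signature = sig), out)
  }
  do.call(rbind, res) %||% data.frame(signature = character(), chisq = numeric(),
                                      df = integer(), p = numeric(), n = integer())
}

#' Cohort summary statistics
#'
#' Counts and percentages of clustered-complex, non-clustered-complex and
#' simple SVs, complex events, and samples carrying each class, for the whole
#' cohort and per tumor type. Percentages are count/total, half-up rounded to
#' one decimal; an empty cohort yields a zero table.
#'
#' @param svs event-annotated SVs (`event_class` column).
#' @param events events table from [classify_events()].
#' @param samples sample sheet.
#' @return list with `overall` (one-row data.frame) and `by_type`.
#' @export
cohort_summary <- function(svs, events, samples) {
  summarize <- function(svs, events, ids) {
    n_sv <- nrow(svs)
    per_sample <- table(factor(svs$sample_id, levels = ids))
    cl <- sum(svs$event_class == "clustered_complex", na.rm = TRUE)
    ncl <- sum(svs$event_class == "nonclustered_complex", na.rm = TRUE)
    sim <- sum(svs$event_class == "simple", na.rm = TRUE)
    has_complex <- unique(svs$sample_id[svs$event_class %in%
                            c("clustered_complex", "nonclustered_complex")])
    has_cl <- unique(svs$sample_id[svs$event_class == "clustered_complex"])
    has_ncl <- unique(svs$sample_id[svs$event_class == "nonclustered_complex"])
    n_samples <- length(ids)
    data.frame(
      n_samples = n_samples, n_sv = n_sv,
      median_sv_per_sample = if (n_samples) stats::median(as.integer(per_sample)) else 0,
      n_clustered = cl, pct_clustered = pct(cl, n_sv),
      n_nonclustered = ncl, pct_nonclustered = pct(ncl, n_sv),
      n_simple = sim, pct_simple = pct(sim, n_sv),
      n_clustered_events = if (is.null(events)) 0L else
        sum(events$event_class == "clustered_complex"),
      n_nonclustered_events = if (is.null(events)) 0L else
        sum(events$event_class == "nonclustered_complex"),
      n_samples_clustered = length(has_cl),
      pct_samples_clustered = pct(length(has_cl), n_samples),
      n_samples_nonclustered = length(has_ncl),
      pct_samples_nonclustered = pct(length(has_ncl), n_samples),
      n_samples_no_complex = n_samples - length(has_complex),
      pct_samples_no_complex = pct(n_samples - length(has_complex), n_samples))
  }
  ids <- samples$sample_id
  overall <- summarize(svs, events, ids)
  by_type <- do.call(rbind, lapply(sort(unique(samples$tumor_type)), function(tt) {
    tids <- samples$sample_id[samples$tumor_type == tt]
    sub <- svs[svs$sample_id %in% tids, , drop = FALSE]
    ev <- if (is.null(events)) NULL else
      events[events$sample_id %in% tids, , drop = FALSE]
    cbind(data.frame(tumor_type = tt), summarize(sub, ev, tids))
  }))
  list(overall = overall, by_type = by_type)
}
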