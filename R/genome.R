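#' Genome model
#'
#' Container for the reference layout every pipeline stage shares: ordered
#' chromosomes with lengths, centromere intervals, telomere anchor positions,
#' fragile-site intervals, gene/exon models and (optionally) the interval used
#' by the BRAF-fusion rule. All coordinates are 1-based inclusive.
#'
#' @param chromosomes `data.frame(name, length)`; order defines genome order.
#' @param centromeres `data.frame(chrom, start, end)`, one row per chromosome
#'   (may be a subset).
#' @param telomeres `data.frame(chrom, pos)`; typically two anchors per
#'   chromosome (1 and the chromosome length).
#' @param fragile_sites `data.frame(chrom, start, end)` fragile-site regions.
#' @param genes `data.frame(gene_id, chrom, strand)` gene table.
#' @param exons `data.frame(gene_id, start, end)` exon intervals, 1-based
#'   inclusive, non-overlapping and sorted within each gene.
#' @param braf_region optional `list(chrom=, start=, end=)` interval for the
#'   BRAF-fusion tandem-duplication rule; `NULL` disables the rule.
#' @param canonical_only if `TRUE`, chromosome names must come from
#'   chr1-chr22, chrX, chrY.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(chromosomes,
                         centromeres = NULL,
                         telomeres = NULL,
                         fragile_sites = NULL,
                         genes = NULL,
                         exons = NULL,
                         braf_region = NULL,
                         canonical_only = TRUE) {
  stopifnot(is.data.frame(chromosomes), all(c("name", "length") %in% names(chromosomes)))
  chromosomes$name <- as.character(chromosomes$name)
  chromosomes$length <- as.numeric(chromosomes$length)
  if (anyDuplicated(chromosomes$name)) stopf("duplicated chromosome names")
  if (any(chromosomes$length < 1)) stopf("chromosome lengths must be >= 1")
  if (canonical_only) {
    bad <- setdiff(chromosomes$name, canonical_chromosomes())
    if (length(bad)) {
      stopf("non-canonical chromosome name(s): %s (allowed: chr1-chr22, chrX, chrY)",
            paste(bad, collapse = ", "))
    }
  }
  empty_iv <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                         stringsAsFactors = FALSE)
  g <- structure(list(
    chromosomes = chromosomes,
    centromeres = centromeres %||% empty_iv,
    telomeres = telomeres %||% data.frame(chrom = character(), pos = numeric()),
    fragile_sites = fragile_sites %||% empty_iv,
    genes = genes %||% data.frame(gene_id = character(), chrom = character(),
                                  strand = character()),
    exons = exons %||% data.frame(gene_id = character(), start = numeric(),
                                  end = numeric()),
    braf_region = braf_region,
    canonical_only = canonical_only
  ), class = "genome_model")
  validate_genome(g)
  g
}

canonical_chromosomes <- function() c(paste0("chr", 1:22), "chrX", "chrY")

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$name)
  if (anyNA(i)) stopf("unknown chromosome(s): %s",
                      paste(unique(chrom[is.na(i)]), collapse = ", "))
  genome$chromosomes$length[i]
}

# integer rank of a chromosome in genome order, used for breakend ordering
chrom_rank <- function(genome, chrom) match(chrom, genome$chromosomes$name)

validate_genome <- function(g) {
  check_iv <- function(df, what) {
    if (!nrow(df)) return(invisible())
    if (any(df$start > df$end)) stopf("%s with start > end", what)
    len <- chrom_length(g, df$chrom)
    if (any(df$start < 1) || any(df$end > len))
      stopf("%s outside [1, chromosome length]", what)
  }
  check_iv(g$centromeres, "centromere interval")
  check_iv(g$fragile_sites, "fragile-site interval")
  if (nrow(g$telomeres)) {
    len <- chrom_length(g, g$telomeres$chrom)
    if (any(g$telomeres$pos < 1) || any(g$telomeres$pos > len))
      stopf("telomere anchor outside chromosome")
  }
  if (nrow(g$exons)) {
    sp <- split(g$exons, g$exons$gene_id)
    for (gene in names(sp)) {
      e <- sp[[gene]]
      e <- e[order(e$start), ]
      if (any(e$start > e$end)) stopf("exon with start > end in gene %s", gene)
      if (nrow(e) > 1 && any(e$start[-1] <= e$end[-nrow(e)]))
        stopf("overlapping exons in gene %s", gene)
    }
  }
  invisible(g)
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %d chromosomes, %.1f Mb total\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6))
  cat(sprintf("  genes: %d | fragile sites: %d | centromeres: %d\n",
              nrow(x$genes), nrow(x$fragile_sites), nrow(x$centromeres)))
  invisible(x)
}

# exon-intron boundary positions for every gene: data.frame(gene_id, pos).
# Boundaries are exon starts and ends, excluding the outermost gene ends
# (transcript termini are not splice boundaries).
exon_intron_boundaries <- function(genome) {
  ex <- genome$exons
  if (!nrow(ex)) return(data.frame(gene_id = character(), pos = numeric()))
  sp <- split(ex, ex$gene_id)
  out <- lapply(names(sp), function(gid) {
    e <- sp[[gid]][order(sp[[gid]]$start), ]
    if (nrow(e) < 2) return(NULL)
    pos <- sort(c(e$end[-nrow(e)], e$start[-1]))
    data.frame(gene_id = gid, pos = pos)
  })
  do.call(rbind, out) %||% data.frame(gene_id = character(), pos = numeric())
}

# GRanges view of an interval data.frame(chrom, start, end)
iv_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
}

# merge an interval data.frame into disjoint sorted intervals per chromosome
merge_intervals <- function(ivs) {
  lapply(split(ivs[, c("start", "end")], ivs$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1) {
      grp <- cumsum(c(1, d$start[-1] > cummax(d$end[-nrow(d)]) + 1))
      d <- data.frame(start = tapply(d$start, grp, min),
                      end = tapply(d$end, grp, max))
    }
    d
  })
}

# distance (bp) from points to the nearest interval of a track; 0 inside.
# Points with no interval on any chromosome get Inf. Plain sorted-sweep
# lookup: this sits in the Monte-Carlo hot path, where per-call S4 container
# overhead dominates.
point_interval_distance <- function(chrom, pos, ivs) {
  d <- rep(Inf, length(pos))
  if (!nrow(ivs)) return(d)
  merged <- merge_intervals(ivs)
  for (chr in intersect(unique(chrom), names(merged))) {
    m <- merged[[chr]]
    qi <- which(chrom == chr)
    idx <- findInterval(pos[qi], m$start)
    left <- ifelse(idx >= 1, pos[qi] - m$end[pmax(idx, 1)], Inf)
    inside <- idx >= 1 & left <= 0
    right <- ifelse(idx < nrow(m), m$start[pmin(idx + 1, nrow(m))] - pos[qi], Inf)
    d[qi] <- ifelse(inside, 0, pmin(pmax(left, 0), right))
  }
  d
}

# TRUE for points lying inside any interval of the track
point_in_interval <- function(chrom, pos, ivs) {
  point_interval_distance(chrom, pos, ivs) == 0
}
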