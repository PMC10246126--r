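#' Structural variant call tables
#'
#' SV junctions are kept in a plain data.frame with one row per junction and
#' columns `sample_id`, `caller`, `chrom1`, `pos1`, `strand1`, `chrom2`,
#' `pos2`, `strand2`, `svtype`, `split_reads`, `read_pairs`, `homology_len`,
#' `insertion_len`. Coordinates are 1-based; breakend 1 never follows breakend
#' 2 in genome order.
#'
#' Breakend orientation encodes the direction of the retained (joined)
#' segment: `+` means it extends leftward from the position, `-` rightward.
#' The type/orientation correspondence is fixed:
#' DEL = (-,+), DUP = (+,-), h2hINV = (-,-), t2tINV = (+,+); TRA spans two
#' chromosomes with any orientation pair.
#'
#' @param df data.frame with at least the coordinate/type columns; missing
#'   metadata columns are added as NA.
#' @param genome optional `genome_model` used to validate positions and order
#'   breakends.
#' @return validated, breakend-ordered data.frame of class `c("sv_calls","data.frame")`.
#' @export
sv_calls <- function(df, genome = NULL) {
  req <- c("chrom1", "pos1", "chrom2", "pos2", "svtype")
  miss <- setdiff(req, names(df))
  if (length(miss)) stopf("sv_calls: missing column(s) %s", paste(miss, collapse = ", "))
  defaults <- list(sample_id = NA_character_, caller = NA_character_,
                   strand1 = NA_character_, strand2 = NA_character_,
                   split_reads = NA_real_, read_pairs = NA_real_,
                   homology_len = NA_real_, insertion_len = NA_real_)
  for (nm in names(defaults)) if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  df <- df[, sv_call_columns()]
  df$pos1 <- as.numeric(df$pos1); df$pos2 <- as.numeric(df$pos2)

  need <- is.na(df$strand1) | is.na(df$strand2)
  if (any(need)) {
    o <- svtype_orientations(df$svtype[need])
    df$strand1[need] <- o$strand1
    df$strand2[need] <- o$strand2
  }
  df <- normalize_breakend_order(df, genome)
  validate_sv_calls(df, genome)
  class(df) <- c("sv_calls", "data.frame")
  df
}

sv_call_columns <- function() {
  c("sample_id", "caller", "chrom1", "pos1", "strand1",
    "chrom2", "pos2", "strand2", "svtype",
    "split_reads", "read_pairs", "homology_len", "insertion_len")
}

sv_types <- function() c("DEL", "DUP", "h2hINV", "t2tINV", "TRA")

# canonical orientation pair for each intra-chromosomal svtype
svtype_orientations <- function(svtype) {
  map <- list(DEL = c("-", "+"), DUP = c("+", "-"),
              h2hINV = c("-", "-"), t2tINV = c("+", "+"),
              TRA = c("-", "+"))  # TRA default; real orientation kept if given
  bad <- setdiff(unique(svtype), names(map))
  if (length(bad)) stopf("unknown svtype: %s", paste(bad, collapse = ", "))
  m <- do.call(rbind, map[svtype])
  list(strand1 = m[, 1], strand2 = m[, 2])
}

# svtype implied by an orientation pair on one chromosome
orientations_svtype <- function(strand1, strand2, same_chrom) {
  out <- rep("TRA", length(strand1))
  key <- paste0(strand1, strand2)
  intra <- same_chrom
  out[intra & key == "-+"] <- "DEL"
  out[intra & key == "+-"] <- "DUP"
  out[intra & key == "--"] <- "h2hINV"
  out[intra & key == "++"] <- "t2tINV"
  out
}

# enforce breakend_a <= breakend_b in genome order (swap rows where needed)
normalize_breakend_order <- function(df, genome = NULL) {
  r1 <- if (!is.null(genome)) chrom_rank(genome, df$chrom1) else
    match(df$chrom1, unique(c(df$chrom1, df$chrom2)))
  r2 <- if (!is.null(genome)) chrom_rank(genome, df$chrom2) else
    match(df$chrom2, unique(c(df$chrom1, df$chrom2)))
  swap <- r2 < r1 | (r1 == r2 & df$pos2 < df$pos1)
  if (any(swap)) {
    tmp <- df[swap, c("chrom1", "pos1", "strand1")]
    df[swap, c("chrom1", "pos1", "strand1")] <- df[swap, c("chrom2", "pos2", "strand2")]
    df[swap, c("chrom2", "pos2", "strand2")] <- tmp
  }
  df
}

validate_sv_calls <- function(df, genome = NULL) {
  bad <- setdiff(unique(df$svtype), sv_types())
  if (length(bad)) stopf("unknown svtype: %s", paste(bad, collapse = ", "))
  intra <- df$chrom1 == df$chrom2
  if (any(df$svtype == "TRA" & intra))
    stopf("TRA call with both breakends on one chromosome")
  if (any(df$svtype != "TRA" & !intra))
    stopf("intra-chromosomal svtype with breakends on two chromosomes")
  exp <- svtype_orientations(df$svtype[df$svtype != "TRA"])
  sub <- df[df$svtype != "TRA", ]
  if (nrow(sub) && (any(sub$strand1 != exp$strand1) || any(sub$strand2 != exp$strand2)))
    stopf("orientation pair inconsistent with svtype")
  if (!is.null(genome)) {
    l1 <- chrom_length(genome, df$chrom1); l2 <- chrom_length(genome, df$chrom2)
    if (any(df$pos1 < 1 | df$pos1 > l1 | df$pos2 < 1 | df$pos2 > l2))
      stopf("breakend position outside [1, chromosome length]")
  }
  invisible(df)
}

# span of an intra-chromosomal junction (NA for TRA)
sv_size <- function(df) {
  ifelse(df$chrom1 == df$chrom2, abs(df$pos2 - df$pos1), NA_real_)
}

# long table of breakends: one row per junction end
sv_breakends <- function(df) {
  n <- nrow(df)
  data.frame(
    row = rep(seq_len(n), 2L),
    end = rep(1:2, each = n),
    sample_id = rep(df$sample_id, 2L),
    chrom = c(df$chrom1, df$chrom2),
    pos = c(df$pos1, df$pos2),
    strand = c(df$strand1, df$strand2),
    stringsAsFactors = FALSE
  )
}

#' @export
print.sv_calls <- function(x, ...) {
  cat(sprintf("<sv_calls> %d junctions, %d sample(s), %d caller(s)\n",
              nrow(x), length(unique(x$sample_id)),
              length(unique(stats::na.omit(x$caller)))))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

empty_sv_calls <- function() {
  df <- data.frame(sample_id = character(), caller = character(),
                   chrom1 = character(), pos1 = numeric(), strand1 = character(),
                   chrom2 = character(), pos2 = numeric(), strand2 = character(),
                   svtype = character(), split_reads = numeric(),
                   read_pairs = numeric(), homology_len = numeric(),
                   insertion_len = numeric(), stringsAsFactors = FALSE)
  class(df) <- c("sv_calls", "data.frame")
  df
}
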