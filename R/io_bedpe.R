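#' Read an SV callset (BEDPE or VCF)
#'
#' Reads one caller's junctions into the internal `sv_calls` table. BEDPE
#' coordinates (0-based half-open) are converted to internal 1-based breakend
#' positions (`pos = start + 1`); VCF positions are used as-is. Each junction
#' appears exactly once (VCF breakend mate pairs collapse to one row).
#'
#' @param path file path.
#' @param caller_id caller identifier stored in the `caller` column.
#' @param dialect `"auto"` (default; sniffs a `##fileformat=VCF` header),
#'   `"bedpe"` or `"vcf"`.
#' @param sample_id optional sample identifier; otherwise taken from the file
#'   where present.
#' @param genome optional `genome_model` for validation.
#' @return `sv_calls` data.frame.
#' @export
read_sv_callset <- function(path, caller_id = NA_character_,
                            dialect = c("auto", "bedpe", "vcf"),
                            sample_id = NULL, genome = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    first <- readLines(path, n = 1L)
    dialect <- if (length(first) && grepl("^##fileformat=VCF", first)) "vcf" else "bedpe"
  }
  calls <- if (dialect == "vcf") read_sv_vcf(path) else read_sv_bedpe(path)
  if (nrow(calls)) {
    calls$caller <- caller_id
    if (!is.null(sample_id)) calls$sample_id <- sample_id
  }
  sv_calls(calls, genome)
}

bedpe_columns <- function() {
  c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
    "name", "score", "strand1", "strand2")
}

read_sv_bedpe <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  if (!any(keep)) return(empty_sv_calls())
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 10L)) {
    stopf("%s line %d: BEDPE record has %d fields (need >= 10)",
          path, lineno[which(nf < 10L)[1]], min(nf))
  }
  get <- function(i) vapply(fields, `[`, "", i)
  opt <- function(i) {
    v <- vapply(fields, function(f) if (length(f) >= i) f[[i]] else NA_character_, "")
    suppressWarnings(as.numeric(v))
  }
  s1 <- suppressWarnings(as.numeric(get(2))); e1 <- suppressWarnings(as.numeric(get(3)))
  s2 <- suppressWarnings(as.numeric(get(5))); e2 <- suppressWarnings(as.numeric(get(6)))
  bad <- which(is.na(s1) | is.na(e1) | is.na(s2) | is.na(e2))
  if (length(bad)) stopf("%s line %d: non-numeric BEDPE coordinates", path, lineno[bad[1]])
  svtype <- get(7)
  unknown <- setdiff(unique(svtype), sv_types())
  if (length(unknown)) {
    stopf("%s line %d: unknown svtype '%s'", path,
          lineno[which(svtype %in% unknown)[1]], unknown[1])
  }
  strand1 <- get(9); strand2 <- get(10)
  strand1[!strand1 %in% c("+", "-")] <- NA_character_
  strand2[!strand2 %in% c("+", "-")] <- NA_character_
  sid <- vapply(fields, function(f) if (length(f) >= 15L) f[[15]] else NA_character_, "")
  data.frame(
    sample_id = sid, caller = NA_character_,
    chrom1 = get(1), pos1 = s1 + 1, strand1 = strand1,
    chrom2 = get(4), pos2 = s2 + 1, strand2 = strand2,
    svtype = svtype,
    split_reads = opt(11), read_pairs = opt(12),
    homology_len = opt(13), insertion_len = opt(14),
    stringsAsFactors = FALSE
  )
}

#' Write SV junctions as BEDPE
#'
#' Inverse of the BEDPE reader: internal 1-based breakend positions become
#' width-1 0-based half-open intervals. Extra columns 11-15 carry split reads,
#' read pairs, homology length, insertion length and sample id so that
#' write-then-read is lossless.
#'
#' @param svs `sv_calls` data.frame.
#' @param path output path.
#' @export
write_sv_bedpe <- function(svs, path) {
  hdr <- paste0("#", paste(c(bedpe_columns(), "split_reads", "read_pairs",
                             "homology_len", "insertion_len", "sample_id"),
                           collapse = "\t"))
  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, scientific = FALSE, trim = TRUE))
  rows <- if (nrow(svs)) {
    paste(svs$chrom1, format(svs$pos1 - 1, scientific = FALSE, trim = TRUE),
          format(svs$pos1, scientific = FALSE, trim = TRUE),
          svs$chrom2, format(svs$pos2 - 1, scientific = FALSE, trim = TRUE),
          format(svs$pos2, scientific = FALSE, trim = TRUE),
          svs$svtype, ".", svs$strand1, svs$strand2,
          fmt_num(svs$split_reads), fmt_num(svs$read_pairs),
          fmt_num(svs$homology_len), fmt_num(svs$insertion_len),
          ifelse(is.na(svs$sample_id), ".", svs$sample_id),
          sep = "\t")
  } else character()
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write consensus SVs with annotations
#'
#' BEDPE with extra columns for the supporting-caller set, the CNV-validation
#' flag and (when present) event/class/signature annotations. Records on
#' non-canonical chromosomes are refused.
#'
#' @param svs consensus table from [sv_consensus()] (optionally annotated by
#'   later stages).
#' @param path output path.
#' @export
write_consensus <- function(svs, path) {
  if (nrow(svs)) {
    bad <- setdiff(unique(c(svs$chrom1, svs$chrom2)), canonical_chromosomes())
    if (length(bad)) stopf("consensus records on non-canonical chromosome(s): %s",
                           paste(bad, collapse = ", "))
  }
  ann_cols <- c("callers", "cnv_validated", "event_id", "event_class",
                "complex_label", "subcategory", "signature")
  hdr <- paste0("#", paste(c(bedpe_columns(), "split_reads", "read_pairs",
                             "homology_len", "insertion_len", "sample_id",
                             ann_cols), collapse = "\t"))
  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, scientific = FALSE, trim = TRUE))
  fmt_chr <- function(x) ifelse(is.na(x) | x == "", ".", as.character(x))
  ann <- lapply(ann_cols, function(cn) {
    v <- svs[[cn]]
    if (is.null(v)) rep(".", nrow(svs))
    else if (is.logical(v)) ifelse(is.na(v), ".", ifelse(v, "1", "0"))
    else fmt_chr(v)
  })
  rows <- if (nrow(svs)) {
    do.call(paste, c(list(
      svs$chrom1, format(svs$pos1 - 1, scientific = FALSE, trim = TRUE),
      format(svs$pos1, scientific = FALSE, trim = TRUE),
      svs$chrom2, format(svs$pos2 - 1, scientific = FALSE, trim = TRUE),
      format(svs$pos2, scientific = FALSE, trim = TRUE),
      svs$svtype, ".", svs$strand1, svs$strand2,
      fmt_num(svs$split_reads), fmt_num(svs$read_pairs),
      fmt_num(svs$homology_len), fmt_num(svs$insertion_len),
      fmt_chr(svs$sample_id)), ann, list(sep = "\t")))
  } else character()
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an annotated consensus BEDPE written by [write_consensus()]
#'
#' @param path file path.
#' @param genome optional `genome_model` for validation.
#' @return consensus `sv_calls` data.frame with annotation columns.
#' @export
read_consensus <- function(path, genome = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  base <- read_sv_bedpe(path)
  out <- sv_calls(base, genome)
  ann_cols <- c("callers", "cnv_validated", "event_id", "event_class",
                "complex_label", "subcategory", "signature")
  if (!any(keep)) {
    for (cn in ann_cols) out[[cn]] <- if (cn == "cnv_validated") logical() else character()
    out$cnv_validated <- logical()
    return(out)
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  for (j in seq_along(ann_cols)) {
    idx <- 15L + j
    v <- vapply(fields, function(f) if (length(f) >= idx) f[[idx]] else ".", "")
    v[v == "."] <- NA_character_
    out[[ann_cols[j]]] <- v
  }
  out$cnv_validated <- !is.na(out$cnv_validated) & out$cnv_validated == "1"
  out
}
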