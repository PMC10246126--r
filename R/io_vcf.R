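# SV VCF reader/writer (VCF 4.2, breakend pairs and symbolic records).
#
# Breakend ALT encoding follows the package orientation convention
# (see ?sv_calls): a local breakend whose retained segment extends leftward
# ('+') places the base before the bracket ("N[..[" / "N]..]"); '-' places it
# after ("]..]N" / "[..[N"). The mate bracket is ']' when the mate's retained
# segment extends leftward ('+') and '[' when it extends rightward ('-').

vcf_info_get <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
  ifelse(lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "="), info))) > 0,
         sub(paste0("^;?", key, "="), "", m), NA_character_)
}

read_sv_vcf <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  if (!length(body)) return(empty_sv_calls())
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8L)) stopf("%s line %d: VCF record has %d fields (need >= 8)",
                          path, body[which(nf < 8L)[1]], min(nf))
  get <- function(i) vapply(fields, `[`, "", i)
  chrom <- get(1)
  pos <- suppressWarnings(as.numeric(get(2)))
  if (anyNA(pos)) stopf("%s line %d: non-numeric POS", path, body[which(is.na(pos))[1]])
  id <- get(3); alt <- get(5); info <- get(8)
  svtype <- vcf_info_get(info, "SVTYPE")
  sample_id <- vcf_info_get(info, "SAMPLEID")
  num <- function(key) suppressWarnings(as.numeric(vcf_info_get(info, key)))
  sr <- num("SR"); pr <- num("PR"); hom <- num("HOMLEN"); ins <- num("INSLEN")

  is_bnd <- !is.na(svtype) & svtype == "BND"
  out <- list()

  if (any(is_bnd)) {
    idx <- which(is_bnd)
    m <- regexec("^([ACGTNacgtn]*)([][])([^]:[]+):([0-9]+)([][])([ACGTNacgtn]*)$",
                 alt[idx])
    parts <- regmatches(alt[idx], m)
    bad <- which(lengths(parts) == 0)
    if (length(bad)) stopf("%s line %d: unparseable breakend ALT '%s'",
                           path, body[idx[bad[1]]], alt[idx[bad[1]]])
    pre <- vapply(parts, `[`, "", 2)
    br <- vapply(parts, `[`, "", 3)
    mchr <- vapply(parts, `[`, "", 4)
    mpos <- as.numeric(vapply(parts, `[`, "", 5))
    local_strand <- ifelse(nzchar(pre), "+", "-")
    mate_strand <- ifelse(br == "]", "+", "-")
    mateid <- vcf_info_get(info[idx], "MATEID")
    if (anyNA(mateid)) stopf("%s line %d: BND record without MATEID",
                             path, body[idx[which(is.na(mateid))[1]]])
    # emit each mate pair once: keep the record whose ID sorts first
    keep <- id[idx] < mateid
    # unpaired records (mate missing from file) are errors
    if (!all(mateid %in% id[idx]))
      stopf("%s line %d: BND mate '%s' not found", path,
            body[idx[which(!mateid %in% id[idx])[1]]],
            mateid[which(!mateid %in% id[idx])[1]])
    k <- which(keep)
    same <- chrom[idx][k] == mchr[k]
    out$bnd <- data.frame(
      sample_id = sample_id[idx][k], caller = NA_character_,
      chrom1 = chrom[idx][k], pos1 = pos[idx][k], strand1 = local_strand[k],
      chrom2 = mchr[k], pos2 = mpos[k], strand2 = mate_strand[k],
      svtype = orientations_svtype(local_strand[k], mate_strand[k], same),
      split_reads = sr[idx][k], read_pairs = pr[idx][k],
      homology_len = hom[idx][k], insertion_len = ins[idx][k],
      stringsAsFactors = FALSE
    )
  }

  sym <- which(!is_bnd)
  if (length(sym)) {
    st <- svtype[sym]
    if (anyNA(st)) stopf("%s line %d: record without SVTYPE", path,
                         body[sym[which(is.na(st))[1]]])
    st[st == "INV"] <- vcf_info_get(info[sym], "INVTYPE")[st == "INV"]
    unknown <- which(is.na(st) | !st %in% sv_types())
    if (length(unknown))
      stopf("%s line %d: unknown or missing SVTYPE/INVTYPE '%s'", path,
            body[sym[unknown[1]]], svtype[sym[unknown[1]]])
    end <- suppressWarnings(as.numeric(vcf_info_get(info[sym], "END")))
    chr2 <- vcf_info_get(info[sym], "CHR2")
    pos2 <- suppressWarnings(as.numeric(vcf_info_get(info[sym], "POS2")))
    is_tra <- st == "TRA"
    if (any(!is_tra & is.na(end)))
      stopf("%s line %d: symbolic SV record without END", path,
            body[sym[which(!is_tra & is.na(end))[1]]])
    if (any(is_tra & (is.na(chr2) | is.na(pos2))))
      stopf("%s line %d: TRA record without CHR2/POS2", path,
            body[sym[which(is_tra & (is.na(chr2) | is.na(pos2)))[1]]])
    out$sym <- data.frame(
      sample_id = sample_id[sym], caller = NA_character_,
      chrom1 = chrom[sym], pos1 = pos[sym], strand1 = NA_character_,
      chrom2 = ifelse(is_tra, chr2, chrom[sym]),
      pos2 = ifelse(is_tra, pos2, end),
      strand2 = NA_character_, svtype = st,
      split_reads = sr[sym], read_pairs = pr[sym],
      homology_len = hom[sym], insertion_len = ins[sym],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write SV junctions as a VCF with breakend pairs
#'
#' Each junction becomes two BND records linked by MATEID. Support counts and
#' homology/insertion lengths travel in INFO (`SR`, `PR`, `HOMLEN`, `INSLEN`,
#' `SAMPLEID`); write-then-read restores the original `sv_calls` rows.
#'
#' @param svs `sv_calls` data.frame.
#' @param path output path.
#' @param genome optional `genome_model` used to emit `##contig` header lines.
#' @export
write_sv_vcf <- function(svs, path, genome = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=svsig",
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
           '##INFO=<ID=MATEID,Number=1,Type=String,Description="Breakend mate id">',
           '##INFO=<ID=SR,Number=1,Type=Float,Description="Split reads">',
           '##INFO=<ID=PR,Number=1,Type=Float,Description="Read pairs">',
           '##INFO=<ID=HOMLEN,Number=1,Type=Float,Description="Breakpoint homology length">',
           '##INFO=<ID=INSLEN,Number=1,Type=Float,Description="Inserted sequence length">',
           '##INFO=<ID=SAMPLEID,Number=1,Type=String,Description="Sample id">')
  if (!is.null(genome)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          genome$chromosomes$name,
                          as.integer(genome$chromosomes$length)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character()
  if (nrow(svs)) {
    fp <- function(x) format(x, scientific = FALSE, trim = TRUE)
    bnd_alt <- function(local_strand, mate_chrom, mate_pos, mate_strand) {
      bracket <- ifelse(mate_strand == "+", "]", "[")
      inner <- paste0(bracket, mate_chrom, ":", fp(mate_pos), bracket)
      ifelse(local_strand == "+", paste0("N", inner), paste0(inner, "N"))
    }
    info_common <- function(i, mate) {
      parts <- c(sprintf("SVTYPE=BND;MATEID=%s", mate),
                 if (!is.na(svs$split_reads[i])) sprintf("SR=%s", fp(svs$split_reads[i])),
                 if (!is.na(svs$read_pairs[i])) sprintf("PR=%s", fp(svs$read_pairs[i])),
                 if (!is.na(svs$homology_len[i])) sprintf("HOMLEN=%s", fp(svs$homology_len[i])),
                 if (!is.na(svs$insertion_len[i])) sprintf("INSLEN=%s", fp(svs$insertion_len[i])),
                 if (!is.na(svs$sample_id[i])) sprintf("SAMPLEID=%s", svs$sample_id[i]))
      paste(parts, collapse = ";")
    }
    rows <- unlist(lapply(seq_len(nrow(svs)), function(i) {
      id1 <- sprintf("sv%06d_1", i); id2 <- sprintf("sv%06d_2", i)
      c(paste(svs$chrom1[i], fp(svs$pos1[i]), id1, "N",
              bnd_alt(svs$strand1[i], svs$chrom2[i], svs$pos2[i], svs$strand2[i]),
              ".", "PASS", info_common(i, id2), sep = "\t"),
        paste(svs$chrom2[i], fp(svs$pos2[i]), id2, "N",
              bnd_alt(svs$strand2[i], svs$chrom1[i], svs$pos1[i], svs$strand1[i]),
              ".", "PASS", info_common(i, id1), sep = "\t"))
    }))
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}
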