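#' Simple-SV catalog configuration
#'
#' @param pair_distance breakend pairing tolerance (bp) for reciprocal
#'   inversion/translocation partner detection.
#' @param foldback_max_gap maximal breakend gap (bp) of a fold-back inversion.
#' @param fragile_site_mode `"either"` (default; one breakend inside a
#'   fragile-site interval suffices) or `"both"`.
#' @return list of class `catalog_config`.
#' @export
catalog_config <- function(pair_distance = 1000,
                           foldback_max_gap = 5000,
                           fragile_site_mode = c("either", "both")) {
  fragile_site_mode <- match.arg(fragile_site_mode)
  structure(list(pair_distance = pair_distance,
                 foldback_max_gap = foldback_max_gap,
                 fragile_site_mode = fragile_site_mode),
            class = "catalog_config")
}

#' The 49-subcategory simple-SV schema
#'
#' Reads the versioned schema resource: fragile-site deletion and tandem
#' duplication (1 each), 18 deletion and 18 tandem-duplication size bins,
#' 3 unbalanced-inversion and 5 reciprocal-inversion size bins, fold-back
#' inversion, reciprocal translocation and unbalanced translocation
#' (1+1+18+18+3+5+1+1+1 = 49). Size bins are `[size_min, size_max)` in bp;
#' the bin edges are configuration data chosen to pass through the signature
#' cut-points (1 kb, 5 kb, 10 Mb for deletions; 1 Mb, 2.5 Mb, 10 Mb for
#' tandem duplications; 50 kb, 5 Mb for unbalanced and 5 Mb for reciprocal
#' inversions). The `signature` column is the deterministic final-signature
#' target of each subcategory.
#'
#' @param path optional alternative schema TSV.
#' @return data.frame with 49 rows and columns `subcategory`, `major_class`,
#'   `qualifier`, `size_min`, `size_max`, `signature`.
#' @export
simple_sv_schema <- function(path = NULL) {
  path <- path %||% system.file("extdata", "simple_sv_schema.tsv",
                                package = "svsig", mustWork = TRUE)
  s <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  s$size_min <- as.numeric(s$size_min)
  s$size_max <- as.numeric(s$size_max)
  s
}

#' The nine final signature names
#' @return character vector.
#' @export
signature_names <- function() {
  c("Del0", "Del1", "Del2", "TD", "BRAF fusion", "Unbal inv", "Large mixed",
    "Recip", "Unbal tra")
}

#' Subtype simple inversions and translocations
#'
#' Reduces a sample's simple (non-event) junctions to typed simple SVs:
#' an h2hINV + t2tINV pair with all four breakends mutually pairable within
#' `pair_distance` becomes one reciprocal inversion; a lone inversion whose
#' breakends are at most `foldback_max_gap` apart becomes a fold-back
#' inversion; remaining lone inversions are unbalanced inversions; TRA pairs
#' with pairable ends and opposite orientations become one reciprocal
#' translocation; lone TRAs are unbalanced translocations. Deletions and
#' tandem duplications pass through. Reciprocal pairs are emitted once.
#'
#' @param svs simple junctions (`sv_calls` rows) of one or more samples.
#' @param config [catalog_config()].
#' @return data.frame of typed simple SVs with columns of `svs` plus
#'   `simple_type` and `size`; paired partners collapse to the first
#'   junction's row with `n_junctions = 2`.
#' @export
subtype_inversions_translocations <- function(svs, config = catalog_config()) {
  if (!nrow(svs)) {
    out <- as.data.frame(svs)
    out$simple_type <- character(0); out$size <- numeric(0)
    out$n_junctions <- integer(0)
    return(out)
  }
  out <- list()
  for (sample in unique(svs$sample_id)) {
    sub <- as.data.frame(svs[svs$sample_id == sample, , drop = FALSE])
    sub$simple_type <- NA_character_
    sub$size <- sv_size(sub)
    sub$n_junctions <- 1L
    drop <- rep(FALSE, nrow(sub))

    sub$simple_type[sub$svtype == "DEL"] <- "deletion"
    sub$simple_type[sub$svtype == "DUP"] <- "tandem_duplication"

    # reciprocal inversions: greedy mutual pairing of h2h and t2t junctions
    h2h <- which(sub$svtype == "h2hINV"); t2t <- which(sub$svtype == "t2tINV")
    for (i in h2h) {
      if (drop[i]) next
      cand <- t2t[!drop[t2t] & sub$chrom1[t2t] == sub$chrom1[i] &
                    abs(sub$pos1[t2t] - sub$pos1[i]) <= config$pair_distance &
                    abs(sub$pos2[t2t] - sub$pos2[i]) <= config$pair_distance]
      if (length(cand)) {
        j <- cand[which.min(abs(sub$pos1[cand] - sub$pos1[i]) +
                              abs(sub$pos2[cand] - sub$pos2[i]))]
        sub$simple_type[i] <- "reciprocal_inversion"
        sub$size[i] <- abs(sub$pos2[i] - sub$pos1[i])
        sub$n_junctions[i] <- 2L
        drop[j] <- TRUE
      }
    }

    # reciprocal translocations: TRA pairs with pairable ends, opposite
    # orientations at both ends
    tra <- which(sub$svtype == "TRA")
    for (ii in seq_along(tra)) {
      i <- tra[ii]
      if (drop[i] || !is.na(sub$simple_type[i])) next
      for (j in tra[-seq_len(ii)]) {
        if (drop[j] || !is.na(sub$simple_type[j])) next
        if (sub$chrom1[j] == sub$chrom1[i] && sub$chrom2[j] == sub$chrom2[i] &&
            abs(sub$pos1[j] - sub$pos1[i]) <= config$pair_distance &&
            abs(sub$pos2[j] - sub$pos2[i]) <= config$pair_distance &&
            sub$strand1[j] != sub$strand1[i] && sub$strand2[j] != sub$strand2[i]) {
          sub$simple_type[i] <- "reciprocal_translocation"
          sub$n_junctions[i] <- 2L
          drop[j] <- TRUE
          break
        }
      }
    }

    inv <- sub$svtype %in% c("h2hINV", "t2tINV") & is.na(sub$simple_type) & !drop
    fb <- inv & sub$size <= config$foldback_max_gap
    sub$simple_type[fb] <- "foldback_inversion"
    sub$simple_type[inv & !fb] <- "unbalanced_inversion"
    sub$simple_type[sub$svtype == "TRA" & is.na(sub$simple_type) & !drop] <-
      "unbalanced_translocation"

    out[[length(out) + 1L]] <- sub[!drop, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify one typed simple SV into its subcategory
#'
#' Fragile-site check first (for deletions and tandem duplications), then
#' size-bin lookup within the SV's class. Exactly one subcategory results.
#'
#' @param typed data.frame from [subtype_inversions_translocations()].
#' @param schema [simple_sv_schema()].
#' @param genome `genome_model` (fragile-site intervals).
#' @param config [catalog_config()].
#' @return character vector of subcategory names, one per row of `typed`.
#' @export
classify_simple <- function(typed, schema = simple_sv_schema(), genome,
                            config = catalog_config()) {
  if (!nrow(typed)) return(character())
  size_needed <- typed$simple_type %in%
    c("deletion", "tandem_duplication", "unbalanced_inversion",
      "reciprocal_inversion")
  if (any(size_needed & (is.na(typed$size) | typed$size <= 0)))
    stopf("simple SV with size <= 0 cannot be classified")

  in_fragile <- if (nrow(genome$fragile_sites)) {
    f1 <- point_in_interval(typed$chrom1, typed$pos1, genome$fragile_sites)
    f2 <- point_in_interval(typed$chrom2, typed$pos2, genome$fragile_sites)
    if (config$fragile_site_mode == "either") f1 | f2 else f1 & f2
  } else rep(FALSE, nrow(typed))

  bin_prefix <- c(deletion = "DEL", tandem_duplication = "TD",
                  unbalanced_inversion = "UINV", reciprocal_inversion = "RINV")
  vapply(seq_len(nrow(typed)), function(i) {
    st <- typed$simple_type[i]
    if (st == "deletion" && in_fragile[i]) return("DEL_fragile_site")
    if (st == "tandem_duplication" && in_fragile[i]) return("TD_fragile_site")
    if (st %in% c("foldback_inversion", "reciprocal_translocation",
                  "unbalanced_translocation")) return(st)
    pre <- bin_prefix[[st]]
    rows <- schema[schema$qualifier %in% c("size_bin", "unbalanced_size_bin",
                                           "reciprocal_size_bin") &
                     startsWith(schema$subcategory, paste0(pre, "_")), ]
    hit <- which(typed$size[i] >= rows$size_min & typed$size[i] < rows$size_max)
    if (length(hit) != 1) stopf("size %g of a %s matches %d bins",
                                typed$size[i], st, length(hit))
    rows$subcategory[hit]
  }, character(1))
}

#' Flag BRAF-fusion tandem duplications
#'
#' `TRUE` for tandem duplications of 1-2.5 Mb with both breakends inside the
#' configured BRAF region; such SVs are assigned the stand-alone "BRAF
#' fusion" signature rather than "TD".
#'
#' @param typed typed simple SVs.
#' @param genome `genome_model`; `genome$braf_region` must be set, otherwise
#'   all flags are `FALSE` with a warning.
#' @return logical vector.
#' @export
flag_braf_fusion <- function(typed, genome) {
  if (is.null(genome$braf_region)) {
    warnf("no BRAF region configured in the genome model; BRAF-fusion flags all FALSE")
    return(rep(FALSE, nrow(typed)))
  }
  br <- genome$braf_region
  inside <- function(chrom, pos) chrom == br$chrom & pos >= br$start & pos <= br$end
  typed$simple_type == "tandem_duplication" &
    !is.na(typed$size) & typed$size >= 1e6 & typed$size <= 2.5e6 &
    inside(typed$chrom1, typed$pos1) & inside(typed$chrom2, typed$pos2)
}

#' Build the per-sample 49-subcategory catalog matrix
#'
#' @param typed typed simple SVs with a `subcategory` column
#'   (see [classify_simple()]); reciprocal pairs occupy a single row and are
#'   counted once.
#' @param schema [simple_sv_schema()].
#' @param sample_ids optional sample universe (rows for samples with zero
#'   simple SVs).
#' @return integer matrix, samples x 49 subcategories.
#' @export
build_catalog <- function(typed, schema = simple_sv_schema(), sample_ids = NULL) {
  sample_ids <- sample_ids %||% sort(unique(typed$sample_id))
  mat <- matrix(0L, nrow = length(sample_ids), ncol = nrow(schema),
                dimnames = list(sample_ids, schema$subcategory))
  if (nrow(typed)) {
    tab <- table(factor(typed$sample_id, levels = sample_ids),
                 factor(typed$subcategory, levels = schema$subcategory))
    mat[] <- as.integer(tab)
  }
  mat
}
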