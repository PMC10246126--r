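#' Run the full SV signature pipeline
#'
#' Chains the analysis stages: consensus calling from per-caller callsets,
#' event partitioning and complex-SV labeling, simple-SV subtyping and
#' 49-subcategory classification, BRAF-fusion flagging, deterministic final
#' signature assignment and catalog construction.
#'
#' @param callsets `sv_calls` from all callers (with `sample_id`, `caller`).
#' @param genome `genome_model`.
#' @param cnv_segments CNV segment table or `NULL`.
#' @param samples sample sheet (defines the sample universe of the catalog).
#' @param consensus_cfg,event_cfg,catalog_cfg stage configurations.
#' @return list of class `svsig_pipeline`: `consensus` (annotated SV table
#'   with `event_id`, `event_class`, `complex_label`, and for simple SVs
#'   `subcategory` and `signature`), `events`, `typed_simple`, `catalog`,
#'   `presence` (list of logical sample x label matrices for `simple`,
#'   `clustered` and `nonclustered` signature families).
#' @export
sv_pipeline <- function(callsets, genome, cnv_segments = NULL, samples = NULL,
                        consensus_cfg = consensus_config(),
                        event_cfg = event_config(),
                        catalog_cfg = catalog_config()) {
  cons <- sv_consensus(callsets, genome, cnv_segments, consensus_cfg)
  ev <- classify_events(cons, cnv_segments, genome, event_cfg)
  svs <- ev$svs

  simple_rows <- which(svs$event_class == "simple")
  typed <- subtype_inversions_translocations(svs[simple_rows, , drop = FALSE],
                                             catalog_cfg)
  schema <- simple_sv_schema()
  if (nrow(typed)) {
    typed$subcategory <- classify_simple(typed, schema, genome, catalog_cfg)
    typed$braf_fusion <- flag_braf_fusion(typed, genome)
    typed$signature <- assign_final_signatures(typed, assignment_rules(schema))
  } else {
    typed$subcategory <- character(0)
    typed$braf_fusion <- logical(0)
    typed$signature <- character(0)
  }

  sample_ids <- if (!is.null(samples)) samples$sample_id else
    sort(unique(svs$sample_id))
  catalog <- build_catalog(typed, schema, sample_ids)

  # propagate per-junction signature labels back onto the consensus table:
  # simple junctions get their nine-signature label, complex junctions their
  # event label
  svs$subcategory <- NA_character_
  svs$signature <- NA_character_
  if (nrow(typed)) {
    key_sv <- paste(svs$sample_id, svs$chrom1, svs$pos1, svs$chrom2, svs$pos2,
                    svs$svtype)
    key_ty <- paste(typed$sample_id, typed$chrom1, typed$pos1, typed$chrom2,
                    typed$pos2, typed$svtype)
    hit <- match(key_sv, key_ty)
    svs$subcategory[!is.na(hit)] <- typed$subcategory[hit[!is.na(hit)]]
    svs$signature[!is.na(hit)] <- typed$signature[hit[!is.na(hit)]]
    # the dropped partner of a reciprocal pair inherits the pair's label
    orphan <- which(svs$event_class == "simple" & is.na(svs$signature))
    for (i in orphan) {
      cand <- which(typed$sample_id == svs$sample_id[i] &
                      typed$n_junctions == 2L &
                      typed$chrom1 == svs$chrom1[i])
      if (length(cand)) {
        d <- abs(typed$pos1[cand] - svs$pos1[i])
        svs$subcategory[i] <- typed$subcategory[cand[which.min(d)]]
        svs$signature[i] <- typed$signature[cand[which.min(d)]]
      }
    }
  }

  presence <- signature_presence_matrices(svs, typed, sample_ids)
  structure(list(consensus = svs, events = ev$events, typed_simple = typed,
                 catalog = catalog, presence = presence, genome = genome),
            class = "svsig_pipeline")
}

# logical presence matrices per signature family
signature_presence_matrices <- function(svs, typed, sample_ids) {
  mk <- function(labels, sample, label) {
    m <- matrix(FALSE, length(sample_ids), length(labels),
                dimnames = list(sample_ids, labels))
    ok <- !is.na(label) & label %in% labels & sample %in% sample_ids
    if (any(ok)) m[cbind(sample[ok], label[ok])] <- TRUE
    m
  }
  clustered <- svs$event_class == "clustered_complex"
  noncl <- svs$event_class == "nonclustered_complex"
  list(
    simple = mk(signature_names(), typed$sample_id, typed$signature),
    clustered = mk(clustered_labels(), svs$sample_id[clustered],
                   svs$complex_label[clustered]),
    nonclustered = mk(nonclustered_labels(), svs$sample_id[noncl],
                      svs$complex_label[noncl]))
}

#' @export
print.svsig_pipeline <- function(x, ...) {
  tab <- table(factor(x$consensus$event_class,
                      levels = c("clustered_complex", "nonclustered_complex",
                                 "simple")))
  cat(sprintf("<svsig_pipeline> %d consensus SVs (%d clustered / %d non-clustered / %d simple)\n",
              nrow(x$consensus), tab[1], tab[2], tab[3]))
  cat(sprintf("  %d events; catalog %d samples x %d subcategories\n",
              if (is.null(x$events)) 0L else nrow(x$events),
              nrow(x$catalog), ncol(x$catalog)))
  invisible(x)
}
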