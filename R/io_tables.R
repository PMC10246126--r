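# tabular readers/writers: CNV segments, sample sheets, feature tracks

#' Default tumor-type label set
#'
#' The 14 named pediatric brain tumor types with at least 10 samples plus the
#' catch-all "Others" category.
#' @return character vector of 15 labels.
#' @export
tumor_type_labels <- function() {
  c("LGAT", "Medulloblastoma", "Ependymoma", "HGG", "Ganglioglioma",
    "Craniopharyngioma", "ATRT", "Meningioma", "DNET", "Mesenchymal",
    "Schwannoma", "Germ cell", "Neurofibroma", "Choroid plexus papilloma",
    "Others")
}

#' Read somatic CNV segments
#'
#' Tab-delimited file with columns `sample_id`, `chrom`, `start`, `end`,
#' `copy_number` (1-based inclusive coordinates). Segments must be
#' non-overlapping within a sample and chromosome.
#'
#' @param path file path.
#' @param genome optional `genome_model` for coordinate validation.
#' @return data.frame of CNV segments sorted by sample, chromosome, start.
#' @export
read_cnv_segments <- function(path, genome = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "")
  names(df) <- sub("^X\\.", "", names(df))
  req <- c("sample_id", "chrom", "start", "end", "copy_number")
  miss <- setdiff(req, names(df))
  if (length(miss)) stopf("CNV file %s: missing column(s) %s", path,
                          paste(miss, collapse = ", "))
  validate_cnv_segments(df[, req], genome, path)
}

validate_cnv_segments <- function(df, genome = NULL, what = "CNV segments") {
  if (!nrow(df)) return(df)
  if (any(df$end < df$start)) stopf("%s: segment end < start", what)
  if (any(df$copy_number < 0)) stopf("%s: negative copy number", what)
  df <- df[order(df$sample_id, df$chrom, df$start), ]
  sp <- split(seq_len(nrow(df)), paste(df$sample_id, df$chrom))
  for (idx in sp) {
    if (length(idx) > 1 && any(df$start[idx][-1] <= df$end[idx][-length(idx)]))
      stopf("%s: overlapping segments within sample %s on %s",
            what, df$sample_id[idx[1]], df$chrom[idx[1]])
  }
  if (!is.null(genome)) {
    len <- chrom_length(genome, df$chrom)
    if (any(df$start < 1 | df$end > len))
      stopf("%s: segment outside chromosome bounds", what)
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_cnv_segments
#' @param segments CNV segment data.frame.
#' @export
write_cnv_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the cohort sample sheet
#'
#' Tab-delimited with columns `sample_id`, `tumor_type`, `sex`,
#' `hypermutated` (0/1), `survival_time` (days, NA if unknown),
#' `survival_event` (`death`/`censored`/`unknown`) and `mutations`
#' (semicolon-separated `gene:class` tokens, empty for none).
#'
#' @param path file path.
#' @param allowed_types permitted tumor-type labels
#'   (default [tumor_type_labels()]).
#' @return sample-sheet data.frame.
#' @export
read_sample_sheet <- function(path, allowed_types = tumor_type_labels()) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "",
                          na.strings = c("NA", "."))
  req <- c("sample_id", "tumor_type", "sex")
  miss <- setdiff(req, names(df))
  if (length(miss)) stopf("sample sheet %s: missing column(s) %s", path,
                          paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$tumor_type), allowed_types)
  if (length(bad)) {
    stopf("sample sheet %s: unknown tumor type(s) %s; allowed labels: %s",
          path, paste(bad, collapse = ", "), paste(allowed_types, collapse = ", "))
  }
  if (is.null(df$hypermutated)) df$hypermutated <- 0L
  if (is.null(df$survival_time)) df$survival_time <- NA_real_
  if (is.null(df$survival_event)) df$survival_event <- "unknown"
  if (is.null(df$mutations)) df$mutations <- ""
  df$mutations[is.na(df$mutations)] <- ""
  df$hypermutated <- as.logical(as.integer(df$hypermutated))
  df
}

#' @rdname read_sample_sheet
#' @param samples sample-sheet data.frame.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

# long table of per-sample protein-altering mutations
parse_mutations <- function(samples) {
  toks <- strsplit(samples$mutations, ";", fixed = TRUE)
  n <- lengths(toks)
  flat <- unlist(toks)
  flat <- flat[nzchar(flat)]
  if (!length(flat)) {
    return(data.frame(sample_id = character(), gene = character(),
                      class = character(), stringsAsFactors = FALSE))
  }
  sid <- rep(samples$sample_id, n)[nzchar(unlist(toks))]
  parts <- strsplit(flat, ":", fixed = TRUE)
  data.frame(sample_id = sid,
             gene = vapply(parts, `[`, "", 1),
             class = vapply(parts, function(p) if (length(p) > 1) p[[2]] else "unknown", ""),
             stringsAsFactors = FALSE)
}

#' Feature tracks
#'
#' A feature track is either interval-type (BED-style intervals; breakpoints
#' are scored by log-transformed distance to the nearest interval, 0 inside)
#' or signal-type (bedGraph-style step function; breakpoints are scored by the
#' annotated value). `units` sets the distance unit for interval tracks
#' ("kb" or "Mb") before the log transform.
#'
#' @param name track name.
#' @param type `"interval"` or `"signal"`.
#' @param data `data.frame(chrom, start, end)` for interval tracks;
#'   `data.frame(chrom, start, end, value)` for signal tracks (1-based
#'   inclusive).
#' @param units distance units for interval tracks (`"kb"` default).
#' @param transform `"log"` (natural log of distance + pseudocount) or
#'   `"identity"`.
#' @param pseudocount added before the log (default 1, in `units`).
#' @return object of class `feature_track`.
#' @export
feature_track <- function(name, type = c("interval", "signal"), data,
                          units = "kb", transform = c("log", "identity"),
                          pseudocount = 1) {
  type <- match.arg(type); transform <- match.arg(transform)
  req <- if (type == "interval") c("chrom", "start", "end")
         else c("chrom", "start", "end", "value")
  miss <- setdiff(req, names(data))
  if (length(miss)) stopf("feature track %s: missing column(s) %s", name,
                          paste(miss, collapse = ", "))
  structure(list(name = name, type = type, data = data[, req], units = units,
                 transform = transform, pseudocount = pseudocount),
            class = "feature_track")
}

#' Build a feature track set
#'
#' @param tracks list of [feature_track()] objects.
#' @return object of class `feature_track_set` (a named list).
#' @export
feature_track_set <- function(tracks) {
  nms <- vapply(tracks, `[[`, "", "name")
  if (anyDuplicated(nms)) stopf("duplicated feature track names")
  names(tracks) <- nms
  structure(tracks, class = "feature_track_set")
}

#' @export
print.feature_track_set <- function(x, ...) {
  cat(sprintf("<feature_track_set> %d tracks\n", length(x)))
  for (t in x) cat(sprintf("  %-24s %s (%d rows)\n", t$name, t$type, nrow(t$data)))
  invisible(x)
}

#' Read feature tracks from a manifest
#'
#' The manifest is a TSV with columns `name`, `type` (`interval`/`signal`),
#' `path`, and optionally `units`, `transform`, `pseudocount`. Interval tracks
#' are read as BED (0-based half-open, converted to 1-based inclusive); signal
#' tracks as bedGraph (`chrom start end value`).
#'
#' @param manifest_path manifest TSV path; relative track paths resolve
#'   against the manifest's directory.
#' @return `feature_track_set`.
#' @export
read_feature_tracks <- function(manifest_path) {
  man <- utils::read.table(manifest_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  tracks <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    raw <- utils::read.table(p, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (man$type[i] == "interval") {
      data <- data.frame(chrom = raw[[1]], start = raw[[2]] + 1, end = raw[[3]])
    } else {
      data <- data.frame(chrom = raw[[1]], start = raw[[2]] + 1, end = raw[[3]],
                         value = raw[[4]])
    }
    feature_track(man$name[i], man$type[i], data,
                  units = man$units[i] %||% "kb",
                  transform = (man$transform[i] %||% "log"),
                  pseudocount = as.numeric(man$pseudocount[i] %||% 1))
  })
  feature_track_set(tracks)
}

#' Write feature tracks and a manifest to a directory
#'
#' @param tracks `feature_track_set`.
#' @param dir output directory (created if needed).
#' @return path of the manifest file.
#' @export
write_feature_tracks <- function(tracks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(tracks, function(t) {
    fname <- paste0(gsub("[^A-Za-z0-9_.-]", "_", t$name),
                    if (t$type == "interval") ".bed" else ".bedgraph")
    d <- t$data
    out <- if (t$type == "interval") {
      data.frame(d$chrom, format(d$start - 1, scientific = FALSE, trim = TRUE),
                 format(d$end, scientific = FALSE, trim = TRUE))
    } else {
      data.frame(d$chrom, format(d$start - 1, scientific = FALSE, trim = TRUE),
                 format(d$end, scientific = FALSE, trim = TRUE), d$value)
    }
    utils::write.table(out, file.path(dir, fname), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    data.frame(name = t$name, type = t$type, path = fname, units = t$units,
               transform = t$transform, pseudocount = t$pseudocount,
               stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(man, manifest_path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest_path
}
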