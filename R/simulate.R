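# Synthetic-cohort simulator: genome, ground-truth SVs drawn from signature
# processes, three imperfect callers, CNV profiles, sample metadata and
# genomic feature tracks.

#' Default per-tumor-type signature activities
#'
#' Expected per-sample counts of each simple-SV signature process and
#' per-sample rates of clustered-complex, chromoplexy and
#' templated-insertion-cycle events. The qualitative pattern mirrors the
#' cohort biology the package targets: high-grade gliomas rich in most
#' processes, low-grade astrocytic tumors dominated by the BRAF-fusion
#' tandem duplication, DNETs carrying essentially only "TD", schwannomas
#' "Recip", choroid plexus papillomas nothing.
#'
#' @return matrix, tumor types x processes.
#' @export
default_signature_activity <- function() {
  procs <- c(signature_names(), "clustered", "chromoplexy", "tic")
  types <- tumor_type_labels()
  m <- matrix(0.03, length(types), length(procs),
              dimnames = list(types, procs))
  m["HGG", ] <- c(0.5, 0.5, 1.5, 1.0, 0, 1.0, 0.4, 0.5, 1.0, 0.5, 0.25, 0.35)
  m["LGAT", ] <- c(0.05, 0.05, 0.05, 0.05, 0.5, 0.02, 0.02, 0.05, 0.05, 0.02, 0.01, 0.01)
  m["Medulloblastoma", ] <- c(0.2, 0.2, 0.4, 1.0, 0, 0.2, 0.2, 0.2, 0.4, 0.3, 0.05, 0.05)
  m["Ependymoma", ] <- c(0.05, 0.25, 0.1, 0.2, 0, 0.1, 0.05, 0.15, 0.1, 0.12, 0.05, 0.02)
  m["HGG", "BRAF fusion"] <- 0
  m["Meningioma", ] <- c(0.1, 0.1, 0.5, 0.2, 0, 0.1, 0.1, 0.1, 0.3, 0.2, 0.03, 0.02)
  m["DNET", ] <- c(0.01, 0.01, 0.01, 0.7, 0, 0, 0, 0.01, 0.01, 0, 0, 0)
  m["Schwannoma", ] <- c(0.02, 0.02, 0.02, 0.05, 0, 0.02, 0.02, 0.8, 0.05, 0, 0, 0)
  m["ATRT", ] <- c(0.1, 0.1, 0.8, 0.1, 0, 0.05, 0.05, 0.1, 0.1, 0.05, 0.02, 0.02)
  m["Mesenchymal", ] <- c(0.1, 0.1, 0.2, 0.2, 0, 0.1, 0.1, 0.2, 0.2, 0.2, 0.15, 0.02)
  m["Neurofibroma", ] <- c(0.05, 0.05, 0.05, 0.1, 0, 0.05, 0.02, 0.2, 0.1, 0.08, 0.02, 0.01)
  m["Choroid plexus papilloma", ] <- 0
  m
}

# within-clustered pattern mix per tumor type (columns sum to 1 per row)
default_clustered_patterns <- function() {
  pats <- c("micronuclei", "chr_bridge", "large_loss", "large_gain",
            "ecdna", "hourglass")
  types <- tumor_type_labels()
  m <- matrix(1 / 6, length(types), length(pats), dimnames = list(types, pats))
  m["HGG", ] <- c(0.10, 0.15, 0.20, 0.10, 0.30, 0.15)
  m["Medulloblastoma", ] <- c(0.15, 0.05, 0.10, 0.45, 0.05, 0.20)
  m["Ependymoma", ] <- c(0.45, 0.05, 0.05, 0.05, 0.05, 0.35)
  m["Meningioma", ] <- c(0.10, 0.05, 0.55, 0.05, 0.05, 0.20)
  m["Mesenchymal", ] <- c(0.60, 0.05, 0.10, 0.05, 0.05, 0.15)
  m["Neurofibroma", ] <- c(0.20, 0.40, 0.10, 0.10, 0.05, 0.15)
  m
}

#' Simulation configuration
#'
#' All knobs of [simulate_cohort()]. Defaults describe the study conditions
#' the package is validated under: a 24-chromosome-compatible 8-chromosome
#' toy genome totalling ~1.2 Gb, the full cohort layout (744 samples over 15
#' tumor types), three callers with distinct sensitivity / breakpoint jitter
#' / caller-specific false-positive rates, log-normal simple-SV sizes
#' separable into the nine signature classes, clustered events with
#' oscillating / stepwise-loss / high-amplification copy-number footprints,
#' and exponential survival with an optional signature effect.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param samples_per_type named integer vector, samples per tumor type.
#' @param activity process-activity matrix (see
#'   [default_signature_activity()]).
#' @param clustered_patterns per-type clustered pattern mix.
#' @param callers list of per-caller specs: `sensitivity`, `jitter_sd` (bp),
#'   `fp_rate` (expected caller-specific false positives per true SV),
#'   `support_mean` (mean read support), `reports_homology`.
#' @param clustered_junctions range of junction counts per clustered event.
#' @param clustered_span range of clustered footprint spans (bp).
#' @param chromoplexy_chain range of chromoplexy chain lengths.
#' @param cnv_resolution minimal DEL/DUP size generating CNV segments (bp).
#' @param cnv_jitter_sd CNV segment boundary jitter sd (bp, capped well
#'   below the 1 kb validation distance).
#' @param n_feature_tracks interval feature tracks built by
#'   [simulate_null_features()].
#' @param feature_interval_density expected intervals per Mb per track.
#' @param feature_interval_width mean interval width (bp).
#' @param planted_enrichment `NULL`, or `list(track=, signature=,
#'   fraction=)`: that fraction of the signature's breakpoints is placed
#'   inside intervals of the named track.
#' @param survival_effect `list(signature=, hr=)`: hazard ratio multiplying
#'   the exponential baseline hazard for carriers.
#' @param baseline_hazard events per day.
#' @param mutation_genes genes simulated in the sample sheet;
#'   `mutation_effects` couples gene mutation probability to a process.
#' @param hypermutation_rate fraction of hypermutated samples.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(
    chrom_lengths = stats::setNames(
      c(240, 200, 180, 160, 140, 120, 100, 80) * 1e6, paste0("chr", 1:8)),
    samples_per_type = stats::setNames(
      c(220, 97, 71, 70, 44, 38, 27, 23, 23, 17, 13, 13, 13, 12, 63),
      c("LGAT", "Medulloblastoma", "Ependymoma", "HGG", "Ganglioglioma",
        "Craniopharyngioma", "ATRT", "Meningioma", "DNET", "Mesenchymal",
        "Schwannoma", "Germ cell", "Neurofibroma", "Choroid plexus papilloma",
        "Others")),
    activity = default_signature_activity(),
    clustered_patterns = default_clustered_patterns(),
    callers = list(
      meerkat = list(sensitivity = 0.75, jitter_sd = 2, fp_rate = 0.10,
                     support_mean = 10, reports_homology = TRUE),
      manta = list(sensitivity = 0.90, jitter_sd = 1, fp_rate = 0.30,
                   support_mean = 16, reports_homology = TRUE),
      delly = list(sensitivity = 0.65, jitter_sd = 3, fp_rate = 0.15,
                   support_mean = 8, reports_homology = FALSE)),
    clustered_junctions = c(8L, 20L),
    clustered_span = c(5e6, 20e6),
    chromoplexy_chain = c(3L, 5L),
    cnv_resolution = 10e3,
    cnv_jitter_sd = 50,
    n_feature_tracks = 20,
    feature_interval_density = 1,
    feature_interval_width = 5e3,
    planted_enrichment = NULL,
    survival_effect = list(signature = "Del2", hr = 3),
    baseline_hazard = 1 / 1500,
    mutation_genes = c("TP53", "H3F3A", "ATRX", "NF1", "NF2", "CTNNB1"),
    hypermutation_rate = 0.004) {
  cfg <- as.list(environment())
  rates <- unlist(cfg$activity)
  if (any(rates < 0)) stopf("negative activity rate")
  sens <- vapply(cfg$callers, `[[`, numeric(1), "sensitivity")
  if (any(sens < 0 | sens > 1)) stopf("caller sensitivity outside [0, 1]")
  structure(cfg, class = "simulation_config")
}

# toy genome with centromeres, telomeres, fragile sites, genes and a BRAF
# region; deterministic given the RNG state
simulate_genome <- function(config) {
  chroms <- data.frame(name = names(config$chrom_lengths),
                       length = unname(config$chrom_lengths),
                       stringsAsFactors = FALSE)
  cent_mid <- chroms$length * stats::runif(nrow(chroms), 0.4, 0.6)
  centromeres <- data.frame(chrom = chroms$name,
                            start = round(cent_mid - 1.5e6),
                            end = round(cent_mid + 1.5e6))
  telomeres <- data.frame(chrom = rep(chroms$name, 2),
                          pos = c(rep(1, nrow(chroms)), chroms$length))
  fs <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    st <- sort(round(stats::runif(2, 1, chroms$length[i] - 2e6)))
    data.frame(chrom = chroms$name[i], start = st, end = st + 1.5e6)
  }))
  n_genes <- 150
  gi <- sample.int(nrow(chroms), n_genes, replace = TRUE)
  gstart <- round(stats::runif(n_genes, 1, chroms$length[gi] - 2e5))
  genes <- data.frame(gene_id = sprintf("G%03d", seq_len(n_genes)),
                      chrom = chroms$name[gi],
                      strand = sample(c("+", "-"), n_genes, replace = TRUE),
                      stringsAsFactors = FALSE)
  exons <- do.call(rbind, lapply(seq_len(n_genes), function(k) {
    n_ex <- sample(2:8, 1)
    w <- round(stats::runif(n_ex, 100, 400))
    gaps <- round(stats::runif(n_ex - 1, 500, 5000))
    st <- gstart[k] + cumsum(c(0, w[-n_ex] + gaps))
    data.frame(gene_id = genes$gene_id[k], start = st, end = st + w - 1)
  }))
  # BRAF-fusion rule region: a 3 Mb window (holding 1-2.5 Mb duplications)
  # placed at 60% of the longest suitable chromosome
  bi <- which.max(chroms$length)
  if (chroms$length[bi] < 2e7)
    stopf("no chromosome long enough to host the BRAF-fusion region")
  bstart <- round(chroms$length[bi] * 0.6)
  braf <- list(chrom = chroms$name[bi], start = bstart,
               end = min(bstart + 3e6, chroms$length[bi] - 1e5))
  genome_model(chroms, centromeres, telomeres, fs, genes, exons,
               braf_region = braf, canonical_only = TRUE)
}

# --- per-process junction generators (operate on the current RNG state) ---

sim_size_ranges <- function() {
  list(`Del0` = c(50, 999), `Del1` = c(1e3, 4.99e3), `Del2` = c(3e4, 2e6),
       `TD` = c(2e4, 8e5), `BRAF fusion` = c(1.05e6, 2.45e6),
       `Unbal inv` = c(6e4, 4.5e6), `Large mixed` = c(1.1e7, 4e7),
       `Recip` = c(1e5, 2e6), `Unbal tra` = c(NA, NA))
}

# log-normal size within the signature's range
draw_size <- function(signature) {
  r <- sim_size_ranges()[[signature]]
  mu <- mean(log(r)); sd <- diff(log(r)) / 4
  for (i in 1:50) {
    s <- round(stats::rlnorm(1, mu, sd))
    if (s >= r[1] && s <= r[2]) return(s)
  }
  round(exp(mu))
}

# homology/insertion lengths per signature: TD/Recip/BRAF fusion peak at 2 bp
# microhomology, Large mixed/ecDNA-like processes at long insertions, the
# rest at blunt ends or 1 bp
draw_homology <- function(signature, n = 1) {
  spec <- switch(signature,
    `TD` = , `Recip` = , `BRAF fusion` = list(p_ins = 0.05, lam = 2.2),
    `Large mixed` = list(p_ins = 0.45, lam = 1.0),
    `Del0` = , `Del1` = list(p_ins = 0.05, lam = 1.1),
    `Unbal inv` = list(p_ins = 0.08, lam = 1.2),
    list(p_ins = 0.05, lam = 0.5))
  ins <- stats::rbinom(n, 1, spec$p_ins) == 1
  hom <- stats::rpois(n, spec$lam)
  data.frame(homology_len = ifelse(ins, 0, hom),
             insertion_len = ifelse(ins, 11 + stats::rpois(n, 6), 0))
}

place_interval <- function(genome, size, chrom = NULL) {
  if (is.null(chrom)) {
    ok <- genome$chromosomes$length > size + 2
    chrom <- sample(genome$chromosomes$name[ok], 1,
                    prob = genome$chromosomes$length[ok])
  }
  L <- chrom_length(genome, chrom)
  start <- floor(stats::runif(1, 1, L - size))
  c(start, start + size)
}

new_truth_row <- function(sample_id, chrom1, pos1, strand1, chrom2, pos2,
                          strand2, svtype, process, event_id, hom) {
  data.frame(sample_id = sample_id, caller = NA_character_,
             chrom1 = chrom1, pos1 = pos1, strand1 = strand1,
             chrom2 = chrom2, pos2 = pos2, strand2 = strand2, svtype = svtype,
             split_reads = NA_real_, read_pairs = NA_real_,
             homology_len = hom$homology_len, insertion_len = hom$insertion_len,
             process = process, true_event = event_id, stringsAsFactors = FALSE)
}

# simple SV of one signature; reciprocal processes emit two junctions
sim_simple_sv <- function(sample_id, signature, genome, event_id) {
  hom <- draw_homology(signature)
  switch(signature,
    `Del0` = , `Del1` = , `Del2` = {
      size <- draw_size(signature)
      ch <- sample(genome$chromosomes$name, 1, prob = genome$chromosomes$length)
      iv <- place_interval(genome, size, ch)
      new_truth_row(sample_id, ch, iv[1], "-", ch, iv[2], "+", "DEL",
                    signature, event_id, hom)
    },
    `TD` = {
      size <- draw_size("TD")
      ch <- sample(genome$chromosomes$name, 1, prob = genome$chromosomes$length)
      iv <- place_interval(genome, size, ch)
      new_truth_row(sample_id, ch, iv[1], "+", ch, iv[2], "-", "DUP",
                    signature, event_id, hom)
    },
    `BRAF fusion` = {
      br <- genome$braf_region
      size <- draw_size("BRAF fusion")
      start <- floor(stats::runif(1, br$start, br$end - size))
      new_truth_row(sample_id, br$chrom, start, "+", br$chrom, start + size, "-",
                    "DUP", signature, event_id, hom)
    },
    `Unbal inv` = {
      size <- draw_size("Unbal inv")
      ch <- sample(genome$chromosomes$name, 1, prob = genome$chromosomes$length)
      iv <- place_interval(genome, size, ch)
      tp <- sample(c("h2hINV", "t2tINV"), 1)
      o <- svtype_orientations(tp)
      new_truth_row(sample_id, ch, iv[1], o$strand1, ch, iv[2], o$strand2, tp,
                    signature, event_id, hom)
    },
    `Large mixed` = {
      size <- draw_size("Large mixed")
      tp <- sample(c("DEL", "DUP", "h2hINV", "t2tINV"), 1)
      ch <- sample(genome$chromosomes$name[genome$chromosomes$length > size + 2],
                   1)
      iv <- place_interval(genome, size, ch)
      o <- svtype_orientations(tp)
      new_truth_row(sample_id, ch, iv[1], o$strand1, ch, iv[2], o$strand2, tp,
                    signature, event_id, hom)
    },
    `Recip` = {
      # half reciprocal inversions, half reciprocal translocations
      if (stats::runif(1) < 0.5) {
        size <- draw_size("Recip")
        ch <- sample(genome$chromosomes$name, 1, prob = genome$chromosomes$length)
        iv <- place_interval(genome, size, ch)
        off <- round(stats::runif(2, 10, 200))
        rbind(
          new_truth_row(sample_id, ch, iv[1], "-", ch, iv[2], "-", "h2hINV",
                        signature, event_id, hom),
          new_truth_row(sample_id, ch, iv[1] + off[1], "+", ch, iv[2] + off[2],
                        "+", "t2tINV", signature, event_id, draw_homology(signature)))
      } else {
        chs <- sample(genome$chromosomes$name, 2)
        p1 <- floor(stats::runif(1, 1e6, chrom_length(genome, chs[1]) - 1e6))
        p2 <- floor(stats::runif(1, 1e6, chrom_length(genome, chs[2]) - 1e6))
        off <- round(stats::runif(2, 10, 200))
        rbind(
          new_truth_row(sample_id, chs[1], p1, "+", chs[2], p2, "-", "TRA",
                        signature, event_id, hom),
          new_truth_row(sample_id, chs[1], p1 + off[1], "-", chs[2], p2 + off[2],
                        "+", "TRA", signature, event_id, draw_homology(signature)))
      }
    },
    `Unbal tra` = {
      chs <- sample(genome$chromosomes$name, 2)
      p1 <- floor(stats::runif(1, 1e6, chrom_length(genome, chs[1]) - 1e6))
      p2 <- floor(stats::runif(1, 1e6, chrom_length(genome, chs[2]) - 1e6))
      st <- sample(c("+", "-"), 2, replace = TRUE)
      new_truth_row(sample_id, chs[1], p1, st[1], chs[2], p2, st[2], "TRA",
                    signature, event_id, hom)
    })
}

# clustered event: interleaved junctions confined to a footprint, plus the
# copy-number truth implied by its pattern class. Returns list(junctions, cnv).
sim_clustered_event <- function(sample_id, pattern, genome, config, event_id) {
  # confined chromothripsis-like footprints stay under ~9 Mb; the large
  # loss/gain patterns occupy larger territories
  span <- if (pattern %in% c("large_loss", "large_gain")) {
    stats::runif(1, max(1.2e7, config$clustered_span[1]), config$clustered_span[2])
  } else {
    stats::runif(1, config$clustered_span[1], min(9e6, config$clustered_span[2]))
  }
  ok <- genome$chromosomes$length > span + 4e6
  ch <- sample(genome$chromosomes$name[ok], 1)
  L <- chrom_length(genome, ch)
  n_j <- sample(seq(config$clustered_junctions[1], config$clustered_junctions[2]), 1)
  start <- if (pattern == "chr_bridge") {
    # anchored at a chromosome end (telomere loss)
    max(1, L - span - round(stats::runif(1, 0, 2e5)))
  } else floor(stats::runif(1, 2e6, L - span - 2e6))
  end <- start + span

  cnvs <- NULL
  if (pattern == "ecdna") {
    # amplified segments chained into a closed cycle of junctions
    k <- sample(6:10, 1)
    bp <- sort(round(stats::runif(2 * k, start, end)))
    segs <- matrix(bp, ncol = 2, byrow = TRUE)
    junctions <- do.call(rbind, lapply(seq_len(k), function(s) {
      nxt <- if (s == k) 1L else s + 1L
      # junction joins the end of segment s to the start of segment nxt;
      # retained segments point into the amplified intervals. In genome
      # order the pattern is (+,-) = DUP going forward and (-,+) = DEL for
      # the closing back-junction.
      tp <- if (segs[s, 2] <= segs[nxt, 1]) "DUP" else "DEL"
      new_truth_row(sample_id, ch, segs[s, 2], "+", ch, segs[nxt, 1], "-",
                    tp, paste0("clustered:", pattern), event_id,
                    draw_homology("Large mixed"))
    }))
    amp <- round(stats::runif(1, 10, 40))
    cnvs <- data.frame(chrom = ch, start = segs[, 1], end = segs[, 2],
                       copy_number = amp)
  } else {
    junctions <- sim_interleaved_junctions(sample_id, ch, start, end, n_j,
                                           pattern, event_id)
    bp <- sort(unique(c(start, round(stats::runif(n_j, start, end)), end)))
    seg <- data.frame(chrom = ch, start = bp[-length(bp)] + 1, end = bp[-1])
    seg$start[1] <- start
    n_s <- nrow(seg)
    seg$copy_number <- switch(pattern,
      micronuclei = rep(c(2, 1), length.out = n_s),
      chr_bridge = rep(c(2, 1), length.out = n_s),
      large_loss = ifelse(stats::runif(n_s) < 0.75, 1, 2),
      large_gain = ifelse(stats::runif(n_s) < 0.75, 3, 2),
      hourglass = ifelse(stats::runif(n_s) < 0.15, 1, 2))
    if (pattern == "chr_bridge") {
      # lose the terminal segment out to the chromosome end
      seg <- rbind(seg, data.frame(chrom = ch, start = seg$end[n_s] + 1,
                                   end = L, copy_number = 1))
    }
    cnvs <- seg
  }
  list(junctions = junctions, cnv = cnvs)
}

# interleaved breakend pairs with random orientations inside [start, end]
sim_interleaved_junctions <- function(sample_id, ch, start, end, n, pattern,
                                      event_id) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    p <- sort(round(stats::runif(2, start, end)))
    tp <- sample(c("DEL", "DUP", "h2hINV", "t2tINV"), 1)
    o <- svtype_orientations(tp)
    new_truth_row(sample_id, ch, p[1], o$strand1, ch, p[2], o$strand2, tp,
                  paste0("clustered:", pattern), event_id,
                  draw_homology(if (pattern %in% c("large_loss", "hourglass"))
                    "Unbal tra" else "Del0"))
  }))
}

# balanced chromoplexy cycle across k chromosomes
sim_chromoplexy <- function(sample_id, genome, config, event_id) {
  k <- sample(seq(config$chromoplexy_chain[1], config$chromoplexy_chain[2]), 1)
  k <- min(k, nrow(genome$chromosomes))
  chs <- sample(genome$chromosomes$name, k)
  loci <- vapply(chs, function(c2)
    floor(stats::runif(1, 2e6, chrom_length(genome, c2) - 2e6)), numeric(1))
  off <- round(stats::runif(k, 20, 300))
  do.call(rbind, lapply(seq_len(k), function(i) {
    j <- if (i == k) 1L else i + 1L
    # join the right flank of locus i to the left flank of locus j
    new_truth_row(sample_id, chs[i], loci[i] + off[i], "-",
                  chs[j], loci[j], "+", "TRA", "chromoplexy", event_id,
                  draw_homology("Unbal tra"))
  }))
}

# templated-insertion cycle: gained template segments bridged into an
# insertion site. Returns list(junctions, cnv).
sim_tic <- function(sample_id, genome, config, event_id) {
  k <- 2L  # one gained template segment bridged into the insertion site
  chs <- sample(genome$chromosomes$name, k)
  site_ch <- chs[1]
  site <- floor(stats::runif(1, 2e6, chrom_length(genome, site_ch) - 2e6))
  delta <- round(stats::runif(1, 20, 200))
  tpl_ch <- chs[-1]
  tpl <- lapply(tpl_ch, function(c2) {
    w <- round(stats::runif(1, 2e4, 2e5))
    st <- floor(stats::runif(1, 2e6, chrom_length(genome, c2) - 2e6 - w))
    c(st, st + w)
  })
  juncs <- list()
  prev_ch <- site_ch; prev_pos <- site; prev_strand <- "+"
  for (t in seq_along(tpl)) {
    juncs[[length(juncs) + 1L]] <- new_truth_row(
      sample_id, prev_ch, prev_pos, prev_strand,
      tpl_ch[t], tpl[[t]][1], "-", "TRA", "tic", event_id,
      draw_homology("Large mixed"))
    prev_ch <- tpl_ch[t]; prev_pos <- tpl[[t]][2]; prev_strand <- "+"
  }
  juncs[[length(juncs) + 1L]] <- new_truth_row(
    sample_id, prev_ch, prev_pos, prev_strand, site_ch, site + delta, "-",
    "TRA", "tic", event_id, draw_homology("Large mixed"))
  cnv <- do.call(rbind, lapply(seq_along(tpl), function(t)
    data.frame(chrom = tpl_ch[t], start = tpl[[t]][1], end = tpl[[t]][2],
               copy_number = 3)))
  list(junctions = do.call(rbind, juncs), cnv = cnv)
}

# assemble a sample's CNV segments from copy-altering truth, with jittered
# boundaries; covers every chromosome at baseline 2 elsewhere
build_cnv_profile <- function(sample_id, truth, extra_cnv, genome, config) {
  alt <- list()
  if (nrow(truth)) {
    big <- truth$svtype %in% c("DEL", "DUP") &
      truth$chrom1 == truth$chrom2 &
      abs(truth$pos2 - truth$pos1) >= config$cnv_resolution &
      !grepl("^clustered", truth$process) & truth$process != "tic"
    if (any(big)) {
      alt[[1]] <- data.frame(
        chrom = truth$chrom1[big],
        start = pmin(truth$pos1[big], truth$pos2[big]),
        end = pmax(truth$pos1[big], truth$pos2[big]),
        copy_number = ifelse(truth$svtype[big] == "DEL", 1, 3))
    }
  }
  if (!is.null(extra_cnv) && nrow(extra_cnv)) alt[[length(alt) + 1L]] <- extra_cnv
  alt <- do.call(rbind, alt)
  segs <- list()
  for (i in seq_len(nrow(genome$chromosomes))) {
    ch <- genome$chromosomes$name[i]; L <- genome$chromosomes$length[i]
    a <- if (!is.null(alt)) alt[alt$chrom == ch, , drop = FALSE] else
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 copy_number = numeric())
    if (!nrow(a)) {
      segs[[length(segs) + 1L]] <- data.frame(sample_id = sample_id, chrom = ch,
                                              start = 1, end = L, copy_number = 2)
      next
    }
    a <- a[order(a$start), , drop = FALSE]
    bp <- sort(unique(c(1, a$start, a$end + 1, L + 1)))
    # jitter internal boundaries, preserving order
    internal <- bp > 1 & bp < L + 1
    jit <- round(stats::rnorm(sum(internal), 0, config$cnv_jitter_sd))
    jit <- pmax(pmin(jit, 400), -400)
    bp[internal] <- bp[internal] + jit
    bp <- sort(unique(pmax(1, pmin(bp, L + 1))))
    st <- bp[-length(bp)]; en <- bp[-1] - 1
    cn <- vapply(seq_along(st), function(s) {
      mid <- (st[s] + en[s]) / 2
      hit <- which(a$start <= mid & a$end >= mid)
      if (length(hit)) a$copy_number[hit[length(hit)]] else 2
    }, numeric(1))
    keep <- en >= st
    segs[[length(segs) + 1L]] <- data.frame(sample_id = sample_id, chrom = ch,
                                            start = st[keep], end = en[keep],
                                            copy_number = cn[keep])
  }
  res <- do.call(rbind, segs)
  # merge adjacent equal-CN segments
  out <- list()
  for (ch in unique(res$chrom)) {
    s <- res[res$chrom == ch, , drop = FALSE]
    grp <- cumsum(c(1, diff(s$copy_number) != 0))
    m <- do.call(rbind, lapply(split(seq_len(nrow(s)), grp), function(ii)
      data.frame(sample_id = sample_id, chrom = ch, start = s$start[ii[1]],
                 end = s$end[ii[length(ii)]], copy_number = s$copy_number[ii[1]])))
    out[[length(out) + 1L]] <- m
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# noisy caller views of a sample's true junctions plus caller-specific FPs
sim_caller_calls <- function(sample_id, truth, genome, config) {
  out <- list()
  for (cname in names(config$callers)) {
    cs <- config$callers[[cname]]
    if (nrow(truth)) {
      det <- stats::runif(nrow(truth)) < cs$sensitivity
      if (any(det)) {
        d <- truth[det, , drop = FALSE]
        jit <- function(pos, chrom) {
          p <- pos + round(stats::rnorm(length(pos), 0, cs$jitter_sd))
          pmax(1, pmin(p, chrom_length(genome, chrom)))
        }
        d$pos1 <- jit(d$pos1, d$chrom1); d$pos2 <- jit(d$pos2, d$chrom2)
        d$caller <- cname
        d$split_reads <- stats::rpois(nrow(d), cs$support_mean / 2)
        d$read_pairs <- stats::rpois(nrow(d), cs$support_mean / 2)
        if (!cs$reports_homology) {
          d$homology_len <- NA_real_; d$insertion_len <- NA_real_
        }
        out[[length(out) + 1L]] <- d[, c(sv_call_columns())]
      }
    }
    n_fp <- stats::rpois(1, cs$fp_rate * max(nrow(truth), 1))
    if (n_fp > 0) {
      fp <- do.call(rbind, lapply(seq_len(n_fp), function(i) {
        tp <- sample(c("DEL", "DUP", "h2hINV", "t2tINV"), 1)
        size <- round(stats::rlnorm(1, log(5e4), 1.5)) + 100
        ch <- sample(genome$chromosomes$name, 1)
        size <- min(size, chrom_length(genome, ch) - 2)
        iv <- place_interval(genome, size, ch)
        o <- svtype_orientations(tp)
        data.frame(sample_id = sample_id, caller = cname,
                   chrom1 = ch, pos1 = iv[1], strand1 = o$strand1,
                   chrom2 = ch, pos2 = iv[2], strand2 = o$strand2, svtype = tp,
                   split_reads = stats::rpois(1, cs$support_mean / 2),
                   read_pairs = stats::rpois(1, cs$support_mean / 2),
                   homology_len = if (cs$reports_homology) stats::rpois(1, 1) else NA_real_,
                   insertion_len = if (cs$reports_homology) 0 else NA_real_,
                   stringsAsFactors = FALSE)
      }))
      out[[length(out) + 1L]] <- fp
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty_sv_calls())
  rownames(res) <- NULL
  res
}

#' Simulate a complete synthetic cohort
#'
#' Generates, deterministically from `seed`: the toy genome; per-sample
#' ground-truth SVs drawn from the configured signature processes (simple
#' SVs, clustered complex events with copy-number footprints, chromoplexy
#' cycles, templated-insertion cycles); CNV profiles consistent with the
#' copy-altering SVs; three noisy caller callsets (per-caller sensitivity,
#' breakpoint jitter and caller-specific false positives that are never
#' shared between callers); and a sample sheet with sex, mutations,
#' hypermutation flags and exponential survival. Per-sample randomness uses
#' substreams derived from `seed`, so changing the cohort size does not
#' perturb earlier samples.
#'
#' @param config [simulation_config()].
#' @param seed master integer seed.
#' @return list of class `sv_cohort`: `genome`, `truth` (ground-truth
#'   junction table with `process` and `true_event` columns), `callsets`
#'   (`sv_calls` over all callers), `cnv`, `samples`, `config`, `seed`.
#' @export
simulate_cohort <- function(config = simulation_config(), seed = 1) {
  genome <- with_seed(substream_seed(seed, 0), simulate_genome(config))
  span_max <- max(config$clustered_span)
  if (span_max >= max(genome$chromosomes$length))
    stopf("clustered event span %g exceeds every chromosome", span_max)

  types <- rep(names(config$samples_per_type), config$samples_per_type)
  n <- length(types)
  sample_ids <- sprintf("S%04d", seq_len(n))
  truth <- list(); cnv <- list(); calls <- list(); sheet <- list()

  for (i in seq_len(n)) {
    res <- with_seed(substream_seed(seed, i), {
      simulate_sample(sample_ids[i], types[i], genome, config)
    })
    truth[[i]] <- res$truth; cnv[[i]] <- res$cnv; calls[[i]] <- res$calls
    sheet[[i]] <- res$sheet
  }
  truth <- do.call(rbind, truth); rownames(truth) <- NULL
  cohort <- list(genome = genome,
                 truth = truth,
                 callsets = {
                   cc <- do.call(rbind, calls); rownames(cc) <- NULL
                   sv_calls(cc, genome)
                 },
                 cnv = { cv <- do.call(rbind, cnv); rownames(cv) <- NULL; cv },
                 samples = do.call(rbind, sheet),
                 config = config, seed = seed)
  class(cohort) <- "sv_cohort"
  cohort
}

# one sample's truth, CNV, caller calls and sample-sheet row
simulate_sample <- function(sample_id, type, genome, config) {
  act <- config$activity[type, ]
  truth <- list(); extra_cnv <- list()
  ev <- 0L
  next_ev <- function() {
    ev <<- ev + 1L
    sprintf("%s_true%03d", sample_id, ev)
  }
  # territory already altered by earlier events; simple SVs avoid it so that
  # independent processes stay spatially distinct (margin 50 kb)
  occupied <- data.frame(chrom = character(), start = numeric(), end = numeric())
  claim <- function(rows) {
    intra <- rows$chrom1 == rows$chrom2
    occ <- rbind(
      if (any(intra)) data.frame(chrom = rows$chrom1[intra],
                                 start = pmin(rows$pos1, rows$pos2)[intra],
                                 end = pmax(rows$pos1, rows$pos2)[intra]),
      if (any(!intra)) data.frame(
        chrom = c(rows$chrom1[!intra], rows$chrom2[!intra]),
        start = c(rows$pos1[!intra], rows$pos2[!intra]),
        end = c(rows$pos1[!intra], rows$pos2[!intra])))
    occupied <<- rbind(occupied, occ)
  }
  is_free <- function(rows, margin = 5e4) {
    if (!nrow(occupied)) return(TRUE)
    be <- data.frame(chrom = c(rows$chrom1, rows$chrom2),
                     pos = c(rows$pos1, rows$pos2))
    all(point_interval_distance(be$chrom, be$pos, occupied) > margin)
  }

  # complex events first: they own large territories
  n_cl <- stats::rpois(1, act[["clustered"]])
  for (s in seq_len(n_cl)) {
    pattern <- sample(colnames(config$clustered_patterns), 1,
                      prob = config$clustered_patterns[type, ])
    for (try in 1:10) {
      r <- sim_clustered_event(sample_id, pattern, genome, config, next_ev())
      if (is_free(r$junctions)) break
    }
    truth[[length(truth) + 1L]] <- r$junctions
    extra_cnv[[length(extra_cnv) + 1L]] <- r$cnv
    claim(r$junctions)
  }
  n_cp <- stats::rpois(1, act[["chromoplexy"]])
  for (s in seq_len(n_cp)) {
    for (try in 1:10) {
      r <- sim_chromoplexy(sample_id, genome, config, next_ev())
      if (is_free(r)) break
    }
    truth[[length(truth) + 1L]] <- r
    claim(r)
  }
  n_tic <- stats::rpois(1, act[["tic"]])
  for (s in seq_len(n_tic)) {
    for (try in 1:10) {
      r <- sim_tic(sample_id, genome, config, next_ev())
      if (is_free(r$junctions)) break
    }
    truth[[length(truth) + 1L]] <- r$junctions
    extra_cnv[[length(extra_cnv) + 1L]] <- r$cnv
    claim(r$junctions)
  }
  for (sig in signature_names()) {
    n_sv <- stats::rpois(1, act[[sig]])
    for (s in seq_len(n_sv)) {
      for (try in 1:30) {
        cand <- sim_simple_sv(sample_id, sig, genome, next_ev())
        if (is_free(cand)) break
      }
      truth[[length(truth) + 1L]] <- cand
      claim(cand)
    }
  }
  truth <- do.call(rbind, truth) %||% cbind(empty_sv_calls(),
                                            data.frame(process = character(),
                                                       true_event = character()))
  if (nrow(truth)) truth <- normalize_breakend_order(truth, genome)
  extra_cnv <- do.call(rbind, extra_cnv)
  cnv <- build_cnv_profile(sample_id, truth, extra_cnv, genome, config)
  calls <- sim_caller_calls(sample_id, truth, genome, config)

  # metadata: mutations coupled to processes, exponential survival
  has_clustered <- any(grepl("^clustered", truth$process))
  has_effect_sig <- config$survival_effect$signature %in% truth$process
  mut <- character()
  for (g in config$mutation_genes) {
    p <- 0.04
    if (g == "TP53" && has_clustered) p <- 0.6
    if (g == "H3F3A" && "tic" %in% truth$process) p <- 0.4
    if (stats::runif(1) < p) {
      cls <- sample(c("missense", "nonsense", "frameshift", "splice_site"), 1)
      mut <- c(mut, paste0(g, ":", cls))
    }
  }
  hazard <- config$baseline_hazard *
    if (has_effect_sig) config$survival_effect$hr else 1
  t_event <- stats::rexp(1, hazard)
  t_cens <- stats::runif(1, 500, 3000)
  sheet <- data.frame(
    sample_id = sample_id, tumor_type = type,
    sex = sample(c("male", "female"), 1),
    hypermutated = as.integer(stats::runif(1) < config$hypermutation_rate),
    survival_time = round(min(t_event, t_cens)),
    survival_event = ifelse(t_event <= t_cens, "death", "censored"),
    mutations = paste(mut, collapse = ";"),
    stringsAsFactors = FALSE)
  list(truth = truth, cnv = cnv, calls = calls, sheet = sheet)
}

#' @export
print.sv_cohort <- function(x, ...) {
  cat(sprintf("<sv_cohort> %d samples, %d true SVs, %d caller calls\n",
              nrow(x$samples), nrow(x$truth), nrow(x$callsets)))
  invisible(x)
}

#' Simulate feature tracks independent of all breakpoints
#'
#' Interval tracks with Poisson-placed intervals; optionally, one track can
#' receive planted enrichment by adding intervals centered on a fraction of
#' the supplied breakpoints.
#'
#' @param config [simulation_config()].
#' @param genome `genome_model`.
#' @param seed integer seed.
#' @param breakends optional `data.frame(chrom, pos)` used only when
#'   `config$planted_enrichment` is set.
#' @return `feature_track_set` with `config$n_feature_tracks` tracks.
#' @export
simulate_null_features <- function(config, genome, seed = 1, breakends = NULL) {
  if (config$n_feature_tracks == 0) return(feature_track_set(list()))
  with_seed(substream_seed(seed, 900001), {
    tracks <- lapply(seq_len(config$n_feature_tracks), function(t) {
      ivs <- do.call(rbind, lapply(seq_len(nrow(genome$chromosomes)), function(i) {
        L <- genome$chromosomes$length[i]
        k <- stats::rpois(1, config$feature_interval_density * L / 1e6)
        if (!k) return(NULL)
        st <- sort(floor(stats::runif(k, 1, L - config$feature_interval_width)))
        w <- pmax(100, round(stats::rexp(k, 1 / config$feature_interval_width)))
        data.frame(chrom = genome$chromosomes$name[i], start = st,
                   end = pmin(st + w, L))
      }))
      feature_track(sprintf("track%02d", t), "interval", ivs, units = "kb")
    })
    pe <- config$planted_enrichment
    if (!is.null(pe) && !is.null(breakends) && nrow(breakends)) {
      ti <- pe$track
      take <- stats::runif(nrow(breakends)) < pe$fraction
      if (any(take)) {
        add <- data.frame(chrom = breakends$chrom[take],
                          start = pmax(1, breakends$pos[take] - 250),
                          end = breakends$pos[take] + 250)
        tracks[[ti]]$data <- rbind(tracks[[ti]]$data, add)
      }
    }
    feature_track_set(tracks)
  })
}

#' Write a simulated cohort to disk in the formats the readers consume
#'
#' Per-caller BEDPE callsets, a CNV TSV, the sample sheet and (optionally)
#' feature tracks with a manifest.
#'
#' @param cohort `sv_cohort` from [simulate_cohort()].
#' @param dir output directory.
#' @param tracks optional `feature_track_set`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, tracks = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cname in unique(cohort$callsets$caller)) {
    write_sv_bedpe(cohort$callsets[cohort$callsets$caller == cname, , drop = FALSE],
                   file.path(dir, paste0(cname, ".bedpe")))
  }
  write_cnv_segments(cohort$cnv, file.path(dir, "cnv_segments.tsv"))
  write_sample_sheet(cohort$samples, file.path(dir, "samples.tsv"))
  if (!is.null(tracks)) write_feature_tracks(tracks, file.path(dir, "features"))
  invisible(dir)
}

#' Match consensus SVs back to simulation ground truth
#'
#' Nearest-truth matching by chromosome pair, orientation pair and both
#' breakends within `tol` bp.
#'
#' @param svs consensus (or any) `sv_calls`.
#' @param truth ground-truth table from [simulate_cohort()].
#' @param tol matching tolerance in bp (default 25, generous to caller
#'   jitter).
#' @return integer vector: matching truth row index per SV, NA if none.
#' @export
match_to_truth <- function(svs, truth, tol = 25) {
  vapply(seq_len(nrow(svs)), function(i) {
    cand <- which(truth$sample_id == svs$sample_id[i] &
                    truth$chrom1 == svs$chrom1[i] & truth$chrom2 == svs$chrom2[i] &
                    truth$strand1 == svs$strand1[i] & truth$strand2 == svs$strand2[i] &
                    abs(truth$pos1 - svs$pos1[i]) <= tol &
                    abs(truth$pos2 - svs$pos2[i]) <= tol)
    if (length(cand)) cand[which.min(abs(truth$pos1[cand] - svs$pos1[i]) +
                                       abs(truth$pos2[cand] - svs$pos2[i]))]
    else NA_integer_
  }, integer(1))
}
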