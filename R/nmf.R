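# Signature extraction: KL-divergence NMF with Poisson-resampled restarts and
# silhouette-based rank selection.

# one multiplicative-update KL NMF run; V is categories x samples.
# trace = TRUE records the KL objective after every iteration.
nmf_kl_run <- function(V, k, max_iter = 2000, tol = 1e-8, trace = FALSE) {
  m <- nrow(V); n <- ncol(V)
  eps <- .Machine$double.eps
  W <- matrix(stats::runif(m * k, 0.1, 1), m, k)
  H <- matrix(stats::runif(k * n, 0.1, 1), k, n)
  obj_prev <- Inf
  kl <- function(V, WH) sum(ifelse(V > 0, V * log(V / WH), 0) - V + WH)
  objectives <- if (trace) numeric(max_iter) else NULL
  for (it in seq_len(max_iter)) {
    WH <- W %*% H + eps
    H <- H * (t(W) %*% (V / WH)) / pmax(colSums(W), eps)
    WH <- W %*% H + eps
    W <- W * ((V / WH) %*% t(H)) / matrix(pmax(rowSums(H), eps), m, k, byrow = TRUE)
    if (trace) objectives[it] <- kl(V, W %*% H + eps)
    if (it %% 10 == 0 || it == max_iter) {
      obj <- kl(V, W %*% H + eps)
      if (is.finite(obj_prev) && (obj_prev - obj) <= tol * max(obj_prev, 1)) break
      obj_prev <- obj
    }
  }
  scale <- pmax(colSums(W), eps)
  W <- sweep(W, 2, scale, "/")
  H <- sweep(H, 1, scale, "*")
  list(W = W, H = H, objective = kl(V, W %*% H + eps), iterations = it,
       objectives = if (trace) objectives[seq_len(it)] else NULL)
}

# mean silhouette of k-means clusters of stacked signature vectors (cosine
# geometry via L2-normalized columns)
signature_silhouette <- function(Ws, k) {
  X <- do.call(cbind, Ws)
  Xn <- sweep(X, 2, pmax(sqrt(colSums(X^2)), .Machine$double.eps), "/")
  if (k == 1) return(list(silhouette = 1, centers = rowMeans(X)))
  km <- stats::kmeans(t(Xn), centers = k, nstart = 5, iter.max = 50)
  d <- 1 - crossprod(Xn)  # cosine distance
  n <- ncol(Xn)
  sil <- vapply(seq_len(n), function(i) {
    own <- km$cluster[i]
    a_idx <- which(km$cluster == own & seq_len(n) != i)
    a <- if (length(a_idx)) mean(d[i, a_idx]) else 0
    b <- min(vapply(setdiff(unique(km$cluster), own),
                    function(cl) mean(d[i, km$cluster == cl]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  centers <- vapply(seq_len(k), function(cl)
    rowMeans(X[, km$cluster == cl, drop = FALSE]), numeric(nrow(X)))
  list(silhouette = mean(sil), centers = centers)
}

#' Extract simple-SV signatures by NMF with rank selection
#'
#' For each candidate rank `k`, runs `n_restarts` KL-divergence
#' multiplicative-update NMF fits on Poisson-resampled copies of the catalog,
#' pools the resulting signature vectors, clusters them into `k` groups and
#' scores cluster stability by the mean cosine silhouette. The chosen rank is
#' the largest `k` whose mean silhouette reaches `stability_threshold` and
#' whose mean resampled reconstruction error improves on the next smaller
#' candidate rank by more than the AIC-style overfitting allowance
#' (`rank_penalty * (categories + samples)` KL units per added component) —
#' a stable split of an already-explained signature improves the fit only by
#' what its extra parameters absorb from noise, and is not evidence for a
#' higher rank; the
#' reported signatures are a final fit on the unresampled catalog, aligned to
#' the cluster centers. Deterministic given `seed`.
#'
#' @param catalog samples x categories count matrix (as [build_catalog()]).
#' @param k_range candidate ranks (subset of `1:min(ncats, nsamples)`).
#' @param n_restarts resampled NMF runs per rank (default 100).
#' @param seed integer seed controlling resampling and initialization.
#' @param stability_threshold minimal mean silhouette (default 0.8).
#' @param rank_penalty multiplier of the per-component parameter count in
#'   the reconstruction-improvement requirement (default 2; 1 is the AIC
#'   scale, and the stricter default guards against plateau noise in the
#'   resampled error curve).
#' @param max_iter,tol multiplicative-update iteration cap and relative
#'   objective tolerance.
#' @return object of class `svsig_nmf` with elements `W` (categories x K,
#'   columns sum to 1), `H` (K x samples), `rank`, `stability` (per-rank mean
#'   silhouette), `reconstruction_error`, `k_range`.
#' @export
nmf_extract <- function(catalog, k_range = 1:12, n_restarts = 100, seed = 1,
                        stability_threshold = 0.8, rank_penalty = 2,
                        max_iter = 2000, tol = 1e-8) {
  V <- t(as.matrix(catalog))  # categories x samples
  if (all(V == 0)) stopf("all-zero catalog: nothing to factorize")
  if (!length(k_range)) stopf("empty k_range")
  k_range <- sort(unique(as.integer(k_range)))
  kmax <- min(nrow(V), ncol(V))
  if (any(k_range < 1 | k_range > kmax))
    stopf("k_range must lie in [1, %d]", kmax)

  with_seed(seed, {
    stability <- numeric(length(k_range))
    mean_error <- numeric(length(k_range))
    centers_by_k <- vector("list", length(k_range))
    for (ki in seq_along(k_range)) {
      k <- k_range[ki]
      runs <- lapply(seq_len(n_restarts), function(r) {
        Vr <- matrix(stats::rpois(length(V), lambda = V), nrow(V), ncol(V))
        if (all(Vr == 0)) Vr <- V
        nmf_kl_run(Vr, k, max_iter = max_iter, tol = tol)
      })
      # poorly converged restarts (stuck local optima) would contaminate the
      # stability clusters; keep the better-converged majority
      objs <- vapply(runs, `[[`, numeric(1), "objective")
      keep <- rank(objs, ties.method = "first") <=
        max(2, ceiling(0.6 * length(runs)))
      runs <- runs[keep]
      s <- signature_silhouette(lapply(runs, `[[`, "W"), k)
      stability[ki] <- s$silhouette
      mean_error[ki] <- mean(objs[keep])
      centers_by_k[[ki]] <- s$centers
    }
    # a rank is supported when its signature clusters are stable AND adding
    # its components buys more KL improvement than the parameters they add
    # can explain by overfitting alone (AIC-style: each component carries
    # ~(categories + samples) free parameters)
    ok <- stability >= stability_threshold
    params_per_rank <- nrow(V) + ncol(V)
    for (ki in seq_along(k_range)) {
      if (ki == 1 || !ok[ki]) next
      dk <- k_range[ki] - k_range[ki - 1]
      if (mean_error[ki - 1] - mean_error[ki] <
          rank_penalty * params_per_rank * dk)
        ok[ki] <- FALSE
    }
    chosen <- if (any(ok)) max(k_range[ok]) else k_range[which.max(stability)]
    ci <- match(chosen, k_range)

    # final deterministic fit on the unresampled catalog; best of a few starts
    fits <- lapply(seq_len(min(5, n_restarts)), function(r)
      nmf_kl_run(V, chosen, max_iter = max_iter, tol = tol))
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
    W <- best$W; H <- best$H
    # align to stability-cluster centers for a reproducible column order
    centers <- matrix(centers_by_k[[ci]], nrow = nrow(V))
    ord <- greedy_match_columns(centers, W)
    W <- W[, ord, drop = FALSE]; H <- H[ord, , drop = FALSE]
    rownames(W) <- colnames(catalog)
    colnames(W) <- paste0("S", seq_len(chosen))
    rownames(H) <- colnames(W); colnames(H) <- rownames(catalog)

    structure(list(W = W, H = H, rank = chosen,
                   stability = stats::setNames(stability, k_range),
                   mean_resampled_error = stats::setNames(mean_error, k_range),
                   reconstruction_error = best$objective,
                   k_range = k_range, n_restarts = n_restarts, seed = seed),
              class = "svsig_nmf")
  })
}

# greedy one-to-one assignment of columns of b to columns of a by cosine
# similarity; returns the permutation of b's columns
greedy_match_columns <- function(a, b) {
  sim <- cosine_sim_matrix(a, b)
  k <- ncol(b)
  ord <- integer(k)
  used_a <- logical(ncol(a)); used_b <- logical(k)
  for (step in seq_len(min(k, ncol(a)))) {
    sim2 <- sim
    sim2[used_a, ] <- -Inf; sim2[, used_b] <- -Inf
    idx <- arrayInd(which.max(sim2), dim(sim2))
    ord[idx[1]] <- idx[2]
    used_a[idx[1]] <- TRUE; used_b[idx[2]] <- TRUE
  }
  ord[ord == 0] <- which(!used_b)
  ord
}

#' @export
print.svsig_nmf <- function(x, ...) {
  cat(sprintf("<svsig_nmf> rank %d over %d categories x %d samples\n",
              x$rank, nrow(x$W), ncol(x$H)))
  cat("  per-rank stability (mean silhouette):\n")
  print(round(x$stability, 3))
  cat(sprintf("  KL reconstruction error: %.4g\n", x$reconstruction_error))
  invisible(x)
}

#' @export
summary.svsig_nmf <- function(object, ...) {
  exp_share <- rowSums(object$H) / sum(object$H)
  top <- apply(object$W, 2, function(w)
    paste(utils::head(rownames(object$W)[order(-w)], 3), collapse = ", "))
  out <- data.frame(signature = colnames(object$W),
                    exposure_share = round(exp_share, 3),
                    top_categories = top, row.names = NULL)
  print(out)
  invisible(out)
}

#' @export
coef.svsig_nmf <- function(object, ...) object$W

#' @export
fitted.svsig_nmf <- function(object, ...) t(object$W %*% object$H)

#' @export
plot.svsig_nmf <- function(x, ...) {
  old <- graphics::par(mfrow = c(x$rank, 1), mar = c(2, 3, 1.5, 0.5))
  on.exit(graphics::par(old))
  for (k in seq_len(x$rank)) {
    graphics::barplot(x$W[, k], main = colnames(x$W)[k], las = 2,
                      cex.names = 0.4, col = "steelblue", border = NA, ...)
  }
  invisible(x)
}

#' Deterministic final-signature assignment rules
#'
#' Total mapping from the 49 subcategories (plus the BRAF-fusion flag) to the
#' nine final signature names.
#'
#' @param schema [simple_sv_schema()].
#' @return named character vector, subcategory -> signature.
#' @export
assignment_rules <- function(schema = simple_sv_schema()) {
  stats::setNames(schema$signature, schema$subcategory)
}

#' Assign final signatures to classified simple SVs
#'
#' Applies [assignment_rules()] to each SV's subcategory; SVs flagged as
#' BRAF-fusion tandem duplications get the stand-alone "BRAF fusion"
#' signature.
#'
#' @param typed typed simple SVs with `subcategory` and `braf_fusion`
#'   columns.
#' @param rules [assignment_rules()].
#' @return character vector of signature labels, one per row.
#' @export
assign_final_signatures <- function(typed, rules = assignment_rules()) {
  if (!nrow(typed)) return(character())
  sig <- unname(rules[typed$subcategory])
  if (anyNA(sig)) stopf("subcategory without an assignment rule: %s",
                        paste(unique(typed$subcategory[is.na(sig)]), collapse = ", "))
  if (!is.null(typed$braf_fusion)) sig[typed$braf_fusion] <- "BRAF fusion"
  sig
}
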