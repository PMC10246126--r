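# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percentage of a count, formatted the way cohort summaries print it
#'
#' Computes `100 * count / total` rounded half-up to `digits` decimal places.
#' Returns 0 when `total` is 0 so empty cohorts never divide by zero.
#'
#' @param count Numerator count.
#' @param total Denominator count.
#' @param digits Decimal places (default 1).
#' @return Numeric percentage.
#' @examples
#' pct(7601, 13199)   # 57.6
#' pct(13, 23, 0)     # 57
#' @export
pct <- function(count, total, digits = 1) {
  if (length(total) == 1L && total == 0) return(rep(0, length(count)))
  round_half_up(100 * count / total, digits)
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; cohort percentage reporting uses the
#' conventional half-up rule (0.05 -> 0.1 at one decimal).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# deterministic substream seed derived from a master seed and an index;
# keeps per-sample draws stable when cohort size changes, and stays < 2^31
substream_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271) %% 2147483647
  x <- (x + as.double(index) * 69621) %% 2147483647
  as.integer((x * 16807) %% 2147483629) + 1L
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# stop with a message assembled from sprintf parts
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# cosine similarity between columns of two matrices (returns length-k vector
# when ncol(a) == ncol(b), comparing matched columns)
cosine_sim <- function(a, b) {
  na <- sqrt(colSums(a^2)); nb <- sqrt(colSums(b^2))
  colSums(a * b) / pmax(na * nb, .Machine$double.eps)
}

# all-pairs cosine similarity matrix between columns of a and columns of b
cosine_sim_matrix <- function(a, b) {
  an <- sweep(a, 2, pmax(sqrt(colSums(a^2)), .Machine$double.eps), "/")
  bn <- sweep(b, 2, pmax(sqrt(colSums(b^2)), .Machine$double.eps), "/")
  crossprod(an, bn)
}

#' Rand index between two partitions
#'
#' Agreement between two clusterings of the same items, as the fraction of
#' item pairs on which the partitions agree (both together or both apart).
#' Used to score event-membership recovery against simulation ground truth.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return Rand index in \[0, 1\]; 1 for identical partitions.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) return(1)
  tab <- table(a, b)
  s_ij <- sum(choose(tab, 2))
  s_a <- sum(choose(rowSums(tab), 2))
  s_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * s_ij - s_a - s_b) / total
}
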