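#' Hi-C matrix comparison metrics
#'
#' Four reproducibility metrics over a pair of matrices sharing one bin table:
#' banded Spearman correlation, Pearson correlation of observed/expected
#' ratios, the stratum-adjusted correlation coefficient (SCC) and a spectral
#' score based on Laplacian eigenvectors. All restrict to intra-chromosomal
#' (cis) contacts up to `max_dist` (except the spectral score, which uses the
#' whole cis block) and to bins unmasked in both matrices; zero cells inside
#' the band are included so that results do not depend on sparsity patterns.
#'
#' @param m1,m2 `ContactMatrix` objects over the same bin table.
#' @param max_dist Maximum genomic distance in bp (default 5e6).
#' @param pair Optional metadata (identifiers, same/different labels) stored in
#'   the result.
#' @return An object of class `oned_comparison`: list with `metric`, `value`,
#'   `max_dist`, `params` and `pair`.
#' @name comparison
NULL

comparison_result <- function(metric, value, max_dist, params = list(),
                              pair = list()) {
  structure(list(metric = metric, value = value, max_dist = max_dist,
                 params = params, pair = pair),
            class = "oned_comparison")
}

#' @export
print.oned_comparison <- function(x, ...) {
  cat(sprintf("%s = %.6f (max_dist = %s)\n", x$metric, x$value,
              format(x$max_dist, big.mark = ",")))
  invisible(x)
}

check_shared_bins <- function(m1, m2) {
  stopifnot(inherits(m1, "ContactMatrix"), inherits(m2, "ContactMatrix"))
  if (!identical(m1$bins, m2$bins))
    stop("matrices must share the same bin table")
}

# dense cis block of one chromosome (local indices)
dense_cis_block <- function(m, chr) {
  idx <- which(m$bins$chrom == chr)
  n <- length(idx)
  M <- matrix(0, n, n)
  p <- m$pixels
  keep <- m$bins$chrom[p$bin1 + 1L] == chr & m$bins$chrom[p$bin2 + 1L] == chr
  p <- p[keep, , drop = FALSE]
  if (nrow(p)) {
    i <- p$bin1 + 1L - idx[1] + 1L
    j <- p$bin2 + 1L - idx[1] + 1L
    M[cbind(i, j)] <- p$count
    M[cbind(j, i)] <- p$count
  }
  M
}

# paired vectors of banded cis cells (i <= j), both bins unmasked in both
band_vectors <- function(m1, m2, max_dist) {
  check_shared_bins(m1, m2)
  res <- resolution(m1)
  dmax <- floor(max_dist / res)
  ok <- !m1$mask & !m2$mask
  v1 <- v2 <- numeric(0)
  for (chr in unique(m1$bins$chrom)) {
    idx <- which(m1$bins$chrom == chr)
    M1 <- dense_cis_block(m1, chr)
    M2 <- dense_cis_block(m2, chr)
    okc <- ok[idx]
    n <- length(idx)
    for (d in 0:min(dmax, n - 1)) {
      i <- seq_len(n - d)
      j <- i + d
      sel <- okc[i] & okc[j]
      if (!any(sel)) next
      v1 <- c(v1, M1[cbind(i[sel], j[sel])])
      v2 <- c(v2, M2[cbind(i[sel], j[sel])])
    }
  }
  if (!length(v1)) stop("empty comparison band")
  list(v1 = v1, v2 = v2)
}

#' @rdname comparison
#' @export
banded_spearman <- function(m1, m2, max_dist = 5e6, pair = list()) {
  b <- band_vectors(m1, m2, max_dist)
  comparison_result("spearman",
                    stats::cor(b$v1, b$v2, method = "spearman"),
                    max_dist, pair = pair)
}

#' @rdname comparison
#' @export
oe_pearson <- function(m1, m2, max_dist = 5e6, pair = list()) {
  b <- band_vectors(observed_over_expected(m1), observed_over_expected(m2),
                    max_dist)
  comparison_result("oe_pearson", stats::cor(b$v1, b$v2), max_dist, pair = pair)
}

# truncated-window 2D mean filter with half-window h (via integral image)
box_smooth <- function(M, h) {
  if (h <= 0) return(M)
  n <- nrow(M)
  S <- matrix(0, n + 1, n + 1)
  S[-1, -1] <- apply(apply(M, 2, cumsum), 1, cumsum)  # transposed integral
  S[-1, -1] <- t(S[-1, -1, drop = FALSE])
  lo <- pmax(seq_len(n) - h, 1L); hi <- pmin(seq_len(n) + h, n)
  cnt1 <- hi - lo + 1L
  out <- S[hi + 1L, hi + 1L, drop = FALSE] - S[lo, hi + 1L, drop = FALSE] -
    S[hi + 1L, lo, drop = FALSE] + S[lo, lo, drop = FALSE]
  out / outer(cnt1, cnt1)
}

#' @rdname comparison
#' @param smooth_h Half-window of the 2D mean filter applied before
#'   stratifying (default 2, i.e. a 5x5 window at the working resolution);
#'   0 disables smoothing.
#' @export
scc <- function(m1, m2, max_dist = 5e6, smooth_h = 2, pair = list()) {
  check_shared_bins(m1, m2)
  res <- resolution(m1)
  dmax <- floor(max_dist / res)
  ok <- !m1$mask & !m2$mask
  wsum <- 0; wr <- 0; n_strata <- 0L
  for (chr in unique(m1$bins$chrom)) {
    idx <- which(m1$bins$chrom == chr)
    okc <- ok[idx]
    M1 <- box_smooth(dense_cis_block(m1, chr), smooth_h)
    M2 <- box_smooth(dense_cis_block(m2, chr), smooth_h)
    n <- length(idx)
    for (d in 0:min(dmax, n - 1)) {
      i <- seq_len(n - d); j <- i + d
      sel <- okc[i] & okc[j]
      if (sum(sel) < 2) next
      a <- M1[cbind(i[sel], j[sel])]
      b <- M2[cbind(i[sel], j[sel])]
      sda <- stats::sd(a); sdb <- stats::sd(b)
      if (sda == 0 || sdb == 0) next   # zero-variance stratum carries no signal
      w <- length(a) * sda * sdb
      wsum <- wsum + w
      wr <- wr + w * stats::cor(a, b)
      n_strata <- n_strata + 1L
    }
  }
  if (wsum == 0) stop("no stratum with variance in the comparison band")
  comparison_result("scc", wr / wsum, max_dist,
                    params = list(smooth_h = smooth_h, n_strata = n_strata),
                    pair = pair)
}

#' @rdname comparison
#' @param n_eigs Number of non-trivial Laplacian eigenvectors compared per
#'   chromosome (default 20; reduced and recorded when a chromosome has too
#'   few usable bins).
#' @export
spectral_score <- function(m1, m2, n_eigs = 20, pair = list()) {
  check_shared_bins(m1, m2)
  ok <- !m1$mask & !m2$mask
  scores <- numeric(0)
  used_eigs <- integer(0)
  for (chr in unique(m1$bins$chrom)) {
    idx <- which(m1$bins$chrom == chr)
    M1 <- dense_cis_block(m1, chr)
    M2 <- dense_cis_block(m2, chr)
    keep <- ok[idx] & rowSums(M1) > 0 & rowSums(M2) > 0
    if (sum(keep) < 3) next
    M1 <- M1[keep, keep, drop = FALSE]
    M2 <- M2[keep, keep, drop = FALSE]
    k <- min(n_eigs, nrow(M1) - 1L)
    V1 <- laplacian_eigenvectors(M1, k)
    V2 <- laplacian_eigenvectors(M2, k)
    d <- vapply(seq_len(k), function(i) {
      a <- V1[, i]; b <- V2[, i]
      min(sqrt(sum((a - b)^2)), sqrt(sum((a + b)^2)))  # sign alignment
    }, numeric(1))
    scores <- c(scores, max(0, 1 - sum(d) / (k * sqrt(2))))
    used_eigs <- c(used_eigs, k)
  }
  if (!length(scores)) stop("no chromosome with enough usable bins")
  comparison_result("spectral", mean(scores), max_dist = NA_real_,
                    params = list(n_eigs = used_eigs), pair = pair)
}

# leading k non-trivial eigenvectors (ascending eigenvalue, unit norm) of the
# symmetric normalized Laplacian L = I - D^-1/2 W D^-1/2
laplacian_eigenvectors <- function(W, k) {
  dg <- rowSums(W)
  s <- 1 / sqrt(dg)
  L <- diag(nrow(W)) - (s * W) * rep(s, each = nrow(W))
  L <- (L + t(L)) / 2
  ev <- eigen(L, symmetric = TRUE)
  n <- ncol(ev$vectors)
  # eigenvalues come in descending order; trivial eigenvector is the last
  V <- ev$vectors[, seq(n - 1, n - k), drop = FALSE]
  sweep(V, 2, sqrt(colSums(V^2)), "/")
}

#' ROC evaluation of comparison scores
#'
#' Interprets similarity scores as a binary classifier of pair relation (e.g.
#' same versus different cell type) and sweeps the score threshold to build a
#' receiver operating characteristic curve; tied scores enter simultaneously.
#' The area under the curve is computed by the trapezoidal rule and equals the
#' normalized Mann-Whitney U statistic.
#'
#' @param results Either a list of `oned_comparison` objects (scores taken
#'   from `value`, labels from `pair$relation`) or a numeric vector of scores.
#' @param labels Labels parallel to `results` (ignored when `results` carry
#'   their own `pair$relation`).
#' @param positive The label counted as positive.
#' @return List with `points` (a `data.frame` of threshold, fpr, tpr) and
#'   `auc`.
#' @export
roc_evaluate <- function(results, labels = NULL, positive) {
  if (is.list(results) && length(results) &&
      inherits(results[[1]], "oned_comparison")) {
    scores <- vapply(results, function(r) r$value, numeric(1))
    labels <- vapply(results, function(r) as.character(r$pair$relation),
                     character(1))
  } else {
    scores <- as.numeric(results)
  }
  stopifnot(length(scores) == length(labels))
  y <- labels == positive
  if (!any(y) || all(y))
    stop("need at least one positive and one negative pair")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(s) mean(scores[y] >= s), numeric(1))
  fpr <- vapply(thr, function(s) mean(scores[!y] >= s), numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  list(points = pts, auc = auc)
}
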