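#' Matrix-balancing baselines
#'
#' Implicit normalizers that enforce equal per-bin totals rather than modeling
#' biases: `vanilla` (a single iteration of iterative correction), `ice`
#' (iterative correction to convergence) and `kr` (Knight-Ruiz Newton-type
#' balancing). All operate on the unmasked submatrix and express their result
#' as a per-bin bias vector `b` with corrected entries `x_ij / (b_i * b_j)`.
#'
#' @param m A `ContactMatrix` (empty bins are masked automatically).
#' @return An object of class `oned_balance`: list with `biases` (per-bin,
#'   `NA` on masked bins), `corrected` (`ContactMatrix`), `n_iter`,
#'   `converged` and `method`.
#' @name balancing
NULL

balance_result <- function(m, biases, n_iter, converged, method) {
  corrected <- apply_bin_correction(m, ifelse(is.na(biases), 1, biases)^2)
  structure(list(biases = biases, corrected = corrected, n_iter = n_iter,
                 converged = converged, method = method),
            class = "oned_balance")
}

#' @export
print.oned_balance <- function(x, ...) {
  cat(sprintf("%s balancing: %d iteration(s), converged: %s\n",
              x$method, x$n_iter, x$converged))
  invisible(x)
}

#' @rdname balancing
#' @export
vanilla <- function(m) {
  stopifnot(inherits(m, "ContactMatrix"))
  m <- set_mask(m, m$mask | auto_mask(m))
  t <- contact_profile(m)
  ok <- !m$mask
  b <- rep(NA_real_, n_bins(m))
  b[ok] <- t[ok] / mean(t[ok])
  balance_result(m, b, n_iter = 1L, converged = TRUE, method = "vanilla")
}

#' @rdname balancing
#' @param tol Convergence tolerance: for `ice`, the coefficient of variation of
#'   per-bin totals (default 1e-5); for `kr`, the maximum deviation of the
#'   balanced row sums from 1 (default 1e-6).
#' @param max_iter Maximum iterations (default 200 for `ice`).
#' @export
ice <- function(m, tol = 1e-5, max_iter = 200) {
  stopifnot(inherits(m, "ContactMatrix"))
  m <- set_mask(m, m$mask | auto_mask(m))
  ok <- !m$mask
  n <- n_bins(m)
  b <- rep(1, n)
  work <- m
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    t <- contact_profile(work)
    cv <- stats::sd(t[ok]) / mean(t[ok])
    if (is.finite(cv) && cv < tol) { converged <- TRUE; break }
    iter <- iter + 1L
    step <- rep(1, n)
    step[ok] <- t[ok] / mean(t[ok])
    b <- b * step
    work <- apply_bin_correction(m, b^2)
  }
  biases <- rep(NA_real_, n)
  biases[ok] <- b[ok]
  res <- balance_result(m, biases, n_iter = iter, converged = converged,
                        method = "ice")
  res
}

#' @rdname balancing
#' @export
kr <- function(m, tol = 1e-6) {
  stopifnot(inherits(m, "ContactMatrix"))
  m <- set_mask(m, m$mask | auto_mask(m))
  ok <- !m$mask
  A <- as.matrix(m)[ok, ok, drop = FALSE]
  x <- kr_balance(A, tol = tol)
  if (is.null(x))
    return(balance_result(m, {
      b <- rep(NA_real_, n_bins(m)); b[ok] <- 1; b
    }, n_iter = 0L, converged = FALSE, method = "kr"))
  biases <- rep(NA_real_, n_bins(m))
  biases[ok] <- 1 / x$vec          # corrected = diag(x) A diag(x)
  balance_result(m, biases, n_iter = x$n_iter, converged = TRUE, method = "kr")
}

# Knight-Ruiz inner-outer Newton iteration for symmetric nonnegative A;
# returns x with rowSums(diag(x) %*% A %*% diag(x)) == 1
kr_balance <- function(A, tol = 1e-6, delta = 0.1, Delta = 3) {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  g <- 0.9; etamax <- 0.1; eta <- etamax
  stop_tol <- tol * 0.5
  rt <- tol^2
  v <- x * as.numeric(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * (rk / v)); rho_km2 <- rho_km1
  rout <- rho_km1; rold <- rout
  MVP <- 0; outer_it <- 0
  Z <- p <- NULL
  while (rout > rt) {
    outer_it <- outer_it + 1
    if (outer_it > 1000) return(NULL)
    k <- 0; y <- e
    innertol <- max(eta^2 * rout, rt)
    while (rho_km1 > innertol) {
      k <- k + 1
      if (k == 1) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.numeric(A %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {          # line search hit the lower safeguard
        if (delta == 0) break
        ind <- which(ap < 0)
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- which(ynew > Delta)
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
      if (k > 200) break
    }
    x <- x * y
    v <- x * as.numeric(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * (rk / v)); rho_km2 <- rho_km1
    rout <- rho_km1
    MVP <- MVP + k + 1
    rat <- rout / rold; rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta; eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / res_norm)
    if (!all(is.finite(x)) || any(x <= 0)) return(NULL)
  }
  list(vec = x, n_iter = MVP)
}

#' Observed-over-expected transformation
#'
#' Divides each cis entry by the expected count at its genomic distance: the
#' mean count over all pairs of unmasked bins of the same chromosome at that
#' bin distance (zeros included in the mean). Trans entries are dropped. This
#' removes the distance-decay trend so that comparisons emphasize structure
#' away from the diagonal.
#'
#' @param m A `ContactMatrix`.
#' @return A `ContactMatrix` of O/E ratios (cis entries only).
#' @export
observed_over_expected <- function(m) {
  stopifnot(inherits(m, "ContactMatrix"))
  exp_tab <- expected_by_distance(m)
  p <- m$pixels
  keep <- !m$mask[p$bin1 + 1L] & !m$mask[p$bin2 + 1L]
  p <- p[keep, , drop = FALSE]
  ch <- m$bins$chrom
  cis <- ch[p$bin1 + 1L] == ch[p$bin2 + 1L]
  p <- p[cis, , drop = FALSE]
  d <- p$bin2 - p$bin1
  key <- paste(ch[p$bin1 + 1L], d)
  e <- exp_tab$expected[match(key, paste(exp_tab$chrom, exp_tab$distance))]
  p$count <- p$count / e
  p <- p[is.finite(p$count), , drop = FALSE]
  contact_matrix(m$bins, p, m$mask)
}

# mean count per (chromosome, bin distance) over all valid pairs, zeros included
expected_by_distance <- function(m) {
  ch <- m$bins$chrom
  ok <- !m$mask
  p <- m$pixels
  keep <- ok[p$bin1 + 1L] & ok[p$bin2 + 1L] &
    ch[p$bin1 + 1L] == ch[p$bin2 + 1L]
  p <- p[keep, , drop = FALSE]
  d <- p$bin2 - p$bin1
  sums <- stats::aggregate(count ~ chrom + distance,
                           data = data.frame(chrom = ch[p$bin1 + 1L],
                                             distance = d, count = p$count),
                           FUN = sum)
  out <- list()
  for (chr in unique(ch)) {
    idx_ok <- which(ok & ch == chr)
    if (!length(idx_ok)) next
    pos <- idx_ok            # consecutive bin indices within chromosome
    nd <- max(pos) - min(pos)
    dd <- 0:nd
    # number of valid pairs at each distance among unmasked bins
    npairs <- vapply(dd, function(del)
      sum((pos + del) %in% pos), numeric(1))
    s <- sums[sums$chrom == chr, ]
    tot <- numeric(length(dd))
    tot[match(s$distance, dd)] <- s$count
    keep_d <- npairs > 0
    out[[chr]] <- data.frame(chrom = chr, distance = dd[keep_d],
                             expected = tot[keep_d] / npairs[keep_d])
  }
  do.call(rbind, out)
}
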