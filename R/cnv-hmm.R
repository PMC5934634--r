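#' Eight-state Student-t hidden Markov model for copy number
#'
#' States 1..7 correspond to 1..7 copies of a bin and state 8 to "8 or more".
#' Emissions are Student-t: state `k` (k = 1..7) has location `k * beta`,
#' state 8 has its own location `mu8`; all states share one scale `sigma` and
#' one degrees-of-freedom `nu`. That makes 4 free emission parameters; with the
#' 8x8 row-stochastic transition matrix (56 free entries) and a fixed uniform
#' initial distribution, the model has 60 free parameters in total.
#'
#' @param beta Per-copy location increment (> 0).
#' @param mu8 Location of the "8 or more" state.
#' @param sigma Shared scale (> 0).
#' @param nu Shared degrees of freedom (in `[1, 100]`).
#' @param A 8x8 transition matrix, rows summing to 1.
#' @return An object of class `t_hmm`.
#' @export
t_hmm <- function(beta, mu8, sigma, nu, A) {
  stopifnot(beta > 0, sigma > 0, nu > 0, is.matrix(A), all(dim(A) == 8),
            all(A >= 0), all(abs(rowSums(A) - 1) < 1e-12),
            is.finite(beta), is.finite(mu8), is.finite(sigma), is.finite(nu))
  structure(list(beta = beta, mu8 = mu8, sigma = sigma, nu = nu, A = A,
                 pi0 = rep(1 / 8, 8)),
            class = "t_hmm")
}

#' State emission locations of a copy-number HMM
#' @param hmm A `t_hmm`.
#' @return Numeric vector of 8 locations `(beta, 2 beta, ..., 7 beta, mu8)`.
#' @export
state_locations <- function(hmm) c(hmm$beta * (1:7), hmm$mu8)

#' @export
print.t_hmm <- function(x, ...) {
  cat(sprintf("Student-t copy-number HMM: beta = %.4g, mu8 = %.4g, sigma = %.4g, nu = %.3g\n",
              x$beta, x$mu8, x$sigma, x$nu))
  cat(sprintf("transition diagonal: %s\n",
              paste(sprintf("%.3f", diag(x$A)), collapse = " ")))
  invisible(x)
}

# log emission density matrix, length(x) x 8
hmm_log_emission <- function(x, hmm) {
  loc <- state_locations(hmm)
  z <- outer(x, loc, "-") / hmm$sigma
  stats::dt(z, df = hmm$nu, log = TRUE) - log(hmm$sigma)
}

#' Initialize the copy-number HMM from a corrected contact profile
#'
#' Moment-style initialization assuming the most common state carries
#' `modal_cn` copies: `beta = median / modal_cn`, `mu8 = 8 beta`,
#' `sigma = MAD`, `nu = 10`, sticky transitions (0.99 on the diagonal).
#'
#' @param x Corrected per-bin totals (unmasked bins; `NA` dropped).
#' @param modal_cn Assumed modal copy number (default 2, diploid).
#' @return A `t_hmm`.
#' @export
init_hmm <- function(x, modal_cn = 2) {
  x <- x[is.finite(x)]
  if (length(x) < 20) stop("need at least 20 bins to initialize the HMM")
  beta <- stats::median(x) / modal_cn
  if (beta <= 0) stop("non-positive median profile: cannot initialize")
  sigma <- stats::mad(x)
  if (sigma <= 0) sigma <- 1e-6 * beta
  A <- matrix(0.01 / 7, 8, 8)
  diag(A) <- 0.99
  t_hmm(beta = beta, mu8 = 8 * beta, sigma = sigma, nu = 10, A = A)
}

#' Forward-backward recursion for one chain
#'
#' Log-space forward-backward over a single chain of consecutive unmasked bins
#' (chains never cross chromosome boundaries or masked gaps). Returns the
#' chain log-likelihood, per-bin posterior state probabilities and the summed
#' pairwise transition posteriors used by the EM updates.
#'
#' @param x Numeric vector of corrected totals for one chain.
#' @param hmm A `t_hmm`.
#' @return List with `loglik`, `gamma` (`T x 8`, rows sum to 1) and `xi_sum`
#'   (8x8 expected transition counts).
#' @export
forward_backward <- function(x, hmm) {
  stopifnot(inherits(hmm, "t_hmm"), all(is.finite(x)), length(x) >= 1)
  Tn <- length(x)
  logE <- hmm_log_emission(x, hmm)
  # scaled recursion; per-bin shift keeps the emissions representable for
  # any finite input, the shift is restored in the log-likelihood
  shift <- apply(logE, 1, max)
  E <- exp(logE - shift)
  A <- hmm$A
  alpha <- matrix(0, Tn, 8)
  cs <- numeric(Tn)
  a <- hmm$pi0 * E[1, ]
  cs[1] <- sum(a)
  alpha[1, ] <- a / cs[1]
  if (Tn > 1) for (t in 2:Tn) {
    a <- as.numeric(alpha[t - 1, ] %*% A) * E[t, ]
    cs[t] <- sum(a)
    alpha[t, ] <- a / cs[t]
  }
  loglik <- sum(log(cs)) + sum(shift)
  beta <- matrix(1, Tn, 8)
  if (Tn > 1) for (t in (Tn - 1):1)
    beta[t, ] <- as.numeric(A %*% (E[t + 1, ] * beta[t + 1, ])) / cs[t + 1]
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi_sum <- matrix(0, 8, 8)
  if (Tn > 1) for (t in 1:(Tn - 1))
    xi_sum <- xi_sum +
      (outer(alpha[t, ], E[t + 1, ] * beta[t + 1, ]) * A) / cs[t + 1]
  list(loglik = loglik, gamma = gamma, xi_sum = xi_sum)
}

# observed-data log-likelihood over a list of chains (forward pass only)
hmm_loglik <- function(chains, hmm) {
  tot <- 0
  for (x in chains) {
    logE <- hmm_log_emission(x, hmm)
    shift <- apply(logE, 1, max)
    E <- exp(logE - shift)
    a <- hmm$pi0 * E[1, ]
    ll <- log(sum(a)) + sum(shift)
    a <- a / sum(a)
    if (length(x) > 1) for (t in 2:length(x)) {
      a <- as.numeric(a %*% hmm$A) * E[t, ]
      s <- sum(a)
      ll <- ll + log(s)
      a <- a / s
    }
    tot <- tot + ll
  }
  tot
}

#' Baum-Welch estimation of the copy-number HMM
#'
#' EM over one or more chains. Transitions are updated from the pairwise
#' posteriors; the tied locations use the latent normal-scale weights of the
#' Student-t (treated as a scale mixture of normals): `beta` by a
#' posterior-weighted least-squares fit over the locations `k * beta`
#' (k = 1..7), `mu8` by the corresponding weighted mean, `sigma` by the
#' standard weighted second moment. The degrees of freedom `nu` are updated by
#' direct 1-D maximization of the observed-data log-likelihood (an ECME step),
#' bounded to `[1, 100]`. The observed-data log-likelihood is non-decreasing
#' across iterations.
#'
#' @param chains A list of numeric vectors (one per chain of consecutive
#'   unmasked bins), or a single numeric vector.
#' @param hmm Initial `t_hmm`, e.g. from [init_hmm()].
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Relative log-likelihood change for convergence (default 1e-6).
#' @return A `t_hmm` with extra fields `loglik`, `loglik_history`, `n_iter`
#'   and `converged`.
#' @export
baum_welch <- function(chains, hmm, max_iter = 500, tol = 1e-6) {
  if (is.numeric(chains)) chains <- list(chains)
  stopifnot(length(chains) >= 1, inherits(hmm, "t_hmm"))
  history <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    loc <- state_locations(hmm)
    xi_tot <- matrix(0, 8, 8)
    ll <- 0
    g_list <- vector("list", length(chains))
    for (ci in seq_along(chains)) {
      fb <- forward_backward(chains[[ci]], hmm)
      ll <- ll + fb$loglik
      xi_tot <- xi_tot + fb$xi_sum
      g_list[[ci]] <- fb$gamma
    }
    history <- c(history, ll)
    if (iter > 1) {
      rel <- abs(ll - history[iter - 1]) / (abs(history[iter - 1]) + 1e-12)
      if (rel < tol) { converged <- TRUE; break }
    }
    x_all <- unlist(chains, use.names = FALSE)
    gamma <- do.call(rbind, g_list)
    # latent scale weights of the t emission (scale mixture of normals)
    d2 <- (outer(x_all, loc, "-") / hmm$sigma)^2
    u <- (hmm$nu + 1) / (hmm$nu + d2)
    w <- gamma * u
    k17 <- 1:7
    denom_beta <- sum(sweep(w[, k17, drop = FALSE], 2, k17^2, "*"))
    beta_new <- if (denom_beta > 1e-12)
      sum(sweep(w[, k17, drop = FALSE] * x_all, 2, k17, "*")) / denom_beta
    else hmm$beta
    if (beta_new <= 0) beta_new <- hmm$beta
    mu8_new <- if (sum(w[, 8]) > 1e-8) sum(w[, 8] * x_all) / sum(w[, 8]) else hmm$mu8
    loc_new <- c(beta_new * k17, mu8_new)
    sq <- (outer(x_all, loc_new, "-"))^2
    sigma2 <- sum(gamma * u * sq) / sum(gamma)
    sigma_new <- max(sqrt(sigma2), 1e-6 * beta_new)
    A_new <- xi_tot
    rs <- rowSums(A_new)
    for (k in 1:8)
      A_new[k, ] <- if (rs[k] > 1e-12) A_new[k, ] / rs[k] else hmm$A[k, ]
    cand <- t_hmm(beta_new, mu8_new, sigma_new, hmm$nu, A_new)
    # ECME step for nu: maximize the actual likelihood on log-nu in [1, 100]
    opt <- stats::optimize(function(lnu) {
      cand$nu <- exp(lnu)
      hmm_loglik(chains, cand)
    }, interval = log(c(1, 100)), maximum = TRUE, tol = 1e-3)
    cand$nu <- if (opt$objective >= hmm_loglik(chains, cand)) exp(opt$maximum) else cand$nu
    hmm <- cand
  }
  hmm$loglik <- history[length(history)]
  hmm$loglik_history <- history
  hmm$n_iter <- length(history)
  hmm$converged <- converged
  hmm
}

#' Viterbi decoding of one chain
#'
#' Maximum-probability state path; ties are broken toward the lower copy
#' number.
#'
#' @param x Numeric vector of corrected totals for one chain.
#' @param hmm A fitted `t_hmm`.
#' @return Integer vector of states in 1..8 (state 8 means "8 or more").
#' @export
viterbi <- function(x, hmm) {
  stopifnot(inherits(hmm, "t_hmm"), all(is.finite(x)))
  Tn <- length(x)
  logE <- hmm_log_emission(x, hmm)
  logA <- log(hmm$A)
  delta <- matrix(-Inf, Tn, 8)
  psi <- matrix(1L, Tn, 8)
  delta[1, ] <- log(hmm$pi0) + logE[1, ]
  if (Tn > 1) for (t in 2:Tn) for (k in 1:8) {
    sc <- delta[t - 1, ] + logA[, k]
    b <- which.max(sc)           # first max: lower state wins ties
    psi[t, k] <- b
    delta[t, k] <- sc[b] + logE[t, k]
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta[Tn, ])
  if (Tn > 1) for (t in (Tn - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

# chains of consecutive unmasked bins; masked bins and chromosome
# boundaries split chains
build_chains <- function(values, chrom) {
  n <- length(values)
  ok <- is.finite(values)
  new_grp <- rep(TRUE, n)
  if (n > 1) new_grp[-1] <- chrom[-1] != chrom[-n] | !ok[-1] | !ok[-n]
  idx <- split(seq_len(n), cumsum(new_grp))
  idx <- idx[vapply(idx, function(i) all(ok[i]), logical(1))]
  unname(idx)
}

#' Infer per-bin copy number from a corrected contact matrix
#'
#' Fits the Student-t HMM on the corrected contact profile (one chain per run
#' of consecutive unmasked bins within a chromosome) with [baum_welch()] and
#' decodes the Viterbi path, which is the inferred copy number of each bin.
#'
#' @param m A bias-corrected `ContactMatrix` (or a raw one; the profile is
#'   whatever the matrix yields).
#' @param modal_cn Assumed modal copy number for initialization (default 2).
#' @param max_iter,tol Passed to [baum_welch()].
#' @return An object of class `CNProfile`: list with `cn` (per-bin integer in
#'   1..8, `NA` for masked bins; 8 means "8 or more"), `loglik`, `segments`
#'   (BED-like `data.frame` of maximal constant-copy-number runs), `hmm` (the
#'   fitted `t_hmm`) and `converged`.
#' @export
infer_copy_number <- function(m, modal_cn = 2, max_iter = 500, tol = 1e-6) {
  stopifnot(inherits(m, "ContactMatrix"))
  t_hat <- contact_profile(m)
  chains_idx <- build_chains(t_hat, m$bins$chrom)
  if (!length(chains_idx)) stop("no unmasked bins: cannot infer copy number")
  chains <- lapply(chains_idx, function(i) t_hat[i])
  hmm <- init_hmm(unlist(chains, use.names = FALSE), modal_cn = modal_cn)
  hmm <- baum_welch(chains, hmm, max_iter = max_iter, tol = tol)
  cn <- rep(NA_integer_, n_bins(m))
  for (ci in seq_along(chains_idx))
    cn[chains_idx[[ci]]] <- viterbi(chains[[ci]], hmm)
  structure(list(cn = cn, loglik = hmm$loglik,
                 segments = cn_segments(cn, m$bins), hmm = hmm,
                 converged = hmm$converged),
            class = "CNProfile")
}

#' @export
print.CNProfile <- function(x, ...) {
  cat(sprintf("Copy-number profile: %d bins called, %d segment(s), loglik = %.4f\n",
              sum(!is.na(x$cn)), nrow(x$segments), x$loglik))
  invisible(x)
}

# maximal runs of constant cn within a chromosome; NA bins break runs
cn_segments <- function(cn, bins) {
  out <- list()
  brk <- c(TRUE, bins$chrom[-1] != bins$chrom[-nrow(bins)] |
                 cn[-1] != cn[-length(cn)] |
                 is.na(cn[-1]) != is.na(cn[-length(cn)]))
  brk[is.na(brk)] <- TRUE
  grp <- cumsum(brk)
  for (g in split(seq_len(nrow(bins)), grp)) {
    if (is.na(cn[g[1]])) next
    out[[length(out) + 1]] <- data.frame(
      chrom = bins$chrom[g[1]], start = bins$start[g[1]],
      end = bins$end[g[length(g)]], cn = cn[g[1]])
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), cn = integer()))
  do.call(rbind, out)
}

#' Divide a matrix by the square root of the copy numbers
#'
#' Entry `(i, j)` becomes `x_ij / sqrt(c_i * c_j)`; with `c = 2` everywhere
#' this is a uniform division by 2. The "8 or more" state is taken at value 8.
#'
#' @param m A `ContactMatrix`.
#' @param cn A `CNProfile` or a per-bin numeric copy-number vector (defined on
#'   all unmasked bins).
#' @return The corrected `ContactMatrix`.
#' @export
apply_cn_correction <- function(m, cn) {
  v <- if (inherits(cn, "CNProfile")) cn$cn else cn
  apply_bin_correction(m, as.numeric(v))
}

#' Write copy-number segments as BED
#'
#' One line per maximal constant-copy-number run: chrom, start, end, cn.
#'
#' @param cn A `CNProfile`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_segments <- function(cn, path) {
  stopifnot(inherits(cn, "CNProfile"))
  utils::write.table(cn$segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
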