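# shared fixtures and independent oracles (all built in code; no stored data)

# tiny 2-bin matrix used throughout: x00 = 5, x01 = 3, x11 = 2
tiny_matrix <- function() {
  contact_matrix(bin_table(c(chrA = 2L), resolution = 100),
                 data.frame(bin1 = c(0, 0, 1), bin2 = c(0, 1, 1),
                            count = c(5, 3, 2)))
}

# random sparse symmetric matrix over a given bin table
random_matrix <- function(bins, density = 0.3, max_count = 20, seed = 1) {
  set.seed(seed)
  n <- nrow(bins)
  ut <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  keep <- runif(nrow(ut)) < density
  ut <- ut[keep, , drop = FALSE]
  contact_matrix(bins, data.frame(bin1 = ut[, 1] - 1L, bin2 = ut[, 2] - 1L,
                                  count = sample.int(max_count, nrow(ut),
                                                     replace = TRUE)))
}

# independent dense textbook iterative-correction oracle: returns bias vector
# b (mean 1 over kept bins) such that corrected = x / (b_i b_j)
dense_ice_oracle <- function(M, tol = 1e-5, max_iter = 200) {
  b <- rep(1, nrow(M))
  W <- M
  for (it in seq_len(max_iter)) {
    s <- rowSums(W)
    if (sd(s) / mean(s) < tol) break
    db <- s / mean(s)
    b <- b * db
    W <- M / outer(b, b)
  }
  b
}

# independent Student-t emission log-density (oracle-side copy)
oracle_emission <- function(x, hmm) {
  loc <- c(hmm$beta * (1:7), hmm$mu8)
  sapply(loc, function(l) dt((x - l) / hmm$sigma, df = hmm$nu, log = TRUE) -
                          log(hmm$sigma))
}

# exhaustive enumeration over all 8^T state paths: log-likelihood and best path
enumerate_hmm <- function(x, hmm) {
  Tn <- length(x)
  em <- oracle_emission(x, hmm)          # T x 8
  paths <- as.matrix(expand.grid(rep(list(1:8), Tn)))
  lp <- log(hmm$pi0)[paths[, 1]] + em[cbind(1, paths[, 1])]
  if (Tn > 1) for (t in 2:Tn)
    lp <- lp + log(hmm$A)[cbind(paths[, t - 1], paths[, t])] +
      em[cbind(t, paths[, t])]
  m <- max(lp)
  list(loglik = m + log(sum(exp(lp - m))),
       best_path = as.integer(paths[which.max(lp), ]))
}

# hand-set HMM with distinguishable states for oracle tests
oracle_hmm <- function() {
  A <- matrix(0.02 / 7, 8, 8)
  diag(A) <- 0.98
  t_hmm(beta = 10, mu8 = 95, sigma = 2, nu = 6, A = A)
}

# negative binomial deviance (fixed theta), y >= 0, mu > 0
nb_deviance <- function(y, mu, theta) {
  term1 <- ifelse(y > 0, y * log(y / mu), 0)
  term2 <- (y + theta) * log((y + theta) / (mu + theta))
  2 * sum(term1 - term2)
}

# localized-bias fixture: short-range contact pattern with a smooth
# gc-driven multiplicative bias; the regime the profile model assumes
localized_bias_fixture <- function(n = 300, seed = 5) {
  set.seed(seed)
  bins <- bin_table(c(chrA = as.integer(n)), resolution = 1e5)
  gc <- 0.45 + 0.12 * sin(2 * pi * seq_len(n) / n)
  b <- exp(1.0 * (gc - 0.45) / 0.12)
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  P <- 200 * exp(-D / 3) + 0.2
  mu <- P * outer(b, b)
  ut <- which(upper.tri(mu, diag = TRUE), arr.ind = TRUE)
  counts <- rpois(nrow(ut), mu[ut])
  keep <- counts > 0
  m <- contact_matrix(bins, data.frame(bin1 = ut[keep, 1] - 1L,
                                       bin2 = ut[keep, 2] - 1L,
                                       count = counts[keep]))
  list(matrix = m, gc = gc, bias = b, bins = bins)
}

# minimal comparison result carrying a relation label
comparison_pair <- function(value, relation) {
  structure(list(metric = "score", value = value, max_dist = NA_real_,
                 params = list(), pair = list(relation = relation)),
            class = "oned_comparison")
}

# bias-free simulator config (copy-number questions in isolation)
flat_bias_funs <- function() {
  list(gc = function(z) 0 * z, map = function(z) 0 * z, res = function(z) 0 * z)
}
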