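test_that("initialization follows the modal-copy-number heuristic", {
  h <- init_hmm(rep(100, 50), modal_cn = 2)
  expect_equal(h$beta, 50)
  expect_equal(h$mu8, 400)
  expect_equal(h$pi0, rep(1 / 8, 8))
  expect_equal(rowSums(h$A), rep(1, 8), tolerance = 1e-12)
  expect_gt(h$sigma, 0)                                 # MAD floor applies

  h1 <- init_hmm(rep(c(100, 101), 25), modal_cn = 1)
  expect_equal(h1$beta, 100.5)

  # piecewise profile, mostly diploid at level 100 with a patch at 150
  x <- c(rep(100, 80), rep(150, 20)) + rnorm(100, 0, 2)
  expect_equal(init_hmm(x, modal_cn = 2)$beta, 50, tolerance = 0.05)

  expect_error(init_hmm(rep(100, 5)), "at least 20")
})

test_that("tied locations are exact multiples of beta by construction", {
  h <- oracle_hmm()
  expect_equal(state_locations(h), c(10 * (1:7), 95))
  set.seed(2)
  x <- c(rep(20, 30), rep(40, 20)) + rnorm(50, 0, 1.5)
  fit <- baum_welch(x, init_hmm(x), max_iter = 30)
  expect_equal(state_locations(fit)[1:7], fit$beta * (1:7))
})

test_that("forward-backward matches exhaustive enumeration for T = 6", {
  h <- oracle_hmm()
  x <- c(19, 21, 20, 42, 39, 88)
  fb <- forward_backward(x, h)
  en <- enumerate_hmm(x, h)
  expect_equal(fb$loglik, en$loglik, tolerance = 1e-10)
  expect_equal(rowSums(fb$gamma), rep(1, 6), tolerance = 1e-12)

  # single observation: closed form log sum of pi0-weighted emissions
  fb1 <- forward_backward(21.5, h)
  em <- oracle_emission(21.5, h)
  expect_equal(fb1$loglik, log(sum(h$pi0 * exp(em))), tolerance = 1e-12)

  # uninformative emissions: posteriors are the chain's marginal distribution
  hu <- oracle_hmm()
  hu$sigma <- 1e6                       # states indistinguishable
  fbu <- forward_backward(c(20, 20, 20, 20), hu)
  marg <- hu$pi0
  for (t in 1:4) {
    expect_equal(unname(fbu$gamma[t, ]), unname(marg), tolerance = 1e-6)
    marg <- as.numeric(marg %*% hu$A)
  }
})

test_that("Viterbi matches brute force and decodes noiseless profiles", {
  h <- oracle_hmm()
  x <- c(19, 31, 20, 78, 41, 88)
  expect_equal(viterbi(x, h), enumerate_hmm(x, h)$best_path)

  beta <- 50
  hn <- t_hmm(beta = beta, mu8 = 8 * beta, sigma = 1, nu = 10,
              A = {A <- matrix(0.01 / 7, 8, 8); diag(A) <- 0.99; A})
  expect_equal(viterbi(beta * c(2, 2, 2, 4, 4, 2), hn), c(2, 2, 2, 4, 4, 2))
  expect_equal(viterbi(rep(2 * beta, 10), hn), rep(2, 10))
})

test_that("one EM step increases the likelihood and matches the M-step oracle", {
  h <- oracle_hmm()
  x <- c(19, 21, 38, 41, 60, 88)
  fb <- forward_backward(x, h)
  fit1 <- baum_welch(x, h, max_iter = 1)    # exactly one parameter update
  ll_before <- fit1$loglik_history[1]
  ll_after <- forward_backward(x, fit1)$loglik
  expect_gte(ll_after, ll_before)

  # oracle: numerically maximize the EM surrogate Q over (beta, mu8, sigma)
  # at the E-step posteriors and latent t scale weights
  loc0 <- state_locations(h)
  u <- (h$nu + 1) / (h$nu + (outer(x, loc0, "-") / h$sigma)^2)
  gam <- fb$gamma
  negQ <- function(par) {
    loc <- c(par[1] * (1:7), par[2])
    sig <- exp(par[3])
    sq <- outer(x, loc, "-")^2
    sum(gam) * log(sig) + sum(gam * u * sq) / (2 * sig^2)
  }
  o <- optim(c(h$beta, h$mu8, log(h$sigma)), negQ, method = "BFGS",
             control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(fit1$beta, o$par[1], tolerance = 1e-6)
  expect_equal(fit1$mu8, o$par[2], tolerance = 1e-6)
  expect_equal(fit1$sigma, exp(o$par[3]), tolerance = 1e-6)

  # transition update: expected transition counts, row-normalized
  A_oracle <- fb$xi_sum / rowSums(fb$xi_sum)
  expect_equal(fit1$A, A_oracle, tolerance = 1e-8)
})

test_that("Baum-Welch is monotone and recovers a known model", {
  set.seed(77)
  # sticky transitions whose stationary distribution is diploid-dominant,
  # as in a genome that is mostly two-copy with occasional aberrations
  A <- matrix(0.002, 8, 8)
  diag(A) <- 0.95
  for (k in 1:8) A[k, 2] <- A[k, 2] + 1 - sum(A[k, ])
  truth <- t_hmm(beta = 50, mu8 = 400, sigma = 3, nu = 8, A = A)
  n <- 2000
  states <- integer(n)
  states[1] <- 2
  for (t in 2:n) states[t] <- sample(1:8, 1, prob = A[states[t - 1], ])
  x <- state_locations(truth)[states] +
    truth$sigma * rt(n, df = truth$nu)
  fit <- baum_welch(x, init_hmm(x, modal_cn = 2), max_iter = 100)
  expect_true(all(diff(fit$loglik_history) > -1e-6))
  expect_equal(fit$beta, truth$beta, tolerance = 0.05)
  expect_equal(fit$sigma, truth$sigma, tolerance = 0.15)
  expect_gt(mean(viterbi(x, fit) == states), 0.95)
})

test_that("chains split at chromosome boundaries and masked gaps", {
  set.seed(5)
  bins <- bin_table(c(chr1 = 40L, chr2 = 30L), resolution = 1e5)
  # diploid everywhere; a noiseless level shift on chr2
  lvl <- c(rep(100, 40), rep(150, 30))
  ut <- expand.grid(i = 0:69, j = 0:69)
  ut <- ut[ut$i <= ut$j, ]
  diagm <- ut$i == ut$j
  m <- contact_matrix(bins, data.frame(bin1 = ut$i[diagm], bin2 = ut$j[diagm],
                                       count = lvl))
  m <- set_mask(m, seq_len(70) %in% c(10, 11))
  cn <- infer_copy_number(m, modal_cn = 2)
  expect_true(all(is.na(cn$cn[c(10, 11)])))
  expect_equal(unique(cn$cn[bins$chrom == "chr1" & !is.na(cn$cn)]), 2L)
  expect_equal(unique(cn$cn[bins$chrom == "chr2"]), 3L)
  # masked gap splits the chr1 segment into two runs
  expect_equal(nrow(cn$segments), 3)
  expect_equal(cn$segments$cn, c(2L, 2L, 3L))
})

test_that("copy-number correction divides by sqrt(c_i c_j)", {
  m <- tiny_matrix()
  expect_equal(apply_cn_correction(m, c(4, 4))$pixels$count, c(5, 3, 2) / 4)
  expect_equal(apply_cn_correction(m, c(2, 2))$pixels$count, c(5, 3, 2) / 2)

  # a CN-4 segment in diploid background: within-segment entries fall by
  # 2x relative to background-background entries
  bins <- bin_table(c(chrA = 6L), resolution = 1e5)
  ut <- expand.grid(i = 0:5, j = 0:5)
  ut <- ut[ut$i <= ut$j, ]
  m6 <- contact_matrix(bins, data.frame(bin1 = ut$i, bin2 = ut$j, count = 8))
  cn <- c(2, 2, 4, 4, 2, 2)
  corr <- apply_cn_correction(m6, cn)
  get <- function(mm, i, j) contact_at(mm, i, j)
  within_ratio <- get(corr, 2, 3) / get(m6, 2, 3)        # 1/4
  bg_ratio <- get(corr, 0, 1) / get(m6, 0, 1)            # 1/2
  expect_equal(within_ratio / bg_ratio, 1 / 2)
})

test_that("segments export as BED and expand back to the bin profile", {
  bins <- bin_table(c(chr1 = 3L), resolution = 1e5)
  cnp <- structure(list(cn = c(2L, 2L, 3L), loglik = 0,
                        segments = onedhic:::cn_segments(c(2L, 2L, 3L), bins)),
                   class = "CNProfile")
  path <- withr::local_tempfile(fileext = ".bed")
  export_segments(cnp, path)
  seg <- read.table(path, col.names = c("chrom", "start", "end", "cn"))
  expect_equal(seg$start, c(0, 2e5))
  expect_equal(seg$end, c(2e5, 3e5))
  expect_equal(seg$cn, c(2L, 3L))

  # expanding segments back to bins reproduces the per-bin profile
  expanded <- unlist(mapply(function(s, e, c) rep(c, (e - s) / 1e5),
                            seg$start, seg$end, seg$cn))
  expect_equal(unname(expanded), c(2L, 2L, 3L))
})

test_that("injected copy number is recovered from a deep unbiased matrix", {
  cfg <- sim_config(chroms = c(chr1 = 120L, chr2 = 120L), depth = 4e6,
                    bias_funs = flat_bias_funs(), seed = 23)
  sim <- simulate_base_matrix(cfg)
  cn_true <- rep(2L, 240)
  cn_true[31:60] <- 3L          # 30-bin gain on chr1
  cn_true[161:180] <- 4L        # 20-bin gain on chr2
  mi <- inject_cnv(sim$matrix, cn_true)
  cn <- infer_copy_number(mi, modal_cn = 2)
  # aberrant regions are recovered almost everywhere; their boundaries fall
  # within one bin of the injected breakpoints
  called_ab <- cn$cn > 2L
  true_ab <- cn_true > 2L
  expect_gt(mean(called_ab == true_ab, na.rm = TRUE), 0.97)
  cp <- function(v) which(diff(v) != 0)
  cp_called <- cp(called_ab)
  cp_true <- cp(true_ab)
  expect_equal(length(cp_called), length(cp_true))
  expect_true(all(abs(sort(cp_called) - sort(cp_true)) <= 1))
  # gained segments are called above the diploid level everywhere inside
  expect_true(all(cn$cn[32:59] > 2L))
  expect_true(all(cn$cn[162:179] > 2L))
})
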