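#' Simulation configuration
#'
#' Bundles the generator parameters: genome layout, distance-decay exponent,
#' sequencing depth, negative-binomial dispersion, trans-contact level and the
#' smooth per-bin bias functions. The defaults describe a small multi-
#' chromosome genome at 100 kb with decay exponent 1, 1e6 expected contacts,
#' moderate overdispersion and trans contacts making up 30% of a bin's total.
#'
#' @param chroms Named integer vector: bins per chromosome.
#' @param resolution Bin size in bp.
#' @param alpha Distance-decay exponent: expected cis counts fall off as
#'   `(1 + |i - j|)^-alpha`.
#' @param depth Expected total count over the upper triangle of the matrix.
#' @param theta Negative-binomial dispersion of the per-cell counts.
#' @param trans_frac Fraction of a typical bin's total contacts that is trans
#'   (inter-chromosomal); trans cells share one constant expected level.
#' @param bias_funs Named list of smooth functions (`gc`, `map`, `res`) giving
#'   the additive log-scale contribution of each genomic feature; see
#'   [default_bias_funs()].
#' @param tad_strength Multiplicative enrichment of cis contacts within a
#'   domain (0 disables domain structure).
#' @param tad_mean_size Mean domain size in bins when `tad_strength > 0`.
#' @param seed Integer seed making every draw reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chroms = c(chr1 = 125L, chr2 = 125L, chr3 = 125L,
                                  chr4 = 125L),
                       resolution = 1e5, alpha = 1, depth = 1e6, theta = 20,
                       trans_frac = 0.3, bias_funs = default_bias_funs(),
                       tad_strength = 0, tad_mean_size = 15, seed = 1L) {
  stopifnot(all(chroms >= 2), resolution >= 1, alpha >= 0, depth > 0,
            theta > 0, trans_frac >= 0, trans_frac < 1, tad_strength >= 0)
  structure(list(chroms = chroms, resolution = resolution, alpha = alpha,
                 depth = depth, theta = theta, trans_frac = trans_frac,
                 bias_funs = bias_funs, tad_strength = tad_strength,
                 tad_mean_size = tad_mean_size, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default smooth bias functions
#'
#' Log-scale contributions of the three canonical covariates: a near-linear
#' smooth effect of G+C fraction, a multiplicative (log) effect of mappability
#' and a saturating effect of the restriction-site count, mirroring the
#' flattening relationship seen in real contact profiles. Amplitudes are set
#' so that the raw contact profile fluctuates with a coefficient of variation
#' around 0.35 within constant-copy-number regions, the magnitude seen in raw
#' profiles of published experiments.
#'
#' @return Named list of functions over the feature values.
#' @export
default_bias_funs <- function() {
  list(gc = function(z) 1.0 * sin(pi * (z - 0.45)),
       map = function(z) 0.6 * log(z),
       res = function(z) 0.45 * log1p(z))
}

#' Random smooth bias functions
#'
#' Draws replicate-specific bias curves (used to emulate batch/protocol
#' effects in benchmarks): each feature gets a random combination of a linear,
#' a sinusoidal and a quadratic shape over its standardized range.
#'
#' @param scale Overall amplitude of the log-scale biases (default 0.6).
#' @return Named list of functions (`gc`, `map`, `res`).
#' @export
random_bias_funs <- function(scale = 0.6) {
  ranges <- list(gc = c(0.3, 0.6), map = c(0.5, 1), res = c(5, 45))
  out <- lapply(ranges, function(r) {
    a <- stats::runif(3, -1, 1) * scale
    force(a); force(r)
    function(z) {
      zs <- 2 * (z - r[1]) / (r[2] - r[1]) - 1
      a[1] * zs + a[2] * sin(pi * zs / 2) + a[3] * zs^2
    }
  })
  out
}

# smooth random track: spline through random knot values, rescaled to [lo, hi]
smooth_random_track <- function(n, lo, hi, n_knots = max(4L, n %/% 40L)) {
  kx <- seq(1, n, length.out = n_knots)
  ky <- stats::runif(n_knots)
  y <- stats::spline(kx, ky, xout = seq_len(n))$y
  y <- (y - min(y)) / (max(y) - min(y) + 1e-12)
  lo + y * (hi - lo)
}

# genomic feature tracks: an isochore-scale backbone (period of a few bins,
# i.e. sub-Mb at 100 kb) plus bin-level jitter. Real covariates fluctuate much
# faster than copy-number segments, which is also what keeps smooth covariate
# effects from soaking up long copy-number segments in the bias fit.
sim_features <- function(n) {
  sm <- function(lo, hi) smooth_random_track(n, lo, hi,
                                             n_knots = max(4L, n %/% 8L))
  gc <- sm(0.33, 0.57) + stats::rnorm(n, 0, 0.025)
  map <- sm(0.6, 0.95) + stats::rnorm(n, 0, 0.02)
  data.frame(gc = pmin(pmax(gc, 0.25), 0.65),
             map = pmin(pmax(map, 0.05), 1),
             res = stats::rpois(n, sm(10, 40)))
}

# random domain (TAD-like) partition: per-bin domain id
random_domains <- function(chrom, mean_size) {
  id <- integer(length(chrom))
  nxt <- 0L
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos <- 0L
    while (pos < length(idx)) {
      len <- max(2L, stats::rpois(1, mean_size))
      nxt <- nxt + 1L
      id[idx[(pos + 1L):min(pos + len, length(idx))]] <- nxt
      pos <- pos + len
    }
  }
  id
}

# expected-count matrix (dense) for a given truth; returns mu and components
sim_expected_matrix <- function(config, features, bias_funs, domains = NULL) {
  chroms <- config$chroms
  n <- sum(chroms)
  chrom <- rep(names(chroms), chroms)
  pos <- unlist(lapply(chroms, seq_len), use.names = FALSE)
  g <- rowSums(vapply(names(bias_funs),
                      function(f) bias_funs[[f]](features[[f]]),
                      numeric(n)))
  b <- exp(g - mean(g))
  B <- matrix(0, n, n)
  same <- outer(chrom, chrom, "==")
  D <- abs(outer(pos, pos, "-"))
  B[same] <- (1 + D[same])^(-config$alpha)
  # trans level set so that trans contacts are trans_frac of a mean bin total
  if (any(!same) && config$trans_frac > 0) {
    mean_cis <- mean(rowSums(B * same))
    mean_ntrans <- mean(rowSums(!same))
    B[!same] <- config$trans_frac / (1 - config$trans_frac) *
      mean_cis / mean_ntrans
  }
  if (!is.null(domains) && config$tad_strength > 0) {
    same_dom <- outer(domains, domains, "==") & same
    B[same_dom] <- B[same_dom] * (1 + config$tad_strength)
  }
  M <- B * outer(b, b)
  scale <- config$depth / sum(M[upper.tri(M, diag = TRUE)])
  list(mu = M * scale, bias = b)
}

# draw a ContactMatrix of NB counts around a dense expected matrix
draw_counts <- function(mu, bins, theta) {
  n <- nrow(mu)
  ut <- which(upper.tri(mu, diag = TRUE), arr.ind = TRUE)
  counts <- stats::rnbinom(nrow(ut), mu = mu[ut], size = theta)
  keep <- counts > 0
  contact_matrix(bins, data.frame(bin1 = ut[keep, 1] - 1L,
                                  bin2 = ut[keep, 2] - 1L,
                                  count = counts[keep]))
}

#' Simulate a base Hi-C matrix with distance decay and smooth biases
#'
#' Generates per-bin feature tracks (G+C, mappability, restriction sites),
#' smooth per-bin biases `b_i = exp(sum_k g_k(z_ki))`, an expected matrix
#' `mu_ij = depth-scaled (1 + |i - j|)^-alpha * b_i * b_j` (cis; constant
#' trans level), and negative-binomial counts around it. The ground truth is
#' returned for recovery tests.
#'
#' @param config A [sim_config()].
#' @param noise_seed Seed for the count draw only (default: `config$seed`).
#'   Two calls with the same config and different `noise_seed` are replicates:
#'   different counts around identical ground truth.
#' @return List with `matrix` (`ContactMatrix`), `features` (`data.frame` with
#'   `gc`, `map`, `res`), `bias` (true per-bin bias), `t_true` (expected
#'   per-bin totals) and `bins`.
#' @export
simulate_base_matrix <- function(config, noise_seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- sum(config$chroms)
  bins <- bin_table(config$chroms, config$resolution)
  features <- sim_features(n)
  domains <- if (config$tad_strength > 0)
    random_domains(bins$chrom, config$tad_mean_size) else NULL
  ex <- sim_expected_matrix(config, features, config$bias_funs, domains)
  set.seed(noise_seed)
  m <- draw_counts(ex$mu, bins, config$theta)
  t_true <- rowSums(ex$mu)
  list(matrix = m, features = features, bias = ex$bias, t_true = t_true,
       bins = bins, domains = domains)
}

#' Draw a random copy-number aberration specification
#'
#' Picks the number of breakpoints uniformly in 3..10, places them uniformly
#' at random along the given chromosomes, and assigns each resulting segment a
#' copy number drawn with equal probability from 2, 3, 4 or 10.
#'
#' @param bins Bin table of the genome to aberrate.
#' @param chroms Chromosomes receiving the aberrations (default: all); the
#'   rest of the genome stays diploid (copy number 2).
#' @param seed Optional seed (otherwise the current RNG stream is used).
#' @return An object of class `CNVSpec`: list with `breakpoints` (0-based bin
#'   ids), `cn` (per-bin copy number) and `segments` (a `data.frame`).
#' @export
draw_cnv_spec <- function(bins, chroms = NULL, seed = NULL) {
  bins <- validate_bins(bins)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(bins)
  if (is.null(chroms)) chroms <- unique(bins$chrom)
  stopifnot(all(chroms %in% bins$chrom))
  target <- bins$chrom %in% chroms
  n_bp <- sample(3:10, 1)
  # a breakpoint sits after bin bp; only boundaries inside target chromosomes
  eligible <- which(target[-n] & target[-1] &
                    bins$chrom[-n] == bins$chrom[-1])
  bp <- sort(sample(eligible, min(n_bp, length(eligible))))
  chrom_brk <- which(bins$chrom[-1] != bins$chrom[-n])
  cuts <- sort(unique(c(bp, chrom_brk)))
  seg_start <- c(1L, cuts + 1L)
  seg_end <- c(cuts, n)
  cn_seg <- ifelse(target[seg_start],
                   sample(c(2L, 3L, 4L, 10L), length(seg_start), replace = TRUE),
                   2L)
  cn <- rep(cn_seg, seg_end - seg_start + 1L)
  segments <- data.frame(chrom = bins$chrom[seg_start],
                         start = bins$start[seg_start],
                         end = bins$end[seg_end], cn = cn_seg)
  structure(list(breakpoints = bp - 1L, cn = cn, segments = segments,
                 n_breakpoints = n_bp),
            class = "CNVSpec")
}

#' Inject copy-number aberrations into a contact matrix
#'
#' Multiplies each entry by the outer product of the per-bin factors
#' `f_i = cn_i / 2` (diploid baseline, so copy number 2 is neutral) and rounds
#' half-up to keep counts integral.
#'
#' @param m A `ContactMatrix`.
#' @param spec A `CNVSpec` or a per-bin numeric copy-number vector.
#' @return The aberrated `ContactMatrix`.
#' @export
inject_cnv <- function(m, spec) {
  stopifnot(inherits(m, "ContactMatrix"))
  cn <- if (inherits(spec, "CNVSpec")) spec$cn else as.numeric(spec)
  stopifnot(length(cn) == n_bins(m), all(cn > 0))
  f <- cn / 2
  p <- m$pixels
  p$count <- floor(p$count * f[p$bin1 + 1L] * f[p$bin2 + 1L] + 0.5)
  p <- p[p$count > 0, , drop = FALSE]
  contact_matrix(m$bins, p, m$mask)
}

#' Simulated reproducibility benchmark
#'
#' Emulates the copy-number benchmark design: per simulation, two "cell types"
#' with distinct ground-truth domain structure, a given number of replicates
#' per type each with its own random smooth biases (batch/protocol effects)
#' and noise draw, and one random copy-number profile injected into every
#' sample of the simulation. The output labels every pairwise comparison as
#' same- or different-type.
#'
#' @param config A [sim_config()]; `tad_strength` should be positive so the
#'   types differ in structure (a value of 1 is used if it is 0).
#' @param n_sims Number of independent simulations (default 20).
#' @param reps_per_type Replicates per cell type (default 2).
#' @param bias_scale Amplitude of the replicate-specific biases (default 0.6).
#' @param seed Master seed.
#' @return A list of simulations; each has `matrices` (list of
#'   `ContactMatrix`), `manifest` (`data.frame` with `id`, `cell_type`,
#'   `replicate`), `features`, `cnv` (the shared `CNVSpec`) and `bins`.
#' @export
simulate_benchmark <- function(config, n_sims = 20, reps_per_type = 2,
                               bias_scale = 0.6, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (config$tad_strength == 0) config$tad_strength <- 1
  bins <- bin_table(config$chroms, config$resolution)
  n <- sum(config$chroms)
  set.seed(seed)
  sim_seeds <- sample.int(.Machine$integer.max, n_sims)
  sims <- vector("list", n_sims)
  for (s in seq_len(n_sims)) {
    set.seed(sim_seeds[s])
    features <- sim_features(n)
    cnv <- draw_cnv_spec(bins)
    matrices <- list()
    manifest <- NULL
    for (ty in 1:2) {
      domains <- random_domains(bins$chrom, config$tad_mean_size)
      for (r in seq_len(reps_per_type)) {
        bf <- random_bias_funs(bias_scale)
        ex <- sim_expected_matrix(config, features, bf, domains)
        m <- draw_counts(ex$mu, bins, config$theta)
        m <- inject_cnv(m, cnv)
        id <- sprintf("sim%02d_t%d_r%d", s, ty, r)
        matrices[[id]] <- m
        manifest <- rbind(manifest,
                          data.frame(id = id, cell_type = paste0("type", ty),
                                     replicate = r))
      }
    }
    sims[[s]] <- list(matrices = matrices, manifest = manifest,
                      features = features, cnv = cnv, bins = bins)
  }
  sims
}
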