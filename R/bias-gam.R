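#' Low-rank penalized spline basis for one covariate
#'
#' Builds the thin-plate regression spline design columns and the associated
#' positive semi-definite wiggliness penalty for a single covariate, as used
#' for each additive term of the bias model. The basis is "low rank": it has
#' `basis_dim` coefficients regardless of the number of bins. The penalty null
#' space contains polynomials below the penalty order, so affine trends are
#' never penalized (with the default second-order penalty).
#'
#' @param values Numeric covariate values (finite; at least `basis_dim + 1`
#'   distinct values required).
#' @param basis_dim Basis dimension `k` (default 10).
#' @param penalty_order Derivative order of the wiggliness penalty (default 2).
#' @return A list with `X` (design matrix, `length(values) x basis_dim`) and
#'   `S` (the `basis_dim x basis_dim` penalty matrix).
#' @export
build_smooth_basis <- function(values, basis_dim = 10, penalty_order = 2) {
  stopifnot(is.numeric(values), basis_dim >= 3)
  if (any(!is.finite(values))) stop("non-finite covariate values")
  if (length(unique(values)) <= basis_dim)
    stop("too few distinct covariate values for the requested basis dimension")
  sm <- mgcv::smoothCon(mgcv::s(z, k = basis_dim, bs = "tp", m = penalty_order),
                        data = data.frame(z = values), absorb.cons = FALSE)[[1]]
  list(X = sm$X, S = sm$S[[1]])
}

#' Fit the negative-binomial GAM to a contact profile
#'
#' Models per-bin totals `t_i ~ NB(lambda_i, theta)` with
#' `log(lambda_i) = intercept + sum_k f_k(z_ki)`, each `f_k` a centered
#' low-rank thin-plate regression spline. Smoothing parameters are selected by
#' REML; the dispersion `theta` is estimated jointly unless fixed. The totals
#' are overdispersed counts, which is why a negative binomial is used rather
#' than a Poisson.
#'
#' @param totals Per-bin totals (the contact profile); `NA` marks masked bins.
#' @param features Per-bin covariates: a `data.frame` (or named list of numeric
#'   vectors) aligned with the bins; the canonical tracks are `gc`, `map` and
#'   `res`. Bins with any non-finite covariate are dropped from the fit.
#' @param basis_dim Spline basis dimension per covariate (default 10).
#' @param theta If non-`NULL`, fixes the NB dispersion instead of estimating it.
#' @param sp Optional fixed smoothing parameter vector (one per smooth),
#'   bypassing REML selection; mainly for validation.
#' @param min_bins Minimum number of usable bins (default 50); below this the
#'   fit refuses (run capture panels at finer resolution instead).
#' @return An object of class `oned_gam`: list with `model` (the underlying
#'   fit), `theta`, `lambda` (fitted means, `NA` on unused bins),
#'   `lambda_prime` (rescaled correction vector, mean 1 over used bins),
#'   `deviance`, `converged` and `used` (logical per bin).
#' @export
fit_nb_gam <- function(totals, features, basis_dim = 10, theta = NULL,
                       sp = NULL, min_bins = 50) {
  features <- as.data.frame(features)
  stopifnot(nrow(features) == length(totals), ncol(features) >= 1)
  used <- !is.na(totals) & Reduce(`&`, lapply(features, is.finite))
  if (sum(used) < min_bins)
    stop(sprintf("only %d usable bins (< %d): refusing to fit", sum(used), min_bins))
  dat <- features[used, , drop = FALSE]
  dat$.t <- totals[used]
  for (f in names(features))
    if (length(unique(dat[[f]])) <= basis_dim)
      stop(sprintf("feature '%s' has too few distinct values for basis_dim %d",
                   f, basis_dim))
  rhs <- paste(sprintf("s(%s, k = %d, bs = \"tp\")", names(features), basis_dim),
               collapse = " + ")
  fml <- stats::as.formula(paste(".t ~", rhs))
  fam <- if (is.null(theta)) mgcv::nb() else mgcv::negbin(theta)
  fit <- mgcv::gam(fml, family = fam, data = dat, method = "REML", sp = sp)
  theta_hat <- if (is.null(theta)) fit$family$getTheta(TRUE) else theta
  lambda <- rep(NA_real_, length(totals))
  lambda[used] <- as.numeric(stats::fitted(fit))
  lambda_prime <- lambda / mean(lambda[used])
  structure(list(model = fit, theta = theta_hat, lambda = lambda,
                 lambda_prime = lambda_prime, deviance = stats::deviance(fit),
                 converged = isTRUE(fit$converged), used = used,
                 features = names(features), basis_dim = basis_dim),
            class = "oned_gam")
}

#' @export
print.oned_gam <- function(x, ...) {
  cat(sprintf("NB-GAM contact-profile fit: %d bins, features: %s\n",
              sum(x$used), paste(x$features, collapse = ", ")))
  cat(sprintf("theta = %.4g, deviance = %.6g, converged: %s\n",
              x$theta, x$deviance, x$converged))
  invisible(x)
}

#' Correction vector from a fitted bias model
#'
#' The fitted means are rescaled to mean one over the bins that entered the
#' fit: `lambda'_i = lambda_i / (sum_j lambda_j / n)`. Any global factor in
#' `lambda` (such as sequencing depth) cancels here, so the correction is scale
#' free.
#'
#' @param fit An `oned_gam` object from [fit_nb_gam()].
#' @return Numeric per-bin vector with mean exactly 1 over used bins; `NA` on
#'   unused bins.
#' @export
correction_vector <- function(fit) {
  stopifnot(inherits(fit, "oned_gam"))
  fit$lambda_prime
}

#' Explicit one-dimensional bias normalization of a Hi-C matrix
#'
#' The full explicit correction: compute the contact profile, fit the NB-GAM of
#' [fit_nb_gam()] on the genomic covariates, rescale the fitted means into a
#' correction vector and divide every entry `x_ij` by
#' `sqrt(lambda'_i * lambda'_j)`. The corrected profile remains proportional to
#' the local copy number: copy-number aberrations are explicitly *not* treated
#' as biases. Setting `cnv = TRUE` additionally infers per-bin copy number from
#' the corrected profile (see [infer_copy_number()]) and divides each entry by
#' `sqrt(c_i * c_j)`, yielding a euploid-equivalent matrix.
#'
#' Empty bins, bins with missing covariates and (when a `map` track is given)
#' bins with zero mappability are masked before fitting and receive no
#' correction.
#'
#' @inheritParams fit_nb_gam
#' @param m A `ContactMatrix`.
#' @param cnv Also apply the copy-number correction (default `FALSE`).
#' @param modal_cn Assumed copy number of the most common state (default 2,
#'   diploid); passed to the copy-number HMM.
#' @return A list of class `oned_norm` with `matrix` (corrected
#'   `ContactMatrix`), `fit` (the `oned_gam`), and `cn` (a `CNProfile` if
#'   `cnv = TRUE`, else `NULL`).
#' @export
oned_normalize <- function(m, features, basis_dim = 10, cnv = FALSE,
                           modal_cn = 2, min_bins = 50) {
  stopifnot(inherits(m, "ContactMatrix"))
  features <- as.data.frame(features)
  bad_cov <- !Reduce(`&`, lapply(features, is.finite))
  if ("map" %in% names(features))
    bad_cov <- bad_cov | (!is.na(features$map) & features$map == 0)
  m <- set_mask(m, m$mask | auto_mask(m) | bad_cov)
  t <- contact_profile(m)
  fit <- fit_nb_gam(t, features, basis_dim = basis_dim, min_bins = min_bins)
  corrected <- apply_bin_correction(m, correction_vector(fit))
  cn <- NULL
  if (cnv) {
    cn <- infer_copy_number(corrected, modal_cn = modal_cn)
    corrected <- apply_cn_correction(corrected, cn)
  }
  structure(list(matrix = corrected, fit = fit, cn = cn), class = "oned_norm")
}

#' @export
print.oned_norm <- function(x, ...) {
  cat("One-dimensional Hi-C normalization\n")
  print(x$fit)
  if (!is.null(x$cn)) print(x$cn)
  invisible(x)
}
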