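#' Binned Hi-C contact matrices
#'
#' A `ContactMatrix` couples a bin table (the genomic axis) with a sparse
#' upper-triangle set of contact counts and a per-bin validity mask. Symmetry
#' is implicit: only entries with `bin1 <= bin2` are stored and any accessor
#' returns `x[i, j] == x[j, i]`. Absent entries read as zero; entries with
#' count zero are never stored. Masked bins are excluded from profiles, model
#' fits and corrected output.
#'
#' @param bins Bin table: a `data.frame` with columns `chrom`, `start`, `end`
#'   and `bin_id`. Coordinates are 0-based half-open; `bin_id` must be the
#'   consecutive integers `0..n-1` in row order. Within a chromosome bins must
#'   be sorted, consecutive and non-overlapping, all of width equal to the
#'   resolution except possibly the last bin of each chromosome.
#' @param pixels Contact entries: a `data.frame` with columns `bin1`, `bin2`
#'   (0-based bin ids) and `count` (non-negative). Lower-triangle entries are
#'   folded to `bin1 <= bin2`; duplicate `(bin1, bin2)` pairs after folding are
#'   an error (silent summation hides upstream bugs). Zero counts are dropped.
#' @param mask Logical vector of length `n`; `TRUE` marks a bin as masked
#'   (excluded). Defaults to all `FALSE`.
#'
#' @return An object of class `ContactMatrix`: a list with elements `bins`,
#'   `pixels` and `mask`.
#' @examples
#' bins <- bin_table(c(chrA = 2L), resolution = 100)
#' m <- contact_matrix(bins, data.frame(bin1 = c(0, 0, 1), bin2 = c(0, 1, 1),
#'                                      count = c(5, 3, 2)))
#' contact_profile(m)
#' @export
contact_matrix <- function(bins, pixels, mask = NULL) {
  bins <- validate_bins(bins)
  n <- nrow(bins)
  if (is.null(mask)) mask <- rep(FALSE, n)
  stopifnot(is.logical(mask), length(mask) == n, !anyNA(mask))
  pixels <- validate_pixels(pixels, n)
  structure(list(bins = bins, pixels = pixels, mask = mask),
            class = "ContactMatrix")
}

validate_bins <- function(bins) {
  stopifnot(is.data.frame(bins),
            all(c("chrom", "start", "end", "bin_id") %in% names(bins)))
  bins <- as.data.frame(bins)[, c("chrom", "start", "end", "bin_id")]
  bins$chrom <- as.character(bins$chrom)
  n <- nrow(bins)
  if (n == 0L) stop("empty bin table")
  if (!identical(as.integer(bins$bin_id), seq_len(n) - 1L))
    stop("bin_id must be the consecutive integers 0..n-1 in row order")
  if (any(bins$end <= bins$start)) stop("bins must have positive width")
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    if (nrow(b) > 1L && !all(b$start[-1] == b$end[-nrow(b)]))
      stop("bins within a chromosome must be consecutive and non-overlapping")
  }
  bins
}

validate_pixels <- function(pixels, n) {
  if (is.null(pixels) || nrow(pixels) == 0L)
    return(data.frame(bin1 = integer(), bin2 = integer(), count = numeric()))
  stopifnot(all(c("bin1", "bin2", "count") %in% names(pixels)))
  p <- data.frame(bin1 = as.integer(pixels$bin1), bin2 = as.integer(pixels$bin2),
                  count = as.numeric(pixels$count))
  if (anyNA(p)) stop("NA in pixels")
  if (any(p$bin1 < 0L | p$bin1 >= n | p$bin2 < 0L | p$bin2 >= n))
    stop("bin_id out of range")
  if (any(p$count < 0)) stop("negative count")
  swap <- p$bin1 > p$bin2            # fold lower triangle
  tmp <- p$bin1[swap]; p$bin1[swap] <- p$bin2[swap]; p$bin2[swap] <- tmp
  key <- p$bin1 * n + p$bin2
  if (anyDuplicated(key)) stop("duplicate entry for the same bin pair")
  p <- p[p$count > 0, , drop = FALSE]
  p <- p[order(p$bin1, p$bin2), , drop = FALSE]
  rownames(p) <- NULL
  p
}

#' Construct a bin table
#'
#' @param chrom_bins Named integer vector: number of bins per chromosome, in
#'   genome order.
#' @param resolution Bin size in base pairs (default 1e5, the usual working
#'   resolution for genome-wide analyses).
#' @return A bin table `data.frame` usable by [contact_matrix()].
#' @export
bin_table <- function(chrom_bins, resolution = 1e5) {
  stopifnot(length(chrom_bins) >= 1, !is.null(names(chrom_bins)),
            all(chrom_bins >= 1), resolution >= 1)
  chrom <- rep(names(chrom_bins), chrom_bins)
  start <- unlist(lapply(chrom_bins,
                         function(k) as.integer((seq_len(k) - 1) * resolution)),
                  use.names = FALSE)
  data.frame(chrom = chrom, start = start,
             end = start + as.integer(resolution),
             bin_id = seq_along(chrom) - 1L)
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %d bins (%d masked), %d chromosome(s), %d stored entries\n",
              n_bins(x), sum(x$mask), length(unique(x$bins$chrom)), nrow(x$pixels)))
  cat(sprintf("resolution: %d bp; total counts: %.6g\n",
              resolution(x), sum(x$pixels$count)))
  invisible(x)
}

#' @export
dim.ContactMatrix <- function(x) c(nrow(x$bins), nrow(x$bins))

#' Number of bins of a ContactMatrix
#' @param m A `ContactMatrix`.
#' @return Integer bin count.
#' @export
n_bins <- function(m) nrow(m$bins)

#' Bin resolution in base pairs
#'
#' The modal bin width (the last bin of a chromosome may be shorter).
#' @param m A `ContactMatrix` or a bin table.
#' @return Integer resolution.
#' @export
resolution <- function(m) {
  bins <- if (inherits(m, "ContactMatrix")) m$bins else m
  w <- bins$end - bins$start
  as.integer(max(w))
}

#' Replace the validity mask of a ContactMatrix
#'
#' @param m A `ContactMatrix`.
#' @param mask Logical vector (`TRUE` = masked/excluded), length `n_bins(m)`.
#' @return A `ContactMatrix` with the new mask. Stored entries are kept (they
#'   are ignored by profiles/fits and dropped from corrected output).
#' @export
set_mask <- function(m, mask) {
  stopifnot(inherits(m, "ContactMatrix"), is.logical(mask),
            length(mask) == n_bins(m), !anyNA(mask))
  m$mask <- mask
  m
}

#' Symmetric accessor for contact counts
#'
#' @param m A `ContactMatrix`.
#' @param i,j 0-based bin ids (vectors of equal length).
#' @return Numeric vector of counts, `x[i, j] == x[j, i]`, zeros for absent
#'   entries.
#' @export
contact_at <- function(m, i, j) {
  n <- n_bins(m)
  a <- pmin(i, j); b <- pmax(i, j)
  key <- a * n + b
  pk <- m$pixels$bin1 * n + m$pixels$bin2
  out <- m$pixels$count[match(key, pk)]
  out[is.na(out)] <- 0
  out
}

#' Dense symmetric matrix view
#'
#' Materializes the full symmetric count matrix. Masked bins' rows/columns are
#' returned as `NA` when `drop_masked = FALSE` semantics are not needed; here
#' they are filled like any other (masking is a downstream concern).
#' @param x A `ContactMatrix`.
#' @param ... Unused.
#' @return A dense `n x n` numeric matrix.
#' @export
as.matrix.ContactMatrix <- function(x, ...) {
  n <- n_bins(x)
  M <- matrix(0, n, n)
  if (nrow(x$pixels)) {
    i <- x$pixels$bin1 + 1L; j <- x$pixels$bin2 + 1L
    M[cbind(i, j)] <- x$pixels$count
    M[cbind(j, i)] <- x$pixels$count
  }
  M
}

#' Contact profile (per-bin totals)
#'
#' The one-dimensional reduction of the matrix: `t_i = sum_j x_ij` genome-wide
#' (cis + trans), with the diagonal counted once. Masked bins (and entries
#' touching them) contribute nothing; masked bins get `NA`.
#'
#' @param m A `ContactMatrix`.
#' @return Numeric vector of length `n_bins(m)`; `NA` for masked bins.
#' @export
contact_profile <- function(m) {
  stopifnot(inherits(m, "ContactMatrix"))
  n <- n_bins(m)
  t <- numeric(n)
  p <- m$pixels
  if (nrow(p)) {
    keep <- !m$mask[p$bin1 + 1L] & !m$mask[p$bin2 + 1L]
    p <- p[keep, , drop = FALSE]
    if (nrow(p)) {
      t <- t + tabulate_weighted(p$bin1 + 1L, p$count, n)
      off <- p$bin1 != p$bin2
      t <- t + tabulate_weighted(p$bin2[off] + 1L, p$count[off], n)
    }
  }
  t[m$mask] <- NA_real_
  t
}

tabulate_weighted <- function(idx, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Mask bins with low totals
#'
#' Computes per-bin totals ignoring the current mask and flags bins whose total
#' is `<= min_total`. This is what makes profile-based normalization applicable
#' to capture designs where most of the genome carries no signal: empty bins
#' are excluded rather than dragged into the fit.
#'
#' @param m A `ContactMatrix`.
#' @param min_total Threshold (default 0: mask empty bins only).
#' @return Logical vector (`TRUE` = mask), to be combined with [set_mask()].
#' @export
auto_mask <- function(m, min_total = 0) {
  stopifnot(inherits(m, "ContactMatrix"), min_total >= 0)
  t <- contact_profile(set_mask(m, rep(FALSE, n_bins(m))))
  t <= min_total
}

#' Apply a per-bin correction vector to a matrix
#'
#' Each stored entry `(i, j)` is divided by `sqrt(v_i * v_j)`. This is the
#' generic correction primitive: the explicit bias correction uses the rescaled
#' fitted means as `v`, the copy-number correction uses the inferred copy
#' numbers, and the balancing baselines use squared bias vectors.
#'
#' @param m A `ContactMatrix`.
#' @param v Numeric vector of length `n_bins(m)`; must be finite and `> 0` on
#'   every unmasked bin (values on masked bins are ignored).
#' @return A `ContactMatrix` with corrected counts; entries touching masked
#'   bins are removed (not zero-filled).
#' @export
apply_bin_correction <- function(m, v) {
  stopifnot(inherits(m, "ContactMatrix"), is.numeric(v), length(v) == n_bins(m))
  ok <- !m$mask
  if (any(!is.finite(v[ok])) || any(v[ok] <= 0))
    stop("correction value missing or <= 0 on an unmasked bin")
  p <- m$pixels
  keep <- !m$mask[p$bin1 + 1L] & !m$mask[p$bin2 + 1L]
  p <- p[keep, , drop = FALSE]
  p$count <- p$count / sqrt(v[p$bin1 + 1L] * v[p$bin2 + 1L])
  contact_matrix(m$bins, p, m$mask)
}

#' Distance (in bins) of each stored entry; NA for trans entries
#' @noRd
pixel_distance <- function(m) {
  ch <- m$bins$chrom
  cis <- ch[m$pixels$bin1 + 1L] == ch[m$pixels$bin2 + 1L]
  d <- m$pixels$bin2 - m$pixels$bin1
  d[!cis] <- NA_integer_
  d
}
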