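#' Read a contact matrix from sparse triplet text
#'
#' The triplet format is plain whitespace/TAB-separated text with one entry per
#' line, `bin1 bin2 count`, using 0-based bin ids against a separately supplied
#' bin table. An optional header line `# resolution=<int>` is accepted and
#' checked against the bin table. Lower-triangle entries are folded to
#' `bin1 <= bin2`; duplicates after folding are an error.
#'
#' @param path Path to the triplet file.
#' @param bins Bin table (see [contact_matrix()]), e.g. from [read_bins()].
#' @return A `ContactMatrix`.
#' @seealso [write_contacts()], [read_bins()]
#' @export
read_contacts <- function(path, bins) {
  bins <- validate_bins(bins)
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  res_h <- regmatches(header, regexpr("resolution=[0-9]+", header))
  if (length(res_h)) {
    res <- as.integer(sub("resolution=", "", res_h[1]))
    if (res != resolution(bins))
      stop(sprintf("triplet resolution (%d) does not match bin table (%d)",
                   res, resolution(bins)))
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(body))
    return(contact_matrix(bins, NULL))
  con <- textConnection(body)
  on.exit(close(con))
  p <- utils::read.table(con, col.names = c("bin1", "bin2", "count"),
                         colClasses = c("integer", "integer", "numeric"))
  contact_matrix(bins, p)
}

#' Write a contact matrix as sparse triplet text
#'
#' Entries are written sorted by `(bin1, bin2)` with `bin1 <= bin2`, preceded
#' by a `# resolution=<int>` header. `read_contacts()` on the output recovers
#' identical entries.
#'
#' @param m A `ContactMatrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_contacts <- function(m, path) {
  stopifnot(inherits(m, "ContactMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# resolution=%d", resolution(m)), con)
  if (nrow(m$pixels))
    utils::write.table(m$pixels, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bin table from 4-column BED
#'
#' Columns: chrom, start, end, bin_id (0-based, consecutive). Read through
#' rtracklayer's BED parser (the `name` field carries the bin id).
#'
#' @param path Path to the BED file.
#' @return A bin table `data.frame`.
#' @export
read_bins <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             bin_id = as.integer(gr$name))
}

#' Write a bin table as 4-column BED
#' @param bins A bin table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bins <- function(bins, path) {
  bins <- validate_bins(bins)
  gr <- bins_to_granges(bins)
  gr$name <- as.character(bins$bin_id)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

bins_to_granges <- function(bins) {
  GenomicRanges::GRanges(bins$chrom,
                         IRanges::IRanges(start = bins$start + 1L, end = bins$end))
}

#' Read a per-bin feature track from bedGraph
#'
#' The bedGraph intervals must tile the bin table exactly (same chromosomes,
#' starts and ends, in any order). Typical tracks are G+C fraction (`gc`, in
#' \[0,1\]), read mappability (`map`, in \[0,1\]) and restriction-site counts
#' (`res`, a non-negative count).
#'
#' @param path Path to the bedGraph file.
#' @param bins Bin table the track must align to.
#' @return Numeric vector of per-bin values aligned with `bins` (missing
#'   values allowed as NA in the file).
#' @export
read_track <- function(path, bins) {
  bins <- validate_bins(bins)
  gr <- rtracklayer::import(path, format = "bedGraph")
  d <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1L,
                  end = GenomicRanges::end(gr),
                  value = as.numeric(gr$score))
  interval_key <- function(chrom, start, end)
    sprintf("%s:%.0f-%.0f", chrom, start, end)
  key_track <- interval_key(d$chrom, d$start, d$end)
  key_bins <- interval_key(bins$chrom, bins$start, bins$end)
  idx <- match(key_bins, key_track)
  if (anyNA(idx) || nrow(d) != nrow(bins))
    stop("bedGraph intervals do not tile the bin table exactly")
  d$value[idx]
}

#' Write a per-bin track as bedGraph
#' @param values Numeric per-bin values (NA bins are skipped).
#' @param bins Bin table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_track <- function(values, bins, path) {
  bins <- validate_bins(bins)
  stopifnot(length(values) == nrow(bins))
  keep <- !is.na(values)
  gr <- bins_to_granges(bins[keep, , drop = FALSE])
  gr$score <- as.numeric(values[keep])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
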