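#' Margin for lineage-specific bin classification
#'
#' The classification margin is a fixed fraction of the bin size; with the
#' default 0.01\% and 100-kb bins the margin is 10 k-mers.
#'
#' @param bin_size Bin size in bp.
#' @param margin_fraction Fraction of the bin size (default 1e-4, i.e.
#'   0.01\%).
#' @return The margin as a count.
#' @export
margin_for <- function(bin_size, margin_fraction = 1e-4) {
  if (bin_size <= 0) stop("bin_size must be positive")
  if (margin_fraction < 0) stop("margin_fraction must be nonnegative")
  bin_size * margin_fraction
}

#' Classify genome bins by lineage-specific k-mer counts
#'
#' A bin is assigned to lineage L iff its L-specific k-mer count strictly
#' exceeds every other lineage's count by more than the margin; otherwise
#' it is UNASSIGNED. The rule is applied symmetrically to all lineages
#' present in the count table.
#'
#' @param counts Data frame with columns `assembly`, `chrom`, `bin_start`
#'   (0-based, multiples of the bin size) and one `count_<lineage>` column
#'   per lineage.
#' @param margin Count margin (see [margin_for()]).
#' @param bin_size Bin size in bp (default 100000).
#' @return A `bin_classification` data.frame: the input plus an `assigned`
#'   column (`"L1"`, ..., or `"UNASSIGNED"`); attributes `margin` and
#'   `bin_size`.
#' @export
classify_bins <- function(counts, margin = margin_for(bin_size),
                          bin_size = 100000L) {
  cols <- grep("^count_", names(counts), value = TRUE)
  if (length(cols) < 2L) stop("need counts for at least 2 lineages")
  lineages <- sub("^count_", "", cols)
  cm <- as.matrix(counts[, cols, drop = FALSE])
  if (any(cm < 0)) stop("negative k-mer counts")
  assigned <- rep("UNASSIGNED", nrow(counts))
  for (j in seq_along(lineages)) {
    others <- cm[, -j, drop = FALSE]
    wins <- rowSums(cm[, j] > others + margin) == ncol(others)
    assigned[wins] <- lineages[j]
  }
  out <- counts
  out$assigned <- assigned
  attr(out, "margin") <- margin
  attr(out, "bin_size") <- as.integer(bin_size)
  class(out) <- c("bin_classification", "data.frame")
  out
}

#' Lineage assignment of the bins overlapping a gene
#'
#' Maps a 1-based inclusive gene interval onto the 0-based half-open bin
#' grid (position p lies in the bin starting at
#' `floor((p - 1) / bin_size) * bin_size`) and reports the lineage
#' assignment of every overlapped bin, with a consensus call when all
#' overlapped bins agree and `"MIXED"` otherwise.
#'
#' @param cls A `bin_classification`.
#' @param chrom Gene chromosome.
#' @param start,end Gene interval, 1-based inclusive.
#' @return List with `bins` (data.frame of overlapped bins and their
#'   assignments) and `consensus` (single lineage, `"UNASSIGNED"`, or
#'   `"MIXED"`).
#' @export
colocalize_gene <- function(cls, chrom, start, end) {
  stopifnot(inherits(cls, "bin_classification"), start <= end)
  bin_size <- attr(cls, "bin_size")
  rows <- cls[cls$chrom == chrom, , drop = FALSE]
  if (nrow(rows) == 0L) stop("chromosome '", chrom,
                             "' absent from bin classification")
  first_bin <- ((start - 1L) %/% bin_size) * bin_size
  last_bin <- ((end - 1L) %/% bin_size) * bin_size
  hit <- rows[rows$bin_start >= first_bin & rows$bin_start <= last_bin, ,
              drop = FALSE]
  calls <- unique(hit$assigned)
  consensus <- if (length(calls) == 1L) calls else "MIXED"
  list(bins = hit, consensus = consensus)
}

#' Read a lineage-specific k-mer bin count table
#'
#' @param path TSV with columns `assembly`, `chrom`, `bin_start` and one
#'   `count_<lineage>` column per lineage.
#' @return Data frame suitable for [classify_bins()].
#' @export
read_bin_counts <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
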