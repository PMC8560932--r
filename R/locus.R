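#' Define the two-gene Glu-D1 locus
#'
#' A locus definition carries the coordinates of the x and y subunit genes,
#' the flank width used for region tagging, and each gene's strand. All
#' coordinates are 1-based closed intervals (VCF/GFF convention). Defaults
#' are the Glu-D1x and Glu-D1y coordinates on the AL8/78 chromosome 1D
#' assembly with 2.5 kb flanks.
#'
#' @param chrom Chromosome name.
#' @param gene_x,gene_y Length-2 integer vectors `c(start, end)` of the x and
#'   y subunit genes (1-based inclusive).
#' @param flank Flank width in bp added on both sides of each gene.
#' @param strand_x,strand_y Strand of each gene, `"+"` or `"-"`.
#' @return An object of class `locus_definition`.
#' @examples
#' loc <- locus_definition()
#' region_of(c(419306988, 419304488, 419304487), loc)
#' @export
locus_definition <- function(chrom = "chr1D",
                             gene_x = c(419306988L, 419309556L),
                             gene_y = c(419364015L, 419365995L),
                             flank = 2500L,
                             strand_x = "+", strand_y = "+") {
  stopifnot(length(gene_x) == 2L, length(gene_y) == 2L,
            gene_x[1] <= gene_x[2], gene_y[1] <= gene_y[2],
            flank >= 0)
  if (max(gene_x[1], gene_y[1]) <= min(gene_x[2], gene_y[2]))
    stop("gene_x and gene_y intervals overlap")
  strand_x <- match.arg(strand_x, c("+", "-"))
  strand_y <- match.arg(strand_y, c("+", "-"))
  structure(list(chrom = chrom,
                 gene_x = as.integer(gene_x), gene_y = as.integer(gene_y),
                 flank = as.integer(flank),
                 strand_x = strand_x, strand_y = strand_y),
            class = "locus_definition")
}

#' @export
print.locus_definition <- function(x, ...) {
  cat("Glu-D1 locus on", x$chrom, "\n")
  cat(sprintf("  gene x: %d-%d (%s)\n", x$gene_x[1], x$gene_x[2], x$strand_x))
  cat(sprintf("  gene y: %d-%d (%s)\n", x$gene_y[1], x$gene_y[2], x$strand_y))
  cat(sprintf("  flank : %d bp\n", x$flank))
  invisible(x)
}

#' Region tag of genomic positions within a locus
#'
#' Tags each position as `coding-x`, `coding-y`, `flank-x`, `flank-y`, or
#' `NA` when outside the locus. Flank windows are the `flank` bp immediately
#' up- and downstream of each gene, boundaries inclusive.
#'
#' @param pos Integer vector of 1-based positions.
#' @param locus A [locus_definition()].
#' @return Character vector of region tags (NA outside the locus).
#' @export
region_of <- function(pos, locus) {
  stopifnot(inherits(locus, "locus_definition"))
  gx <- locus$gene_x; gy <- locus$gene_y; fl <- locus$flank
  out <- rep(NA_character_, length(pos))
  out[pos >= gx[1] - fl & pos <= gx[2] + fl] <- "flank-x"
  out[pos >= gy[1] - fl & pos <= gy[2] + fl] <- "flank-y"
  out[pos >= gx[1] & pos <= gx[2]] <- "coding-x"
  out[pos >= gy[1] & pos <= gy[2]] <- "coding-y"
  out
}

#' Genotype-calling thresholds
#'
#' Thresholds for converting per-sample DP (total depth), DV (alternate
#' depth) and site QUAL into hard genotype calls. The QUAL comparison is
#' strict: a site is callable only when QUAL > `qual_min`. The DV/DP ratio
#' cutoffs are symmetric defaults for inbred (effectively homozygous)
#' panels; intermediate ratios are treated as ambiguous and yield MISSING.
#'
#' @param qual_min Minimum site QUAL (strictly exceeded to call).
#' @param ratio_homref_max Max DV/DP ratio still called homozygous REF.
#' @param ratio_homalt_min Min DV/DP ratio called homozygous ALT.
#' @param depth_min Minimum DP to attempt a call.
#' @return An object of class `call_thresholds`.
#' @export
call_thresholds <- function(qual_min = 40, ratio_homref_max = 0.2,
                            ratio_homalt_min = 0.8, depth_min = 2L) {
  stopifnot(qual_min >= 0, depth_min >= 0,
            ratio_homref_max >= 0, ratio_homalt_min <= 1,
            ratio_homref_max < ratio_homalt_min)
  structure(list(qual_min = qual_min,
                 ratio_homref_max = ratio_homref_max,
                 ratio_homalt_min = ratio_homalt_min,
                 depth_min = as.integer(depth_min)),
            class = "call_thresholds")
}
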