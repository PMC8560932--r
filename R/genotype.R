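#' Call a hard genotype from depth ratio and site quality
#'
#' Implements the DV/DP ratio rule used for inbred panels: a call is
#' attempted only when the site QUAL strictly exceeds `qual_min` and DP
#' reaches `depth_min`; the call is REF when DV/DP is at most
#' `ratio_homref_max`, ALT when at least `ratio_homalt_min`, and MISSING
#' (flagged het-ambiguous) for intermediate ratios — accessions are
#' effectively homozygous, so intermediate ratios are treated as noise.
#'
#' Vectorized over `dp`, `dv` and `qual`. NA depth or QUAL yields MISSING
#' with flag `no-data`.
#'
#' @param dp Total read depth(s).
#' @param dv Alternate-allele read depth(s); must satisfy `dv <= dp`.
#' @param qual Site QUAL score(s).
#' @param thresholds A [call_thresholds()].
#' @return Character vector in `{"REF","ALT","MISSING"}` with attribute
#'   `flag` giving the reason for each MISSING call
#'   (`low-qual`, `low-depth`, `het-ambiguous`, `no-data`).
#' @examples
#' call_genotype(10, 0, 60, call_thresholds())   # REF
#' call_genotype(10, 5, 60, call_thresholds())   # MISSING, het-ambiguous
#' @export
call_genotype <- function(dp, dv, qual, thresholds = call_thresholds()) {
  stopifnot(inherits(thresholds, "call_thresholds"))
  n <- max(length(dp), length(dv), length(qual))
  dp <- rep_len(as.numeric(dp), n)
  dv <- rep_len(as.numeric(dv), n)
  qual <- rep_len(as.numeric(qual), n)
  if (any(dv > dp, na.rm = TRUE)) stop("dv exceeds dp")
  if (any(dv < 0 | dp < 0, na.rm = TRUE)) stop("negative depths")

  call <- rep("MISSING", n)
  flag <- rep(NA_character_, n)
  nodata <- is.na(dp) | is.na(dv) | is.na(qual)
  flag[nodata] <- "no-data"
  lowq <- !nodata & qual <= thresholds$qual_min
  flag[lowq] <- "low-qual"
  lowd <- !nodata & !lowq & dp < thresholds$depth_min
  flag[lowd] <- "low-depth"
  ok <- !nodata & !lowq & !lowd
  ratio <- ifelse(ok & dp > 0, dv / dp, NA_real_)
  call[ok & ratio <= thresholds$ratio_homref_max] <- "REF"
  call[ok & ratio >= thresholds$ratio_homalt_min] <- "ALT"
  het <- ok & call == "MISSING"
  flag[het] <- "het-ambiguous"
  attr(call, "flag") <- flag
  call
}

#' Build a genotype matrix from an extracted VCF region
#'
#' Applies [call_genotype()] to every site-by-sample cell of a
#' [read_vcf_region()] result.
#'
#' @param region A `vcf_region`.
#' @param thresholds A [call_thresholds()].
#' @return An object of class `genotype_matrix`: list with `calls` (integer
#'   matrix, 0 = REF, 1 = ALT, NA = MISSING; sites in rows), `flags`
#'   (character matrix of MISSING reasons), `sites` and `samples`.
#' @export
build_genotype_matrix <- function(region, thresholds = call_thresholds()) {
  stopifnot(inherits(region, "vcf_region"))
  ns <- nrow(region$sites)
  qual <- matrix(rep(region$sites$qual, ncol(region$dp)), nrow = ns)
  cc <- call_genotype(as.vector(region$dp), as.vector(region$dv),
                      as.vector(qual), thresholds)
  calls <- matrix(ifelse(cc == "REF", 0L, ifelse(cc == "ALT", 1L, NA_integer_)),
                  nrow = ns, dimnames = list(NULL, region$samples))
  flags <- matrix(attr(cc, "flag"), nrow = ns,
                  dimnames = list(NULL, region$samples))
  new_genotype_matrix(calls, region$sites, flags)
}

#' Construct a genotype matrix directly
#'
#' Mostly useful for tests and for importing externally called matrices.
#'
#' @param calls Integer matrix of 0/1/NA calls, sites in rows, named
#'   sample columns.
#' @param sites Data frame describing the rows; a `pos` column is required
#'   and a `region` column is needed for scope-based operations.
#' @param flags Optional character matrix of MISSING reasons.
#' @return A `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, sites, flags = NULL) {
  stopifnot("pos" %in% names(sites))
  new_genotype_matrix(calls, sites, flags)
}

new_genotype_matrix <- function(calls, sites, flags = NULL) {
  stopifnot(nrow(calls) == nrow(sites))
  if (ncol(calls) > 0L && is.null(colnames(calls)))
    stop("calls must have sample names")
  structure(list(calls = calls, sites = sites, flags = flags,
                 samples = colnames(calls)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "sites x", length(x$samples),
      "samples;", sprintf("%.1f%% missing\n", 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Filter variant sites by polymorphism, MAF and missingness
#'
#' Removes sites that are monomorphic among called samples, have minor
#' allele frequency below `maf_min` (computed over non-missing calls), or
#' are missing in more than `miss_max` of samples. The sample set is
#' unchanged and the operation is idempotent.
#'
#' @param m A `genotype_matrix`.
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param miss_max Maximum fraction of missing calls (default 0.90).
#' @return A filtered `genotype_matrix`.
#' @export
apply_site_filters <- function(m, maf_min = 0.01, miss_max = 0.90) {
  stopifnot(inherits(m, "genotype_matrix"),
            maf_min >= 0, maf_min < 1, miss_max > 0, miss_max <= 1)
  if (length(m$samples) == 0L) stop("genotype matrix has zero samples")
  ncall <- rowSums(!is.na(m$calls))
  miss_frac <- 1 - ncall / length(m$samples)
  p <- rowMeans(m$calls, na.rm = TRUE)           # ALT frequency among called
  maf <- pmin(p, 1 - p)
  poly <- ncall > 0 & p > 0 & p < 1
  keep <- poly & maf >= maf_min & miss_frac <= miss_max
  keep[is.na(keep)] <- FALSE
  new_genotype_matrix(m$calls[keep, , drop = FALSE],
                      m$sites[keep, , drop = FALSE],
                      if (!is.null(m$flags)) m$flags[keep, , drop = FALSE])
}

#' Group samples sharing nearly identical genome-wide calls
#'
#' Duplicated accessions are detected as pairs whose genome-wide variant
#' calls agree at more than `identity_min` of co-called sites; connected
#' components of the resulting graph are returned (singletons included).
#'
#' @param calls Integer matrix of genome-wide calls (sites x samples;
#'   0/1/NA) or a `genotype_matrix`.
#' @param identity_min Identity threshold, strictly exceeded to link a pair
#'   (default 0.998).
#' @return List of character vectors, each a group of sample names.
#' @export
find_duplicates <- function(calls, identity_min = 0.998) {
  if (inherits(calls, "genotype_matrix")) calls <- calls$calls
  stopifnot(is.matrix(calls), identity_min >= 0, identity_min <= 1)
  samples <- colnames(calls)
  n <- ncol(calls)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq((i + 1L), n)) {
      both <- !is.na(calls[, i]) & !is.na(calls[, j])
      nco <- sum(both)
      if (nco == 0L) {
        warning("no co-called sites for pair ", samples[i], "/", samples[j],
                "; pair skipped")
        next
      }
      ident <- sum(calls[both, i] == calls[both, j]) / nco
      if (ident > identity_min) parent[find(j)] <- find(i)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  unname(lapply(split(samples, root), sort))
}

#' Hamming distance between two allele vectors
#'
#' Counts positions where both vectors are called and differ; positions
#' with MISSING in either vector are excluded and reported via the
#' `n_excluded` attribute.
#'
#' @param a,b Equal-length vectors of calls (0/1/NA).
#' @return Integer count with attribute `n_excluded`.
#' @export
hamming <- function(a, b) {
  if (length(a) != length(b)) stop("allele vectors differ in length")
  both <- !is.na(a) & !is.na(b)
  structure(sum(a[both] != b[both]), n_excluded = sum(!both))
}
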