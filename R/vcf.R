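#' Read the Glu-D1 region of a VCF
#'
#' Parses a VCF (via \pkg{vcfR}), keeps only records falling inside the
#' coding or flanking regions of either subunit gene, splits multiallelic
#' records into one record per ALT allele, and extracts per-sample DP and DV
#' depths. When the FORMAT lacks a DV field, the per-allele AD field is used
#' and DV derived as the depth of the record's ALT allele.
#'
#' @param vcf_source Path to a VCF file (plain text or gzipped).
#' @param locus A [locus_definition()].
#' @return An object of class `vcf_region`: a list with `sites` (data.frame
#'   with chrom, pos, ref, alt, qual, region), `dp` and `dv` (numeric
#'   site-by-sample matrices) and `samples`.
#' @export
read_vcf_region <- function(vcf_source, locus) {
  stopifnot(inherits(locus, "locus_definition"))
  validate_vcf_lines(vcf_source)
  v <- vcfR::read.vcfR(vcf_source, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)      # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L || !any(fix$CHROM == locus$chrom)) {
    warning("locus chromosome '", locus$chrom, "' absent from VCF")
    return(empty_vcf_region(colnames(v@gt)[-1]))
  }
  pos <- as.integer(fix$POS)
  region <- region_of(pos, locus)
  keep <- fix$CHROM == locus$chrom & !is.na(region)
  if (!any(keep)) {
    warning("no VCF records fall inside the locus regions")
    return(empty_vcf_region(colnames(v@gt)[-1]))
  }
  fix <- fix[keep, , drop = FALSE]
  pos <- pos[keep]; region <- region[keep]
  samples <- colnames(v@gt)[-1]

  as_site_matrix <- function(x) {
    if (is.null(dim(x))) x <- t(x)
    x[keep, , drop = FALSE]
  }
  dp <- as_site_matrix(suppressWarnings(vcfR::extract.gt(v, "DP", as.numeric = TRUE)))
  fmt <- v@gt[keep, 1]
  has_dv <- all(grepl("(^|:)DV(:|$)", fmt))
  dv_raw <- if (has_dv) {
    as_site_matrix(suppressWarnings(vcfR::extract.gt(v, "DV", as.numeric = TRUE)))
  } else {
    as_site_matrix(vcfR::extract.gt(v, "AD"))   # character "ref,alt1,..."
  }

  # split multiallelic records into one row per ALT
  out_sites <- list(); out_dp <- list(); out_dv <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (j in seq_along(alts)) {
      out_sites[[length(out_sites) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = pos[i],
        ref = fix$REF[i], alt = alts[j],
        qual = as.numeric(fix$QUAL[i]), region = region[i],
        stringsAsFactors = FALSE)
      out_dp[[length(out_dp) + 1L]] <- dp[i, ]
      if (has_dv) {
        out_dv[[length(out_dv) + 1L]] <- dv_raw[i, ]
      } else {
        ad <- strsplit(dv_raw[i, ], ",", fixed = TRUE)
        out_dv[[length(out_dv) + 1L]] <- vapply(ad, function(x) {
          if (length(x) > j) as.numeric(x[j + 1L]) else NA_real_
        }, numeric(1))
      }
    }
  }
  sites <- do.call(rbind, out_sites)
  dpm <- do.call(rbind, out_dp); dvm <- do.call(rbind, out_dv)
  storage.mode(dpm) <- "double"; storage.mode(dvm) <- "double"
  colnames(dpm) <- colnames(dvm) <- samples

  ord <- order(sites$chrom, sites$pos, sites$alt)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(sites = sites,
                 dp = dpm[ord, , drop = FALSE],
                 dv = dvm[ord, , drop = FALSE],
                 samples = samples),
            class = "vcf_region")
}

empty_vcf_region <- function(samples) {
  structure(list(sites = data.frame(chrom = character(), pos = integer(),
                                    ref = character(), alt = character(),
                                    qual = numeric(), region = character(),
                                    stringsAsFactors = FALSE),
                 dp = matrix(numeric(), 0, length(samples),
                             dimnames = list(NULL, samples)),
                 dv = matrix(numeric(), 0, length(samples),
                             dimnames = list(NULL, samples)),
                 samples = samples),
            class = "vcf_region")
}

# Light structural validation so malformed lines are reported with their
# line number before the parser sees them.
validate_vcf_lines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  n_fields <- NA_integer_
  i <- 0L
  repeat {
    lines <- readLines(con, n = 5000L)
    if (length(lines) == 0L) break
    for (ln in lines) {
      i <- i + 1L
      if (startsWith(ln, "##")) next
      nf <- length(strsplit(ln, "\t", fixed = TRUE)[[1]])
      if (startsWith(ln, "#CHROM")) { n_fields <- nf; next }
      if (nf < 8L || (!is.na(n_fields) && nf != n_fields))
        stop("malformed VCF line ", i, ": expected ",
             if (is.na(n_fields)) "at least 8" else n_fields,
             " fields, found ", nf)
    }
  }
  invisible(TRUE)
}

#' @export
print.vcf_region <- function(x, ...) {
  cat("vcf_region:", nrow(x$sites), "site records x", length(x$samples),
      "samples\n")
  if (nrow(x$sites)) print(table(x$sites$region))
  invisible(x)
}
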