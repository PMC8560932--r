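# Independent brute-force oracles used across the suite. These deliberately
# recompute quantities with the most literal, loop-based expression of the
# defining formulae, sharing no code with the package internals they check.

# VanRaden method-1 A matrix, elementwise.
oracle_amatrix <- function(calls) {
  n_sites <- nrow(calls); n_samp <- ncol(calls)
  p <- sapply(seq_len(n_sites), function(j) mean(calls[j, ], na.rm = TRUE))
  w <- matrix(0, n_sites, n_samp)
  for (j in seq_len(n_sites)) {
    for (s in seq_len(n_samp)) {
      code <- if (is.na(calls[j, s])) 2 * p[j] - 1 else 2 * calls[j, s] - 1
      w[j, s] <- code - (2 * p[j] - 1)
    }
  }
  denom <- 2 * sum(p * (1 - p))
  A <- matrix(0, n_samp, n_samp)
  for (i in seq_len(n_samp))
    for (k in seq_len(n_samp))
      A[i, k] <- sum(w[, i] * w[, k]) / denom
  dimnames(A) <- list(colnames(calls), colnames(calls))
  A
}

# Naive O(n^3) agglomerative clustering; returns sorted merge heights.
oracle_agglom_heights <- function(D, method = "complete") {
  D <- as.matrix(D)
  clusters <- as.list(seq_len(nrow(D)))
  linkfun <- switch(method, complete = max, single = min, average = mean)
  heights <- numeric()
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(length(clusters) - 1L))
      for (j in seq(i + 1L, length(clusters))) {
        d <- linkfun(D[clusters[[i]], clusters[[j]]])
        if (d < best) { best <- d; bi <- i; bj <- j }
      }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  sort(heights)
}

# Literal transcription of the bin rule for one count triple.
oracle_classify_triple <- function(cnt, margin, lineages) {
  for (l in seq_along(cnt)) {
    if (all(cnt[l] > cnt[-l] + margin)) return(lineages[l])
  }
  "UNASSIGNED"
}

# Effect class by full-CDS translation diffing.
oracle_effect_class <- function(cds, cds_pos, alt_base) {
  alt_cds <- cds
  substr(alt_cds, cds_pos, cds_pos) <- alt_base
  tr <- function(s) as.character(Biostrings::translate(Biostrings::DNAString(s)))
  rp <- tr(cds); ap <- tr(alt_cds)
  if (rp == ap) return("synonymous")
  i <- which(strsplit(rp, "")[[1]] != strsplit(ap, "")[[1]])[1]
  ra <- substr(rp, i, i); aa <- substr(ap, i, i)
  if (aa == "*") "nonsense"
  else if (ra == "*") "stop-loss"
  else if (i == 1 && substr(cds, 1, 3) == "ATG") "start-loss"
  else "missense"
}

# Random additive distance matrix from a random tree with positive branches.
random_additive_matrix <- function(n_taxa) {
  tree <- ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.1, 2))
  list(tree = tree, D = ape::cophenetic.phylo(tree))
}

# Small genotype_matrix builder for unit tests.
make_gm <- function(calls, pos = seq_len(nrow(calls)),
                    region = rep("coding-x", nrow(calls))) {
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("s%02d", seq_len(ncol(calls)))
  genotype_matrix(calls,
                  data.frame(chrom = "chr1D", pos = pos,
                             ref = "A", alt = "T", qual = 99,
                             region = region, stringsAsFactors = FALSE))
}

# Zero-noise fixture config used by the planted-truth checks: 3 lineages,
# 9 pool pairs + 2 recombinant pairs = 11 combined haplotypes, 1 duplicate.
fixture_config <- function(seed = 42L) {
  panel_config(n_samples_per_lineage = c(18L, 24L, 5L),
               n_haplotypes_x = c(4L, 4L, 1L),
               n_haplotypes_y = c(4L, 4L, 1L),
               recombinant_count = 2L, shared_haplotype_count = 1L,
               error_rate = 0, qual_low_fraction = 0,
               duplicate_pairs = 1L, seed = seed)
}
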