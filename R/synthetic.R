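#' Configuration for a synthetic Glu-D1 panel
#'
#' Describes a structured diploid panel patterned on the wild-wheat
#' diversity panels used for Glu-D1 haplotype analysis: three diverged
#' lineages with lineage-private haplotype pools at two linked genes,
#' near-complete x-y linkage with rare planted recombinants, fully
#' homozygous inbred samples, and sequencing noise entering through DP/DV
#' depths and site QUAL. Defaults give a desk-scale panel whose lineage
#' proportions mirror a large Aegilops tauschii collection (lineage 2
#' largest, lineage 3 rare).
#'
#' @param n_samples_per_lineage Integer vector of samples per lineage (its
#'   length sets the number of lineages).
#' @param n_haplotypes_x,n_haplotypes_y Planted haplotype pool sizes per
#'   lineage for the x and y subunit.
#' @param n_sites_x,n_sites_y Polymorphic site counts inside each CDS.
#' @param n_sites_flank Polymorphic site count across the four 2.5 kb
#'   flank windows.
#' @param recombinant_count Planted x/y clade-discordant samples (drawn
#'   from lineage 1, paired with a foreign-lineage y haplotype).
#' @param shared_haplotype_count Lineage-1 haplotypes additionally planted
#'   in lineage-2 samples (inter-lineage sharing).
#' @param mean_depth Expected per-cell read depth DP (>= 2; simulated
#'   depths are conditioned to be callable, noise enters via DV and QUAL).
#' @param error_rate Per-read miscall probability feeding DV noise.
#' @param qual_low_fraction Fraction of sites emitted with QUAL <= 40.
#' @param duplicate_pairs Samples cloned as re-sequenced duplicates
#'   (>99.8\% genome-wide identity).
#' @param seed Integer seed; a fixed seed makes the output byte-identical.
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(n_samples_per_lineage = c(24L, 30L, 6L),
                         n_haplotypes_x = c(5L, 6L, 2L),
                         n_haplotypes_y = c(5L, 6L, 2L),
                         n_sites_x = 40L, n_sites_y = 30L,
                         n_sites_flank = 30L,
                         recombinant_count = 2L,
                         shared_haplotype_count = 1L,
                         mean_depth = 12,
                         error_rate = 0.002,
                         qual_low_fraction = 0.05,
                         duplicate_pairs = 1L,
                         seed = 1L) {
  nl <- length(n_samples_per_lineage)
  stopifnot(nl >= 1L,
            length(n_haplotypes_x) == nl, length(n_haplotypes_y) == nl,
            all(n_samples_per_lineage >= 0), all(n_haplotypes_x >= 1),
            all(n_haplotypes_y >= 1), n_sites_x >= 1, n_sites_y >= 1,
            n_sites_flank >= 0, recombinant_count >= 0,
            shared_haplotype_count >= 0, mean_depth >= 2,
            error_rate >= 0, error_rate <= 1,
            qual_low_fraction >= 0, qual_low_fraction <= 1,
            duplicate_pairs >= 0)
  if (sum(n_samples_per_lineage) == 0L) stop("panel has zero samples")
  if (recombinant_count > sum(n_samples_per_lineage))
    stop("more recombinants than samples")
  if (recombinant_count > 0L && nl < 2L)
    stop("recombinants need at least two lineages")
  if (shared_haplotype_count > 0L && nl < 2L)
    stop("shared haplotypes need at least two lineages")
  structure(list(n_samples_per_lineage = as.integer(n_samples_per_lineage),
                 n_haplotypes_x = as.integer(n_haplotypes_x),
                 n_haplotypes_y = as.integer(n_haplotypes_y),
                 n_sites_x = as.integer(n_sites_x),
                 n_sites_y = as.integer(n_sites_y),
                 n_sites_flank = as.integer(n_sites_flank),
                 recombinant_count = as.integer(recombinant_count),
                 shared_haplotype_count = as.integer(shared_haplotype_count),
                 mean_depth = mean_depth, error_rate = error_rate,
                 qual_low_fraction = qual_low_fraction,
                 duplicate_pairs = as.integer(duplicate_pairs),
                 seed = as.integer(seed)),
            class = "panel_config")
}

# Lineage collection-site centroids (lat, lon): Transcaucasia, the
# south-east Caspian shore, and the western Iranian range.
lineage_centroids <- function(n) {
  base <- matrix(c(39.5, 45.0,
                   36.5, 53.5,
                   35.5, 46.5), ncol = 2, byrow = TRUE)
  if (n <= 3L) return(base[seq_len(n), , drop = FALSE])
  rbind(base, cbind(30 + 2 * seq_len(n - 3L), 40 + 3 * seq_len(n - 3L)))
}

# Random CDS: ATG start, sense codons, one terminal stop.
random_cds <- function(n_codons) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  paste0("ATG", paste(sample(sense, n_codons - 2L, replace = TRUE),
                      collapse = ""), "TGA")
}

minimal_effect <- function(ref_codon, off, alt_base) {
  code <- Biostrings::GENETIC_CODE
  alt_codon <- ref_codon
  substr(alt_codon, off, off) <- alt_base
  ra <- unname(code[ref_codon]); aa <- unname(code[alt_codon])
  if (ra == aa) "synonymous" else if (aa == "*") "nonsense"
  else if (ra == "*") "stop-loss" else "missense"
}

#' Simulate a structured panel with planted truth
#'
#' Generates a VCF document (DP/DV/QUAL annotations over the Glu-D1
#' locus), sample metadata with lineage-clustered collection coordinates,
#' a genome-wide call matrix for duplicate detection, and the full planted
#' truth. Lineage backbone haplotypes are drawn to differ at >= 30\% of
#' sites per gene; within a lineage, haplotypes differ by single planted
#' mutations. Flank-site alleles are deterministic functions of the coding
#' haplotypes, so flanks are in complete linkage and add no haplotypes.
#' Recombinant samples pair a lineage-1 x haplotype with a foreign
#' lineage's y haplotype.
#'
#' @param config A [panel_config()].
#' @param locus A [locus_definition()] (defaults to the Glu-D1
#'   coordinates).
#' @return An object of class `synthetic_panel`: list with `vcf`
#'   (character lines), `metadata`, `truth` (samples, haplotype pools,
#'   sites, planted pair table, expected combined-haplotype count, gene
#'   models) and `genomewide` (call matrix for duplicate detection).
#' @export
simulate_panel <- function(config, locus = locus_definition()) {
  stopifnot(inherits(config, "panel_config"))
  set.seed(config$seed)
  nl <- length(config$n_samples_per_lineage)
  nx <- config$n_haplotypes_x; ny <- config$n_haplotypes_y
  if (any(nx - 1L > config$n_sites_x) || any(ny - 1L > config$n_sites_y))
    stop("haplotype pool larger than representable by the site count")

  # --- gene models with random reference CDS ---------------------------
  cds_x_len <- 3L * ((locus$gene_x[2] - locus$gene_x[1] + 1L) %/% 3L)
  cds_y_len <- 3L * ((locus$gene_y[2] - locus$gene_y[1] + 1L) %/% 3L)
  gm_x <- gene_model("GluD1x", locus$chrom,
                     data.frame(start = locus$gene_x[1],
                                end = locus$gene_x[1] + cds_x_len - 1L),
                     locus$strand_x, random_cds(cds_x_len %/% 3L))
  gm_y <- gene_model("GluD1y", locus$chrom,
                     data.frame(start = locus$gene_y[1],
                                end = locus$gene_y[1] + cds_y_len - 1L),
                     locus$strand_y, random_cds(cds_y_len %/% 3L))

  # --- site positions and ref/alt alleles ------------------------------
  pos_x <- sort(sample(seq(gm_x$cds$start, gm_x$cds$end), config$n_sites_x))
  pos_y <- sort(sample(seq(gm_y$cds$start, gm_y$cds$end), config$n_sites_y))
  flank_windows <- rbind(
    c(locus$gene_x[1] - locus$flank, locus$gene_x[1] - 1L),
    c(locus$gene_x[2] + 1L, locus$gene_x[2] + locus$flank),
    c(locus$gene_y[1] - locus$flank, locus$gene_y[1] - 1L),
    c(locus$gene_y[2] + 1L, locus$gene_y[2] + locus$flank))
  nf <- config$n_sites_flank
  per_win <- diff(round(seq(0, nf, length.out = 5L)))
  pos_f <- sort(unlist(lapply(seq_len(4L), function(w)
    if (per_win[w] > 0) sample(seq(flank_windows[w, 1], flank_windows[w, 2]),
                               per_win[w]) else integer())))
  bases <- c("A", "C", "G", "T")
  ref_at <- function(pos) {
    out <- character(length(pos))
    cx <- cds_position(gm_x, pos); cy <- cds_position(gm_y, pos)
    out[!is.na(cx)] <- substring(gm_x$cds_seq, cx[!is.na(cx)], cx[!is.na(cx)])
    out[!is.na(cy)] <- substring(gm_y$cds_seq, cy[!is.na(cy)], cy[!is.na(cy)])
    out[out == ""] <- sample(bases, sum(out == ""), replace = TRUE)
    out
  }
  sites <- data.frame(chrom = locus$chrom,
                      pos = c(pos_x, pos_y, pos_f),
                      stringsAsFactors = FALSE)
  sites <- sites[order(sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  sites$ref <- ref_at(sites$pos)
  sites$alt <- vapply(sites$ref, function(r)
    sample(setdiff(bases, r), 1L), character(1))
  sites$region <- region_of(sites$pos, locus)
  sites$is_coding <- !is.na(cds_position(gm_x, sites$pos)) |
    !is.na(cds_position(gm_y, sites$pos))
  idx_x <- which(sites$pos %in% pos_x)
  idx_y <- which(sites$pos %in% pos_y)
  idx_fx <- which(!sites$is_coding & sites$region == "flank-x")
  idx_fy <- which(!sites$is_coding & sites$region == "flank-y")

  sites$planted_effect <- NA_character_
  for (i in which(sites$is_coding)) {
    gm <- if (!is.na(cds_position(gm_x, sites$pos[i]))) gm_x else gm_y
    cp <- cds_position(gm, sites$pos[i])
    ci <- (cp - 1L) %/% 3L + 1L; off <- (cp - 1L) %% 3L + 1L
    sites$planted_effect[i] <- minimal_effect(
      substr(gm$cds_seq, 3L * (ci - 1L) + 1L, 3L * ci), off, sites$alt[i])
  }

  # --- lineage backbones: >= 30% divergence per gene -------------------
  draw_backbones <- function(n_sites) {
    need <- max(1L, ceiling(0.3 * n_sites))
    bb <- matrix(0L, nl, n_sites)
    for (l in seq_len(nl)[-1]) {
      repeat {
        cand <- stats::rbinom(n_sites, 1L, 0.5)
        if (all(vapply(seq_len(l - 1L), function(k)
          sum(cand != bb[k, ]) >= need, logical(1)))) break
      }
      bb[l, ] <- cand
    }
    bb
  }
  bb_x <- draw_backbones(config$n_sites_x)
  bb_y <- draw_backbones(config$n_sites_y)

  # --- haplotype pools: backbone + one private mutation per extra hap --
  make_pool <- function(bb, n_hap, gene) {
    pools <- list()
    for (l in seq_len(nl)) {
      haps <- list(bb[l, ])
      if (n_hap[l] > 1L)
        for (j in seq(2L, n_hap[l])) {
          v <- bb[l, ]
          v[j - 1L] <- 1L - v[j - 1L]
          haps[[j]] <- v
        }
      names(haps) <- sprintf("L%d%s%d", l, gene, seq_len(n_hap[l]))
      pools[[l]] <- haps
    }
    pools
  }
  pool_x <- make_pool(bb_x, nx, "x")
  pool_y <- make_pool(bb_y, ny, "y")

  # --- planted combined pairs per lineage ------------------------------
  pair_table <- do.call(rbind, lapply(seq_len(nl), function(l) {
    n_comb <- max(nx[l], ny[l])
    data.frame(lineage = l,
               x_hap = names(pool_x[[l]])[1L + (seq_len(n_comb) - 1L) %% nx[l]],
               y_hap = names(pool_y[[l]])[1L + (seq_len(n_comb) - 1L) %% ny[l]],
               stringsAsFactors = FALSE)
  }))

  # --- assign samples to pairs -----------------------------------------
  ns <- config$n_samples_per_lineage
  reserve <- integer(nl)
  reserve[1L] <- config$recombinant_count
  if (nl >= 2L) reserve[2L] <- reserve[2L] + config$shared_haplotype_count
  n_comb_l <- vapply(seq_len(nl), function(l)
    sum(pair_table$lineage == l), integer(1))
  if (any(ns - reserve < n_comb_l))
    stop("not enough samples to carry every planted haplotype ",
         "(after reserving recombinant/shared samples)")
  if (config$shared_haplotype_count > 0L &&
      config$shared_haplotype_count > n_comb_l[1L])
    stop("shared_haplotype_count exceeds lineage 1 pool")

  samples <- character(); lineage <- integer()
  x_of <- character(); y_of <- character()
  is_rec <- logical()
  sid <- 0L
  for (l in seq_len(nl)) {
    for (s in seq_len(ns[l])) {
      sid <- sid + 1L
      samples <- c(samples, sprintf("TA%04d", sid))
      lineage <- c(lineage, l)
      free <- ns[l] - reserve[l]
      if (s <= free) {
        row <- which(pair_table$lineage == l)[1L + (s - 1L) %% n_comb_l[l]]
        x_of <- c(x_of, pair_table$x_hap[row])
        y_of <- c(y_of, pair_table$y_hap[row])
        is_rec <- c(is_rec, FALSE)
      } else if (l == 2L && s > ns[l] - config$shared_haplotype_count) {
        k <- s - (ns[l] - config$shared_haplotype_count)  # shared hap index
        row <- which(pair_table$lineage == 1L)[k]
        x_of <- c(x_of, pair_table$x_hap[row])
        y_of <- c(y_of, pair_table$y_hap[row])
        is_rec <- c(is_rec, FALSE)
      } else {                                   # lineage-1 recombinant
        k <- s - (ns[l] - config$recombinant_count)
        foreign <- 2L + (k - 1L) %% (nl - 1L)
        x_of <- c(x_of, names(pool_x[[1L]])[1L + (k - 1L) %% nx[1L]])
        y_of <- c(y_of, names(pool_y[[foreign]])[1L + (k - 1L) %/% (nl - 1L) %% ny[foreign]])
        is_rec <- c(is_rec, TRUE)
      }
    }
  }

  truth_samples <- data.frame(sample = samples, lineage = paste0("L", lineage),
                              x_hap = x_of, y_hap = y_of,
                              is_recombinant = is_rec,
                              duplicate_of = NA_character_,
                              stringsAsFactors = FALSE)

  # --- duplicates: clones of the first samples -------------------------
  if (config$duplicate_pairs > 0L) {
    for (d in seq_len(config$duplicate_pairs)) {
      orig <- truth_samples[d, ]
      clone <- orig
      clone$sample <- sprintf("TA%04d", 9000L + d)
      clone$duplicate_of <- orig$sample
      truth_samples <- rbind(truth_samples, clone)
    }
  }
  n_total <- nrow(truth_samples)

  # --- true allele matrix over all sites -------------------------------
  all_x <- do.call(c, pool_x); all_y <- do.call(c, pool_y)
  n_sites <- nrow(sites)
  truth_alleles <- matrix(0L, n_sites, n_total,
                          dimnames = list(NULL, truth_samples$sample))
  for (s in seq_len(n_total)) {
    hx <- all_x[[truth_samples$x_hap[s]]]
    hy <- all_y[[truth_samples$y_hap[s]]]
    truth_alleles[idx_x, s] <- hx
    truth_alleles[idx_y, s] <- hy
    if (length(idx_fx))
      truth_alleles[idx_fx, s] <- hx[1L + (seq_along(idx_fx) - 1L) %% length(hx)]
    if (length(idx_fy))
      truth_alleles[idx_fy, s] <- hy[1L + (seq_along(idx_fy) - 1L) %% length(hy)]
  }

  # --- depths, noise, QUAL ---------------------------------------------
  dp <- matrix(2L + stats::rpois(n_sites * n_total, config$mean_depth - 2),
               n_sites, n_total)
  p_alt <- ifelse(truth_alleles == 1L, 1 - config$error_rate, config$error_rate)
  dv <- matrix(stats::rbinom(n_sites * n_total, as.vector(dp), as.vector(p_alt)),
               n_sites, n_total)
  qual <- round(stats::runif(n_sites, 55, 999), 1)
  n_low <- round(config$qual_low_fraction * n_sites)
  if (n_low > 0L) {
    low <- sample(n_sites, n_low)
    qual[low] <- round(stats::runif(n_low, 10, 40), 1)
  }

  # --- metadata: lineage centroid + isotropic jitter -------------------
  cent <- lineage_centroids(nl)
  li <- match(truth_samples$lineage, paste0("L", seq_len(nl)))
  metadata <- data.frame(sample = truth_samples$sample,
                         lineage = truth_samples$lineage,
                         lat = round(cent[li, 1] + stats::rnorm(n_total, 0, 0.7), 5),
                         lon = round(cent[li, 2] + stats::rnorm(n_total, 0, 0.7), 5),
                         stringsAsFactors = FALSE)

  # --- genome-wide call matrix for duplicate detection -----------------
  n_gw <- 1500L
  gw_bb <- matrix(stats::rbinom(nl * n_gw, 1L, 0.5), nl, n_gw)
  genomewide <- matrix(0L, n_gw, n_total,
                       dimnames = list(NULL, truth_samples$sample))
  for (s in seq_len(n_total)) {
    if (!is.na(truth_samples$duplicate_of[s])) next
    v <- gw_bb[li[s], ]
    flip <- stats::rbinom(n_gw, 1L, 0.05) == 1L
    v[flip] <- 1L - v[flip]
    genomewide[, s] <- v
  }
  for (s in which(!is.na(truth_samples$duplicate_of))) {
    v <- genomewide[, truth_samples$duplicate_of[s]]
    if (config$error_rate > 0) {
      flip <- stats::rbinom(n_gw, 1L, min(config$error_rate, 5e-4)) == 1L
      v[flip] <- 1L - v[flip]
    }
    genomewide[, s] <- v
  }

  vcf <- render_vcf(sites, qual, dp, dv, truth_samples$sample, locus$chrom)

  n_combined <- nrow(unique(truth_samples[, c("x_hap", "y_hap")]))
  structure(list(vcf = vcf, metadata = metadata,
                 truth = list(samples = truth_samples,
                              haplotypes_x = all_x, haplotypes_y = all_y,
                              sites = sites, pairs = pair_table,
                              alleles = truth_alleles,
                              n_combined = n_combined,
                              n_x = length(unique(truth_samples$x_hap)),
                              n_y = length(unique(truth_samples$y_hap)),
                              gene_models = list(x = gm_x, y = gm_y),
                              locus = locus),
                 genomewide = genomewide,
                 config = config),
            class = "synthetic_panel")
}

render_vcf <- function(sites, qual, dp, dv, samples, chrom) {
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", chrom),
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
              "##FORMAT=<ID=DV,Number=1,Type=Integer,Description=\"Alternate allele read depth\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(sites)), function(i) {
    paste(c(sites$chrom[i], sites$pos[i], ".", sites$ref[i], sites$alt[i],
            sprintf("%.1f", qual[i]), ".", ".", "DP:DV",
            paste0(dp[i, ], ":", dv[i, ])), collapse = "\t")
  }, character(1))
  c(header, body)
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat("synthetic_panel:", nrow(x$truth$samples), "samples,",
      nrow(x$truth$sites), "sites,", x$truth$n_combined,
      "planted combined haplotypes\n")
  invisible(x)
}

#' Write a synthetic panel to disk
#'
#' Writes the VCF, sample metadata TSV, truth tables and the genome-wide
#' call matrix.
#'
#' @param panel A `synthetic_panel`.
#' @param dir Output directory (created if needed).
#' @return Named list of the paths written.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "synthetic_panel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(vcf = file.path(dir, "panel.vcf"),
                metadata = file.path(dir, "metadata.tsv"),
                truth_samples = file.path(dir, "truth_samples.tsv"),
                truth_sites = file.path(dir, "truth_sites.tsv"),
                genomewide = file.path(dir, "genomewide_calls.tsv"))
  writeLines(panel$vcf, paths$vcf)
  utils::write.table(panel$metadata, paths$metadata, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(panel$truth$samples, paths$truth_samples, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(panel$truth$sites, paths$truth_sites, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(panel$genomewide, paths$genomewide, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}

#' Simulate a lineage-specific k-mer bin count table
#'
#' Planted bins receive a count for their lineage that exceeds every other
#' lineage's count by more than the classification margin; background bins
#' receive small counts guaranteed to stay within the margin of each
#' other, so they remain unassigned.
#'
#' @param n_bins Number of bins.
#' @param bin_size Bin size in bp (default 100000).
#' @param planted Named character vector mapping 1-based bin index to a
#'   lineage label (e.g. `c("3" = "L3")`); empty for none.
#' @param background_rate Poisson mean of background counts.
#' @param seed Integer seed.
#' @param chrom,assembly Identifiers written into the table.
#' @param lineages Lineage labels (count columns).
#' @return Data frame as produced by [read_bin_counts()].
#' @export
simulate_kmer_bins <- function(n_bins, bin_size = 100000L, planted = c(),
                               background_rate = 2, seed = 1L,
                               chrom = "chr1D", assembly = "synthetic",
                               lineages = c("L1", "L2", "L3")) {
  if (bin_size <= 0) stop("bin_size must be positive")
  stopifnot(n_bins >= 1)
  if (length(planted)) {
    idx <- as.integer(names(planted))
    if (any(is.na(idx)) || any(idx < 1L | idx > n_bins))
      stop("planted bin index out of range")
    if (!all(planted %in% lineages)) stop("planted lineage not in labels")
  }
  set.seed(seed)
  margin <- margin_for(bin_size)
  cm <- matrix(pmin(stats::rpois(n_bins * length(lineages), background_rate),
                    floor(margin)),
               n_bins, length(lineages))
  if (length(planted)) {
    for (k in seq_along(planted)) {
      b <- as.integer(names(planted)[k])
      l <- match(planted[[k]], lineages)
      cm[b, l] <- 3L * ceiling(margin) + 50L + stats::rpois(1L, background_rate)
    }
  }
  out <- data.frame(assembly = assembly, chrom = chrom,
                    bin_start = (seq_len(n_bins) - 1L) * as.integer(bin_size),
                    stringsAsFactors = FALSE)
  for (j in seq_along(lineages)) out[[paste0("count_", lineages[j])]] <- cm[, j]
  out
}
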