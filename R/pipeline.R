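#' Subset a genotype matrix to a region scope
#'
#' @param m A `genotype_matrix`.
#' @param scope Scope as in [group_haplotypes()].
#' @return A `genotype_matrix` over the scope's sites.
#' @export
subset_genotype_matrix <- function(m, scope) {
  tags <- scope_tags(scope)
  keep <- m$sites$region %in% tags
  if (!any(keep)) stop("no sites in scope")
  new_genotype_matrix(m$calls[keep, , drop = FALSE],
                      m$sites[keep, , drop = FALSE],
                      if (!is.null(m$flags)) m$flags[keep, , drop = FALSE])
}

#' Pipeline run configuration
#'
#' Collects every tunable of the Glu-D1 haplotype pipeline. When `panel`
#' is a [panel_config()] the input data are simulated; otherwise `vcf`,
#' `metadata`, `gene_models` (and optionally `genomewide`, `kmer_bins`)
#' must point to real inputs.
#'
#' @param panel A [panel_config()] for synthetic mode, or NULL.
#' @param vcf,metadata,genomewide,kmer_bins Input file paths (ignored in
#'   synthetic mode).
#' @param gene_models List with elements `x` and `y` ([gene_model()]s).
#' @param locus A [locus_definition()].
#' @param thresholds A [call_thresholds()].
#' @param maf_min,miss_max Site filters (defaults 0.01 and 0.90).
#' @param k_major,k_sub Clade cut sizes (defaults 3 and 15; `k_sub` is
#'   capped at the number of samples).
#' @param linkage Clustering linkage (default `"complete"`).
#' @param minority_max Recombinant minority fraction (default 0.5).
#' @param margin_fraction k-mer bin margin fraction (default 1e-4).
#' @param identity_min Duplicate identity threshold (default 0.998).
#' @param mantel_permutations Mantel permutation count (default 999).
#' @param seed Seed for the Mantel permutations.
#' @return An object of class `run_config`.
#' @export
run_config <- function(panel = panel_config(), vcf = NULL, metadata = NULL,
                       genomewide = NULL, kmer_bins = NULL,
                       gene_models = NULL,
                       locus = locus_definition(),
                       thresholds = call_thresholds(),
                       maf_min = 0.01, miss_max = 0.90,
                       k_major = 3, k_sub = 15,
                       linkage = "complete", minority_max = 0.5,
                       margin_fraction = 1e-4, identity_min = 0.998,
                       mantel_permutations = 999, seed = 1L) {
  if (is.null(panel)) {
    for (p in c(vcf, metadata))
      if (!is.null(p) && !file.exists(p)) stop("input path not found: ", p)
    if (is.null(vcf)) stop("either a panel_config or a VCF path is required")
  }
  structure(list(panel = panel, vcf = vcf, metadata = metadata,
                 genomewide = genomewide, kmer_bins = kmer_bins,
                 gene_models = gene_models, locus = locus,
                 thresholds = thresholds, maf_min = maf_min,
                 miss_max = miss_max, k_major = k_major, k_sub = k_sub,
                 linkage = linkage, minority_max = minority_max,
                 margin_fraction = margin_fraction,
                 identity_min = identity_min,
                 mantel_permutations = mantel_permutations,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full Glu-D1 haplotype pipeline
#'
#' Executes simulate (optional) -> extract -> call -> filter -> haplotype
#' -> clades -> names -> recombinants -> duplicates -> effects -> k-mer
#' colocalization -> geography, logging input/output counts per stage,
#' and returns a report bundle with a JSON-ready summary.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory for the report files.
#' @return A `pipeline_report` list; see the `summary` element for the
#'   headline numbers.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  log <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }

  # --- input ------------------------------------------------------------
  if (!is.null(config$panel)) {
    panel <- simulate_panel(config$panel, config$locus)
    vcf_path <- tempfile(fileext = ".vcf")
    on.exit(unlink(vcf_path), add = TRUE)
    writeLines(panel$vcf, vcf_path)
    metadata <- panel$metadata
    genomewide <- panel$genomewide
    gene_models <- panel$truth$gene_models
    say("simulate: %d samples, %d sites, %d planted combined haplotypes",
        nrow(metadata), nrow(panel$truth$sites), panel$truth$n_combined)
  } else {
    panel <- NULL
    vcf_path <- config$vcf
    metadata <- if (!is.null(config$metadata))
      utils::read.delim(config$metadata, stringsAsFactors = FALSE) else NULL
    genomewide <- if (!is.null(config$genomewide))
      as.matrix(utils::read.delim(config$genomewide, check.names = FALSE))
      else NULL
    gene_models <- config$gene_models
  }

  # --- extract / call / filter -----------------------------------------
  region <- read_vcf_region(vcf_path, config$locus)
  say("extract: %d site records in locus regions", nrow(region$sites))
  gm <- build_genotype_matrix(region, config$thresholds)
  say("call: %.1f%% missing cells", 100 * mean(is.na(gm$calls)))
  gmf <- apply_site_filters(gm, config$maf_min, config$miss_max)
  say("filter: %d of %d sites retained", nrow(gmf$sites), nrow(gm$sites))

  # --- haplotypes -------------------------------------------------------
  px <- group_haplotypes(gmf, "coding-x", prefix = "X")
  py <- group_haplotypes(gmf, "coding-y", prefix = "Y")
  comb <- combine_subunits(px, py)
  p_coding <- group_haplotypes(gmf, "combined")
  has_flanks <- any(gmf$sites$region %in% c("flank-x", "flank-y"))
  n_added <- if (has_flanks)
    flank_consistency(p_coding, group_haplotypes(gmf, "combined+flanks"))
    else 0L
  say("haplotype: %d x, %d y, %d combined; flanks add %d",
      n_haplotypes(px), n_haplotypes(py), n_haplotypes(comb), n_added)

  # --- clades and nomenclature -----------------------------------------
  clade_cut <- function(scope) {
    sub <- subset_genotype_matrix(gmf, scope)
    D <- distance_from_A(additive_relationship(sub))
    h <- hierarchical_cluster(D, config$linkage)
    k_sub <- max(config$k_major, min(config$k_sub, length(h$labels)))
    cut_clades(h, config$k_major, k_sub)
  }
  x_clades <- haplotype_clades(px, clade_cut("coding-x"))
  y_clades <- haplotype_clades(py, clade_cut("coding-y"))
  names_x <- assign_names(px, x_clades, "x")
  names_y <- assign_names(py, y_clades, "y")
  cnames <- combined_names(comb, names_x, names_y)
  say("clades: %d x major-clades, %d y major-clades",
      length(unique(x_clades$major_clade)), length(unique(y_clades$major_clade)))

  recomb <- detect_recombinants(comb, x_clades, y_clades, config$minority_max)
  say("recombinants: %d sample(s) flagged", nrow(recomb))

  # --- duplicates -------------------------------------------------------
  dup_groups <- list()
  if (!is.null(genomewide)) {
    dup_groups <- Filter(function(g) length(g) > 1L,
                         find_duplicates(genomewide, config$identity_min))
    say("duplicates: %d group(s) of re-sequenced accessions", length(dup_groups))
  }

  # --- coding effects ---------------------------------------------------
  effects <- list(); tallies <- list(); cys <- NULL
  if (!is.null(gene_models)) {
    for (g in c("x", "y")) {
      tag <- paste0("coding-", g)
      sites_g <- gmf$sites[gmf$sites$region == tag, , drop = FALSE]
      effects[[g]] <- classify_effects(gene_models[[g]], sites_g)
      tallies[[g]] <- effect_tally(effects[[g]])
    }
    cys <- cysteine_audit(effects)
    say("effects: x %d/%d non-syn/coding, y %d/%d; Cys gains %d, losses %d",
        tallies$x["non_synonymous"], tallies$x["coding"],
        tallies$y["non_synonymous"], tallies$y["coding"],
        sum(cys$cys_gain), sum(cys$cys_loss))
  }

  # --- k-mer colocalization --------------------------------------------
  kmer <- NULL
  bins <- NULL
  if (!is.null(config$panel)) {
    bs <- 100000L
    first_bin <- ((config$locus$gene_x[1] - 1L) %/% bs - 3L) * bs
    n_bins <- 10L
    gene_bins <- ((config$locus$gene_x[1] - 1L) %/% bs):((config$locus$gene_x[2] - 1L) %/% bs)
    planted <- stats::setNames(rep("L3", length(gene_bins)),
                               gene_bins - first_bin %/% bs + 1L)
    bins <- simulate_kmer_bins(n_bins, bs, planted, seed = config$panel$seed,
                               chrom = config$locus$chrom)
    bins$bin_start <- bins$bin_start + first_bin
  } else if (!is.null(config$kmer_bins)) {
    bins <- read_bin_counts(config$kmer_bins)
  }
  if (!is.null(bins)) {
    cls <- classify_bins(bins, margin_for(100000L, config$margin_fraction))
    kmer <- colocalize_gene(cls, config$locus$chrom,
                            config$locus$gene_x[1], config$locus$gene_x[2])
    say("kmer: gene bins assigned %s", kmer$consensus)
  }

  # --- geography --------------------------------------------------------
  mantel <- NULL
  A <- additive_relationship(gmf)
  if (!is.null(metadata)) {
    D_gen <- distance_from_A(A)
    D_geo <- geo_distance_matrix(metadata)
    mantel <- mantel_test(D_gen, D_geo, config$mantel_permutations,
                          seed = config$seed)
    say("geo: Mantel r = %.3f, p = %.4f", mantel$r, mantel$p)
  }

  summary <- list(
    n_sites_raw = nrow(gm$sites),
    n_sites_filtered = nrow(gmf$sites),
    n_x_haplotypes = n_haplotypes(px),
    n_y_haplotypes = n_haplotypes(py),
    n_combined_haplotypes = n_haplotypes(comb),
    n_added_by_flanks = n_added,
    n_ambiguous_samples = sum(comb$assignment == "AMBIGUOUS"),
    recombinant_samples = recomb$sample,
    duplicate_groups = dup_groups,
    effect_tallies = tallies,
    cysteine_audit = cys,
    gene_lineage_call = if (!is.null(kmer)) kmer$consensus else NA,
    mantel = mantel[c("r", "p", "n_perm")])

  report <- structure(list(summary = summary, log = log,
                           genotypes = gmf, partition_x = px,
                           partition_y = py, combined = comb,
                           x_clades = x_clades, y_clades = y_clades,
                           names_x = names_x, names_y = names_y,
                           combined_names = cnames,
                           recombinants = recomb, effects = effects,
                           relationship = A, bins = bins,
                           panel = panel, config = config),
                      class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Glu-D1 pipeline report\n")
  for (line in x$log) cat(" ", line, "\n")
  invisible(x)
}

#' Write the pipeline report bundle to a directory
#'
#' Writes the summary JSON, the per-subunit haplotype tables, the
#' combined-haplotype table, the recombinant report, effect tables and
#' the stage log; all tables round-trip through `read.delim`.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(summary = file.path(dir, "summary.json"),
             log = file.path(dir, "pipeline.log"))
  jsonlite::write_json(report$summary, paths["summary"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  writeLines(report$log, paths["log"])
  for (side in c("x", "y")) {
    p <- report[[paste0("partition_", side)]]
    nm <- report[[paste0("names_", side)]]
    f <- file.path(dir, sprintf("haplotypes_%s.tsv", side))
    tab <- data.frame(
      name = nm$name, subclade = nm$subclade, major_clade = nm$major_clade,
      members = nm$members,
      alleles = vapply(p$haplotypes[nm$haplotype_id], function(v)
        paste(ifelse(v == 0, "R", "A"), collapse = ""), character(1)),
      stringsAsFactors = FALSE)
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[paste0("haplotypes_", side)] <- f
  }
  f <- file.path(dir, "haplotypes_combined.tsv")
  utils::write.table(report$combined_names, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["combined"] <- f
  f <- file.path(dir, "recombinants.tsv")
  utils::write.table(report$recombinants, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["recombinants"] <- f
  if (length(report$effects)) {
    for (g in names(report$effects)) {
      f <- file.path(dir, sprintf("effects_%s.tsv", g))
      utils::write.table(report$effects[[g]], f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths[paste0("effects_", g)] <- f
    }
  }
  invisible(paths)
}
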