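#' Group samples into exact-match molecular haplotypes
#'
#' Samples sharing the same variant calls over the scope's sites share a
#' molecular haplotype. Samples with complete calls over the scope are
#' grouped by exact vector equality; a sample with MISSING calls joins a
#' haplotype only when its called positions are consistent with exactly one
#' existing haplotype, and is otherwise AMBIGUOUS (missing data never
#' invents haplotypes). Haplotype ids are canonical: ordered by descending
#' member count, ties broken by the lexicographically smallest member
#' sample id, so the partition is invariant to sample and site order.
#'
#' @param m A `genotype_matrix` (typically post-[apply_site_filters()]).
#' @param scope Region scope: `"coding-x"`, `"coding-y"`, `"combined"`
#'   (both coding regions) or `"combined+flanks"` (all locus sites), or a
#'   character vector of region tags.
#' @param prefix Haplotype id prefix; default derived from scope.
#' @return An object of class `haplotype_partition`: list with
#'   `assignment` (named character, sample -> haplotype id or
#'   `"AMBIGUOUS"`), `haplotypes` (named list of allele vectors), `counts`,
#'   `scope` and `sites` (data.frame of the sites used).
#' @export
group_haplotypes <- function(m, scope = "combined", prefix = NULL) {
  stopifnot(inherits(m, "genotype_matrix"))
  tags <- scope_tags(scope)
  idx <- which(m$sites$region %in% tags)
  if (length(idx) == 0L) stop("empty scope: no sites with region in {",
                              paste(tags, collapse = ", "), "}")
  idx <- idx[order(m$sites$pos[idx])]
  calls <- m$calls[idx, , drop = FALSE]
  samples <- m$samples
  if (is.null(prefix))
    prefix <- switch(paste(sort(tags), collapse = ","),
                     "coding-x" = "X", "coding-y" = "Y", "H")

  key <- apply(calls, 2, function(v) paste(ifelse(is.na(v), ".", v), collapse = ""))
  complete <- colSums(is.na(calls)) == 0L
  hap_keys <- unique(key[complete])
  hap_vecs <- lapply(hap_keys, function(k) calls[, match(k, key)])

  assignment <- rep(NA_character_, length(samples))
  names(assignment) <- samples
  hap_index <- match(key, hap_keys)           # exact complete matches
  assignment[complete] <- as.character(hap_index[complete])
  for (s in which(!complete)) {
    v <- calls[, s]
    called <- !is.na(v)
    if (!any(called)) { assignment[s] <- "AMBIGUOUS"; next }
    compat <- which(vapply(hap_vecs, function(h)
      all(h[called] == v[called]), logical(1)))
    assignment[s] <- if (length(compat) == 1L) as.character(compat) else "AMBIGUOUS"
  }

  canonicalize_partition(assignment, hap_vecs, prefix, tags,
                         m$sites[idx, , drop = FALSE])
}

scope_tags <- function(scope) {
  all_tags <- c("coding-x", "coding-y", "flank-x", "flank-y")
  if (length(scope) == 1L && scope %in% c("combined", "combined+flanks"))
    return(if (scope == "combined") c("coding-x", "coding-y") else all_tags)
  bad <- setdiff(scope, all_tags)
  if (length(bad)) stop("unknown region tag(s): ", paste(bad, collapse = ", "))
  scope
}

# Relabel haplotypes into canonical order: descending member count, ties by
# lexicographically smallest member sample id.
canonicalize_partition <- function(assignment, hap_vecs, prefix, tags, sites) {
  old_ids <- as.character(seq_along(hap_vecs))
  members <- lapply(old_ids, function(id) sort(names(assignment)[assignment == id]))
  counts <- lengths(members)
  keep <- counts > 0L
  old_ids <- old_ids[keep]; hap_vecs <- hap_vecs[keep]
  members <- members[keep]; counts <- counts[keep]
  first <- vapply(members, function(m) m[1], character(1))
  ord <- order(-counts, first)
  new_ids <- sprintf("%s%02d", prefix, seq_along(ord))
  relabel <- stats::setNames(new_ids, old_ids[ord])
  assignment[assignment %in% old_ids] <- relabel[assignment[assignment %in% old_ids]]
  haplotypes <- stats::setNames(hap_vecs[ord], new_ids)
  structure(list(assignment = assignment,
                 haplotypes = haplotypes,
                 counts = stats::setNames(counts[ord], new_ids),
                 scope = tags, sites = sites),
            class = "haplotype_partition")
}

#' @export
print.haplotype_partition <- function(x, ...) {
  cat("haplotype_partition over {", paste(x$scope, collapse = ", "), "}: ",
      length(x$haplotypes), " haplotypes, ",
      sum(x$assignment == "AMBIGUOUS"), " ambiguous of ",
      length(x$assignment), " samples\n", sep = "")
  invisible(x)
}

#' Number of non-ambiguous haplotypes in a partition
#' @param p A `haplotype_partition`.
#' @return Integer count.
#' @export
n_haplotypes <- function(p) {
  stopifnot(inherits(p, "haplotype_partition"))
  length(p$haplotypes)
}

#' Combine x- and y-subunit partitions into locus-level haplotypes
#'
#' A combined haplotype is the ordered pair of a sample's x and y subunit
#' haplotypes; a sample AMBIGUOUS in either subunit is AMBIGUOUS combined.
#'
#' @param px,py `haplotype_partition`s for the x and y subunits over the
#'   same sample universe.
#' @return A `haplotype_partition` whose `pairs` element maps each combined
#'   id to its `(x, y)` subunit ids.
#' @export
combine_subunits <- function(px, py) {
  stopifnot(inherits(px, "haplotype_partition"), inherits(py, "haplotype_partition"))
  if (!setequal(names(px$assignment), names(py$assignment)))
    stop("sample universes differ between subunit partitions")
  samples <- names(px$assignment)
  ax <- px$assignment; ay <- py$assignment[samples]
  ok <- ax != "AMBIGUOUS" & ay != "AMBIGUOUS"
  pair_key <- ifelse(ok, paste(ax, ay, sep = "|"), "AMBIGUOUS")
  keys <- unique(pair_key[ok])
  assignment <- stats::setNames(rep("AMBIGUOUS", length(samples)), samples)
  assignment[ok] <- as.character(match(pair_key[ok], keys))
  vecs <- lapply(keys, function(k) strsplit(k, "|", fixed = TRUE)[[1]])
  p <- canonicalize_partition(assignment, vecs, "C",
                              union(px$scope, py$scope),
                              rbind(px$sites, py$sites))
  p$pairs <- do.call(rbind, lapply(names(p$haplotypes), function(id)
    data.frame(combined = id, x = p$haplotypes[[id]][1],
               y = p$haplotypes[[id]][2], stringsAsFactors = FALSE)))
  p$haplotypes <- stats::setNames(
    lapply(p$haplotypes, function(v) stats::setNames(v, c("x", "y"))),
    names(p$haplotypes))
  p
}

#' Haplotypes added by widening the scope (e.g. adding flanks)
#'
#' Counts how many haplotypes a wider-scope partition has beyond a
#' narrower one over the same samples. Because adding sites can only split
#' groups, the result is nonnegative when missingness does not interfere.
#'
#' @param p_coding Partition over the narrower scope.
#' @param p_full Partition over the wider scope (superset of sites).
#' @return Integer difference in haplotype counts.
#' @export
flank_consistency <- function(p_coding, p_full) {
  stopifnot(inherits(p_coding, "haplotype_partition"),
            inherits(p_full, "haplotype_partition"))
  if (!setequal(names(p_coding$assignment), names(p_full$assignment)))
    stop("partitions cover different samples")
  if (!all(p_coding$scope %in% p_full$scope))
    stop("p_full scope must contain p_coding scope")
  n_haplotypes(p_full) - n_haplotypes(p_coding)
}
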