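#' Additive (genomic) relationship matrix from biallelic calls
#'
#' Computes the VanRaden method-1 additive relationship matrix from hard
#' calls coded -1 (REF) / +1 (ALT), the coding appropriate for a fully
#' inbred diploid panel. Missing calls are imputed to the marker mean;
#' markers are centered by `2p - 1`, where `p` is the ALT allele frequency
#' among called samples, and the cross-product is scaled by
#' `2 * sum(p * (1 - p))`.
#'
#' @param m A filtered `genotype_matrix`, or an integer matrix of 0/1/NA
#'   calls with sites in rows and named sample columns.
#' @return A `relationship_matrix`: the sample-by-sample matrix with
#'   attributes `n_markers` and `denominator`.
#' @examples
#' calls <- matrix(c(0L, 1L), 1, dimnames = list(NULL, c("s1", "s2")))
#' additive_relationship(calls)  # [[2, -2], [-2, 2]]
#' @export
additive_relationship <- function(m) {
  calls <- if (inherits(m, "genotype_matrix")) m$calls else m
  stopifnot(is.matrix(calls))
  if (ncol(calls) < 2L) stop("need at least two samples")
  p <- rowMeans(calls, na.rm = TRUE)
  if (any(is.na(p) | p <= 0 | p >= 1))
    stop("monomorphic or uncalled marker present; filter sites first")
  code <- 2 * calls - 1                       # -1 / +1
  mu <- 2 * p - 1                             # marker mean under this coding
  for (i in which(rowSums(is.na(code)) > 0L))
    code[i, is.na(code[i, ])] <- mu[i]
  w <- sweep(code, 1, mu, "-")                # centered, sites x samples
  denom <- 2 * sum(p * (1 - p))
  A <- crossprod(w) / denom
  structure(A, n_markers = nrow(calls), denominator = denom,
            class = c("relationship_matrix", "matrix", "array"))
}

#' Euclidean distances between relationship-matrix rows
#'
#' Genetic distance between two samples is the Euclidean norm of the
#' difference of their rows of the additive relationship matrix.
#'
#' @param A A `relationship_matrix` (or any symmetric numeric matrix).
#' @return A symmetric distance matrix with zero diagonal.
#' @export
distance_from_A <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (max(abs(A - t(A))) > 1e-8) stop("relationship matrix must be symmetric")
  as.matrix(stats::dist(unclass(A), method = "euclidean"))
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Thin wrapper around [stats::hclust()] restricted to the linkages whose
#' merge heights are guaranteed nondecreasing here.
#'
#' @param D Symmetric distance matrix (or `dist`).
#' @param linkage `"complete"` (default), `"average"` or `"single"`.
#' @return An `hclust` tree.
#' @export
hierarchical_cluster <- function(D, linkage = c("complete", "average", "single")) {
  linkage <- match.arg(linkage)
  d <- stats::as.dist(D)
  if (attr(d, "Size") < 2L) stop("need at least two units to cluster")
  stats::hclust(d, method = linkage)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou–Nei neighbor joining (via [ape::nj()]); on additive
#' input distances the output tree's path lengths reproduce the input
#' exactly. Negative branch lengths, which NJ can produce on non-additive
#' input, are clamped to zero with a warning.
#'
#' @param D Symmetric distance matrix with at least 3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  d <- stats::as.dist(D)
  if (attr(d, "Size") < 3L) stop("neighbor joining needs at least 3 taxa")
  tree <- ape::nj(d)
  if (any(tree$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Cut a dendrogram into nested major clades and subclades
#'
#' Cuts one `hclust` tree at `k_major` and `k_sub` groups (nested by
#' construction). Major clades are labelled I, II, III, ... by descending
#' member count (ties by the lexicographically smallest member); subclades
#' are numbered 1..`k_sub` following the major-clade order, and by
#' descending size within each major clade.
#'
#' @param dendrogram An `hclust` object.
#' @param k_major Number of major clades.
#' @param k_sub Number of subclades (`k_major <= k_sub <= n`).
#' @return A `clade_partition` over the clustered units.
#' @export
cut_clades <- function(dendrogram, k_major = 3, k_sub = 15) {
  stopifnot(inherits(dendrogram, "hclust"))
  n <- length(dendrogram$labels)
  if (k_sub < k_major) stop("k_sub must be >= k_major (nested partition)")
  if (k_sub > n) stop("k_sub exceeds the number of units")
  maj <- stats::cutree(dendrogram, k = k_major)
  sub <- stats::cutree(dendrogram, k = k_sub)

  maj_order <- order(-tabulate(maj, k_major),
                     vapply(seq_len(k_major),
                            function(g) min(names(maj)[maj == g]), character(1)))
  maj_label <- stats::setNames(as.character(utils::as.roman(seq_len(k_major))),
                               maj_order)
  major_clade <- maj_label[as.character(maj)]

  sub_number <- integer(length(sub)); names(sub_number) <- names(sub)
  next_num <- 1L
  for (g in maj_order) {
    subs_here <- unique(sub[maj == g])
    sizes <- vapply(subs_here, function(s) sum(sub == s), integer(1))
    firsts <- vapply(subs_here, function(s) min(names(sub)[sub == s]), character(1))
    for (s in subs_here[order(-sizes, firsts)]) {
      sub_number[sub == s] <- next_num
      next_num <- next_num + 1L
    }
  }
  clade_partition(data.frame(unit = names(sub), major_clade = major_clade,
                             subclade = sub_number, stringsAsFactors = FALSE),
                  source = "dendrogram-cut")
}

#' Read and write newick trees
#'
#' `read_newick()` accepts a newick string or a file path and validates
#' parenthesis balance and tip-label uniqueness; `write_newick()` renders a
#' `phylo` tree back to a newick string. Writing then reading preserves
#' topology, labels and branch lengths.
#'
#' @param text Newick string or path to a newick file.
#' @return For `read_newick`, a `phylo` tree; for `write_newick`, a string.
#' @export
read_newick <- function(text) {
  if (length(text) == 1L && !grepl("(", text, fixed = TRUE) && file.exists(text))
    text <- paste(readLines(text), collapse = "")
  chars <- strsplit(text, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0) || depth[length(depth)] != 0)
    stop("unbalanced parentheses in newick")
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("failed to parse newick")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  tree
}

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}
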