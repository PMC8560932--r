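#' Build a clade partition from a table
#'
#' A clade partition maps units (haplotype ids or sample ids) to a major
#' clade (Roman numeral label) and a subclade number nested within it.
#' Partitions can come from a dendrogram cut ([cut_clades()]), an imported
#' tree, or a manual table; this constructor validates the nesting.
#'
#' @param df Data frame with columns `unit`, `major_clade`, `subclade`.
#' @param source Provenance tag.
#' @return An object of class `clade_partition` (a data.frame).
#' @export
clade_partition <- function(df, source = "manual-table") {
  stopifnot(all(c("unit", "major_clade", "subclade") %in% names(df)))
  if (anyDuplicated(df$unit)) stop("duplicate units in clade table")
  nest <- unique(df[, c("major_clade", "subclade")])
  if (anyDuplicated(nest$subclade))
    stop("subclade assigned to more than one major clade")
  out <- df[, c("unit", "major_clade", "subclade")]
  out$unit <- as.character(out$unit)
  out$major_clade <- as.character(out$major_clade)
  out$subclade <- as.integer(out$subclade)
  attr(out, "source") <- source
  class(out) <- c("clade_partition", "data.frame")
  out
}

#' Lift a sample-level clade partition to haplotypes by majority vote
#'
#' Each haplotype inherits the subclade carried by the majority of its
#' member samples (ties broken by the smallest subclade number); its major
#' clade is the one that subclade nests in.
#'
#' @param p A `haplotype_partition`.
#' @param sample_clades A `clade_partition` over sample ids.
#' @return A `clade_partition` over haplotype ids.
#' @export
haplotype_clades <- function(p, sample_clades) {
  stopifnot(inherits(p, "haplotype_partition"),
            inherits(sample_clades, "clade_partition"))
  sub_of <- stats::setNames(sample_clades$subclade, sample_clades$unit)
  major_of_sub <- unique(sample_clades[, c("subclade", "major_clade")])
  rows <- lapply(names(p$haplotypes), function(id) {
    members <- names(p$assignment)[p$assignment == id]
    subs <- sub_of[members]
    subs <- subs[!is.na(subs)]
    if (length(subs) == 0L)
      stop("no clade information for members of haplotype ", id)
    tab <- table(subs)
    win <- as.integer(min(names(tab)[tab == max(tab)]))
    data.frame(unit = id,
               major_clade = major_of_sub$major_clade[match(win, major_of_sub$subclade)],
               subclade = win, stringsAsFactors = FALSE)
  })
  clade_partition(do.call(rbind, rows), source = attr(sample_clades, "source"))
}

#' Assign subclade-letter haplotype names
#'
#' Haplotype names take the form `D<subunit><subclade><letter>` (e.g.
#' `Dx1a`): the letter enumerates gene-level haplotypes within their
#' subclade in canonical order (descending carrier count, ties by the
#' lexicographically smallest member sample id). Letters carry no meaning
#' across subclades.
#'
#' @param p A `haplotype_partition` for one subunit.
#' @param clades A `clade_partition` over the haplotype ids of `p`.
#' @param subunit `"x"` or `"y"`.
#' @return A `nomenclature_table` data.frame with columns `haplotype_id`,
#'   `subclade`, `major_clade`, `name`, `members`.
#' @export
assign_names <- function(p, clades, subunit = c("x", "y")) {
  subunit <- match.arg(subunit)
  stopifnot(inherits(p, "haplotype_partition"), inherits(clades, "clade_partition"))
  ids <- names(p$haplotypes)
  missing <- setdiff(ids, clades$unit)
  if (length(missing))
    stop("haplotype(s) lacking clade assignment: ", paste(missing, collapse = ", "))
  sub <- clades$subclade[match(ids, clades$unit)]
  maj <- clades$major_clade[match(ids, clades$unit)]
  out <- data.frame(haplotype_id = ids, subclade = sub, major_clade = maj,
                    name = NA_character_, members = as.integer(p$counts[ids]),
                    stringsAsFactors = FALSE)
  # ids are already in canonical order (descending count, tie by member id),
  # so within each subclade the letter follows id order
  for (s in unique(sub)) {
    i <- which(sub == s)
    out$name[i] <- paste0("D", subunit, s, hap_letters(length(i)))
  }
  class(out) <- c("nomenclature_table", "data.frame")
  out
}

hap_letters <- function(n) {
  if (n <= 26L) return(letters[seq_len(n)])
  c(letters, as.vector(outer(letters, letters, function(a, b) paste0(a, b))))[seq_len(n)]
}

#' Name combined haplotypes from their subunit names
#'
#' Combined names take the form `x<subclade><letter>+y<subclade><letter>`,
#' dropping the leading `D` of each subunit name.
#'
#' @param combined A combined `haplotype_partition` (from
#'   [combine_subunits()]).
#' @param names_x,names_y Nomenclature tables for the subunits.
#' @return Data frame with `combined_id`, `x`, `y`, `name`, `members`.
#' @export
combined_names <- function(combined, names_x, names_y) {
  stopifnot(!is.null(combined$pairs))
  nx <- stats::setNames(names_x$name, names_x$haplotype_id)
  ny <- stats::setNames(names_y$name, names_y$haplotype_id)
  pr <- combined$pairs
  data.frame(combined_id = pr$combined, x = nx[pr$x], y = ny[pr$y],
             name = paste0(sub("^D", "", nx[pr$x]), "+", sub("^D", "", ny[pr$y])),
             members = as.integer(combined$counts[pr$combined]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Detect x/y recombinant haplotypes
#'
#' The two subunit genes are so tightly linked that x and y haplotypes are
#' almost exclusively associated. For each x haplotype the majority y
#' major-clade among its carriers defines the expected linkage; a combined
#' haplotype is flagged as recombinant when its x and y major-clades
#' disagree AND the pairing is carried by fewer than `minority_max` of
#' that x haplotype's carriers. The symmetric check is run from the y side
#' and the union reported. When all pairings of a haplotype are tied the
#' tie is reported and nothing flagged for it.
#'
#' @param combined Combined `haplotype_partition` (with `pairs`).
#' @param x_clades,y_clades `clade_partition`s over x and y haplotype ids.
#' @param minority_max Carrier fraction below which a discordant pairing is
#'   in the minority (default 0.5).
#' @return A `recombinant_calls` data.frame: one row per flagged sample
#'   with its subunit haplotypes, their clades, the expected y major-clade
#'   under majority linkage, and an evidence note. Attribute `ties` lists
#'   haplotypes whose linkage vote was tied.
#' @export
detect_recombinants <- function(combined, x_clades, y_clades,
                                minority_max = 0.5) {
  stopifnot(!is.null(combined$pairs),
            inherits(x_clades, "clade_partition"),
            inherits(y_clades, "clade_partition"))
  pr <- combined$pairs
  pr$members <- as.integer(combined$counts[pr$combined])
  xmaj <- stats::setNames(x_clades$major_clade, x_clades$unit)
  ymaj <- stats::setNames(y_clades$major_clade, y_clades$unit)
  xsub <- stats::setNames(x_clades$subclade, x_clades$unit)
  ysub <- stats::setNames(y_clades$subclade, y_clades$unit)

  flag_side <- function(side) {
    anchor <- if (side == "x") pr$x else pr$y
    partner_maj <- if (side == "x") ymaj[pr$y] else xmaj[pr$x]
    own_maj <- if (side == "x") xmaj[pr$x] else ymaj[pr$y]
    flagged <- logical(nrow(pr)); expected <- rep(NA_character_, nrow(pr))
    ties <- character()
    for (a in unique(anchor)) {
      rows <- which(anchor == a)
      carriers <- sum(pr$members[rows])
      votes <- tapply(pr$members[rows], partner_maj[rows], sum)
      top <- names(votes)[votes == max(votes)]
      if (length(top) > 1L) { ties <- c(ties, a); next }
      expected[rows] <- top
      disc <- rows[own_maj[rows] != partner_maj[rows] &
                     pr$members[rows] / carriers < minority_max]
      flagged[disc] <- TRUE
    }
    list(flagged = flagged, expected = expected, ties = ties)
  }
  fx <- flag_side("x"); fy <- flag_side("y")
  hit <- fx$flagged | fy$flagged
  rows <- which(hit)
  calls <- do.call(rbind, lapply(rows, function(i) {
    samples <- names(combined$assignment)[combined$assignment == pr$combined[i]]
    data.frame(sample = samples,
               combined_id = pr$combined[i],
               x_haplotype = pr$x[i], x_subclade = xsub[pr$x[i]],
               x_major = xmaj[pr$x[i]],
               y_haplotype = pr$y[i], y_subclade = ysub[pr$y[i]],
               y_major = ymaj[pr$y[i]],
               expected_y_major = fx$expected[i],
               evidence = sprintf(
                 "minority pairing (%d of %d carriers of %s); x clade %s vs y clade %s",
                 pr$members[i], sum(pr$members[pr$x == pr$x[i]]), pr$x[i],
                 xmaj[pr$x[i]], ymaj[pr$y[i]]),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  if (is.null(calls))
    calls <- data.frame(sample = character(), combined_id = character(),
                        x_haplotype = character(), x_subclade = integer(),
                        x_major = character(), y_haplotype = character(),
                        y_subclade = integer(), y_major = character(),
                        expected_y_major = character(), evidence = character(),
                        stringsAsFactors = FALSE)
  attr(calls, "ties") <- union(fx$ties, fy$ties)
  class(calls) <- c("recombinant_calls", "data.frame")
  calls
}
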