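#' Define a gene model with its reference CDS
#'
#' A gene model ties one or more CDS intervals (1-based inclusive, given in
#' genomic order) and a strand to the reference CDS sequence, which is
#' always stored in coding orientation (5'->3' of the mRNA).
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param cds Matrix or data.frame with columns `start`, `end` (one row per
#'   CDS interval, ascending genomic order).
#' @param strand `"+"` or `"-"`.
#' @param cds_seq Reference CDS sequence (character), length divisible by 3
#'   and equal to the summed interval widths.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, cds, strand, cds_seq) {
  cds <- as.data.frame(cds)
  stopifnot(all(c("start", "end") %in% names(cds)),
            all(cds$end >= cds$start))
  strand <- match.arg(strand, c("+", "-"))
  cds_seq <- toupper(cds_seq)
  width <- sum(cds$end - cds$start + 1L)
  if (nchar(cds_seq) != width)
    stop("CDS sequence length (", nchar(cds_seq),
         ") does not match interval width (", width, ")")
  if (width %% 3L != 0L) stop("CDS length not divisible by 3")
  structure(list(gene_id = gene_id, chrom = chrom,
                 cds = cds[order(cds$start), , drop = FALSE],
                 strand = strand, cds_seq = cds_seq),
            class = "gene_model")
}

# 1-based CDS coordinate of a genomic position (NA outside the CDS).
# For minus-strand genes the CDS runs from the highest genomic coordinate
# backwards.
cds_position <- function(gm, pos) {
  widths <- gm$cds$end - gm$cds$start + 1L
  offsets <- cumsum(c(0L, widths[-length(widths)]))
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(gm$cds))) {
    inside <- pos >= gm$cds$start[i] & pos <= gm$cds$end[i]
    out[inside] <- offsets[i] + (pos[inside] - gm$cds$start[i]) + 1L
  }
  if (gm$strand == "-") out <- sum(widths) - out + 1L
  out
}

comp_base <- function(b) chartr("ACGTacgt", "TGCAtgca", b)

#' Apply a haplotype's variants to the reference CDS
#'
#' Substitutes the ALT base (strand-adjusted) at every CDS site where the
#' haplotype carries the alternate allele; sites outside the CDS are
#' ignored. The ref allele of every CDS site must match the reference
#' sequence at its mapped position, else an error names the offending
#' genomic position.
#'
#' @param gm A [gene_model()].
#' @param alleles Vector of 0/1/NA calls, one per row of `sites`; NA sites
#'   are left at the reference base.
#' @param sites Data frame with columns `pos`, `ref`, `alt` (SNVs only).
#' @return The haplotype CDS as a character string (same length as the
#'   reference CDS).
#' @export
build_haplotype_cds <- function(gm, alleles, sites) {
  stopifnot(inherits(gm, "gene_model"), length(alleles) == nrow(sites))
  if (any(nchar(sites$ref) != 1L | nchar(sites$alt) != 1L))
    stop("only single-nucleotide variants are supported")
  seq <- strsplit(gm$cds_seq, "")[[1]]
  cp <- cds_position(gm, sites$pos)
  for (i in which(!is.na(cp))) {
    ref_cds <- if (gm$strand == "-") comp_base(sites$ref[i]) else toupper(sites$ref[i])
    alt_cds <- if (gm$strand == "-") comp_base(sites$alt[i]) else toupper(sites$alt[i])
    if (seq[cp[i]] != ref_cds)
      stop("ref allele mismatch at position ", sites$pos[i],
           ": reference CDS has ", seq[cp[i]], ", VCF ref maps to ", ref_cds)
    if (!is.na(alleles[i]) && alleles[i] == 1L) seq[cp[i]] <- alt_cds
  }
  paste(seq, collapse = "")
}

#' Translate a CDS to protein
#'
#' @param seq CDS nucleotide sequence (character), length divisible by 3.
#' @return Amino-acid string (stop codons rendered as `*`).
#' @export
translate_cds <- function(seq) {
  as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                     if.fuzzy.codon = "X"))
}

#' Classify coding effects of SNVs against the reference CDS
#'
#' Each SNV inside the CDS is classified per site against the reference
#' codon under the standard nuclear genetic code: synonymous, missense,
#' nonsense (gain of stop), stop-loss, or start-loss (initial codon no
#' longer ATG). Sites outside the CDS are classified `non-coding` and are
#' excluded from syn/non-syn tallies. `cysteine_delta` records the change
#' in cysteine count caused by the substitution (+1 gain, -1 loss).
#'
#' @param gm A [gene_model()].
#' @param sites Data frame with columns `pos`, `ref`, `alt` (SNVs only).
#' @return A `coding_effects` data.frame with one row per site: `pos`,
#'   `cds_pos`, `codon_index`, `ref_codon`, `alt_codon`, `ref_aa`,
#'   `alt_aa`, `class`, `cysteine_delta`.
#' @export
classify_effects <- function(gm, sites) {
  stopifnot(inherits(gm, "gene_model"))
  if (any(nchar(sites$ref) != 1L | nchar(sites$alt) != 1L))
    stop("multi-nucleotide variants rejected; SNVs only")
  code <- Biostrings::GENETIC_CODE
  cp <- cds_position(gm, sites$pos)
  out <- data.frame(pos = sites$pos, cds_pos = cp,
                    codon_index = NA_integer_, ref_codon = NA_character_,
                    alt_codon = NA_character_, ref_aa = NA_character_,
                    alt_aa = NA_character_, class = "non-coding",
                    cysteine_delta = 0L, stringsAsFactors = FALSE)
  for (i in which(!is.na(cp))) {
    ci <- (cp[i] - 1L) %/% 3L + 1L
    off <- (cp[i] - 1L) %% 3L + 1L
    ref_codon <- substr(gm$cds_seq, 3L * (ci - 1L) + 1L, 3L * ci)
    alt_base <- if (gm$strand == "-") comp_base(sites$alt[i]) else toupper(sites$alt[i])
    ref_base <- if (gm$strand == "-") comp_base(sites$ref[i]) else toupper(sites$ref[i])
    if (substr(ref_codon, off, off) != ref_base)
      stop("ref allele mismatch at position ", sites$pos[i])
    alt_codon <- ref_codon
    substr(alt_codon, off, off) <- alt_base
    ref_aa <- unname(code[ref_codon]); alt_aa <- unname(code[alt_codon])
    cls <- if (ref_aa == alt_aa) "synonymous"
      else if (alt_aa == "*") "nonsense"
      else if (ref_aa == "*") "stop-loss"
      else if (ci == 1L && ref_codon == "ATG") "start-loss"
      else "missense"
    out$codon_index[i] <- ci
    out$ref_codon[i] <- ref_codon; out$alt_codon[i] <- alt_codon
    out$ref_aa[i] <- ref_aa; out$alt_aa[i] <- alt_aa
    out$class[i] <- cls
    out$cysteine_delta[i] <- (alt_aa == "C") - (ref_aa == "C")
  }
  class(out) <- c("coding_effects", "data.frame")
  out
}

#' Audit cysteine gains and losses among coding effects
#'
#' Cysteine residues form the disulfide bonds that build the gluten
#' network, so substitutions creating or removing a cysteine are the most
#' functionally suspect variants. Counts Cys-gaining and Cys-losing
#' substitutions, optionally restricted to codon ranges (e.g. the
#' non-repetitive N- and C-terminal domains).
#'
#' @param effects A `coding_effects` table (or a list of them, one per
#'   gene, in which case names are used as gene ids).
#' @param domains Optional data.frame with `start`, `end` codon indices to
#'   restrict the audit; default is the whole CDS.
#' @return Data frame with `gene`, `cys_gain`, `cys_loss`.
#' @export
cysteine_audit <- function(effects, domains = NULL) {
  if (inherits(effects, "coding_effects")) effects <- list(gene = effects)
  do.call(rbind, lapply(names(effects), function(g) {
    e <- effects[[g]]
    if (!is.null(domains)) {
      keep <- rep(FALSE, nrow(e))
      for (k in seq_len(nrow(domains)))
        keep <- keep | (!is.na(e$codon_index) &
                          e$codon_index >= domains$start[k] &
                          e$codon_index <= domains$end[k])
      e <- e[keep, , drop = FALSE]
    }
    data.frame(gene = g,
               cys_gain = sum(e$cysteine_delta > 0),
               cys_loss = sum(e$cysteine_delta < 0),
               stringsAsFactors = FALSE)
  }))
}

#' Tally synonymous and non-synonymous coding variants
#'
#' @param effects A `coding_effects` table.
#' @return Named integer vector: `coding`, `synonymous`, `non_synonymous`.
#' @export
effect_tally <- function(effects) {
  cls <- effects$class[effects$class != "non-coding"]
  c(coding = length(cls),
    synonymous = sum(cls == "synonymous"),
    non_synonymous = sum(cls != "synonymous"))
}
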