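---
title: "Molecular haplotype analysis of the Glu-D1 locus: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular haplotype analysis of the Glu-D1 locus: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gluhap)
```

## The problem

The high-molecular-weight glutenin locus *Glu-D1* on wheat chromosome 1D
carries two tightly linked genes, the x and y subunits, separated by some
55 kb. The disulfide network built from cysteine residues of these
subunits is the backbone of the gluten matrix, so allelic variation at
this locus drives bread-making quality. Classical allele typing by
SDS-PAGE mobility is coarse: very different molecular haplotypes can
co-migrate. This package types the locus from short-read variant calls
instead. Given a VCF restricted to the locus, it calls hard genotypes from
depth ratios, groups accessions into exact-match molecular haplotypes per
subunit and for the combined locus, names haplotypes by their position in
a clade hierarchy, detects the rare historical recombinants between the
two genes, audits coding variants for cysteine changes, tests whether the
locus falls in genome bins dominated by one lineage's diagnostic k-mers,
and quantifies isolation by distance between molecular and geographic
distances.

The target panels are wild wheat relatives (*Aegilops tauschii*), selfing
diploids structured into three diverged lineages, with lineage 2 the main
D-genome donor of bread wheat and lineage 3 a minor, recently
characterized donor.

## Genotype calling from depth ratios

Short-read callers emit, per site and sample, the total read depth DP and
the alternate-allele depth DV. Because the accessions are inbred and
effectively homozygous, a hard call can be made from the ratio DV/DP
alone:

* a site is callable only when its QUAL strictly exceeds `qual_min`
  (default 40) and DP is at least `depth_min` (default 2);
* DV/DP at most `ratio_homref_max` (default 0.2) is homozygous REF;
* DV/DP at least `ratio_homalt_min` (default 0.8) is homozygous ALT;
* anything between is flagged het-ambiguous and treated as MISSING —
  with no true heterozygotes in a selfing panel, intermediate ratios are
  noise, not signal.

The ratio cutoffs are symmetric, conventional values for inbred panels
and are configurable in `call_thresholds()`; the QUAL and depth rules are
fixed conventions of the calling recipe. The call is monotone in DV at
fixed DP: more alternate reads can never move a call from ALT toward REF
(a property test enforces this).

Sites are then filtered (`apply_site_filters()`): a retained site must be
polymorphic among called samples, have minor allele frequency at least
`maf_min` (default 1%, computed over non-missing calls), and be missing
in no more than `miss_max` (default 90%) of samples. Monomorphism, MAF
and missingness are applied as three separate predicates; the filter is
idempotent. Duplicated accessions (re-sequenced material) are detected
from genome-wide calls as pairs exceeding 99.8% identity over co-called
sites, then merged into connected components.

## Haplotype grouping and nomenclature

A molecular haplotype is an exact combination of alleles over the
retained sites of a scope (x coding region, y coding region, both, or
both plus 2.5 kb flanks). Samples fully called over the scope are grouped
by vector equality. A sample with missing calls joins a haplotype only
when its called positions are consistent with exactly one existing
haplotype; otherwise it is AMBIGUOUS. This policy never invents a
haplotype from incomplete data, and degrades gracefully as missingness
grows. Haplotype identifiers are canonical — ordered by descending
carrier count, ties broken by the smallest member sample id — so results
are invariant to sample and site order.

Combined haplotypes are ordered pairs of subunit haplotypes. Because
adding sites can only split groups, the combined count is at least the
larger subunit count, and widening the scope with flanking sites can only
add haplotypes (`flank_consistency()` reports how many; in tightly linked
regions the expected answer is zero).

Names follow the subclade-letter convention: `Dx9a` is the first (by
carrier count) x-subunit haplotype of subclade 9; a combined haplotype is
written `x9a+y5a`. Letters are assigned within each subclade in canonical
order and carry no meaning across subclades. Published letter suffixes of
this nomenclature are historical, so the package prioritizes determinism
over reproducing any particular published letter.

## Distances, clades and trees

Genetic distances derive from the additive (genomic) relationship matrix
computed VanRaden-style from calls coded −1/+1 (the natural coding for
fully inbred diploids): missing calls are imputed to the marker mean,
markers are centered by twice the ALT allele frequency minus one, and the
cross-product is scaled by `2 Σ p(1−p)`. The distance between two samples
is the Euclidean norm between their rows of this matrix, and complete-
linkage agglomerative clustering of those distances gives the dendrogram
(the same linkage default as the clustering routine standard in this
field). Cutting the dendrogram at `k_major` (default 3) and `k_sub`
(default 15, capped at the number of units) groups gives nested
major-clades (labelled I, II, III, ... by descending size) and subclades
(numbered within the major-clade order). Both cut sizes are configuration
choices, not estimated quantities: how many subclades a curator
recognizes is a judgement call, so the package treats the counts as
inputs. Clade partitions can equally be supplied from an imported newick
tree (e.g. an externally computed maximum-likelihood tree) or a manual
table; downstream naming and recombinant logic need only the partition.
Neighbor joining is provided for building trees from the same distances;
maximum-likelihood inference is deliberately out of scope.

Haplotype-level clades are obtained by cutting the sample dendrogram per
subunit and lifting labels to haplotypes by majority vote over carriers
(ties to the smallest subclade number).

## Recombinant detection

The two subunit genes recombine extremely rarely, so the x and y
haplotype of an accession should come from the same clade. For each
x haplotype, the majority y major-clade among its carriers defines the
expected linkage. A combined haplotype is flagged as recombinant when its
x and y major-clades disagree and the pairing is carried by fewer than
`minority_max` (default 0.5) of that x haplotype's carriers; the
symmetric test runs from the y side and the union is reported. Ties in
the majority vote are reported and flag nothing. The minority threshold
generalizes what is, in practice, a by-eye call on a tree figure; it is
configurable.

## Coding effects and the cysteine audit

Each coding SNV is classified per site against the reference codon under
the standard nuclear code (synonymous, missense, nonsense, stop-loss,
start-loss); variants in flanks are tagged non-coding and excluded from
the synonymous/non-synonymous tally. The `cysteine_delta` of a
substitution records any gain or loss of a cysteine — including loss via
a gained stop codon, since either way a disulfide-bonding residue
disappears. Haplotype-level CDS sequences are also built by substituting
ALT bases into the reference CDS (strand-aware), so protein sequences can
be exported. The audit optionally restricts to codon windows for the
non-repetitive N- and C-terminal domains; the domain boundaries are
configuration inputs with the whole CDS as default. The central repeat
region is represented only by whatever SNVs the input contains — repeat
length variation is invisible to short reads and no reconstruction is
attempted.

## Lineage-specific k-mer bins

Diagnostic k-mers private to one lineage, counted in 100-kb bins of a
wheat assembly, localize the lineage of origin of D-subgenome segments. A
bin is assigned to lineage L iff its count strictly exceeds every other
lineage's count by more than a margin of 0.01% of the bin size (10 for
100-kb bins). The published rule is stated for lineage 3 only; it is
applied here symmetrically to all lineages, which reduces to the original
rule when only lineage 3 is of interest. The margin is applied per
competitor; for two competitors this is equivalent to using their
maximum. Ties at exactly count-plus-margin stay unassigned (the rule says
strictly greater). Bins use 0-based half-open coordinates; gene intervals
are 1-based inclusive and are mapped at the overlap step, where position
p falls in the bin starting at `floor((p−1)/bin_size)·bin_size`.
`colocalize_gene()` reports the assignment of every overlapped bin and a
consensus.

## Geography

Collection-site distances are great-circle (haversine) distances on a
sphere of radius 6371.0088 km. The association between genetic and
geographic distance is quantified with a one-sided Mantel test: Pearson
correlation over upper-triangle entries, significance from joint
row/column permutations, `p = (1 + #{r* ≥ r}) / (1 + n_perm)`. The test
is one-sided for positive association because the biological claim being
quantified — alleles diverge with distance — is directional. The
underlying field observation is qualitative; the Mantel statistic is this
package's added quantification and is labelled as such in reports.

## The synthetic panel generator

`simulate_panel()` generates panels with planted truth so that every
stage is testable without any download. What it emulates:

* three diverged lineages whose backbone haplotypes differ at ≥ 30% of
  sites per gene (re-drawn until the bound holds), with within-lineage
  haplotypes one planted mutation apart;
* near-complete x–y linkage: each lineage's pools are paired into
  combined haplotypes, and flank-site alleles are deterministic functions
  of the coding haplotypes (complete linkage, so flanks add nothing);
* planted recombinants: lineage-1 accessions carrying a foreign
  lineage's y haplotype;
* inter-lineage sharing: lineage-2 accessions carrying a lineage-1
  haplotype;
* re-sequenced duplicates: cloned accessions sharing >99.8% of
  genome-wide calls;
* sequencing noise: DP is 2 plus a Poisson(mean_depth − 2) draw — a
  depth floor reflecting panels sequenced to several-fold coverage, so
  that with the error rate at zero every cell is callable and planted
  truth is recovered exactly — DV is binomial around the true allele with
  the per-read error rate, and a configured fraction of sites is emitted
  with QUAL ≤ 40;
* geography: lineage centroids in Transcaucasia, the south-east Caspian
  and the western Iranian range, with isotropic Gaussian jitter (0.7°),
  the minimal model that makes genetic and geographic distance correlate.

Default panel size is 24 + 30 + 6 accessions over 40 + 30 + 30 sites —
a deliberately desk-scale rendering of a panel an order of magnitude
larger, keeping lineage proportions (lineage 2 largest, lineage 3 rare)
while letting the whole pipeline run in seconds.

What it does **not** emulate: coalescent genealogies within lineages,
recurrent or back mutation, indels and structural variants, true
heterozygosity (samples are fully homozygous; intermediate DV/DP arises
only from noise, which is exactly how the het-ambiguous policy is meant
to be exercised), alignment artifacts in the repetitive central domain,
and calibrated mutation rates. Passing the planted-truth tests therefore
demonstrates the correctness of the pipeline's logic under its own data
model, not robustness to every pathology of real short-read data.

`simulate_kmer_bins()` builds bin count tables by construction: planted
bins exceed all competitors by more than the margin, background bins stay
within it.

## Numerical and design choices

* Coordinates are 1-based closed intervals throughout (VCF/GFF
  convention); conversion to 0-based half-open happens only inside the
  bin-overlap step and any BED-style export.
* Multiallelic VCF records are split into one record per ALT before
  calling, keeping the cell domain binary as the haplotype model
  requires. When the FORMAT lacks DV, the per-allele AD field supplies
  the ALT depth.
* QUAL is compared strictly (a site at exactly 40 is not callable).
* Degenerate inputs: empty scopes, zero-sample matrices, monomorphic
  markers reaching the relationship matrix, sub-3-taxon NJ and malformed
  newick all raise errors rather than guessing.
* Ties: canonical ordering everywhere is descending carrier count with
  the lexicographically smallest member id as tiebreak; tied linkage
  votes in recombinant detection flag nothing and are reported.
* Negative NJ branch lengths (possible on non-additive input) are
  clamped to zero with a warning.
* Problem sizes in the test-suite and acceptance runs: panels of ~50–60
  samples and ~100 sites, 20 random 6–10-sample oracle instances, an
  exhaustive 26³ grid for the bin rule, 450 codon-substitution cases,
  and 200 Mantel null replicates at 999 permutations — sizes chosen so a
  full check runs on a laptop in about a minute while still exercising
  every code path.

## Limitations

Haplotype letters are reproducible but not guaranteed to match
historically assigned letters; clade counts are curator inputs; the
DV/DP ratio cutoffs are conventional defaults rather than values with a
published provenance, and should be revisited for outbred material;
recombinant detection presumes clade labels computed per subunit are
comparable, which holds when major clades track the same underlying
population structure on both genes (true for diverged lineages, the
intended use).
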