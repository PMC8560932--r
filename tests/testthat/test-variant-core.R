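test_that("region tagging honours the 2.5 kb flank boundaries (1-based closed)", {
  loc <- locus_definition()
  expect_equal(region_of(loc$gene_x[1] - 2500L, loc), "flank-x")
  expect_true(is.na(region_of(loc$gene_x[1] - 2501L, loc)))
  expect_equal(region_of(loc$gene_x[1], loc), "coding-x")
  expect_equal(region_of(loc$gene_y[2] + 2500L, loc), "flank-y")
  expect_true(is.na(region_of(loc$gene_y[2] + 2501L, loc)))
})

write_toy_vcf <- function(records, path = tempfile(fileext = ".vcf")) {
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
               "##FORMAT=<ID=DV,Number=1,Type=Integer,Description=\"d\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "s1", "s2"), collapse = "\t"),
               records), path)
  path
}

test_that("read_vcf_region keeps only locus records and tags them", {
  loc <- locus_definition()
  rec <- function(pos) paste(c("chr1D", pos, ".", "A", "T", "90", ".", ".",
                               "DP:DV", "10:0", "10:10"), collapse = "\t")
  path <- write_toy_vcf(c(rec(loc$gene_x[1]), rec(loc$gene_x[1] - 2500L),
                          rec(loc$gene_x[1] - 9000L), rec(loc$gene_y[1] + 5L),
                          rec(1000L)))
  v <- read_vcf_region(path, loc)
  expect_equal(nrow(v$sites), 3L)
  expect_setequal(v$sites$region, c("coding-x", "flank-x", "coding-y"))
  expect_equal(v$samples, c("s1", "s2"))
  expect_equal(unname(v$dv[, "s2"]), rep(10, 3))
})

test_that("malformed VCF lines are reported with their line number", {
  path <- write_toy_vcf(c(paste(c("chr1D", 419306988, ".", "A", "T", "90", ".",
                                  ".", "DP:DV", "10:0", "10:10"),
                                collapse = "\t"),
                          "chr1D\tbroken"))
  expect_error(read_vcf_region(path, locus_definition()), "line 6")
})

test_that("an absent locus chromosome yields an empty result with a warning", {
  path <- write_toy_vcf(paste(c("chrUn", 5, ".", "A", "T", "90", ".", ".",
                                "DP:DV", "3:0", "3:3"), collapse = "\t"))
  expect_warning(v <- read_vcf_region(path, locus_definition()), "absent")
  expect_equal(nrow(v$sites), 0L)
})

test_that("multiallelic records are split into per-ALT records", {
  loc <- locus_definition()
  path <- write_toy_vcf(paste(c("chr1D", loc$gene_x[1], ".", "A", "T,G", "90",
                                ".", ".", "DP:DV", "10:2", "10:9"),
                              collapse = "\t"))
  v <- read_vcf_region(path, loc)
  expect_equal(nrow(v$sites), 2L)
  expect_setequal(v$sites$alt, c("T", "G"))
})

test_that("depth-ratio genotype calls follow the QUAL/DP/DV rules", {
  t <- call_thresholds()
  expect_equal(as.vector(call_genotype(10, 0, 60, t)), "REF")
  expect_equal(as.vector(call_genotype(10, 10, 60, t)), "ALT")
  # QUAL comparison is strict: exactly 40 is not callable
  g <- call_genotype(10, 10, 40, t)
  expect_equal(as.vector(g), "MISSING")
  expect_equal(attr(g, "flag"), "low-qual")
  # intermediate ratio is het-ambiguous, hence MISSING for an inbred panel
  g <- call_genotype(10, 5, 60, t)
  expect_equal(as.vector(g), "MISSING")
  expect_equal(attr(g, "flag"), "het-ambiguous")
  g <- call_genotype(1, 0, 60, t)
  expect_equal(attr(g, "flag"), "low-depth")
  expect_error(call_genotype(5, 6, 60, t), "exceeds")
})

test_that("genotype calling is monotone in DV at fixed DP and QUAL", {
  t <- call_thresholds()
  rank_of <- c(REF = 1, MISSING = 2, ALT = 3)
  for (dp in c(2, 5, 10, 37)) {
    calls <- as.vector(call_genotype(rep(dp, dp + 1), 0:dp, 60, t))
    expect_true(all(diff(rank_of[calls]) >= 0), info = paste("dp =", dp))
  }
})

test_that("site filters drop monomorphic, rare and mostly-missing sites", {
  # site 1: all REF; site 2: 1 ALT among 273 called (MAF < 1%); site 3: fine
  calls <- rbind(rep(0L, 273),
                 c(1L, rep(0L, 272)),
                 c(rep(1L, 100), rep(0L, 173)))
  m <- make_gm(calls)
  f <- apply_site_filters(m, maf_min = 0.01, miss_max = 0.90)
  expect_equal(nrow(f$calls), 1L)
  expect_equal(f$sites$pos, 3L)

  # missing in 91% of samples exceeds the 90% cap
  calls <- rbind(c(rep(NA_integer_, 91), rep(c(0L, 1L), length.out = 9)),
                 rep(c(0L, 1L), 50))
  f <- apply_site_filters(make_gm(calls), 0.01, 0.90)
  expect_equal(nrow(f$calls), 1L)
  expect_error(apply_site_filters(make_gm(calls[, 0, drop = FALSE])), "zero samples")
})

test_that("site filtering is idempotent over random matrices", {
  set.seed(7)
  for (i in 1:1000) {
    calls <- matrix(sample(c(0L, 1L, NA), 8 * 10, replace = TRUE,
                           prob = c(0.45, 0.45, 0.10)), nrow = 8)
    colnames(calls) <- sprintf("s%02d", 1:10)
    m <- make_gm(calls)
    f1 <- apply_site_filters(m)
    f2 <- apply_site_filters(f1)
    expect_identical(f1$calls, f2$calls)
  }
})

test_that("duplicate detection groups near-identical genome-wide calls", {
  calls <- cbind(a = rep(0L, 1000), b = rep(0L, 1000), c = rep(1L, 1000))
  g <- find_duplicates(calls, 0.998)
  expect_true(any(vapply(g, identical, logical(1), c("a", "b"))))
  # 3 mismatches in 1000 sites is 99.7% identity: below the bar
  calls2 <- calls
  calls2[1:3, "b"] <- 1L
  g2 <- find_duplicates(calls2, 0.998)
  expect_equal(lengths(g2), c(1L, 1L, 1L))
  # grouping is invariant under sample order
  g3 <- find_duplicates(calls[, c("c", "b", "a")], 0.998)
  expect_setequal(lapply(g3, sort), lapply(g, sort))
})

test_that("hamming counts called differences and excludes missing positions", {
  a <- rep(0L, 308); b <- a; b[sample(308, 8)] <- 1L
  expect_equal(as.integer(hamming(a, b)), 8L)
  expect_equal(as.integer(hamming(a, a)), 0L)
  h <- hamming(rep(NA_integer_, 5), c(0L, 1L, 0L, 1L, 0L))
  expect_equal(as.integer(h), 0L)
  expect_equal(attr(h, "n_excluded"), 5L)
  expect_error(hamming(1:3, 1:4), "length")
})

test_that("hamming is a metric on fully called vectors", {
  set.seed(11)
  for (i in 1:50) {
    v <- replicate(3, sample(0:1, 12, replace = TRUE), simplify = FALSE)
    d_ab <- as.integer(hamming(v[[1]], v[[2]]))
    d_bc <- as.integer(hamming(v[[2]], v[[3]]))
    d_ac <- as.integer(hamming(v[[1]], v[[3]]))
    expect_lte(d_ac, d_ab + d_bc)
    expect_equal(d_ab, as.integer(hamming(v[[2]], v[[1]])))
  }
})
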