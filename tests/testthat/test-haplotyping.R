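test_that("exact-match grouping partitions samples by allele vector", {
  calls <- cbind(s1 = c(0L, 0L), s2 = c(0L, 0L), s3 = c(1L, 0L))
  p <- group_haplotypes(make_gm(calls), "coding-x")
  expect_equal(n_haplotypes(p), 2L)
  expect_equal(unname(p$counts), c(2L, 1L))
  expect_equal(unname(p$assignment[c("s1", "s2")]), c("X01", "X01"))
})

test_that("a missing call compatible with several haplotypes is AMBIGUOUS", {
  calls <- cbind(s1 = c(0L, 0L), s2 = c(1L, 0L), s3 = c(NA, 0L),
                 s4 = c(NA, 1L))
  p <- group_haplotypes(make_gm(calls), "coding-x")
  expect_equal(unname(p$assignment["s3"]), "AMBIGUOUS")
  # s4's called position is consistent with no existing haplotype
  expect_equal(unname(p$assignment["s4"]), "AMBIGUOUS")
  # uniquely compatible: only one haplotype matches the called positions
  calls2 <- cbind(s1 = c(0L, 0L), s2 = c(1L, 1L), s3 = c(NA, 1L))
  p2 <- group_haplotypes(make_gm(calls2), "coding-x")
  expect_equal(unname(p2$assignment["s3"]), unname(p2$assignment["s2"]))
})

test_that("grouping is invariant under sample and site permutations", {
  set.seed(3)
  calls <- matrix(sample(0:1, 12 * 9, replace = TRUE), 12,
                  dimnames = list(NULL, sprintf("s%02d", 1:9)))
  m <- make_gm(calls)
  p <- group_haplotypes(m, "coding-x")
  ps <- group_haplotypes(make_gm(calls[, sample(9)]), "coding-x")
  expect_equal(p$assignment[names(p$assignment)],
               ps$assignment[names(p$assignment)])
  ord <- sample(12)
  pr <- group_haplotypes(make_gm(calls[ord, , drop = FALSE], pos = ord),
                         "coding-x")
  expect_equal(p$assignment, pr$assignment[names(p$assignment)])
})

test_that("adding sites refines but never merges haplotypes", {
  set.seed(5)
  for (i in 1:25) {
    calls <- matrix(sample(0:1, 10 * 8, replace = TRUE), 10,
                    dimnames = list(NULL, sprintf("s%02d", 1:8)))
    narrow <- group_haplotypes(make_gm(calls[1:6, , drop = FALSE]), "coding-x")
    wide <- group_haplotypes(make_gm(calls), "coding-x")
    expect_gte(n_haplotypes(wide), n_haplotypes(narrow))
    # samples sharing a wide haplotype must share the narrow one
    for (id in names(wide$haplotypes)) {
      members <- names(wide$assignment)[wide$assignment == id]
      expect_length(unique(narrow$assignment[members]), 1L)
    }
  }
})

test_that("combining subunits enumerates observed x/y pairs", {
  px <- group_haplotypes(make_gm(cbind(a = 0L, b = 0L, c = 1L, d = 1L, e = 0L),
                                 region = "coding-x"), "coding-x")
  py <- group_haplotypes(make_gm(cbind(a = 0L, b = 1L, c = 0L, d = 1L, e = 0L),
                                 region = "coding-y"), "coding-y")
  comb <- combine_subunits(px, py)
  # one x haplotype paired with several y haplotypes yields several combined
  expect_equal(n_haplotypes(comb), 4L)
  expect_gte(n_haplotypes(comb), max(n_haplotypes(px), n_haplotypes(py)))
  bad <- group_haplotypes(make_gm(cbind(z = matrix(0L, 1))), "coding-x")
  expect_error(combine_subunits(px, bad), "universes")
})

test_that("perfect 1:1 linkage gives as many combined as subunit haplotypes", {
  hapvecs <- rbind(c(0L, 0L, 0L), c(1L, 0L, 0L), c(0L, 1L, 0L),
                   c(1L, 1L, 0L), c(0L, 0L, 1L))
  calls_x <- t(hapvecs[rep(1:5, each = 3), ])        # 3 sites x 15 samples
  colnames(calls_x) <- sprintf("s%02d", 1:15)
  px <- group_haplotypes(make_gm(calls_x, region = rep("coding-x", 3)), "coding-x")
  py <- group_haplotypes(make_gm(calls_x, pos = 11:13,
                                 region = rep("coding-y", 3)), "coding-y")
  expect_equal(n_haplotypes(combine_subunits(px, py)), n_haplotypes(px))
})

test_that("flank sites in complete linkage add no haplotypes; a planted flank mutation adds one", {
  calls <- cbind(s1 = c(0L, 0L), s2 = c(1L, 1L), s3 = c(0L, 0L))
  region <- c("coding-x", "flank-x")
  m <- make_gm(calls, region = region)
  p_cod <- group_haplotypes(m, "combined")
  p_full <- group_haplotypes(m, "combined+flanks")
  expect_equal(flank_consistency(p_cod, p_full), 0L)
  # flank-only mutation splits s3 away from s1
  calls2 <- calls; calls2[2, "s3"] <- 1L
  m2 <- make_gm(calls2, region = region)
  expect_equal(flank_consistency(group_haplotypes(m2, "combined"),
                                 group_haplotypes(m2, "combined+flanks")), 1L)
  expect_equal(flank_consistency(p_cod, p_cod), 0L)
})

test_that("nomenclature letters follow carrier count within each subclade", {
  calls <- cbind(matrix(0L, 2, 10), matrix(c(1L, 0L), 2, 3),
                 matrix(c(0L, 1L), 2, 2))
  colnames(calls) <- sprintf("s%02d", 1:15)
  p <- group_haplotypes(make_gm(calls), "coding-x")
  cl <- clade_partition(data.frame(unit = names(p$haplotypes),
                                   major_clade = "I",
                                   subclade = c(1L, 1L, 2L)))
  nm <- assign_names(p, cl, "x")
  expect_equal(nm$name[nm$members == 10], "Dx1a")
  expect_equal(nm$name[nm$members == 3], "Dx1b")
  expect_equal(nm$name[nm$members == 2], "Dx2a")
  # determinism under sample shuffling
  set.seed(1)
  p2 <- group_haplotypes(make_gm(calls[, sample(15)]), "coding-x")
  expect_equal(assign_names(p2, cl, "x")$name, nm$name)
  expect_error(assign_names(p, cl[-1, ], "x"), "lacking clade")
})

test_that("assign_names rejects haplotypes without clade assignment, names which", {
  calls <- cbind(s1 = c(0L, 0L), s2 = c(1L, 1L))
  p <- group_haplotypes(make_gm(calls), "coding-x")
  cl <- clade_partition(data.frame(unit = names(p$haplotypes)[1],
                                   major_clade = "I", subclade = 1L))
  expect_error(assign_names(p, cl, "x"), names(p$haplotypes)[2])
})

make_combined <- function(assign_df) {
  # assign_df: sample, x, y
  cx <- t(vapply(assign_df$x, function(i) as.integer(intToBits(i))[1:4],
                 integer(4)))
  cy <- t(vapply(assign_df$y, function(i) as.integer(intToBits(i))[1:4],
                 integer(4)))
  rownames(cx) <- rownames(cy) <- assign_df$sample
  px <- group_haplotypes(make_gm(t(cx), region = rep("coding-x", 4)), "coding-x")
  py <- group_haplotypes(make_gm(t(cy), pos = 5:8,
                                 region = rep("coding-y", 4)), "coding-y")
  list(px = px, py = py, comb = combine_subunits(px, py))
}

test_that("recombinant detection flags minority clade-discordant pairings", {
  # 10 samples x-hap 1 / y-hap 1 (clade I), 10 samples x2/y2 (clade II),
  # one sample joining x1 with y2: a minority, clade-discordant pairing
  df <- data.frame(sample = sprintf("s%02d", 1:21),
                   x = c(rep(1, 10), rep(2, 10), 1),
                   y = c(rep(1, 10), rep(2, 10), 2))
  parts <- make_combined(df)
  id_of <- function(p, sample) unname(p$assignment[sample])
  x_cl <- clade_partition(data.frame(
    unit = names(parts$px$haplotypes),
    major_clade = ifelse(names(parts$px$haplotypes) == id_of(parts$px, "s01"), "I", "II"),
    subclade = ifelse(names(parts$px$haplotypes) == id_of(parts$px, "s01"), 1L, 2L)))
  y_cl <- clade_partition(data.frame(
    unit = names(parts$py$haplotypes),
    major_clade = ifelse(names(parts$py$haplotypes) == id_of(parts$py, "s01"), "I", "II"),
    subclade = ifelse(names(parts$py$haplotypes) == id_of(parts$py, "s01"), 1L, 2L)))
  rec <- detect_recombinants(parts$comb, x_cl, y_cl)
  expect_equal(rec$sample, "s21")
  expect_equal(rec$expected_y_major, "I")

  # perfect linkage: nothing flagged
  rec0 <- detect_recombinants(make_combined(df[1:20, ])$comb, x_cl, y_cl)
  expect_equal(nrow(rec0), 0L)
})

test_that("tied linkage votes are reported and not flagged", {
  df <- data.frame(sample = sprintf("s%02d", 1:4),
                   x = c(1, 1, 2, 2), y = c(1, 2, 1, 2))
  parts <- make_combined(df)
  ids_x <- names(parts$px$haplotypes); ids_y <- names(parts$py$haplotypes)
  x_cl <- clade_partition(data.frame(unit = ids_x, major_clade = c("I", "II"),
                                     subclade = 1:2))
  y_cl <- clade_partition(data.frame(unit = ids_y, major_clade = c("I", "II"),
                                     subclade = 1:2))
  rec <- detect_recombinants(parts$comb, x_cl, y_cl)
  expect_equal(nrow(rec), 0L)
  expect_setequal(attr(rec, "ties"), c(ids_x, ids_y))
})
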