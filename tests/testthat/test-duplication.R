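test_that("self-alignment is full-length and fully identical", {
  res <- smith_waterman("MKVLAW", "MKVLAW")
  expect_equal(res$identity_pct, 100)
  expect_equal(res$similarity_pct, 100)
  expect_equal(res$aligned_a, "MKVLAW")
  expect_equal(res$aligned_b, "MKVLAW")
  expect_error(smith_waterman("", "MK"), "empty")
})

test_that("local and global scores equal exhaustive enumeration on toy pairs", {
  tm <- toy_matrix()
  set.seed(707)
  cases <- list()
  for (k in 1:30) {
    cases[[k]] <- c(
      paste(sample(c("A", "C", "G", "T"), sample(1:6, 1), TRUE), collapse = ""),
      paste(sample(c("A", "C", "G", "T"), sample(1:6, 1), TRUE), collapse = ""))
  }
  cases <- c(cases, list(c("ACGT", "TGCA"), c("AAAA", "AATAA"),
                         c("ACACAC", "CACACA"), c("A", "T"),
                         c("GATTAC", "GATC")))
  for (cs in cases) {
    expect_equal(
      smith_waterman(cs[1], cs[2], matrix = tm, gap_open = 2,
                     gap_extend = 0.5)$score,
      enumerate_local_score(cs[1], cs[2], tm, 2, 0.5),
      info = paste("local", cs[1], cs[2]))
    expect_equal(
      needleman_wunsch(cs[1], cs[2], matrix = tm, gap_open = 2,
                       gap_extend = 0.5)$score,
      enumerate_global_score(cs[1], cs[2], tm, 2, 0.5),
      info = paste("global", cs[1], cs[2]))
  }
})

test_that("protein scores cross-check against Biostrings pairwiseAlignment", {
  set.seed(708)
  pool <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K")
  for (k in 1:10) {
    a <- paste(sample(pool, sample(10:30, 1), TRUE), collapse = "")
    b <- paste(sample(pool, sample(10:30, 1), TRUE), collapse = "")
    ref_l <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "local"))
    ref_g <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global"))
    expect_equal(smith_waterman(a, b)$score, ref_l)
    expect_equal(needleman_wunsch(a, b)$score, ref_g)
  }
})

test_that("alignment of point-mutated paralogs preserves identity bounds", {
  set.seed(709)
  pool <- c("A", "R", "N", "D", "E", "Q", "G", "I", "L", "K", "S", "T")
  anc <- sample(pool, 200, replace = TRUE)
  mut <- anc
  flip <- sample(200, 30)  # 85% identical
  mut[flip] <- vapply(mut[flip], function(x) sample(setdiff(pool, x), 1), "")
  res <- smith_waterman(paste(anc, collapse = ""), paste(mut, collapse = ""))
  expect_gte(res$identity_pct, 80)
  expect_gte(res$similarity_pct, res$identity_pct)
  expect_lte(res$similarity_pct, 100)
})

test_that("the tandem rule needs same chromosome, <=5 loci, <=100 kb, >=80%", {
  mk <- function(chrom, start, end, idx) {
    list(gene_id = "g", chrom_label = chrom, start = start, end = end,
         locus_index = idx)
  }
  a <- mk("chr1", 100000, 102000, 10L)
  expect_true(is_tandem(a, mk("chr1", 150001, 152000, 13L), 85)$is_tandem)
  ev <- is_tandem(a, mk("chr1", 150001, 152000, 13L), 85)$evidence
  expect_equal(ev$intervening_loci, 2L)
  expect_equal(ev$distance_bp, 48000)

  # locus criterion fails (6 intervening)
  expect_false(is_tandem(a, mk("chr1", 150001, 152000, 17L), 85)$is_tandem)
  # distance criterion fails
  expect_false(is_tandem(a, mk("chr1", 252001, 254000, 12L), 85)$is_tandem)
  # similarity criterion fails
  expect_false(is_tandem(a, mk("chr1", 150001, 152000, 13L), 60)$is_tandem)
  # overlap counts as distance zero
  expect_equal(is_tandem(a, mk("chr1", 101000, 104000, 11L), 85)
               $evidence$distance_bp, 0)
  # different chromosome is evidence, not an error
  far <- is_tandem(a, mk("chr2", 100000, 102000, 1L), 99)
  expect_false(far$is_tandem)
  expect_equal(far$evidence$reason, "different_chromosome")
  # symmetry
  b <- mk("chr1", 150001, 152000, 13L)
  expect_equal(is_tandem(a, b, 85)$is_tandem, is_tandem(b, a, 85)$is_tandem)
  expect_equal(is_tandem(a, b, 85)$evidence$distance_bp,
               is_tandem(b, a, 85)$evidence$distance_bp)
})

test_that("duplication typing is exclusive, exhaustive and matches planted truth", {
  sim <- gen_gene_map(n_chrom = 3L, genes_per_chrom = 20L,
                      tandem_arrays = 3L, array_size = 3L,
                      block_pairs = 3L, genes_per_block = 4L,
                      o_pairs = 2L, seed = 5L)
  truth <- sim$truth$pairs
  typed <- vapply(seq_len(nrow(truth)), function(i) {
    assign_duplication_type(truth$gene1[i], truth$gene2[i],
                            sim$loci, sim$blocks,
                            similarity_pct = 85)$duplication_type
  }, character(1))
  expect_identical(typed, truth$type)
  expect_true(all(typed %in% c("W", "T", "O")))

  summ <- summarize_duplication(typed)
  expect_equal(summ$count[summ$type == "W"], 12L)
  expect_equal(summ$count[summ$type == "T"], 6L)
  expect_equal(summ$count[summ$type == "O"], 2L)
  expect_equal(sum(summ$count), nrow(truth))
  expect_equal(sum(summ$pct), 100, tolerance = 0.2)

  expect_error(assign_duplication_type("nope", truth$gene2[1], sim$loci,
                                       sim$blocks, 85), "nope")
})

test_that("a map without blocks never yields W, and single types sum to 100%", {
  sim <- gen_gene_map(n_chrom = 2L, genes_per_chrom = 10L,
                      tandem_arrays = 1L, array_size = 3L,
                      block_pairs = 0L, o_pairs = 1L, seed = 8L)
  expect_null(sim$blocks)
  truth <- sim$truth$pairs
  typed <- vapply(seq_len(nrow(truth)), function(i) {
    assign_duplication_type(truth$gene1[i], truth$gene2[i],
                            sim$loci, sim$blocks,
                            similarity_pct = 90)$duplication_type
  }, character(1))
  expect_false(any(typed == "W"))

  one <- summarize_duplication("T")
  expect_equal(one$pct[one$type == "T"], 100.0)
  expect_equal(one$count[one$type == "W"], 0L)
})
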