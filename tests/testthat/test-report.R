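make_bundle <- function(seed = 1L) {
  proteome <- gen_proteome(n_proteins = 12L, nes_rate = 0.4, tzf_rate = 0.2,
                           seed = seed)
  gmap <- gen_gene_map(n_chrom = 2L, genes_per_chrom = 10L,
                       tandem_arrays = 1L, array_size = 3L,
                       block_pairs = 1L, genes_per_block = 3L,
                       o_pairs = 1L, seed = seed)
  expr <- gen_expression(pair_categories = c(1L, 2L, 3L, 4L),
                         noise_sd = 0.1, seed = seed)
  list(proteome = proteome, gmap = gmap, expr = expr)
}

test_that("run_all populates every report section on a full bundle", {
  b <- make_bundle(seed = 2L)
  pairs <- data.frame(gene1 = b$expr$truth$gene1, gene2 = b$expr$truth$gene2)
  res <- suppressMessages(run_all(
    proteins = b$proteome$records,
    pairs = pairs,
    loci = b$gmap$loci, blocks = b$gmap$blocks,
    expression = b$expr$matrix))
  expect_equal(nrow(res$gene_table), 12L)
  expect_true(all(c("gene_id", "length", "mol_wt_kd", "pi", "n_motifs",
                    "motif_labels", "subfamily", "has_nes", "is_tzf")
                  %in% names(res$gene_table)))
  expect_equal(res$summary$n_genes, 12L)
  truth_counts <- table(b$proteome$truth$motifs$protein_id)
  got <- stats::setNames(res$gene_table$n_motifs, res$gene_table$gene_id)
  expect_equal(unname(got[names(truth_counts)]), as.integer(truth_counts))
  expect_equal(res$summary$n_tzf, sum(b$proteome$truth$tzf$is_tzf))
  expect_equal(res$summary$n_with_nes,
               length(unique(b$proteome$truth$nes$protein_id)))
  # expression categories recovered against planted truth
  expect_equal(res$pair_table$expression_category, b$expr$truth$category)
  expect_s3_class(res$expression$dendrogram, "hclust")
})

test_that("stages without inputs are skipped, not failed", {
  b <- make_bundle(seed = 4L)
  expect_message(res <- run_all(proteins = b$proteome$records), "skipped")
  expect_null(res$pair_table)
  expect_null(res$expression)
  expect_equal(nrow(res$gene_table), 12L)
  expect_false(is.null(res$summary$min_length))
})

test_that("duplication typing inside run_all matches planted truth", {
  b <- make_bundle(seed = 6L)
  truth <- b$gmap$truth$pairs
  # give every planted pair a shared high-similarity protein stand-in
  prot <- data.frame(
    id = unique(c(truth$gene1, truth$gene2)),
    desc = "",
    seq = strrep("MKVLAWDEQR", 8),
    stringsAsFactors = FALSE)
  res <- suppressMessages(run_all(
    proteins = prot,
    pairs = truth[, c("gene1", "gene2")],
    loci = b$gmap$loci, blocks = b$gmap$blocks))
  expect_identical(res$pair_table$duplication_type, truth$type)
  summ <- res$summary$duplication
  expect_equal(sum(summ$count), nrow(truth))
})

test_that("run_all computes Ka/Ks when coding sequences are supplied", {
  g <- gen_cds_pairs(2L, n_codons = 40L, omega = 0.2,
                     expected_sub_per_codon = 0.2, seed = 12L)
  prot <- data.frame(
    id = g$records$id, desc = "",
    seq = vapply(g$records$seq,
                 function(s) suppressMessages(translate_cds(s)),
                 character(1)),
    stringsAsFactors = FALSE)
  pairs <- data.frame(gene1 = c("pair001_a", "pair002_a"),
                      gene2 = c("pair001_b", "pair002_b"))
  res <- suppressMessages(run_all(proteins = prot, cds = g$records,
                                  pairs = pairs))
  expect_true(all(is.finite(res$pair_table$ks)))
  expect_true(all(res$pair_table$selection %in%
                    c("purifying", "relaxed_or_positive", "undefined")))
  expect_gte(min(res$pair_table$similarity_pct), 80)
})

test_that("reports round-trip deterministically through the TSV writer", {
  b <- make_bundle(seed = 8L)
  res <- suppressMessages(run_all(proteins = b$proteome$records))
  cfg <- pipeline_config(seed = 8L)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_report_tsv(res$gene_table, f1, cfg)
  write_report_tsv(res$gene_table, f2, cfg)
  expect_identical(readLines(f1), readLines(f2))
  # front matter parses back as YAML with the thresholds intact
  header <- grep("^# ", readLines(f1), value = TRUE)
  meta <- yaml::yaml.load(paste(sub("^# ", "", header), collapse = "\n"))
  expect_equal(meta$tandem_max_distance, 100000)
  expect_equal(meta$kaks_threshold, 0.5)
  expect_equal(meta$seed, 8)
  # body reads back as the same table
  body <- read.delim(f1, comment.char = "#", stringsAsFactors = FALSE)
  expect_equal(body$gene_id, res$gene_table$gene_id)
})

test_that("packaged family tables load with the published shapes", {
  t1 <- ptc3h_gene_table()
  expect_equal(nrow(t1), 91L)
  expect_true(all(c("gene", "locus_id", "length_aa", "n_motifs") %in% names(t1)))
  t2 <- ptc3h_pair_table()
  expect_equal(nrow(t2), 34L)
  expect_true(all(t2$duplication %in% c("W", "T", "O")))
})
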