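#' Pipeline configuration
#'
#' Bundles every tunable threshold of the pipeline with the survey's
#' standard values: tandem rule (<= 5 intervening loci, <= 100 kb,
#' >= 80 % similarity), Ka/Ks purifying-selection threshold 0.5, and
#' expressed-set threshold tau = 0 on normalized values.
#'
#' @param scan A [scan_config()].
#' @param tandem_max_intervening,tandem_max_distance,tandem_min_similarity
#'   Tandem-duplication rule thresholds.
#' @param kaks_threshold Selection-call boundary for [classify_selection()].
#' @param tau Expressed-set threshold for [expressed_sets()].
#' @param tzf_spacing TZF spacer length for [detect_tzf()].
#' @param seed Seed recorded in report front matter.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scan = scan_config(),
                            tandem_max_intervening = 5L,
                            tandem_max_distance = 100000,
                            tandem_min_similarity = 80,
                            kaks_threshold = 0.5,
                            tau = 0, tzf_spacing = 18L, seed = 1L) {
  stopifnot(tandem_max_intervening > 0, tandem_max_distance > 0,
            tandem_min_similarity > 0, kaks_threshold > 0)
  structure(list(scan = scan,
                 tandem_max_intervening = tandem_max_intervening,
                 tandem_max_distance = tandem_max_distance,
                 tandem_min_similarity = tandem_min_similarity,
                 kaks_threshold = kaks_threshold,
                 tau = tau, tzf_spacing = tzf_spacing, seed = seed),
            class = "pipeline_config")
}

#' Run the full survey pipeline
#'
#' Orchestrates all stages on whatever inputs are supplied; stages
#' whose inputs are missing are skipped with a message. The returned
#' bundle mirrors the two summary tables of a family survey: a
#' per-gene table (locus, physico-chemical parameters, motif content,
#' subfamily, NES/TZF flags) and a per-pair table (Ka, Ks, Ka/Ks,
#' selection call, duplication type, expression category).
#'
#' @param proteins Protein records (data.frame `id`, `seq`) or `NULL`.
#' @param cds CDS records for Ka/Ks, ids matching `proteins`/`pairs`.
#' @param pairs `data.frame` with columns `gene1`, `gene2` naming
#'   paralogous pairs, or `NULL`.
#' @param loci Locus table ([read_locus_table()] format), or `NULL`.
#' @param blocks Block table, or `NULL`.
#' @param expression Expression matrix (genes x samples), or `NULL`.
#' @param probe_map Optional probe map; when given, `expression` is
#'   treated as probe-level and collapsed first.
#' @param config A [pipeline_config()].
#' @return A list with `gene_table`, `pair_table`, `expression`
#'   (normalized matrix, expressed sets, highest tissue, `hclust`
#'   dendrogram), `summary`, and the `config` used.
#' @export
run_all <- function(proteins = NULL, cds = NULL, pairs = NULL,
                    loci = NULL, blocks = NULL, expression = NULL,
                    probe_map = NULL, config = pipeline_config()) {
  gene_table <- NULL
  annotations <- NULL
  if (!is.null(proteins)) {
    annotations <- lapply(seq_len(nrow(proteins)), function(i) {
      scan_ccch(proteins$seq[i], config$scan, protein_id = proteins$id[i])
    })
    names(annotations) <- proteins$id
    rows <- lapply(seq_len(nrow(proteins)), function(i) {
      ann <- annotations[[i]]
      pc <- phys_chem(proteins$seq[i], on_x = "skip")
      nes <- find_nes(proteins$seq[i])
      tzf <- detect_tzf(ann, proteins$seq[i], spacing = config$tzf_spacing)
      sf <- if (nrow(ann$motifs) > 0L) assign_subfamily(ann)$subfamily
            else "unclassified"
      data.frame(gene_id = proteins$id[i],
                 length = pc$length,
                 mol_wt_kd = round(pc$mol_wt / 1000, 2L),
                 pi = round(pc$pi, 2L),
                 n_motifs = nrow(ann$motifs),
                 motif_labels = paste(ann$motifs$label, collapse = ";"),
                 subfamily = sf,
                 n_nes = nrow(nes),
                 has_nes = nrow(nes) > 0L,
                 is_tzf = tzf$is_tzf,
                 stringsAsFactors = FALSE)
    })
    gene_table <- do.call(rbind, rows)
    if (!is.null(loci)) {
      keep <- c("gene_id", "chrom_label", "start", "end", "strand",
                "locus_index", intersect("exons", names(loci)))
      gene_table <- merge(gene_table, loci[, keep], by = "gene_id",
                          all.x = TRUE, sort = FALSE)
    }
  } else {
    message("no proteins supplied; gene table skipped")
  }

  expr_report <- NULL
  sets <- NULL
  if (!is.null(expression)) {
    mat <- expression
    if (!is.null(probe_map)) mat <- collapse_probes(mat, probe_map)
    norm <- genewise_normalize(mat)
    sets <- expressed_sets(norm, tau = config$tau)
    expr_report <- list(normalized = norm, expressed_sets = sets,
                        highest_tissue = highest_tissue(mat),
                        dendrogram = if (nrow(norm) >= 2L)
                          cluster_genes(norm) else NULL)
  } else {
    message("no expression matrix supplied; expression stage skipped")
  }

  pair_table <- NULL
  if (!is.null(pairs)) {
    seq_of <- function(g) {
      if (is.null(proteins)) return(NA_character_)
      s <- proteins$seq[proteins$id == g]
      if (length(s) == 1L) s else NA_character_
    }
    cds_of <- function(g) {
      if (is.null(cds)) return(NA_character_)
      s <- cds$seq[cds$id == g]
      if (length(s) == 1L) s else NA_character_
    }
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
      g1 <- pairs$gene1[i]; g2 <- pairs$gene2[i]
      sim <- NA_real_
      s1 <- seq_of(g1); s2 <- seq_of(g2)
      if (!is.na(s1) && !is.na(s2)) {
        sim <- smith_waterman(s1, s2)$similarity_pct
      }
      dup <- NA_character_; blk <- NA_character_
      if (!is.null(loci) && all(c(g1, g2) %in% loci$gene_id)) {
        pp <- assign_duplication_type(
          g1, g2, loci, blocks, similarity_pct = sim,
          max_intervening = config$tandem_max_intervening,
          max_distance = config$tandem_max_distance,
          min_similarity = config$tandem_min_similarity)
        dup <- pp$duplication_type
        blk <- pp$block_pair_id
      }
      ks <- ka <- ratio <- NA_real_; sel <- NA_character_
      c1 <- cds_of(g1); c2 <- cds_of(g2)
      if (!is.na(c1) && !is.na(c2)) {
        kk <- kaks_pair(c1, c2, threshold = config$kaks_threshold)
        ks <- kk$Ks; ka <- kk$Ka; ratio <- kk$ratio; sel <- kk$selection
      }
      expr_cat <- NA_integer_
      if (!is.null(sets) && g1 %in% names(sets) && g2 %in% names(sets)) {
        expr_cat <- categorize_pair(sets[[g1]], sets[[g2]])$category
      }
      data.frame(gene1 = g1, gene2 = g2,
                 similarity_pct = sim, duplication_type = dup,
                 block_pair_id = blk, ks = ks, ka = ka, ratio = ratio,
                 selection = sel, expression_category = expr_cat,
                 stringsAsFactors = FALSE)
    })
    pair_table <- do.call(rbind, rows)
  } else {
    message("no pairs supplied; pair table skipped")
  }

  summary <- list()
  if (!is.null(gene_table)) {
    summary <- family_summary(gene_table$length, gene_table$n_motifs)
    summary$n_with_nes <- sum(gene_table$has_nes)
    summary$n_tzf <- sum(gene_table$is_tzf)
  }
  if (!is.null(pair_table) && any(!is.na(pair_table$duplication_type))) {
    ok <- !is.na(pair_table$duplication_type)
    summary$duplication <- summarize_duplication(pair_table$duplication_type[ok])
  }
  list(gene_table = gene_table, pair_table = pair_table,
       expression = expr_report, summary = summary, config = config)
}

#' Family-level length and motif-count summary
#'
#' The headline statistics of a gene-family survey, computable from a
#' transcribed characteristics table alone (no sequences needed):
#' protein length range and mean, and the fraction of proteins with at
#' least two CCCH motifs.
#'
#' @param lengths Integer vector of protein lengths (residues).
#' @param n_motifs Optional integer vector of per-protein motif counts.
#' @return A list with `n_genes`, `min_length`, `max_length`,
#'   `mean_length` (one decimal) and, when motif counts are given,
#'   `pct_at_least_2_motifs` (percentage, one decimal).
#' @examples
#' family_summary(ptc3h_gene_table()$length_aa,
#'                ptc3h_gene_table()$n_motifs)
#' @export
family_summary <- function(lengths, n_motifs = NULL) {
  stopifnot(is.numeric(lengths), length(lengths) > 0L)
  out <- list(n_genes = length(lengths),
              min_length = min(lengths),
              max_length = max(lengths),
              mean_length = round(mean(lengths), 1L))
  if (!is.null(n_motifs)) {
    stopifnot(length(n_motifs) == length(lengths))
    out$pct_at_least_2_motifs <- summarize_motifs(n_motifs)$pct_at_least_k
  }
  out
}

config_yaml <- function(config) {
  flat <- list(
    m_range = paste(config$scan$m_range, collapse = ":"),
    n_range = paste(config$scan$n_range, collapse = ":"),
    p_range = paste(config$scan$p_range, collapse = ":"),
    overlap_policy = config$scan$overlap_policy,
    tandem_max_intervening = config$tandem_max_intervening,
    tandem_max_distance = config$tandem_max_distance,
    tandem_min_similarity = config$tandem_min_similarity,
    kaks_threshold = config$kaks_threshold,
    tau = config$tau, tzf_spacing = config$tzf_spacing,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("ccchfamily")))
  yaml::as.yaml(flat)
}

#' Write a report table as TSV with a YAML front-matter block
#'
#' The configuration (thresholds, scanner ranges, seed, package
#' version) is written as `#`-prefixed YAML lines above the header so
#' every number in the table is traceable to its parameters.
#'
#' @param df The table to write.
#' @param path Output path.
#' @param config The [pipeline_config()] used to produce `df`.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(df, path, config = pipeline_config()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", strsplit(config_yaml(config), "\n")[[1]]), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Published gene characteristics of the Populus CCCH family
#'
#' The printed per-gene characteristics of the 91 *Populus trichocarpa*
#' CCCH genes (PtC3H1-91): locus identifier, ORF length, exon count,
#' protein length, molecular weight, isoelectric point and CCCH motif
#' count. Shipped as a worked fixture for desk audits of the summary
#' operations.
#'
#' @return A `data.frame` with 91 rows.
#' @export
ptc3h_gene_table <- function() {
  read.delim(system.file("extdata", "ptc3h_gene_characteristics.tsv",
                         package = "ccchfamily", mustWork = TRUE),
             stringsAsFactors = FALSE)
}

#' Published paralogous-pair table of the Populus CCCH family
#'
#' The printed divergence table of the 34 paralogous PtC3H pairs: Ks,
#' Ka, Ka/Ks, duplication type (W/T/O), structure class and expression
#' class.
#'
#' @return A `data.frame` with 34 rows.
#' @export
ptc3h_pair_table <- function() {
  read.delim(system.file("extdata", "ptc3h_paralog_pairs.tsv",
                         package = "ccchfamily", mustWork = TRUE),
             stringsAsFactors = FALSE)
}
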