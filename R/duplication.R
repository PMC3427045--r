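#' Test two gene loci for tandem duplication
#'
#' Two genes are tandem duplicates when they lie on the same chromosome
#' separated by at most `max_intervening` gene loci (locus-index
#' difference minus one) within `max_distance` base pairs (the gap
#' between the nearer gene ends, 0 if the intervals overlap), and their
#' proteins are at least `min_similarity` percent similar.
#'
#' @param a,b Single-row gene loci (lists or data.frame rows with
#'   `gene_id`, `chrom_label`, `start`, `end`, `locus_index`).
#' @param similarity_pct Protein similarity of the pair (percent), e.g.
#'   from [smith_waterman()].
#' @param max_intervening,max_distance,min_similarity Rule thresholds
#'   (defaults: 5 loci, 100 kb, 80 %).
#' @return A list with `is_tandem` and `evidence` (a list with
#'   `intervening_loci`, `distance_bp`, `similarity_pct`, and `reason`
#'   when the rule fails). Different chromosomes give `is_tandem =
#'   FALSE` with reason `"different_chromosome"`, not an error.
#' @export
is_tandem <- function(a, b, similarity_pct,
                      max_intervening = 5L, max_distance = 100000,
                      min_similarity = 80) {
  if (a$chrom_label != b$chrom_label) {
    return(list(is_tandem = FALSE,
                evidence = list(reason = "different_chromosome",
                                similarity_pct = similarity_pct)))
  }
  intervening <- abs(a$locus_index - b$locus_index) - 1L
  distance <- max(0, max(a$start, b$start) - min(a$end, b$end) - 1)
  ev <- list(intervening_loci = intervening, distance_bp = distance,
             similarity_pct = similarity_pct)
  ok <- intervening <= max_intervening && distance <= max_distance &&
    similarity_pct >= min_similarity
  if (!ok) {
    ev$reason <- if (intervening > max_intervening) "too_many_intervening_loci"
    else if (distance > max_distance) "too_distant"
    else "similarity_below_threshold"
  }
  list(is_tandem = ok, evidence = ev)
}

locus_in_interval <- function(locus, chrom, start, end) {
  locus$chrom_label == chrom && locus$start >= start && locus$end <= end
}

#' Type a paralogous pair as segmental (W), tandem (T) or other (O)
#'
#' W: both genes lie fully inside the two sides (either orientation) of
#' a single duplicated block pair. Failing that, T by the tandem rule of
#' [is_tandem()]; everything else is O. W takes precedence over T, so a
#' tandem-looking pair inside a homologous block pair is typed W.
#'
#' @param gene1,gene2 Gene identifiers.
#' @param loci Locus table as from [read_locus_table()].
#' @param blocks Block table as from [read_block_table()], or `NULL`
#'   when no block annotation is available.
#' @param similarity_pct Protein similarity of the pair (percent).
#' @param ... Passed on to [is_tandem()] (rule thresholds).
#' @return A list (`paralog_pair`) with `gene1`, `gene2`,
#'   `duplication_type` (`"W"`, `"T"` or `"O"`), `block_pair_id`
#'   (or `NA`) and `tandem_evidence`.
#' @export
assign_duplication_type <- function(gene1, gene2, loci, blocks = NULL,
                                    similarity_pct = NA_real_, ...) {
  for (g in c(gene1, gene2)) {
    if (!(g %in% loci$gene_id)) stop("gene absent from locus table: ", g)
  }
  l1 <- as.list(loci[loci$gene_id == gene1, ])
  l2 <- as.list(loci[loci$gene_id == gene2, ])
  block_id <- NA_character_
  if (!is.null(blocks) && nrow(blocks) > 0L) {
    for (k in seq_len(nrow(blocks))) {
      blk <- blocks[k, ]
      fwd <- locus_in_interval(l1, blk$chrom_a, blk$start_a, blk$end_a) &&
        locus_in_interval(l2, blk$chrom_b, blk$start_b, blk$end_b)
      rev <- locus_in_interval(l2, blk$chrom_a, blk$start_a, blk$end_a) &&
        locus_in_interval(l1, blk$chrom_b, blk$start_b, blk$end_b)
      if (fwd || rev) { block_id <- blk$block_id; break }
    }
  }
  tandem <- is_tandem(l1, l2, similarity_pct = similarity_pct, ...)
  type <- if (!is.na(block_id)) "W" else if (tandem$is_tandem) "T" else "O"
  structure(list(gene1 = gene1, gene2 = gene2, duplication_type = type,
                 block_pair_id = block_id,
                 tandem_evidence = tandem$evidence),
            class = "paralog_pair")
}

#' Summarize duplication types across paralogous pairs
#'
#' @param pairs Either a character vector of `"W"`/`"T"`/`"O"` labels or
#'   a list of `paralog_pair` objects.
#' @return A `data.frame` with one row per type: `type`, `count`, `pct`
#'   (percentage of all pairs, one decimal).
#' @export
summarize_duplication <- function(pairs) {
  types <- if (is.character(pairs)) {
    pairs
  } else {
    vapply(pairs, function(p) p$duplication_type, character(1))
  }
  if (length(types) == 0L) stop("no pairs supplied")
  if (!all(types %in% c("W", "T", "O"))) {
    stop("duplication types must be W, T or O")
  }
  counts <- vapply(c("W", "T", "O"), function(t) sum(types == t), integer(1))
  data.frame(type = names(counts), count = unname(counts),
             pct = round(100 * unname(counts) / length(types), 1L),
             stringsAsFactors = FALSE)
}
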