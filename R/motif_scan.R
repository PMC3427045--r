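#' Scanner configuration for CCCH motifs
#'
#' Spacer ranges for the C-X(m)-C-X(n)-C-X(p)-H geometry. The defaults
#' cover both conventional classes, (7,5,3) and (8,5,3), and the
#' non-conventional classes reported in plant CCCH families: m from 4 to
#' 15, n from 4 to 6, p fixed at 3 (every named class ends C-X3-H; the
#' range is configurable for generality).
#'
#' @param m_range,n_range,p_range Integer vectors `c(lo, hi)`; bounds are
#'   inclusive and must be >= 1.
#' @param overlap_policy `"greedy_nonoverlap"` (left-to-right sweep,
#'   smallest span wins, span consumed) or `"all_matches"` (every
#'   geometric match, overlapping or not).
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(m_range = c(4L, 15L), n_range = c(4L, 6L),
                        p_range = c(3L, 3L),
                        overlap_policy = c("greedy_nonoverlap", "all_matches")) {
  overlap_policy <- match.arg(overlap_policy)
  for (r in list(m_range, n_range, p_range)) {
    if (length(r) != 2L || any(r < 1L) || r[1] > r[2]) {
      stop("spacer ranges must be c(lo, hi) with 1 <= lo <= hi")
    }
  }
  structure(list(m_range = as.integer(m_range),
                 n_range = as.integer(n_range),
                 p_range = as.integer(p_range),
                 overlap_policy = overlap_policy),
            class = "scan_config")
}

#' Scan a protein sequence for CCCH zinc-finger motifs
#'
#' Finds occurrences of the C-X(m)-C-X(n)-C-X(p)-H geometry, where the
#' spacer residues X are unrestricted (any amino acid, including C and
#' H). Under the default greedy policy the sequence is swept left to
#' right; at each cysteine all in-range geometries are considered, the
#' candidate with the smallest span (ties: smallest m) is accepted, its
#' span is consumed, and the sweep continues after it, so reported
#' motifs never overlap. Under `all_matches` every geometric match is
#' returned.
#'
#' @param seq A protein sequence (single string, uppercase).
#' @param config A [scan_config()].
#' @param protein_id Optional identifier stored in the annotation.
#' @return An object of class `motif_annotation`: a list with
#'   `protein_id`, `motifs` (data.frame with 0-based `start`, `m`, `n`,
#'   `p`, `label`, `conventional`, sorted by `start`) and
#'   `counts_by_label` (named integer vector).
#' @examples
#' scan_ccch("MCAAAAAAACAAAAACAAAHGG")  # one conventional (7,5,3) motif
#' @export
scan_ccch <- function(seq, config = scan_config(), protein_id = NA_character_) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty sequence")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% AA_ALPHABET_X))
  if (length(bad) > 0L) {
    stop("illegal residue '", chars[bad[1]], "' at position ", bad[1])
  }
  geoms <- expand.grid(
    m = seq.int(config$m_range[1], config$m_range[2]),
    n = seq.int(config$n_range[1], config$n_range[2]),
    p = seq.int(config$p_range[1], config$p_range[2])
  )
  geoms$span <- geoms$m + geoms$n + geoms$p + 4L
  # greedy preference: smallest span, then smallest m
  geoms <- geoms[order(geoms$span, geoms$m, geoms$n), , drop = FALSE]
  L <- length(chars)
  hits <- list()
  greedy <- config$overlap_policy == "greedy_nonoverlap"
  i <- 1L
  while (i <= L) {
    if (chars[i] != "C") { i <- i + 1L; next }
    found_any <- FALSE
    for (g in seq_len(nrow(geoms))) {
      m <- geoms$m[g]; n <- geoms$n[g]; p <- geoms$p[g]
      hpos <- i + 3L + m + n + p
      if (hpos > L) next
      if (chars[i + 1L + m] == "C" && chars[i + 2L + m + n] == "C" &&
          chars[hpos] == "H") {
        hits[[length(hits) + 1L]] <- c(start = i - 1L, m = m, n = n, p = p)
        found_any <- TRUE
        if (greedy) break
      }
    }
    if (greedy && found_any) {
      last <- hits[[length(hits)]]
      i <- i + last[["m"]] + last[["n"]] + last[["p"]] + 4L
    } else {
      i <- i + 1L
    }
  }
  motifs <- if (length(hits) == 0L) {
    data.frame(start = integer(), m = integer(), n = integer(),
               p = integer(), label = character(),
               conventional = logical(), stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(do.call(rbind, hits))
    cls <- classify_motif(df$m, df$n, df$p)
    df$label <- cls$label
    df$conventional <- cls$conventional
    df[order(df$start), , drop = FALSE]
  }
  rownames(motifs) <- NULL
  counts <- if (nrow(motifs) > 0L) {
    tab <- table(motifs$label)
    setNames(as.integer(tab), names(tab))
  } else {
    integer()
  }
  structure(list(protein_id = protein_id, motifs = motifs,
                 counts_by_label = counts),
            class = "motif_annotation")
}

#' @export
print.motif_annotation <- function(x, ...) {
  cat("CCCH motif annotation", if (!is.na(x$protein_id)) x$protein_id else "",
      "-", nrow(x$motifs), "motif(s)\n")
  if (nrow(x$motifs) > 0L) print(x$motifs)
  invisible(x)
}

# (m, n, p) spacings reported in the Populus CCCH family; (10,5,3) is the
# non-conventional class reported in Arabidopsis/rice but absent from Populus
POPULUS_MOTIF_CLASSES <- rbind(
  c(7, 5, 3), c(8, 5, 3),                       # conventional
  c(5, 4, 3), c(7, 4, 3), c(8, 4, 3),           # C-X{5,7,8}-C-X4-C-X3-H
  c(8, 6, 3),                                   # C-X8-C-X6-C-X3-H
  c(9, 5, 3), c(11, 5, 3),                      # C-X{9,11}-C-X5-C-X3-H
  c(11, 6, 3)                                   # unique to Populus
)

#' Classify a CCCH motif geometry
#'
#' @param m,n,p Integer spacer lengths (vectorized).
#' @param populus_catalogue Matrix of (m, n, p) rows regarded as observed
#'   in the *Populus* family; defaults to the classes reported for the
#'   91-member survey.
#' @return A `data.frame` with columns `label` (canonical
#'   `"C-Xm-C-Xn-C-Xp-H"` string), `conventional` (`(7,5,3)` or
#'   `(8,5,3)`), `known_in_populus`, and `absent_in_populus` (`TRUE` for
#'   `(10,5,3)`, the class never observed in *Populus*).
#' @export
classify_motif <- function(m, n, p,
                           populus_catalogue = POPULUS_MOTIF_CLASSES) {
  stopifnot(length(m) == length(n), length(n) == length(p))
  label <- sprintf("C-X%d-C-X%d-C-X%d-H", m, n, p)
  key <- paste(m, n, p)
  conventional <- key %in% c("7 5 3", "8 5 3")
  known <- key %in% apply(populus_catalogue, 1L, paste, collapse = " ")
  absent <- key == "10 5 3"
  data.frame(label = label, conventional = conventional,
             known_in_populus = known, absent_in_populus = absent,
             stringsAsFactors = FALSE)
}

#' Summarize CCCH motif content across a protein family
#'
#' @param annotations Either a list of `motif_annotation` objects or a
#'   (optionally named) integer vector of per-protein motif counts (the
#'   form available when only a published census is at hand).
#' @param k Motif-count threshold for the reported fraction
#'   (default 2, i.e. "proteins with at least two motifs").
#' @return A list with `per_protein` (data.frame `protein_id`,
#'   `n_motifs`), `class_totals` (named integer vector, empty when only
#'   counts were supplied), `n_proteins`, `total_motifs`, and
#'   `pct_at_least_k` (percentage, one decimal).
#' @export
summarize_motifs <- function(annotations, k = 2L) {
  if (is.numeric(annotations)) {
    counts <- as.integer(annotations)
    ids <- names(annotations) %||% paste0("protein", seq_along(counts))
    class_totals <- integer()
  } else {
    stopifnot(is.list(annotations), length(annotations) > 0L)
    counts <- vapply(annotations, function(a) nrow(a$motifs), integer(1))
    ids <- vapply(annotations, function(a) a$protein_id, character(1))
    ids[is.na(ids)] <- paste0("protein", which(is.na(ids)))
    all_labels <- unlist(lapply(annotations, function(a) a$motifs$label))
    class_totals <- if (length(all_labels) > 0L) {
      tab <- table(all_labels)
      setNames(as.integer(tab), names(tab))
    } else {
      integer()
    }
  }
  if (length(counts) == 0L) stop("no annotations supplied")
  list(per_protein = data.frame(protein_id = ids, n_motifs = counts,
                                stringsAsFactors = FALSE),
       class_totals = class_totals,
       n_proteins = length(counts),
       total_motifs = sum(counts),
       pct_at_least_k = round(100 * mean(counts >= k), 1L))
}
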