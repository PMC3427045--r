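#' Collapse probe-level expression to gene level
#'
#' Genes with several probe sets receive the per-sample median across
#' their probes; genes sharing one probe set receive identical rows
#' (they are treated as having the same transcriptional profile).
#' Probes absent from the map are dropped with a warning.
#'
#' @param probe_matrix Numeric matrix, probes x samples, probe ids as
#'   row names.
#' @param probe_map `data.frame` with columns `probe_id`, `gene_id`.
#' @return Numeric matrix, genes x samples.
#' @export
collapse_probes <- function(probe_matrix, probe_map) {
  stopifnot(is.matrix(probe_matrix),
            all(c("probe_id", "gene_id") %in% names(probe_map)))
  unmapped <- setdiff(rownames(probe_matrix), probe_map$probe_id)
  if (length(unmapped) > 0L) {
    warning("dropping ", length(unmapped), " unmapped probe(s)")
  }
  map <- probe_map[probe_map$probe_id %in% rownames(probe_matrix), ]
  genes <- unique(map$gene_id)
  out <- matrix(NA_real_, length(genes), ncol(probe_matrix),
                dimnames = list(genes, colnames(probe_matrix)))
  for (g in genes) {
    probes <- map$probe_id[map$gene_id == g]
    out[g, ] <- apply(probe_matrix[probes, , drop = FALSE], 2L, median)
  }
  out
}

#' Gene-wise normalization (row z-scores)
#'
#' Each row is centred and scaled to unit sample standard deviation
#' (n - 1). Constant rows become all-zero with a message.
#'
#' @param matrix Numeric matrix, genes x samples (>= 2 samples).
#' @return Matrix of the same shape.
#' @export
genewise_normalize <- function(matrix) {
  stopifnot(is.matrix(matrix))
  if (ncol(matrix) < 2L) stop("need at least two samples to normalize")
  means <- rowMeans(matrix)
  sds <- apply(matrix, 1L, sd)
  flat <- sds == 0
  if (any(flat)) {
    message(sum(flat), " constant row(s) set to zero")
    sds[flat] <- 1
  }
  out <- (matrix - means) / sds
  out[flat, ] <- 0
  out
}

#' Hierarchical clustering of gene expression profiles
#'
#' Agglomerative clustering on the distance 1 - Pearson r with average
#' linkage (UPGMA), via [stats::hclust()]. Degenerate (zero-variance)
#' rows are excluded with a warning.
#'
#' @param matrix Numeric matrix, genes x samples (>= 2 genes).
#' @return An `hclust` object (merge order and heights).
#' @export
cluster_genes <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) >= 2L)
  sds <- apply(matrix, 1L, sd)
  if (any(sds == 0)) {
    warning("excluding ", sum(sds == 0), " degenerate row(s) from clustering")
    matrix <- matrix[sds > 0, , drop = FALSE]
  }
  if (nrow(matrix) < 2L) stop("fewer than two non-degenerate rows")
  d <- as.dist(1 - cor(t(matrix)))
  hclust(d, method = "average")
}

#' Per-gene expressed-tissue sets
#'
#' A sample label belongs to a gene's expressed set when its gene-wise
#' normalized value exceeds `tau`; the default `tau = 0` reads as
#' "above the gene's own mean". The matrix must already be gene-wise
#' normalized.
#'
#' @param matrix Normalized numeric matrix, genes x samples, with
#'   sample labels as column names.
#' @param tau Threshold on normalized values (default 0).
#' @return Named list of character vectors (one per gene).
#' @export
expressed_sets <- function(matrix, tau = 0) {
  stopifnot(is.matrix(matrix), !is.null(colnames(matrix)))
  labels <- colnames(matrix)
  sets <- apply(matrix, 1L, function(x) labels[x > tau], simplify = FALSE)
  lapply(sets, as.character)
}

#' Categorize the expression divergence of a paralog pair
#'
#' The four categories are set relations between the two expressed-
#' tissue sets: 1 non-overlapping (disjoint, not both empty),
#' 2 identical, 3 one a proper subset of the other, 4 partial overlap
#' (shared members plus mutual exclusive members). Two empty sets are
#' category 2 with a note.
#'
#' @param setA,setB Character vectors of sample labels from the same
#'   label universe.
#' @return A list with `category` (integer 1-4), `sets` (list of the
#'   two inputs), `subset_direction` (for category 3: `"A_in_B"` or
#'   `"B_in_A"`, else `NA`) and `note`.
#' @export
categorize_pair <- function(setA, setB) {
  setA <- unique(as.character(setA))
  setB <- unique(as.character(setB))
  shared <- intersect(setA, setB)
  note <- ""
  if (length(setA) == 0L && length(setB) == 0L) {
    category <- 2L
    note <- "both sets empty"
  } else if (length(shared) == 0L) {
    category <- 1L
  } else if (setequal(setA, setB)) {
    category <- 2L
  } else if (all(setA %in% setB) || all(setB %in% setA)) {
    category <- 3L
  } else {
    category <- 4L
  }
  direction <- if (category == 3L) {
    if (all(setA %in% setB)) "A_in_B" else "B_in_A"
  } else {
    NA_character_
  }
  list(category = category, sets = list(setA, setB),
       subset_direction = direction, note = note)
}

#' Tissue of highest expression per gene
#'
#' @param matrix Numeric matrix, genes x samples, sample labels as
#'   column names. Ties are broken by column order (first label wins)
#'   with a message.
#' @return Named character vector of sample labels.
#' @export
highest_tissue <- function(matrix) {
  stopifnot(is.matrix(matrix), !is.null(colnames(matrix)))
  ties <- apply(matrix, 1L, function(x) sum(x == max(x)) > 1L)
  if (any(ties)) {
    message(sum(ties), " row(s) with tied maxima; first label kept")
  }
  idx <- apply(matrix, 1L, which.max)
  setNames(colnames(matrix)[idx], rownames(matrix))
}

#' Reference-gene-relative expression from qPCR cycle thresholds
#'
#' The delta-Ct quantity `2^-(ct_target - ct_reference)`: the fold
#' abundance of the target transcript relative to the reference gene
#' in the same sample.
#'
#' @param ct_target,ct_reference Cycle-threshold values (> 0;
#'   vectorized).
#' @return Numeric fold values.
#' @examples
#' relative_expression(25, 20)  # 2^-5 = 0.03125
#' @export
relative_expression <- function(ct_target, ct_reference) {
  stopifnot(all(ct_target > 0), all(ct_reference > 0))
  2^(-(ct_target - ct_reference))
}
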