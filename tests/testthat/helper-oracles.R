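# Independent oracles used to validate the package implementations.
# Each is deliberately written against a different mechanism than the
# code it checks (regex engine, exhaustive enumeration, naive
# recomputation) so agreement is evidence, not tautology.

# --- CCCH motif scanning -------------------------------------------------

# every (start, m, n, p) geometric match, by direct position checks
brute_force_ccch_all <- function(seq, m_range = c(4L, 15L),
                                 n_range = c(4L, 6L), p_range = c(3L, 3L)) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  out <- list()
  for (start in seq_len(L)) {
    for (m in m_range[1]:m_range[2]) {
      for (n in n_range[1]:n_range[2]) {
        for (p in p_range[1]:p_range[2]) {
          i2 <- start + 1L + m; i3 <- start + 2L + m + n
          ih <- start + 3L + m + n + p
          if (ih <= L && chars[start] == "C" && chars[i2] == "C" &&
              chars[i3] == "C" && chars[ih] == "H") {
            out[[length(out) + 1L]] <- c(start = start - 1L, m = m, n = n, p = p)
          }
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), m = integer(),
                      n = integer(), p = integer()))
  }
  as.data.frame(do.call(rbind, out))
}

# leftmost / smallest-span / consume sweep over the full candidate list
brute_force_ccch_greedy <- function(seq, ...) {
  cand <- brute_force_ccch_all(seq, ...)
  cand$span <- cand$m + cand$n + cand$p + 4L
  kept <- list()
  pos <- 0L  # 0-based: next allowed start
  repeat {
    live <- cand[cand$start >= pos, , drop = FALSE]
    if (nrow(live) == 0L) break
    live <- live[live$start == min(live$start), , drop = FALSE]
    live <- live[order(live$span, live$m), , drop = FALSE]
    pick <- live[1L, ]
    kept[[length(kept) + 1L]] <- pick
    pos <- pick$start + pick$span
  }
  if (length(kept) == 0L) {
    return(data.frame(start = integer(), m = integer(),
                      n = integer(), p = integer()))
  }
  df <- do.call(rbind, kept)
  rownames(df) <- NULL
  df[, c("start", "m", "n", "p")]
}

random_protein <- function(n, alphabet = c("A", "C", "D", "E", "G", "H",
                                           "K", "L", "S", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --- NES consensus -------------------------------------------------------

# match starts via the PCRE engine and a lookahead (finds overlapping
# matches), 0-based
nes_starts_regex <- function(seq) {
  hits <- gregexpr("(?=[LV].{2,3}[LIVFM].{2,3}L.[LIMTKD])", seq, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
}

# --- alignment -----------------------------------------------------------

toy_matrix <- function(match = 2, mismatch = -1,
                       alphabet = c("A", "C", "G", "T")) {
  m <- matrix(mismatch, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  diag(m) <- match
  m
}

# all global alignments of a vs b as column sequences, scored with
# affine gaps costing open + L * extend per maximal gap run
enumerate_global_score <- function(a, b, matrix, gap_open, gap_extend) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  best <- -Inf
  score_cols <- function(cols_a, cols_b) {
    s <- 0
    run <- 0L; run_side <- ""
    flush <- function(s, run) if (run > 0L) s - (gap_open + gap_extend * run) else s
    for (k in seq_along(cols_a)) {
      ga <- cols_a[k] == "-"; gb <- cols_b[k] == "-"
      side <- if (ga) "a" else if (gb) "b" else ""
      if (side == "") {
        s <- flush(s, run); run <- 0L; run_side <- ""
        s <- s + matrix[cols_a[k], cols_b[k]]
      } else if (side == run_side) {
        run <- run + 1L
      } else {
        s <- flush(s, run); run <- 1L; run_side <- side
      }
    }
    flush(s, run)
  }
  recurse <- function(i, j, cols_a, cols_b) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score_cols(cols_a, cols_b))
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      recurse(i + 1L, j + 1L, c(cols_a, av[i]), c(cols_b, bv[j]))
    }
    if (i <= length(av)) recurse(i + 1L, j, c(cols_a, av[i]), c(cols_b, "-"))
    if (j <= length(bv)) recurse(i, j + 1L, c(cols_a, "-"), c(cols_b, bv[j]))
  }
  recurse(1L, 1L, character(0), character(0))
  best
}

# best local score: max over all substring pairs of their best global
# alignment, floored at the empty alignment (0)
enumerate_local_score <- function(a, b, matrix, gap_open, gap_extend) {
  best <- 0
  for (i1 in seq_len(nchar(a))) for (i2 in i1:nchar(a)) {
    for (j1 in seq_len(nchar(b))) for (j2 in j1:nchar(b)) {
      s <- enumerate_global_score(substr(a, i1, i2), substr(b, j1, j2),
                                  matrix, gap_open, gap_extend)
      best <- max(best, s)
    }
  }
  best
}

# --- NG86 site counts ----------------------------------------------------

# synonymous-site count of one codon by explicit mutant enumeration,
# structured differently from the package version (expand.grid over all
# nine mutants at once)
oracle_syn_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  chars <- strsplit(codon, "", fixed = TRUE)[[1]]
  grid <- expand.grid(pos = 1:3, alt = c("A", "C", "G", "T"),
                      stringsAsFactors = FALSE)
  grid <- grid[apply(grid, 1L, function(r) chars[as.integer(r["pos"])] != r["alt"]), ]
  grid$mut <- apply(grid, 1L, function(r) {
    x <- chars; x[as.integer(r["pos"])] <- r["alt"]; paste(x, collapse = "")
  })
  grid$aa <- gc[grid$mut]
  grid <- grid[grid$aa != "*", ]
  s <- 0
  for (pos in 1:3) {
    sub <- grid[grid$pos == pos, ]
    if (nrow(sub) > 0L) s <- s + sum(sub$aa == gc[codon]) / nrow(sub)
  }
  s
}

# --- average-linkage clustering ------------------------------------------

# naive UPGMA: recompute every between-cluster average distance (over
# the original pairwise matrix) at each step; returns merge heights and
# the leaf set created by each merge
naive_upgma <- function(mat) {
  d <- 1 - cor(t(mat))
  clusters <- as.list(seq_len(nrow(mat)))
  heights <- numeric(0)
  members <- list()
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        if (avg < best[1]) best <- c(avg, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    merged <- sort(c(clusters[[i]], clusters[[j]]))
    heights <- c(heights, best[1])
    members[[length(members) + 1L]] <- merged
    clusters <- c(clusters[-c(i, j)], list(merged))
  }
  list(heights = heights, members = members)
}

# leaf sets created by each hclust merge, in merge order
hclust_members <- function(hc) {
  sets <- list()
  out <- list()
  for (k in seq_len(nrow(hc$merge))) {
    get <- function(x) if (x < 0) -x else sets[[x]]
    sets[[k]] <- sort(c(get(hc$merge[k, 1]), get(hc$merge[k, 2])))
    out[[k]] <- sets[[k]]
  }
  out
}

# --- misc ----------------------------------------------------------------

codon_frame <- function(seq_a, seq_b) {
  n <- nchar(seq_a)
  data.frame(
    codon_a = substring(seq_a, seq(1L, n, 3L), seq(3L, n, 3L)),
    codon_b = substring(seq_b, seq(1L, n, 3L), seq(3L, n, 3L)),
    stringsAsFactors = FALSE)
}

make_annotation <- function(mnps, protein_id = "p1") {
  starts <- cumsum(c(0, vapply(mnps, function(x) sum(x) + 5,
                               numeric(1))))[seq_along(mnps)]
  df <- data.frame(start = as.integer(starts),
                   m = vapply(mnps, function(x) as.integer(x[1]), integer(1)),
                   n = vapply(mnps, function(x) as.integer(x[2]), integer(1)),
                   p = vapply(mnps, function(x) as.integer(x[3]), integer(1)))
  cls <- classify_motif(df$m, df$n, df$p)
  df$label <- cls$label
  df$conventional <- cls$conventional
  tab <- table(df$label)
  structure(list(protein_id = protein_id, motifs = df,
                 counts_by_label = stats::setNames(as.integer(tab), names(tab))),
            class = "motif_annotation")
}
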