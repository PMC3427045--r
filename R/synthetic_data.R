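# Background alphabet for synthetic proteins: no C or H (so planted
# motifs are the only CCCH-geometry matches) and no L or V (the NES
# consensus needs [LV] at its first slot and a literal L later, so
# planted NES instances are the only matches, at their exact starts).
AA_BG <- setdiff(AA20, c("C", "H", "L", "V"))
# x-spacer alphabet for NES instantiation: additionally avoids every
# class residue of the consensus slots, so a planted NES matches at
# exactly one start position
NES_X <- setdiff(AA_BG, c("V", "I", "F", "M", "T", "K", "D"))

default_motif_spec <- function() {
  list(classes = list(c(7L, 5L, 3L), c(8L, 5L, 3L),
                      c(5L, 4L, 3L), c(8L, 6L, 3L)),
       weights = c(0.4, 0.4, 0.1, 0.1),
       copy_range = 1:3)
}

# sample one element of a vector, immune to R's sample(n, 1) scalar trap
pick1 <- function(x) x[sample.int(length(x), 1L)]

bg_run <- function(n) {
  if (n <= 0L) return("")
  paste(sample(AA_BG, n, replace = TRUE), collapse = "")
}

motif_instance <- function(mnp) {
  paste0("C", bg_run(mnp[1]), "C", bg_run(mnp[2]), "C", bg_run(mnp[3]), "H")
}

nes_instance <- function() {
  paste0("L", paste(sample(NES_X, 2L, TRUE), collapse = ""),
         "M", paste(sample(NES_X, 2L, TRUE), collapse = ""),
         "L", sample(NES_X, 1L), "K")
}

#' Generate a synthetic proteome with planted features
#'
#' Builds proteins over a background alphabet that excludes C, H and L,
#' so every CCCH-geometry match and every NES match in the output is a
#' planted one (recall and precision against the returned truth are
#' exactly 1 for the default scanners). Planted features are separated
#' by at least one background residue.
#'
#' @param n_proteins Number of proteins.
#' @param motif_spec List with `classes` (list of `(m, n, p)` vectors),
#'   `weights` (sampling weights) and `copy_range` (motif copies per
#'   protein); see `default_motif_spec()` for the default mixture.
#' @param nes_rate,tzf_rate Per-protein probabilities of planting one
#'   NES instance / a TZF architecture (two (8,5,3) motifs separated by
#'   `tzf_spacing` residues). TZF proteins carry exactly the two TZF
#'   motifs.
#' @param length_range Protein length bounds; proteins whose features
#'   do not fit are extended to the minimum feasible length, and an
#'   error is raised if even `max(length_range)` cannot hold them.
#' @param tzf_spacing Residues between the H of the first TZF motif and
#'   the first C of the second (default 18).
#' @param seed Integer seed; identical `(arguments, seed)` give
#'   byte-identical output.
#' @return A list with `records` (data.frame `id`, `desc`, `seq`) and
#'   `truth` (list of data.frames: `motifs` with 0-based `start` and
#'   `m`, `n`, `p`; `nes` with 0-based `start`; `tzf` with `is_tzf`).
#' @export
gen_proteome <- function(n_proteins = 30L, motif_spec = default_motif_spec(),
                         nes_rate = 0.3, tzf_rate = 0.1,
                         length_range = c(150L, 400L),
                         tzf_spacing = 18L, seed = 1L) {
  with_seed(seed, {
    records <- vector("list", n_proteins)
    motif_truth <- list(); nes_truth <- list(); tzf_truth <- list()
    for (pi in seq_len(n_proteins)) {
      id <- sprintf("syn%03d", pi)
      is_tzf <- runif(1) < tzf_rate
      has_nes <- runif(1) < nes_rate
      feats <- list()
      if (is_tzf) {
        span853 <- 8L + 5L + 3L + 4L
        feats[[1]] <- list(kind = "tzf",
                          text = paste0(motif_instance(c(8L, 5L, 3L)),
                                        bg_run(tzf_spacing),
                                        motif_instance(c(8L, 5L, 3L))),
                          spans = c(span853, tzf_spacing, span853))
      } else {
        n_copies <- pick1(motif_spec$copy_range)
        picks <- sample(seq_along(motif_spec$classes), n_copies,
                        replace = TRUE, prob = motif_spec$weights)
        for (cls in picks) {
          mnp <- motif_spec$classes[[cls]]
          feats[[length(feats) + 1L]] <- list(kind = "motif", mnp = mnp,
                                              text = motif_instance(mnp))
        }
      }
      if (has_nes) {
        feats[[length(feats) + 1L]] <- list(kind = "nes",
                                            text = nes_instance())
      }
      feats <- feats[sample(seq_along(feats))]
      flens <- vapply(feats, function(f) nchar(f$text), integer(1))
      nf <- length(feats)
      need <- sum(flens) + (nf - 1L)  # >= 1 background residue between
      L <- pick1(seq.int(length_range[1], length_range[2]))
      if (need > length_range[2]) {
        stop("planted features (", need, " residues) exceed max length ",
             length_range[2])
      }
      L <- max(L, need)
      slack <- L - sum(flens) - (nf - 1L)
      parts <- as.vector(stats::rmultinom(1L, slack, rep(1, nf + 1L)))
      gaps <- parts + c(0L, rep(1L, nf - 1L), 0L)
      pos <- 0L  # 0-based cursor
      pieces <- character(0)
      for (k in seq_len(nf)) {
        pieces <- c(pieces, bg_run(gaps[k]))
        pos <- pos + gaps[k]
        f <- feats[[k]]
        if (f$kind == "motif") {
          motif_truth[[length(motif_truth) + 1L]] <- data.frame(
            protein_id = id, start = pos,
            m = f$mnp[1], n = f$mnp[2], p = f$mnp[3])
        } else if (f$kind == "tzf") {
          motif_truth[[length(motif_truth) + 1L]] <- data.frame(
            protein_id = id, start = pos, m = 8L, n = 5L, p = 3L)
          motif_truth[[length(motif_truth) + 1L]] <- data.frame(
            protein_id = id, start = pos + f$spans[1] + f$spans[2],
            m = 8L, n = 5L, p = 3L)
        } else {
          nes_truth[[length(nes_truth) + 1L]] <- data.frame(
            protein_id = id, start = pos)
        }
        pieces <- c(pieces, f$text)
        pos <- pos + nchar(f$text)
      }
      pieces <- c(pieces, bg_run(gaps[nf + 1L]))
      tzf_truth[[length(tzf_truth) + 1L]] <- data.frame(
        protein_id = id, is_tzf = is_tzf)
      records[[pi]] <- data.frame(id = id, desc = "",
                                  seq = paste(pieces, collapse = ""),
                                  stringsAsFactors = FALSE)
    }
    empty <- function(cols) {
      do.call(data.frame, c(cols, stringsAsFactors = FALSE))
    }
    list(records = do.call(rbind, records),
         truth = list(
           motifs = if (length(motif_truth)) do.call(rbind, motif_truth)
                    else empty(list(protein_id = character(), start = integer(),
                                    m = integer(), n = integer(), p = integer())),
           nes = if (length(nes_truth)) do.call(rbind, nes_truth)
                 else empty(list(protein_id = character(), start = integer())),
           tzf = do.call(rbind, tzf_truth)))
  })
}

#' Generate a synthetic gene map with planted duplication structure
#'
#' Lays out genes along chromosomes with large inter-gene distances,
#' then plants tandem arrays (consecutive loci a few tens of kb apart,
#' satisfying the <= 5-intervening-loci / <= 100 kb tandem rule),
#' homologous block pairs containing matched segmental (W) gene pairs,
#' and cross-chromosome "other" (O) pairs outside any block.
#'
#' @param n_chrom Number of chromosomes (>= 2).
#' @param genes_per_chrom Genes per chromosome.
#' @param tandem_arrays Number of planted tandem arrays.
#' @param array_size Genes per tandem array.
#' @param block_pairs Number of planted homologous block pairs.
#' @param genes_per_block W gene pairs per block pair.
#' @param o_pairs Number of planted O pairs.
#' @param seed Integer seed.
#' @return A list with `loci` (locus table), `blocks` (block table) and
#'   `truth` (list with `pairs`: data.frame `gene1`, `gene2`, `type`).
#' @export
gen_gene_map <- function(n_chrom = 3L, genes_per_chrom = 20L,
                         tandem_arrays = 2L, array_size = 3L,
                         block_pairs = 2L, genes_per_block = 4L,
                         o_pairs = 2L, seed = 1L) {
  stopifnot(n_chrom >= 2L)
  with_seed(seed, {
    chroms <- sprintf("chr%02d", seq_len(n_chrom))
    avail <- lapply(seq_len(n_chrom), function(i) rep(TRUE, genes_per_chrom))
    claim_run <- function(ci, len) {
      free <- avail[[ci]]
      # starts of free runs of the requested length
      ok <- vapply(seq_len(genes_per_chrom - len + 1L),
                   function(s) all(free[s:(s + len - 1L)]), logical(1))
      if (!any(ok)) stop("cannot place a run of ", len, " genes on ",
                         chroms[ci], "; increase genes_per_chrom")
      s <- pick1(which(ok))
      avail[[ci]][s:(s + len - 1L)] <<- FALSE
      s:(s + len - 1L)
    }
    gene_id <- function(ci, k) sprintf("g_%s_%03d", chroms[ci], k)
    small_gap <- function() sample(10000:30000, 1L)
    big_gap <- function() sample(150000:300000, 1L)

    arrays <- list()
    for (k in seq_len(tandem_arrays)) {
      ci <- ((k - 1L) %% n_chrom) + 1L
      arrays[[k]] <- list(chrom = ci, idx = claim_run(ci, array_size))
    }
    blocks_plan <- list()
    for (k in seq_len(block_pairs)) {
      ca <- ((k - 1L) %% n_chrom) + 1L
      cb <- (k %% n_chrom) + 1L
      blocks_plan[[k]] <- list(chrom_a = ca, idx_a = claim_run(ca, genes_per_block),
                               chrom_b = cb, idx_b = claim_run(cb, genes_per_block))
    }
    o_plan <- list()
    for (k in seq_len(o_pairs)) {
      ca <- ((k - 1L) %% n_chrom) + 1L
      cb <- (k %% n_chrom) + 1L
      o_plan[[k]] <- list(a = c(ca, claim_run(ca, 1L)),
                          b = c(cb, claim_run(cb, 1L)))
    }

    # which adjacent gaps are small (inside a tandem array)?
    small <- lapply(seq_len(n_chrom), function(i) rep(FALSE, genes_per_chrom))
    for (arr in arrays) {
      small[[arr$chrom]][arr$idx[-length(arr$idx)]] <- TRUE
    }
    loci <- list()
    coord <- setNames(vector("list", n_chrom), chroms)
    for (ci in seq_len(n_chrom)) {
      pos <- sample(50000:100000, 1L)
      starts <- integer(genes_per_chrom); ends <- integer(genes_per_chrom)
      for (k in seq_len(genes_per_chrom)) {
        len <- sample(2000:5000, 1L)
        starts[k] <- pos
        ends[k] <- pos + len - 1L
        gap <- if (small[[ci]][k]) small_gap() else big_gap()
        pos <- ends[k] + gap + 1L
      }
      coord[[ci]] <- list(starts = starts, ends = ends)
      loci[[ci]] <- data.frame(
        gene_id = vapply(seq_len(genes_per_chrom), function(k) gene_id(ci, k),
                         character(1)),
        chrom_label = chroms[ci], start = starts, end = ends,
        strand = sample(c("+", "-"), genes_per_chrom, replace = TRUE),
        locus_index = seq_len(genes_per_chrom),
        stringsAsFactors = FALSE)
    }
    loci <- do.call(rbind, loci)

    blocks <- list(); pairs <- list()
    for (k in seq_along(blocks_plan)) {
      bp <- blocks_plan[[k]]
      side <- function(ci, idx) {
        c(coord[[ci]]$starts[idx[1]] - 1000L,
          coord[[ci]]$ends[idx[length(idx)]] + 1000L)
      }
      sa <- side(bp$chrom_a, bp$idx_a); sb <- side(bp$chrom_b, bp$idx_b)
      blocks[[k]] <- data.frame(
        block_id = sprintf("B%02d", k),
        chrom_a = chroms[bp$chrom_a], start_a = sa[1], end_a = sa[2],
        chrom_b = chroms[bp$chrom_b], start_b = sb[1], end_b = sb[2],
        stringsAsFactors = FALSE)
      for (j in seq_len(genes_per_block)) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          gene1 = gene_id(bp$chrom_a, bp$idx_a[j]),
          gene2 = gene_id(bp$chrom_b, bp$idx_b[j]),
          type = "W", stringsAsFactors = FALSE)
      }
    }
    for (arr in arrays) {
      for (j in seq_len(length(arr$idx) - 1L)) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          gene1 = gene_id(arr$chrom, arr$idx[j]),
          gene2 = gene_id(arr$chrom, arr$idx[j + 1L]),
          type = "T", stringsAsFactors = FALSE)
      }
    }
    for (op in o_plan) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        gene1 = gene_id(op$a[1], op$a[2]),
        gene2 = gene_id(op$b[1], op$b[2]),
        type = "O", stringsAsFactors = FALSE)
    }
    list(loci = loci,
         blocks = if (length(blocks)) do.call(rbind, blocks) else NULL,
         truth = list(pairs = do.call(rbind, pairs)))
  })
}

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

#' Simulate coding-sequence pairs at a known dN/dS
#'
#' Each pair is an ancestor of random sense codons plus a derived copy
#' produced by an acceptance-thinning substitution process: random
#' single-nucleotide changes are proposed, proposals creating stop
#' codons are rejected outright, synonymous proposals are accepted with
#' probability 1 and nonsynonymous ones with probability `omega`. The
#' number of accepted substitutions per pair is Poisson with mean
#' `n_codons * expected_sub_per_codon`. This is a simple thinning
#' process, not a full codon model; its realized dN/dS matches `omega`
#' in expectation, which is what the NG86 recovery tests need.
#'
#' @param n_pairs Number of pairs.
#' @param n_codons Codons per sequence.
#' @param omega Acceptance probability for nonsynonymous proposals
#'   (> 0 allowed to be 0: all substitutions synonymous).
#' @param expected_sub_per_codon Expected accepted substitutions per
#'   codon (0 gives identical pairs).
#' @param seed Integer seed.
#' @return A list with `records` (data.frame `id`, `desc`, `seq`; ids
#'   `pairK_a`/`pairK_b`) and `truth` (data.frame `pair_id`, `omega`,
#'   `n_sub`, `syn_events`, `nonsyn_events`).
#' @export
gen_cds_pairs <- function(n_pairs = 1L, n_codons = 300L, omega = 0.3,
                          expected_sub_per_codon = 0.25, seed = 1L) {
  stopifnot(omega >= 0, expected_sub_per_codon >= 0)
  with_seed(seed, {
    gc <- genetic_code()
    sense <- sense_codons()
    records <- list(); truth <- list()
    for (k in seq_len(n_pairs)) {
      anc_cod <- sample(sense, n_codons, replace = TRUE)
      anc <- strsplit(paste(anc_cod, collapse = ""), "", fixed = TRUE)[[1]]
      der <- anc
      target <- rpois(1L, n_codons * expected_sub_per_codon)
      accepted <- 0L; syn_ev <- 0L; nonsyn_ev <- 0L
      guard <- 0L
      while (accepted < target) {
        guard <- guard + 1L
        if (guard > 1000L * (target + 10L)) {
          stop("substitution process failed to reach target count")  # nocov
        }
        pos <- sample.int(3L * n_codons, 1L)
        alt <- sample(setdiff(BASES, der[pos]), 1L)
        ci <- (pos - 1L) %/% 3L
        old_codon <- paste(der[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
        new <- der
        new[pos] <- alt
        new_codon <- paste(new[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
        if (gc[new_codon] == "*") next
        syn <- gc[new_codon] == gc[old_codon]
        if (syn || runif(1) < omega) {
          der <- new
          accepted <- accepted + 1L
          if (syn) syn_ev <- syn_ev + 1L else nonsyn_ev <- nonsyn_ev + 1L
        }
      }
      pid <- sprintf("pair%03d", k)
      records[[length(records) + 1L]] <- data.frame(
        id = paste0(pid, "_a"), desc = "",
        seq = paste(anc, collapse = ""), stringsAsFactors = FALSE)
      records[[length(records) + 1L]] <- data.frame(
        id = paste0(pid, "_b"), desc = "",
        seq = paste(der, collapse = ""), stringsAsFactors = FALSE)
      truth[[k]] <- data.frame(pair_id = pid, omega = omega,
                               n_sub = target, syn_events = syn_ev,
                               nonsyn_events = nonsyn_ev,
                               stringsAsFactors = FALSE)
    }
    list(records = do.call(rbind, records), truth = do.call(rbind, truth))
  })
}

draw_sets <- function(category, labels) {
  nL <- length(labels)
  if (category == 1L) {
    four <- sample(labels, 4L)
    list(A = four[1:2], B = four[3:4])
  } else if (category == 2L) {
    A <- sample(labels, sample(2:3, 1L))
    list(A = A, B = A)
  } else if (category == 3L) {
    A <- sample(labels, 2L)
    n_extra <- sample(seq_len(min(2L, nL - 3L)), 1L)  # keep B a proper subset of labels
    list(A = A, B = c(A, sample(setdiff(labels, A), n_extra)))
  } else if (category == 4L) {
    three <- sample(labels, 3L)
    list(A = three[1:2], B = three[c(1L, 3L)])
  } else {
    stop("category must be 1, 2, 3 or 4")
  }
}

#' Simulate paralog expression matrices with planted divergence categories
#'
#' For each planted pair a category-consistent pair of expressed-tissue
#' sets is drawn (cardinalities 2-4 out of the label universe, so the
#' above-mean rule has a comfortable margin); each gene's row is +1 on
#' its set and -1 elsewhere, plus Gaussian noise. At `noise_sd = 0` the
#' downstream normalize / threshold / categorize chain recovers the
#' planted categories exactly.
#'
#' @param pair_categories Integer vector of planted categories (1-4),
#'   one entry per pair.
#' @param labels Sample labels (>= 5 required for all four categories;
#'   default: the six-tissue panel Rt, ML, YL, FC, MC, XL).
#' @param noise_sd Gaussian noise SD relative to the unit signal.
#' @param seed Integer seed.
#' @return A list with `matrix` (genes x samples; rows `pairK_g1`,
#'   `pairK_g2`) and `truth` (data.frame `pair_id`, `gene1`, `gene2`,
#'   `category`, plus list column `sets`).
#' @export
gen_expression <- function(pair_categories = c(1L, 2L, 3L, 4L),
                           labels = c("Rt", "ML", "YL", "FC", "MC", "XL"),
                           noise_sd = 0.2, seed = 1L) {
  if (length(labels) < 5L) stop("need at least 5 labels for all categories")
  with_seed(seed, {
    rows <- list(); truth <- list()
    for (k in seq_along(pair_categories)) {
      cat_k <- pair_categories[k]
      sets <- draw_sets(cat_k, labels)
      pid <- sprintf("pair%02d", k)
      for (side in c("g1", "g2")) {
        S <- if (side == "g1") sets$A else sets$B
        signal <- ifelse(labels %in% S, 1, -1)
        rows[[paste0(pid, "_", side)]] <-
          signal + rnorm(length(labels), 0, noise_sd)
      }
      truth[[k]] <- data.frame(pair_id = pid,
                               gene1 = paste0(pid, "_g1"),
                               gene2 = paste0(pid, "_g2"),
                               category = cat_k, stringsAsFactors = FALSE)
      truth[[k]]$sets <- list(sets)
    }
    m <- do.call(rbind, rows)
    colnames(m) <- labels
    list(matrix = m, truth = do.call(rbind, truth))
  })
}
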