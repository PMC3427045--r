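NES_SLOT1 <- c("L", "V")
NES_SLOT3 <- c("L", "I", "V", "F", "M")
NES_SLOT7 <- c("L", "I", "M", "T", "K", "D")

#' Scan for leucine-rich nuclear export signals (NES)
#'
#' Matches the consensus `[LV]-x(2,3)-[LIVFM]-x(2,3)-L-x-[LIMTKD]`
#' (9-11 residues). Every match start position is reported once; when
#' both spacer widths can match at a start, the shortest instantiation
#' is recorded (ties between the two 10-residue width combinations go to
#' the one with the shorter first spacer).
#'
#' @param seq A protein sequence (single string, uppercase).
#' @return A `data.frame` with 0-based `start`, 0-based exclusive `end`,
#'   and `text` (the matched substring). Zero rows when no match.
#' @examples
#' find_nes("LAAMAALAK")  # single match at 0
#' @export
find_nes <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  # width combinations in preference order: total span, then first spacer
  widths <- list(c(2L, 2L), c(2L, 3L), c(3L, 2L), c(3L, 3L))
  out <- list()
  for (i in seq_len(L)) {
    if (!(chars[i] %in% NES_SLOT1)) next
    for (w in widths) {
      w1 <- w[1]; w2 <- w[2]
      span <- 4L + w1 + w2 + 1L  # slots 1,3,5,7 plus spacers plus slot-6 x
      end <- i + span - 1L
      if (end > L) next
      if (chars[i + w1 + 1L] %in% NES_SLOT3 &&
          chars[i + w1 + w2 + 2L] == "L" &&
          chars[end] %in% NES_SLOT7) {
        out[[length(out) + 1L]] <- data.frame(
          start = i - 1L, end = end,
          text = substr(seq, i, end), stringsAsFactors = FALSE)
        break
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      text = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Detect the tandem zinc-finger (TZF) architecture
#'
#' A TZF protein carries two identical C-X8-C-X5-C-X3-H motifs separated
#' by a fixed spacer (18 residues by default), measured as the residues
#' strictly between the H of the first motif and the first C of the
#' second. The 5 residues preceding the first motif (the "lead-in",
#' part of the RNA-binding surface in characterized TZF proteins) are
#' extracted for reporting only, never used as a filter.
#'
#' @param annotation A `motif_annotation` produced from `seq` by
#'   [scan_ccch()].
#' @param seq The protein sequence the annotation was produced from.
#' @param spacing Required spacer length (default 18).
#' @return A list with `is_tzf`, `motif1_start`, `motif2_start` (0-based,
#'   `NA` when not a TZF), `spacer_len` and `leadin`.
#' @export
detect_tzf <- function(annotation, seq, spacing = 18L) {
  stopifnot(inherits(annotation, "motif_annotation"))
  mt <- annotation$motifs
  res <- list(is_tzf = FALSE, motif1_start = NA_integer_,
              motif2_start = NA_integer_, spacer_len = NA_integer_,
              leadin = NA_character_)
  idx853 <- which(mt$m == 8L & mt$n == 5L & mt$p == 3L)
  if (length(idx853) < 2L) return(res)
  for (a in idx853) {
    for (b in idx853[idx853 > a]) {
      h_pos <- mt$start[a] + mt$m[a] + mt$n[a] + mt$p[a] + 3L  # 0-based H
      gap <- mt$start[b] - h_pos - 1L
      if (gap == spacing) {
        s1 <- mt$start[a]  # 0-based
        lead_from <- max(1L, s1 + 1L - 5L)
        res$is_tzf <- TRUE
        res$motif1_start <- s1
        res$motif2_start <- mt$start[b]
        res$spacer_len <- gap
        res$leadin <- if (s1 > 0L) substr(seq, lead_from, s1) else ""
        return(res)
      }
    }
  }
  res
}

# average (isotope-weighted) residue masses, Da
AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
             C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
             H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
             M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
             T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01524

# EMBOSS iep default pKa values
PKA <- list(nterm = 8.6, cterm = 3.6,
            pos = c(K = 10.8, R = 12.5, H = 6.5),
            neg = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1))

net_charge <- function(pH, counts) {
  pos_groups <- c(nterm = 1, counts[names(PKA$pos)])
  pos_pka <- c(PKA$nterm, PKA$pos)
  neg_groups <- c(cterm = 1, counts[names(PKA$neg)])
  neg_pka <- c(PKA$cterm, PKA$neg)
  sum(pos_groups / (1 + 10^(pH - pos_pka))) -
    sum(neg_groups / (1 + 10^(neg_pka - pH)))
}

#' Protein length, molecular weight and isoelectric point
#'
#' Molecular weight is the sum of average residue masses plus one water.
#' The isoelectric point is solved by bisection on the
#' Henderson-Hasselbalch net-charge function over the termini and the
#' ionizable side chains (D, E, C, Y, H, K, R) using the EMBOSS default
#' pKa set, to |charge| < 1e-4.
#'
#' @param seq A protein sequence (single string, uppercase, 20 standard
#'   residues).
#' @param on_x How to handle unknown residues `X`: `"error"` (default)
#'   or `"skip"` (drop them from the mass/charge computation with a
#'   warning; `length` still counts them).
#' @return A list with `length` (residues), `mol_wt` (Da) and `pi`.
#' @export
phys_chem <- function(seq, on_x = c("error", "skip")) {
  on_x <- match.arg(on_x)
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty sequence")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_res <- length(chars)
  if (any(chars == "X")) {
    if (on_x == "error") stop("sequence contains unknown residue X")
    warning("dropping ", sum(chars == "X"), " X residue(s) from mass/pI")
    chars <- chars[chars != "X"]
  }
  bad <- which(!(chars %in% AA20))
  if (length(bad) > 0L) {
    stop("illegal residue '", chars[bad[1]], "' at position ", bad[1])
  }
  mol_wt <- sum(AA_MASS[chars]) + WATER_MASS
  counts <- setNames(numeric(length(c(names(PKA$pos), names(PKA$neg)))),
                     c(names(PKA$pos), names(PKA$neg)))
  tab <- table(chars)
  counts[names(counts)] <- ifelse(names(counts) %in% names(tab),
                                  tab[names(counts)], 0)
  counts[is.na(counts)] <- 0
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(mid, counts)
    if (abs(q) < 1e-4 || (hi - lo) < 1e-9) break
    if (q > 0) lo <- mid else hi <- mid
  }
  list(length = n_res, mol_wt = unname(mol_wt), pi = mid)
}
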