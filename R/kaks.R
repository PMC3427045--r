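BASES <- c("A", "C", "G", "T")

genetic_code <- function() Biostrings::GENETIC_CODE

split_codons <- function(cds) {
  if (nchar(cds) %% 3L != 0L) stop("CDS length not divisible by 3")
  substring(cds, seq(1L, nchar(cds), by = 3L), seq(3L, nchar(cds), by = 3L))
}

translate_codons <- function(codons) {
  gc <- genetic_code()
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"  # ambiguous bases
  unname(aa)
}

#' Translate an in-frame CDS to protein
#'
#' Frame is anchored at position 1; a trailing stop codon is trimmed
#' with a message; internal stops raise an error. Codons containing
#' ambiguous bases translate to `X`.
#'
#' @param cds Nucleotide sequence over A/C/G/T/N, length divisible by 3.
#' @return The amino-acid sequence (single string).
#' @export
translate_cds <- function(cds) {
  codons <- split_codons(toupper(cds))
  aa <- translate_codons(codons)
  if (length(aa) > 0L && aa[length(aa)] == "*") {
    message("trimmed trailing stop codon")
    aa <- aa[-length(aa)]
  }
  if (any(aa == "*")) {
    stop("internal stop codon at codon ", which(aa == "*")[1])
  }
  paste(aa, collapse = "")
}

#' Thread a protein guide alignment back onto the coding sequences
#'
#' Maps each aligned residue column of a global protein alignment to the
#' corresponding codon pair. Columns with a gap on either side are
#' dropped, as are codon pairs containing stop codons or ambiguous
#' bases (counted in a message).
#'
#' @param guide An `alignment_result` from [needleman_wunsch()] whose
#'   ungapped rows equal the translations of `cds_a` and `cds_b`.
#' @param cds_a,cds_b In-frame coding sequences (trailing stop allowed).
#' @return A `codon_alignment`: data.frame with columns `codon_a`,
#'   `codon_b`, one row per retained aligned codon pair.
#' @export
thread_codons <- function(guide, cds_a, cds_b) {
  stopifnot(inherits(guide, "alignment_result"))
  cod_a <- split_codons(toupper(cds_a))
  cod_b <- split_codons(toupper(cds_b))
  # trim trailing stops
  gc <- genetic_code()
  if (length(cod_a) > 0L && !is.na(gc[cod_a[length(cod_a)]]) &&
      gc[cod_a[length(cod_a)]] == "*") cod_a <- cod_a[-length(cod_a)]
  if (length(cod_b) > 0L && !is.na(gc[cod_b[length(cod_b)]]) &&
      gc[cod_b[length(cod_b)]] == "*") cod_b <- cod_b[-length(cod_b)]
  prot_a <- gsub("-", "", guide$aligned_a, fixed = TRUE)
  prot_b <- gsub("-", "", guide$aligned_b, fixed = TRUE)
  for (side in list(list(cod = cod_a, prot = prot_a, which = "a"),
                    list(cod = cod_b, prot = prot_b, which = "b"))) {
    trans <- translate_codons(side$cod)
    ref <- strsplit(side$prot, "", fixed = TRUE)[[1]]
    if (length(trans) != length(ref)) {
      stop("cds_", side$which, " translates to ", length(trans),
           " residues but the guide row has ", length(ref))
    }
    bad <- which(trans != ref & trans != "X" & ref != "X")
    if (length(bad) > 0L) {
      stop("translation mismatch for cds_", side$which,
           " at residue ", bad[1], ": ", trans[bad[1]], " vs ", ref[bad[1]])
    }
  }
  ca <- strsplit(guide$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(guide$aligned_b, "", fixed = TRUE)[[1]]
  ia <- 0L; ib <- 0L
  pair_a <- character(0); pair_b <- character(0)
  for (k in seq_along(ca)) {
    if (ca[k] != "-") ia <- ia + 1L
    if (cb[k] != "-") ib <- ib + 1L
    if (ca[k] != "-" && cb[k] != "-") {
      pair_a <- c(pair_a, cod_a[ia])
      pair_b <- c(pair_b, cod_b[ib])
    }
  }
  clean <- grepl("^[ACGT]{3}$", pair_a) & grepl("^[ACGT]{3}$", pair_b) &
    gc[pair_a] != "*" & gc[pair_b] != "*"
  clean[is.na(clean)] <- FALSE
  if (any(!clean)) {
    message("dropped ", sum(!clean),
            " codon pair(s) with stops or ambiguous bases")
  }
  structure(data.frame(codon_a = pair_a[clean], codon_b = pair_b[clean],
                       stringsAsFactors = FALSE),
            class = c("codon_alignment", "data.frame"))
}

# per-codon synonymous site count: at each position, the fraction of the
# single-nucleotide changes (stop-codon targets excluded from the
# denominator) that preserve the amino acid; summed over positions.
# Memoized over the 61 sense codons.
.ng86_cache <- new.env(parent = emptyenv())

syn_sites <- function(codon) {
  hit <- .ng86_cache[[paste0("s_", codon)]]
  if (!is.null(hit)) return(hit)
  gc <- genetic_code()
  aa <- gc[codon]
  chars <- strsplit(codon, "", fixed = TRUE)[[1]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0L; viable <- 0L
    for (alt in setdiff(BASES, chars[pos])) {
      mutant <- chars
      mutant[pos] <- alt
      maa <- gc[paste(mutant, collapse = "")]
      if (maa == "*") next
      viable <- viable + 1L
      if (maa == aa) syn <- syn + 1L
    }
    if (viable > 0L) s <- s + syn / viable
  }
  .ng86_cache[[paste0("s_", codon)]] <- s
  s
}

# expected (syn, nonsyn) difference counts between two sense codons:
# pathways of single steps over all orderings of the differing
# positions, equally weighted; orderings passing through a stop codon
# are excluded (all orderings kept if every one hits a stop). Memoized.
codon_diffs <- function(codon_a, codon_b) {
  key <- paste0("d_", codon_a, codon_b)
  hit <- .ng86_cache[[key]]
  if (!is.null(hit)) return(hit)
  gc <- genetic_code()
  a <- strsplit(codon_a, "", fixed = TRUE)[[1]]
  b <- strsplit(codon_b, "", fixed = TRUE)[[1]]
  diff_pos <- which(a != b)
  k <- length(diff_pos)
  if (k == 0L) {
    res <- c(sd = 0, nd = 0)
  } else {
    orders <- perms(diff_pos)
    paths <- list()
    for (o in seq_len(nrow(orders))) {
      cur <- a
      sd <- 0L; nd <- 0L; hit_stop <- FALSE
      for (pos in orders[o, ]) {
        nxt <- cur
        nxt[pos] <- b[pos]
        aa_cur <- gc[paste(cur, collapse = "")]
        aa_nxt <- gc[paste(nxt, collapse = "")]
        if (aa_nxt == "*") hit_stop <- TRUE
        if (aa_cur == aa_nxt) sd <- sd + 1L else nd <- nd + 1L
        cur <- nxt
      }
      paths[[o]] <- c(sd = sd, nd = nd, ok = !hit_stop)
    }
    pm <- do.call(rbind, paths)
    keep <- if (any(pm[, "ok"] == 1)) pm[, "ok"] == 1 else rep(TRUE, nrow(pm))
    res <- c(sd = mean(pm[keep, "sd"]), nd = mean(pm[keep, "nd"]))
  }
  .ng86_cache[[key]] <- res
  res
}

perms <- function(x) {
  if (length(x) == 1L) return(matrix(x, 1L, 1L))
  out <- NULL
  for (i in seq_along(x)) {
    rest <- perms(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 3 / 4) return(NA_real_)
  -3 / 4 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori (1986) Ka/Ks estimation
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per codon by
#' enumerating the three single-nucleotide changes at each position
#' (changes producing stop codons are excluded from the averaging
#' denominator), averaging site totals over the two sequences. Observed
#' differences in multi-substitution codons are averaged over all
#' orderings of single steps with equal weight, excluding orderings
#' that pass through a stop codon. Proportions are corrected with the
#' Jukes-Cantor formula d = -(3/4) ln(1 - 4p/3); proportions >= 3/4 are
#' flagged `undefined` rather than returned as silent `NaN`.
#'
#' @param codon_alignment A `codon_alignment` from [thread_codons()], or
#'   any data.frame with columns `codon_a`, `codon_b` (sense codons).
#' @param threshold Ka/Ks value below which the pair is called
#'   `purifying` (default 0.5, the interpretation used for plant
#'   paralog surveys; the conventional neutrality threshold 1.0 can be
#'   supplied instead).
#' @return A `kaks_result` list: `S`, `N` (sites), `Sd`, `Nd`
#'   (differences), `pS`, `pN`, `Ks`, `Ka`, `ratio` (`NA` when
#'   undefined), `selection` (`"purifying"`, `"relaxed_or_positive"` or
#'   `"undefined"`) and `n_codons`.
#' @export
ng86 <- function(codon_alignment, threshold = 0.5) {
  stopifnot(is.data.frame(codon_alignment),
            all(c("codon_a", "codon_b") %in% names(codon_alignment)))
  n_codons <- nrow(codon_alignment)
  if (n_codons == 0L) stop("empty codon alignment")
  s_a <- sum(vapply(codon_alignment$codon_a, syn_sites, numeric(1)))
  s_b <- sum(vapply(codon_alignment$codon_b, syn_sites, numeric(1)))
  S <- (s_a + s_b) / 2
  N <- 3 * n_codons - S
  Sd <- 0; Nd <- 0
  differing <- which(codon_alignment$codon_a != codon_alignment$codon_b)
  for (i in differing) {
    d <- codon_diffs(codon_alignment$codon_a[i], codon_alignment$codon_b[i])
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  Ks <- jc_correct(pS)
  Ka <- jc_correct(pN)
  ratio <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 Ks = Ks, Ka = Ka, ratio = ratio,
                 selection = classify_selection(ratio, threshold),
                 n_codons = n_codons),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf(
    "NG86: %d codons  S=%.2f N=%.2f  Sd=%.2f Nd=%.2f  Ks=%s Ka=%s  Ka/Ks=%s (%s)\n",
    x$n_codons, x$S, x$N, x$Sd, x$Nd,
    format(x$Ks, digits = 4), format(x$Ka, digits = 4),
    format(x$ratio, digits = 4), x$selection))
  invisible(x)
}

#' Call the selection regime from a Ka/Ks ratio
#'
#' @param ratio Ka/Ks value, or `NA` when undefined (e.g. Ks = 0).
#' @param threshold Boundary; ratios strictly below it are `purifying`,
#'   ratios at or above it `relaxed_or_positive` (default 0.5).
#' @return One of `"purifying"`, `"relaxed_or_positive"`, `"undefined"`.
#' @export
classify_selection <- function(ratio, threshold = 0.5) {
  vapply(ratio, function(r) {
    if (is.na(r)) "undefined"
    else if (r < threshold) "purifying"
    else "relaxed_or_positive"
  }, character(1))
}

#' Full Ka/Ks workflow for one coding-sequence pair
#'
#' Translates both CDSs, builds a global protein guide alignment,
#' threads it back to codons and applies [ng86()].
#'
#' @param cds_a,cds_b In-frame coding sequences.
#' @param threshold Selection-call threshold, see [classify_selection()].
#' @param ... Passed to [needleman_wunsch()].
#' @return A `kaks_result`.
#' @export
kaks_pair <- function(cds_a, cds_b, threshold = 0.5, ...) {
  guide <- needleman_wunsch(translate_cds(cds_a), translate_cds(cds_b), ...)
  ng86(thread_codons(guide, cds_a, cds_b), threshold = threshold)
}
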