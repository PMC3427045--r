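#' Assign a motif-composition subfamily (CCCH-a to CCCH-e)
#'
#' Classifies a protein by the multiset of its CCCH motif spacings:
#' \describe{
#'   \item{CCCH-a}{1-3 motifs, all (7,5,3)}
#'   \item{CCCH-b}{1-6 motifs, all (8,5,3)}
#'   \item{CCCH-c}{2-3 motifs mixing (7,5,3) and (8,5,3), at least one
#'     of each}
#'   \item{CCCH-d}{exactly one (5,4,3) plus exactly one of (7,5,3),
#'     (8,5,3) or (10,5,3)}
#'   \item{CCCH-e}{any remaining composition containing a
#'     non-conventional motif}
#' }
#' The published composition rules overlap, so they are tested in the
#' fixed precedence d, c, a, b, e (most specific composite rules first);
#' the matched rule is recorded in `rationale`. Only-conventional
#' compositions exceeding the stated count ranges are `unclassified`.
#'
#' @param annotation A `motif_annotation` with at least one motif.
#' @return A list with `protein_id`, `subfamily` (one of `"CCCH-a"` ..
#'   `"CCCH-e"`, `"unclassified"`) and `rationale`.
#' @export
assign_subfamily <- function(annotation) {
  stopifnot(inherits(annotation, "motif_annotation"))
  mt <- annotation$motifs
  if (nrow(mt) == 0L) stop("zero motifs: not a CCCH protein")
  key <- paste(mt$m, mt$n, mt$p)
  total <- nrow(mt)
  n753 <- sum(key == "7 5 3")
  n853 <- sum(key == "8 5 3")
  n543 <- sum(key == "5 4 3")
  n1053 <- sum(key == "10 5 3")
  n_nonconv <- sum(!mt$conventional)
  call <- function(subfamily, rationale) {
    list(protein_id = annotation$protein_id, subfamily = subfamily,
         rationale = rationale)
  }
  # d: exactly one (5,4,3) plus exactly one of {(7,5,3),(8,5,3),(10,5,3)}
  if (n543 == 1L && (n753 + n853 + n1053) == 1L && total == 2L) {
    return(call("CCCH-d", "one (5,4,3) plus one (7|8|10,5,3)"))
  }
  # c: both conventional classes present, total 2-3, nothing else
  if (n753 >= 1L && n853 >= 1L && total >= 2L && total <= 3L &&
      n753 + n853 == total) {
    return(call("CCCH-c", "2-3 motifs mixing (7,5,3) and (8,5,3)"))
  }
  # a: only (7,5,3), 1-3 copies
  if (n753 == total && total <= 3L) {
    return(call("CCCH-a", "1-3 (7,5,3) motifs only"))
  }
  # b: only (8,5,3), 1-6 copies
  if (n853 == total && total <= 6L) {
    return(call("CCCH-b", "1-6 (8,5,3) motifs only"))
  }
  # e: any remaining composition containing a non-conventional motif
  if (n_nonconv >= 1L) {
    return(call("CCCH-e", "contains non-conventional motif(s)"))
  }
  call("unclassified", "")
}
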