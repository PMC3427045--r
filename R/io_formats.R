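#' Read a FASTA file of protein or nucleotide sequences
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that adds the
#' validation this pipeline relies on: unique identifiers, a restricted
#' residue alphabet, uppercase sequences, and (for proteins) silent
#' stripping of a single trailing stop character `*`.
#'
#' @param path Path to a FASTA file.
#' @param type `"protein"` (20 standard residues plus `X`) or
#'   `"dna"` (`A`, `C`, `G`, `T`, plus `N` for ambiguity).
#' @return A `data.frame` with columns `id` (first whitespace-delimited
#'   token of the header), `desc` (remainder of the header, possibly
#'   empty) and `seq` (uppercase sequence). Row order follows the file.
#' @export
read_fasta <- function(path, type = c("protein", "dna")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (type == "protein") {
    has_stop <- grepl("\\*$", seqs)
    if (any(has_stop)) {
      message("stripped trailing '*' from ", sum(has_stop), " sequence(s)")
      seqs <- sub("\\*$", "", seqs)
    }
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  alphabet <- if (type == "protein") AA_ALPHABET_X else c("A", "C", "G", "T", "N")
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!(chars %in% alphabet))
    if (length(bad) > 0L) {
      stop("illegal residue '", chars[bad[1]], "' at position ", bad[1],
           " in sequence ", ids[i])
    }
  }
  data.frame(id = ids, desc = desc, seq = unname(seqs),
             stringsAsFactors = FALSE)
}

AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_ALPHABET_X <- c(AA20, "X")

#' Write sequence records to FASTA
#'
#' @param records A `data.frame` with columns `id`, `seq` and optionally
#'   `desc`, as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  headers <- records$id
  if (!is.null(records$desc)) {
    headers <- ifelse(nzchar(records$desc),
                      paste(records$id, records$desc), records$id)
  }
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

ROMAN19 <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X",
             "XI", "XII", "XIII", "XIV", "XV", "XVI", "XVII", "XVIII", "XIX")

#' Parse POPTR-style locus identifiers into chromosome labels
#'
#' Identifiers of the form `POPTR_<nnnn>s<nnnnn>.<v>` encode the
#' assembly unit in the 4-digit field: values 0001-0019 are the 19
#' linkage groups (chromosomes) of the *Populus trichocarpa* assembly,
#' anything else is an unplaced scaffold.
#'
#' @param locus_id Character vector of locus identifiers.
#' @param lenient If `TRUE`, identifiers that do not match the pattern
#'   are passed through as their own label (flagged non-linkage-group)
#'   with a message instead of raising an error.
#' @return A `data.frame` with columns `locus_id`, `chrom_label`
#'   (e.g. `"LG_VII"` or `"scaffold_308"`) and `is_linkage_group`.
#' @examples
#' parse_poptr_chrom("POPTR_0007s01080.1")  # LG_VII
#' parse_poptr_chrom("POPTR_0308s00200.1")  # scaffold_308
#' @export
parse_poptr_chrom <- function(locus_id, lenient = FALSE) {
  pat <- "^POPTR_([0-9]{4})s[0-9]+\\.[0-9]+$"
  ok <- grepl(pat, locus_id)
  if (any(!ok) && !lenient) {
    stop("locus id(s) do not match POPTR pattern: ",
         paste(locus_id[!ok][seq_len(min(3, sum(!ok)))], collapse = ", "))
  }
  num <- rep(NA_integer_, length(locus_id))
  num[ok] <- as.integer(sub(pat, "\\1", locus_id[ok]))
  is_lg <- !is.na(num) & num >= 1L & num <= 19L
  label <- character(length(locus_id))
  label[is_lg] <- paste0("LG_", ROMAN19[num[is_lg]])
  label[ok & !is_lg] <- paste0("scaffold_", num[ok & !is_lg])
  if (any(!ok)) {
    message(sum(!ok), " locus id(s) passed through unparsed (lenient mode)")
    label[!ok] <- locus_id[!ok]
  }
  data.frame(locus_id = locus_id, chrom_label = label,
             is_linkage_group = is_lg, stringsAsFactors = FALSE)
}

#' Read a gene-locus table
#'
#' Expects a TSV with columns `gene_id`, `chrom_label`, `start`, `end`,
#' `strand` (1-based inclusive coordinates). A `locus_index` column (the
#' rank of each gene along its chromosome) is recomputed from the start
#' coordinates when absent; ties are broken by `gene_id` with a message.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of loci, ordered by chromosome then start.
#' @export
read_locus_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene_id", "chrom_label", "start", "end", "strand")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("locus table is missing column(s): ", paste(missing, collapse = ", "))
  }
  for (col in c("start", "end")) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      stop("non-numeric '", col, "' at line ", bad + 1L, " of ", path)
    }
  }
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup) > 0L) {
    stop("duplicate gene id(s) in locus table: ",
         paste(unique(dup), collapse = ", "))
  }
  if (any(df$start > df$end)) {
    stop("start > end for gene(s): ",
         paste(df$gene_id[df$start > df$end], collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  df <- assign_locus_index(df)
  df[order(df$chrom_label, df$start, df$gene_id), , drop = FALSE]
}

assign_locus_index <- function(df) {
  if (!is.null(df$locus_index)) return(df)
  df$locus_index <- NA_integer_
  for (chrom in unique(df$chrom_label)) {
    sel <- df$chrom_label == chrom
    o <- order(df$start[sel], df$gene_id[sel])
    if (anyDuplicated(df$start[sel])) {
      message("tied start coordinates on ", chrom,
              "; locus_index ties broken by gene_id")
    }
    df$locus_index[sel][o] <- seq_len(sum(sel))
  }
  df
}

#' Read a duplicated-block table
#'
#' Expects a TSV with columns `block_id`, `chrom_a`, `start_a`, `end_a`,
#' `chrom_b`, `start_b`, `end_b` describing pairs of homologous
#' chromosome segments (1-based inclusive).
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of block pairs.
#' @export
read_block_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("block_id", "chrom_a", "start_a", "end_a",
                "chrom_b", "start_b", "end_b")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("block table is missing column(s): ", paste(missing, collapse = ", "))
  }
  for (col in c("start_a", "end_a", "start_b", "end_b")) {
    if (!is.numeric(df[[col]])) stop("non-numeric '", col, "' in ", path)
  }
  if (any(df$start_a > df$end_a) || any(df$start_b > df$end_b)) {
    stop("invalid block interval (start > end) in ", path)
  }
  df
}

#' Read an expression table
#'
#' First column is the gene (or probe) identifier; remaining columns are
#' per-sample expression values. Rows containing missing values are
#' dropped with a message.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix with gene ids as row names and sample labels
#'   as column names.
#' @export
read_expression_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("expression table needs an id column plus samples")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) stop("duplicate sample labels in ", path)
  incomplete <- apply(m, 1L, function(x) any(is.na(x)))
  if (any(incomplete)) {
    message("dropped ", sum(incomplete), " row(s) with missing values")
    m <- m[!incomplete, , drop = FALSE]
  }
  m
}

#' Read a probe-to-gene map
#'
#' @param path Path to a TSV with columns `probe_id`, `gene_id`.
#' @return A `data.frame` with those two columns.
#' @export
read_probe_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_id") %in% names(df))) {
    stop("probe map needs columns probe_id, gene_id")
  }
  df[, c("probe_id", "gene_id")]
}
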