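#' Promoter sequence sets anchored at the TSS
#'
#' A `promoter_set` holds N same-length nucleotide sequences, each spanning a
#' fixed window around the transcription start site (TSS) of one gene,
#' oriented 5'->3' on the gene's strand.  Position 0 is the TSS (first
#' transcribed base); upstream positions are negative.  Window spans are
#' half-open `[span_start, span_end)` on a 1-bp integer grid, so a sequence
#' has exactly `span_end - span_start` bases.
#'
#' @param seqs named character vector of sequences over `{A,C,G,T,N}`
#'   (lower case accepted, stored upper case); names are unique gene ids.
#' @param span_start,span_end integer TSS-relative bounds of the window
#'   (half-open; defaults -3000 and +2000).
#' @param label optional label for the set.
#' @param tags optional character vector (same length as `seqs`) of
#'   free-form header tags (`key=value` pairs), passed through on write.
#' @return An object of class `promoter_set`.
#' @export
promoter_set <- function(seqs, span_start = -3000L, span_end = 2000L,
                         label = "", tags = NULL) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, span_start < span_end)
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("every sequence must be named by a gene id")
  if (anyDuplicated(ids))
    stop("duplicate gene ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  width <- span_end - span_start
  bad <- nchar(seqs) != width
  if (any(bad))
    stop("sequence length != span width for: ", paste(ids[bad], collapse = ", "))
  seqs <- toupper(seqs)
  if (any(grepl("[^ACGTN]", seqs)))
    stop("sequences may only contain A, C, G, T, N")
  if (!is.null(tags)) stopifnot(length(tags) == length(seqs))
  structure(
    list(seqs = seqs, span_start = as.integer(span_start),
         span_end = as.integer(span_end), label = label,
         tags = if (is.null(tags)) rep("", length(seqs)) else tags),
    class = "promoter_set")
}

#' @export
length.promoter_set <- function(x) length(x$seqs)

#' @export
`[.promoter_set` <- function(x, i) {
  promoter_set(x$seqs[i], x$span_start, x$span_end, x$label, x$tags[i])
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("promoter_set '%s': %d sequences, span [%d, %d)\n",
              x$label, length(x), x$span_start, x$span_end))
  invisible(x)
}

#' Read TSS-anchored promoter sequences from FASTA
#'
#' Headers follow `>geneID key=value ...`; the first whitespace-delimited
#' token is the gene id, the rest is kept as pass-through tags.  Records
#' whose length does not equal `span_end - span_start` are skipped with a
#' warning; duplicated gene ids are an error.
#'
#' @inheritParams promoter_set
#' @param path FASTA file.
#' @return A [promoter_set].
#' @export
read_promoters <- function(path, span_start = -3000L, span_end = 2000L,
                           label = basename(path)) {
  x <- Biostrings::readBStringSet(path)
  hdr <- names(x)
  ids <- sub("\\s.*$", "", hdr)
  tags <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  seqs <- toupper(as.character(x))
  width <- span_end - span_start
  bad <- nchar(seqs) != width
  if (any(bad)) {
    warning(sum(bad), " record(s) skipped (length != ", width, "): ",
            paste(utils::head(ids[bad], 5L), collapse = ", "))
    seqs <- seqs[!bad]; ids <- ids[!bad]; tags <- tags[!bad]
  }
  if (length(seqs) == 0L) stop("no usable records in ", path)
  names(seqs) <- ids
  promoter_set(seqs, span_start, span_end, label, tags)
}

#' Write a promoter set to FASTA
#'
#' Inverse of [read_promoters()]: ids and any header tags are restored, so a
#' read/write round trip is byte-preserving for sequences and ids.
#'
#' @param set a [promoter_set].
#' @param path output FASTA file.
#' @export
write_promoters <- function(set, path) {
  x <- Biostrings::BStringSet(set$seqs)
  names(x) <- ifelse(set$tags == "", names(set$seqs),
                     paste(names(set$seqs), set$tags))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

# integer codes 1..4 for A,C,G,T; NA for anything else (N)
.base_codes <- function(seq) {
  ints <- utf8ToInt(seq)
  code <- rep(NA_integer_, length(ints))
  code[ints == 65L] <- 1L  # A
  code[ints == 67L] <- 2L  # C
  code[ints == 71L] <- 3L  # G
  code[ints == 84L] <- 4L  # T
  code
}

#' GC-content profile of a promoter sequence
#'
#' GC content in 20 bins of 100 bp over the TSS-relative region
#' `[-1000, +1000)`.  Per bin, GC = (#G + #C) / (#A + #C + #G + #T); N bases
#' count in neither numerator nor denominator.  A bin with no countable base
#' is reported `NA` (missing) and is imputed downstream with that bin's
#' genomic mean.
#'
#' @param seq a single sequence (character scalar).
#' @param span_start TSS-relative coordinate of the first base of `seq`.
#' @return numeric vector of 20 GC fractions (possibly `NA`).
#' @export
gc_profile <- function(seq, span_start) {
  width <- nchar(seq)
  if (span_start > -1000L || span_start + width < 1000L)
    stop("sequence span must cover [-1000, +1000)")
  off <- -1000L - span_start          # 0-based offset of bin region start
  code <- .base_codes(substr(seq, off + 1L, off + 2000L))
  bin <- rep(seq_len(20L), each = 100L)
  gc <- tapply(code %in% c(2L, 3L), bin, sum)
  tot <- tapply(!is.na(code), bin, sum)
  out <- as.numeric(gc) / as.numeric(tot)
  out[tot == 0L] <- NA_real_
  unname(out)
}

#' GC-content profiles for every sequence in a set
#'
#' @param set a [promoter_set] whose span covers `[-1000, +1000)`.
#' @return numeric matrix, one row per gene (rownames = gene ids), 20 columns.
#' @export
gc_profiles <- function(set) {
  out <- t(vapply(set$seqs, gc_profile, numeric(20L),
                  span_start = set$span_start))
  rownames(out) <- names(set$seqs)
  out
}

#' Read / write a TSS-relative site table
#'
#' Tab-separated with columns `gene_id`, `motif_id`, `position` (integer
#' TSS-relative site anchor), `strand` (+/-), `score` (log-odds),
#' `rel_score`, `class` (`strong`/`weak`) and `overlaps_strong` (logical,
#' for weak sites overlapping a strong site of the same motif).
#'
#' @param path TSV file.
#' @param gene_ids ordered gene ids of the scanned set (so genes with zero
#'   sites are represented); defaults to the ids present in the table.
#' @param width motif width in bp (stored as an attribute; needed by the
#'   conservation test to expand anchors to covered bases).
#' @return for `read_sites`, a `site_collection`.
#' @export
read_sites <- function(path, gene_ids = NULL, width = NA_integer_) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "motif_id", "position", "strand", "score", "class")
  if (!all(need %in% names(df)))
    stop("site table must have columns: ", paste(need, collapse = ", "))
  if (is.null(df$rel_score)) df$rel_score <- NA_real_
  if (is.null(df$overlaps_strong)) df$overlaps_strong <- FALSE
  site_collection(df, motif_id = if (nrow(df)) df$motif_id[1L] else "",
                  gene_ids = if (is.null(gene_ids)) unique(df$gene_id) else gene_ids,
                  width = width)
}

#' @rdname read_sites
#' @param sites a `site_collection`.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(sites$sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
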