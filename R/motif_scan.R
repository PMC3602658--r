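BASES <- c("A", "C", "G", "T")

#' Motif matrix (PWM) with log-odds scoring model
#'
#' Wraps a 4 x w count matrix (rows A, C, G, T) as a position weight matrix.
#' Column probabilities are `(count + pseudocount * background) /
#' (colsum + pseudocount)` and log-odds weights are `log2(p / background)`,
#' the MATCH/TRANSFAC-style convention.  Hits are classified by relative
#' score `(score - min) / (max - min)`: "strong" at or above
#' `strong_fraction`, "weak" in `[weak_fraction, strong_fraction)`.
#'
#' @param motif_id motif identifier.
#' @param counts 4 x w nonnegative matrix; rownames A,C,G,T (assumed in that
#'   order if absent); `w >= 4`.
#' @param pseudocount total pseudocount per column, split by background
#'   (default 0.8).
#' @param background base frequencies (A,C,G,T) summing to 1; default
#'   uniform.
#' @param strong_fraction,weak_fraction relative-score thresholds for the
#'   strong and weak site classes (defaults 0.85 and 0.70).
#' @return An object of class `motif_matrix` with elements `counts`, `prob`,
#'   `logodds`, per-column `min`/`max` scores and the thresholds.
#' @export
motif_matrix <- function(motif_id, counts, pseudocount = 0.8,
                         background = rep(0.25, 4),
                         strong_fraction = 0.85, weak_fraction = 0.70) {
  counts <- as.matrix(counts)
  if (!is.null(rownames(counts))) counts <- counts[BASES, , drop = FALSE]
  stopifnot(nrow(counts) == 4L, ncol(counts) >= 4L, all(counts >= 0),
            length(background) == 4L, abs(sum(background) - 1) < 1e-8,
            strong_fraction > 0, strong_fraction <= 1,
            weak_fraction > 0, weak_fraction < strong_fraction)
  rownames(counts) <- BASES
  if (pseudocount <= 0 && any(colSums(counts) == 0))
    stop("column with zero counts requires a positive pseudocount")
  prob <- sweep(counts + pseudocount * background, 2,
                colSums(counts) + pseudocount, "/")
  logodds <- log2(prob / background)
  smin <- sum(apply(logodds, 2, min))
  smax <- sum(apply(logodds, 2, max))
  if (!(smax > smin)) stop("degenerate matrix: max score not above min score")
  structure(
    list(motif_id = motif_id, counts = counts, prob = prob,
         logodds = logodds, pseudocount = pseudocount,
         background = background, min_score = smin, max_score = smax,
         width = ncol(counts), strong_fraction = strong_fraction,
         weak_fraction = weak_fraction),
    class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("motif_matrix '%s': width %d, consensus %s\n",
              x$motif_id, x$width, motif_consensus(x)))
  invisible(x)
}

#' Consensus word of a motif (column-wise argmax base)
#' @param motif a [motif_matrix].
#' @export
motif_consensus <- function(motif) {
  paste(BASES[apply(motif$prob, 2, which.max)], collapse = "")
}

#' Reverse complement of a motif matrix
#' @param motif a [motif_matrix].
#' @export
reverse_complement_motif <- function(motif) {
  counts <- motif$counts[4:1, rev(seq_len(motif$width)), drop = FALSE]
  rownames(counts) <- BASES
  motif_matrix(motif$motif_id, counts, motif$pseudocount,
               rev(motif$background), motif$strong_fraction,
               motif$weak_fraction)
}

#' Parse motif matrices from JASPAR PFM or TRANSFAC flat files
#'
#' JASPAR PFM: `>id name` header followed by four rows `A [ 1 2 3 ]` (or
#' bare numbers) in A,C,G,T order.  TRANSFAC: blocks with `AC`/`ID`/`NA`
#' identifiers and numbered rows following a `P0  A  C  G  T` header.
#'
#' @param path matrix file.
#' @param dialect `"jaspar_pfm"` or `"transfac"`.
#' @param ... passed to [motif_matrix()] (pseudocount, background,
#'   thresholds).
#' @return list of [motif_matrix] objects.
#' @export
parse_motifs <- function(path, dialect = c("jaspar_pfm", "transfac"), ...) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  if (dialect == "jaspar_pfm") .parse_jaspar(lines, ...) else .parse_transfac(lines, ...)
}

.num_row <- function(line, lineno) {
  x <- suppressWarnings(as.numeric(
    strsplit(gsub("^[ACGT]?\\s*\\[|\\]", "", line), "\\s+")[[1]]))
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("malformed matrix row at line ", lineno)
  x
}

.parse_jaspar <- function(lines, ...) {
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no '>' header found (line 1)")
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    at <- starts[i]
    id <- sub("^>\\s*", "", lines[at])
    id <- sub("\\s.*$", "", id)
    body <- lines[(at + 1L):min(at + 4L, length(lines))]
    if (length(body) < 4L || any(grepl("^>", body)))
      stop("motif block at line ", at, " must have 4 matrix rows")
    rows <- lapply(seq_along(body), function(j) {
      ln <- body[j]
      base <- sub("^\\s*([ACGTacgt]).*$", "\\1", ln)
      .num_row(ln, at + j)
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("unequal row lengths in block at line ", at)
    counts <- do.call(rbind, rows)
    rownames(counts) <- BASES
    out[[i]] <- motif_matrix(id, counts, ...)
  }
  out
}

.parse_transfac <- function(lines, ...) {
  p0 <- grep("^P0\\b|^PO\\b", lines)
  if (length(p0) == 0L) stop("no P0 header row found (line 1)")
  out <- vector("list", length(p0))
  for (i in seq_along(p0)) {
    at <- p0[i]
    # motif id: nearest preceding AC or ID line
    hdr <- grep("^(AC|ID|NA)\\s", lines[seq_len(at - 1L)])
    id <- if (length(hdr)) sub("^(AC|ID|NA)\\s+", "", lines[max(hdr)]) else paste0("M", i)
    cols <- strsplit(trimws(sub("^P[0O]\\s+", "", lines[at])), "\\s+")[[1]]
    ord <- match(BASES, toupper(cols))
    if (anyNA(ord)) stop("P0 header at line ", at, " must name A C G T")
    j <- at + 1L
    rows <- list()
    while (j <= length(lines) && grepl("^\\s*[0-9]+\\s", lines[j])) {
      x <- strsplit(trimws(lines[j]), "\\s+")[[1]]
      v <- suppressWarnings(as.numeric(x[2:5]))
      if (anyNA(v)) stop("malformed matrix row at line ", j)
      rows[[length(rows) + 1L]] <- v[order(ord)]
      j <- j + 1L
    }
    if (length(rows) == 0L) stop("empty matrix block at line ", at)
    counts <- t(do.call(rbind, rows))   # rows were per-position
    rownames(counts) <- BASES
    out[[i]] <- motif_matrix(id, counts, ...)
  }
  out
}

#' Collection of predicted sites for one motif over a promoter set
#'
#' @param sites data.frame with columns `gene_id`, `motif_id`, `position`
#'   (TSS-relative anchor = floor of match midpoint), `strand`, `score`,
#'   `rel_score`, `class`, `overlaps_strong`.
#' @param motif_id motif identifier.
#' @param gene_ids ordered gene ids of the scanned set (zero-site genes
#'   included).
#' @param width motif width in bp.
#' @return An object of class `site_collection`.
#' @export
site_collection <- function(sites, motif_id, gene_ids, width = NA_integer_) {
  stopifnot(is.data.frame(sites))
  if (nrow(sites) && !all(sites$gene_id %in% gene_ids))
    stop("site table contains gene ids absent from `gene_ids`")
  structure(list(motif_id = motif_id, gene_ids = gene_ids,
                 width = as.integer(width), sites = sites),
            class = "site_collection")
}

#' @export
print.site_collection <- function(x, ...) {
  cat(sprintf("site_collection '%s': %d sites (%d strong) in %d sequences\n",
              x$motif_id, nrow(x$sites), sum(x$sites$class == "strong"),
              length(x$gene_ids)))
  invisible(x)
}

#' Restrict a site collection to a subset of genes
#' @param sites a [site_collection]; @param gene_ids genes to keep (order kept).
#' @export
subset_sites <- function(sites, gene_ids) {
  stopifnot(all(gene_ids %in% sites$gene_ids))
  site_collection(sites$sites[sites$sites$gene_id %in% gene_ids, , drop = FALSE],
                  sites$motif_id, gene_ids, sites$width)
}

# named list gene_id -> integer positions of sites of the given class(es)
sites_by_gene <- function(sites, site_class = "strong") {
  df <- sites$sites
  keep <- df$class %in% site_class
  split(df$position[keep], factor(df$gene_id[keep], levels = sites$gene_ids))
}

# score every window of one coded sequence against a 4 x w log-odds matrix;
# windows containing N come out NA
.score_windows <- function(code, lo) {
  w <- ncol(lo)
  L <- length(code) - w + 1L
  if (L < 1L) return(numeric(0))
  sc <- numeric(L)
  for (j in seq_len(w))
    sc <- sc + lo[(j - 1L) * 4L + code[j:(j + L - 1L)]]
  sc
}

#' Scan a promoter set for motif sites on both strands
#'
#' Every window on both strands is scored by log-odds; hits at relative
#' score `>= weak_fraction` are kept and classified strong/weak.  The site
#' anchor is the floor of the match midpoint in TSS-relative coordinates
#' (symmetric for Gaussian peak fitting).  Windows containing N never
#' score as hits.  All overlapping hits are kept; weak sites overlapping a
#' strong site of the same motif on the same sequence are flagged
#' (`overlaps_strong`), so the weak-site enrichment test can exclude them.
#'
#' @param set a [promoter_set].
#' @param motif a [motif_matrix].
#' @return a [site_collection].
#' @export
scan_promoters <- function(set, motif) {
  w <- motif$width
  lo_f <- motif$logodds
  lo_r <- reverse_complement_motif(motif)$logodds
  rng <- motif$max_score - motif$min_score
  acc <- vector("list", length(set))
  for (s in seq_along(set$seqs)) {
    code <- .base_codes(set$seqs[[s]])
    rows <- list()
    for (strand in c("+", "-")) {
      sc <- .score_windows(code, if (strand == "+") lo_f else lo_r)
      rel <- (sc - motif$min_score) / rng
      hit <- which(!is.na(rel) & rel >= motif$weak_fraction)
      if (length(hit)) {
        pos <- set$span_start + (hit - 1L) + (w - 1L) %/% 2L  # midpoint floor
        rows[[strand]] <- data.frame(
          gene_id = names(set$seqs)[s], motif_id = motif$motif_id,
          position = pos, strand = strand, score = sc[hit],
          rel_score = rel[hit],
          class = ifelse(rel[hit] >= motif$strong_fraction, "strong", "weak"),
          start = set$span_start + (hit - 1L),
          stringsAsFactors = FALSE)
      }
    }
    acc[[s]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  df <- do.call(rbind, acc)
  if (is.null(df))
    df <- data.frame(gene_id = character(), motif_id = character(),
                     position = integer(), strand = character(),
                     score = numeric(), rel_score = numeric(),
                     class = character(), start = integer(),
                     stringsAsFactors = FALSE)
  df$overlaps_strong <- logical(nrow(df))
  if (nrow(df)) {
    df <- df[order(df$gene_id, df$position, df$strand), , drop = FALSE]
    for (g in unique(df$gene_id[df$class == "weak"])) {
      i_w <- which(df$gene_id == g & df$class == "weak")
      i_s <- which(df$gene_id == g & df$class == "strong")
      if (length(i_s))
        df$overlaps_strong[i_w] <- vapply(i_w, function(i) {
          any(df$start[i] <= df$start[i_s] + w - 1L &
                df$start[i_s] <= df$start[i] + w - 1L)
        }, logical(1))
    }
  }
  df$start <- NULL
  rownames(df) <- NULL
  site_collection(df, motif$motif_id, names(set$seqs), width = w)
}
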