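#' GC-composition class for the synthetic promoter universe
#'
#' Promoters are simulated i.i.d. per position with a position-dependent
#' GC probability `baseline_gc + tss_bump * exp(-x^2 / (2 bump_halfwidth^2))`,
#' which reproduces the GC elevation around the TSS typical of
#' CpG-island-associated promoters; a class with `tss_bump = 0` stands in
#' for GC-poor, CpG-less promoters.
#'
#' @param label class label (stored in FASTA header tags).
#' @param baseline_gc baseline GC probability in (0, 1).
#' @param tss_bump additive GC elevation at the TSS (may be 0).
#' @param bump_halfwidth Gaussian half-width of the elevation, bp.
#' @param proportion fraction of the universe in this class.
#' @export
gc_class_spec <- function(label, baseline_gc, tss_bump = 0,
                          bump_halfwidth = 300, proportion = 1) {
  stopifnot(baseline_gc > 0, baseline_gc + tss_bump > 0,
            baseline_gc + tss_bump < 1, proportion > 0, proportion <= 1)
  structure(list(label = label, baseline_gc = baseline_gc,
                 tss_bump = tss_bump, bump_halfwidth = bump_halfwidth,
                 proportion = proportion),
            class = "gc_class_spec")
}

#' Generate a synthetic genomic promoter universe
#'
#' @param n number of promoters.
#' @param classes list of [gc_class_spec()]; proportions must sum to 1.
#'   Class sizes are `n * proportion` (largest-remainder rounding) and
#'   class labels are recorded as `class=` header tags.
#' @param span TSS-relative window `c(start, end)` (half-open; default
#'   `c(-1000, 1000)` so GC profiles are defined).
#' @param seed integer seed; output is byte-deterministic given it.
#' @return a [promoter_set].
#' @export
generate_universe <- function(n, classes, span = c(-1000L, 1000L),
                              seed = 1L) {
  stopifnot(n >= 1L, length(classes) >= 1L)
  props <- vapply(classes, `[[`, numeric(1), "proportion")
  if (abs(sum(props) - 1) > 1e-8) stop("class proportions must sum to 1")
  counts <- floor(n * props)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- n * props - counts
    counts[order(-frac)[seq_len(rem)]] <- counts[order(-frac)[seq_len(rem)]] + 1
  }
  L <- span[2L] - span[1L]
  x <- span[1L]:(span[2L] - 1L)
  seqs <- character(n)
  labels <- character(n)
  at <- 0L
  withr::with_seed(seed, {
    for (ci in seq_along(classes)) {
      cl <- classes[[ci]]
      if (counts[ci] == 0L) next
      p_gc <- cl$baseline_gc +
        if (cl$tss_bump != 0)
          cl$tss_bump * exp(-x^2 / (2 * cl$bump_halfwidth^2)) else 0
      for (i in seq_len(counts[ci])) {
        is_gc <- stats::runif(L) < p_gc
        pick <- stats::runif(L) < 0.5
        # A=65 C=67 G=71 T=84
        ints <- ifelse(is_gc, ifelse(pick, 71L, 67L),
                       ifelse(pick, 65L, 84L))
        at <- at + 1L
        seqs[at] <- intToUtf8(ints)
        labels[at] <- cl$label
      }
    }
  })
  names(seqs) <- sprintf("g%05d", seq_len(n))
  promoter_set(seqs, span[1L], span[2L], label = "synthetic_universe",
               tags = paste0("class=", labels))
}

#' Implantation plan for motif instances
#'
#' @param motif a [motif_matrix]; implanted words are sampled column-wise
#'   from its probability matrix.
#' @param center TSS-relative midpoint of the implantation distribution.
#' @param positional_sd spread of implant midpoints, bp (`distribution =
#'   "gaussian"`: standard deviation, rounded to the grid; `"uniform"`:
#'   half-range).
#' @param insertion_rate fraction of sequences receiving one instance.
#' @param strand_policy `"gene_strand"` (implant the word as-is) or
#'   `"both"` (each implant reverse-complemented with probability 1/2).
#' @param distribution positional distribution of midpoints.
#' @param n_per_sequence implants per selected sequence (default 1,
#'   matching the zero-or-one intuition; larger values exercise
#'   `Z_s > 1`).
#' @export
implant_spec <- function(motif, center, positional_sd = 0,
                         insertion_rate = 1,
                         strand_policy = c("gene_strand", "both"),
                         distribution = c("gaussian", "uniform"),
                         n_per_sequence = 1L) {
  stopifnot(inherits(motif, "motif_matrix"), positional_sd >= 0,
            insertion_rate >= 0, insertion_rate <= 1, n_per_sequence >= 1L)
  structure(list(motif = motif, center = as.integer(center),
                 positional_sd = positional_sd,
                 insertion_rate = insertion_rate,
                 strand_policy = match.arg(strand_policy),
                 distribution = match.arg(distribution),
                 n_per_sequence = as.integer(n_per_sequence)),
            class = "implant_spec")
}

.revcomp_word <- function(word) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(word, "")[[1]]), collapse = ""))
}

#' Implant motif instances into a promoter set
#'
#' A fraction `insertion_rate` of the sequences (chosen without
#' replacement) receives `n_per_sequence` motif instances: words sampled
#' column-wise from the motif's probability matrix, overwriting the
#' background at midpoints drawn from the implantation distribution.
#'
#' @param set a [promoter_set].
#' @param spec an [implant_spec()].
#' @param seed integer seed.
#' @return the modified [promoter_set], with attribute `"implant_log"`: a
#'   data.frame of (`gene_id`, `position`, `strand`, `word`).
#' @export
implant_motifs <- function(set, spec, seed = 1L) {
  w <- spec$motif$width
  lead <- (w - 1L) %/% 2L             # bases left of the midpoint anchor
  n_imp <- round(spec$insertion_rate * length(set))
  log <- data.frame(gene_id = character(), position = integer(),
                    strand = character(), word = character(),
                    stringsAsFactors = FALSE)
  if (n_imp > 0L) withr::with_seed(seed, {
    chosen <- sample(seq_len(length(set)), n_imp)
    for (s in chosen) {
      for (rep_i in seq_len(spec$n_per_sequence)) {
        pos <- spec$center + if (spec$positional_sd == 0) 0L else
          if (spec$distribution == "gaussian")
            as.integer(round(stats::rnorm(1, 0, spec$positional_sd))) else
              as.integer(round(stats::runif(1, -spec$positional_sd,
                                            spec$positional_sd)))
        i1 <- pos - lead - set$span_start + 1L   # 1-based start in string
        i2 <- i1 + w - 1L
        if (i1 < 1L || i2 > nchar(set$seqs[[s]]))
          stop("implant at midpoint ", pos, " extends past the span of ",
               names(set$seqs)[s])
        word <- paste(vapply(seq_len(w), function(j)
          sample(BASES, 1L, prob = spec$motif$prob[, j]), character(1)),
          collapse = "")
        strand <- "+"
        if (spec$strand_policy == "both" && stats::runif(1) < 0.5) {
          word <- .revcomp_word(word)
          strand <- "-"
        }
        substr(set$seqs[[s]], i1, i2) <- word
        log <- rbind(log, data.frame(
          gene_id = names(set$seqs)[s], position = pos, strand = strand,
          word = word, stringsAsFactors = FALSE))
      }
    }
  })
  attr(set, "implant_log") <- log
  set
}
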