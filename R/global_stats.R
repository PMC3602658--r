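# per-gene counts of strong sites with TSS-relative anchor in [-1000, 0)
.upstream_counts <- function(sites) {
  df <- sites$sites
  keep <- df$class == "strong" & df$position >= -1000L & df$position < 0L
  cnt <- table(factor(df$gene_id[keep], levels = sites$gene_ids))
  as.integer(cnt)
}

#' Over-Representation Index (ORI) of a motif in an input set
#'
#' Global (position-free) enrichment over the 1000 bp upstream of the TSS:
#' `ORI = (Density_S / Density_genomic) * (Proportion_S /
#' Proportion_genomic)`, where Density is predicted sites per sequence and
#' Proportion the fraction of sequences carrying at least one site.  A set
#' identical to the genomic universe has ORI = 1 by construction.
#'
#' @param sites_S [site_collection] of the input set.
#' @param sites_genomic [site_collection] of the genomic universe.
#' @return An object of class `ori_result` with the two densities, the two
#'   proportions, `ori`, and `p_ori = NA` (see [p_ori()]).
#' @export
ori <- function(sites_S, sites_genomic) {
  cnt_s <- .upstream_counts(sites_S)
  cnt_g <- .upstream_counts(sites_genomic)
  N <- length(sites_S$gene_ids)
  Ng <- length(sites_genomic$gene_ids)
  density_g <- sum(cnt_g) / Ng
  proportion_g <- mean(cnt_g > 0L)
  if (density_g == 0 || proportion_g == 0)
    stop("motif '", sites_S$motif_id,
         "' has no upstream sites in the genomic set; ORI is undefined")
  density_s <- sum(cnt_s) / N
  proportion_s <- mean(cnt_s > 0L)
  structure(list(motif_id = sites_S$motif_id,
                 density_S = density_s, density_genomic = density_g,
                 proportion_S = proportion_s,
                 proportion_genomic = proportion_g,
                 ori = (density_s / density_g) *
                   (proportion_s / proportion_g),
                 p_ori = NA_real_),
            class = "ori_result")
}

#' @export
print.ori_result <- function(x, ...) {
  cat(sprintf("ORI '%s' = %.4f (density %.3f vs %.3f, proportion %.3f vs %.3f), P_ORI = %s\n",
              x$motif_id, x$ori, x$density_S, x$density_genomic,
              x$proportion_S, x$proportion_genomic, format(x$p_ori)))
  invisible(x)
}

#' Resampling p-value for the ORI
#'
#' GC-matched stratified sampling as in [null_pvalues()]; `P_ORI` is the
#' proportion of sampled sets whose ORI is strictly higher than the
#' observed one (note the asymmetry with P_dep's `>=`).  The customary
#' significance threshold is 0.01.
#'
#' @param obs an `ori_result` for the input set.
#' @param genomic,sites_genomic,model,input_set as in [null_pvalues()].
#' @param n_samples sampled sets (default 10000).
#' @param seed integer seed.
#' @return the `ori_result` with `p_ori` filled in.
#' @export
p_ori <- function(obs, genomic, sites_genomic, model, input_set,
                  n_samples = 10000L, seed = 1L) {
  cnt_g <- .upstream_counts(sites_genomic)
  names(cnt_g) <- sites_genomic$gene_ids
  cnt_g <- cnt_g[names(genomic$seqs)]
  has_g <- cnt_g > 0L
  density_g <- obs$density_genomic
  proportion_g <- obs$proportion_genomic
  ci <- cluster_counts(model, input_set)
  N <- sum(ci)
  exceed <- 0L
  withr::with_seed(seed, {
    for (r in seq_len(n_samples)) {
      idx <- sample_matched_idx(model, ci)
      ori_r <- (sum(cnt_g[idx]) / N / density_g) *
        (mean(has_g[idx]) / proportion_g)
      if (ori_r > obs$ori) exceed <- exceed + 1L
    }
  })
  obs$p_ori <- exceed / n_samples
  obs
}

# weak sites of the motif inside [start, end], excluding weak sites that
# overlap a strong site of the same motif
.weak_counts <- function(sites, start, end) {
  df <- sites$sites
  keep <- df$class == "weak" & !df$overlaps_strong &
    df$position >= start & df$position <= end
  cnt <- table(factor(df$gene_id[keep], levels = sites$gene_ids))
  as.integer(cnt)
}

#' Weak-site enrichment within a called region
#'
#' Counts the motif's weak sites (excluding weak sites overlapping a
#' strong site of the same motif) inside `[region_start, region_end]`
#' across the input set, and compares the count with GC-matched sampled
#' sets: `p = P(count_sampled >= count_observed)`.  A significant excess
#' suggests the region also accumulates lower-affinity binding sites.
#'
#' @param region one row of an `enriched_regions` data.frame.
#' @param sites_S [site_collection] of the input set (weak sites flagged).
#' @inheritParams p_ori
#' @param n_samples sampled sets (default 10000).
#' @return An object of class `weak_site_test`: `n_weak_obs`,
#'   `null_mean`, `null_median`, `p_value`.
#' @export
weak_site_enrichment <- function(region, sites_S, genomic, sites_genomic,
                                 model, input_set, n_samples = 10000L,
                                 seed = 1L) {
  stopifnot(nrow(region) == 1L,
            region$motif_id == sites_S$motif_id)
  rs <- region$region_start; re <- region$region_end
  obs <- sum(.weak_counts(sites_S, rs, re))
  cnt_g <- .weak_counts(sites_genomic, rs, re)
  names(cnt_g) <- sites_genomic$gene_ids
  cnt_g <- cnt_g[names(genomic$seqs)]
  ci <- cluster_counts(model, input_set)
  null_counts <- numeric(n_samples)
  withr::with_seed(seed, {
    for (r in seq_len(n_samples))
      null_counts[r] <- sum(cnt_g[sample_matched_idx(model, ci)])
  })
  structure(list(motif_id = region$motif_id,
                 region_start = rs, region_end = re,
                 n_weak_obs = obs,
                 null_mean = mean(null_counts),
                 null_median = stats::median(null_counts),
                 p_value = mean(null_counts >= obs),
                 n_samples = as.integer(n_samples)),
            class = "weak_site_test")
}

#' @export
print.weak_site_test <- function(x, ...) {
  cat(sprintf(
    "weak sites '%s' in [%d, %d]: observed %d, expected %.1f, p %s\n",
    x$motif_id, x$region_start, x$region_end, x$n_weak_obs, x$null_mean,
    if (x$p_value == 0) paste0("< ", format(1 / x$n_samples))
    else format(x$p_value)))
  invisible(x)
}

#' Per-base score track in TSS-relative coordinates
#'
#' Generic container for conservation-style per-base scores (PhastCons,
#' phyloP, or synthetic tracks).  Built from a long table `gene_id`,
#' `position` (TSS-relative integer), `score`.
#'
#' @param df data.frame with those three columns.
#' @return An object of class `score_track` (dense matrix lookup).
#' @export
score_track <- function(df) {
  stopifnot(all(c("gene_id", "position", "score") %in% names(df)))
  genes <- unique(df$gene_id)
  rng <- range(df$position)
  mat <- matrix(NA_real_, nrow = length(genes),
                ncol = rng[2L] - rng[1L] + 1L,
                dimnames = list(genes, NULL))
  mat[cbind(match(df$gene_id, genes), df$position - rng[1L] + 1L)] <- df$score
  structure(list(mat = mat, pos0 = rng[1L]), class = "score_track")
}

#' @rdname score_track
#' @param path TSV file with columns `gene_id`, `position`, `score`.
#' @export
read_score_track <- function(path) {
  score_track(utils::read.delim(path, stringsAsFactors = FALSE))
}

# vectorized lookup; fails naming the first missing (gene, position)
track_values <- function(track, gene_ids, positions) {
  ri <- match(gene_ids, rownames(track$mat))
  cj <- positions - track$pos0 + 1L
  bad <- is.na(ri) | cj < 1L | cj > ncol(track$mat)
  vals <- rep(NA_real_, length(gene_ids))
  vals[!bad] <- track$mat[cbind(ri[!bad], cj[!bad])]
  if (anyNA(vals)) {
    i <- which(is.na(vals))[1L]
    stop("score track has no value for gene ", gene_ids[i],
         " at position ", positions[i])
  }
  vals
}

#' Conservation Z-score of sites within an enriched region
#'
#' Averages the track score over every base covered by the motif's strong
#' sites inside the region, and compares it with the mean/SD of
#' `n_samples` draws in which the same number of bases is read at the
#' identical TSS-relative offsets in uniformly sampled genomic promoters
#' (one random promoter per site and draw).  Intended for regions with at
#' least 10 sites; fewer raises a warning.
#'
#' @param region one row of an `enriched_regions` data.frame.
#' @param sites_S [site_collection] of the input set (`width` set).
#' @param track a [score_track] covering all needed positions.
#' @param genomic the universe [promoter_set].
#' @param n_samples null draws (default 1000).
#' @param seed integer seed.
#' @return An object of class `conservation_z`: `mean_obs`, `null_mean`,
#'   `null_sd`, `z`, `n_sites`, `n_bases`.
#' @export
conservation_z <- function(region, sites_S, track, genomic,
                           n_samples = 1000L, seed = 1L) {
  stopifnot(nrow(region) == 1L, !is.na(sites_S$width))
  w <- sites_S$width
  df <- sites_S$sites
  keep <- df$class == "strong" & df$position >= region$region_start &
    df$position <= region$region_end
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop("no strong sites inside the region")
  if (nrow(df) < 10L)
    warning("only ", nrow(df), " sites in the region; Z-scores are ",
            "intended for regions with >= 10 sites", call. = FALSE)
  # bases covered by each site: anchor is the midpoint floor
  off <- -((w - 1L) %/% 2L) + 0:(w - 1L)
  base_pos <- rep(df$position, each = w) + off
  base_gene <- rep(df$gene_id, each = w)
  mean_obs <- mean(track_values(track, base_gene, base_pos))
  null_means <- numeric(n_samples)
  withr::with_seed(seed, {
    for (r in seq_len(n_samples)) {
      g <- sample(names(genomic$seqs), nrow(df), replace = TRUE)
      null_means[r] <- mean(track_values(track, rep(g, each = w), base_pos))
    }
  })
  null_mean <- mean(null_means)
  null_sd <- stats::sd(null_means)
  if (null_sd == 0) stop("degenerate score track: null SD is zero")
  structure(list(motif_id = region$motif_id,
                 region_start = region$region_start,
                 region_end = region$region_end,
                 mean_obs = mean_obs, null_mean = null_mean,
                 null_sd = null_sd,
                 z = (mean_obs - null_mean) / null_sd,
                 n_sites = nrow(df), n_bases = length(base_pos)),
            class = "conservation_z")
}

#' @export
print.conservation_z <- function(x, ...) {
  cat(sprintf(
    "conservation '%s' in [%d, %d]: mean %.3f vs null %.3f (sd %.3f), Z = %.2f\n",
    x$motif_id, x$region_start, x$region_end, x$mean_obs, x$null_mean,
    x$null_sd, x$z))
  invisible(x)
}
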