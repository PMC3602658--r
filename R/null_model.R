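# impute missing bins with the genomic per-bin mean
.impute_profiles <- function(prof, col_means = NULL) {
  if (is.null(col_means)) col_means <- colMeans(prof, na.rm = TRUE)
  for (j in seq_len(ncol(prof))) {
    miss <- is.na(prof[, j])
    if (any(miss)) prof[miss, j] <- col_means[j]
  }
  prof
}

#' Cluster the genomic promoter universe by GC-content profile
#'
#' Each genomic promoter is represented by its 20-bin GC profile over
#' `[-1000, +1000)`; bins are scaled to mean 0 / sd 1 across the universe
#' and clustered by k-means (Hartigan-Wong).  Clustering is repeated
#' `restarts` times from random initializations (up to `max_iter`
#' iterations each) and the solution with the smallest total
#' within-cluster sum of squares is kept.  With k = 2 the clusters
#' correspond to promoters with high (especially TSS-proximal) and low GC
#' content.
#'
#' @param genomic a [promoter_set] (the universe), `length >= 10 * k`.
#' @param k number of clusters (2..10).
#' @param restarts,max_iter restart and iteration budget (defaults 100, 100).
#' @param seed integer seed; results are deterministic given it.
#' @param profiles optional precomputed [gc_profiles()] matrix (cache).
#' @return An object of class `gc_cluster_model`: `k`, `bin_means`,
#'   `bin_sds`, `centroids` (k x 20, scaled space), `assignment` (named
#'   integer), `sizes`, `tot_withinss`.
#' @export
fit_gc_clusters <- function(genomic, k, restarts = 100L, max_iter = 100L,
                            seed = 1L, profiles = NULL) {
  stopifnot(k >= 2L, k <= 10L)
  if (length(genomic) < 10L * k)
    stop("need at least ", 10L * k, " genomic sequences for k = ", k)
  if (is.null(profiles)) profiles <- gc_profiles(genomic)
  prof <- .impute_profiles(profiles)
  bin_means <- colMeans(prof)
  bin_sds <- apply(prof, 2, stats::sd)
  bin_sds[bin_sds == 0] <- 1          # constant bin: scaling is a no-op
  xs <- scale(prof, center = bin_means, scale = bin_sds)
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(restarts)) {
      km <- NULL
      tries <- 0L
      while (is.null(km) && tries < 10L) {  # empty cluster -> re-initialize
        tries <- tries + 1L
        km <- tryCatch(
          stats::kmeans(xs, centers = k, iter.max = max_iter, nstart = 1L,
                        algorithm = "Hartigan-Wong"),
          error = function(e) NULL, warning = function(w) NULL)
        if (!is.null(km) && any(km$size == 0L)) km <- NULL
      }
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  if (is.null(best)) stop("k-means failed for every restart")
  assignment <- best$cluster
  names(assignment) <- rownames(prof)
  structure(list(k = k, bin_means = bin_means, bin_sds = bin_sds,
                 centroids = best$centers, assignment = assignment,
                 sizes = as.integer(best$size),
                 tot_withinss = best$tot.withinss),
            class = "gc_cluster_model")
}

#' Fit GC-cluster models for a range of k
#' @inheritParams fit_gc_clusters
#' @param ks values of k (default 2:10).
#' @return named list of [fit_gc_clusters()] models (`"2"`, `"3"`, ...).
#' @export
fit_gc_models <- function(genomic, ks = 2:10, restarts = 100L,
                          max_iter = 100L, seed = 1L, profiles = NULL) {
  if (is.null(profiles)) profiles <- gc_profiles(genomic)
  out <- lapply(seq_along(ks), function(i)
    fit_gc_clusters(genomic, ks[i], restarts, max_iter,
                    seed = seed + i - 1L, profiles = profiles))
  names(out) <- as.character(ks)
  out
}

# cluster index for arbitrary sequences: stored assignment when the gene is
# part of the clustered universe, else nearest centroid in scaled space
assign_clusters <- function(model, set, profiles = NULL) {
  ids <- names(set$seqs)
  out <- unname(model$assignment[ids])
  need <- is.na(out)
  if (any(need)) {
    if (is.null(profiles)) profiles <- gc_profiles(set[need])
    prof <- .impute_profiles(profiles, model$bin_means)
    xs <- scale(prof, center = model$bin_means, scale = model$bin_sds)
    d2 <- outer(rowSums(xs^2), rowSums(model$centroids^2), "+") -
      2 * xs %*% t(model$centroids)
    out[need] <- apply(d2, 1, which.min)
  }
  as.integer(out)
}

#' Per-cluster membership counts of an input set
#' @param model a `gc_cluster_model`; @param input_set a [promoter_set].
#' @return integer vector `c_i` of length `model$k` (sums to N).
#' @export
cluster_counts <- function(model, input_set) {
  tabulate(assign_clusters(model, input_set), nbins = model$k)
}

# Eq.-8-style rule: smallest k with RMSD_k <= RMSD_{k+1} + SD_{k+1};
# if no k up to max-1 qualifies, fall back to the largest k considered
k_star_rule <- function(ks, rmsd_mean, rmsd_sd) {
  for (i in seq_len(length(ks) - 1L))
    if (rmsd_mean[i] <= rmsd_mean[i + 1L] + rmsd_sd[i + 1L]) return(ks[i])
  ks[length(ks)]
}

#' Choose the number of GC clusters (k*) for stratified sampling
#'
#' For each k, `reps` stratified samples of size N (cluster counts matching
#' the input set's `c_i`) are drawn from the universe; the RMSD between the
#' 20 mean GC bins of a sampled set and those of the input set is recorded.
#' k* is the smallest k whose mean RMSD is at most the mean RMSD + SD of
#' k + 1 (a Gap-statistic-like rule); k = 1 is never considered, and when
#' no k below the maximum qualifies the largest k is used.
#'
#' @param genomic the universe [promoter_set].
#' @param models list of `gc_cluster_model` as from [fit_gc_models()].
#' @param input_set the input [promoter_set] (N sequences).
#' @param reps samplings per k (default 1000).
#' @param seed integer seed.
#' @return An object of class `k_star_report`: `per_k` data.frame
#'   (`k`, `rmsd_mean`, `rmsd_sd`) and `k_star`.
#' @export
choose_k_star <- function(genomic, models, input_set, reps = 1000L,
                          seed = 1L) {
  ks <- as.integer(names(models))
  stopifnot(!is.unsorted(ks))
  gprof <- .impute_profiles(gc_profiles(genomic))
  target <- colMeans(.impute_profiles(gc_profiles(input_set),
                                      colMeans(gprof)))
  per_k <- data.frame(k = ks, rmsd_mean = NA_real_, rmsd_sd = NA_real_)
  withr::with_seed(seed, {
    for (i in seq_along(ks)) {
      model <- models[[i]]
      ci <- cluster_counts(model, input_set)
      pools <- split(seq_len(length(genomic)),
                     factor(model$assignment, levels = seq_len(model$k)))
      rmsd <- vapply(seq_len(reps), function(r) {
        idx <- unlist(lapply(seq_len(model$k), function(j)
          if (ci[j] > 0L) sample(pools[[j]], ci[j]) else integer(0)),
          use.names = FALSE)
        sqrt(mean((colMeans(gprof[idx, , drop = FALSE]) - target)^2))
      }, numeric(1))
      per_k$rmsd_mean[i] <- mean(rmsd)
      per_k$rmsd_sd[i] <- stats::sd(rmsd)
    }
  })
  structure(list(per_k = per_k,
                 k_star = k_star_rule(ks, per_k$rmsd_mean, per_k$rmsd_sd)),
            class = "k_star_report")
}

#' @export
print.k_star_report <- function(x, ...) {
  cat("k* =", x$k_star, "\n")
  print(x$per_k, row.names = FALSE)
  invisible(x)
}

# stratified sample of row indices into the universe, matching counts ci;
# without replacement within a set; uses the current RNG state
sample_matched_idx <- function(model, ci) {
  pools <- split(seq_along(model$assignment),
                 factor(model$assignment, levels = seq_len(model$k)))
  short <- which(ci > vapply(pools, length, 0L))
  if (length(short))
    stop("cluster ", short[1L], " has ", length(pools[[short[1L]]]),
         " sequences but ", ci[short[1L]], " are requested")
  unlist(lapply(seq_len(model$k), function(j)
    if (ci[j] > 0L) sample(pools[[j]], ci[j]) else integer(0)),
    use.names = FALSE)
}

#' Draw one GC-matched promoter set from the universe
#'
#' Samples `c_i` sequences (without replacement) from each GC cluster,
#' where `c_i` is the input set's membership count in cluster i, so the
#' sampled set matches the input set's GC-profile composition.  Input
#' genes are not excluded from the pool.
#'
#' @inheritParams choose_k_star
#' @param model the `gc_cluster_model` at k*.
#' @return a [promoter_set] of the same size as `input_set`.
#' @export
sample_matched_set <- function(genomic, model, input_set) {
  idx <- sample_matched_idx(model, cluster_counts(model, input_set))
  out <- genomic[idx]
  out$label <- "gc_matched_sample"
  out
}

#' Empirical p-values for local enrichment by GC-matched resampling
#'
#' Repeatedly draws GC-matched sets of N promoters from the universe,
#' recomputes `S_local` from their (pre-scanned) sites, and reports for
#' each position x the position-dependent p-value
#' `P_dep(x) = P(S_sampled(x) >= S_obs(x))` and the position-independent
#' `P_ind(x) = P(max_x' S_sampled(x') >= S_obs(x))`.  P_dep asks whether
#' the observed enrichment at x beats matched sets at the same position;
#' P_ind asks whether it beats their best position anywhere, guarding
#' against profiles that are globally flat but locally lucky.  P-values
#' are plain proportions over `n_samples` (the conservative
#' `(r + 1)/(n + 1)` variant is available via `conservative = TRUE`).
#'
#' @param obs observed `enrichment_profile` of the input set.
#' @param genomic the universe [promoter_set].
#' @param sites_genomic [site_collection] of the scanned universe (same
#'   motif).
#' @param model `gc_cluster_model` at k*.
#' @param input_set the input [promoter_set].
#' @param n_samples number of sampled sets (default 25000; resolving the
#'   strictest width-dependent threshold of 5e-5 needs at least 20000,
#'   below which a warning is raised).
#' @param seed integer seed; results are bit-reproducible given it.
#' @param conservative use `(r + 1)/(n + 1)` p-values.
#' @param profiles optional precomputed [site_profiles()] matrix for the
#'   universe on the same grid/kernel (cache; computed when missing).
#' @return An object of class `null_distribution`: `p_dep`, `p_ind`,
#'   `exceed_count`, `sampled_maxima`, grid metadata.
#' @export
null_pvalues <- function(obs, genomic, sites_genomic, model, input_set,
                         n_samples = 25000L, seed = 1L,
                         conservative = FALSE, profiles = NULL) {
  stopifnot(inherits(obs, "enrichment_profile"), n_samples >= 1L)
  if (n_samples < 20000L)
    warning("n_samples = ", n_samples,
            " cannot resolve P_dep below 5e-05; use >= 20000 for the ",
            "strictest width threshold", call. = FALSE)
  missing_genes <- setdiff(names(genomic$seqs), sites_genomic$gene_ids)
  if (length(missing_genes))
    stop("no pre-scanned sites for genomic gene(s): ",
         paste(utils::head(missing_genes, 5L), collapse = ", "))
  if (is.null(profiles)) {
    profiles <- site_profiles(sites_genomic, obs$kernel, obs$x_start,
                              obs$x_stop)
  } else {
    stopifnot(attr(profiles, "x_start") == obs$x_start,
              attr(profiles, "x_stop") == obs$x_stop)
  }
  profiles <- profiles[names(genomic$seqs), , drop = FALSE]
  ci <- cluster_counts(model, input_set)
  m <- length(obs$scores)
  exceed <- integer(m)
  maxima <- numeric(n_samples)
  withr::with_seed(seed, {
    for (r in seq_len(n_samples)) {
      idx <- sample_matched_idx(model, ci)
      prof <- colSums(profiles[idx, , drop = FALSE])
      exceed <- exceed + (prof >= obs$scores)
      maxima[r] <- max(prof)
    }
  })
  denom <- if (conservative) n_samples + 1L else n_samples
  add <- if (conservative) 1L else 0L
  p_dep <- (exceed + add) / denom
  p_ind <- (vapply(obs$scores, function(v) sum(maxima >= v), numeric(1)) +
              add) / denom
  structure(list(motif_id = obs$motif_id, kernel = obs$kernel,
                 x_start = obs$x_start, x_stop = obs$x_stop,
                 n_samples = as.integer(n_samples),
                 exceed_count = exceed, sampled_maxima = maxima,
                 p_dep = p_dep, p_ind = p_ind,
                 conservative = conservative),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "null_distribution '%s' (%s h/2=%g): %d samples, min P_dep %.3g at %d\n",
    x$motif_id, x$kernel$shape, x$kernel$half_width, x$n_samples,
    min(x$p_dep), x$x_start + which.min(x$p_dep) - 1L))
  invisible(x)
}
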