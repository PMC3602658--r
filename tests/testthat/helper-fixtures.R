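# Shared fixtures, memoized across test files (expensive universes and
# scans are built once per test run).
.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

# AT-rich 8-bp test motif, consensus TATAAATA (dominant count 12 vs 1)
fx_motif <- function() {
  cnt <- matrix(1, nrow = 4, ncol = 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  consensus <- c("T", "A", "T", "A", "A", "A", "T", "A")
  for (j in seq_len(8)) cnt[consensus[j], j] <- 12
  motif_matrix("TATA_test", cnt)
}

# GC-rich 8-bp control motif, consensus GCCACGCC (never implanted)
fx_control_motif <- function() {
  cnt <- matrix(1, nrow = 4, ncol = 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  consensus <- c("G", "C", "C", "A", "C", "G", "C", "C")
  for (j in seq_len(8)) cnt[consensus[j], j] <- 12
  motif_matrix("GC_control", cnt)
}

fx_classes <- function() {
  list(gc_class_spec("hi", 0.45, tss_bump = 0.20, bump_halfwidth = 300,
                     proportion = 0.5),
       gc_class_spec("lo", 0.38, proportion = 0.5))
}

# two-class universes over [-1000, 1000)
fx_universe <- function(n) {
  memo(paste0("uni", n),
       generate_universe(n, fx_classes(), span = c(-1000L, 1000L),
                         seed = 100L + n %% 1000L))
}

fx_scan <- function(n, motif = fx_motif()) {
  memo(paste0("scan", n, "_", motif$motif_id),
       scan_promoters(fx_universe(n), motif))
}

fx_model <- function(n, k = 2L) {
  memo(paste0("model", n, "_", k),
       fit_gc_clusters(fx_universe(n), k, seed = 11L))
}

# per-gene normalized profile cache for null resampling
fx_profiles <- function(n, h2, x_start = -500L, x_stop = 500L) {
  memo(sprintf("prof%d_%d_%d_%d", n, h2, x_start, x_stop),
       site_profiles(fx_scan(n), kernel_spec("gaussian", h2),
                     x_start, x_stop))
}

# bare enrichment_profile / null_distribution fixtures for rule tests
fx_profile_obj <- function(scores, x_start, h2 = 10, motif_id = "M") {
  structure(list(motif_id = motif_id,
                 kernel = kernel_spec("gaussian", h2),
                 x_start = as.integer(x_start),
                 x_stop = as.integer(x_start + length(scores) - 1L),
                 scores = scores, z = numeric(0),
                 n_sequences = 0L),
            class = "enrichment_profile")
}

fx_null_obj <- function(p_dep, p_ind, x_start, h2 = 10, motif_id = "M",
                        n_samples = 100000L) {
  structure(list(motif_id = motif_id,
                 kernel = kernel_spec("gaussian", h2),
                 x_start = as.integer(x_start),
                 x_stop = as.integer(x_start + length(p_dep) - 1L),
                 n_samples = n_samples,
                 exceed_count = as.integer(round(p_dep * n_samples)),
                 sampled_maxima = numeric(0),
                 p_dep = p_dep, p_ind = p_ind, conservative = FALSE),
            class = "null_distribution")
}

# region table row in the shape call_regions() emits
fx_region <- function(region_start, region_end, n_sites, h2 = 10,
                      motif_id = "M", min_p_dep = 1e-5, p_ind = 0.001) {
  structure(data.frame(motif_id = motif_id, half_width = as.integer(h2),
                       x1 = as.integer(region_start + h2),
                       x2 = as.integer(region_end - h2),
                       region_start = as.integer(region_start),
                       region_end = as.integer(region_end),
                       n_sites = as.integer(n_sites),
                       min_p_dep = min_p_dep, p_ind_at_peak = p_ind,
                       stringsAsFactors = FALSE),
            class = c("enriched_regions", "data.frame"))
}

# site collection from a flat spec: data.frame(gene_id, position, class,
# overlaps_strong); gene_ids supplies the full (possibly siteless) universe
fx_sites <- function(df, gene_ids, motif_id = "M", width = 8L) {
  n <- nrow(df)
  if (is.null(df$motif_id)) df$motif_id <- rep(motif_id, n)
  if (is.null(df$strand)) df$strand <- rep("+", n)
  if (is.null(df$score)) df$score <- rep(1, n)
  if (is.null(df$rel_score)) df$rel_score <- rep(0.9, n)
  if (is.null(df$class)) df$class <- rep("strong", n)
  if (is.null(df$overlaps_strong)) df$overlaps_strong <- rep(FALSE, n)
  site_collection(df, motif_id, gene_ids, width)
}
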