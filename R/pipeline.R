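#' Validated run configuration for the full pipeline
#'
#' Holds the spans, kernel widths, thresholds, sampling depths and seeds
#' used by [run_pipeline()].  Validation is strict and happens before any
#' compute: every configured kernel width must have a P_dep threshold.
#'
#' @param scan_span TSS-relative scan window (half-open), default
#'   `c(-3000, 2000)`.
#' @param score_span inclusive scoring bounds for `S_local`, default
#'   `c(-2000, 1000)`.
#' @param half_widths kernel half-widths h/2 (default 10, 20, 50, 100, 200).
#' @param p_dep_thresholds named threshold map by h/2 (default
#'   [default_pdep_thresholds()]).
#' @param p_ind_threshold,p_ori_threshold uniform thresholds (default 0.01).
#' @param n_samples_local,n_samples_ori sampled sets for local enrichment
#'   and ORI p-values (defaults 25000 and 10000: the strictest P_dep
#'   threshold of 5e-5 needs resolution finer than 1/20000).
#' @param kstar_reps samplings per k when choosing k* (default 1000).
#' @param strong_fraction,weak_fraction relative-score site thresholds.
#' @param ks candidate cluster numbers (default 2:10).
#' @param seed master seed; stage seeds are derived from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(scan_span = c(-3000L, 2000L),
                       score_span = c(-2000L, 1000L),
                       half_widths = c(10L, 20L, 50L, 100L, 200L),
                       p_dep_thresholds = default_pdep_thresholds(),
                       p_ind_threshold = 0.01, p_ori_threshold = 0.01,
                       n_samples_local = 25000L, n_samples_ori = 10000L,
                       kstar_reps = 1000L,
                       strong_fraction = 0.85, weak_fraction = 0.70,
                       ks = 2:10, seed = 1L) {
  missing <- setdiff(as.character(half_widths), names(p_dep_thresholds))
  if (length(missing))
    stop("no P_dep threshold configured for h/2 = ",
         paste(missing, collapse = ", "))
  stopifnot(scan_span[1L] < scan_span[2L],
            score_span[1L] < score_span[2L],
            scan_span[1L] <= score_span[1L],
            score_span[2L] <= scan_span[2L],
            p_ind_threshold > 0, p_ori_threshold > 0,
            n_samples_local >= 1L, n_samples_ori >= 1L,
            weak_fraction < strong_fraction, all(ks >= 2L), all(ks <= 10L))
  structure(list(scan_span = as.integer(scan_span),
                 score_span = as.integer(score_span),
                 half_widths = as.integer(half_widths),
                 p_dep_thresholds = p_dep_thresholds,
                 p_ind_threshold = p_ind_threshold,
                 p_ori_threshold = p_ori_threshold,
                 n_samples_local = as.integer(n_samples_local),
                 n_samples_ori = as.integer(n_samples_ori),
                 kstar_reps = as.integer(kstar_reps),
                 strong_fraction = strong_fraction,
                 weak_fraction = weak_fraction,
                 ks = as.integer(ks), seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full local-enrichment pipeline
#'
#' Stages, in order: scan the universe and the input set for each motif;
#' cluster the universe by GC profile and choose k*; compute `S_local`
#' per motif and kernel width; resample the GC-matched null; call,
#' merge and deduplicate enriched regions; compute ORI and P_ORI.  All
#' randomness is driven by seeds derived from `config$seed`, so a rerun
#' with the same inputs is byte-identical.  Inputs are never mutated.
#'
#' @param config a [run_config()].
#' @param genomic the universe [promoter_set].
#' @param input_set the input [promoter_set] (members need not be drawn
#'   from the universe, but spans must match).
#' @param motifs list of [motif_matrix] objects.
#' @param out_dir optional directory; when given, writes
#'   `sites_<motif>.tsv`, `kstar.json`, `profile_<motif>_<h2>.tsv`,
#'   `regions.tsv` and `ori.tsv`.
#' @param quiet suppress progress messages.
#' @return list with `k_star_report`, `model`, per-motif `sites`,
#'   `profiles`, `nulls`, and the `regions` and `ori` tables.
#' @export
run_pipeline <- function(config, genomic, input_set, motifs,
                         out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  motifs <- stats::setNames(motifs,
                            vapply(motifs, `[[`, character(1), "motif_id"))

  say("scanning ", length(genomic), " genomic + ", length(input_set),
      " input promoters for ", length(motifs), " motif(s)")
  sites_g <- lapply(motifs, function(m) scan_promoters(genomic, m))
  sites_s <- lapply(motifs, function(m) scan_promoters(input_set, m))

  say("clustering GC profiles (k = ", min(config$ks), "..",
      max(config$ks), ") and choosing k*")
  gprof <- gc_profiles(genomic)
  models <- fit_gc_models(genomic, ks = config$ks,
                          seed = config$seed, profiles = gprof)
  report <- choose_k_star(genomic, models, input_set,
                          reps = config$kstar_reps, seed = config$seed + 100L)
  model <- models[[as.character(report$k_star)]]
  say("k* = ", report$k_star)

  xs <- config$score_span[1L]; xe <- config$score_span[2L]
  regions_all <- list()
  profiles <- list()
  nulls <- list()
  seed_i <- config$seed + 1000L
  for (mid in names(motifs)) {
    per_width <- list()
    for (h2 in config$half_widths) {
      kern <- kernel_spec("gaussian", h2)
      obs <- local_enrichment(sites_s[[mid]], kern, xs, xe)
      seed_i <- seed_i + 1L
      null <- suppressWarnings(null_pvalues(
        obs, genomic, sites_g[[mid]], model, input_set,
        n_samples = config$n_samples_local, seed = seed_i))
      regs <- call_regions(null, obs, sites = sites_s[[mid]],
                           p_dep_thresholds = config$p_dep_thresholds,
                           p_ind_threshold = config$p_ind_threshold)
      if (nrow(regs)) regs <- merge_same_width(regs, sites = sites_s[[mid]])
      per_width[[as.character(h2)]] <- regs
      profiles[[paste(mid, h2, sep = "_")]] <- obs
      nulls[[paste(mid, h2, sep = "_")]] <- null
    }
    combined <- do.call(rbind, per_width)
    if (!is.null(combined) && nrow(combined) > 1L)
      combined <- remove_cross_width_redundancy(combined)
    regions_all[[mid]] <- combined
    say("motif ", mid, ": ",
        if (is.null(combined)) 0L else nrow(combined), " region(s)")
  }
  regions <- do.call(rbind, regions_all)
  if (is.null(regions)) regions <- .region_df()
  rownames(regions) <- NULL

  say("computing ORI and P_ORI")
  ori_rows <- lapply(names(motifs), function(mid) {
    res <- tryCatch(ori(sites_s[[mid]], sites_g[[mid]]),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    seed_o <- config$seed + 5000L + match(mid, names(motifs))
    res <- p_ori(res, genomic, sites_g[[mid]], model, input_set,
                 n_samples = config$n_samples_ori, seed = seed_o)
    data.frame(motif_id = mid, density_S = res$density_S,
               density_genomic = res$density_genomic,
               proportion_S = res$proportion_S,
               proportion_genomic = res$proportion_genomic,
               ori = res$ori, p_ori = res$p_ori,
               stringsAsFactors = FALSE)
  })
  ori_tab <- do.call(rbind, ori_rows)

  if (!is.null(out_dir)) {
    for (mid in names(motifs))
      write_sites(sites_s[[mid]],
                  file.path(out_dir, paste0("sites_", mid, ".tsv")))
    jsonlite::write_json(
      list(k_star = report$k_star, per_k = report$per_k),
      file.path(out_dir, "kstar.json"), auto_unbox = TRUE, digits = NA)
    for (nm in names(profiles))
      write_profile(profiles[[nm]],
                    file.path(out_dir, paste0("profile_", nm, ".tsv")))
    write_regions(regions, file.path(out_dir, "regions.tsv"))
    if (!is.null(ori_tab))
      utils::write.table(ori_tab, file.path(out_dir, "ori.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(k_star_report = report, model = model, sites_input = sites_s,
       sites_genomic = sites_g, profiles = profiles, nulls = nulls,
       regions = regions, ori = ori_tab)
}
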