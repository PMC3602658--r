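#' Width-dependent P_dep thresholds
#'
#' Narrower kernels evaluate more independent positions, so their
#' position-dependent p-value threshold is stricter: 1e-3, 5e-4, 2e-4,
#' 1e-4 and 5e-5 for h/2 = 200, 100, 50, 20 and 10 bp respectively.
#'
#' @return named numeric vector (names are h/2 values).
#' @export
default_pdep_thresholds <- function() {
  c(`200` = 1e-3, `100` = 5e-4, `50` = 2e-4, `20` = 1e-4, `10` = 5e-5)
}

# count strong sites of the collection inside [start, end] inclusive
count_region_sites <- function(sites, start, end, site_class = "strong") {
  df <- sites$sites
  sum(df$class %in% site_class & df$position >= start & df$position <= end)
}

.region_df <- function(motif_id = character(), half_width = integer(),
                       x1 = integer(), x2 = integer(),
                       region_start = integer(), region_end = integer(),
                       n_sites = integer(), min_p_dep = numeric(),
                       p_ind_at_peak = numeric()) {
  structure(data.frame(motif_id, half_width, x1, x2, region_start,
                       region_end, n_sites, min_p_dep, p_ind_at_peak,
                       stringsAsFactors = FALSE),
            class = c("enriched_regions", "data.frame"))
}

#' Call locally enriched regions from empirical p-values
#'
#' A position is significant when `P_dep(x)` is below the width-dependent
#' threshold and `P_ind(x) < p_ind_threshold`.  Each maximal run of
#' consecutive significant positions `[x1, x2]` becomes a region, expanded
#' by h/2 on both sides to `[x1 - h/2, x2 + h/2]`.  Runs separated by even
#' a single non-significant bp stay separate (the later same-width merge
#' bridges small gaps via the expansion).
#'
#' @param null a `null_distribution` from [null_pvalues()].
#' @param obs the matching `enrichment_profile`.
#' @param sites optional input-set [site_collection] used to count the
#'   motif's strong sites per region (`n_sites`; `NA` when absent).
#' @param p_dep_thresholds named threshold map by h/2; a configured width
#'   missing from the map is an error.
#' @param p_ind_threshold uniform P_ind threshold (default 0.01).
#' @return an `enriched_regions` data.frame (possibly zero rows) with
#'   columns `motif_id`, `half_width`, `x1`, `x2`, `region_start`,
#'   `region_end`, `n_sites`, `min_p_dep`, `p_ind_at_peak`.
#' @export
call_regions <- function(null, obs, sites = NULL,
                         p_dep_thresholds = default_pdep_thresholds(),
                         p_ind_threshold = 0.01) {
  stopifnot(null$x_start == obs$x_start, null$x_stop == obs$x_stop,
            null$kernel$half_width == obs$kernel$half_width)
  h2 <- obs$kernel$half_width
  thr <- unname(p_dep_thresholds[as.character(h2)])
  if (length(thr) != 1L || is.na(thr))
    stop("no P_dep threshold configured for h/2 = ", h2,
         "; supply one via `p_dep_thresholds`")
  sig <- null$p_dep < thr & null$p_ind < p_ind_threshold
  if (!any(sig)) return(.region_df())
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  xs <- obs$x_start
  out <- lapply(keep, function(i) {
    x1 <- xs + starts[i] - 1L
    x2 <- xs + ends[i] - 1L
    idx <- starts[i]:ends[i]
    peak <- idx[which.max(obs$scores[idx])]
    .region_df(motif_id = obs$motif_id, half_width = as.integer(h2),
               x1 = x1, x2 = x2,
               region_start = as.integer(x1 - h2),
               region_end = as.integer(x2 + h2),
               n_sites = if (is.null(sites)) NA_integer_ else
                 count_region_sites(sites, x1 - h2, x2 + h2),
               min_p_dep = min(null$p_dep[idx]),
               p_ind_at_peak = null$p_ind[peak])
  })
  do.call(rbind, out)
}

# transitive overlap groups over inclusive [start, end] intervals
.overlap_groups <- function(start, end) {
  ord <- order(start, end)
  grp <- integer(length(start))
  g <- 0L
  cur_end <- -Inf
  for (i in ord) {
    if (start[i] > cur_end) {
      g <- g + 1L
      cur_end <- end[i]
    } else cur_end <- max(cur_end, end[i])
    grp[i] <- g
  }
  grp
}

#' Merge overlapping regions of the same kernel width
#'
#' Overlapping (expanded) regions for the same motif and h/2 are unioned
#' into one region; `x1`/`x2` span the members, the reported `min_p_dep`
#' is the members' minimum with its member's `p_ind_at_peak`, and
#' `n_sites` is recounted over the union when `sites` is given.
#'
#' @param regions an `enriched_regions` data.frame (one motif, one width).
#' @inheritParams call_regions
#' @export
merge_same_width <- function(regions, sites = NULL) {
  if (nrow(regions) <= 1L) return(regions)
  stopifnot(length(unique(regions$half_width)) == 1L,
            length(unique(regions$motif_id)) == 1L)
  grp <- .overlap_groups(regions$region_start, regions$region_end)
  out <- lapply(split(seq_len(nrow(regions)), grp), function(i) {
    r <- regions[i, , drop = FALSE]
    best <- which.min(r$min_p_dep)
    rs <- min(r$region_start); re <- max(r$region_end)
    .region_df(motif_id = r$motif_id[1L], half_width = r$half_width[1L],
               x1 = min(r$x1), x2 = max(r$x2),
               region_start = rs, region_end = re,
               n_sites = if (is.null(sites)) {
                 if (anyNA(r$n_sites)) NA_integer_ else sum(r$n_sites)
               } else count_region_sites(sites, rs, re),
               min_p_dep = r$min_p_dep[best],
               p_ind_at_peak = r$p_ind_at_peak[best])
  })
  res <- do.call(rbind, out)
  res[order(res$region_start), , drop = FALSE]
}

# deterministic pick among candidate rows: largest span, then more sites,
# then smaller region_start
.pick_largest <- function(r) {
  span <- r$region_end - r$region_start
  r <- r[order(-span, -r$n_sites, r$region_start), , drop = FALSE]
  r[1L, , drop = FALSE]
}

#' Remove redundancy between regions called at different kernel widths
#'
#' Regions of the same motif that overlap (any widths) are grouped
#' transitively; each group is reduced to one representative.  The largest
#' region (by bp span) is kept, unless a smaller member contains strictly
#' more than 2/3 of the largest member's sites — then the smallest such
#' member is kept instead, preferring narrow regions dense in sites.
#' Ties (equal span) resolve to the member with more sites, then the
#' smaller `region_start`.
#'
#' @param regions an `enriched_regions` data.frame for one motif with
#'   `n_sites` populated.
#' @export
remove_cross_width_redundancy <- function(regions) {
  if (nrow(regions) <= 1L) return(regions)
  stopifnot(length(unique(regions$motif_id)) == 1L,
            !anyNA(regions$n_sites))
  grp <- .overlap_groups(regions$region_start, regions$region_end)
  out <- lapply(split(seq_len(nrow(regions)), grp), function(i) {
    r <- regions[i, , drop = FALSE]
    largest <- .pick_largest(r)
    span <- r$region_end - r$region_start
    qualifies <- span < (largest$region_end - largest$region_start) &
      r$n_sites > (2 / 3) * largest$n_sites
    if (!any(qualifies)) return(largest)
    q <- r[qualifies, , drop = FALSE]
    qspan <- q$region_end - q$region_start
    q <- q[order(qspan, -q$n_sites, q$region_start), , drop = FALSE]
    q[1L, , drop = FALSE]
  })
  res <- do.call(rbind, out)
  res <- res[order(res$region_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write called regions as TSV
#' @param regions an `enriched_regions` data.frame; @param path output file.
#' @export
write_regions <- function(regions, path) {
  utils::write.table(regions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export regions as genome-anchored BED6
#'
#' Needs `tss=chrom:pos:strand` header tags in the promoter set.  The BED
#' score is `-10 log10(min_p_dep)` capped at 1000 (p-values of 0 map to
#' the cap).  TSS-relative coordinates are projected through the strand.
#'
#' @param regions an `enriched_regions` data.frame.
#' @param set the [promoter_set] whose tags carry the TSS anchors; the
#'   first tagged gene's anchor is used per region (regions are
#'   set-level, not per-gene, so one representative anchor is exported).
#' @param path output BED file.
#' @export
regions_to_bed <- function(regions, set, path) {
  tag <- regmatches(set$tags, regexpr("tss=\\S+", set$tags))
  if (length(tag) == 0L) stop("no tss=chrom:pos:strand tags in the set")
  parts <- strsplit(sub("^tss=", "", tag[1L]), ":")[[1]]
  chrom <- parts[1L]; tsspos <- as.integer(parts[2L]); strand <- parts[3L]
  score <- pmin(1000, ifelse(regions$min_p_dep <= 0, 1000,
                             -10 * log10(regions$min_p_dep)))
  if (strand == "+") {
    start <- tsspos + regions$region_start
    end <- tsspos + regions$region_end + 1L
  } else {
    start <- tsspos - regions$region_end - 1L
    end <- tsspos - regions$region_start
  }
  bed <- data.frame(chrom, start, end, name = regions$motif_id,
                    score = round(score), strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
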