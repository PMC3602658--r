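test_that("significant runs become regions expanded by h/2", {
  # positions -100..100, significant run at -50..-40, h/2 = 10
  x <- -100:100
  p_dep <- rep(0.5, length(x)); p_ind <- rep(0.5, length(x))
  run <- x >= -50 & x <= -40
  p_dep[run] <- 1e-6; p_ind[run] <- 0.001
  null <- fx_null_obj(p_dep, p_ind, -100L)
  obs <- fx_profile_obj(rep(1, length(x)), -100L)
  regs <- call_regions(null, obs)
  expect_equal(nrow(regs), 1L)
  expect_equal(regs$x1, -50L); expect_equal(regs$x2, -40L)
  expect_equal(regs$region_start, -60L); expect_equal(regs$region_end, -30L)

  # both filters must pass
  p_ind[run] <- 0.5
  empty <- call_regions(fx_null_obj(p_dep, p_ind, -100L), obs)
  expect_equal(nrow(empty), 0L)
})

test_that("width-dependent P_dep thresholds are enforced as configured", {
  thr <- default_pdep_thresholds()
  expect_equal(thr[["200"]], 1e-3)
  expect_equal(thr[["100"]], 5e-4)
  expect_equal(thr[["50"]], 2e-4)
  expect_equal(thr[["20"]], 1e-4)
  expect_equal(thr[["10"]], 5e-5)

  x <- -20:20
  p_dep <- rep(1.2e-4, length(x))   # between the h/2=20 and h/2=50 cutoffs
  p_ind <- rep(1e-3, length(x))
  obs20 <- fx_profile_obj(rep(1, length(x)), -20L, h2 = 20)
  expect_equal(nrow(call_regions(fx_null_obj(p_dep, p_ind, -20L, h2 = 20),
                                 obs20)), 0L)
  obs50 <- fx_profile_obj(rep(1, length(x)), -20L, h2 = 50)
  expect_equal(nrow(call_regions(fx_null_obj(p_dep, p_ind, -20L, h2 = 50),
                                 obs50)), 1L)

  # unknown width needs an explicit threshold
  obs30 <- fx_profile_obj(rep(1, length(x)), -20L, h2 = 30)
  expect_error(call_regions(fx_null_obj(p_dep, p_ind, -20L, h2 = 30), obs30),
               "h/2 = 30")
  expect_equal(nrow(call_regions(fx_null_obj(p_dep, p_ind, -20L, h2 = 30),
                                 obs30, p_dep_thresholds = c(`30` = 1.5e-4))),
               1L)
})

test_that("runs split by one non-significant bp merge via expansion only", {
  x <- -100:100
  p_dep <- rep(0.5, length(x)); p_ind <- rep(0.5, length(x))
  sig <- (x >= -50 & x <= -45) | (x >= -43 & x <= -40)   # gap at -44
  p_dep[sig] <- 1e-6; p_ind[sig] <- 0.001
  null <- fx_null_obj(p_dep, p_ind, -100L)
  obs <- fx_profile_obj(rep(1, length(x)), -100L)
  regs <- call_regions(null, obs)
  expect_equal(nrow(regs), 2L)                   # runs are NOT joined
  merged <- merge_same_width(regs)
  expect_equal(nrow(merged), 1L)                 # expansion bridges the gap
  expect_equal(merged$region_start, -60L)
  expect_equal(merged$region_end, -30L)
})

test_that("same-width merging unions overlaps and recounts sites", {
  a <- fx_region(-60, -30, 5, min_p_dep = 1e-5, p_ind = 0.002)
  b <- fx_region(-35, -10, 7, min_p_dep = 1e-6, p_ind = 0.004)
  m <- merge_same_width(rbind(a, b))
  expect_equal(nrow(m), 1L)
  expect_equal(m$region_start, -60L); expect_equal(m$region_end, -10L)
  expect_equal(m$min_p_dep, 1e-6)                # member minimum
  expect_equal(m$p_ind_at_peak, 0.004)           # that member's P_ind

  # disjoint regions stay apart
  d <- merge_same_width(rbind(fx_region(-60, -30, 5), fx_region(100, 150, 3)))
  expect_equal(nrow(d), 2L)

  # three chained overlaps collapse to one
  ch <- merge_same_width(rbind(fx_region(-60, -30, 2), fx_region(-35, -5, 2),
                               fx_region(-10, 20, 2)))
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$region_start, -60L); expect_equal(ch$region_end, 20L)

  # recount against a site collection covers the union
  sites <- fx_sites(data.frame(gene_id = "g1",
                               position = c(-55L, -40L, -20L, 90L)),
                    gene_ids = "g1")
  m2 <- merge_same_width(rbind(a, b), sites = sites)
  expect_equal(m2$n_sites, 3L)
})

test_that("the 2/3 rule keeps the right representative per overlap group", {
  # strictly more than 2/3: B (21 > 20) beats the 400-bp region
  g <- rbind(fx_region(-200, 200, 30, h2 = 200),
             fx_region(-100, 20, 21, h2 = 20))
  expect_equal(remove_cross_width_redundancy(g)$n_sites, 21L)
  # exactly 2/3 does not qualify: the largest region stays
  g2 <- rbind(fx_region(-200, 200, 30, h2 = 200),
              fx_region(-100, 20, 20, h2 = 20))
  expect_equal(remove_cross_width_redundancy(g2)$n_sites, 30L)
  # smallest qualifying region wins over an intermediate one
  g3 <- rbind(fx_region(-200, 200, 30, h2 = 200),
              fx_region(-100, 20, 22, h2 = 20),
              fx_region(-150, 50, 25, h2 = 50))
  expect_equal(remove_cross_width_redundancy(g3)$n_sites, 22L)
  # non-overlapping groups are resolved independently; in the first group
  # the 100-bp region holds 9 > 2/3 * 10 sites and displaces the larger one
  g4 <- rbind(fx_region(-200, 0, 10, h2 = 100),
              fx_region(-150, -50, 9, h2 = 20),
              fx_region(300, 500, 4, h2 = 100))
  out <- remove_cross_width_redundancy(g4)
  expect_equal(nrow(out), 2L)
  expect_equal(out$n_sites, c(9L, 4L))
  g5 <- rbind(fx_region(-200, 0, 10, h2 = 100),
              fx_region(-150, -50, 6, h2 = 20),   # 6 < 2/3 * 10
              fx_region(300, 500, 4, h2 = 100))
  expect_equal(remove_cross_width_redundancy(g5)$n_sites, c(10L, 4L))
})

test_that("span ties resolve to more sites, then smaller start", {
  t1 <- rbind(fx_region(-100, 0, 10, h2 = 50),
              fx_region(-50, 50, 14, h2 = 50))
  expect_equal(remove_cross_width_redundancy(t1)$n_sites, 14L)
  t2 <- rbind(fx_region(-100, 0, 10, h2 = 50),
              fx_region(-50, 50, 10, h2 = 50))
  expect_equal(remove_cross_width_redundancy(t2)$region_start, -100L)
})

test_that("deduplicated regions never overlap and recounts are exact", {
  withr::with_seed(14, {
    for (trial in 1:10) {
      n <- sample(3:8, 1)
      start <- sample(seq(-400, 200, by = 10), n)
      len <- sample(c(40, 100, 200, 400), n, replace = TRUE)
      regs <- do.call(rbind, lapply(seq_len(n), function(i)
        fx_region(start[i], start[i] + len[i], sample(0:30, 1),
                  h2 = sample(c(10, 20, 50, 100, 200), 1))))
      out <- remove_cross_width_redundancy(regs)
      if (nrow(out) > 1L) {
        o <- out[order(out$region_start), ]
        expect_true(all(o$region_start[-1] > o$region_end[-nrow(o)]))
      }
    }
  })
  # n_sites equals a brute-force recount of strong sites within bounds
  sc <- fx_scan(800)
  input <- fx_universe(800)[1:50]
  sub <- subset_sites(sc, names(input$seqs))
  reg <- fx_region(-120, -40, 0)
  cnt <- localmotif:::count_region_sites(sub, -120, -40)
  df <- sub$sites
  brute <- sum(df$class == "strong" & df$position >= -120 & df$position <= -40)
  expect_equal(cnt, brute)
})

test_that("BED export projects TSS-relative regions through the anchor", {
  set <- promoter_set(c(g1 = strrep("A", 100)), -50L, 50L,
                      tags = "tss=chr7:5000:+")
  regs <- fx_region(-60, -30, 5, min_p_dep = 1e-4)
  f <- tempfile(fileext = ".bed")
  regions_to_bed(regs, set, f)
  bed <- utils::read.delim(f, header = FALSE)
  expect_equal(bed$V1, "chr7")
  expect_equal(bed$V2, 5000 - 60)
  expect_equal(bed$V3, 5000 - 30 + 1)
  expect_equal(bed$V5, 40)          # -10 log10(1e-4)
  set_m <- promoter_set(c(g1 = strrep("A", 100)), -50L, 50L,
                        tags = "tss=chr7:5000:-")
  regions_to_bed(regs, set_m, f)
  bed <- utils::read.delim(f, header = FALSE)
  expect_equal(bed$V2, 5000 + 30 - 1)
  expect_equal(bed$V3, 5000 + 60)
})
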