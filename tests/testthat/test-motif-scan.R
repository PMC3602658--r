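# naive per-window rescoring oracle: double loop over strands and windows
naive_scan <- function(seq, motif, span_start) {
  w <- motif$width
  bases <- strsplit(seq, "")[[1]]
  rc_lo <- reverse_complement_motif(motif)$logodds
  hits <- list()
  for (i in seq_len(nchar(seq) - w + 1L)) {
    win <- bases[i:(i + w - 1L)]
    if (any(!win %in% c("A", "C", "G", "T"))) next
    for (strand in c("+", "-")) {
      lo <- if (strand == "+") motif$logodds else rc_lo
      sc <- 0
      for (j in seq_len(w)) sc <- sc + lo[win[j], j]
      rel <- (sc - motif$min_score) / (motif$max_score - motif$min_score)
      if (rel >= motif$weak_fraction)
        hits[[length(hits) + 1L]] <- data.frame(
          position = span_start + (i - 1L) + (w - 1L) %/% 2L,
          strand = strand, score = sc,
          class = if (rel >= motif$strong_fraction) "strong" else "weak",
          stringsAsFactors = FALSE)
    }
  }
  if (length(hits)) do.call(rbind, hits) else NULL
}

test_that("motif_matrix applies pseudocount and rejects degenerate input", {
  cnt <- matrix(c(10, 0, 0, 0), nrow = 4, ncol = 6,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  m <- motif_matrix("polyA", cnt)
  expect_equal(colSums(m$prob), rep(1, 6))
  expect_equal(unname(m$prob["A", 1]), (10 + 0.8 * 0.25) / 10.8)
  expect_gt(m$max_score, m$min_score)
  # all-zero column without a pseudocount is rejected
  cnt0 <- cnt; cnt0[, 3] <- 0
  expect_error(motif_matrix("bad", cnt0, pseudocount = 0), "pseudocount")
})

test_that("JASPAR PFM and TRANSFAC dialects parse to the same matrix", {
  fj <- tempfile(fileext = ".pfm")
  writeLines(c(">M0001 test",
               "A [ 0  3 79 40 66 48 ]",
               "C [94 75  4  3  1  2 ]",
               "G [ 1  0  3  4  1  0 ]",
               "T [ 2 19 11 50 29 47 ]"), fj)
  mj <- parse_motifs(fj, "jaspar_pfm")
  expect_length(mj, 1L)
  expect_equal(mj[[1]]$width, 6L)
  expect_equal(unname(mj[[1]]$counts["C", ]), c(94, 75, 4, 3, 1, 2))

  ft <- tempfile(fileext = ".dat")
  writeLines(c("AC M0001", "XX", "P0      A      C      G      T",
               "01      0     94      1      2      S",
               "02      3     75      0     19      C",
               "03     79      4      3     11      A",
               "04     40      3      4     50      W",
               "05     66      1      1     29      A",
               "06     48      2      0     47      W",
               "XX", "//"), ft)
  mt <- parse_motifs(ft, "transfac")
  expect_equal(mt[[1]]$counts, mj[[1]]$counts)
  expect_equal(mt[[1]]$logodds, mj[[1]]$logodds)

  # malformed block reports the offending line
  writeLines(c(">M0002 bad", "A [ 1 2 3 ]", "C [ x ]"), fj)
  expect_error(parse_motifs(fj, "jaspar_pfm"), "line")
})

test_that("scan finds a planted consensus exactly once at its midpoint", {
  m <- fx_motif()                       # consensus TATAAATA, w = 8
  bg <- strrep("C", 100)
  seq <- paste0(substr(bg, 1, 40), motif_consensus(m),
                substr(bg, 49, 100))    # word occupies index 41..48
  ps <- promoter_set(stats::setNames(seq, "g1"), -50L, 50L)
  sc <- scan_promoters(ps, m)
  strong <- sc$sites[sc$sites$class == "strong", ]
  expect_equal(nrow(strong), 1L)
  # midpoint floor: start index 41 -> rel start -10, anchor -10 + 3 = -7
  expect_equal(strong$position, -7L)
  expect_equal(strong$rel_score, 1)
})

test_that("all-N sequences yield no sites", {
  ps <- promoter_set(c(g1 = strrep("N", 100)), -50L, 50L)
  sc <- scan_promoters(ps, fx_motif())
  expect_equal(nrow(sc$sites), 0L)
  expect_equal(sc$gene_ids, "g1")
})

test_that("a word at intermediate relative score is classified weak", {
  m <- fx_motif()
  # two mismatches to the consensus: direct evaluation gives the oracle
  word <- "TGTAAATG"
  chars <- strsplit(word, "")[[1]]
  sc <- sum(vapply(1:8, function(j) m$logodds[chars[j], j], numeric(1)))
  rel <- (sc - m$min_score) / (m$max_score - m$min_score)
  expect_gte(rel, 0.70); expect_lt(rel, 0.85)   # sits in the weak band

  seq <- paste0(strrep("C", 40), word, strrep("C", 52))
  ps <- promoter_set(stats::setNames(seq, "g1"), -50L, 50L)
  hits <- scan_promoters(ps, m)$sites
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$class, "weak")
  expect_equal(hits$rel_score, rel)
})

test_that("hits on short sequences match the exhaustive rescoring oracle", {
  m <- fx_motif()
  withr::with_seed(9, {
    for (trial in 1:20) {
      seq <- paste(sample(c("A", "C", "G", "T", "N"), 60, replace = TRUE,
                          prob = c(0.3, 0.2, 0.2, 0.29, 0.01)),
                   collapse = "")
      ps <- promoter_set(stats::setNames(seq, "g1"), -30L, 30L)
      got <- scan_promoters(ps, m)$sites
      want <- naive_scan(seq, m, -30L)
      if (is.null(want)) {
        expect_equal(nrow(got), 0L)
      } else {
        want <- want[order(want$position, want$strand), ]
        got <- got[order(got$position, got$strand), ]
        expect_equal(got$position, want$position)
        expect_equal(got$strand, want$strand)
        expect_equal(got$score, want$score)
        expect_equal(got$class, want$class)
      }
    }
  })
})

test_that("reverse-complementing set and matrix mirrors site positions", {
  # odd width keeps the midpoint-floor anchor exactly mirror-symmetric
  cnt <- matrix(1, 4, 7, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in 1:7) cnt[c("T", "A", "T", "A", "A", "A", "T")[j], j] <- 10
  m <- motif_matrix("odd", cnt)
  withr::with_seed(31, {
    seqs <- vapply(1:5, function(i)
      paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
            collapse = ""), character(1))
  })
  names(seqs) <- paste0("g", 1:5)
  ps <- promoter_set(seqs, -40L, 40L)
  rc <- vapply(seqs, function(s)
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = "")),
    character(1))
  ps_rc <- promoter_set(rc, -40L, 40L)
  a <- scan_promoters(ps, m)$sites
  b <- scan_promoters(ps_rc, reverse_complement_motif(m))$sites
  # anchor a on the forward set maps to (start + end - 1) - a = -1 - a
  expect_setequal(paste(a$gene_id, -1L - a$position),
                  paste(b$gene_id, b$position))
  expect_equal(sort(a$score), sort(b$score))
})

test_that("lowering strong_fraction never loses strong hits", {
  uni <- fx_universe(800)[1:20]
  cnt <- fx_motif()$counts
  hits <- vapply(c(0.95, 0.85, 0.75), function(f) {
    m <- motif_matrix("m", cnt, strong_fraction = f, weak_fraction = f - 0.05)
    sum(scan_promoters(uni, m)$sites$class == "strong")
  }, numeric(1))
  expect_true(all(diff(hits) >= 0))
})

test_that("weak sites overlapping strong sites of the same motif are flagged", {
  m <- fx_motif()
  # strong consensus at index 41..48; overlapping weak word at 45..52 would
  # disturb the strong one, so implant consensus then check flags from scan
  seq <- paste0(strrep("C", 40), "TATAAATA", "TATCAATA", strrep("C", 44))
  ps <- promoter_set(stats::setNames(seq, "g1"), -50L, 50L)
  df <- scan_promoters(ps, m)$sites
  expect_true(any(df$class == "strong"))
  # any weak hit within 7 bp of a strong hit must carry the flag
  strong_pos <- df$position[df$class == "strong"]
  for (i in which(df$class == "weak")) {
    near <- any(abs(df$position[i] - strong_pos) < 8L)
    expect_equal(df$overlaps_strong[i], near)
  }
})
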