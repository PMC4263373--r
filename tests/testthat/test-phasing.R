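test_that("strand merge applies the 2-nt Dicer overhang adjustment", {
  # plus 21-mer at [1000,1021) and its duplex partner at [998,1019)
  rec <- make_records(start = c(1000L, 998L), length = 21L,
                      strand = c("+", "-"), copies = c(2L, 3L))
  pm <- merge_strands(rec, abundance = "copies")
  expect_equal(nrow(pm), 1L)
  expect_equal(pm$pos, 1000L)
  expect_equal(pm$abundance, 5)
  expect_equal(pm$reads, 5)
  # plus read alone maps to its start; minus at leftmost 0 maps to 2
  pm2 <- merge_strands(make_records(start = c(10L, 0L), length = 21L,
                                    strand = c("+", "-")),
                       abundance = "copies")
  expect_equal(pm2$pos, c(2L, 10L))
})

test_that("phase cycle counts match floor(window / k)", {
  expect_identical(phase_cycles(21L), 23L)
  expect_identical(phase_cycles(22L), 22L)
  expect_identical(phase_cycles(24L), 20L)
})

test_that("phasing score matches direct arithmetic and its boundary rules", {
  expect_equal(phasing_score(100, 0, 5), 3 * log(1001))
  expect_equal(phasing_score(100, 100, 10), 8 * log(1 + 1000 / 101))
  expect_equal(phasing_score(50, 3, 2), 0)   # n < 3 scores zero
  expect_equal(phasing_score(0, 10, 5), 0)   # no in-phase abundance
  expect_error(phasing_score(-1, 0, 5), "non-negative")
  # monotonicity: non-decreasing in P and n, non-increasing in U
  expect_gte(phasing_score(200, 10, 5), phasing_score(100, 10, 5))
  expect_gte(phasing_score(100, 10, 6), phasing_score(100, 10, 5))
  expect_lte(phasing_score(100, 20, 5), phasing_score(100, 10, 5))
})

test_that("scan_windows agrees with brute-force register enumeration", {
  set.seed(42)
  for (k in c(21L, 22L, 24L)) {
    for (rep in 1:20) {
      n_pos <- sample(4:25, 1)
      pm <- tibble::tibble(
        chrom = "chr1",
        pos = sort(sample.int(480L, n_pos)),
        abundance = round(runif(n_pos, 0.5, 50), 2),
        reads = sample.int(20L, n_pos, replace = TRUE)
      )
      got <- scan_windows(pm, k = k, window_len = 500L, step = 500L,
                          min_inphase_reads = 1, threshold = 25)
      want <- brute_force_phase(pm$pos, pm$abundance, pm$reads,
                                w = 0L, k = k, window_len = 500L)
      expect_equal(got$score[1], want$score, tolerance = 1e-9)
      expect_equal(got$register[1], want$register)
      expect_equal(got$n[1], want$n)
      expect_equal(got$P[1], want$P)
      expect_equal(got$U[1], want$U)
    }
  }
})

test_that("scores and registers are equivariant under +k translation", {
  set.seed(7)
  pm <- tibble::tibble(
    chrom = "chr1",
    pos = sort(sample.int(400L, 12L)) + 21L,
    abundance = runif(12, 1, 30),
    reads = rep(3L, 12)
  )
  a <- scan_windows(pm, k = 21L, step = 21L, min_inphase_reads = 1)
  pm2 <- pm
  pm2$pos <- pm$pos + 21L
  b <- scan_windows(pm2, k = 21L, step = 21L, min_inphase_reads = 1)
  # compare the window starting 21 nt later on the shifted data
  ab <- dplyr::inner_join(a, dplyr::mutate(b, start = start - 21L),
                          by = "start", suffix = c("", ".shift"))
  ab <- ab[ab$n == ab$n.shift, , drop = FALSE]  # same reads in window
  expect_gt(nrow(ab), 0)
  expect_equal(ab$score, ab$score.shift, tolerance = 1e-9)
  expect_equal(ab$register, ab$register.shift)
})

test_that("perfectly phased reads qualify and sparse ones do not", {
  # 6 phased 21-mers, 10 copies each, zero noise
  pm <- tibble::tibble(chrom = "chr1", pos = 100L + 21L * (0:5),
                       abundance = 10, reads = 10L)
  w <- scan_windows(pm, k = 21L, step = 500L)
  expect_true(w$candidate[1])
  expect_equal(w$n[1], 6L)
  expect_equal(w$U[1], 0)
  expect_equal(w$score[1], 4 * log(1 + 10 * 60))
  expect_true(w$qualifies[1])
  # 4 in-register reads only: below the 5-read candidacy floor
  pm4 <- tibble::tibble(chrom = "chr1", pos = 100L + 21L * (0:3),
                        abundance = 100, reads = 1L)
  w4 <- scan_windows(pm4, k = 21L, step = 500L)
  expect_false(w4$candidate[1])
  expect_false(w4$qualifies[1])
})

test_that("uniform random positions rarely reach the score threshold", {
  set.seed(99)
  hits <- 0L
  for (i in 1:100) {
    pm <- tibble::tibble(
      chrom = "chr1",
      pos = sort(sample.int(499L, 40L)),
      abundance = 60 / 40,  # equal total abundance to a phased locus
      reads = 1L
    )
    w <- scan_windows(pm, k = 21L, step = 500L)
    if (any(w$score >= 25)) hits <- hits + 1L
  }
  expect_lte(hits, 1L)
})

test_that("qualifying windows merge into clusters keeping the best window", {
  w <- tibble::tibble(
    chrom = "chr1",
    start = c(0L, 250L, 2000L),
    end = c(500L, 750L, 2500L),
    k = 21L,
    register = c(4L, 4L, 9L),
    n = c(6L, 8L, 5L),
    P = c(50, 80, 40), U = c(1, 2, 1),
    inphase_reads = c(20, 30, 12),
    score = c(30, 45, 28),
    candidate = TRUE,
    qualifies = TRUE
  )
  cl <- merge_clusters(w)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$start, c(0L, 2000L))
  expect_equal(cl$end, c(750L, 2500L))
  expect_equal(cl$score, c(45, 28))
  expect_equal(cl$register, c(4L, 9L))
  expect_equal(cl$n_windows, c(2L, 1L))
  # non-qualifying windows are dropped; empty input gives empty output
  w$qualifies <- FALSE
  expect_equal(nrow(merge_clusters(w)), 0L)
})

test_that("clusters are flagged by overlap with down-in-mutant windows", {
  cl <- tibble::tibble(chrom = "chr1", start = 100L, end = 600L, k = 21L,
                       register = 1L, n = 6L, P = 50, U = 1, score = 30,
                       n_windows = 1L)
  diff_down <- tibble::tibble(chrom = "chr1", start = 500L, end = 1000L,
                              size_class = 21L, log2fc = -3, p = 1e-5,
                              q = 1e-4, direction = "down_in_mutant",
                              passes = TRUE, reason = "pass")
  expect_true(flag_lbl1_dependent(cl, diff_down)$lbl1_dependent)
  # up-in-mutant overlap does not flag
  diff_up <- diff_down
  diff_up$direction <- "up_in_mutant"
  expect_false(flag_lbl1_dependent(cl, diff_up)$lbl1_dependent)
  # no differential data -> NA
  expect_true(is.na(flag_lbl1_dependent(cl, NULL)$lbl1_dependent))
})
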