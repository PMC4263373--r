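make_design <- function(n_rep = 3L, total = 1e6) {
  library_design(
    name = c(paste0("wt", seq_len(n_rep)), paste0("mut", seq_len(n_rep))),
    genotype = rep(c("wildtype", "mutant"), each = n_rep),
    replicate = rep(seq_len(n_rep), 2L),
    genome_matched_total = rep(total, 2L * n_rep)
  )
}

# counts tibble for one window per row, from a matrix of library counts
counts_from_matrix <- function(m, design, size_class = 21L) {
  colnames(m) <- design$name
  out <- tibble::tibble(
    chrom = "chr1",
    start = (seq_len(nrow(m)) - 1L) * 500L,
    end = seq_len(nrow(m)) * 500L,
    size_class = size_class
  )
  dplyr::bind_cols(out, tibble::as_tibble(m))
}

test_that("reads are assigned to the window containing their 5' end", {
  rec <- make_records(
    start = c(499L, 500L, 480L, 0L),
    length = c(21L, 21L, 21L, 22L),
    strand = c("+", "+", "-", "+"),
    library = "wt1"
  )
  # minus read at [480,501): 5' end = 500 -> second window
  cnt <- count_windows(rec, size_class = 21L, window_len = 500L,
                       libraries = c("wt1", "wt2"))
  expect_equal(cnt$start, c(0L, 500L))
  expect_equal(cnt$wt1, c(1, 2))
  expect_equal(cnt$wt2, c(0, 0))  # absent library -> all-zero column
  # the 22-nt read appears only in the 22-nt matrix
  cnt22 <- count_windows(rec, size_class = 22L, libraries = "wt1")
  expect_equal(sum(cnt22$wt1), 1)
})

test_that("window counts conserve retained reads per library and size", {
  set.seed(21)
  rec <- make_records(
    start = sample.int(5000L, 200L, replace = TRUE),
    length = sample(c(21L, 22L, 24L), 200L, replace = TRUE),
    strand = sample(c("+", "-"), 200L, replace = TRUE),
    copies = sample.int(5L, 200L, replace = TRUE),
    library = sample(c("wt1", "mut1"), 200L, replace = TRUE)
  )
  for (k in c(21L, 22L, 24L)) {
    cnt <- count_windows(rec, size_class = k,
                         libraries = c("wt1", "mut1"))
    for (lb in c("wt1", "mut1")) {
      expect_equal(sum(cnt[[lb]]),
                   sum(rec$copies[rec$length == k & rec$library == lb]))
    }
  }
})

test_that("low-count windows are removed at the stated boundary", {
  design <- make_design()
  m <- rbind(c(3, 3, 3, 0, 0, 0),   # total 9  -> removed
             c(3, 3, 3, 1, 0, 0),   # total 10 -> kept
             c(50, 60, 55, 5, 5, 5))
  counts <- counts_from_matrix(m, design)
  kept <- filter_low_windows(counts, min_total = 10,
                             libraries = design$name)
  expect_equal(kept$start, c(500L, 1000L))
  expect_warning(
    empty <- filter_low_windows(counts_from_matrix(m[1, , drop = FALSE],
                                                   design),
                                min_total = 10, libraries = design$name),
    "below the minimum"
  )
  expect_equal(nrow(empty), 0L)
})

test_that("nb_test fold changes use the 0.5 pseudo-count on normalized means", {
  design <- make_design()
  m <- rbind(c(0, 0, 0, 50, 60, 55),
             c(20, 20, 20, 20, 20, 20),
             c(100, 110, 90, 210, 190, 200))
  res <- nb_test(counts_from_matrix(m, design), design)
  # WT (0,0,0) vs mut (50,60,55): log2((55 + 0.5) / (0 + 0.5))
  expect_equal(res$log2fc[1], log2(55.5 / 0.5), tolerance = 1e-12)
  expect_equal(res$direction[1], "up_in_mutant")
  # identical counts: no fold change, p near 1
  expect_equal(res$log2fc[2], 0)
  expect_gt(res$p[2], 0.9)
  expect_true(all(res$p >= 0 & res$p <= 1))
})

test_that("nb_test is symmetric under genotype label swap", {
  design <- make_design()
  m <- rbind(c(10, 14, 12, 44, 50, 47),
             c(30, 28, 33, 29, 31, 30),
             c(80, 75, 90, 20, 22, 18))
  counts <- counts_from_matrix(m, design)
  res <- nb_test(counts, design)
  swapped <- design
  swapped$genotype <- rev(swapped$genotype)
  m2 <- m[, c(4:6, 1:3)]
  res2 <- nb_test(counts_from_matrix(m2, swapped[c(4:6, 1:3), ]), swapped[c(4:6, 1:3), ])
  expect_equal(res2$log2fc, -res$log2fc, tolerance = 1e-9)
  expect_equal(res2$p, res$p, tolerance = 1e-9)
})

test_that("nb_test requires two libraries per genotype", {
  design <- make_design(n_rep = 1L)
  m <- rbind(c(5, 10))
  expect_error(nb_test(counts_from_matrix(m, design), design),
               "at least two")
})

test_that("BH adjustment matches the direct step-up computation", {
  # independent oracle: q_i = min_{j >= i} (m * p_(j) / j), clipped at 1
  step_up <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- rep(NA_real_, m)
    running <- Inf
    for (r in m:1) {
      running <- min(running, m * p[o[r]] / r)
      q[o[r]] <- min(running, 1)
    }
    q
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(5)
  for (i in 1:5) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), step_up(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")
})

test_that("differential calls apply fold, q and exclusion rules", {
  res <- tibble::tibble(
    chrom = "chr1",
    start = c(0L, 500L, 1000L),
    end = c(500L, 1000L, 1500L),
    size_class = 21L,
    log2fc = c(0.9, 3, 3),
    p = c(0.001, 0.04, 0.001),
    q = c(0.001, 0.049, 0.001),
    direction = c("up_in_mutant", "up_in_mutant", "down_in_mutant")
  )
  out <- call_differential(res, min_fold = 2, max_q = 0.05)
  expect_equal(out$passes, c(FALSE, TRUE, TRUE))
  expect_equal(out$reason[1], "fold")
  excl <- tibble::tibble(chrom = "chr1", start = 1100L, end = 1200L)
  out2 <- call_differential(res, exclude = excl)
  expect_equal(out2$passes, c(FALSE, TRUE, FALSE))
  expect_equal(out2$reason[3], "excluded_region")
})

test_that("size-class t-test matches the textbook Welch formula", {
  design <- make_design()
  totals <- tibble::tibble(
    library = rep(design$name, each = 2),
    length = rep(c(21L, 22L), 6),
    total = c(100, 50, 101, 49, 99, 51,   # wt
              50, 50, 52, 51, 48, 49)     # mut
  )
  res <- size_class_ttest(totals, design)
  # oracle: Welch statistic by hand for the 21-nt class
  x <- c(100, 101, 99); y <- c(50, 52, 48)
  tw <- (mean(x) - mean(y)) / sqrt(var(x) / 3 + var(y) / 3)
  r21 <- res[res$length == 21L, ]
  expect_equal(r21$t, tw, tolerance = 1e-12)
  expect_lt(r21$p, 0.05)
  r22 <- res[res$length == 22L, ]
  expect_gt(r22$p, 0.5)
})

test_that("size-class t-test handles degenerate inputs", {
  design <- make_design()
  # zero variance in both groups, equal means -> p = 1
  tot_eq <- tibble::tibble(library = design$name, length = 21L,
                           total = rep(10, 6))
  res <- size_class_ttest(tot_eq, design)
  expect_equal(res$p, 1)
  # one library per group -> hard error
  d1 <- make_design(n_rep = 1L)
  tot1 <- tibble::tibble(library = d1$name, length = 21L, total = c(5, 9))
  expect_error(size_class_ttest(tot1, d1), "at least two")
})
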