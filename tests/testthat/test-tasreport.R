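test_that("D-indexed ta-siRNAs tile the inter-site span on both strands", {
  # span of exactly 9 cycles -> 9 per strand, 18 total
  cleavage <- 500L
  tab <- enumerate_tasirnas(cleavage, site5_end = cleavage - 9L * 21L)
  expect_equal(nrow(tab), 18L)
  expect_equal(sum(tab$strand == "+"), 9L)
  # D-index round trip: start of D_i(+) = cleavage - 21 * i
  plus <- tab[tab$strand == "+", ]
  expect_equal(plus$start, cleavage - 21L * plus$d_index)
  expect_equal(plus$end - plus$start, rep(21L, 9L))
  # strand parity: every D_i(-) is the duplex partner offset by 2 nt
  minus <- tab[tab$strand == "-", ]
  expect_equal(minus$start, plus$start - 2L)
  # span of 20 nt -> no complete cycle, empty table
  expect_equal(nrow(enumerate_tasirnas(500L, 480L)), 0L)
  # non-multiple span: only complete 21-mers before the 5' site count
  tab2 <- enumerate_tasirnas(500L, 500L - 9L * 21L - 10L)
  expect_equal(nrow(tab2), 18L)
})

test_that("ta-siRNA sequences come from the right strand of the template", {
  set.seed(61)
  seq <- random_seq(300L)
  tab <- enumerate_tasirnas(250L, 250L - 3L * 21L, seq = seq)
  d1p <- tab[tab$d_index == 1L & tab$strand == "+", ]
  expect_equal(d1p$sequence, substr(seq, 250L - 21L + 1L, 250L))
  d1m <- tab[tab$d_index == 1L & tab$strand == "-", ]
  expect_equal(d1m$sequence,
               revcomp(substr(seq, 250L - 23L + 1L, 250L - 2L)))
})

test_that("reads classify by register with the overhang adjustment", {
  cleavage <- 1000L
  rec <- make_records(
    start = c(cleavage - 21L,        # D1(+): in phase
              cleavage - 20L,        # 1 nt off register
              cleavage - 42L - 2L,   # minus-strand duplex partner of D2
              cleavage - 63L),
    length = 21L,
    strand = c("+", "+", "-", "+"),
    copies = c(4L, 2L, 3L, 1L)
  )
  cls <- classify_reads(rec, cleavage, region_start = 800L,
                        region_end = 1100L)
  expect_equal(cls$in_phase_total, 8)
  expect_equal(cls$out_of_phase_total, 2)
  pos <- cls$positions
  expect_true(pos$in_phase[pos$pos == cleavage - 21L])
  expect_false(pos$in_phase[pos$pos == cleavage - 20L])
  expect_true(pos$in_phase[pos$pos == cleavage - 42L])
  # conservation: in + out equals total in-region abundance
  expect_equal(cls$in_phase_total + cls$out_of_phase_total,
               sum(rec$copies))
  # size profile covers 18-26 with mass at 21
  expect_equal(sum(cls$size_profile$abundance), sum(rec$copies))
  expect_equal(cls$size_profile$abundance[cls$size_profile$length == 21L],
               sum(rec$copies))
})

test_that("tasiR-ARF flags are set by qualifying sites in ARF transcripts", {
  set.seed(71)
  tarf <- random_seq(21L)
  arf <- paste0(random_seq(50L), revcomp(tarf), random_seq(50L))
  tab <- tibble::tibble(d_index = c(7L, 8L), strand = "+",
                        start = c(0L, 21L), end = c(21L, 42L),
                        sequence = c(tarf, random_seq(21L)))
  out <- flag_tasirarfs(tab, c(arf3a = arf), max_score = 3)
  expect_true(out$tasirarf[1])
  expect_false(out$tasirarf[2])
  # empty transcript set: warning, all FALSE
  expect_warning(out2 <- flag_tasirarfs(tab, character(0)), "no ARF3")
  expect_false(any(out2$tasirarf))
  # empty table: empty flags
  empty <- flag_tasirarfs(tab[0, ], c(arf3a = arf))
  expect_equal(nrow(empty), 0L)
})

test_that("locus summaries assemble counts, scores and fold changes", {
  design <- library_design(
    name = c("wt1", "wt2", "mut1", "mut2"),
    genotype = c("wildtype", "wildtype", "mutant", "mutant"),
    replicate = c(1L, 2L, 1L, 2L),
    genome_matched_total = rep(1e6, 4)
  )
  cleavage <- 1000L
  tab <- enumerate_tasirnas(cleavage, cleavage - 4L * 21L)
  rec <- dplyr::bind_rows(
    make_records(start = rep(cleavage - 21L, 3), length = 21L,
                 copies = c(50L, 46L, 1L),
                 library = c("wt1", "wt2", "mut1")),
    make_records(start = cleavage - 42L, length = 21L, copies = 20L,
                 library = "wt1")
  )
  clusters <- tibble::tibble(chrom = "chr1", start = 800L, end = 1300L,
                             k = 21L, register = cleavage %% 21L, n = 5L,
                             P = 100, U = 2, score = 33.3, n_windows = 2L)
  diff <- tibble::tibble(chrom = "chr1", start = 500L, end = 1000L,
                         size_class = 21L, log2fc = -5, p = 1e-6, q = 1e-5,
                         direction = "down_in_mutant", passes = TRUE,
                         reason = "pass")
  row <- summarize_tas_locus("tasX", "chr1", 900L, 1100L, tab, rec,
                             design, clusters, diff)
  expect_equal(row$n_predicted_tasirnas, 8L)
  expect_equal(row$reads_wt, 116)
  expect_equal(row$phasing_score, 33.3)
  expect_true(row$significant)
  # fold: WT per-library totals (70, 46) -> mean 58; mutant (1, 0) -> 0.5
  expect_equal(row$fold_wt_mut, (58 + 0.5) / (0.5 + 0.5))
  # zero mutant reads handled by the pseudo-count (finite fold)
  expect_true(is.finite(row$fold_wt_mut))
})

test_that("the reference TAS3 table is internally consistent", {
  ref <- tas3_reference()
  expect_equal(nrow(ref), 9L)
  # per-locus predicted counts recomputed through the enumeration rule
  per_locus <- vapply(ref$span_nt, function(s) {
    predicted_tasirna_total(s)
  }, numeric(1))
  expect_equal(per_locus, 2 * ref$tasirnas_per_strand)
})
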