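# Phased siRNA cluster discovery.
#
# Reads from both strands are merged onto shared phase positions,
# adjusting for the 2-nt 3' overhangs left by DICER processing: a duplex
# partner on the minus strand sits 2 nt to the left of its plus-strand
# mate, so its leftmost coordinate + 2 recovers the shared phase position.
# Sliding 500-bp windows are then scored per register (residue class of
# position mod k) with the phasing score.

#' Merge strands onto Dicer-adjusted phase positions
#'
#' Plus-strand reads contribute at their leftmost coordinate; minus-strand
#' reads at leftmost coordinate + 2 (the 2-nt 3' overhang adjustment), so
#' both strands of one Dicer duplex land on the same phase position.
#'
#' @param records alignment record tibble, normally pooled wild-type
#'   libraries of a single size class with an `rpm` column.
#' @param abundance column used as abundance: `"rpm"` (default when
#'   present) or `"copies"`.
#' @return tibble `chrom`, `pos`, `abundance` (summed), `reads` (summed
#'   raw copies), one row per occupied phase position.
#' @export
merge_strands <- function(records, abundance = NULL) {
  abundance <- abundance %||% if ("rpm" %in% names(records)) "rpm" else "copies"
  stopifnot(abundance %in% names(records))
  pos <- ifelse(records$strand == "+", records$start, records$start + 2L)
  tibble::tibble(
    chrom = records$chrom,
    pos = as.integer(pos),
    ab = records[[abundance]],
    copies = records$copies
  ) |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(abundance = sum(.data$ab),
                     reads = sum(.data$copies), .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Number of phase cycles fitting in a window
#'
#' `floor(window_len / k)`: 23 for 21-nt, 22 for 22-nt, and 20 for 24-nt
#' small RNAs in a 500-bp window.
#'
#' @param k phase length in nt.
#' @param window_len window length in nt.
#' @return integer cycle count C.
#' @export
phase_cycles <- function(k, window_len = 500L) {
  stopifnot(k >= 1L, window_len >= k)
  as.integer(window_len %/% k)
}

#' Phasing score
#'
#' `score = (n - 2) * ln(1 + 10 * P / (1 + U))` for `n >= 3`, else 0,
#' where P is the abundance on the register's phase-cycle positions, U the
#' out-of-phase abundance in the window, and n the number of occupied
#' phase-cycle positions. Monotone non-decreasing in P and n,
#' non-increasing in U.
#'
#' @param P in-phase abundance (>= 0).
#' @param U out-of-phase abundance (>= 0).
#' @param n occupied phase-cycle positions (0..C).
#' @return numeric score (vectorized).
#' @export
phasing_score <- function(P, U, n) {
  if (any(P < 0) || any(U < 0) || any(n < 0)) {
    stop("phasing_score inputs must be non-negative")
  }
  ifelse(n < 3, 0, (n - 2) * log1p(10 * P / (1 + U)))
}

#' Scan sliding windows for phased siRNA clusters
#'
#' For each window of `window_len` starting every `step` nt, each of the k
#' registers (absolute residue class of position mod k) is evaluated over
#' its C = floor(window_len / k) phase-cycle positions; the
#' best-scoring register is reported (ties broken toward the smaller
#' register). A window is a candidate when the raw pooled read count on
#' the best register's phase positions reaches `min_inphase_reads`, and
#' qualifies when its score additionally reaches `threshold`.
#'
#' @param posmap phase-position abundance map from [merge_strands()],
#'   built from size-class-k reads only.
#' @param k phase length in nt.
#' @param window_len window length in nt (> k).
#' @param step slide step in nt.
#' @param min_inphase_reads candidacy threshold on raw in-register reads.
#' @param threshold qualification threshold on the phasing score.
#' @return tibble of scored windows (`chrom`, `start`, `end`, `k`,
#'   `register`, `n`, `P`, `U`, `inphase_reads`, `score`, `candidate`,
#'   `qualifies`); windows without reads are omitted.
#' @export
scan_windows <- function(posmap, k, window_len = 500L, step = 250L,
                         min_inphase_reads = 5, threshold = 25) {
  if (window_len < k) stop("window_len must be at least the phase length k")
  C <- phase_cycles(k, window_len)
  out <- lapply(split(posmap, posmap$chrom), function(pm) {
    pm <- pm[order(pm$pos), , drop = FALSE]
    pos <- pm$pos; ab <- pm$abundance; rd <- pm$reads
    max_start <- max(pos)
    starts <- seq(0L, max_start, by = step)
    rows <- lapply(starts, function(w) {
      idx <- which(pos >= w & pos < w + window_len)
      if (length(idx) == 0L) return(NULL)
      best <- score_phase_window(pos[idx], ab[idx], rd[idx], w, k, C)
      tibble::tibble(
        chrom = pm$chrom[1], start = w, end = w + window_len, k = k,
        register = best$register, n = best$n, P = best$P, U = best$U,
        inphase_reads = best$inphase_reads, score = best$score
      )
    })
    dplyr::bind_rows(rows)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), k = integer(),
                          register = integer(), n = integer(),
                          P = numeric(), U = numeric(),
                          inphase_reads = numeric(), score = numeric())
  }
  res$candidate <- res$inphase_reads >= min_inphase_reads
  res$qualifies <- res$candidate & res$score >= threshold
  res
}

# Best register for one window: positions/abundances already restricted
# to [w, w + window_len). Exactly C phase positions per register are
# enumerated from the window start; an occupied position beyond the C-th
# cycle counts toward U.
score_phase_window <- function(pos, ab, rd, w, k, C) {
  res <- pos %% k
  first <- w + ((0:(k - 1)) - w) %% k        # first in-window pos per register
  last <- first + k * (C - 1)                # last of the C cycle positions
  inph <- pos <= last[res + 1L]
  tot_ab <- sum(ab)
  P <- rep(0, k); n <- rep(0L, k); ir <- rep(0, k)
  if (any(inph)) {
    f <- factor(res[inph], levels = 0:(k - 1))
    P <- as.numeric(tapply(ab[inph], f, sum, default = 0))
    n <- as.integer(tapply(rep(1L, sum(inph)), f, sum, default = 0L))
    ir <- as.numeric(tapply(rd[inph], f, sum, default = 0))
  }
  U <- tot_ab - P
  sc <- phasing_score(P, U, n)
  b <- which.max(sc)  # ties broken toward the smaller register
  list(register = b - 1L, n = n[b], P = P[b], U = U[b],
       inphase_reads = ir[b], score = sc[b])
}

#' Merge qualifying windows into phased clusters
#'
#' Overlapping or abutting qualifying windows of equal phase length are
#' merged; each cluster carries its best-scoring constituent window's
#' register, score, n, P and U (ties broken toward the earlier window).
#'
#' @param windows scored window tibble from [scan_windows()].
#' @return tibble of clusters (`chrom`, `start`, `end`, `k`, `register`,
#'   `n`, `P`, `U`, `score`, `n_windows`).
#' @export
merge_clusters <- function(windows) {
  q <- windows[windows$qualifies, , drop = FALSE]
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), k = integer(),
                          register = integer(), n = integer(),
                          P = numeric(), U = numeric(), score = numeric(),
                          n_windows = integer())
  if (nrow(q) == 0L) return(empty)
  parts <- split(q, list(q$chrom, q$k), drop = TRUE)
  rows <- lapply(parts, function(qq) {
    ir <- IRanges::IRanges(start = qq$start + 1L, end = qq$end)
    red <- IRanges::reduce(ir)
    hits <- IRanges::findOverlaps(ir, red)
    cl <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
    qq$cluster <- cl
    qq |>
      dplyr::group_by(.data$cluster) |>
      dplyr::arrange(dplyr::desc(.data$score), .data$start,
                     .by_group = TRUE) |>
      dplyr::summarise(
        chrom = .data$chrom[1],
        start = min(.data$start), end = max(.data$end),
        k = .data$k[1], register = .data$register[1],
        n = .data$n[1], P = .data$P[1], U = .data$U[1],
        score = .data$score[1], n_windows = dplyr::n(),
        .groups = "drop"
      ) |>
      dplyr::select(-"cluster")
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$chrom, .data$start)
}

#' Flag clusters whose small RNAs are mutant-dependent
#'
#' A cluster is flagged when it overlaps at least one window of the same
#' size class called significantly down in the mutant. With no
#' differential calls available the flag is `NA`.
#'
#' @param clusters cluster tibble from [merge_clusters()].
#' @param diff_calls differential results from [call_differential()] for
#'   the same size class, or `NULL`.
#' @return `clusters` with a logical `lbl1_dependent` column.
#' @export
flag_lbl1_dependent <- function(clusters, diff_calls = NULL) {
  if (nrow(clusters) == 0L) {
    clusters$lbl1_dependent <- logical(0)
    return(clusters)
  }
  if (is.null(diff_calls) || nrow(diff_calls) == 0L) {
    clusters$lbl1_dependent <- NA
    return(clusters)
  }
  down <- diff_calls[diff_calls$passes &
                       diff_calls$direction == "down_in_mutant", ,
                     drop = FALSE]
  if (nrow(down) == 0L) {
    clusters$lbl1_dependent <- FALSE
    return(clusters)
  }
  cl_gr <- GenomicRanges::GRanges(
    clusters$chrom,
    IRanges::IRanges(start = clusters$start + 1L, end = clusters$end)
  )
  dn_gr <- GenomicRanges::GRanges(
    down$chrom,
    IRanges::IRanges(start = down$start + 1L, end = down$end)
  )
  clusters$lbl1_dependent <- IRanges::overlapsAny(cl_gr, dn_gr)
  clusters
}
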