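# PARE / degradome validation of predicted cleavage sites.
#
# PARE tags mark uncapped 5' ends of cleavage products. A predicted site
# is validated when the tag abundance concentrates on the cleavage
# position: W_S (tags within +/-2 nt, a 5-nt window) over W_L (tags
# within +/-15 nt, a 31-nt window) must reach min_ratio, with an absolute
# floor of min_ws tags in the small window. Tags are pooled across PARE
# libraries before windowing; thresholds apply to raw tag counts.

#' Read a PARE tag table
#'
#' @param path TSV with columns `transcript`, `pos` (0-based 5'-end
#'   position) and `count`.
#' @return tibble of pooled tag counts per (transcript, position).
#' @export
read_pare_tags <- function(path) {
  x <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("transcript", "pos", "count") %in% names(x)))
  x |>
    dplyr::count(.data$transcript, .data$pos, wt = .data$count,
                 name = "count") |>
    tibble::as_tibble()
}

#' Summed PARE tag abundance in a window around a position
#'
#' Sums tag counts over `[pos - half_width, pos + half_width]` inclusive
#' (2 * half_width + 1 positions); with `half_width = 2` the window spans
#' 5 nt, with 15 it spans 31 nt. Windows are truncated at transcript
#' boundaries with a warning when `tx_len` is supplied.
#'
#' @param tags tag tibble (`transcript`, `pos`, `count`).
#' @param transcript transcript identifier.
#' @param pos 0-based cleavage position.
#' @param half_width window half-width in nt (>= 0).
#' @param tx_len optional transcript length for boundary truncation.
#' @return summed tag count in the window.
#' @export
window_abundance <- function(tags, transcript, pos, half_width,
                             tx_len = NULL) {
  if (half_width < 0) stop("half_width must be non-negative")
  lo <- pos - half_width
  hi <- pos + half_width
  if (!is.null(tx_len) && (lo < 0 || hi > tx_len - 1)) {
    warning("window around position ", pos,
            " truncated at transcript boundary")
    lo <- max(lo, 0)
    hi <- min(hi, tx_len - 1)
  }
  sel <- tags$transcript == transcript & tags$pos >= lo & tags$pos <= hi
  sum(tags$count[sel])
}

#' Validate predicted cleavage sites against PARE tags
#'
#' For each hit, computes W_S (tags in cleavage +/-2 nt), W_L (tags in
#' cleavage +/-15 nt) and their ratio; a site is validated when
#' `W_S / W_L >= min_ratio` and `W_S >= min_ws`. When W_L is zero the
#' ratio is undefined (`NA`) and the site is not validated.
#'
#' @param hits tibble with at least `transcript_id` and `cleavage`
#'   columns (e.g. from [find_sites()]).
#' @param tags PARE tag tibble (`transcript`, `pos`, `count`), pooled
#'   across libraries.
#' @param min_ratio minimum W_S / W_L.
#' @param min_ws minimum raw tag count in the small window.
#' @param tx_len optional named vector of transcript lengths.
#' @return `hits` with `ws`, `wl`, `ratio` and `validated` columns.
#' @export
validate_sites <- function(hits, tags, min_ratio = 0.75, min_ws = 4,
                           tx_len = NULL) {
  n <- nrow(hits)
  ws <- numeric(n); wl <- numeric(n)
  for (i in seq_len(n)) {
    tl <- if (!is.null(tx_len)) unname(tx_len[hits$transcript_id[i]]) else NULL
    ws[i] <- window_abundance(tags, hits$transcript_id[i],
                              hits$cleavage[i], 2L, tl)
    wl[i] <- window_abundance(tags, hits$transcript_id[i],
                              hits$cleavage[i], 15L, tl)
  }
  hits$ws <- ws
  hits$wl <- wl
  hits$ratio <- ifelse(wl > 0, ws / wl, NA_real_)
  hits$validated <- !is.na(hits$ratio) &
    hits$ratio >= min_ratio & ws >= min_ws
  hits
}
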