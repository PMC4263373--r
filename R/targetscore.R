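# Small RNA : target duplex scoring with the Allen penalty scheme.
#
# Penalties per sRNA position (counted from the sRNA 5' end): mismatch 1,
# G:U wobble 0.5, each bulged nucleotide 1; every penalty is doubled in
# the core region, sRNA positions 2-13. Cleavage is predicted opposite
# sRNA position 10 (the cut falls between the target nucleotides paired
# to positions 10 and 11). T and U are treated as equivalent on input.
# The site search slides the sRNA exhaustively along the transcript,
# ungapped plus all single-nucleotide bulge variants on either strand of
# the duplex. A bulged target nucleotide between sRNA positions b and b+1
# is charged at position b+1 for core doubling.

ALLEN_PENALTY <- c(match = 0, GU = 0.5, mismatch = 1,
                   bulge_srna = 1, bulge_target = 1)
ALLEN_CORE <- 2:13

normalize_seq <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

# Pairing state of sRNA base s against target base t (both DNA alphabet,
# target read in sense orientation): Watson-Crick -> match, G:T / T:G ->
# GU wobble, anything else mismatch.
pair_state <- function(s, t) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  st <- rep("mismatch", length(s))
  st[comp[s] == t] <- "match"
  st[(s == "G" & t == "T") | (s == "T" & t == "G")] <- "GU"
  st
}

#' Score a small RNA : target duplex from its pairing states
#'
#' @param states character vector of per-position pairing states over the
#'   sRNA positions: `"match"`, `"GU"`, `"mismatch"`, `"bulge_srna"` or
#'   `"bulge_target"`.
#' @param positions sRNA position (1-based from the 5' end) each state is
#'   charged at; defaults to `seq_along(states)`.
#' @return the duplex penalty score (doubled inside the core, positions
#'   2-13).
#' @export
score_duplex <- function(states, positions = seq_along(states)) {
  unknown <- setdiff(states, names(ALLEN_PENALTY))
  if (length(unknown) > 0L) {
    stop("unknown pairing state(s): ", paste(unknown, collapse = ", "))
  }
  pen <- ALLEN_PENALTY[states]
  wt <- ifelse(positions %in% ALLEN_CORE, 2, 1)
  sum(pen * wt)
}

#' Find target sites of a small RNA on a transcript
#'
#' Exhaustive sliding of the sRNA along the transcript, scoring the
#' antiparallel duplex at every offset: ungapped, plus variants with one
#' single-nucleotide bulge on either strand at every internal position
#' (when `max_bulges >= 1`). All sites with score `<= max_score` are
#' reported; when several configurations predict the same cleavage
#' position only the best-scoring one (preferring fewer bulges, then the
#' smaller start) is kept. Hits are sorted by score then position.
#'
#' @param srna small RNA sequence, 5' to 3' (RNA or DNA alphabet).
#' @param transcript transcript sequence, 5' to 3'.
#' @param max_score maximum Allen penalty score to report.
#' @param max_bulges 0 or 1 single-nucleotide bulges per duplex.
#' @param srna_id,transcript_id identifiers carried into the output.
#' @return tibble with columns `srna_id`, `transcript_id`, `start`, `end`
#'   (target site, 0-based half-open), `score`, `cleavage` (0-based target
#'   position paired to sRNA position 10), `config`, `pass`.
#' @export
find_sites <- function(srna, transcript, max_score = 4.5, max_bulges = 1L,
                       srna_id = "srna", transcript_id = "tx") {
  srna <- normalize_seq(srna)
  transcript <- normalize_seq(transcript)
  sr <- strsplit(srna, "")[[1]]
  tc <- strsplit(transcript, "")[[1]]
  if (any(!sr %in% c("A", "C", "G", "T")) ||
      any(!tc %in% c("A", "C", "G", "T"))) {
    stop("sequences must be over the A/C/G/U-T alphabet")
  }
  L <- length(sr)
  Tn <- length(tc)
  empty <- tibble::tibble(srna_id = character(), transcript_id = character(),
                          start = integer(), end = integer(),
                          score = numeric(), cleavage = integer(),
                          config = character(), pass = logical())
  if (Tn < L) return(empty)

  configs <- list(list(type = "ungapped", b = NA_integer_))
  if (max_bulges >= 1L) {
    for (b in 2:(L - 1)) configs <- c(configs, list(list(type = "srna_bulge", b = b)))
    for (b in 1:(L - 1)) configs <- c(configs, list(list(type = "target_bulge", b = b)))
  }

  hits <- lapply(configs, function(cf) {
    score_config(sr, tc, cf, max_score)
  })
  hits <- dplyr::bind_rows(hits)
  if (nrow(hits) == 0L) return(empty)
  hits$srna_id <- srna_id
  hits$transcript_id <- transcript_id
  hits$pass <- TRUE
  hits <- hits[order(hits$cleavage, hits$score, hits$n_bulges, hits$start), ,
               drop = FALSE]
  hits <- hits[!duplicated(hits$cleavage), , drop = FALSE]
  hits <- hits[order(hits$score, hits$start), , drop = FALSE]
  tibble::as_tibble(hits[, c("srna_id", "transcript_id", "start", "end",
                             "score", "cleavage", "config", "pass")])
}

# Vectorized scoring of one alignment configuration over all target
# offsets. Returns qualifying hits for that configuration.
score_config <- function(sr, tc, cf, max_score) {
  L <- length(sr)
  Tn <- length(tc)
  site_len <- switch(cf$type, ungapped = L, srna_bulge = L - 1L,
                     target_bulge = L + 1L)
  n_start <- Tn - site_len + 1L
  if (n_start < 1L) return(NULL)
  s0 <- seq_len(n_start) - 1L  # 0-based site starts

  # 1-based target index paired to sRNA position i, for site start s0:
  # built as offset(i) + s0.
  off <- switch(cf$type,
    ungapped = L - seq_len(L) + 1L,
    srna_bulge = {
      o <- L - seq_len(L) + 1L           # i > b
      o[seq_len(cf$b - 1L)] <- L - seq_len(cf$b - 1L)  # i < b
      o[cf$b] <- NA_integer_             # bulged sRNA nt: unpaired
      o
    },
    target_bulge = {
      o <- L - seq_len(L) + 1L           # i > b
      o[seq_len(cf$b)] <- L + 2L - seq_len(cf$b)       # i <= b
      o
    }
  )

  pen_pos <- seq_len(L)
  wt <- ifelse(pen_pos %in% ALLEN_CORE, 2, 1)
  total <- numeric(n_start)
  for (i in seq_len(L)) {
    if (is.na(off[i])) {  # bulged sRNA nucleotide
      total <- total + ALLEN_PENALTY[["bulge_srna"]] * wt[i]
      next
    }
    tchar <- tc[off[i] + s0]
    st <- pair_state(rep(sr[i], n_start), tchar)
    total <- total + ALLEN_PENALTY[st] * wt[i]
  }
  if (cf$type == "target_bulge") {
    bw <- if ((cf$b + 1L) %in% ALLEN_CORE) 2 else 1
    total <- total + ALLEN_PENALTY[["bulge_target"]] * bw
  }

  keep <- which(total <= max_score)
  if (length(keep) == 0L) return(NULL)
  cleav <- off[10L] + s0[keep] - 1L  # 0-based target nt opposite position 10
  data.frame(
    start = s0[keep],
    end = s0[keep] + site_len,
    score = unname(total[keep]),
    cleavage = cleav,
    config = if (cf$type == "ungapped") "ungapped"
             else paste0(cf$type, "@", cf$b),
    n_bulges = if (cf$type == "ungapped") 0L else 1L,
    stringsAsFactors = FALSE
  )
}

#' Detect a two-hit (dual trigger site) target transcript
#'
#' Finds the pair of non-overlapping qualifying trigger sites with the
#' smallest combined score, ordered by transcript coordinate. The
#' predicted cleavage position is taken from the 3' site (under the
#' two-hit model the 5' site need not be cleaved).
#'
#' @param transcript transcript sequence, 5' to 3'.
#' @param trigger trigger small RNA sequence (e.g. miR390), 5' to 3'.
#' @param max_score maximum per-site Allen score.
#' @param transcript_id identifier carried into the output.
#' @param ... passed to [find_sites()].
#' @return one-row tibble (`transcript_id`, `site5_start`, `site5_end`,
#'   `site5_score`, `site3_start`, `site3_end`, `site3_score`,
#'   `cleavage`) or `NULL` when fewer than two qualifying sites exist.
#' @export
detect_two_hit <- function(transcript, trigger, max_score = 4.5,
                           transcript_id = "tx", ...) {
  sites <- find_sites(trigger, transcript, max_score = max_score,
                      transcript_id = transcript_id, ...)
  if (nrow(sites) < 2L) return(NULL)
  sites <- sites[order(sites$start), , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(sites) - 1L)) {
    for (j in (i + 1L):nrow(sites)) {
      if (sites$end[i] > sites$start[j]) next  # overlapping pair rejected
      comb <- sites$score[i] + sites$score[j]
      if (is.null(best) || comb < best$comb) {
        best <- list(i = i, j = j, comb = comb)
      }
    }
  }
  if (is.null(best)) return(NULL)
  s5 <- sites[best$i, ]; s3 <- sites[best$j, ]
  tibble::tibble(
    transcript_id = transcript_id,
    site5_start = s5$start, site5_end = s5$end, site5_score = s5$score,
    site3_start = s3$start, site3_end = s3$end, site3_score = s3$score,
    cleavage = s3$cleavage
  )
}
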