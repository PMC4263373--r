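# Two-hit TAS locus characterization.
#
# The 3' trigger cleavage site sets the 21-nt register; ta-siRNAs are
# processed 5'-ward (upstream) of the cut in exact 21-nt steps. D1(+) is
# the first complete 21-mer immediately 5' of the cleavage position on
# the sense strand, D2(+) the next, and so on up to the 5' trigger site;
# each D_i(-) is the duplex partner offset 2 nt left (the Dicer 2-nt 3'
# overhang).

#' Enumerate D-indexed ta-siRNAs of a two-hit locus
#'
#' @param cleavage 0-based cleavage position of the 3' trigger site (the
#'   target nucleotide paired to trigger position 10); D1(+) occupies
#'   `[cleavage - 21, cleavage)`, strictly upstream of the cut.
#' @param site5_end 0-based end (exclusive) of the 5' trigger site;
#'   enumeration stops at the last complete phase cycle before it.
#' @param seq optional sequence (character or `Biostrings::DNAString`) of
#'   the transcript/chromosome the coordinates refer to, used to attach
#'   ta-siRNA sequences (minus-strand entries reverse-complemented).
#' @param k phase length in nt.
#' @return tibble `d_index`, `strand`, `start`, `end`, `sequence` with
#'   `2 * floor((cleavage - site5_end) / k)` rows.
#' @export
enumerate_tasirnas <- function(cleavage, site5_end, seq = NULL, k = 21L) {
  span <- cleavage - site5_end
  m <- if (span >= k) span %/% k else 0L
  if (m == 0L) {
    return(tibble::tibble(d_index = integer(), strand = character(),
                          start = integer(), end = integer(),
                          sequence = character()))
  }
  i <- seq_len(m)
  plus <- tibble::tibble(d_index = i, strand = "+",
                         start = as.integer(cleavage - k * i),
                         end = as.integer(cleavage - k * (i - 1L)))
  minus <- tibble::tibble(d_index = i, strand = "-",
                          start = plus$start - 2L, end = plus$end - 2L)
  out <- dplyr::bind_rows(plus, minus) |>
    dplyr::arrange(.data$d_index, dplyr::desc(.data$strand))
  if (!is.null(seq)) {
    s <- Biostrings::DNAString(as.character(seq))
    out$sequence <- vapply(seq_len(nrow(out)), function(r) {
      sub <- Biostrings::subseq(s, start = out$start[r] + 1L,
                                end = out$end[r])
      if (out$strand[r] == "-") {
        as.character(Biostrings::reverseComplement(sub))
      } else {
        as.character(sub)
      }
    }, character(1))
  } else {
    out$sequence <- NA_character_
  }
  out
}

#' Classify locus reads as in- or out-of-phase and profile sizes
#'
#' Reads are placed on Dicer-adjusted phase positions (see
#' [merge_strands()]); a read is in phase when its adjusted 5' position is
#' congruent to the cleavage position mod k. Only reads whose adjusted
#' position falls in `[region_start, region_end)` are counted.
#'
#' @param records alignment record tibble (any sizes).
#' @param cleavage 0-based cleavage position defining the register.
#' @param region_start,region_end locus interval (0-based half-open).
#' @param k phase length in nt.
#' @param sizes size range for the length profile.
#' @return list with `positions` (per adjusted position: `pos`,
#'   `in_phase`, `abundance`), `size_profile` (`length`, `abundance`),
#'   `in_phase_total`, `out_of_phase_total`.
#' @export
classify_reads <- function(records, cleavage, region_start, region_end,
                           k = 21L, sizes = 18:26) {
  ab_col <- if ("rpm" %in% names(records)) "rpm" else "copies"
  pos <- ifelse(records$strand == "+", records$start, records$start + 2L)
  keep <- pos >= region_start & pos < region_end
  r <- records[keep, , drop = FALSE]
  pos <- pos[keep]
  register <- cleavage %% k
  in_phase <- (pos %% k) == register
  positions <- tibble::tibble(pos = as.integer(pos), in_phase = in_phase,
                              abundance = r[[ab_col]]) |>
    dplyr::group_by(.data$pos, .data$in_phase) |>
    dplyr::summarise(abundance = sum(.data$abundance), .groups = "drop") |>
    dplyr::arrange(.data$pos)
  size_profile <- tibble::tibble(length = r$length,
                                 abundance = r[[ab_col]]) |>
    dplyr::count(.data$length, wt = .data$abundance, name = "abundance") |>
    tidyr::complete(length = sizes, fill = list(abundance = 0)) |>
    dplyr::filter(.data$length %in% sizes)
  list(
    positions = positions,
    size_profile = size_profile,
    in_phase_total = sum(r[[ab_col]][in_phase]),
    out_of_phase_total = sum(r[[ab_col]][!in_phase])
  )
}

#' Flag ta-siRNAs that target ARF3-like transcripts
#'
#' A ta-siRNA is flagged tasiR-ARF when it has at least one qualifying
#' target site (Allen score `<= max_score`) in any provided ARF3-like
#' transcript.
#'
#' @param tasirnas ta-siRNA table from [enumerate_tasirnas()] (needs a
#'   `sequence` column).
#' @param transcripts named character vector (or `DNAStringSet`) of
#'   ARF3-like transcript sequences.
#' @param max_score maximum Allen score for a qualifying site.
#' @return `tasirnas` with a logical `tasirarf` column.
#' @export
flag_tasirarfs <- function(tasirnas, transcripts, max_score = 3) {
  if (nrow(tasirnas) == 0L) {
    tasirnas$tasirarf <- logical(0)
    return(tasirnas)
  }
  if (length(transcripts) == 0L) {
    warning("no ARF3-like transcripts provided; all flags FALSE")
    tasirnas$tasirarf <- FALSE
    return(tasirnas)
  }
  txs <- vapply(as.list(transcripts), as.character, character(1))
  seqs <- unique(tasirnas$sequence)
  flagged <- vapply(seqs, function(sq) {
    for (ti in seq_along(txs)) {
      hits <- find_sites(sq, txs[ti], max_score = max_score)
      if (nrow(hits) > 0L) return(TRUE)
    }
    FALSE
  }, logical(1))
  tasirnas$tasirarf <- unname(flagged[match(tasirnas$sequence, seqs)])
  tasirnas
}

#' Summarize a characterized TAS locus
#'
#' Produces one summary row per locus in the style of a TAS locus table:
#' predicted ta-siRNA count (both strands), tasiR-ARF count, best phasing
#' score of any overlapping cluster, total in-region reads of the phase
#' size class in wild-type libraries, and the wild-type/mutant fold
#' change of those reads (0.5 pseudo-count on normalized means) with a
#' significance flag from the differential calls.
#'
#' @param locus_id locus identifier.
#' @param chrom,region_start,region_end locus interval (0-based half-open).
#' @param tasirnas table from [enumerate_tasirnas()] (optionally flagged
#'   by [flag_tasirarfs()]).
#' @param records alignment record tibble with `library` column.
#' @param design library design table.
#' @param clusters optional phased cluster tibble ([merge_clusters()]).
#' @param diff_calls optional differential calls ([call_differential()]).
#' @param k phase size class counted as ta-siRNA reads.
#' @return one-row tibble.
#' @export
summarize_tas_locus <- function(locus_id, chrom, region_start, region_end,
                                tasirnas, records, design,
                                clusters = NULL, diff_calls = NULL,
                                k = 21L) {
  n_predicted <- nrow(tasirnas)
  n_tasirarf <- if ("tasirarf" %in% names(tasirnas)) {
    sum(tasirnas$tasirarf)
  } else {
    NA_integer_
  }
  pos <- ifelse(records$strand == "+", records$start, records$start + 2L)
  in_region <- records$chrom == chrom & pos >= region_start &
    pos < region_end & records$length == k
  r <- records[in_region, , drop = FALSE]
  per_lib <- vapply(design$name, function(lb) {
    sum(r$copies[r$library == lb])
  }, numeric(1))
  sf <- design$genome_matched_total / mean(design$genome_matched_total)
  norm <- per_lib / sf
  mean_wt <- mean(norm[design$genotype == "wildtype"])
  mean_mut <- mean(norm[design$genotype == "mutant"])
  fold_wt_mut <- (mean_wt + 0.5) / (mean_mut + 0.5)

  score <- NA_real_
  if (!is.null(clusters) && nrow(clusters) > 0L) {
    ov <- clusters$chrom == chrom & clusters$start < region_end &
      clusters$end > region_start & clusters$k == k
    if (any(ov)) score <- max(clusters$score[ov])
  }
  significant <- NA
  if (!is.null(diff_calls) && nrow(diff_calls) > 0L) {
    ov <- diff_calls$chrom == chrom & diff_calls$start < region_end &
      diff_calls$end > region_start
    significant <- any(diff_calls$passes[ov])
  }
  tibble::tibble(
    locus_id = locus_id,
    chrom = chrom, start = region_start, end = region_end,
    n_predicted_tasirnas = n_predicted,
    n_tasirarfs = n_tasirarf,
    phasing_score = score,
    reads_wt = sum(per_lib[design$genotype == "wildtype"]),
    fold_wt_mut = fold_wt_mut,
    significant = significant
  )
}

#' Predicted ta-siRNA total from inter-site spans
#'
#' Applies the two-hit enumeration rule to a vector of inter-site spans
#' (distance from the 5' trigger-site end to the 3' cleavage position):
#' each locus yields `floor(span / k)` ta-siRNAs per strand, counted on
#' both strands.
#'
#' @param spans inter-site spans in nt.
#' @param k phase length in nt.
#' @return total predicted ta-siRNA count over all loci.
#' @export
predicted_tasirna_total <- function(spans, k = 21L) {
  stopifnot(all(spans >= 0))
  sum(2L * (spans %/% k))
}

#' Reference summary of the nine maize TAS3 loci
#'
#' The published per-locus summary of the nine maize TAS3 family loci
#' (tas3a-tas3i): predicted ta-siRNAs per strand between the miR390
#' sites, tasiR-ARF count, phasing score, wild-type read total, and
#' wild-type/mutant fold change. `span_nt` is the inter-site span implied
#' by the per-strand count (used by consistency checks through
#' [predicted_tasirna_total()]).
#'
#' @return tibble with one row per locus.
#' @export
tas3_reference <- function() {
  path <- system.file("extdata", "tas3_maize_reference.tsv",
                      package = "phasitrack", mustWork = TRUE)
  x <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
  x$span_nt <- x$tasirnas_per_strand * 21L + 10L
  x
}
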