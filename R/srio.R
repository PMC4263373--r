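# Alignment ingest: the shared coordinate and abundance model.
#
# An alignment record set is a tibble with one row per genomic alignment:
#   chrom   sequence name
#   start   0-based leftmost coordinate
#   length  read length (nt)
#   strand  "+" or "-"
#   name    read identifier (shared across alignments of one read)
#   copies  number of identical sequenced reads collapsed on the alignment
#   n_hits  number of genomic alignments of the read sequence
# normalize_rpm() adds an `rpm` column.

#' Load small RNA alignments
#'
#' Reads alignments from SAM/BAM (via Rsamtools) or 6-column BED (via
#' rtracklayer) into the package's 0-based half-open coordinate convention
#' and applies the standard small RNA filters: read length between
#' `min_len` and `max_len` and at most `max_hits` genomic alignments per
#' read. For SAM/BAM, `n_hits` is taken from the NH tag when present and
#' otherwise counted from read names, and reads with mismatches (NM > 0)
#' are dropped when `perfect_only = TRUE`. Collapsed-read multiplicities
#' are recovered from a `_xN` read-name suffix (SAM/BAM) or the BED score
#' column.
#'
#' @param path path to a SAM, BAM or BED file.
#' @param format input format; `"auto"` infers it from the file extension.
#' @param max_hits maximum number of genomic alignments per read.
#' @param min_len,max_len retained read-length range in nt.
#' @param perfect_only drop SAM/BAM records whose NM tag reports mismatches.
#' @return a tibble of alignment records (see package help for columns),
#'   with a `filter_report` attribute counting dropped records.
#' @export
load_alignments <- function(path, format = c("auto", "sam", "bam", "bed"),
                            max_hits = 20L, min_len = 18L, max_len = 26L,
                            perfect_only = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      sam = "sam", bam = "bam", bed = "bed",
      stop("cannot infer alignment format from extension: ", ext)
    )
  }
  rec <- switch(format,
    sam = read_alignments_sam(path, is_sam = TRUE, perfect_only = perfect_only),
    bam = read_alignments_sam(path, is_sam = FALSE, perfect_only = perfect_only),
    bed = read_alignments_bed(path)
  )
  mm_dropped <- attr(rec, "mismatch_dropped") %||% 0L
  filter_alignments(rec, max_hits = max_hits, min_len = min_len,
                    max_len = max_len, mismatch_dropped = mm_dropped)
}

#' Apply the length and multimapping filters to alignment records
#'
#' @param records alignment record tibble.
#' @inheritParams load_alignments
#' @param mismatch_dropped count of records already dropped upstream for
#'   mismatches, carried into the filter report.
#' @return filtered records with a `filter_report` attribute.
#' @export
filter_alignments <- function(records, max_hits = 20L, min_len = 18L,
                              max_len = 26L, mismatch_dropped = 0L) {
  stopifnot(max_hits >= 1L, min_len >= 1L, max_len >= min_len)
  n0 <- nrow(records)
  len_ok <- !is.na(records$length) & records$length >= min_len &
    records$length <= max_len
  hit_ok <- !is.na(records$n_hits) & records$n_hits <= max_hits
  out <- records[len_ok & hit_ok, , drop = FALSE]
  attr(out, "filter_report") <- list(
    input = n0,
    dropped_length = sum(!len_ok),
    dropped_multihit = sum(len_ok & !hit_ok),
    dropped_mismatch = mismatch_dropped,
    retained = nrow(out)
  )
  out
}

read_alignments_sam <- function(path, is_sam, perfect_only) {
  bam <- if (is_sam) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else {
    path
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "qwidth"),
    tag = c("NH", "NM"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(x$pos)
  rec <- tibble::tibble(
    chrom = as.character(x$rname),
    start = x$pos - 1L,
    length = x$qwidth,
    strand = as.character(x$strand),
    name = x$qname
  )
  nm <- x$tag$NM %||% rep(NA_integer_, n)
  mm_dropped <- 0L
  if (perfect_only && n > 0L) {
    bad <- !is.na(nm) & nm > 0L
    mm_dropped <- sum(bad)
    rec <- rec[!bad, , drop = FALSE]
  }
  nh <- x$tag$NH %||% rep(NA_integer_, n)
  if (perfect_only && n > 0L) nh <- nh[!(!is.na(nm) & nm > 0L)]
  if (all(is.na(nh))) {
    tab <- table(rec$name)
    nh <- as.integer(tab[rec$name])
  } else {
    nh[is.na(nh)] <- 1L
  }
  rec$n_hits <- as.integer(nh)
  rec$copies <- copies_from_name(rec$name)
  attr(rec, "mismatch_dropped") <- mm_dropped
  rec[, c("chrom", "start", "length", "strand", "name", "copies", "n_hits")]
}

read_alignments_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  name <- gr$name %||% rep(NA_character_, length(gr))
  score <- gr$score %||% rep(1, length(gr))
  score[is.na(score) | score < 1] <- 1
  rec <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    length = GenomicRanges::width(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    name = name,
    copies = as.integer(round(score))
  )
  rec$strand[rec$strand == "*"] <- "+"
  if (all(is.na(rec$name))) {
    rec$name <- sprintf("rec%06d", seq_len(nrow(rec)))
    rec$n_hits <- 1L
  } else {
    tab <- table(rec$name)
    rec$n_hits <- as.integer(tab[rec$name])
  }
  rec
}

copies_from_name <- function(name) {
  m <- regexpr("_x([0-9]+)$", name)
  copies <- rep(1L, length(name))
  has <- !is.na(m) & m > 0L
  copies[has] <- as.integer(sub("^_x", "", regmatches(name, m)))
  copies
}

#' Write alignment records to a 6-column BED file
#'
#' Coordinates are written 0-based half-open (the BED convention), the
#' score column carries `copies`, and the name column carries the read
#' name so multimapping multiplicity survives a round trip.
#'
#' @param records alignment record tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignments_bed <- function(records, path) {
  bed <- data.frame(
    chrom = records$chrom,
    start = records$start,
    end = records$start + records$length,
    name = records$name,
    score = records$copies,
    strand = records$strand
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Remove alignments overlapping structural RNA intervals
#'
#' Any record whose genomic interval overlaps a blacklist interval by at
#' least one nucleotide is removed. Blacklist intervals on sequences not
#' present in `records` trigger a warning and are ignored.
#'
#' @param records alignment record tibble.
#' @param blacklist tibble with columns `chrom`, `start`, `end`
#'   (0-based half-open), e.g. rRNA/tRNA/snRNA/snoRNA annotations.
#' @return filtered records; the number removed is reported via a
#'   `blacklist_removed` attribute.
#' @export
apply_blacklist <- function(records, blacklist) {
  if (is.null(blacklist) || nrow(blacklist) == 0L) {
    attr(records, "blacklist_removed") <- 0L
    return(records)
  }
  stopifnot(all(blacklist$start < blacklist$end))
  unknown <- setdiff(unique(blacklist$chrom), unique(records$chrom))
  if (length(unknown) > 0L) {
    warning("blacklist intervals on unknown sequence(s) ignored: ",
            paste(unknown, collapse = ", "))
    blacklist <- blacklist[!blacklist$chrom %in% unknown, , drop = FALSE]
  }
  if (nrow(blacklist) == 0L || nrow(records) == 0L) {
    attr(records, "blacklist_removed") <- 0L
    return(records)
  }
  rec_gr <- GenomicRanges::GRanges(
    records$chrom,
    IRanges::IRanges(start = records$start + 1L,
                     end = records$start + records$length)
  )
  bl_gr <- GenomicRanges::GRanges(
    blacklist$chrom,
    IRanges::IRanges(start = blacklist$start + 1L, end = blacklist$end)
  )
  hit <- IRanges::overlapsAny(rec_gr, bl_gr, minoverlap = 1L)
  out <- records[!hit, , drop = FALSE]
  attr(out, "blacklist_removed") <- sum(hit)
  out
}

#' Read a structural RNA blacklist from BED
#'
#' @param path BED file of structural RNA intervals.
#' @return tibble with columns `chrom`, `start`, `end` (0-based half-open).
#' @export
read_blacklist_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Normalize alignment abundances to reads per million
#'
#' Adds an `rpm` column: `copies * 1e6 / genome_matched_total`. Summed
#' over all genome-matched reads of a library this equals 1e6.
#'
#' @param records alignment record tibble.
#' @param genome_matched_total total genome-matched read count of the
#'   library (the normalization denominator).
#' @return `records` with an `rpm` column.
#' @export
normalize_rpm <- function(records, genome_matched_total) {
  if (!is.numeric(genome_matched_total) || genome_matched_total <= 0) {
    stop("genome_matched_total must be a positive number")
  }
  records$rpm <- records$copies * 1e6 / genome_matched_total
  records
}

#' Strand-aware 5' end positions of alignment records
#'
#' @param records alignment record tibble.
#' @return integer vector: `start` on the plus strand,
#'   `start + length - 1` on the minus strand (0-based).
#' @export
five_prime_pos <- function(records) {
  ifelse(records$strand == "+",
         records$start,
         records$start + records$length - 1L)
}

#' Construct a library design table
#'
#' @param name library names.
#' @param genotype `"wildtype"` or `"mutant"` per library.
#' @param replicate replicate index per library.
#' @param genome_matched_total normalization denominator per library.
#' @return a tibble with one row per library.
#' @export
library_design <- function(name, genotype, replicate,
                           genome_matched_total) {
  stopifnot(all(genotype %in% c("wildtype", "mutant")),
            all(genome_matched_total > 0))
  tibble::tibble(
    name = name,
    genotype = genotype,
    replicate = as.integer(replicate),
    genome_matched_total = as.numeric(genome_matched_total)
  )
}
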