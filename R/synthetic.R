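# Synthetic data generator with full ground truth.
#
# Emulates the study design the pipeline assumes: a toy genome carrying
# two-hit TAS-like loci (dual trigger sites an exact number of 21-nt
# cycles apart, a shared tasiR-ARF planted at D7(+)), miRNA loci, 22-nt
# hairpin/antisense loci, multimapping LTR-repeat families, 24-nt
# heterochromatic loci and null background loci; 3 replicates x 2
# genotypes of sRNA-seq with negative-binomial replicate noise; and PARE
# tags concentrated on true cleavage positions over uniform background.
# Everything is deterministic given the seed.

#' Generator configuration
#'
#' Defaults define the emulated study conditions: 8 TAS-like loci at a
#' mean of 400 RPM with a wild-type/mutant fold of 50 (mutant fold 0.02),
#' 10% out-of-phase and 10% off-size reads; repeat families gaining 21/22-nt
#' siRNAs in the mutant; 24-nt heterochromatic loci losing them; 50 null
#' background loci; NB dispersion 0.1; 3 replicates per genotype with a
#' genome-matched total of 1e6 (so RPM equals raw counts); PARE depth
#' Poisson(20) over a 0.02 tags/nt background.
#'
#' @param ... overrides for any default field.
#' @return a named list of generator parameters.
#' @export
generator_config <- function(...) {
  cfg <- list(
    n_chrom = 2L, chrom_len = 60000L, slot_len = 700L,
    n_tas = 8L, tas_cycles = 8:13, tas_mean_rpm = 400,
    tas_fold = 0.02, phase_noise = 0.1, off_size = 0.1, tarf_d = 7L,
    n_mirna = 4L, mirna_mean_rpm = 200, mirna_fold = 1,
    n_hairpin = 4L, hairpin_mean_rpm = 150, hairpin_fold = 1,
    n_repeat = 3L, repeat_copies = 3L, repeat_mean_rpm = 100,
    repeat_fold = 4,
    n_het = 6L, het_mean_rpm = 150, het_fold = 0.3,
    n_null = 50L, null_mean_rpm = 60, null_fold = 1,
    dispersion = 0.1, n_rep = 3L, lib_size = 1e6,
    n_arf = 2L, arf_len = 1500L, arf_site_spacing = 200L,
    pare_depth = 20, pare_background = 0.02
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown generator parameter(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(ov)] <- ov
  stopifnot(cfg$phase_noise >= 0, cfg$phase_noise <= 1,
            cfg$off_size >= 0, cfg$off_size <= 1,
            cfg$tas_fold > 0, cfg$dispersion >= 0, cfg$lib_size > 0)
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

write_seq <- function(genome, chrom, start0, what) {
  Biostrings::subseq(genome[[chrom]], start = start0 + 1L,
                     width = nchar(what)) <- Biostrings::DNAString(what)
  genome
}

#' Generate a toy genome with planted loci and ground truth
#'
#' @param config list from [generator_config()].
#' @param seed integer seed; all outputs are byte-identical given the
#'   same seed and config.
#' @return list with `genome` (`DNAStringSet`), `transcripts`
#'   (`DNAStringSet`: one per TAS locus, locus +/- 50 nt flanks, plus the
#'   ARF3-like transcripts), `annotation` (tibble of all planted loci)
#'   and `truth` (trigger and tasiR-ARF sequences, per-TAS-locus
#'   geometry, per-locus expected abundances and fold changes, cleavage
#'   and decoy positions).
#' @export
make_genome <- function(config = generator_config(), seed = 1L) {
  set.seed(seed)
  cfg <- config
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  genome <- Biostrings::DNAStringSet(
    vapply(chroms, function(x) random_dna(cfg$chrom_len), character(1))
  )
  names(genome) <- chroms

  n_loci <- cfg$n_tas + cfg$n_mirna + cfg$n_hairpin +
    cfg$n_repeat * cfg$repeat_copies + cfg$n_het + cfg$n_null
  slots_per_chrom <- (cfg$chrom_len - 100L) %/% cfg$slot_len
  slots <- expand.grid(chrom = chroms,
                       slot = seq_len(slots_per_chrom) - 1L,
                       stringsAsFactors = FALSE)
  if (nrow(slots) < n_loci) {
    stop("genome too small for the requested locus counts")
  }
  pick <- slots[sample.int(nrow(slots), n_loci), , drop = FALSE]
  pick$pos <- 100L + pick$slot * cfg$slot_len
  row <- 0L

  trigger <- random_dna(21L)
  tarf <- random_dna(21L)
  site5_seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(trigger)))
  tarf_site <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(tarf)))

  tas <- tibble::tibble(
    locus_id = character(), chrom = character(), start = integer(),
    end = integer(), site5_start = integer(), site5_end = integer(),
    site3_start = integer(), site3_end = integer(), cleavage = integer(),
    register = integer(), cycles = integer(), tarf_d = integer()
  )
  for (i in seq_len(cfg$n_tas)) {
    row <- row + 1L
    ch <- pick$chrom[row]; p <- pick$pos[row]
    cycles <- sample(cfg$tas_cycles, 1L)
    site5_start <- p
    site5_end <- p + 21L
    cleavage <- site5_end + cycles * 21L
    site3_start <- cleavage - 11L
    site3_end <- site3_start + 21L
    genome <- write_seq(genome, ch, site5_start, site5_seq)
    genome <- write_seq(genome, ch, site3_start, site5_seq)
    # shared tasiR-ARF at D_tarf(+)
    genome <- write_seq(genome, ch, cleavage - 21L * cfg$tarf_d, tarf)
    tas <- dplyr::bind_rows(tas, tibble::tibble(
      locus_id = sprintf("tas%02d", i), chrom = ch,
      start = site5_start, end = site3_end,
      site5_start = site5_start, site5_end = site5_end,
      site3_start = site3_start, site3_end = site3_end,
      cleavage = cleavage, register = cleavage %% 21L,
      cycles = cycles, tarf_d = cfg$tarf_d
    ))
  }

  other <- NULL
  add_locus <- function(class, n, len, size_class, mean_rpm, fold,
                        family = NA_character_) {
    res <- NULL
    for (i in seq_len(n)) {
      row <<- row + 1L
      res <- dplyr::bind_rows(res, tibble::tibble(
        locus_id = sprintf("%s%02d", class, i), class = class,
        chrom = pick$chrom[row], start = pick$pos[row],
        end = pick$pos[row] + len, size_class = size_class,
        mean_rpm = mean_rpm, fold = fold, family = family
      ))
    }
    res
  }
  other <- dplyr::bind_rows(
    add_locus("mirna", cfg$n_mirna, 120L, 21L, cfg$mirna_mean_rpm,
              cfg$mirna_fold),
    add_locus("hairpin", cfg$n_hairpin, 300L, 22L, cfg$hairpin_mean_rpm,
              cfg$hairpin_fold),
    add_locus("het", cfg$n_het, 300L, 24L, cfg$het_mean_rpm, cfg$het_fold),
    add_locus("null", cfg$n_null, 300L, NA_integer_, cfg$null_mean_rpm,
              cfg$null_fold)
  )
  # repeat families: identical sequence written at each copy
  rep_loci <- NULL
  for (f in seq_len(cfg$n_repeat)) {
    fam_seq <- random_dna(300L)
    for (cp in seq_len(cfg$repeat_copies)) {
      row <- row + 1L
      ch <- pick$chrom[row]; p <- pick$pos[row]
      genome <- write_seq(genome, ch, p, fam_seq)
      rep_loci <- dplyr::bind_rows(rep_loci, tibble::tibble(
        locus_id = sprintf("repeat%02d_c%d", f, cp), class = "repeat",
        chrom = ch, start = p, end = p + 300L, size_class = NA_integer_,
        mean_rpm = cfg$repeat_mean_rpm, fold = cfg$repeat_fold,
        family = sprintf("repfam%02d", f)
      ))
    }
  }
  other <- dplyr::bind_rows(other, rep_loci)

  # transcripts: TAS locus +/- 50 nt flanks, plus ARF3-like transcripts
  tx <- list()
  for (i in seq_len(nrow(tas))) {
    tx[[tas$locus_id[i]]] <- Biostrings::subseq(
      genome[[tas$chrom[i]]],
      start = tas$start[i] - 50L + 1L, end = tas$end[i] + 50L
    )
  }
  arf_sites <- NULL
  for (a in seq_len(cfg$n_arf)) {
    id <- sprintf("arf3_%d", a)
    s <- Biostrings::DNAString(random_dna(cfg$arf_len))
    p1 <- 400L
    p2 <- p1 + cfg$arf_site_spacing
    Biostrings::subseq(s, start = p1 + 1L, width = 21L) <-
      Biostrings::DNAString(tarf_site)
    Biostrings::subseq(s, start = p2 + 1L, width = 21L) <-
      Biostrings::DNAString(tarf_site)
    tx[[id]] <- s
    arf_sites <- dplyr::bind_rows(arf_sites, tibble::tibble(
      transcript = id, site_start = c(p1, p2), site_end = c(p1, p2) + 21L,
      cleavage = c(p1, p2) + 21L - 10L
    ))
  }
  transcripts <- Biostrings::DNAStringSet(tx)

  # true cleavage positions (transcript coordinates) and uncleaved decoys
  cleavages <- dplyr::bind_rows(
    tibble::tibble(
      transcript = tas$locus_id,
      pos = tas$cleavage - tas$start + 50L,
      cleaved = TRUE, type = "tas_site3"
    ),
    tibble::tibble(
      transcript = arf_sites$transcript, pos = arf_sites$cleavage,
      cleaved = TRUE, type = "arf_site"
    ),
    tibble::tibble(
      transcript = rep(sprintf("arf3_%d", seq_len(cfg$n_arf)), each = 2L),
      pos = rep(c(1000L, 1100L), cfg$n_arf),
      cleaved = FALSE, type = "decoy"
    )
  )

  annotation <- dplyr::bind_rows(
    tibble::tibble(locus_id = tas$locus_id, class = "tas",
                   chrom = tas$chrom, start = tas$start, end = tas$end,
                   size_class = 21L, mean_rpm = cfg$tas_mean_rpm,
                   fold = cfg$tas_fold, family = NA_character_),
    other
  )
  list(
    genome = genome,
    transcripts = transcripts,
    annotation = annotation,
    truth = list(trigger = trigger, tarf = tarf, tas = tas,
                 arf_sites = arf_sites, cleavages = cleavages),
    config = cfg
  )
}

# NB count for one locus in one library.
nb_count <- function(mean_rpm, fold, lib_size, dispersion) {
  mu <- mean_rpm * fold * lib_size / 1e6
  if (dispersion <= 0) return(as.integer(round(mu)))
  rnbinom(1L, size = 1 / dispersion, mu = mu)
}

sample_offsize <- function(n, off_size, k = 21L) {
  off <- runif(n) < off_size
  len <- rep(k, n)
  len[off] <- sample(setdiff(c(20L, 22L, 24L), k), sum(off), replace = TRUE)
  len
}

#' Simulate sRNA-seq libraries from a generated genome
#'
#' Per library and locus, a negative-binomial count is drawn around
#' `mean_rpm * genotype fold`; TAS reads fall on D positions (both
#' strands, minus-strand reads at the exact duplex-partner coordinates,
#' leftmost = plus partner - 2) with probability `1 - phase_noise` and
#' off-register otherwise; repeat-family reads are emitted once per
#' planted copy with `n_hits` equal to the copy number.
#'
#' @param gen output of [make_genome()].
#' @param seed integer seed.
#' @return list with `design` (library design tibble) and `reads`
#'   (alignment record tibble with a `library` column).
#' @export
simulate_reads <- function(gen, seed = 1L) {
  set.seed(seed)
  cfg <- gen$config
  design <- library_design(
    name = c(paste0("wt", seq_len(cfg$n_rep)),
             paste0("mut", seq_len(cfg$n_rep))),
    genotype = rep(c("wildtype", "mutant"), each = cfg$n_rep),
    replicate = rep(seq_len(cfg$n_rep), 2L),
    genome_matched_total = rep(cfg$lib_size, 2L * cfg$n_rep)
  )
  # fixed per-locus anchors shared across libraries
  mirna <- gen$annotation[gen$annotation$class == "mirna", , drop = FALSE]
  mirna$site <- mirna$start + 40L
  all_reads <- list()
  for (li in seq_len(nrow(design))) {
    lib <- design$name[li]
    mut <- design$genotype[li] == "mutant"
    reads <- list()

    for (i in seq_len(nrow(gen$truth$tas))) {
      t <- gen$truth$tas[i, ]
      n <- nb_count(cfg$tas_mean_rpm, if (mut) cfg$tas_fold else 1,
                    cfg$lib_size, cfg$dispersion)
      if (n == 0L) next
      inreg <- runif(n) >= cfg$phase_noise
      strand <- sample(c("+", "-"), n, replace = TRUE)
      len <- sample_offsize(n, cfg$off_size)
      d <- sample.int(t$cycles, n, replace = TRUE)
      phase_pos <- t$cleavage - 21L * d
      # off-register reads: uniform non-register adjusted position
      n_off <- sum(!inreg)
      if (n_off > 0L) {
        cand <- seq.int(t$start, t$end - 21L)
        cand <- cand[cand %% 21L != t$register]
        phase_pos[!inreg] <- sample(cand, n_off, replace = TRUE)
      }
      start <- ifelse(strand == "+", phase_pos, phase_pos - 2L)
      reads[[length(reads) + 1L]] <- tibble::tibble(
        chrom = t$chrom, start = as.integer(start), length = len,
        strand = strand,
        name = sprintf("%s_%s_%04d", lib, t$locus_id, seq_len(n)),
        copies = 1L, n_hits = 1L, library = lib
      )
    }

    for (i in seq_len(nrow(mirna))) {
      mr <- mirna[i, ]
      n <- nb_count(mr$mean_rpm, if (mut) mr$fold else 1,
                    cfg$lib_size, cfg$dispersion)
      if (n == 0L) next
      reads[[length(reads) + 1L]] <- tibble::tibble(
        chrom = mr$chrom, start = mr$site, length = 21L, strand = "+",
        name = sprintf("%s_%s_%04d", lib, mr$locus_id, seq_len(n)),
        copies = 1L, n_hits = 1L, library = lib
      )
    }

    scatter <- gen$annotation[gen$annotation$class %in%
                                c("hairpin", "het", "null"), , drop = FALSE]
    for (i in seq_len(nrow(scatter))) {
      lc <- scatter[i, ]
      n <- nb_count(lc$mean_rpm, if (mut) lc$fold else 1,
                    cfg$lib_size, cfg$dispersion)
      if (n == 0L) next
      len <- if (is.na(lc$size_class)) {
        sample(c(21L, 22L, 24L), n, replace = TRUE)
      } else {
        rep(lc$size_class, n)
      }
      start <- sample(seq.int(lc$start, lc$end - 25L), n, replace = TRUE)
      reads[[length(reads) + 1L]] <- tibble::tibble(
        chrom = lc$chrom, start = start, length = len,
        strand = sample(c("+", "-"), n, replace = TRUE),
        name = sprintf("%s_%s_%04d", lib, lc$locus_id, seq_len(n)),
        copies = 1L, n_hits = 1L, library = lib
      )
    }

    reps <- gen$annotation[gen$annotation$class == "repeat", , drop = FALSE]
    for (fam in unique(reps$family)) {
      copies <- reps[reps$family == fam, , drop = FALSE]
      n <- nb_count(copies$mean_rpm[1], if (mut) copies$fold[1] else 1,
                    cfg$lib_size, cfg$dispersion)
      if (n == 0L) next
      offset <- sample.int(300L - 22L, n, replace = TRUE) - 1L
      len <- sample(c(21L, 22L), n, replace = TRUE)
      n_copies <- nrow(copies)
      for (cp in seq_len(n_copies)) {
        reads[[length(reads) + 1L]] <- tibble::tibble(
          chrom = copies$chrom[cp], start = copies$start[cp] + offset,
          length = len, strand = "+",
          name = sprintf("%s_%s_%04d", lib, fam, seq_len(n)),
          copies = 1L, n_hits = n_copies, library = lib
        )
      }
    }
    all_reads[[lib]] <- dplyr::bind_rows(reads)
  }
  list(design = design, reads = dplyr::bind_rows(all_reads))
}

#' Simulate PARE tags from ground truth
#'
#' True cleavage positions receive Poisson(`pare_depth`) tags; every
#' transcript additionally receives a uniform background of
#' `pare_background` tags per nucleotide. Decoy (uncleaved) sites receive
#' background only.
#'
#' @param gen output of [make_genome()].
#' @param seed integer seed.
#' @return tag tibble (`transcript`, `pos`, `count`).
#' @export
simulate_pare <- function(gen, seed = 1L) {
  set.seed(seed)
  cfg <- gen$config
  tags <- list()
  cl <- gen$truth$cleavages
  true <- cl[cl$cleaved, , drop = FALSE]
  cnt <- rpois(nrow(true), cfg$pare_depth)
  tags[[1]] <- tibble::tibble(transcript = true$transcript,
                              pos = true$pos, count = cnt)
  tx_len <- Biostrings::width(gen$transcripts)
  for (i in seq_along(gen$transcripts)) {
    nbg <- rpois(1L, tx_len[i] * cfg$pare_background)
    if (nbg == 0L) next
    tags[[length(tags) + 1L]] <- tibble::tibble(
      transcript = names(gen$transcripts)[i],
      pos = sample.int(tx_len[i], nbg, replace = TRUE) - 1L,
      count = 1L
    )
  }
  dplyr::bind_rows(tags) |>
    dplyr::count(.data$transcript, .data$pos, wt = .data$count,
                 name = "count") |>
    dplyr::filter(.data$count > 0)
}
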