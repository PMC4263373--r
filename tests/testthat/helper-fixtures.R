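# Fixtures are built in code at test time; no binary files.

# A minimal alignment record tibble.
make_records <- function(chrom = "chr1", start = 0L, length = 21L,
                         strand = "+", name = NULL, copies = 1L,
                         n_hits = 1L, library = NULL) {
  n <- max(lengths(list(chrom, start, length, strand, copies, n_hits)))
  out <- tibble::tibble(
    chrom = rep_len(chrom, n),
    start = as.integer(rep_len(start, n)),
    length = as.integer(rep_len(length, n)),
    strand = rep_len(strand, n),
    name = if (is.null(name)) sprintf("r%03d", seq_len(n)) else rep_len(name, n),
    copies = as.integer(rep_len(copies, n)),
    n_hits = as.integer(rep_len(n_hits, n))
  )
  if (!is.null(library)) out$library <- rep_len(library, n)
  out
}

# Write a small SAM file; each alignment is a perfect ungapped match.
# aln: data.frame with qname, chrom, pos1 (1-based), len, minus (logical),
# and optional nh, nm.
write_test_sam <- function(aln, path = tempfile(fileext = ".sam"),
                           sq = c(chr1 = 10000L, chr2 = 10000L)) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq))
  nh <- if ("nh" %in% names(aln)) aln$nh else rep(1L, nrow(aln))
  nm <- if ("nm" %in% names(aln)) aln$nm else rep(0L, nrow(aln))
  body <- vapply(seq_len(nrow(aln)), function(i) {
    paste(aln$qname[i], if (aln$minus[i]) 16L else 0L, aln$chrom[i],
          aln$pos1[i], 255L, paste0(aln$len[i], "M"), "*", 0L, 0L,
          strrep("A", aln$len[i]), "*",
          paste0("NH:i:", nh[i]), paste0("NM:i:", nm[i]),
          sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# Independent brute-force best register/score for one window: enumerates
# all k registers with explicit loops over the C cycle positions.
brute_force_phase <- function(pos, ab, rd, w, k, window_len) {
  C <- window_len %/% k
  keep <- pos >= w & pos < w + window_len
  pos <- pos[keep]; ab <- ab[keep]; rd <- rd[keep]
  best <- list(score = -Inf, register = NA_integer_)
  for (r in 0:(k - 1)) {
    first <- w + ((r - w) %% k)
    cyc <- first + k * (0:(C - 1))
    P <- 0; n <- 0L; ir <- 0
    for (cp in cyc) {
      sel <- pos == cp
      if (any(sel)) {
        n <- n + 1L
        P <- P + sum(ab[sel])
        ir <- ir + sum(rd[sel])
      }
    }
    U <- sum(ab) - P
    sc <- if (n < 3) 0 else (n - 2) * log(1 + 10 * P / (1 + U))
    if (sc > best$score) {
      best <- list(score = sc, register = r, n = n, P = P, U = U,
                   inphase_reads = ir)
    }
  }
  best
}

# Independent Allen scorer from explicit character alignments: srna_chars
# aligned (5'->3') against target_chars (3'->5', i.e. the target read
# backwards), with "-" marking a bulge on the opposite strand.
naive_allen_score <- function(srna_chars, target_chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  score <- 0
  spos <- 0L
  for (i in seq_along(srna_chars)) {
    s <- srna_chars[i]; t <- target_chars[i]
    if (s != "-") spos <- spos + 1L
    pen <- if (s == "-") {          # bulged target nucleotide
      1
    } else if (t == "-") {          # bulged sRNA nucleotide
      1
    } else if (comp[[s]] == t) {
      0
    } else if ((s == "G" && t == "T") || (s == "T" && t == "G")) {
      0.5
    } else {
      1
    }
    core_pos <- if (s == "-") spos + 1L else spos
    if (core_pos >= 2 && core_pos <= 13) pen <- pen * 2
    score <- score + pen
  }
  score
}

# Independent site enumerator: all ungapped and single-bulge alignments
# of srna against transcript, returning best score per cleavage position.
naive_find_sites <- function(srna, transcript, max_score = 4.5) {
  sr <- strsplit(gsub("U", "T", toupper(srna)), "")[[1]]
  tc <- strsplit(gsub("U", "T", toupper(transcript)), "")[[1]]
  L <- length(sr); Tn <- length(tc)
  hits <- list()
  add <- function(s_aln, t_idx, start0, end0, n_bulges) {
    # t_idx: target indices (1-based) aligned to s_aln, NA for sRNA bulge
    t_aln <- ifelse(is.na(t_idx), "-", tc[t_idx])
    sc <- naive_allen_score(s_aln, t_aln)
    if (sc <= max_score) {
      # cleavage: target nt opposite sRNA position 10
      sp <- cumsum(s_aln != "-")
      cl <- t_idx[which(sp == 10 & s_aln != "-")[1]] - 1L
      hits[[length(hits) + 1L]] <<- data.frame(start = start0, end = end0,
                                               score = sc, cleavage = cl,
                                               n_bulges = n_bulges)
    }
  }
  # ungapped
  for (s in 0:(Tn - L)) {
    add(sr, (s + L):(s + 1), s, s + L, 0L)
  }
  # sRNA bulge at internal position b (target shows "-")
  if (L >= 3 && Tn >= L - 1) {
    for (b in 2:(L - 1)) {
      for (s in 0:(Tn - (L - 1))) {
        t_idx <- integer(L)
        t_idx[seq_len(b - 1)] <- s + (L - 1) - seq_len(b - 1) + 1
        t_idx[b] <- NA
        if (b < L) t_idx[(b + 1):L] <- s + L - ((b + 1):L) + 1
        add(sr, t_idx, s, s + L - 1L, 1L)
      }
    }
  }
  # target bulge between sRNA positions b and b+1 ("-" in the sRNA row)
  if (Tn >= L + 1) {
    for (b in 1:(L - 1)) {
      for (s in 0:(Tn - (L + 1))) {
        s_aln <- append(sr, "-", after = b)
        t_idx <- s + (L + 1) - seq_len(L + 1) + 1
        add(s_aln, t_idx, s, s + L + 1L, 1L)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      score = numeric(), cleavage = integer()))
  }
  h <- do.call(rbind, hits)
  # per cleavage position keep the best score, preferring fewer bulges
  h <- h[order(h$cleavage, h$score, h$n_bulges, h$start), , drop = FALSE]
  h <- h[!duplicated(h$cleavage), , drop = FALSE]
  h[order(h$score, h$start), , drop = FALSE]
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# A small generator configuration for fast end-to-end tests.
small_generator <- function(...) {
  generator_config(n_chrom = 1L, chrom_len = 30000L, n_tas = 3L,
                   n_mirna = 2L, n_hairpin = 2L, n_repeat = 1L,
                   n_het = 2L, n_null = 10L, ...)
}
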