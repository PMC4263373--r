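# Windowed differential small RNA abundance between two genotypes.
#
# Counts are taken in non-overlapping windows tiling each sequence from
# coordinate 0; a read is assigned to the window containing its
# strand-aware 5' end, both strands pooled, one count matrix per size
# class. Differential testing uses the exact negative-binomial test with
# a single common dispersion shared across windows (the small-replicate
# regime), with library sizes set to the genome-matched totals.

window_meta_cols <- c("chrom", "start", "end", "size_class")

#' Count reads of one size class in non-overlapping genomic windows
#'
#' @param records alignment record tibble with a `library` column.
#' @param size_class read length (nt) to count, e.g. 21, 22 or 24.
#' @param window_len window length in nt (windows tile from coordinate 0).
#' @param libraries library names defining the count columns; defaults to
#'   the libraries present in `records`. Pass the full design so that
#'   empty libraries yield all-zero columns.
#' @return tibble with columns `chrom`, `start`, `end`, `size_class` and
#'   one count column per library (summed `copies`); only windows with at
#'   least one read appear (absent windows are all-zero by construction).
#' @export
count_windows <- function(records, size_class, window_len = 500L,
                          libraries = NULL) {
  stopifnot(window_len >= 1L)
  if (is.null(libraries)) libraries <- unique(records$library)
  r <- records[records$length == size_class, , drop = FALSE]
  if (nrow(r) == 0L) {
    out <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), size_class = integer())
    for (lib in libraries) out[[lib]] <- numeric()
    return(out)
  }
  pos5 <- five_prime_pos(r)
  r$start_win <- (pos5 %/% window_len) * window_len
  cnt <- r |>
    dplyr::count(.data$chrom, .data$start_win, .data$library,
                 wt = .data$copies, name = "count") |>
    tidyr::pivot_wider(names_from = "library", values_from = "count",
                       values_fill = 0)
  for (lib in setdiff(libraries, names(cnt))) cnt[[lib]] <- 0
  out <- tibble::tibble(
    chrom = cnt$chrom,
    start = as.integer(cnt$start_win),
    end = as.integer(cnt$start_win + window_len),
    size_class = as.integer(size_class)
  )
  out <- dplyr::bind_cols(out, cnt[, libraries, drop = FALSE])
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Remove windows with too few reads across all libraries
#'
#' @param counts window count tibble from [count_windows()].
#' @param min_total minimum summed count across all libraries.
#' @param libraries library column names; defaults to every non-metadata
#'   column.
#' @return filtered count tibble; warns when nothing survives.
#' @export
filter_low_windows <- function(counts, min_total = 10, libraries = NULL) {
  libraries <- libraries %||% setdiff(names(counts), window_meta_cols)
  tot <- rowSums(as.matrix(counts[, libraries, drop = FALSE]))
  out <- counts[tot >= min_total, , drop = FALSE]
  if (nrow(out) == 0L && nrow(counts) > 0L) {
    warning("all windows fall below the minimum total of ", min_total)
  }
  out
}

#' Exact negative-binomial test of genotype effect per window
#'
#' Fits the two-group exact NB test with one common dispersion shared
#' across windows (quantile-adjusted conditional maximum likelihood, as
#' implemented in edgeR), with library sizes fixed at the genome-matched
#' totals. The log2 fold change (mutant vs wild-type) is computed on
#' size-factor-normalized group means with a 0.5 pseudo-count, so windows
#' empty in one genotype remain finite.
#'
#' @param counts filtered window count tibble.
#' @param design library design from [library_design()]; at least two
#'   libraries per genotype.
#' @return tibble with the window identity plus `log2fc`, `p`,
#'   `direction` (`"up_in_mutant"` / `"down_in_mutant"`) and the common
#'   dispersion as attribute `common_dispersion`.
#' @export
nb_test <- function(counts, design) {
  ngrp <- table(factor(design$genotype, c("wildtype", "mutant")))
  if (any(ngrp == 0L)) stop("each genotype needs at least one library")
  if (any(ngrp < 2L)) stop("each genotype needs at least two libraries")
  m <- as.matrix(counts[, design$name, drop = FALSE])
  rownames(m) <- paste(counts$chrom, counts$start, sep = ":")
  group <- factor(design$genotype, levels = c("wildtype", "mutant"))

  dge <- edgeR::DGEList(counts = m, group = group,
                        lib.size = design$genome_matched_total)
  dge <- suppressWarnings(edgeR::estimateCommonDisp(dge))
  disp <- dge$common.dispersion
  if (is.null(disp) || is.na(disp)) {
    disp <- moment_dispersion(m, group, design$genome_matched_total)
  }
  if (disp <= 0) {
    warning("non-positive common dispersion estimate clamped to 1e-6")
    disp <- 1e-6
  }
  dge$common.dispersion <- disp
  et <- edgeR::exactTest(dge, pair = c("wildtype", "mutant"),
                         dispersion = disp)
  p <- et$table$PValue

  sf <- design$genome_matched_total / mean(design$genome_matched_total)
  nm <- sweep(m, 2, sf, "/")
  mean_wt <- unname(rowMeans(nm[, group == "wildtype", drop = FALSE]))
  mean_mut <- unname(rowMeans(nm[, group == "mutant", drop = FALSE]))
  log2fc <- log2((mean_mut + 0.5) / (mean_wt + 0.5))

  out <- tibble::tibble(
    chrom = counts$chrom,
    start = counts$start,
    end = counts$end,
    size_class = counts$size_class,
    mean_wt = mean_wt,
    mean_mut = mean_mut,
    log2fc = log2fc,
    p = p,
    direction = ifelse(log2fc > 0, "up_in_mutant", "down_in_mutant")
  )
  attr(out, "common_dispersion") <- disp
  out
}

# Method-of-moments common dispersion on size-factor-scaled counts:
# pooled across windows, phi = (var - mu) / mu^2 averaged over windows.
moment_dispersion <- function(m, group, lib_size) {
  sf <- lib_size / mean(lib_size)
  nm <- sweep(m, 2, sf, "/")
  phis <- apply(nm, 1L, function(x) {
    res <- unlist(lapply(split(x, group), function(g) g - mean(g)))
    mu <- mean(x)
    if (mu <= 0) return(NA_real_)
    (sum(res^2) / (length(x) - 2L) - mu) / mu^2
  })
  phi <- mean(phis, na.rm = TRUE)
  if (!is.finite(phi)) phi <- 1e-6
  phi
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return BH-adjusted q-values (monotone step-up, clipped to 1).
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Call differential windows
#'
#' A window passes when `|log2fc| >= log2(min_fold)`, `q < max_q`, and it
#' does not overlap an excluded interval (e.g. an introgression interval).
#'
#' @param results tibble from [nb_test()]; a `q` column is added with
#'   [bh_adjust()] if absent.
#' @param min_fold minimum fold change.
#' @param max_q maximum BH-adjusted p-value.
#' @param exclude optional tibble of intervals (`chrom`, `start`, `end`,
#'   0-based half-open) whose windows are failed with reason
#'   `"excluded_region"`.
#' @return `results` with `q`, `passes` and `reason` columns.
#' @export
call_differential <- function(results, min_fold = 2, max_q = 0.05,
                              exclude = NULL) {
  if (!"q" %in% names(results)) results$q <- bh_adjust(results$p)
  fold_ok <- abs(results$log2fc) >= log2(min_fold)
  q_ok <- results$q < max_q
  excluded <- rep(FALSE, nrow(results))
  if (!is.null(exclude) && nrow(exclude) > 0L && nrow(results) > 0L) {
    win_gr <- GenomicRanges::GRanges(
      results$chrom,
      IRanges::IRanges(start = results$start + 1L, end = results$end)
    )
    ex_gr <- GenomicRanges::GRanges(
      exclude$chrom,
      IRanges::IRanges(start = exclude$start + 1L, end = exclude$end)
    )
    excluded <- IRanges::overlapsAny(win_gr, ex_gr)
  }
  results$passes <- fold_ok & q_ok & !excluded
  results$reason <- dplyr::case_when(
    excluded ~ "excluded_region",
    !fold_ok & !q_ok ~ "fold_and_q",
    !fold_ok ~ "fold",
    !q_ok ~ "q",
    TRUE ~ "pass"
  )
  results
}

#' Per-library read totals by size class
#'
#' @param records alignment record tibble with a `library` column.
#' @param sizes size classes to tabulate.
#' @return tibble `library`, `length`, `total` (summed copies; zero rows
#'   filled in for absent combinations).
#' @export
size_class_totals <- function(records, sizes = 18:26) {
  libs <- unique(records$library)
  records |>
    dplyr::filter(.data$length %in% sizes) |>
    dplyr::count(.data$library, .data$length, wt = .data$copies,
                 name = "total") |>
    tidyr::complete(library = libs, length = sizes,
                    fill = list(total = 0))
}

#' Two-tailed t-test on size-class totals between genotypes
#'
#' Welch two-sample test per size class on per-library totals.
#'
#' @param totals tibble from [size_class_totals()].
#' @param design library design table.
#' @return tibble `length`, `t`, `p`, `mean_wt`, `mean_mut`.
#' @export
size_class_ttest <- function(totals, design) {
  wt_libs <- design$name[design$genotype == "wildtype"]
  mut_libs <- design$name[design$genotype == "mutant"]
  if (length(wt_libs) < 2L || length(mut_libs) < 2L) {
    stop("each genotype needs at least two libraries for the t-test")
  }
  totals |>
    dplyr::group_by(.data$length) |>
    dplyr::summarise(res = {
      x <- .data$total[.data$library %in% wt_libs]
      y <- .data$total[.data$library %in% mut_libs]
      tt <- tryCatch(t.test(x, y), error = function(e) NULL)
      if (is.null(tt)) {
        # constant data: equal means -> no evidence; unequal -> certain
        if (isTRUE(all.equal(mean(x), mean(y)))) {
          list(t = 0, p = 1, mean_wt = mean(x), mean_mut = mean(y))
        } else {
          list(t = sign(mean(x) - mean(y)) * Inf, p = 0,
               mean_wt = mean(x), mean_mut = mean(y))
        }
      } else {
        list(t = unname(tt$statistic), p = tt$p.value,
             mean_wt = mean(x), mean_mut = mean(y))
      }
    } |> list(), .groups = "drop") |>
    tidyr::unnest_wider("res")
}
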