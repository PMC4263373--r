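# End-to-end orchestration of the synthetic study:
# simulate -> ingest -> diffwin + phasing -> targetscore -> pare ->
# tasreport, under a single configuration whose defaults are the
# pipeline's standard thresholds.

#' Pipeline run configuration
#'
#' Defaults: 500-nt windows, minimum 10 reads per window, 2-fold change at
#' adjusted p < 0.05, phasing score threshold 25 with at least 5
#' in-register reads, target score cap 4.5 (3.0 for tasiR-ARF calls),
#' PARE W_S/W_L >= 0.75 with W_S >= 4, at most 20 alignments per read,
#' read lengths 18-26 nt.
#'
#' @param seed integer seed driving every stochastic stage.
#' @param generator generator configuration from [generator_config()].
#' @param stages named logical vector toggling stages.
#' @param ... overrides for threshold parameters.
#' @return a run configuration list.
#' @export
run_config <- function(seed = 1L, generator = generator_config(),
                       stages = c(simulate = TRUE, diffwin = TRUE,
                                  phasing = TRUE, targetscore = TRUE,
                                  pare = TRUE, tasreport = TRUE),
                       ...) {
  cfg <- list(
    seed = as.integer(seed), generator = generator, stages = stages,
    window_len = 500L, min_total = 10, min_fold = 2, max_q = 0.05,
    step = 250L, min_inphase_reads = 5, p_threshold = 25,
    size_classes = c(21L, 22L, 24L),
    max_score = 4.5, tarf_max_score = 3,
    pare_min_ratio = 0.75, pare_min_ws = 4,
    max_hits = 20L, min_len = 18L, max_len = 26L
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown run parameter(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(ov)] <- ov
  cfg
}

stage_on <- function(config, stage) {
  isTRUE(config$stages[[stage]])
}

need_stage <- function(config, stage, needed_by) {
  if (!stage_on(config, stage)) {
    stop("stage '", needed_by, "' requires output of disabled stage '",
         stage, "'")
  }
}

#' Run the full synthetic study
#'
#' Executes the enabled stages in dependency order on generated data and
#' returns every intermediate result plus a run manifest (parameters,
#' seed, input sizes and result digests); identical configuration yields
#' identical outputs.
#'
#' @param config run configuration from [run_config()].
#' @return a result bundle: `gen`, `design`, `reads`, `diff` (per size
#'   class), `windows`, `clusters`, `two_hits`, `tas` (locus table),
#'   `tasirnas`, `pare`, `manifest`.
#' @export
run_all <- function(config = run_config()) {
  if (!stage_on(config, "simulate")) {
    stop("stage 'simulate' must be enabled: this runner reproduces the ",
         "synthetic study end to end")
  }
  seed <- config$seed
  gen <- make_genome(config$generator, seed = seed)
  sim <- simulate_reads(gen, seed = seed + 1L)
  tags <- simulate_pare(gen, seed = seed + 2L)
  design <- sim$design

  reads <- filter_alignments(sim$reads, max_hits = config$max_hits,
                             min_len = config$min_len,
                             max_len = config$max_len)
  reads <- reads |>
    dplyr::group_by(.data$library) |>
    dplyr::group_modify(function(df, key) {
      tot <- design$genome_matched_total[design$name == key$library]
      normalize_rpm(df, tot)
    }) |>
    dplyr::ungroup()

  out <- list(gen = gen, design = design, reads = reads, tags = tags)

  if (stage_on(config, "diffwin")) {
    out$diff <- lapply(stats::setNames(config$size_classes,
                                       config$size_classes), function(k) {
      counts <- count_windows(reads, size_class = k,
                              window_len = config$window_len,
                              libraries = design$name)
      counts <- filter_low_windows(counts, min_total = config$min_total,
                                   libraries = design$name)
      if (nrow(counts) == 0L) return(NULL)
      res <- nb_test(counts, design)
      call_differential(res, min_fold = config$min_fold,
                        max_q = config$max_q)
    })
  }

  if (stage_on(config, "phasing")) {
    wt_reads <- reads[reads$library %in%
                        design$name[design$genotype == "wildtype"], ,
                      drop = FALSE]
    out$windows <- list()
    out$clusters <- list()
    for (k in config$size_classes) {
      pm <- merge_strands(wt_reads[wt_reads$length == k, , drop = FALSE])
      w <- scan_windows(pm, k = k, window_len = config$window_len,
                        step = config$step,
                        min_inphase_reads = config$min_inphase_reads,
                        threshold = config$p_threshold)
      cl <- merge_clusters(w)
      dk <- if (stage_on(config, "diffwin")) out$diff[[as.character(k)]] else NULL
      cl <- flag_lbl1_dependent(cl, dk)
      out$windows[[as.character(k)]] <- w
      out$clusters[[as.character(k)]] <- cl
    }
  }

  if (stage_on(config, "targetscore")) {
    txs <- gen$transcripts
    tas_ids <- gen$truth$tas$locus_id
    out$two_hits <- dplyr::bind_rows(lapply(tas_ids, function(id) {
      detect_two_hit(as.character(txs[[id]]), gen$truth$trigger,
                     max_score = config$max_score, transcript_id = id)
    }))
  }

  if (stage_on(config, "tasreport")) {
    need_stage(config, "targetscore", "tasreport")
    need_stage(config, "phasing", "tasreport")
    arf_ids <- grep("^arf3_", names(gen$transcripts), value = TRUE)
    arf_txs <- vapply(arf_ids, function(id) {
      as.character(gen$transcripts[[id]])
    }, character(1))
    tas_rows <- list()
    tasir <- list()
    for (i in seq_len(nrow(out$two_hits))) {
      th <- out$two_hits[i, ]
      id <- th$transcript_id
      locus <- gen$truth$tas[gen$truth$tas$locus_id == id, ]
      tsr <- enumerate_tasirnas(th$cleavage, th$site5_end,
                                seq = gen$transcripts[[id]])
      tsr <- flag_tasirarfs(tsr, arf_txs, max_score = config$tarf_max_score)
      tsr$locus_id <- id
      tasir[[id]] <- tsr
      dk <- if (stage_on(config, "diffwin")) out$diff[["21"]] else NULL
      tas_rows[[id]] <- summarize_tas_locus(
        locus_id = id, chrom = locus$chrom,
        region_start = locus$start, region_end = locus$end,
        tasirnas = tsr, records = reads, design = design,
        clusters = out$clusters[["21"]], diff_calls = dk
      )
    }
    out$tasirnas <- dplyr::bind_rows(tasir)
    out$tas <- dplyr::bind_rows(tas_rows)
  }

  if (stage_on(config, "pare")) {
    need_stage(config, "targetscore", "pare")
    tx_len <- stats::setNames(Biostrings::width(gen$transcripts),
                              names(gen$transcripts))
    # predicted sites: 3' trigger sites on TAS transcripts plus
    # tasiR-ARF sites on the ARF3-like transcripts, plus truth decoys
    sites <- tibble::tibble(transcript_id = out$two_hits$transcript_id,
                            cleavage = out$two_hits$cleavage,
                            site = "tas_site3")
    arf_ids <- grep("^arf3_", names(gen$transcripts), value = TRUE)
    arf_hits <- dplyr::bind_rows(lapply(arf_ids, function(id) {
      find_sites(gen$truth$tarf, as.character(gen$transcripts[[id]]),
                 max_score = config$tarf_max_score, srna_id = "tasiR-ARF",
                 transcript_id = id)
    }))
    if (nrow(arf_hits) > 0L) {
      sites <- dplyr::bind_rows(sites, tibble::tibble(
        transcript_id = arf_hits$transcript_id,
        cleavage = arf_hits$cleavage, site = "arf_site"
      ))
    }
    decoys <- gen$truth$cleavages[!gen$truth$cleavages$cleaved, ,
                                  drop = FALSE]
    sites <- dplyr::bind_rows(sites, tibble::tibble(
      transcript_id = decoys$transcript, cleavage = decoys$pos,
      site = "decoy"
    ))
    out$pare <- validate_sites(sites, tags,
                               min_ratio = config$pare_min_ratio,
                               min_ws = config$pare_min_ws,
                               tx_len = tx_len)
  }

  out$manifest <- run_manifest(config, out)
  out
}

run_manifest <- function(config, out) {
  digest <- function(x) rlang::hash(x)
  list(
    package_version = as.character(utils::packageVersion("phasitrack")),
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c("generator", "stages", "seed"))],
    generator = config$generator,
    n_reads = nrow(out$reads),
    n_libraries = nrow(out$design),
    digests = list(
      reads = digest(out$reads),
      diff = digest(out$diff %||% NULL),
      clusters = digest(out$clusters %||% NULL),
      tas = digest(out$tas %||% NULL),
      pare = digest(out$pare %||% NULL)
    )
  )
}
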