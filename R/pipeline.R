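#' Summarise one meiosis
#'
#' Tallies crossovers, noncrossovers, complex and multi-DSB events,
#' trans-DSB (8:0/7:1) events, non-exchange chromosomes, per-chromosome CO
#' counts, inter-CO distances and event mid-lengths for a classified
#' meiosis.  Type-U events are excluded from all tallies.
#'
#' @param events_by_chrom Named list of classified `event_table`s.
#' @param genome A [genome_model()]; chromosomes without markers still
#'   count as non-exchange.
#' @param meiosis_id,genotype Labels carried into the summary row.
#' @return A list of class `meiosis_summary`: `summary` (1-row data frame),
#'   `co_per_chrom` (named integer vector over all genome chromosomes),
#'   `icds`, `midlengths`.
#' @export
summarize_meiosis <- function(events_by_chrom, genome, meiosis_id = 1L,
                              genotype = "unknown") {
  co_per_chrom <- stats::setNames(integer(nrow(genome)), genome$chrom)
  nco_per_chrom <- co_per_chrom
  n_co <- n_nco <- n_complex <- n_trans <- 0L
  multi <- c(dCO = 0L, dNCO_sister = 0L, dNCO_overlap = 0L, CO_plus_NCO = 0L)
  midlengths <- numeric(0)
  n_u <- 0L
  for (chr in names(events_by_chrom)) {
    ev <- events_by_chrom[[chr]]
    if (!nrow(ev)) next
    n_u <- n_u + sum(ev$type_U)
    ok <- !ev$type_U
    co_per_chrom[chr] <- sum(ev$co_count[ok], na.rm = TRUE)
    nco_per_chrom[chr] <- sum(ev$nco_count[ok], na.rm = TRUE)
    n_co <- n_co + co_per_chrom[chr]
    n_nco <- n_nco + nco_per_chrom[chr]
    n_complex <- n_complex + sum(ev$complex[ok])
    if ("multi_class" %in% names(ev)) {
      t <- table(ev$multi_class[ok])
      for (cl in names(multi)) if (cl %in% names(t)) multi[cl] <- multi[cl] + t[[cl]]
      n_trans <- n_trans + sum(ev$trans_dsb[ok], na.rm = TRUE)
    }
    is_multi <- if ("multi_class" %in% names(ev)) ev$multi_class != "none"
                else rep(FALSE, nrow(ev))
    ml <- event_midlength(ev)
    midlengths <- c(midlengths, ml[ok & !is_multi & !is.na(ml)])
  }
  icds <- compute_icds(events_by_chrom)
  nonx <- names(co_per_chrom)[co_per_chrom == 0]
  nonx_strict <- names(co_per_chrom)[co_per_chrom == 0 & nco_per_chrom == 0]
  summary <- data.frame(
    meiosis = meiosis_id, genotype = genotype,
    n_co = n_co, n_nco = n_nco, n_events_U = n_u, n_complex = n_complex,
    n_multi_dsb = sum(multi), n_dCO = multi[["dCO"]],
    n_dNCO_sister = multi[["dNCO_sister"]],
    n_dNCO_overlap = multi[["dNCO_overlap"]],
    n_CO_plus_NCO = multi[["CO_plus_NCO"]],
    n_trans_dsb = n_trans,
    n_nonexchange = length(nonx),
    n_nonexchange_strict = length(nonx_strict),
    nonexchange_chroms = paste(nonx, collapse = ","),
    stringsAsFactors = FALSE
  )
  structure(list(summary = summary, co_per_chrom = co_per_chrom,
                 icds = icds, midlengths = midlengths),
            class = "meiosis_summary")
}

#' Run the post-alignment analysis pipeline
#'
#' Executes genotyping, octad/mocktad assembly, segmentation, event calling,
#' classification, QC and per-meiosis summaries, writing TSV outputs and a
#' manifest.  Inputs are either files (marker map, site counts, sample
#' sheet) or a `simulate` block that generates a synthetic dataset.
#'
#' @param config A list:
#'   * `mode`: `"octad"`, `"tetrad"` or `"mocktad"`;
#'   * `marker_map`, `site_counts`, `sample_sheet`: input TSV paths, or
#'   * `simulate`: list with `n_meioses` and optional [sim_params()]
#'     arguments, in which case inputs are generated;
#'   * `genome`: genome-table TSV path (default: [yeast_genome()]);
#'   * `hotspots`: optional BED path;
#'   * `out_dir`: output directory (required);
#'   * `min_gap`: event separation (default 1500);
#'   * `caller`: list of [caller_config()] overrides;
#'   * `seed`: integer seed recorded in the manifest (required when
#'     simulating).
#' @return Invisibly, a list with `events` (combined data frame),
#'   `summaries`, `qc`, and the output paths.
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mode <- match.arg(config$mode, c("octad", "tetrad", "mocktad"))
  min_gap <- config$min_gap %||% 1500
  cfg <- do.call(caller_config, config$caller %||% list())
  genome <- if (!is.null(config$genome)) read_genome_table(config$genome)
            else yeast_genome()

  ## ---- inputs -----------------------------------------------------------
  if (!is.null(config$simulate)) {
    if (is.null(config$seed))
      stop("a seed is required when simulating", call. = FALSE)
    sim_cfg <- config$simulate
    n_meioses <- sim_cfg$n_meioses %||% 1L
    sim_cfg$n_meioses <- NULL
    params <- do.call(sim_params, sim_cfg)
    map <- generate_marker_map(genome, seed = config$seed)
    strands_per_meiosis <- vector("list", n_meioses)
    truths <- vector("list", n_meioses)
    for (m in seq_len(n_meioses)) {
      sim <- simulate_meiosis(map, genome, params, seed = config$seed + m)
      strands_per_meiosis[[m]] <- sim$strands
      truths[[m]] <- sim$truth
    }
    message(sprintf("[simulate] %d meioses over %d markers", n_meioses, nrow(map)))
  } else {
    map <- read_marker_map(config$marker_map)
    counts <- read_site_counts(config$site_counts)
    sheet <- read_sample_sheet(config$sample_sheet, mode)
    calls <- call_genotypes_table(counts, map, cfg)
    meiosis_ids <- unique(sheet$meiosis)
    strands_per_meiosis <- vector("list", length(meiosis_ids))
    for (m in seq_along(meiosis_ids)) {
      sub <- sheet[sheet$meiosis == meiosis_ids[m], , drop = FALSE]
      main <- sub[sub$role != "colony", , drop = FALSE]
      main <- main[order(main$spore, main$role == "daughter"), , drop = FALSE]
      strands_per_meiosis[[m]] <- switch(mode,
        octad = {
          ord <- order(main$spore, match(main$role, c("mother", "daughter")))
          assemble_octad(calls, main$sample[ord], map)
        },
        tetrad = assemble_tetrad(calls, main$sample[order(main$spore)], map),
        mocktad = {
          mt <- build_mocktad(calls, main$sample[order(main$spore)], map, cfg)
          cols <- sub[sub$role == "colony", , drop = FALSE]
          for (ci in seq_len(nrow(cols))) {
            ccalls <- calls[calls$sample == cols$sample[ci], , drop = FALSE]
            mt <- phase_with_colony(mt, ccalls, cols$spore[ci])
          }
          mt
        })
    }
    truths <- NULL
    message(sprintf("[genotype] %d meioses, %d markers", length(meiosis_ids),
                    nrow(map)))
  }

  ## ---- events and classification ---------------------------------------
  tetrad_mode <- mode == "tetrad"
  meioses <- lapply(strands_per_meiosis, function(strands) {
    ev <- call_events_meiosis(strands, min_gap = min_gap)
    lapply(ev, classify_events, tetrad_mode = tetrad_mode)
  })
  n_ev <- sum(vapply(meioses, function(m) sum(vapply(m, nrow, 0L)), 0))
  message(sprintf("[events] %d events called", n_ev))

  qc <- qc_filter(meioses, strands_per_meiosis)
  meioses <- qc$events
  message(sprintf("[qc] %d removals, %d premeiotic-suspect meioses",
                  sum(qc$report$n), sum(qc$premeiotic_suspect)))

  events <- combine_events(meioses)
  if (!is.null(config$hotspots)) {
    hs <- read_hotspots(config$hotspots)
    flags <- unlist(lapply(meioses, function(m) lapply(m, hotspot_overlap, hs)))
    events$hotspot_overlap <- if (nrow(events)) as.logical(flags) else logical(0)
  } else {
    events$hotspot_overlap <- NA
  }

  summaries <- lapply(seq_along(meioses), function(m)
    summarize_meiosis(meioses[[m]], genome, meiosis_id = m,
                      genotype = config$genotype %||% "unknown"))
  summary_df <- do.call(rbind, lapply(summaries, `[[`, "summary"))
  summary_df$premeiotic_suspect <- qc$premeiotic_suspect
  icd_df <- do.call(rbind, lapply(seq_along(summaries), function(m) {
    ic <- summaries[[m]]$icds
    if (!length(ic)) return(NULL)
    data.frame(meiosis = m, icd = ic)
  }))

  ## ---- outputs ----------------------------------------------------------
  paths <- list(
    events = file.path(out_dir, "events.tsv"),
    events_bed = file.path(out_dir, "events.bed"),
    summary = file.path(out_dir, "summary.tsv"),
    icds = file.path(out_dir, "icds.tsv"),
    qc = file.path(out_dir, "qc_report.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_tsv(events, paths$events)
  if (nrow(events)) write_events_bed(events, paths$events_bed)
  write_tsv(summary_df, paths$summary)
  write_tsv(icd_df %||% data.frame(meiosis = integer(0), icd = numeric(0)),
            paths$icds)
  write_tsv(qc$report, paths$qc)
  manifest <- list(
    package = "meiorec",
    version = as.character(utils::packageVersion("meiorec")),
    seed = config$seed,
    mode = mode, min_gap = min_gap,
    n_meioses = length(meioses), n_events = nrow(events),
    config_hash = config_hash(config),
    elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(truths)) {
    truth_df <- do.call(rbind, lapply(seq_along(truths), function(m) {
      t <- truths[[m]]; if (nrow(t)) t$meiosis <- m; t
    }))
    paths$truth <- file.path(out_dir, "truth.tsv")
    write_tsv(truth_df, paths$truth)
  }
  invisible(list(events = events, summaries = summaries, qc = qc,
                 meioses = meioses, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Stable hash of the configuration (md5 of its serialisation).
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2)
  unname(tools::md5sum(f))
}
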