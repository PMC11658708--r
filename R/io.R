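## TSV helpers: plain tab-separated text, gzip-tolerant on read.
read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " file ", path, " is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read / write a marker map
#'
#' TSV with columns `chrom`, `pos` (1-based), `allele_A`, `allele_B`,
#' `kind` (`SNP`/`insertion`/`deletion`); gzip-tolerant.
#'
#' @param path File path.
#' @return A `marker_map` data frame.
#' @export
read_marker_map <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "pos", "allele_A", "allele_B", "kind"),
                         "marker map")
  df$chrom <- as.character(df$chrom)
  class(df) <- c("marker_map", "data.frame")
  validate_marker_map(df)
  df
}

#' @rdname read_marker_map
#' @param map A `marker_map`.
#' @export
write_marker_map <- function(map, path) {
  validate_marker_map(map)
  write_tsv(as.data.frame(map), path)
}

#' Read / write a site-counts table
#'
#' TSV with columns `sample`, `chrom`, `pos`, `n_ref`, `n_var`, `n_other`,
#' `depth`.
#'
#' @param path File path.
#' @return A `site_counts` data frame.
#' @export
read_site_counts <- function(path) {
  df <- read_tsv_checked(path, c("sample", "chrom", "pos", "n_ref", "n_var",
                                 "n_other", "depth"), "site counts")
  if (any(df$n_ref < 0 | df$n_var < 0 | df$depth < 0))
    stop("negative counts in ", path, call. = FALSE)
  bad <- which(df$n_ref + df$n_var > df$depth)
  if (length(bad))
    stop("ref+var exceed depth at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), " of ", path,
         call. = FALSE)
  class(df) <- c("site_counts", "data.frame")
  df
}

#' @rdname read_site_counts
#' @param counts A `site_counts` data frame.
#' @export
write_site_counts <- function(counts, path) {
  write_tsv(as.data.frame(counts), path)
}

#' Read a genome table
#'
#' TSV with columns `chrom`, `length`, `cen`.
#'
#' @param path File path.
#' @return A [genome_model()].
#' @export
read_genome_table <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "length", "cen"), "genome table")
  genome_model(df$length, df$cen, df$chrom)
}

#' @rdname read_genome_table
#' @param genome A `genome_model`.
#' @export
write_genome_table <- function(genome, path) {
  write_tsv(as.data.frame(genome)[c("chrom", "length", "cen")], path)
}

#' Read a sample sheet
#'
#' TSV with columns `meiosis`, `sample`, `spore` (1-4) and `role`
#' (`mother`/`daughter` for octads, `spore` for tetrads and mocktads,
#' `colony` for resequenced phasing colonies).  Octad meioses must have
#' exactly 8 mother/daughter samples, tetrad/mocktad meioses exactly 4
#' spore samples.
#'
#' @param path File path.
#' @param mode `"octad"`, `"tetrad"` or `"mocktad"`.
#' @return The validated sample-sheet data frame.
#' @export
read_sample_sheet <- function(path, mode = c("octad", "tetrad", "mocktad")) {
  mode <- match.arg(mode)
  df <- read_tsv_checked(path, c("meiosis", "sample", "spore", "role"),
                         "sample sheet")
  for (m in unique(df$meiosis)) {
    sub <- df[df$meiosis == m & df$role != "colony", , drop = FALSE]
    if (mode == "octad") {
      if (nrow(sub) != 8)
        stop("meiosis ", m, ": octad mode requires 8 samples, found ",
             nrow(sub), call. = FALSE)
      if (!all(sort(paste(sub$spore, sub$role)) ==
               sort(paste(rep(1:4, each = 2), c("mother", "daughter")))))
        stop("meiosis ", m, ": octad sheet must pair mother/daughter for ",
             "spores 1-4", call. = FALSE)
    } else {
      if (nrow(sub) != 4)
        stop("meiosis ", m, ": ", mode, " mode requires 4 samples, found ",
             nrow(sub), call. = FALSE)
      if (!setequal(sub$spore, 1:4))
        stop("meiosis ", m, ": spores must be numbered 1-4", call. = FALSE)
    }
  }
  df
}

#' Read a DSB-hotspot track from BED
#'
#' BED intervals are half-open and 0-based on disk; internally they are
#' kept half-open with 1-based starts, i.e. BED `(0, 100)` becomes
#' `[1, 101)` covering bases 1-100.  Requires the rtracklayer package.
#'
#' @param path BED file path.
#' @return A `hotspot_track` data frame: `chrom`, `start`, `end`
#'   (half-open), sorted within chromosome.
#' @export
read_hotspots <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading BED hotspot tracks requires the rtracklayer package",
         call. = FALSE)
  gr <- rtracklayer::import(path, format = "BED")
  hotspot_track(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr) + 1L
  )
}

#' Construct a hotspot track
#'
#' @param chrom,start,end Interval columns; `[start, end)` half-open,
#'   1-based starts, `start < end`.
#' @return A sorted `hotspot_track` data frame.
#' @export
hotspot_track <- function(chrom, start, end) {
  if (any(end <= start))
    stop("hotspot intervals must satisfy start < end", call. = FALSE)
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("hotspot_track", "data.frame")
  df
}

#' Export event spans as BED
#'
#' Internal 1-based inclusive spans become 0-based half-open BED intervals.
#'
#' @param events A combined event data frame with `chrom`, `start`, `end`
#'   columns (e.g. from [combine_events()]).
#' @param path Output path.
#' @export
write_events_bed <- function(events, path) {
  bed <- data.frame(chrom = events$chrom,
                    start = as.integer(floor(events$start)) - 1L,
                    end = as.integer(ceiling(events$end)),
                    name = if ("event_id" %in% names(events)) events$event_id
                           else seq_len(nrow(events)))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Flatten per-chromosome event tables into one data frame
#'
#' @param events_by_chrom Named list of `event_table`s (one meiosis) or a
#'   list of such lists; a `meiosis` column is added in the latter case.
#' @return A plain data frame with one row per event.
#' @export
combine_events <- function(events_by_chrom) {
  single <- length(events_by_chrom) &&
    inherits(events_by_chrom[[1]], "event_table")
  if (single) events_by_chrom <- list(events_by_chrom)
  out <- list()
  for (m in seq_along(events_by_chrom)) {
    for (chr in names(events_by_chrom[[m]])) {
      ev <- as.data.frame(events_by_chrom[[m]][[chr]])
      if (!nrow(ev)) next
      ev$meiosis <- m
      out[[length(out) + 1]] <- ev
    }
  }
  if (!length(out)) {
    ev <- as.data.frame(empty_event_table())
    ev$meiosis <- integer(0)
    return(ev)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (single) out$meiosis <- NULL
  out$event_id <- seq_len(nrow(out))
  out
}
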