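#' Group segments into recombination events
#'
#' Non-Mendelian segments (and crossover breakpoints between Mendelian
#' segments of different chromatid arrangement) are grouped into one
#' recombination event unless separated by at least `min_gap` bp of
#' Mendelian 4:4 segregation, measured between the outermost non-Mendelian
#' markers of the neighbouring groups.  Groups running into a chromosome
#' end without returning to 4:4 are type "U" and are excluded from CO/NCO
#' tallies.
#'
#' For each non-U event, chromatid parental identities are read from the
#' flanking Mendelian segments; the CO count is the number of chromatids
#' whose identity differs between the flanks divided by two, and chromatids
#' with internal non-Mendelian calls but unchanged flanks contribute NCO
#' involvement.  An odd number of switching chromatids marks the event
#' complex/irregular (CO count reported as the largest even fit, with a
#' warning).
#'
#' @param segs A `seg_table` from [segment_chromosome()].
#' @param sm The [strand_matrix()] the segments were derived from.
#' @param min_gap Minimum bp of Mendelian segregation separating two events
#'   (default 1500; a gap of exactly `min_gap` separates).
#' @return A data frame of class `event_table`, one row per event:
#'   `chrom`, `start`, `end` (bp span of the non-Mendelian markers; for a
#'   clean crossover with no strand transfer, the breakpoint midpoint),
#'   `n_markers`, `type_U`, `co_count`, `nco_count`, `complex`,
#'   `chromatids`, `co_chromatids`, `pattern`, `clean_bp`.  The per-event
#'   analysis needed by the classifiers is kept in `attr(, "detail")`;
#'   retained marker positions in `attr(, "pos")`.
#' @export
call_events <- function(segs, sm, min_gap = 1500) {
  pos <- attr(segs, "pos")
  col_idx <- attr(segs, "col_idx")
  Gk <- if (length(col_idx)) unclass(sm)[, col_idx, drop = FALSE] else
    matrix(integer(0), 8, 0)
  ## ---- anchors ----------------------------------------------------------
  anch <- list()
  if (nrow(segs)) {
    for (r in which(!segs$mendelian)) {
      anch[[length(anch) + 1]] <- list(
        type = "seg", row1 = r, row2 = r,
        first_pos = segs$start_pos[r], last_pos = segs$end_pos[r],
        ki1 = segs$first[r], ki2 = segs$last[r])
    }
    if (nrow(segs) > 1) {
      for (r in seq_len(nrow(segs) - 1)) {
        if (segs$mendelian[r] && segs$mendelian[r + 1]) {
          mid <- (segs$end_pos[r] + segs$start_pos[r + 1]) / 2
          anch[[length(anch) + 1]] <- list(
            type = "bp", row1 = r + 1L, row2 = r,   # empty segment range
            first_pos = mid, last_pos = mid,
            ki1 = segs$first[r + 1], ki2 = segs$last[r])
        }
      }
    }
  }
  empty <- empty_event_table()
  attr(empty, "pos") <- pos
  attr(empty, "chrom") <- attr(segs, "chrom")
  if (!length(anch)) return(empty)
  o <- order(vapply(anch, `[[`, 0, "first_pos"))
  anch <- anch[o]
  ## ---- cluster anchors by the Mendelian-gap rule ------------------------
  ## two anchors are separate events only when a Mendelian segment lies
  ## between them *and* the gap between their outermost non-Mendelian
  ## markers reaches min_gap; marker-adjacent non-Mendelian segments always
  ## share an event (breakpoint anchors are Mendelian-flanked by
  ## construction)
  n <- length(anch)
  grp <- integer(n); grp[1] <- 1L
  if (n > 1) for (i in 2:n) {
    p <- anch[[i - 1]]; cur <- anch[[i]]
    gap <- cur$first_pos - p$last_pos
    mend_between <- !(p$type == "seg" && cur$type == "seg" &&
                        cur$row1 == p$row2 + 1L)
    grp[i] <- if (gap >= min_gap && mend_between) grp[i - 1] + 1L else grp[i - 1]
  }
  rows_out <- list(); details <- list()
  for (g in unique(grp)) {
    members <- anch[grp == g]
    r1 <- min(vapply(members, `[[`, 0L, "row1"))
    r2 <- max(vapply(members, `[[`, 0L, "row2"))
    is_seg <- vapply(members, function(a) a$type == "seg", TRUE)
    clean_bp <- !any(is_seg)
    ## span of anomalous markers (seg anchors only)
    if (any(is_seg)) {
      ki1 <- min(vapply(members[is_seg], `[[`, 0L, "ki1"))
      ki2 <- max(vapply(members[is_seg], `[[`, 0L, "ki2"))
      start <- pos[ki1]; end <- pos[ki2]
      n_markers <- ki2 - ki1 + 1L
    } else {
      ki1 <- ki2 <- NA_integer_
      start <- min(vapply(members, `[[`, 0, "first_pos"))
      end <- max(vapply(members, `[[`, 0, "last_pos"))
      n_markers <- 0L
    }
    type_U <- FALSE
    ## flanking Mendelian segments: immediately left/right of the outermost
    ## anchors (for a breakpoint anchor the flank is one of its two sides)
    lf <- min(vapply(members, function(a)
      if (a$type == "seg") a$row1 - 1L else a$row2, 0L))
    rf <- max(vapply(members, function(a)
      if (a$type == "seg") a$row2 + 1L else a$row1, 0L))
    if (lf < 1 || !segs$mendelian[lf]) { type_U <- TRUE; lf <- NA_integer_ }
    if (rf > nrow(segs) || !segs$mendelian[rf]) {
      type_U <- TRUE; rf <- NA_integer_
    }
    det <- list(r1 = r1, r2 = r2, ki1 = ki1, ki2 = ki2,
                left_flank = lf, right_flank = rf, clean_bp = clean_bp)
    co_count <- NA_integer_; nco_count <- NA_integer_
    complex <- FALSE
    chromatids <- ""; co_chromatids <- ""
    if (!type_U) {
      id_l <- chromatid_ids(segs$vec[lf])
      id_r <- chromatid_ids(segs$vec[rf])
      switch_k <- which(id_l != id_r)
      if (length(switch_k) %% 2L == 1L) {
        complex <- TRUE
        warning("event with an odd number of switching chromatids on ",
                attr(segs, "chrom"), " near ", round(start),
                "; CO count set to the largest even fit", call. = FALSE)
      }
      co_count <- length(switch_k) %/% 2L
      ## involvement: any strand call differing from the flank identity
      nco_k <- integer(0)
      if (!is.na(ki1) && ki2 >= ki1) {
        scan1 <- ki1; scan2 <- ki2
        for (k in setdiff(1:4, switch_k)) {
          block <- Gk[chromatid_rows(k), scan1:scan2, drop = FALSE]
          if (any(block != id_l[k])) nco_k <- c(nco_k, k)
        }
      }
      involved <- sort(c(switch_k, nco_k))
      nco_count <- length(nco_k)
      if (nco_count > 2) complex <- TRUE
      chromatids <- paste(involved, collapse = ",")
      co_chromatids <- paste(switch_k, collapse = ",")
      det$id_left <- id_l; det$id_right <- id_r
      det$switchers <- switch_k; det$nco_chromatids <- nco_k
    }
    pattern <- paste(segs$pattern[min(r1, r2):max(r1, r2)], collapse = "|")
    rows_out[[length(rows_out) + 1]] <- data.frame(
      chrom = attr(segs, "chrom"), start = start, end = end,
      first_idx = if (!is.na(ki1)) col_idx[ki1] else NA_integer_,
      last_idx = if (!is.na(ki2)) col_idx[ki2] else NA_integer_,
      n_markers = n_markers, type_U = type_U,
      co_count = co_count, nco_count = nco_count, complex = complex,
      chromatids = chromatids, co_chromatids = co_chromatids,
      pattern = pattern, clean_bp = clean_bp, stringsAsFactors = FALSE
    )
    details[[length(details) + 1]] <- det
  }
  out <- do.call(rbind, rows_out)
  rownames(out) <- NULL
  attr(out, "detail") <- details
  attr(out, "pos") <- pos
  attr(out, "segs") <- segs
  attr(out, "Gk") <- Gk
  attr(out, "chrom") <- attr(segs, "chrom")
  attr(out, "polarity_unknown") <- attr(sm, "polarity_unknown")
  class(out) <- c("event_table", "data.frame")
  out
}

empty_event_table <- function() {
  out <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                    first_idx = integer(0), last_idx = integer(0),
                    n_markers = integer(0), type_U = logical(0),
                    co_count = integer(0), nco_count = integer(0),
                    complex = logical(0), chromatids = character(0),
                    co_chromatids = character(0), pattern = character(0),
                    clean_bp = logical(0), stringsAsFactors = FALSE)
  attr(out, "detail") <- list()
  class(out) <- c("event_table", "data.frame")
  out
}

## Chromatid identities (length 4) from a concordant strand-vector string.
chromatid_ids <- function(vec) {
  v <- as.integer(strsplit(vec, "")[[1]])
  id <- v[c(1, 3, 5, 7)]
  stopifnot(all(id == v[c(2, 4, 6, 8)]))
  id
}

#' Segment and call events for every chromosome of a meiosis
#'
#' Convenience wrapper running [segment_chromosome()] and [call_events()]
#' over a named list of strand matrices.
#'
#' @param strands Named list of [strand_matrix()] objects.
#' @param min_gap Passed to [call_events()].
#' @return Named list of `event_table`s.
#' @export
call_events_meiosis <- function(strands, min_gap = 1500) {
  lapply(strands, function(sm) call_events(segment_chromosome(sm), sm,
                                           min_gap = min_gap))
}
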