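## Per-marker pair state codes for one chromatid over a set of columns:
## 0 = both strands parent-B, 1 = both strands parent-A, 2 = discordant
## (heteroduplex).
pair_states <- function(Gk, k, j) {
  m <- Gk[2L * k - 1L, j]
  d <- Gk[2L * k, j]
  ifelse(m != d, 2L, m)
}

## Maximal runs of TRUE in a logical vector -> data.frame(i1, i2) of indices.
runs_of <- function(x) {
  r <- rle(x)
  last <- cumsum(r$lengths)
  first <- last - r$lengths + 1L
  data.frame(i1 = first[r$values], i2 = last[r$values])
}

#' Classify the events of one chromosome
#'
#' Adds the category systems to an event table:
#'
#' * `multi_class`: conservative multi-DSB class.  `dCO` requires a double
#'   reciprocal exchange affecting all four chromatids; `CO_plus_NCO` a
#'   crossover plus a conversion on a third chromatid; `dNCO_sister` two
#'   conversion tracts on sister chromatids; `dNCO_overlap` tracts on two
#'   homologues with perfect overlap (identical first and last converted
#'   marker).  Everything else is `"none"`.
#' * `trans_dsb`: `TRUE` when the event contains an 8:0/0:8 or 7:1/1:7
#'   segment (for 8:0, only when adjacent within the event to a
#'   heteroduplex-bearing segment); `NA` in tetrad mode, where such
#'   patterns cannot be observed.
#' * `nco_class` (events with NCOs and no CO): `full_conversion`,
#'   `one_sided`, `one_sided_patch`, `two_sided_trans`,
#'   `two_sided_restoration`, `two_chromatid`, or `NA` when the
#'   distinction needs strand polarity that an unphased spore lacks
#'   (`nco_assessable = FALSE`).
#' * `co_class` (single-CO events without extra conversions):
#'   `no_strand_transfer`, `full_conversion`,
#'   `one_sided_unidirectional`, `one_sided_bidirectional`,
#'   `two_sided_unidirectional`, `two_sided_bidirectional`,
#'   `symmetric_hDNA`.
#' * `qc_no_flanking_hdna_8_0`: the event contains an 8:0 segment with no
#'   adjacent heteroduplex, the signature of a premeiotic (mitotic) event.
#'
#' @param events An `event_table` from [call_events()].
#' @param tetrad_mode `TRUE` for MMR-proficient tetrads, where strand-level
#'   patterns (5:3, 7:1, 8:0-with-hDNA) cannot be observed.
#' @return The event table with classification columns appended.
#' @export
classify_events <- function(events, tetrad_mode = FALSE) {
  det <- attr(events, "detail")
  segs <- attr(events, "segs")
  Gk <- attr(events, "Gk")
  pu <- attr(events, "polarity_unknown")
  if (is.null(pu)) pu <- rep(FALSE, 4)
  n <- nrow(events)
  events$multi_class <- rep("none", n)
  events$trans_dsb <- rep(if (tetrad_mode) NA else FALSE, n)
  events$nco_class <- rep(NA_character_, n)
  events$nco_assessable <- rep(TRUE, n)
  events$co_class <- rep(NA_character_, n)
  events$qc_no_flanking_hdna_8_0 <- rep(FALSE, n)
  if (!n) return(events)
  for (i in seq_len(n)) {
    d <- det[[i]]
    if (events$type_U[i]) next
    tr <- trans_dsb_flags(events, d, segs, tetrad_mode)
    events$trans_dsb[i] <- tr$flag
    events$qc_no_flanking_hdna_8_0[i] <- tr$qc
    events$multi_class[i] <- classify_multi_dsb_one(events[i, ], d, Gk)
    if (!events$complex[i] && events$co_count[i] == 0 &&
        events$nco_count[i] >= 1 &&
        events$multi_class[i] %in% c("none")) {
      cl <- classify_nco_one(d, Gk, pu)
      events$nco_class[i] <- cl$class
      events$nco_assessable[i] <- cl$assessable
    }
    if (!events$complex[i] && events$co_count[i] == 1 &&
        events$nco_count[i] == 0) {
      events$co_class[i] <- classify_co_one(d, Gk)
    }
  }
  events
}

## ---- multi-DSB ----------------------------------------------------------
classify_multi_dsb_one <- function(ev, d, Gk) {
  if (ev$complex) return("none")
  sw <- d$switchers
  if (ev$co_count == 2 && length(sw) == 4) return("dCO")
  if (ev$co_count == 1 && ev$nco_count >= 1) return("CO_plus_NCO")
  if (ev$co_count == 0 && ev$nco_count == 2) {
    ks <- d$nco_chromatids
    if (d$id_left[ks[1]] == d$id_left[ks[2]]) return("dNCO_sister")
    ## homologues: perfect overlap = identical first and last converted marker
    r1 <- anomalous_range(Gk, ks[1], d)
    r2 <- anomalous_range(Gk, ks[2], d)
    if (!is.null(r1) && !is.null(r2) && identical(r1, r2))
      return("dNCO_overlap")
  }
  "none"
}

anomalous_range <- function(Gk, k, d) {
  if (is.na(d$ki1)) return(NULL)
  j <- d$ki1:d$ki2
  st <- pair_states(Gk, k, j)
  bad <- which(st != d$id_left[k])
  if (!length(bad)) return(NULL)
  c(min(bad), max(bad))
}

## ---- trans-DSB (8:0 / 7:1) ---------------------------------------------
trans_dsb_flags <- function(events, d, segs, tetrad_mode) {
  if (tetrad_mode) return(list(flag = NA, qc = FALSE))
  rows <- min(d$r1, d$r2):max(d$r1, d$r2)
  pat <- segs$pattern[rows]
  has_71 <- any(pat %in% c("7:1", "1:7"))
  rows80 <- rows[segs$countA[rows] %in% c(0L, 8L)]
  flag <- has_71
  qc <- FALSE
  if (length(rows80)) {
    hdna <- segs$star[rows] | segs$countA[rows] %% 2L == 1L
    ok80 <- vapply(rows80, function(r) {
      nb <- intersect(c(r - 1L, r + 1L), rows)
      any(hdna[match(nb, rows)])
    }, TRUE)
    if (any(ok80)) flag <- TRUE
    if (any(!ok80)) qc <- TRUE
  }
  list(flag = flag, qc = qc)
}

## ---- NCO subclasses -----------------------------------------------------
classify_nco_one <- function(d, Gk, pu) {
  ks <- d$nco_chromatids
  if (length(ks) == 2) {
    ## non-sister, non-perfect-overlap pairs reach here
    return(list(class = "two_chromatid", assessable = TRUE))
  }
  k <- ks[1]
  j <- d$ki1:d$ki2
  st <- pair_states(Gk, k, j)
  bg <- d$id_left[k]
  anom <- st != bg
  rr <- runs_of(anom)
  if (nrow(rr) >= 2)
    return(list(class = "two_sided_restoration", assessable = TRUE))
  sts <- st[rr$i1[1]:rr$i2[1]]
  has_h <- any(sts == 2L)
  has_conv <- any(sts == 1L - bg)
  if (!has_h) return(list(class = "full_conversion", assessable = TRUE))
  if (has_conv) return(list(class = "one_sided_patch", assessable = TRUE))
  spore_unphased <- pu[k]
  if (spore_unphased)
    return(list(class = NA_character_, assessable = FALSE))
  ## polarity of each heteroduplex marker: which strand carries the donor
  jj <- j[rr$i1[1]:rr$i2[1]]
  donor_on_daughter <- Gk[2L * k, jj] != bg
  if (length(unique(donor_on_daughter)) > 1)
    return(list(class = "two_sided_trans", assessable = TRUE))
  list(class = "one_sided", assessable = TRUE)
}

## ---- CO subclasses ------------------------------------------------------
## The exchange point is estimated, in event-local marker-index space, from
## the two recombining chromatids: for each, the boundary after its initial
## left-background run and before its terminal right-background run; the
## exchange estimate is the midpoint of max(first boundaries) and
## min(last boundaries).  Transferred markers are those inconsistent with
## the background expected on their side of the exchange (heteroduplex
## markers always; concordant markers when they show the wrong parent for
## their side).  Sidedness comes from the transferred runs' positions, and
## directionality from the set of donor alleles (the allele foreign to the
## local background); ties at the exchange point resolve to "left", which
## only matters for runs symmetric about it.
classify_co_one <- function(d, Gk) {
  sw <- d$switchers
  if (length(sw) != 2) return(NA_character_)
  if (is.na(d$ki1)) return("no_strand_transfer")
  j <- d$ki1:d$ki2
  stA <- pair_states(Gk, sw[1], j)
  stB <- pair_states(Gk, sw[2], j)
  if (any(stA == 2L & stB == 2L)) return("symmetric_hDNA")
  st <- list(stA, stB)
  m <- length(j)
  bounds <- lapply(seq_along(sw), function(a) {
    k <- sw[a]; s <- st[[a]]
    bl <- d$id_left[k]; br <- d$id_right[k]
    L0 <- 0L
    while (L0 < m && s[L0 + 1L] == bl) L0 <- L0 + 1L
    L1 <- 0L
    while (L1 < m && s[m - L1] == br) L1 <- L1 + 1L
    c(first_b = 0.5 + L0, last_b = m + 0.5 - L1)
  })
  x0 <- (max(vapply(bounds, `[[`, 0, "first_b")) +
           min(vapply(bounds, `[[`, 0, "last_b"))) / 2
  idx <- seq_len(m)
  anom <- lapply(seq_along(sw), function(a) {
    k <- sw[a]; s <- st[[a]]
    side_bg <- ifelse(idx < x0, d$id_left[k], d$id_right[k])
    s == 2L | s != side_bg
  })
  if (!any(st[[1]] == 2L | st[[2]] == 2L)) {
    if (any(unlist(anom))) return("full_conversion")
    return("no_strand_transfer")
  }
  sides <- character(0); donors <- integer(0)
  for (a in seq_along(sw)) {
    k <- sw[a]
    rr <- runs_of(anom[[a]])
    for (r in seq_len(nrow(rr))) {
      i1 <- rr$i1[r]; i2 <- rr$i2[r]
      side <- if (i2 < x0) "left"
              else if (i1 > x0) "right"
              else if ((x0 - (i1 - 0.5)) >= ((i2 + 0.5) - x0)) "left"
              else "right"
      bg <- if (side == "left") d$id_left[k] else d$id_right[k]
      sides <- c(sides, side)
      donors <- c(donors, 1L - bg)
    }
  }
  sided <- if (length(unique(sides)) > 1) "two_sided" else "one_sided"
  dir <- if (length(unique(donors)) > 1) "bidirectional" else "unidirectional"
  paste(sided, dir, sep = "_")
}

#' Flag events overlapping DSB hotspots
#'
#' For each event, the maximum possible event region extends from the
#' nearest flanking Mendelian marker on the left to the nearest on the
#' right; the event has hotspot overlap when any hotspot interval
#' intersects this region.  Intervals are treated as half-open
#' (`[start, end)`), so a hotspot ending exactly at the region start does
#' not overlap.
#'
#' @param events An `event_table`.
#' @param hotspots A `hotspot_track` data frame (see [read_hotspots()]):
#'   columns `chrom`, `start`, `end` with half-open 1-based intervals,
#'   sorted within chromosome.
#' @return Logical vector, one flag per event.
#' @export
hotspot_overlap <- function(events, hotspots) {
  n <- nrow(events)
  if (!n) return(logical(0))
  if (is.null(hotspots) || !nrow(hotspots)) {
    warning("empty hotspot track: no event overlaps any hotspot")
    return(rep(FALSE, n))
  }
  pos <- attr(events, "pos")
  det <- attr(events, "detail")
  out <- logical(n)
  for (i in seq_len(n)) {
    d <- det[[i]]
    if (is.na(d$ki1)) {
      span <- c(events$start[i], events$end[i])
    } else {
      lo <- if (d$ki1 > 1) pos[d$ki1 - 1] else pos[d$ki1]
      hi <- if (d$ki2 < length(pos)) pos[d$ki2 + 1] else pos[d$ki2]
      span <- c(lo, hi)
    }
    hs <- hotspots[hotspots$chrom == events$chrom[i], , drop = FALSE]
    out[i] <- any(hs$start < span[2] & span[1] < hs$end)
  }
  out
}

#' Quality-control filter across meioses
#'
#' Removes event patterns whose most plausible origin is premeiotic
#' (mitotic) rather than meiotic:
#'
#' * events whose only non-Mendelian content is an 8:0 segment with no
#'   adjacent heteroduplex are dropped;
#' * 8:0-bearing events recurring at the same marker interval in more than
#'   one meiosis are dropped from all of them (presumed marker-table
#'   errors);
#' * meioses with a chromosome-scale 8:0 block (> `max_80_block` bp) or a
#'   whole-chromosome heteroduplex pattern in exactly two spores (disomy
#'   signature) are flagged `premeiotic_suspect`; such meioses should be
#'   excluded from count statistics but may still contribute tract lengths.
#'
#' @param meioses A list; each element is a named list of classified
#'   `event_table`s (one per chromosome) for one meiosis.
#' @param strands_list Optional list (parallel to `meioses`) of the strand
#'   matrices, used for the disomy check on mocktads.
#' @param max_80_block Size threshold (bp) for chromosome-scale 8:0 blocks.
#' @param het_chrom_fraction Fraction of a chromosome's markers
#'   heteroduplex in exactly two spores that triggers the disomy flag.
#' @return A list: `events` (the filtered per-meiosis lists, with a
#'   `qc_recurrent_locus` column added), `premeiotic_suspect` (logical per
#'   meiosis), `report` (data frame of removals).
#' @export
qc_filter <- function(meioses, strands_list = NULL, max_80_block = 1e5,
                      het_chrom_fraction = 0.8) {
  report <- list()
  ## --- collect 8:0 loci (marker-index identity) across meioses ----------
  loci <- list()
  for (m in seq_along(meioses)) {
    for (chr in names(meioses[[m]])) {
      ev <- meioses[[m]][[chr]]
      if (!nrow(ev)) next
      has80 <- grepl("(^|\\|)(8:0|0:8)(\\||$)", ev$pattern)
      for (i in which(has80)) {
        loci[[length(loci) + 1]] <- data.frame(
          meiosis = m, chrom = chr, i = i,
          key = paste(chr, ev$first_idx[i], ev$last_idx[i]),
          stringsAsFactors = FALSE)
      }
    }
  }
  loci <- if (length(loci)) do.call(rbind, loci) else
    data.frame(meiosis = integer(0), chrom = character(0), i = integer(0),
               key = character(0))
  recurrent <- names(which(table(unique(loci[c("meiosis", "key")])$key) > 1))
  premeiotic <- rep(FALSE, length(meioses))
  for (m in seq_along(meioses)) {
    for (chr in names(meioses[[m]])) {
      ev <- meioses[[m]][[chr]]
      if (!nrow(ev)) next
      ev$qc_recurrent_locus <-
        paste(chr, ev$first_idx, ev$last_idx) %in% recurrent
      drop <- rep(FALSE, nrow(ev))
      ## isolated 8:0 without adjacent hDNA
      if ("qc_no_flanking_hdna_8_0" %in% names(ev)) {
        only80 <- ev$qc_no_flanking_hdna_8_0 &
          !grepl("[57]:3|3:5|1:7|7:1|\\*", ev$pattern)
        drop <- drop | only80
        if (any(only80)) report[[length(report) + 1]] <- data.frame(
          meiosis = m, chrom = chr, n = sum(only80),
          reason = "8:0 without adjacent hDNA", stringsAsFactors = FALSE)
      }
      drop <- drop | ev$qc_recurrent_locus
      if (any(ev$qc_recurrent_locus)) report[[length(report) + 1]] <- data.frame(
        meiosis = m, chrom = chr, n = sum(ev$qc_recurrent_locus),
        reason = "recurrent 8:0 locus", stringsAsFactors = FALSE)
      ## chromosome-scale 8:0 block
      big80 <- grepl("(^|\\|)(8:0|0:8)(\\||$)", ev$pattern) &
        (ev$end - ev$start) > max_80_block
      if (any(big80)) premeiotic[m] <- TRUE
      keep <- ev[!drop, , drop = FALSE]
      for (a in c("detail")) {
        attr(keep, a) <- attr(ev, a)[!drop]
      }
      for (a in c("pos", "segs", "Gk", "chrom", "polarity_unknown")) {
        attr(keep, a) <- attr(ev, a)
      }
      class(keep) <- class(ev)
      meioses[[m]][[chr]] <- keep
    }
    ## disomy signature on mocktads
    if (!is.null(strands_list)) {
      for (chr in names(strands_list[[m]])) {
        sm <- strands_list[[m]][[chr]]
        hx <- attr(sm, "het_idx")
        if (is.null(hx) || ncol(sm) == 0) next
        frac <- lengths(hx) / ncol(sm)
        if (sum(frac > het_chrom_fraction) == 2) premeiotic[m] <- TRUE
      }
    }
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(meiosis = integer(0), chrom = character(0), n = integer(0),
               reason = character(0))
  list(events = meioses, premeiotic_suspect = premeiotic, report = report)
}
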