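#' Classify one marker column into a segregation pattern
#'
#' The pattern is the ratio of parent-A to parent-B calls over the 8
#' strands (`"4:4"`, `"5:3"`, `"6:2"`, `"7:1"`, `"8:0"` and reciprocals).  A
#' star marks aberrant arrangements: any even-count column in which at
#' least one mother/daughter strand pair is discordant (heteroduplex), e.g.
#' `"6:2*"` (trans half-conversions), `"4:4*"` (symmetric hDNA), and — when
#' a parental configuration is supplied — a concordant 4:4 column whose
#' chromatid arrangement differs from it.  Odd-count patterns are never
#' starred.
#'
#' @param g Integer vector of 8 genotype calls (0/1, no `NA`), ordered as
#'   mother/daughter pairs.
#' @param parental Optional 8-vector giving the local parental
#'   configuration against which a concordant 4:4 is judged Mendelian;
#'   `NULL` (the default) accepts any concordant 4:4 arrangement, leaving
#'   crossover breakpoints to be read from arrangement changes between
#'   segments.
#' @return A list: `pattern` (e.g. `"5:3"`), `countA`, `star`, `mendelian`.
#' @export
classify_column <- function(g, parental = NULL) {
  if (anyNA(g)) stop("classify_column requires complete calls", call. = FALSE)
  g <- as.integer(g)
  stopifnot(length(g) == 8, all(g %in% 0:1))
  countA <- sum(g)
  discordant <- any(g[c(1, 3, 5, 7)] != g[c(2, 4, 6, 8)])
  even <- countA %% 2L == 0L
  star <- even && discordant
  if (!star && countA == 4L && !discordant && !is.null(parental)) {
    star <- !all(g == as.integer(parental))
  }
  pattern <- paste0(countA, ":", 8L - countA, if (star) "*")
  list(pattern = pattern, countA = countA, star = star,
       mendelian = countA == 4L && !star)
}

## Compact per-column key: columns with identical strand vectors share a
## key; NA-containing columns get key NA.
column_keys <- function(G) {
  as.integer(2L^(0:7) %*% G)
}

#' Split a chromosome into segregation-pattern segments
#'
#' Maximal runs of identical 8-strand genotype vectors.  Columns containing
#' any missing call are excluded and do not interrupt runs (depth gaps do
#' not split segments).  Each segment is labelled with its segregation
#' pattern; `mendelian` marks concordant 4:4 segments of any arrangement.
#'
#' @param sm A [strand_matrix()].
#' @return A data frame of class `seg_table` with one row per segment:
#'   `chrom`, `first`, `last` (indices into the retained-marker sequence),
#'   `first_idx`, `last_idx` (original column indices of `sm`),
#'   `start_pos`, `end_pos`, `n_markers`, `pattern`, `countA`, `star`,
#'   `mendelian`, `vec` (strand vector as a string, e.g. `"11110000"`).
#'   Attributes `pos` and `col_idx` give positions/column indices of the
#'   retained markers; `dropped` the excluded column indices.
#' @export
segment_chromosome <- function(sm) {
  G <- unclass(sm)
  pos <- attr(sm, "pos")
  keep <- which(colSums(is.na(G)) == 0L)
  empty <- data.frame(chrom = character(0), first = integer(0), last = integer(0),
                      first_idx = integer(0), last_idx = integer(0),
                      start_pos = numeric(0), end_pos = numeric(0),
                      n_markers = integer(0), pattern = character(0),
                      countA = integer(0), star = logical(0),
                      mendelian = logical(0), vec = character(0),
                      stringsAsFactors = FALSE)
  if (!length(keep)) {
    out <- empty
  } else {
    Gk <- G[, keep, drop = FALSE]
    keys <- column_keys(Gk)
    r <- rle(keys)
    last <- cumsum(r$lengths)
    first <- last - r$lengths + 1L
    reps <- Gk[, first, drop = FALSE]
    cls <- apply(reps, 2, classify_column)
    out <- data.frame(
      chrom = attr(sm, "chrom"),
      first = first, last = last,
      first_idx = keep[first], last_idx = keep[last],
      start_pos = pos[keep[first]], end_pos = pos[keep[last]],
      n_markers = r$lengths,
      pattern = vapply(cls, `[[`, "", "pattern"),
      countA = vapply(cls, `[[`, 0L, "countA"),
      star = vapply(cls, `[[`, TRUE, "star"),
      mendelian = vapply(cls, `[[`, TRUE, "mendelian"),
      vec = apply(reps, 2, paste, collapse = ""),
      stringsAsFactors = FALSE
    )
  }
  attr(out, "pos") <- pos[keep]
  attr(out, "col_idx") <- keep
  attr(out, "dropped") <- setdiff(seq_len(ncol(G)), keep)
  attr(out, "chrom") <- attr(sm, "chrom")
  class(out) <- c("seg_table", "data.frame")
  out
}
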