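#' Construct an 8-strand genotype matrix for one chromosome
#'
#' The central object of octad analysis: an 8 x markers matrix of binary
#' parental genotype calls, one row per DNA strand.  Rows `2k - 1` and `2k`
#' are the "mother" and "daughter" strands of chromatid `k` (the two cells
#' of the first post-meiotic division of spore `k`); chromatids 1-2 derive
#' from parent A and chromatids 3-4 from parent B at the chromosome start.
#'
#' Values are `1` (parent-A allele), `0` (parent-B allele) or `NA`
#' (no confident call).
#'
#' @param mat An 8-row matrix of values in `{0, 1, NA}`.
#' @param chrom Chromosome name.
#' @param pos Numeric vector of marker positions (bp), one per column,
#'   strictly increasing.
#' @param marker_idx Optional indices of the columns in the full marker map.
#' @param polarity_unknown Logical length-4 flag per spore: `TRUE` when the
#'   mother/daughter orientation of that spore's strand pair is arbitrary
#'   (unphased mocktads), in which case strand-polarity-dependent
#'   classifications are suppressed.
#'
#' @return A `strand_matrix`.
#' @export
strand_matrix <- function(mat, chrom, pos, marker_idx = seq_len(ncol(mat)),
                          polarity_unknown = rep(FALSE, 4)) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 8)
    stop("a strand matrix must have exactly 8 rows", call. = FALSE)
  if (length(pos) != ncol(mat))
    stop("`pos` must have one entry per marker column", call. = FALSE)
  if (ncol(mat) > 1 && any(diff(pos) <= 0))
    stop("marker positions must be strictly increasing", call. = FALSE)
  if (!all(mat %in% c(0L, 1L, NA)))
    stop("strand matrix values must be 0, 1 or NA", call. = FALSE)
  storage.mode(mat) <- "integer"
  rownames(mat) <- strand_names()
  structure(mat,
            chrom = as.character(chrom), pos = as.numeric(pos),
            marker_idx = as.integer(marker_idx),
            polarity_unknown = as.logical(polarity_unknown),
            class = c("strand_matrix", "matrix", "array"))
}

#' Canonical octad sample names
#'
#' The 8 strand sample names in matrix row order: spore 1 mother, spore 1
#' daughter, ..., spore 4 daughter.
#'
#' @return Character vector of length 8.
#' @export
strand_names <- function() {
  paste0("spore", rep(1:4, each = 2), c("_mother", "_daughter"))
}

## Rows of chromatid k (mother, daughter).
chromatid_rows <- function(k) c(2L * k - 1L, 2L * k)

#' @export
print.strand_matrix <- function(x, ...) {
  cat(sprintf("<strand_matrix> %s: 8 strands x %d markers (%.0f-%.0f bp)\n",
              attr(x, "chrom"), ncol(x),
              if (ncol(x)) min(attr(x, "pos")) else NA,
              if (ncol(x)) max(attr(x, "pos")) else NA))
  invisible(x)
}

## Subset columns, keeping attributes coherent.
sm_subset <- function(sm, j) {
  strand_matrix(unclass(sm)[, j, drop = FALSE], attr(sm, "chrom"),
                attr(sm, "pos")[j], attr(sm, "marker_idx")[j],
                attr(sm, "polarity_unknown"))
}
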