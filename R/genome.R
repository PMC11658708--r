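#' Build a genome model
#'
#' A genome model records chromosome lengths and centromere positions and is
#' used for length-proportional crossover allocation (the non-exchange
#' chromosome null model), for the synthetic-meiosis simulator, and for
#' telomere/centromere distance statistics.
#'
#' @param lengths Numeric vector of chromosome lengths in bp.
#' @param centromeres Numeric vector of centromere positions (bp, 1-based),
#'   same length and order as `lengths`.
#' @param chrom Character vector of chromosome names; defaults to
#'   `names(lengths)` or `chr1..chrN`.
#'
#' @return A `genome_model`: a data frame with columns `chrom`, `length`,
#'   `cen`, carrying the allocation probabilities `length / sum(length)` in
#'   column `p`.
#' @seealso [yeast_genome()] for the default S. cerevisiae model.
#' @export
genome_model <- function(lengths, centromeres = round(lengths / 2), chrom = NULL) {
  if (is.null(chrom)) {
    chrom <- names(lengths)
    if (is.null(chrom)) chrom <- paste0("chr", seq_along(lengths))
  }
  lengths <- as.numeric(lengths)
  centromeres <- as.numeric(centromeres)
  if (length(centromeres) != length(lengths))
    stop("`centromeres` must match `lengths` in length", call. = FALSE)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("all chromosome lengths must be positive", call. = FALSE)
  if (any(centromeres < 1 | centromeres > lengths))
    stop("centromere positions must lie within their chromosome", call. = FALSE)
  g <- data.frame(
    chrom = as.character(chrom), length = lengths, cen = centromeres,
    p = lengths / sum(lengths), stringsAsFactors = FALSE
  )
  stopifnot(abs(sum(g$p) - 1) < 1e-12)
  class(g) <- c("genome_model", "data.frame")
  g
}

#' The 16-chromosome S. cerevisiae genome model
#'
#' Chromosome lengths and centromere midpoints of the S288c reference
#' assembly (R64).  These lengths define the allocation probabilities used
#' by the non-exchange chromosome simulation, where each crossover lands on
#' a chromosome with probability proportional to its length.
#'
#' @return A [genome_model()] with 16 chromosomes.
#' @export
yeast_genome <- function() {
  lengths <- c(
    chr01 = 230218,  chr02 = 813184,  chr03 = 316620,  chr04 = 1531933,
    chr05 = 576874,  chr06 = 270161,  chr07 = 1090940, chr08 = 562643,
    chr09 = 439888,  chr10 = 745751,  chr11 = 666816,  chr12 = 1078177,
    chr13 = 924431,  chr14 = 784333,  chr15 = 1091291, chr16 = 948066
  )
  cen <- c(151465, 238207, 114385, 449711, 151987, 148510, 496920, 105586,
           355629, 436307, 440129, 150828, 268031, 628758, 326584, 555957)
  genome_model(lengths, cen)
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %d chromosomes, %.2f Mb total\n",
              nrow(x), sum(x$length) / 1e6))
  NextMethod()
}

## Run `code` under a temporary RNG state seeded with `seed` (NULL = use the
## current stream).  Keeps every simulation seed-deterministic without
## clobbering the caller's RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
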