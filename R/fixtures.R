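## Builders for small hand-constructed octad matrices, used by the
## taxonomy fixtures and the test-suite.

#' Build a parental (all 4:4) octad matrix
#'
#' @param m Number of markers.
#' @param spacing Marker spacing in bp.
#' @param chrom Chromosome name.
#' @return A [strand_matrix()] with chromatids 1-2 parent A, 3-4 parent B.
#' @export
parental_octad <- function(m = 16, spacing = 400, chrom = "chrF") {
  S <- matrix(rep(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L), m), nrow = 8)
  strand_matrix(S, chrom, spacing * seq_len(m))
}

#' Edit helpers for fixture matrices
#'
#' `fx_co()` reciprocally exchanges two chromatids downstream of a marker;
#' `fx_set()` sets one or both strands of a chromatid over a marker range.
#'
#' @param sm A [strand_matrix()].
#' @param after Marker index after which the exchange applies.
#' @param a,b Chromatid indices (1-4) to exchange.
#' @return The edited matrix.
#' @export
fx_co <- function(sm, after, a, b) {
  j <- seq_len(ncol(sm)) > after
  ra <- chromatid_rows(a); rb <- chromatid_rows(b)
  tmp <- sm[ra, j]
  sm[ra, j] <- sm[rb, j]
  sm[rb, j] <- tmp
  sm
}

#' @rdname fx_co
#' @param chromatid Chromatid index (1-4).
#' @param strand `"mother"`, `"daughter"` or `"both"`.
#' @param markers Marker indices to set.
#' @param value Genotype value (0 or 1).
#' @export
fx_set <- function(sm, chromatid, strand, markers, value) {
  rows <- chromatid_rows(chromatid)
  rows <- switch(strand, mother = rows[1], daughter = rows[2], both = rows)
  sm[rows, markers] <- as.integer(value)
  sm
}

#' Hand-built fixture matrices for the event taxonomy
#'
#' One octad matrix per labelled category of the multi-DSB, NCO and CO
#' example panels: double NCO on sisters / on homologues with perfect
#' overlap, double CO, CO+NCO on a third chromatid (with and without a 7:1
#' segment), double NCO with 8:0 or 7:1 trans-DSB evidence; NCO
#' full-conversion, one-sided, one-sided with conversion patch, two-sided
#' trans, two-sided with central restoration, two-chromatid; CO with no
#' strand transfer, full conversion, one-/two-sided uni-/bidirectional
#' heteroduplex and symmetric hDNA.
#'
#' @return A named list; each element has `sm` (the [strand_matrix()]) and
#'   `expected` (a list of the expected `co_count`, `nco_count`,
#'   `multi_class`, `trans_dsb`, `nco_class`, `co_class`).
#' @export
taxonomy_fixtures <- function() {
  fx <- list()
  exp0 <- list(co_count = 0L, nco_count = 0L, multi_class = "none",
               trans_dsb = FALSE, nco_class = NA_character_,
               co_class = NA_character_)
  add <- function(name, sm, ...) {
    e <- utils::modifyList(exp0, list(...))
    fx[[name]] <<- list(sm = sm, expected = e)
  }
  P <- function() parental_octad()

  ## ---- multi-DSB panels -------------------------------------------------
  sm <- fx_set(P(), 1, "daughter", 5:6, 0)
  sm <- fx_set(sm, 2, "daughter", 7:8, 0)
  add("multi_dNCO_sister", sm, nco_count = 2L, multi_class = "dNCO_sister")

  sm <- fx_set(P(), 1, "daughter", 5:7, 0)
  sm <- fx_set(sm, 3, "daughter", 5:7, 1)
  add("multi_dNCO_overlap", sm, nco_count = 2L, multi_class = "dNCO_overlap")

  sm <- fx_co(fx_co(P(), 6, 1, 3), 7, 2, 4)
  add("multi_dCO", sm, co_count = 2L, multi_class = "dCO")

  sm <- fx_set(P(), 1, "daughter", 5:6, 0)
  sm <- fx_co(sm, 6, 1, 3)
  sm <- fx_set(sm, 2, "daughter", 7:8, 0)
  add("multi_CO_plus_NCO", sm, co_count = 1L, nco_count = 1L,
      multi_class = "CO_plus_NCO")

  sm <- fx_set(P(), 3, "both", 5:6, 1)
  sm <- fx_set(sm, 4, "daughter", 5:6, 1)
  sm <- fx_co(sm, 6, 1, 3)
  add("multi_CO_plus_NCO_71", sm, co_count = 1L, nco_count = 1L,
      multi_class = "CO_plus_NCO", trans_dsb = TRUE)

  sm <- fx_set(P(), 3, "both", 6:7, 1)
  sm <- fx_set(sm, 4, "both", 6:7, 1)
  sm <- fx_set(sm, 3, "daughter", 5, 1)
  sm <- fx_set(sm, 3, "daughter", 8, 1)
  add("multi_dNCO_sister_80", sm, nco_count = 2L,
      multi_class = "dNCO_sister", trans_dsb = TRUE)

  sm <- fx_set(P(), 3, "both", 5:7, 1)
  sm <- fx_set(sm, 4, "daughter", 6:7, 1)
  add("multi_dNCO_sister_71", sm, nco_count = 2L,
      multi_class = "dNCO_sister", trans_dsb = TRUE)

  ## ---- NCO panels -------------------------------------------------------
  add("nco_full_conversion", fx_set(P(), 3, "both", 5:7, 1),
      nco_count = 1L, nco_class = "full_conversion")
  add("nco_one_sided", fx_set(P(), 3, "daughter", 5:7, 1),
      nco_count = 1L, nco_class = "one_sided")
  sm <- fx_set(P(), 3, "daughter", 5:7, 1)
  sm <- fx_set(sm, 3, "mother", 6, 1)
  add("nco_one_sided_patch", sm, nco_count = 1L,
      nco_class = "one_sided_patch")
  sm <- fx_set(P(), 3, "daughter", 5:6, 1)
  sm <- fx_set(sm, 3, "mother", 7:8, 1)
  add("nco_two_sided_trans", sm, nco_count = 1L,
      nco_class = "two_sided_trans")
  sm <- fx_set(P(), 3, "daughter", 4:5, 1)
  sm <- fx_set(sm, 3, "daughter", 8:9, 1)
  add("nco_two_sided_restoration", sm, nco_count = 1L,
      nco_class = "two_sided_restoration")
  sm <- fx_set(P(), 1, "daughter", 5:6, 0)
  sm <- fx_set(sm, 3, "daughter", 6:8, 1)
  add("nco_two_chromatid", sm, nco_count = 2L, nco_class = "two_chromatid")

  ## ---- CO panels --------------------------------------------------------
  add("co_no_strand_transfer", fx_co(P(), 6, 1, 3),
      co_count = 1L, co_class = "no_strand_transfer")
  sm <- fx_set(P(), 3, "both", 5:6, 1)
  add("co_full_conversion", fx_co(sm, 6, 1, 3),
      co_count = 1L, co_class = "full_conversion")
  sm <- fx_set(P(), 1, "daughter", 5:6, 0)
  add("co_one_sided_unidirectional", fx_co(sm, 6, 1, 3),
      co_count = 1L, co_class = "one_sided_unidirectional")
  sm <- fx_set(P(), 1, "daughter", 4:5, 0)
  sm <- fx_set(sm, 3, "daughter", 6, 1)
  add("co_one_sided_bidirectional", fx_co(sm, 6, 1, 3),
      co_count = 1L, co_class = "one_sided_bidirectional")
  sm <- fx_set(P(), 1, "daughter", 5:6, 0)
  sm <- fx_co(sm, 6, 1, 3)
  sm <- fx_set(sm, 3, "daughter", 7:8, 0)
  add("co_two_sided_unidirectional", sm,
      co_count = 1L, co_class = "two_sided_unidirectional")
  sm <- fx_set(P(), 1, "daughter", 4:5, 0)
  sm <- fx_co(sm, 6, 1, 3)
  sm <- fx_set(sm, 1, "mother", 8:9, 1)
  add("co_two_sided_bidirectional", sm,
      co_count = 1L, co_class = "two_sided_bidirectional")
  sm <- fx_set(P(), 1, "daughter", 5:6, 0)
  sm <- fx_set(sm, 3, "daughter", 5:6, 1)
  add("co_symmetric_hDNA", fx_co(sm, 6, 1, 3),
      co_count = 1L, co_class = "symmetric_hDNA")

  fx
}
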