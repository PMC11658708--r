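#' Genotype-caller thresholds
#'
#' The calling rules convert per-marker read counts into binary parental
#' calls.  A position needs depth >= `min_depth` (default 5).  A SNP is
#' called as the parent-B variant when >= 70% of reads match the variant, as
#' the parent-A reference when >= 90% match the reference, and as
#' heteroduplex when reference plus variant reads make up >= 90% of all
#' reads *and* the two counts are within 70% of each other.  Indels use a
#' low variant threshold (30%) because alignment is biased towards the
#' reference, require >= 95% reference reads *and* fewer than 2 variant
#' reads for a reference call, and are never called heteroduplex.
#'
#' @param min_depth Minimum read depth for any call.
#' @param snp_var,snp_ref SNP variant / reference fraction thresholds.
#' @param het_combined Minimum (ref+var)/depth for a heteroduplex call.
#' @param het_balance Balance threshold: with the default `"ratio"` rule the
#'   smaller of the two counts must be at least `het_balance` times the
#'   larger; the alternative `"diff"` rule requires
#'   `|ref - var| / depth <= 1 - het_balance`.
#' @param indel_var,indel_ref Indel variant / reference fraction thresholds.
#' @param indel_max_var_reads Maximum variant reads tolerated in an indel
#'   reference call (exclusive bound: fewer than 2 reads by default).
#' @param recurrent_het_cutoff Markers heteroduplex in more than this many
#'   samples of a tetrad are eliminated as presumed marker-table errors.
#' @param het_rule `"ratio"` (default) or `"diff"`, see `het_balance`.
#' @return A list of class `caller_config`.
#' @export
caller_config <- function(min_depth = 5, snp_var = 0.70, snp_ref = 0.90,
                          het_combined = 0.90, het_balance = 0.70,
                          indel_var = 0.30, indel_ref = 0.95,
                          indel_max_var_reads = 1, recurrent_het_cutoff = 2,
                          het_rule = c("ratio", "diff")) {
  het_rule <- match.arg(het_rule)
  thr <- c(snp_var, snp_ref, het_combined, het_balance, indel_var, indel_ref)
  stopifnot(all(thr > 0), all(thr <= 1), min_depth >= 1,
            indel_max_var_reads >= 0, recurrent_het_cutoff >= 0)
  structure(list(min_depth = min_depth, snp_var = snp_var, snp_ref = snp_ref,
                 het_combined = het_combined, het_balance = het_balance,
                 indel_var = indel_var, indel_ref = indel_ref,
                 indel_max_var_reads = indel_max_var_reads,
                 recurrent_het_cutoff = recurrent_het_cutoff,
                 het_rule = het_rule),
            class = "caller_config")
}

#' Call genotypes from allele counts
#'
#' Pure function of the counts, the marker kind and the thresholds; all
#' thresholds are inclusive (`>=`).  Returns integer codes: `1` parent A
#' (reference), `0` parent B (variant), `2` heteroduplex, `NA` no call.
#'
#' @param n_ref,n_var,depth Integer vectors of reference-supporting reads,
#'   variant-supporting reads and total depth.
#' @param kind Character vector: `"SNP"`, `"insertion"` or `"deletion"`
#'   (the latter two share the indel rules).
#' @param cfg A [caller_config()].
#' @return Integer vector of genotype codes.
#' @export
call_genotypes <- function(n_ref, n_var, depth, kind, cfg = caller_config()) {
  if (!all(kind %in% c("SNP", "insertion", "deletion")))
    stop("unknown marker kind", call. = FALSE)
  n <- length(depth)
  stopifnot(length(n_ref) == n, length(n_var) == n, length(kind) %in% c(1L, n))
  if (length(kind) == 1L) kind <- rep(kind, n)
  out <- rep(NA_integer_, n)
  ok <- depth >= cfg$min_depth
  fr <- ifelse(depth > 0, n_ref / depth, 0)
  fv <- ifelse(depth > 0, n_var / depth, 0)
  is_snp <- kind == "SNP"
  ## SNP rules, in order of precedence
  out[ok & is_snp & fv >= cfg$snp_var] <- GT_B
  sel <- ok & is_snp & is.na(out) & fr >= cfg$snp_ref
  out[sel] <- GT_A
  comb <- fr + fv >= cfg$het_combined
  bal <- if (cfg$het_rule == "ratio") {
    pmax(n_ref, n_var) > 0 & pmin(n_ref, n_var) / pmax(n_ref, n_var) >= cfg$het_balance
  } else {
    ifelse(depth > 0, abs(n_ref - n_var) / depth <= 1 - cfg$het_balance, FALSE)
  }
  sel <- ok & is_snp & is.na(out) & comb & bal
  out[sel] <- GT_HET
  ## indel rules: variant first, conservative reference call, never het
  out[ok & !is_snp & fv >= cfg$indel_var] <- GT_B
  sel <- ok & !is_snp & is.na(out) & fr >= cfg$indel_ref &
    n_var <= cfg$indel_max_var_reads
  out[sel] <- GT_A
  out
}

#' Call genotypes for a whole site-counts table
#'
#' Joins a `site_counts` table to a marker map (to obtain each marker's
#' kind) and applies [call_genotypes()].  Positions absent from the map are
#' dropped with a warning.
#'
#' @param counts A `site_counts` data frame (see [emit_site_counts()] /
#'   [read_site_counts()]).
#' @param map A `marker_map`.
#' @param cfg A [caller_config()].
#' @return `counts` with an integer `call` column appended.
#' @export
call_genotypes_table <- function(counts, map, cfg = caller_config()) {
  key_c <- paste(counts$chrom, counts$pos)
  key_m <- paste(map$chrom, map$pos)
  idx <- match(key_c, key_m)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " count rows at positions absent from the marker map were dropped")
    counts <- counts[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  counts$call <- call_genotypes(counts$n_ref, counts$n_var, counts$depth,
                                map$kind[idx], cfg)
  counts
}

## Pivot called counts into a samples x markers code matrix for one
## chromosome, with columns following the marker map.
calls_matrix <- function(calls, samples, map, chrom) {
  mk <- map_chrom(map, chrom)
  M <- matrix(NA_integer_, nrow = length(samples), ncol = nrow(mk),
              dimnames = list(samples, NULL))
  sub <- calls[calls$chrom == chrom & calls$sample %in% samples, , drop = FALSE]
  i <- match(sub$sample, samples)
  j <- match(sub$pos, mk$pos)
  keep <- !is.na(j)
  M[cbind(i[keep], j[keep])] <- sub$call[keep]
  attr(M, "pos") <- mk$pos
  attr(M, "marker_idx") <- as.integer(rownames(mk))
  M
}

#' Assemble an octad strand matrix from 8 called samples
#'
#' The 8 post-meiotic cells of an octad are single haploid genomes, so
#' heteroduplex calls are not biologically possible and are discarded
#' (set to missing), as are heteroduplex calls in MMR-proficient tetrads.
#' Columns in which any strand is missing are retained in the matrix but
#' excluded from segmentation downstream.
#'
#' @param calls Output of [call_genotypes_table()].
#' @param samples Character vector of exactly 8 sample ids, ordered as
#'   mother/daughter pairs: spore1 mother, spore1 daughter, spore2 mother, ...
#' @param map A `marker_map`.
#' @return Named list of [strand_matrix()] objects, one per chromosome with
#'   markers.
#' @export
assemble_octad <- function(calls, samples, map) {
  if (length(samples) != 8)
    stop("octad assembly needs exactly 8 samples, got ", length(samples),
         call. = FALSE)
  out <- list()
  for (chr in unique(map$chrom)) {
    M <- calls_matrix(calls, samples, map, chr)
    if (!ncol(M)) next
    M[M == GT_HET] <- NA_integer_
    out[[chr]] <- strand_matrix(M, chr, attr(M, "pos"), attr(M, "marker_idx"))
  }
  out
}

#' Assemble an MMR-proficient tetrad as a duplicated octad
#'
#' Each spore's calls are duplicated onto a mother/daughter strand pair so
#' that tetrads and octads share the downstream machinery; heteroduplex
#' calls are discarded.  Only even segregation patterns can arise.
#'
#' @param calls Output of [call_genotypes_table()].
#' @param samples Character vector of exactly 4 spore sample ids.
#' @param map A `marker_map`.
#' @return Named list of [strand_matrix()] objects.
#' @export
assemble_tetrad <- function(calls, samples, map) {
  if (length(samples) != 4)
    stop("tetrad assembly needs exactly 4 samples, got ", length(samples),
         call. = FALSE)
  out <- list()
  for (chr in unique(map$chrom)) {
    M <- calls_matrix(calls, samples, map, chr)
    if (!ncol(M)) next
    M[M == GT_HET] <- NA_integer_
    S <- M[rep(1:4, each = 2), , drop = FALSE]
    out[[chr]] <- strand_matrix(S, chr, attr(M, "pos"), attr(M, "marker_idx"))
  }
  out
}

#' Reconstruct a pseudo-octad ("mocktad") from an MMR-deficient tetrad
#'
#' In msh2-deficient tetrads, heteroduplex DNA segregates at the first
#' post-meiotic division, so a whole spore colony shows mixed (~50:50)
#' reads at hDNA positions.  Each spore is duplicated into a strand pair;
#' at heteroduplex calls the mother strand is assigned the parent-B allele
#' and the daughter strand the parent-A allele.  This polarity is an
#' arbitrary global convention — strand orientation cannot be known without
#' resequencing (see [phase_with_colony()]) — so every spore with at least
#' one heteroduplex call carries a `polarity_unknown` flag.  Markers
#' heteroduplex in more than `cfg$recurrent_het_cutoff` samples are
#' eliminated as presumed errors in the marker table.
#'
#' @param calls Output of [call_genotypes_table()].
#' @param samples Character vector of exactly 4 spore sample ids, in spore
#'   order.
#' @param map A `marker_map`.
#' @param cfg A [caller_config()] (for the recurrent-heteroduplex cutoff).
#' @return Named list of [strand_matrix()] objects with attributes
#'   `het_idx` (per-spore column indices that were heteroduplex) and
#'   `polarity_unknown`.
#' @export
build_mocktad <- function(calls, samples, map, cfg = caller_config()) {
  if (length(samples) != 4)
    stop("mocktad assembly needs exactly 4 samples, got ", length(samples),
         call. = FALSE)
  out <- list()
  for (chr in unique(map$chrom)) {
    M <- calls_matrix(calls, samples, map, chr)
    if (!ncol(M)) next
    n_het <- colSums(M == GT_HET, na.rm = TRUE)
    keep <- which(n_het <= cfg$recurrent_het_cutoff)
    pos <- attr(M, "pos")[keep]
    midx <- attr(M, "marker_idx")[keep]
    M <- M[, keep, drop = FALSE]
    S <- matrix(NA_integer_, 8, ncol(M))
    het_idx <- vector("list", 4)
    for (k in 1:4) {
      rows <- chromatid_rows(k)
      v <- M[k, ]
      h <- which(!is.na(v) & v == GT_HET)
      S[rows[1], ] <- S[rows[2], ] <- v
      S[rows[1], h] <- GT_B      # arbitrary polarity: mother -> parent B
      S[rows[2], h] <- GT_A
      het_idx[[k]] <- h
    }
    sm <- strand_matrix(S, chr, pos, midx,
                        polarity_unknown = lengths(het_idx) > 0)
    attr(sm, "het_idx") <- het_idx
    out[[chr]] <- sm
  }
  out
}

#' Phase a mocktad spore with a resequenced colony
#'
#' A single colony restreaked from a spore colony carries the complete
#' haplotype of one strand of the mother/daughter pair.  At each marker
#' where the spore was heteroduplex, the colony's call is assigned to one
#' strand (`colony_is`, default `"daughter"`) and the complementary
#' parental call to the other, replacing the arbitrary mocktad polarity.
#' Positions where the colony itself is heteroduplex or missing keep the
#' arbitrary polarity; the spore's `polarity_unknown` flag is cleared only
#' when every heteroduplex marker was resolved.  Non-heteroduplex positions
#' are never altered.
#'
#' @param mocktad Named list of mocktad [strand_matrix()] objects (from
#'   [build_mocktad()]).
#' @param colony_calls Called counts table ([call_genotypes_table()]) of the
#'   colony sample.
#' @param spore Spore index 1-4 that the colony derives from.
#' @param colony_is Which strand of the pair the colony is taken to carry.
#' @return The phased mocktad list.
#' @export
phase_with_colony <- function(mocktad, colony_calls, spore,
                              colony_is = c("daughter", "mother")) {
  colony_is <- match.arg(colony_is)
  stopifnot(spore %in% 1:4)
  rows <- chromatid_rows(spore)
  target_row <- if (colony_is == "mother") rows[1] else rows[2]
  other_row <- setdiff(rows, target_row)
  for (chr in names(mocktad)) {
    sm <- mocktad[[chr]]
    h <- attr(sm, "het_idx")[[spore]]
    if (!length(h)) next
    pos <- attr(sm, "pos")
    cc <- colony_calls[colony_calls$chrom == chr, , drop = FALSE]
    cidx <- match(pos[h], cc$pos)
    call <- rep(NA_integer_, length(h))
    call[!is.na(cidx)] <- cc$call[cidx[!is.na(cidx)]]
    usable <- !is.na(call) & call %in% c(GT_A, GT_B)
    sm[target_row, h[usable]] <- call[usable]
    sm[other_row, h[usable]] <- 1L - call[usable]
    unresolved <- h[!usable]
    attr(sm, "het_idx")[[spore]] <- unresolved
    pu <- attr(sm, "polarity_unknown")
    pu[spore] <- length(unresolved) > 0
    attr(sm, "polarity_unknown") <- pu
    mocktad[[chr]] <- sm
  }
  mocktad
}
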