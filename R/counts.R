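#' Emit per-marker allele counts from simulated strand matrices
#'
#' Emulates the per-position read-count tables produced by a pileup
#' summarizer.  In `"octad"` mode each of the 8 strands is a sample and its
#' reads derive from a single haploid genome.  In `"tetrad"` mode each spore
#' colony is a sample whose reads are drawn from a 50:50 mixture of the
#' spore's mother and daughter strands, so retained-heteroduplex positions
#' yield mixed (~50% variant) counts.
#'
#' Per marker, depth is Poisson(`depth_mean`) and each read reports the true
#' allele with probability `1 - error_rate`, the other parental allele with
#' probability `error_rate / 3`, and some other base otherwise.  With
#' `deterministic = TRUE` depth is fixed at `round(depth_mean)` and counts
#' at their rounded expectations, which is convenient for exact round-trip
#' tests.
#'
#' @param strands A single [strand_matrix()] or a named list of them (one
#'   meiosis).
#' @param depth_mean Mean depth (> 0).
#' @param error_rate Per-read error probability in `[0, 0.5)`.
#' @param mode `"octad"` or `"tetrad"`.
#' @param deterministic Emit expected counts instead of sampling.
#' @param seed Optional integer seed.
#'
#' @return A `site_counts` data frame: `sample`, `chrom`, `pos`, `n_ref`,
#'   `n_var`, `n_other`, `depth`.  `n_ref` counts reads supporting the
#'   parent-A (reference) allele and `n_var` the parent-B (variant) allele.
#' @export
emit_site_counts <- function(strands, depth_mean = 44, error_rate = 0.002,
                             mode = c("octad", "tetrad"),
                             deterministic = FALSE, seed = NULL) {
  mode <- match.arg(mode)
  if (depth_mean <= 0) stop("`depth_mean` must be > 0", call. = FALSE)
  if (error_rate < 0 || error_rate >= 0.5)
    stop("`error_rate` must be in [0, 0.5)", call. = FALSE)
  if (inherits(strands, "strand_matrix")) strands <- list(strands)
  with_seed(seed, {
    out <- lapply(strands, function(sm) {
      pos <- attr(sm, "pos"); chrom <- attr(sm, "chrom")
      G <- unclass(sm)
      if (mode == "octad") {
        frac_A <- G                               # 8 samples, pure strands
        samples <- strand_names()
      } else {
        frac_A <- (G[c(1, 3, 5, 7), , drop = FALSE] +
                   G[c(2, 4, 6, 8), , drop = FALSE]) / 2
        samples <- paste0("spore", 1:4)
      }
      do.call(rbind, lapply(seq_along(samples), function(s) {
        counts_one_sample(frac_A[s, ], depth_mean, error_rate, deterministic,
                          samples[s], chrom, pos)
      }))
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    class(out) <- c("site_counts", "data.frame")
    out
  })
}

#' Emit counts for a resequenced single colony (one strand)
#'
#' A restreaked single colony retains the haplotype of one strand of a
#' spore's mother/daughter pair; sequencing it recovers that strand's
#' genotype at every marker, which is what [phase_with_colony()] consumes.
#'
#' @param strands As in [emit_site_counts()].
#' @param spore Spore index 1-4.
#' @param strand `"mother"` or `"daughter"`: which strand the colony carries.
#' @param sample_name Sample id used in the output.
#' @inheritParams emit_site_counts
#' @return A `site_counts` data frame with one sample.
#' @export
emit_colony_counts <- function(strands, spore, strand = c("daughter", "mother"),
                               depth_mean = 44, error_rate = 0.002,
                               deterministic = FALSE, seed = NULL,
                               sample_name = sprintf("spore%d_colony", spore)) {
  strand <- match.arg(strand)
  if (inherits(strands, "strand_matrix")) strands <- list(strands)
  row <- chromatid_rows(spore)[if (strand == "mother") 1 else 2]
  with_seed(seed, {
    out <- do.call(rbind, lapply(strands, function(sm) {
      counts_one_sample(unclass(sm)[row, ], depth_mean, error_rate,
                        deterministic, sample_name,
                        attr(sm, "chrom"), attr(sm, "pos"))
    }))
    rownames(out) <- NULL
    class(out) <- c("site_counts", "data.frame")
    out
  })
}

## frac_A: per-marker probability that a read derives from a parent-A
## haplotype (1, 0.5 or 0; NA markers yield depth 0).
counts_one_sample <- function(frac_A, depth_mean, error_rate, deterministic,
                              sample, chrom, pos) {
  m <- length(frac_A)
  e <- error_rate
  fA <- ifelse(is.na(frac_A), 0, frac_A)
  p_ref <- fA * (1 - e) + (1 - fA) * e / 3
  p_var <- (1 - fA) * (1 - e) + fA * e / 3
  if (deterministic) {
    depth <- rep(max(1L, as.integer(round(depth_mean))), m)
    n_ref <- as.integer(round(depth * p_ref))
    n_var <- pmin(as.integer(round(depth * p_var)), depth - n_ref)
  } else {
    depth <- stats::rpois(m, depth_mean)
    n_ref <- stats::rbinom(m, depth, p_ref)
    p_rest <- ifelse(p_ref < 1, p_var / (1 - p_ref), 0)
    n_var <- stats::rbinom(m, depth - n_ref, p_rest)
  }
  depth[is.na(frac_A)] <- 0L
  n_ref[is.na(frac_A)] <- 0L
  n_var[is.na(frac_A)] <- 0L
  data.frame(sample = sample, chrom = chrom, pos = pos,
             n_ref = n_ref, n_var = n_var,
             n_other = depth - n_ref - n_var, depth = depth,
             stringsAsFactors = FALSE)
}
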