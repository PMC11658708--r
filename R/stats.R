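#' Event mid-length tract estimates
#'
#' Because apparent event extents depend on local marker density, tract
#' length is estimated as the distance between the midpoints of the
#' inter-marker intervals surrounding the event: the midpoint between the
#' last upstream Mendelian marker and the first event marker, to the
#' midpoint between the last event marker and the first downstream
#' Mendelian marker.  Type-U events (no flank on one side) and clean
#' crossovers without any converted marker have no defined mid-length
#' (`NA`); multi-DSB events are conventionally omitted from length
#' summaries, which [length_quartiles()] honours via `omit_multi`.
#'
#' @param events An `event_table` from [call_events()].
#' @return Numeric vector of mid-lengths (bp), one per event.
#' @export
event_midlength <- function(events) {
  pos <- attr(events, "pos")
  det <- attr(events, "detail")
  n <- nrow(events)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d <- det[[i]]
    if (events$type_U[i] || is.na(d$ki1)) next
    if (d$ki1 <= 1 || d$ki2 >= length(pos)) next
    left <- (pos[d$ki1 - 1] + pos[d$ki1]) / 2
    right <- (pos[d$ki2] + pos[d$ki2 + 1]) / 2
    out[i] <- right - left
  }
  out
}

#' Quartiles of event mid-lengths
#'
#' @param lengths Numeric vector of mid-lengths (bp); `NA`s are dropped.
#' @param multi Optional logical vector marking multi-DSB events.
#' @param omit_multi Drop multi-DSB events before summarising (default).
#' @return Named vector: `lower`, `median`, `upper` (type-7 quantiles).
#' @export
length_quartiles <- function(lengths, multi = NULL, omit_multi = TRUE) {
  if (!is.null(multi) && omit_multi) lengths <- lengths[!multi]
  lengths <- lengths[!is.na(lengths)]
  if (!length(lengths)) stop("no event lengths to summarise", call. = FALSE)
  q <- stats::quantile(lengths, c(0.25, 0.5, 0.75), names = FALSE)
  c(lower = q[1], median = q[2], upper = q[3])
}

#' Simulate non-exchange chromosome counts under random CO allocation
#'
#' The null model for crossover assurance: `n_co` crossovers are allocated
#' to chromosomes with probability proportional to chromosome length, and
#' the number of chromosomes receiving none is recorded, `replicates`
#' times.
#'
#' @param genome A [genome_model()].
#' @param n_co Number of crossovers per simulated meiosis (>= 1).
#' @param replicates Number of replicates (default 10,000).
#' @param seed Optional integer seed.
#' @return Object of class `nonexchange_sim`: list with `n_co`, `counts`
#'   (integer vector of zero-CO chromosome counts per replicate) and `p`
#'   (the allocation probabilities).
#' @export
simulate_nonexchange <- function(genome, n_co, replicates = 10000, seed = NULL) {
  stopifnot(n_co >= 1, replicates >= 1)
  with_seed(seed, {
    alloc <- stats::rmultinom(replicates, n_co, genome$p)
    counts <- colSums(alloc == 0L)
    structure(list(n_co = n_co, counts = as.integer(counts), p = genome$p),
              class = "nonexchange_sim")
  })
}

#' Build the simulation grid over CO counts
#'
#' Runs [simulate_nonexchange()] for every crossover count on a grid
#' (1-200 by default).
#'
#' @inheritParams simulate_nonexchange
#' @param n_co_grid Integer vector of CO counts.
#' @return Named list of `nonexchange_sim` objects, names = CO counts.
#' @export
nonexchange_grid <- function(genome, n_co_grid = 1:200, replicates = 10000,
                             seed = NULL) {
  with_seed(seed, {
    sims <- lapply(n_co_grid, function(N)
      simulate_nonexchange(genome, N, replicates))
    stats::setNames(sims, as.character(n_co_grid))
  })
}

#' Tail probability of an observed non-exchange chromosome count
#'
#' The chance, under random length-proportional allocation, of observing an
#' equal or greater (`tail = "greater"`) or equal or lesser
#' (`tail = "lesser"`) number of non-exchange chromosomes, given the
#' meiosis's total crossover count.
#'
#' @param observed_k Observed number of zero-CO chromosomes.
#' @param sim A `nonexchange_sim` (for the matching CO count) or a grid
#'   from [nonexchange_grid()].
#' @param n_co CO count used to select from a grid.
#' @param tail `"greater"` or `"lesser"`.
#' @return Empirical tail probability.
#' @export
nonexchange_pvalue <- function(observed_k, sim, n_co = NULL,
                               tail = c("greater", "lesser")) {
  tail <- match.arg(tail)
  if (!inherits(sim, "nonexchange_sim")) {
    if (is.null(n_co)) stop("`n_co` is required with a simulation grid", call. = FALSE)
    sim <- sim[[as.character(n_co)]]
    if (is.null(sim))
      stop("CO count ", n_co, " is outside the simulated grid", call. = FALSE)
  }
  if (tail == "greater") mean(sim$counts >= observed_k)
  else mean(sim$counts <= observed_k)
}

#' Aggregate per-meiosis tail probabilities to a genotype-level probability
#'
#' The median of the per-meiosis probabilities raised to the power of the
#' number of meioses.  This down-weights outlier meioses but is *not* a
#' standard combined p-value (a warning notes this); greater and lesser
#' tails must be aggregated separately.
#'
#' @param p Numeric vector of per-meiosis tail probabilities (same tail).
#' @return A single probability.
#' @export
aggregate_nonexchange <- function(p) {
  stopifnot(length(p) >= 1, all(p >= 0), all(p <= 1))
  warning("median^n aggregation is not a calibrated combined p-value; ",
          "interpret comparatively", call. = FALSE)
  stats::median(p)^length(p)
}

#' Inter-crossover distances
#'
#' Successive bp distances between adjacent crossover positions within each
#' chromosome.  Each crossover-bearing event contributes its span midpoint
#' once per crossover; chromosomes with fewer than two crossovers
#' contribute nothing, and zero distances (double crossovers within one
#' event) are dropped.
#'
#' @param events_by_chrom Named list of `event_table`s for one meiosis, or
#'   a list of such lists (several meioses, pooled).
#' @return Numeric vector of inter-CO distances in bp.
#' @export
compute_icds <- function(events_by_chrom) {
  if (length(events_by_chrom) && inherits(events_by_chrom[[1]], "event_table"))
    events_by_chrom <- list(events_by_chrom)
  out <- numeric(0)
  for (meiosis in events_by_chrom) {
    for (ev in meiosis) {
      if (!nrow(ev)) next
      keep <- !ev$type_U & !is.na(ev$co_count) & ev$co_count > 0
      if (!any(keep)) next
      mids <- rep((ev$start[keep] + ev$end[keep]) / 2, ev$co_count[keep])
      if (length(mids) < 2) next
      d <- diff(sort(mids))
      out <- c(out, d[d > 0])
    }
  }
  out
}

#' Maximum-likelihood gamma fit of inter-crossover distances
#'
#' Fits shape (gamma-alpha) and scale (gamma-beta) by maximising the
#' profile likelihood in the shape parameter; the scale follows from the
#' MLE identity shape x scale = sample mean.  Shape 1 corresponds to an
#' exponential distribution, i.e. random crossover placement; larger
#' shapes indicate more even spacing (interference).
#'
#' @param x Positive distances (>= 10 values).
#' @param shape_max Cap for near-constant data where the MLE diverges
#'   (capped fit is returned with a warning).
#' @return Object of class `gamma_fit`: `shape`, `scale`, `n`, `loglik`.
#' @export
fit_gamma_mle <- function(x, shape_max = 1e6) {
  x <- as.numeric(x)
  if (length(x) < 10) stop("need at least 10 distances", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("distances must be positive and finite", call. = FALSE)
  m <- mean(x)
  s <- log(m) - mean(log(x))     # > 0 unless x is constant
  ## solve log(a) - digamma(a) = s
  f <- function(a) log(a) - digamma(a) - s
  if (s < f(shape_max)) {
    warning("near-constant distances: gamma shape capped at ", shape_max,
            call. = FALSE)
    a <- shape_max
  } else {
    a0 <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)  # Minka starter
    lo <- max(a0 / 10, 1e-8); hi <- a0 * 10
    while (f(lo) < 0) lo <- lo / 10
    while (f(hi) > 0) hi <- hi * 10
    a <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  }
  scale <- m / a
  ll <- sum(stats::dgamma(x, shape = a, scale = scale, log = TRUE))
  structure(list(shape = a, scale = scale, n = length(x), loglik = ll),
            class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf("<gamma_fit> shape %.4f, scale %.1f, n = %d, logLik = %.1f\n",
              x$shape, x$scale, x$n, x$loglik))
  invisible(x)
}

#' Random (shape 1) reference ICD sample with matched means and counts
#'
#' For comparison with experimental inter-CO distance distributions, a
#' random reference is drawn from a gamma distribution with shape 1 (an
#' exponential) with the same mean as the data, matching the per-cell
#' event counts of the experiment.
#'
#' @param mean_icd Mean inter-CO distance of the data (bp).
#' @param n_events Vector of per-cell ICD counts to match (recycled over
#'   cells).
#' @param n_cells Number of simulated cells (default 10,000).
#' @param seed Optional integer seed.
#' @return Numeric vector of reference ICDs (length
#'   `sum(recycled n_events)`).
#' @export
random_icd_reference <- function(mean_icd, n_events, n_cells = 10000,
                                 seed = NULL) {
  stopifnot(mean_icd > 0, all(n_events >= 0))
  with_seed(seed, {
    per_cell <- rep_len(n_events, n_cells)
    stats::rexp(sum(per_cell), rate = 1 / mean_icd)
  })
}

#' Crossover homeostasis trend
#'
#' Least-squares fit of the per-meiosis CO:NCO ratio against the total
#' number of detectable recombination events.  A negative slope is the
#' signature of crossover homeostasis: CO numbers are buffered against
#' variation in total event (DSB) numbers.  Meioses with zero NCOs are
#' excluded with a warning.
#'
#' @param co,nco Integer vectors of per-meiosis CO and NCO counts.
#' @return List: `slope`, `intercept`, `n`, and the fitted `lm` object.
#' @export
homeostasis_trend <- function(co, nco) {
  stopifnot(length(co) == length(nco))
  keep <- nco > 0
  if (any(!keep))
    warning(sum(!keep), " meioses with zero NCOs excluded from the ",
            "homeostasis fit", call. = FALSE)
  co <- co[keep]; nco <- nco[keep]
  if (length(co) < 2)
    stop("need at least 2 meioses with NCOs", call. = FALSE)
  ratio <- co / nco
  total <- co + nco
  fit <- stats::lm(ratio ~ total)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(co), fit = fit)
}

#' Distance of events to the nearest telomere or centromere
#'
#' @param events_by_chrom Named list of `event_table`s (or list of lists).
#' @param genome A [genome_model()].
#' @param feature `"telomere"` (nearest chromosome end, 1-based ends) or
#'   `"centromere"`.
#' @return A data frame sorted by distance with columns `distance` (bp) and
#'   `cumfrac` (cumulative fraction of events), suitable for CDF plotting.
#' @export
distance_to_feature_cdf <- function(events_by_chrom, genome,
                                    feature = c("telomere", "centromere")) {
  feature <- match.arg(feature)
  if (length(events_by_chrom) && inherits(events_by_chrom[[1]], "event_table"))
    events_by_chrom <- list(events_by_chrom)
  dist <- numeric(0)
  for (meiosis in events_by_chrom) {
    for (chr in names(meiosis)) {
      ev <- meiosis[[chr]]
      if (!nrow(ev)) next
      g <- genome[genome$chrom == chr, ]
      if (!nrow(g)) stop("chromosome ", chr, " absent from genome model", call. = FALSE)
      mid <- (ev$start + ev$end) / 2
      d <- if (feature == "telomere") pmin(mid - 1, g$length - mid)
           else abs(mid - g$cen)
      dist <- c(dist, d)
    }
  }
  dist <- sort(dist)
  data.frame(distance = dist,
             cumfrac = seq_along(dist) / max(1L, length(dist)))
}

#' Hypothesis tests used by the analysis
#'
#' Thin wrappers with the conventions fixed: all tests two-sided, Wilcoxon
#' with continuity correction, Fisher's exact test on 2x2 tables,
#' two-sample Kolmogorov-Smirnov.
#'
#' @param x,y Samples (numeric) or, for Fisher, `x` a 2x2 matrix.
#' @param test One of `"fisher"`, `"wilcoxon"`, `"ttest"`, `"ks"`.
#' @param ... Passed to the underlying test.
#' @return List with `statistic` and `p_value`.
#' @export
stat_test <- function(x, y = NULL, test = c("fisher", "wilcoxon", "ttest", "ks"),
                      ...) {
  test <- match.arg(test)
  res <- switch(test,
    fisher = {
      if (is.null(dim(x)) || !all(dim(x) == c(2, 2)))
        stop("fisher test requires a 2x2 table", call. = FALSE)
      if (any(rowSums(x) == 0) || any(colSums(x) == 0))
        stop("fisher test table has a zero margin", call. = FALSE)
      stats::fisher.test(x, alternative = "two.sided")
    },
    wilcoxon = {
      check_two_samples(x, y)
      stats::wilcox.test(x, y, alternative = "two.sided", correct = TRUE,
                         exact = FALSE, ...)
    },
    ttest = {
      check_two_samples(x, y)
      stats::t.test(x, y, alternative = "two.sided", ...)
    },
    ks = {
      check_two_samples(x, y)
      stats::ks.test(x, y, alternative = "two.sided", ...)
    })
  list(statistic = unname(if (!is.null(res$statistic)) res$statistic else NA_real_),
       p_value = res$p.value)
}

check_two_samples <- function(x, y) {
  if (is.null(y) || !length(x) || !length(y))
    stop("two non-empty samples are required", call. = FALSE)
  invisible(TRUE)
}

#' Benjamini-Hochberg adjustment
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values (monotone after ordering, each >= raw, <= 1).
#' @export
adjust_pvalues <- function(p) {
  stats::p.adjust(p, method = "BH")
}
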