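test_that("event mid-lengths follow the flanking-midpoint formula", {
  pos <- c(8000, 9000, 10000, 11000, 12000, 13000, 14000)
  sm <- strand_matrix(matrix(rep(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L), 7), 8),
                      "chrF", pos)
  sm <- fx_set(sm, 3, "daughter", 3:5, 1)    # event markers 10,000-12,000
  ev <- call_events(segment_chromosome(sm), sm)
  expect_equal(event_midlength(ev), 3000)    # 12,500 - 9,500
  ## single-marker event: half the flanking inter-marker span
  pos <- c(100, 900, 1000, 1100, 2000)
  sm <- strand_matrix(matrix(rep(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L), 5), 8),
                      "chrF", pos)
  sm <- fx_set(sm, 3, "daughter", 3, 1)
  ev <- call_events(segment_chromosome(sm), sm)
  expect_equal(event_midlength(ev), 100)   # midpoints at 950 and 1,050
  ## type-U events have no defined length
  sm <- fx_set(parental_octad(), 3, "daughter", 14:16, 1)
  ev <- call_events(segment_chromosome(sm), sm)
  expect_true(is.na(event_midlength(ev)))
})

test_that("planted tract extents are recovered within a marker spacing on average", {
  g <- toy_genome()
  map <- generate_marker_map(g, mean_spacing = 150, seed = 31)
  sim <- simulate_meiosis(map, g, toy_params(mean_co = 0, mean_nco = 12,
                                             p_gap_conversion = 0), seed = 32)
  err <- c()
  for (chr in names(sim$strands)) {
    ev <- call_events(segment_chromosome(sim$strands[[chr]]), sim$strands[[chr]])
    ml <- event_midlength(ev)
    t <- sim$truth[sim$truth$chrom == chr & sim$truth$detectable, ]
    for (i in seq_len(nrow(t))) {
      hit <- which(!ev$type_U & ev$start <= t$pos[i] & ev$end >= t$pos[i] - 1)
      if (length(hit) == 1 && !is.na(ml[hit]))
        err <- c(err, ml[hit] - (t$tract_end[i] - t$tract_start[i]))
    }
  }
  expect_gt(length(err), 5)
  expect_lt(abs(mean(err)), 150)
})

test_that("length quartiles summarise the mid-length distribution", {
  expect_equal(unname(length_quartiles(c(1, 2, 3, 4, 5) * 1000)["median"]), 3000)
  q <- length_quartiles(rep(2500, 10))
  expect_true(all(q == 2500))
  expect_error(length_quartiles(numeric(0)), "no event lengths")
  ## multi-DSB events omitted
  q <- length_quartiles(c(1000, 2000, 1e6), multi = c(FALSE, FALSE, TRUE))
  expect_equal(unname(q["upper"]), 1750)
  ## Monte-Carlo: quartiles of a known distribution
  set.seed(5)
  x <- rexp(20000, 1 / 2000)
  q <- length_quartiles(x)
  expect_lt(abs(q["median"] - 2000 * log(2)) / (2000 * log(2)), 0.05)
})

test_that("non-exchange simulation matches trivial and analytic expectations", {
  eq <- genome_model(rep(1e5, 16))
  s <- simulate_nonexchange(eq, 1, replicates = 500, seed = 1)
  expect_true(all(s$counts == 15L))
  one <- genome_model(c(solo = 1e6))
  s <- simulate_nonexchange(one, 5, replicates = 100, seed = 1)
  expect_true(all(s$counts == 0L))
  g <- yeast_genome()
  s <- simulate_nonexchange(g, 90, replicates = 10000, seed = 2)
  expected <- sum((1 - g$p)^90)
  se <- sd(s$counts) / sqrt(length(s$counts))
  expect_lt(abs(mean(s$counts) - expected), 3 * se + 1e-9)
})

test_that("non-exchange tail probabilities and aggregation behave as defined", {
  g <- yeast_genome()
  grid <- nonexchange_grid(g, n_co_grid = c(1, 30), replicates = 2000, seed = 3)
  expect_equal(nonexchange_pvalue(0, grid, n_co = 30, tail = "greater"), 1)
  expect_equal(nonexchange_pvalue(17, grid, n_co = 30, tail = "greater"), 0)
  eq <- genome_model(rep(1e5, 16))
  s <- simulate_nonexchange(eq, 1, replicates = 200, seed = 1)
  expect_equal(nonexchange_pvalue(15, s, tail = "greater"), 1)
  expect_error(nonexchange_pvalue(3, grid, n_co = 999), "grid")
  expect_warning(a <- aggregate_nonexchange(0.5), "combined")
  expect_equal(a, 0.5)
  expect_equal(suppressWarnings(aggregate_nonexchange(c(0.5, 0.5, 0.5))), 0.125)
  p <- runif(5)
  expect_lte(suppressWarnings(aggregate_nonexchange(p)), median(p))
})

test_that("inter-CO distances are successive within-chromosome gaps", {
  sm <- parental_octad(m = 40, spacing = 10000)  # 400 kb chromosome
  sm <- fx_co(sm, 10, 1, 3)   # CO near 105 kb
  sm <- fx_co(sm, 30, 1, 3)   # CO near 305 kb
  ev <- list(chrF = call_events(segment_chromosome(sm), sm))
  ic <- compute_icds(ev)
  expect_length(ic, 1)
  expect_equal(ic, 200000)
  ## one CO per chromosome: nothing
  one <- fx_co(parental_octad(), 8, 1, 3)
  expect_length(compute_icds(list(chrF = call_events(segment_chromosome(one), one))), 0)
})

test_that("gamma MLE recovers parameters and satisfies the mean identity", {
  set.seed(11)
  x <- rgamma(3000, shape = 2, scale = 5e4)
  fit <- fit_gamma_mle(x)
  expect_lt(abs(fit$shape - 2) / 2, 0.1)
  expect_lt(abs(fit$shape * fit$scale - mean(x)) / mean(x), 1e-6)
  ## degenerate inputs
  expect_error(fit_gamma_mle(c(x[1:5])), "at least 10")
  expect_error(fit_gamma_mle(c(x[1:9], -1)), "positive")
  expect_warning(fit_gamma_mle(rep(100, 50) + rnorm(50, 0, 1e-9)), "capped")
  ## cross-check against an independent fitter
  skip_if_not_installed("MASS")
  ref <- suppressWarnings(MASS::fitdistr(x / 1e4, "gamma"))
  expect_lt(abs(fit$shape - unname(ref$estimate["shape"])), 1e-3)
})

test_that("the random ICD reference matches means and per-cell counts", {
  ref <- random_icd_reference(5e4, n_events = 50, n_cells = 2000, seed = 2)
  expect_length(ref, 1e5)
  se <- 5e4 / sqrt(length(ref))
  expect_lt(abs(mean(ref) - 5e4), 2 * se)
  expect_length(random_icd_reference(5e4, n_events = c(0, 3), n_cells = 10, seed = 1), 15)
})

test_that("homeostasis trend is the least-squares slope of CO:NCO on totals", {
  expect_equal(homeostasis_trend(c(10, 20, 30), c(5, 10, 15))$slope, 0)
  fit <- homeostasis_trend(c(200 / 3, 100), c(100 / 3, 100))  # ratios 2,1 at totals 100,200
  expect_equal(fit$slope, -0.01)
  expect_warning(homeostasis_trend(c(5, 6, 7), c(1, 0, 2)), "zero NCOs")
  ## constructed homeostasis: fixed CO, varying NCO -> negative slope
  set.seed(3)
  nco <- 20:60
  co <- rep(50, length(nco))
  expect_lt(homeostasis_trend(co, nco)$slope, 0)
})

test_that("feature distance CDFs use 1-based ends and centromere offsets", {
  g <- genome_model(c(chrZ = 1e6), centromeres = 3e5)
  sm <- parental_octad(m = 3, spacing = 100)
  ev <- call_events(segment_chromosome(sm), sm)    # empty table
  fake <- structure(
    data.frame(chrom = "chrZ", start = 5000, end = 5000, type_U = FALSE,
               co_count = 1L, nco_count = 0L),
    class = c("event_table", "data.frame"))
  cdf <- distance_to_feature_cdf(list(chrZ = fake), g, "telomere")
  expect_equal(cdf$distance, 4999)
  fake$start <- fake$end <- 3e5
  cdf <- distance_to_feature_cdf(list(chrZ = fake), g, "centromere")
  expect_equal(cdf$distance, 0)
  ## uniform positions: distance CDF within a KS band of the triangular null
  set.seed(8)
  pos <- runif(2000, 1, 1e6)
  evs <- structure(data.frame(chrom = "chrZ", start = pos, end = pos,
                              type_U = FALSE, co_count = 1L, nco_count = 0L),
                   class = c("event_table", "data.frame"))
  cdf <- distance_to_feature_cdf(list(chrZ = evs), g, "telomere")
  ## telomere distance of uniform positions ~ Uniform(0, L/2)
  ks <- suppressWarnings(stats::ks.test(cdf$distance, "punif", 0, 5e5))
  expect_gt(ks$p.value, 0.01)
})

test_that("test wrappers enforce conventions and reject degenerate input", {
  expect_lt(stat_test(matrix(c(10, 0, 0, 10), 2), test = "fisher")$p_value, 1e-4)
  expect_error(stat_test(matrix(c(5, 0, 7, 0), 2), test = "fisher"), "margin")
  expect_error(stat_test(matrix(1:6, 3, 2), test = "fisher"), "2x2")
  x <- rnorm(40)
  ks <- stat_test(x, x, test = "ks")
  expect_equal(ks$statistic, 0)
  expect_equal(ks$p_value, 1)
  expect_error(stat_test(x, numeric(0), test = "wilcoxon"), "non-empty")
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- runif(20)
  expect_true(all(adjust_pvalues(p) >= p & adjust_pvalues(p) <= 1))
})
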