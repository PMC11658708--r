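test_that("marker map gaps are exponential with the requested mean", {
  g <- genome_model(c(chr1 = 1e6), 5e5)
  map <- generate_marker_map(g, mean_spacing = 169, seed = 42)
  gaps <- diff(map$pos)
  expect_gt(length(gaps), 5000)
  expect_lt(abs(mean(gaps) - 169) / 169, 0.05)
  ## heavier tail than normal: median well below mean, as for an exponential
  expect_lt(median(gaps), mean(gaps))
})

test_that("marker map respects truncation, kinds and validation", {
  g <- genome_model(c(chr1 = 1e5), 5e4)
  map <- generate_marker_map(g, mean_spacing = 1e9, seed = 1)
  expect_lte(nrow(map), 1)
  map <- generate_marker_map(g, mean_spacing = 500, indel_fraction = 0, seed = 2)
  expect_true(all(map$kind == "SNP"))
  map <- generate_marker_map(g, mean_spacing = 300, indel_fraction = 1, seed = 2)
  expect_true(all(map$kind %in% c("insertion", "deletion")))
  expect_error(generate_marker_map(g, mean_spacing = 0), "mean_spacing")
  expect_error(generate_marker_map(g, indel_fraction = 2), "indel_fraction")
  ## reproducibility
  expect_identical(generate_marker_map(g, seed = 7), generate_marker_map(g, seed = 7))
})

test_that("a meiosis without events is entirely Mendelian parental", {
  g <- toy_genome()
  map <- generate_marker_map(g, mean_spacing = 500, seed = 3)
  sim <- simulate_meiosis(map, g, toy_params(mean_co = 0, mean_nco = 0), seed = 1)
  for (sm in sim$strands) {
    expect_true(all(unclass(sm) == c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L)))
  }
  expect_identical(nrow(sim$truth), 0L)
})

test_that("simulate_meiosis is seed-deterministic and conserves 4:4 outside events", {
  g <- toy_genome()
  map <- generate_marker_map(g, mean_spacing = 400, seed = 3)
  p <- toy_params(multi_dsb_rate = 1)
  s1 <- simulate_meiosis(map, g, p, seed = 11)
  s2 <- simulate_meiosis(map, g, p, seed = 11)
  expect_identical(s1, s2)
  ## columns far from every planted tract are parental two-pairs-per-parent
  for (chr in names(s1$strands)) {
    sm <- s1$strands[[chr]]
    pos <- attr(sm, "pos")
    t <- s1$truth[s1$truth$chrom == chr, ]
    touched <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(t))) {
      touched <- touched | (pos >= t$tract_start[i] - 1 & pos <= t$tract_end[i] + 1)
      touched <- touched | (pos >= min(t$pos[i], t$pos2[i], na.rm = TRUE) - 1 &
                              pos <= max(t$pos[i], t$pos2[i], na.rm = TRUE) + 1)
    }
    G <- unclass(sm)[, !touched, drop = FALSE]
    expect_true(all(colSums(G) == 4L))
    expect_true(all(G[c(1, 3, 5, 7), ] == G[c(2, 4, 6, 8), ]))
  }
})

test_that("each planted CO exchanges exactly one strand pair per parent downstream", {
  g <- genome_model(c(chr1 = 2e5), 1e5)
  map <- generate_marker_map(g, mean_spacing = 400, seed = 5)
  p <- toy_params(mean_co = 1, mean_nco = 0, tract_mean = 200, tract_sd = 50)
  found <- 0
  for (seed in 1:15) {
    sim <- simulate_meiosis(map, g, p, seed = seed)
    t <- sim$truth[sim$truth$kind == "CO", ]
    if (nrow(t) != 1) next
    found <- found + 1
    sm <- unclass(sim$strands$chr1)
    pos <- attr(sim$strands$chr1, "pos")
    first <- sm[, 1]
    last <- sm[, length(pos)]
    changed <- which(first[c(1, 3, 5, 7)] != last[c(1, 3, 5, 7)])
    expect_length(changed, 2)
    expect_setequal(first[c(1, 3, 5, 7)][changed], c(0L, 1L))  # one per parent
  }
  expect_gte(found, 3)
})

test_that("pooled truth inter-CO gaps at shape 1 refit as exponential", {
  g <- yeast_genome()
  map <- generate_marker_map(g, mean_spacing = 5000, seed = 5)
  p <- toy_params(mean_co = 90, mean_nco = 0)
  icds <- c()
  for (m in 1:60) {
    sim <- simulate_meiosis(map, g, p, seed = 900 + m)
    t <- sim$truth[sim$truth$kind == "CO", ]
    icds <- c(icds, unlist(lapply(split(t$pos, t$chrom), function(x) diff(sort(x)))))
  }
  expect_gt(length(icds), 3000)
  fit <- fit_gamma_mle(icds)
  expect_lt(abs(fit$shape - 1), 0.1)
})

test_that("emit_site_counts matches expectations in the clean corners", {
  sm <- parental_octad(m = 10, spacing = 100)
  cts <- emit_site_counts(sm, depth_mean = 50, error_rate = 0, deterministic = TRUE)
  a <- cts[cts$sample == "spore1_mother", ]
  expect_true(all(a$n_ref == 50 & a$n_var == 0 & a$depth == 50))
  b <- cts[cts$sample == "spore3_mother", ]   # parent-B chromatid
  expect_true(all(b$n_ref == 0 & b$n_var == 50))
  ## retained-hDNA marker in tetrad mode: 50:50 mixture
  smh <- fx_set(sm, 1, "daughter", 5, 0)
  t <- emit_site_counts(smh, depth_mean = 50, error_rate = 0,
                        mode = "tetrad", deterministic = TRUE)
  hrow <- t[t$sample == "spore1" & t$pos == 500, ]
  expect_equal(hrow$n_ref, 25)
  expect_equal(hrow$n_var, 25)
})

test_that("low depth drives the expected fraction of sites under the calling floor", {
  sm <- parental_octad(m = 2000, spacing = 10)
  cts <- emit_site_counts(sm, depth_mean = 4, error_rate = 0, seed = 8)
  frac <- mean(cts$depth < 5)
  expected <- ppois(4, 4)        # Poisson CDF at the floor
  expect_lt(abs(frac - expected), 0.02)
  calls <- call_genotypes(cts$n_ref, cts$n_var, cts$depth, "SNP")
  expect_gt(mean(is.na(calls)), 0.5)
})
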