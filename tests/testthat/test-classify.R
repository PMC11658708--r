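classify_one <- function(sm, ...) {
  classify_events(call_events(segment_chromosome(sm), sm), ...)
}

test_that("multi-DSB classification is conservative", {
  ## overlap at all but one marker on homologues: not a dNCO_overlap
  sm <- fx_set(parental_octad(), 1, "daughter", 5:7, 0)
  sm <- fx_set(sm, 3, "daughter", 5:6, 1)
  ev <- classify_one(sm)
  expect_equal(ev$multi_class, "none")
  expect_equal(ev$nco_class, "two_chromatid")
  ## sister conversions at distinct loci are dNCO_sister regardless of overlap
  sm <- fx_set(parental_octad(), 3, "daughter", 5:6, 1)
  sm <- fx_set(sm, 4, "daughter", 6:8, 1)
  expect_equal(classify_one(sm)$multi_class, "dNCO_sister")
})

test_that("trans-DSB detection follows the 8:0/7:1 rules and is monotone", {
  fx <- taxonomy_fixtures()
  ev <- classify_one(fx$multi_dNCO_sister_80$sm)
  expect_true(ev$trans_dsb)
  ## removing the 8:0 clears the flag (monotonicity)
  sm <- fx$multi_dNCO_sister_80$sm
  sm <- fx_set(sm, 4, "both", 6:7, 0)           # undo sister 2 conversion
  sm <- fx_set(sm, 3, "mother", 6:7, 0)         # 8:0 collapses to 5:3 run
  ev <- classify_one(sm)
  expect_false(ev$trans_dsb)
  ## isolated 8:0 between clean 4:4: no trans flag, QC flag instead
  sm <- fx_set(parental_octad(), 3, "both", 6:7, 1)
  sm <- fx_set(sm, 4, "both", 6:7, 1)
  ev <- classify_one(sm)
  expect_false(ev$trans_dsb)
  expect_true(ev$qc_no_flanking_hdna_8_0)
  ## tetrad mode: pattern-level evidence not observable
  expect_true(is.na(classify_one(sm, tetrad_mode = TRUE)$trans_dsb))
})

test_that("every fixture panel is classified into exactly its category", {
  fx <- taxonomy_fixtures()
  for (nm in names(fx)) {
    ev <- classify_one(fx[[nm]]$sm)
    e <- fx[[nm]]$expected
    expect_equal(nrow(ev), 1, info = nm)
    expect_identical(ev$co_count, e$co_count, info = nm)
    expect_identical(ev$nco_count, e$nco_count, info = nm)
    expect_identical(ev$multi_class, e$multi_class, info = nm)
    expect_identical(ev$trans_dsb, e$trans_dsb, info = nm)
    expect_identical(ev$nco_class, e$nco_class, info = nm)
    expect_identical(ev$co_class, e$co_class, info = nm)
  }
})

test_that("polarity-dependent NCO distinctions are suppressed for unphased spores", {
  sm <- fx_set(parental_octad(), 3, "daughter", 5:7, 1)   # one-sided hDNA
  attr(sm, "polarity_unknown") <- c(FALSE, FALSE, TRUE, FALSE)
  ev <- classify_one(sm)
  expect_true(is.na(ev$nco_class))
  expect_false(ev$nco_assessable)
  ## full conversions stay assessable
  sm <- fx_set(parental_octad(), 3, "both", 5:7, 1)
  attr(sm, "polarity_unknown") <- c(FALSE, FALSE, TRUE, FALSE)
  ev <- classify_one(sm)
  expect_equal(ev$nco_class, "full_conversion")
})

test_that("hotspot overlap uses the maximal event span, half-open", {
  sm <- fx_set(parental_octad(m = 16, spacing = 1000), 3, "daughter", 11:13, 1)
  ev <- call_events(segment_chromosome(sm), sm)
  ## maximal span: flanking Mendelian markers at 10,000 and 14,000
  expect_true(hotspot_overlap(ev, hotspot_track("chrF", 13500, 13900)))
  expect_false(hotspot_overlap(ev, hotspot_track("chrF", 9000, 10000)))
  expect_true(hotspot_overlap(ev, hotspot_track("chrF", 9000, 10001)))
  expect_false(hotspot_overlap(ev, hotspot_track("chrX", 13500, 13900)))
  expect_warning(res <- hotspot_overlap(ev, hotspot_track(character(0), numeric(0), numeric(0) + 1)),
                 "empty")
  expect_false(res)
})

test_that("hotspot overlap equals the brute-force all-pairs oracle", {
  set.seed(99)
  for (i in 1:200) {
    m <- 30
    sm <- parental_octad(m = m, spacing = sample(200:2000, 1))
    j <- sort(sample(3:(m - 2), 2))
    k <- sample(1:4, 1)
    sm <- fx_set(sm, k, "daughter", j[1]:j[2], if (k <= 2) 0 else 1)
    ev <- call_events(segment_chromosome(sm), sm)
    starts <- sort(sample.int(3e4, 5))
    hs <- hotspot_track("chrF", start = starts,
                        end = starts + sample(50:2000, 5, replace = TRUE))
    pos <- attr(ev, "pos")
    d <- attr(ev, "detail")[[1]]
    span <- c(pos[max(1, d$ki1 - 1)], pos[min(length(pos), d$ki2 + 1)])
    expect_identical(hotspot_overlap(ev, hs)[1], overlap_oracle(span, hs))
  }
})

test_that("QC drops recurrent and unflanked 8:0 loci and flags premeiotic patterns", {
  mk <- function() {
    sm <- fx_set(parental_octad(m = 30, spacing = 1000), 3, "both", 10:11, 1)
    sm <- fx_set(sm, 4, "both", 10:11, 1)     # isolated 8:0, no hDNA
    list(chrF = classify_one(sm))
  }
  out <- qc_filter(list(mk(), mk(), mk()))
  expect_true(all(vapply(out$events, function(m) nrow(m$chrF) == 0, TRUE)))
  expect_true(all(out$report$reason != ""))
  ## chromosome-scale 8:0 block flags the meiosis as premeiotic suspect
  sm <- fx_set(parental_octad(m = 300, spacing = 1000), 3, "both", 50:200, 1)
  sm <- fx_set(sm, 4, "both", 50:200, 1)
  sm <- fx_set(sm, 3, "daughter", 49, 1)      # adjacent hDNA keeps the event
  out <- qc_filter(list(list(chrF = classify_one(sm))))
  expect_true(out$premeiotic_suspect)
  ## clean simulated dataset: zero removals
  g <- toy_genome()
  map <- generate_marker_map(g, mean_spacing = 300, seed = 4)
  sim <- simulate_meiosis(map, g, toy_params(), seed = 5)
  out <- qc_filter(list(run_octad(sim$strands)))
  expect_equal(nrow(out$report), 0)
  expect_false(out$premeiotic_suspect)
})
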