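test_that("genotype caller follows the threshold rules at spot cases", {
  cc <- caller_config()
  ## SNP: 8/10 variant reads -> parent B
  expect_identical(call_genotypes(2, 8, 10, "SNP", cc), 0L)
  ## below the depth floor
  expect_identical(call_genotypes(4, 0, 4, "SNP", cc), NA_integer_)
  ## indel: 7/20 variant reads -> parent B (30% rule)
  expect_identical(call_genotypes(13, 7, 20, "insertion", cc), 0L)
  ## balanced heteroduplex: 48/47 of 100
  expect_identical(call_genotypes(48, 47, 100, "SNP", cc), 2L)
  ## unknown kind
  expect_error(call_genotypes(1, 1, 10, "weird", cc), "kind")
})

test_that("the alternative heteroduplex balance rule is switchable", {
  cc_diff <- caller_config(het_rule = "diff")
  ## ref 60 var 30 of 100: ratio rule fails (0.5 < 0.7), diff rule fails too
  expect_identical(call_genotypes(60, 30, 100, "SNP", cc_diff), NA_integer_)
  ## ref 55 var 40 of 100: |diff|/depth = 0.15 <= 0.30 -> het under diff rule,
  ## but min/max = 0.727 >= 0.7 also het under ratio; use 60/35 to separate
  expect_identical(call_genotypes(60, 35, 100, "SNP", cc_diff), 2L)
  expect_identical(call_genotypes(60, 35, 100, "SNP", caller_config()), NA_integer_)
})

test_that("octad assembly discards heteroduplex, flags missing columns", {
  g <- genome_model(c(chrA = 1e4), 5e3)
  map <- generate_marker_map(g, mean_spacing = 500, indel_fraction = 0, seed = 2)
  sm <- parental_octad(m = nrow(map), spacing = 1)
  cts <- emit_site_counts(strand_matrix(unclass(sm), "chrA", map$pos),
                          depth_mean = 30, error_rate = 0, deterministic = TRUE)
  calls <- call_genotypes_table(cts, map)
  ## poke one heteroduplex and one missing call
  calls$call[calls$sample == "spore2_mother" & calls$pos == map$pos[3]] <- 2L
  calls$call[calls$sample == "spore4_daughter" & calls$pos == map$pos[5]] <- NA
  oct <- assemble_octad(calls, strand_names(), map)
  M <- unclass(oct$chrA)
  expect_true(is.na(M[3, 3]))   # heteroduplex discarded
  expect_true(is.na(M[8, 5]))
  segs <- segment_chromosome(oct$chrA)
  expect_false(3 %in% attr(segs, "col_idx"))
  expect_equal(nrow(segs), 1)   # remaining columns still one parental segment
  expect_error(assemble_octad(calls, strand_names()[1:7], map), "8 samples")
})

test_that("mocktad construction splits heteroduplex with fixed polarity", {
  g <- genome_model(c(chrA = 1e4), 5e3)
  pos <- seq(500, 9500, by = 500)
  map <- data.frame(chrom = "chrA", pos = pos, allele_A = "A", allele_B = "C",
                    kind = "SNP")
  class(map) <- c("marker_map", "data.frame")
  mk_calls <- function(f) {
    do.call(rbind, lapply(1:4, function(k) {
      data.frame(sample = paste0("spore", k), chrom = "chrA", pos = pos,
                 call = f(k), stringsAsFactors = FALSE)
    }))
  }
  base <- function(k) if (k <= 2) rep(1L, length(pos)) else rep(0L, length(pos))
  ## spore 3 heteroduplex at 3 consecutive markers
  calls <- mk_calls(base)
  calls$call[calls$sample == "spore3" & calls$pos %in% pos[8:10]] <- 2L
  mt <- build_mocktad(calls, paste0("spore", 1:4), map)
  M <- unclass(mt$chrA)
  expect_false(any(M == 2L, na.rm = TRUE))
  expect_true(all(M[5, 8:10] == 0L))  # mother -> parent B
  expect_true(all(M[6, 8:10] == 1L))  # daughter -> parent A
  expect_identical(attr(mt$chrA, "polarity_unknown"), c(FALSE, FALSE, TRUE, FALSE))
  segs <- segment_chromosome(mt$chrA)
  ev <- call_events(segs, mt$chrA)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_markers, 3L)
  expect_match(ev$pattern, "5:3")
  ## heteroduplex in 3 of 4 spores -> marker eliminated
  calls <- mk_calls(base)
  calls$call[calls$pos == pos[4] & calls$sample %in% paste0("spore", 1:3)] <- 2L
  mt <- build_mocktad(calls, paste0("spore", 1:4), map)
  expect_false(pos[4] %in% attr(mt$chrA, "pos"))
  expect_error(build_mocktad(calls, paste0("spore", 1:3), map), "4 samples")
})

test_that("colony phasing resolves polarity and never touches other calls", {
  g <- genome_model(c(chrA = 1e4), 5e3)
  map <- generate_marker_map(g, mean_spacing = 400, indel_fraction = 0, seed = 9)
  sim <- simulate_meiosis(map, g, toy_params(mean_co = 2, mean_nco = 2), seed = 21)
  tcalls <- call_genotypes_table(
    emit_site_counts(sim$strands, depth_mean = 60, error_rate = 0,
                     mode = "tetrad", deterministic = TRUE), map)
  mock <- build_mocktad(tcalls, paste0("spore", 1:4), map)
  before <- unclass(mock$chrA)
  for (k in 1:4) {
    cc <- call_genotypes_table(
      emit_colony_counts(sim$strands, k, "daughter", depth_mean = 60,
                         error_rate = 0, deterministic = TRUE), map)
    mock <- phase_with_colony(mock, cc, k)
  }
  after <- unclass(mock$chrA)
  expect_false(any(attr(mock$chrA, "polarity_unknown")))
  ## non-heteroduplex positions bitwise stable
  het_cols <- sort(unique(unlist(attr(mock$chrA, "het_idx"))))
  untouched <- setdiff(seq_len(ncol(before)), Reduce(union, lapply(1:4, function(k)
    which(before[2 * k - 1, ] != before[2 * k, ]))))
  expect_identical(before[, untouched], after[, untouched])
  ## full round trip to the simulated octad
  expect_identical(after[, ], unclass(sim$strands$chrA)[, ])
})

test_that("a colony matching the arbitrary polarity leaves the matrix unchanged", {
  pos <- seq(500, 5000, by = 500)
  map <- data.frame(chrom = "chrA", pos = pos, allele_A = "A", allele_B = "C",
                    kind = "SNP")
  class(map) <- c("marker_map", "data.frame")
  calls <- do.call(rbind, lapply(1:4, function(k)
    data.frame(sample = paste0("spore", k), chrom = "chrA", pos = pos,
               call = if (k <= 2) 1L else 0L)))
  calls$call[calls$sample == "spore1" & calls$pos == pos[5]] <- 2L
  mt <- build_mocktad(calls, paste0("spore", 1:4), map)
  before <- unclass(mt$chrA)
  ## colony carries the daughter strand as assigned arbitrarily (parent A)
  colony <- data.frame(sample = "c", chrom = "chrA", pos = pos,
                       call = before[2, ])
  mt2 <- phase_with_colony(mt, colony, 1)
  expect_identical(unclass(mt2$chrA)[, ], before[, ])
  expect_false(attr(mt2$chrA, "polarity_unknown")[1])
})
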