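## Shared builders for small simulated worlds.

toy_genome <- function() {
  genome_model(c(chrA = 3e5, chrB = 2e5), centromeres = c(1.5e5, 1e5))
}

## Quiet parameters for well-separated simple events on a toy genome.
toy_params <- function(...) {
  args <- utils::modifyList(
    list(mean_co = 6, mean_nco = 4, interference_shape = 1,
         tract_mean = 1500, tract_sd = 300, mmr = "deficient",
         p_gap_conversion = 0.2, multi_dsb_rate = 0),
    list(...))
  do.call(sim_params, args)
}

## Random complete 8 x m strand matrix biased towards realistic columns:
## mixes parental, conversion and heteroduplex columns with short runs.
random_strand_matrix <- function(m = 20, chrom = "chrR") {
  base <- c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L)
  G <- matrix(base, 8, m)
  n_edit <- sample(0:6, 1)
  for (e in seq_len(n_edit)) {
    j <- sort(sample.int(m, 2, replace = TRUE))
    rows <- sample.int(8, sample(1:3, 1))
    G[rows, j[1]:j[2]] <- sample(0:1, length(rows), replace = TRUE)
  }
  strand_matrix(G, chrom, 500 * seq_len(m))
}

run_octad <- function(strands, ...) {
  lapply(call_events_meiosis(strands, ...), classify_events)
}
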