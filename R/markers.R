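#' Generate a synthetic hybrid marker map
#'
#' Diagnostic polymorphisms distinguishing the two parental genomes are
#' placed along each chromosome with exponentially distributed inter-marker
#' gaps, emulating the roughly random spread of SNPs/indels in an
#' S288c x SK1 hybrid (about 65,000 markers at a mean spacing of 169 bp
#' genome-wide).
#'
#' @param genome A [genome_model()].
#' @param mean_spacing Mean inter-marker gap in bp (default 169).
#' @param indel_fraction Fraction of markers that are indels (default 0.058,
#'   i.e. roughly 4,000 indels among 68,500 markers); indels are split evenly
#'   between insertions and deletions.
#' @param seed Optional integer seed.
#'
#' @return A `marker_map` data frame with columns `chrom`, `pos` (1-based,
#'   strictly increasing within a chromosome), `allele_A`, `allele_B`, and
#'   `kind` (`"SNP"`, `"insertion"` or `"deletion"`).
#' @export
generate_marker_map <- function(genome, mean_spacing = 169,
                                indel_fraction = 0.058, seed = NULL) {
  if (!is.finite(mean_spacing) || mean_spacing <= 0)
    stop("`mean_spacing` must be > 0", call. = FALSE)
  if (indel_fraction < 0 || indel_fraction > 1)
    stop("`indel_fraction` must be in [0, 1]", call. = FALSE)
  with_seed(seed, {
    maps <- lapply(seq_len(nrow(genome)), function(i) {
      L <- genome$length[i]
      ## draw a comfortable surplus of gaps, then truncate at the chromosome end
      n_guess <- max(16L, ceiling(1.5 * L / mean_spacing) + 16L)
      pos <- numeric(0)
      last <- 0
      repeat {
        gaps <- pmax(1, round(stats::rexp(n_guess, rate = 1 / mean_spacing)))
        pos <- c(pos, last + cumsum(gaps))
        last <- pos[length(pos)]
        if (last > L) break
      }
      pos <- pos[pos <= L]
      if (!length(pos)) return(NULL)
      data.frame(chrom = genome$chrom[i], pos = pos, stringsAsFactors = FALSE)
    })
    map <- do.call(rbind, maps)
    if (is.null(map)) {
      map <- data.frame(chrom = character(0), pos = numeric(0))
    }
    n <- nrow(map)
    bases <- c("A", "C", "G", "T")
    map$allele_A <- sample(bases, n, replace = TRUE)
    map$allele_B <- vapply(map$allele_A,
                           function(a) sample(setdiff(bases, a), 1L), "")
    kind <- rep("SNP", n)
    n_indel <- round(indel_fraction * n)
    if (n_indel > 0) {
      idx <- sample.int(n, n_indel)
      kind[idx] <- sample(c("insertion", "deletion"), n_indel, replace = TRUE)
      map$allele_B[idx] <- ifelse(kind[idx] == "insertion",
                                  paste0("+", map$allele_A[idx]), "-")
    }
    map$kind <- kind
    class(map) <- c("marker_map", "data.frame")
    validate_marker_map(map)
    map
  })
}

validate_marker_map <- function(map) {
  need <- c("chrom", "pos", "allele_A", "allele_B", "kind")
  miss <- setdiff(need, names(map))
  if (length(miss))
    stop("marker map is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(map$kind %in% c("SNP", "insertion", "deletion")))
    stop("marker `kind` must be SNP, insertion or deletion", call. = FALSE)
  bad <- unlist(lapply(split(map$pos, map$chrom),
                       function(p) any(diff(p) <= 0)))
  if (any(bad))
    stop("marker positions must be strictly increasing within a chromosome",
         call. = FALSE)
  invisible(map)
}

## Markers of one chromosome, in map order.
map_chrom <- function(map, chrom) map[map$chrom == chrom, , drop = FALSE]
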