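#' Parameters for the synthetic-meiosis simulator
#'
#' Defaults describe a wild-type meiosis of the S288c x SK1 hybrid: about
#' 74.5 crossovers and 30.5 detectable noncrossovers per meiosis, read depth
#' 44x, and heteroduplex tracts on the scale of meiotic DSB resection
#' (~1.5 kb).  Interference is expressed as the shape of the gamma
#' distribution from which successive inter-crossover distances are drawn
#' (shape 1 = exponential = no interference).
#'
#' @param mean_co Expected number of crossovers per meiosis, distributed
#'   across chromosomes proportionally to length.
#' @param mean_nco Expected number of simple noncrossovers per meiosis.
#' @param interference_shape Gamma shape for inter-CO distance sampling
#'   (>= 1e-2); 1 gives random (exponential) placement.
#' @param tract_mean,tract_sd Mean and sd (bp) of the per-side heteroduplex /
#'   conversion tract length (truncated normal, minimum 50 bp).
#' @param mmr `"deficient"` (msh2-delta-like: heteroduplex retained) or
#'   `"proficient"` (each tract fully converted or restored).
#' @param p_conversion In MMR-proficient meioses, probability that a tract is
#'   converted rather than restored.  The 0.5 default is a free modelling
#'   choice, not an empirical estimate.
#' @param p_gap_conversion In MMR-deficient meioses, probability that a tract
#'   appears as a full-conversion (6:2-type) patch, emulating double-strand
#'   gap repair, rather than as retained heteroduplex (5:3-type).
#' @param multi_dsb_rate Expected number of multi-DSB event clusters per
#'   meiosis (double COs, double NCOs, CO+NCO; ~5% of events in wild type).
#' @param multi_spacing_max Maximum within-cluster DSB spacing in bp
#'   (must be < 1500 so clusters are called as single events).
#' @param depth_mean Mean sequencing depth per marker.
#' @param error_rate Per-read error probability (in `[0, 0.5)`).
#' @param seed Default seed used by [simulate_meiosis()] when none is given.
#'
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(mean_co = 74.5, mean_nco = 30.5,
                       interference_shape = 2,
                       tract_mean = 1500, tract_sd = 500,
                       mmr = c("deficient", "proficient"),
                       p_conversion = 0.5, p_gap_conversion = 0.25,
                       multi_dsb_rate = 5, multi_spacing_max = 1400,
                       depth_mean = 44, error_rate = 0.002, seed = NULL) {
  mmr <- match.arg(mmr)
  stopifnot(
    mean_co >= 0, mean_nco >= 0, interference_shape >= 1e-2,
    tract_mean > 0, tract_sd >= 0,
    p_conversion >= 0, p_conversion <= 1,
    p_gap_conversion >= 0, p_gap_conversion <= 1,
    multi_dsb_rate >= 0, multi_spacing_max > 0, multi_spacing_max < 1500,
    depth_mean > 0, error_rate >= 0, error_rate < 0.5
  )
  structure(list(
    mean_co = mean_co, mean_nco = mean_nco,
    interference_shape = interference_shape,
    tract_mean = tract_mean, tract_sd = tract_sd, mmr = mmr,
    p_conversion = p_conversion, p_gap_conversion = p_gap_conversion,
    multi_dsb_rate = multi_dsb_rate, multi_spacing_max = multi_spacing_max,
    depth_mean = depth_mean, error_rate = error_rate, seed = seed
  ), class = "sim_params")
}

## Per-side tract length: truncated normal, floor 50 bp.
draw_tract_len <- function(n, params) {
  pmax(50, stats::rnorm(n, params$tract_mean, params$tract_sd))
}

#' Simulate one meiosis of the hybrid cross
#'
#' Plants crossovers, noncrossovers and (optionally) multi-DSB clusters on a
#' marker map and returns the resulting post-repair 8-strand genotype
#' matrices together with a ground-truth event table.
#'
#' Crossover positions are placed per chromosome by sampling successive
#' inter-CO distances from a gamma distribution with shape
#' `interference_shape` and a scale chosen so that the expected genome-wide
#' CO count equals `mean_co`.  Each CO reciprocally exchanges the flanking
#' haplotypes of one parent-A and one parent-B chromatid (chosen uniformly)
#' and deposits heteroduplex tracts on the two recombining chromatids,
#' extending away from the exchange point.  NCOs are placed uniformly and
#' deposit a single tract on one chromatid.  Under MMR deficiency each tract
#' is retained as a mother/daughter strand mismatch (5:3-type) or appears as
#' a full-conversion patch (see `p_gap_conversion`); under MMR proficiency
#' it is fully converted or silently restored.
#'
#' Multi-DSB clusters inject a second DSB within `multi_spacing_max` bp on a
#' distinct chromatid, producing the four conservative multi-DSB categories:
#' double CO (four-chromatid double reciprocal exchange), CO+NCO on a third
#' chromatid, double NCO on sisters, and double NCO on homologues with
#' perfectly overlapping tracts.
#'
#' @param map A `marker_map` (see [generate_marker_map()]).
#' @param genome A [genome_model()].
#' @param params A [sim_params()] list.
#' @param seed Integer seed (defaults to `params$seed`).
#'
#' @return A list with elements
#'   * `strands`: named list of [strand_matrix()] objects, one per
#'     chromosome that carries markers;
#'   * `truth`: data frame of planted events (`event_id`, `chrom`, `kind`,
#'     `pos`, `pos2`, `chromatids`, `outcome`, `tract_start`, `tract_end`,
#'     `n_tract_markers`, `detectable`);
#'   * `co_per_chrom`: named integer vector of *observable* CO counts per
#'     chromosome: haplotype switches between successive Mendelian marker
#'     columns of the finished matrices.  Crossovers beyond the terminal
#'     markers, or whose tracts run into a chromosome end (type-U events),
#'     are unobservable by construction and are not counted.
#' @export
simulate_meiosis <- function(map, genome, params = sim_params(), seed = params$seed) {
  validate_marker_map(map)
  if (!nrow(map)) stop("marker map is empty", call. = FALSE)
  with_seed(seed, {
    plans <- plan_meiosis(genome, params)
    strands <- list()
    truth <- list()
    co_obs <- stats::setNames(integer(nrow(genome)), genome$chrom)
    for (i in seq_len(nrow(genome))) {
      chr <- genome$chrom[i]
      mk <- map_chrom(map, chr)
      if (!nrow(mk)) next
      res <- simulate_chromosome(mk$pos, genome$length[i],
                                 plans[[chr]], params)
      strands[[chr]] <- strand_matrix(res$S, chr, mk$pos,
                                      marker_idx = as.integer(rownames(mk)))
      co_obs[chr] <- res$co_observable
      if (nrow(res$truth)) res$truth$chrom <- chr
      truth[[chr]] <- res$truth
    }
    truth <- do.call(rbind, truth)
    if (is.null(truth)) truth <- empty_truth()
    rownames(truth) <- NULL
    truth$event_id <- seq_len(nrow(truth))
    list(strands = strands, truth = truth, co_per_chrom = co_obs)
  })
}

empty_truth <- function() {
  data.frame(event_id = integer(0), chrom = character(0), kind = character(0),
             pos = numeric(0), pos2 = numeric(0), chromatids = character(0),
             outcome = character(0), tract_start = numeric(0),
             tract_end = numeric(0), n_tract_markers = integer(0),
             detectable = logical(0), stringsAsFactors = FALSE)
}

## Decide event kinds, chromosomes and positions for a whole meiosis.
## Returns a per-chromosome list of plan data frames.
plan_meiosis <- function(genome, params) {
  plans <- stats::setNames(vector("list", nrow(genome)), genome$chrom)
  for (i in seq_len(nrow(genome))) {
    L <- genome$length[i]
    ## interfering renewal process for COs
    n_exp <- params$mean_co * genome$p[i]
    co_pos <- numeric(0)
    if (n_exp > 0) {
      gap_mean <- L / n_exp
      scale <- gap_mean / params$interference_shape
      x <- 0
      repeat {
        x <- x + stats::rgamma(1, shape = params$interference_shape, scale = scale)
        if (x > L) break
        co_pos <- c(co_pos, x)
      }
    }
    n_nco <- stats::rpois(1, params$mean_nco * genome$p[i])
    nco_pos <- sort(stats::runif(n_nco, 1, L))
    plans[[i]] <- data.frame(
      kind = c(rep("CO", length(co_pos)), rep("NCO", length(nco_pos))),
      pos = c(co_pos, nco_pos), stringsAsFactors = FALSE
    )
  }
  ## multi-DSB clusters, allocated length-proportionally
  n_multi <- stats::rpois(1, params$multi_dsb_rate)
  if (n_multi > 0) {
    kinds <- sample(c("dCO", "dNCO_sister", "dNCO_overlap", "CO_plus_NCO"),
                    n_multi, replace = TRUE)
    chroms <- sample(genome$chrom, n_multi, replace = TRUE, prob = genome$p)
    for (j in seq_len(n_multi)) {
      L <- genome$length[match(chroms[j], genome$chrom)]
      x <- stats::runif(1, 0.05 * L, 0.95 * L)
      plans[[chroms[j]]] <- rbind(plans[[chroms[j]]],
                                  data.frame(kind = kinds[j], pos = x,
                                             stringsAsFactors = FALSE))
    }
  }
  plans
}

## Core per-chromosome engine: applies CO exchanges on the 4 chromatid
## haplotypes, expands to 8 strands, deposits tracts, records truth.
## Crossover partners are chosen by local haplotype content — one chromatid
## carrying the parent-A and one carrying the parent-B haplotype at the
## exchange point — as in a real meiosis, where exchanges join the two
## homologues whatever mosaic the chromatids already are.
simulate_chromosome <- function(pos, L, plan, params) {
  m <- length(pos)
  H <- rbind(matrix(1L, 2, m), matrix(0L, 2, m))  # chromatids x markers
  tracts <- list()        # chromatid, start, end (half-open), id
  truth <- list()
  if (is.null(plan) || !nrow(plan)) plan <- data.frame(kind = character(0), pos = numeric(0))
  plan <- plan[order(plan$pos), , drop = FALSE]
  id <- 0
  new_truth <- function(kind, pos, pos2, chromatids, outcome, ts, te) {
    data.frame(event_id = NA_integer_, chrom = NA_character_, kind = kind,
               pos = pos, pos2 = pos2,
               chromatids = paste(sort(chromatids), collapse = ","),
               outcome = outcome, tract_start = ts, tract_end = te,
               n_tract_markers = NA_integer_, detectable = NA,
               stringsAsFactors = FALSE)
  }
  draw_outcome <- function() {
    if (params$mmr == "deficient") {
      if (stats::runif(1) < params$p_gap_conversion) "converted" else "retained-hDNA"
    } else {
      if (stats::runif(1) < params$p_conversion) "converted" else "restored"
    }
  }
  ## haplotype content of the 4 chromatids just right of x
  content_at <- function(x) {
    j <- which(pos > x)
    H[, if (length(j)) j[1] else m]
  }
  apply_co <- function(x, exclude = integer(0)) {
    idv <- content_at(x)
    cand_a <- setdiff(which(idv == 1L), exclude)
    cand_b <- setdiff(which(idv == 0L), exclude)
    a <- cand_a[sample.int(length(cand_a), 1)]
    b <- cand_b[sample.int(length(cand_b), 1)]
    j <- which(pos > x)
    if (length(j)) {
      tmp <- H[a, j]; H[a, j] <<- H[b, j]; H[b, j] <<- tmp
    }
    lenL <- draw_tract_len(1, params); lenR <- draw_tract_len(1, params)
    oL <- draw_outcome(); oR <- draw_outcome()
    tracts[[length(tracts) + 1]] <<-
      list(chromatid = a, start = x - lenL, end = x, outcome = oL, id = id)
    tracts[[length(tracts) + 1]] <<-
      list(chromatid = b, start = x, end = x + lenR, outcome = oR, id = id)
    list(a = a, b = b, start = x - lenL, end = x + lenR,
         outcome = paste(oL, oR, sep = "|"))
  }
  add_nco <- function(x, k, outcome = draw_outcome(),
                      lenL = draw_tract_len(1, params),
                      lenR = draw_tract_len(1, params)) {
    tracts[[length(tracts) + 1]] <<-
      list(chromatid = k, start = x - lenL, end = x + lenR,
           outcome = outcome, id = id)
    list(start = x - lenL, end = x + lenR, outcome = outcome)
  }
  for (r in seq_len(nrow(plan))) {
    kind <- plan$kind[r]; x <- plan$pos[r]
    id <- id + 1
    if (kind == "CO") {
      co <- apply_co(x)
      truth[[id]] <- new_truth("CO", x, NA, c(co$a, co$b), co$outcome,
                               co$start, co$end)
    } else if (kind == "NCO") {
      k <- sample(1:4, 1)
      tr <- add_nco(x, k)
      truth[[id]] <- new_truth("NCO", x, NA, k, tr$outcome, tr$start, tr$end)
    } else {
      delta <- stats::runif(1, 100, params$multi_spacing_max)
      x2 <- min(x + delta, L)
      if (kind == "dCO") {
        co1 <- apply_co(x)
        co2 <- apply_co(x2, exclude = c(co1$a, co1$b))
        truth[[id]] <- new_truth("dCO", x, x2, 1:4,
                                 paste(co1$outcome, co2$outcome, sep = "|"),
                                 min(co1$start, co2$start),
                                 max(co1$end, co2$end))
      } else if (kind == "CO_plus_NCO") {
        co <- apply_co(x)
        third <- sample(setdiff(1:4, c(co$a, co$b)), 1)
        tr <- add_nco(x2, third)
        truth[[id]] <- new_truth("CO_plus_NCO", x, x2, c(co$a, co$b, third),
                                 paste(co$outcome, tr$outcome, sep = "|"),
                                 min(co$start, tr$start), max(co$end, tr$end))
      } else if (kind == "dNCO_sister") {
        par0 <- sample(c(0L, 2L), 1)
        k1 <- par0 + 1L; k2 <- par0 + 2L
        tr1 <- add_nco(x, k1)
        tr2 <- add_nco(x2, k2)
        truth[[id]] <- new_truth("dNCO_sister", x, x2, c(k1, k2),
                                 paste(tr1$outcome, tr2$outcome, sep = "|"),
                                 min(tr1$start, tr2$start),
                                 max(tr1$end, tr2$end))
      } else { # dNCO_overlap: identical tract on two homologues
        kA <- sample(1:2, 1); kB <- sample(3:4, 1)
        lenL <- draw_tract_len(1, params); lenR <- draw_tract_len(1, params)
        o <- draw_outcome()
        tr1 <- add_nco(x, kA, outcome = o, lenL = lenL, lenR = lenR)
        tr2 <- add_nco(x, kB, outcome = o, lenL = lenL, lenR = lenR)
        truth[[id]] <- new_truth("dNCO_overlap", x, x, c(kA, kB), o,
                                 tr1$start, tr1$end)
      }
    }
  }
  ## expand to 8 strands and deposit tracts
  S <- H[rep(1:4, each = 2), , drop = FALSE]
  n_tr_markers <- integer(length(truth))
  for (tr in tracts) {
    j <- which(pos >= tr$start & pos < tr$end)
    n_tr_markers[tr$id] <- n_tr_markers[tr$id] + length(j)
    if (!length(j) || tr$outcome == "restored") next
    rows <- chromatid_rows(tr$chromatid)
    if (tr$outcome == "retained-hDNA") {
      S[rows[2], j] <- 1L - S[rows[2], j]       # daughter strand mismatch
    } else {                                    # converted
      S[rows[1], j] <- 1L - S[rows[1], j]
      S[rows[2], j] <- 1L - S[rows[2], j]
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else empty_truth()
  if (nrow(truth)) {
    truth$n_tract_markers <- n_tr_markers
    is_co <- truth$kind %in% c("CO", "dCO", "CO_plus_NCO")
    truth$detectable <- ifelse(
      is_co,
      truth$pos > min(pos) & truth$pos < max(pos),
      n_tr_markers > 0 & truth$outcome != "restored"
    )
  }
  list(S = S, truth = truth, co_observable = co_observable(S))
}

## Observable crossover count of a finished strand matrix: haplotype
## switches between successive Mendelian (concordant 4:4) marker columns,
## divided by two.  Exchanges that are never framed by Mendelian columns
## (e.g. tracts running into a chromosome end) are unobservable by the
## event-calling method and are not counted.
co_observable <- function(S) {
  conc <- S[c(1, 3, 5, 7), , drop = FALSE] == S[c(2, 4, 6, 8), , drop = FALSE]
  mend <- colSums(conc) == 4L & colSums(S) == 4L
  ids <- S[c(1, 3, 5, 7), mend, drop = FALSE]
  if (ncol(ids) < 2) return(0L)
  as.integer(sum(ids[, -1, drop = FALSE] != ids[, -ncol(ids), drop = FALSE]) / 2)
}
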