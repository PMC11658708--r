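## Independent brute-force oracles used across the suite.  These are kept
## deliberately naive and separate from the package implementation.

## Run-length segmentation oracle: walk columns one by one, start a new
## segment whenever the complete 8-strand vector changes; label patterns
## from first principles.
seg_oracle <- function(sm) {
  G <- unclass(sm)
  keep <- which(colSums(is.na(G)) == 0L)
  out <- list()
  prev <- NULL
  for (idx in seq_along(keep)) {
    j <- keep[idx]
    v <- paste(G[, j], collapse = "")
    if (is.null(prev) || v != prev) {
      out[[length(out) + 1]] <- list(first_idx = j, last_idx = j, vec = v)
    } else {
      out[[length(out)]]$last_idx <- j
    }
    prev <- v
  }
  lab <- function(v) {
    g <- as.integer(strsplit(v, "")[[1]])
    cA <- sum(g)
    disc <- any(g[c(1, 3, 5, 7)] != g[c(2, 4, 6, 8)])
    star <- (cA %% 2L == 0L) && disc
    paste0(cA, ":", 8L - cA, if (star) "*")
  }
  data.frame(first_idx = vapply(out, `[[`, 0L, "first_idx"),
             last_idx = vapply(out, `[[`, 0L, "last_idx"),
             pattern = vapply(out, function(s) lab(s$vec), ""),
             vec = vapply(out, `[[`, "", "vec"),
             stringsAsFactors = FALSE)
}

## Crossover count oracle: identity changes between successive Mendelian
## (concordant 4:4) complete columns, divided by two.
co_switch_oracle <- function(sm) {
  G <- unclass(sm)
  ok <- colSums(is.na(G)) == 0L
  conc <- G[c(1, 3, 5, 7), , drop = FALSE] == G[c(2, 4, 6, 8), , drop = FALSE]
  mend <- ok & colSums(conc) == 4L & colSums(G) == 4L
  ids <- G[c(1, 3, 5, 7), mend, drop = FALSE]
  if (ncol(ids) < 2) return(0L)
  as.integer(sum(ids[, -1, drop = FALSE] != ids[, -ncol(ids), drop = FALSE]) / 2)
}

## All-pairs half-open interval intersection oracle.
overlap_oracle <- function(span, hs) {
  any(hs$start < span[2] & span[1] < hs$end)
}

## Benjamini-Hochberg from the definition: min over the tail of p * m / rank.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) adj[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

## Two-sided Fisher exact p by hypergeometric enumeration.
fisher_oracle <- function(m) {
  x <- m[1, 1]; r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  d <- stats::dhyper(lo:hi, r1, n - r1, c1)
  sum(d[d <= stats::dhyper(x, r1, n - r1, c1) * (1 + 1e-7)])
}

## Two-sided Wilcoxon rank-sum, normal approximation with continuity and
## tie corrections, assembled from the textbook formulas.
wilcox_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  z <- W - n1 * n2 / 2
  nt <- table(r)
  sigma <- sqrt((n1 * n2 / 12) *
                  ((n1 + n2 + 1) - sum(nt^3 - nt) / ((n1 + n2) * (n1 + n2 - 1))))
  z <- (z - sign(z) * 0.5) / sigma
  min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
}

## Exact two-sample two-sided Kolmogorov-Smirnov by lattice-path counting
## (valid without ties).
ks_exact_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  w <- c(x, y)
  z <- cumsum(ifelse(order(w) <= m, 1 / m, -1 / n))
  D <- max(abs(z))
  A <- matrix(0, m + 1, n + 1)
  A[1, 1] <- 1
  for (i in 0:m) for (j in 0:n) {
    if (i == 0 && j == 0) next
    if (abs(i / m - j / n) >= D - 1e-12) next
    A[i + 1, j + 1] <- (if (i > 0) A[i, j + 1] else 0) +
      (if (j > 0) A[i + 1, j] else 0)
  }
  A[m + 1, n + 1] <- A[m, n + 1] + A[m + 1, n]
  p <- 1 - A[m + 1, n + 1] / choose(m + n, n)
  list(D = D, p = max(0, min(1, p)))
}
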