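# Independent oracles used across the suite. These deliberately use the
# slowest, most transparent formulation available so they stay
# independent of the package's implementations.

# all-pairs nearest-neighbor oracle: full distance matrix, which.min
# (lowest index wins ties, matching the stated tie-break)
nnd_bruteforce <- function(x, y) {
  n <- length(x)
  D <- as.matrix(stats::dist(cbind(x, y)))
  diag(D) <- Inf
  nb <- apply(D, 1, which.min)
  list(nnd = D[cbind(seq_len(n), nb)], neighbor = unname(nb))
}

# exhaustive two-sided Fisher p: enumerate every table with the observed
# margins via the hypergeometric point probability written out with
# lchoose, and sum the outcomes no more probable than the observed one
# (1e-7 relative tolerance for floating-point ties, the convention of
# standard software)
fisher_enumeration_oracle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  support <- max(0, k - n2):min(m, k)
  logp <- lchoose(m, support) + lchoose(n2, k - support) -
    lchoose(m + n2, k)
  p <- exp(logp)
  pobs <- p[support == a]
  min(1, sum(p[p <= pobs * (1 + 1e-7)]))
}

# random 2x2 table with total at most nmax (all cells >= 0, total >= 1)
random_table <- function(nmax = 40) {
  repeat {
    cnt <- as.integer(stats::rmultinom(1, sample.int(nmax, 1), rep(1, 4)))
    if (sum(cnt) > 0) return(cnt)
  }
}

# greedy one-to-one matching of detected centroids to ground truth;
# returns per-detection distance to its matched truth (Inf if unmatched)
match_to_truth <- function(det_x, det_y, true_x, true_y) {
  nd <- length(det_x); nt <- length(true_x)
  D <- sqrt(outer(det_x, true_x, "-")^2 + outer(det_y, true_y, "-")^2)
  used <- rep(FALSE, nt)
  out <- rep(Inf, nd)
  for (i in order(apply(D, 1, min))) {
    j <- which.min(ifelse(used, Inf, D[i, ]))
    if (is.finite(D[i, j])) {
      out[i] <- D[i, j]
      used[j] <- TRUE
    }
  }
  out
}
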