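# Independent reference implementations used to cross-check the package.

# All permutations of 1:m in lexicographic order, built by explicit
# recursion (independent of the package's internal table).
oracle_perms <- function(m) {
  if (m == 1) return(matrix(1L, 1, 1))
  sub <- oracle_perms(m - 1)
  do.call(rbind, lapply(seq_len(m), function(first) {
    rest <- setdiff(seq_len(m), first)
    cbind(first, matrix(rest[sub], nrow(sub)))
  }))
}

# Ordinal code of each window by explicit stable sort and permutation
# lookup among all m! candidates.
oracle_encode <- function(x, m = 5, tau = 1) {
  perms <- oracle_perms(m)
  npat <- length(x) - (m - 1) * tau
  vapply(seq_len(npat), function(i) {
    w <- x[i + (seq_len(m) - 1) * tau]
    o <- order(w)  # stable: earlier index wins ties
    which(apply(perms, 1, function(p) all(p == o))) - 1L
  }, integer(1))
}

# Transfer entropy by explicit tabulation of the four distributions over
# the common index range, each term computed with its own table() call.
oracle_te <- function(x, y, delta) {
  rng <- seq_len(length(x) - delta)
  h <- function(...) {
    p <- table(...) / length(rng)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  h(y[rng], y[rng + delta]) - h(y[rng]) -
    h(x[rng], y[rng], y[rng + delta]) + h(x[rng], y[rng])
}

# Exhaustive threshold scan: every observed score and points just below /
# beyond the extremes; returns the best achievable accuracy.
oracle_best_accuracy <- function(samples) {
  v <- sort(unique(samples$score))
  eps <- min(diff(c(v, v[length(v)] + 1))) / 2
  cand <- sort(c(v, v - eps, v[1] - 1, v[length(v)] + 1))
  max(vapply(cand, function(th) {
    mean((samples$score > th) == samples$responsive)
  }, numeric(1)))
}

# Cyclic de Bruijn-style sequence over K = 4 symbols in which every ordered
# pair of consecutive symbols occurs exactly once (verified in the tests).
debruijn4 <- function() {
  c(0L, 0L, 1L, 0L, 2L, 0L, 3L, 1L, 1L, 2L, 1L, 3L, 2L, 2L, 3L, 3L)
}
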