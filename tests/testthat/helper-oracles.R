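# Independent brute-force oracles; deliberately naive implementations.

# All perfect matchings of an even-sized index set, as lists of 2-column
# matrices ((2n-1)!! of them).
enumerate_matchings <- function(idx) {
  if (!length(idx)) return(list(matrix(integer(), 0, 2)))
  i <- idx[1]
  out <- list()
  for (j in idx[-1]) {
    rest <- setdiff(idx, c(i, j))
    for (m in enumerate_matchings(rest)) {
      out[[length(out) + 1L]] <- rbind(c(i, j), m)
    }
  }
  out
}

# Minimum total cost over all perfect matchings.
brute_min_matching_cost <- function(cost) {
  best <- Inf
  for (m in enumerate_matchings(seq_len(nrow(cost)))) {
    tot <- sum(apply(m, 1, function(pr) cost[pr[1], pr[2]]))
    if (tot < best) best <- tot
  }
  best
}

matching_cost <- function(cost, pairs) {
  sum(apply(pairs, 1, function(pr) cost[pr[1], pr[2]]))
}

# Cophenetic distances straight from the merge matrix: the height at which
# two leaves first share a cluster (independent of stats::cophenetic).
brute_cophenetic <- function(tree) {
  n <- length(tree$labels)
  cm <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  members <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    side <- function(v) if (v < 0) -v else members[[v]]
    a <- side(tree$merge[k, 1]); b <- side(tree$merge[k, 2])
    for (i in a) for (j in b) cm[i, j] <- cm[j, i] <- tree$height[k]
    members[[k]] <- c(a, b)
  }
  cm
}

# Pairing cost used by the package, recomputed from first principles.
oracle_pair_cost <- function(p, q) {
  cl <- p + q
  ci <- 100 * p / cl
  abs(outer(cl, cl, "-")) / mean(cl) + abs(outer(ci, ci, "-")) / 50
}
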