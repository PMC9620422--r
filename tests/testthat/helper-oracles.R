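# Independent oracles used to cross-check package computations. Each is a
# deliberately naive re-derivation from first principles (or an unrelated
# library), kept free of the package's own code paths.

# Bounded-BFS h-hop downstream neighborhood via igraph's ego machinery.
oracle_hln_igraph <- function(net, h) {
  skip_if_not_installed("igraph")
  g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                     vertices = data.frame(name = net$nodes))
  sizes <- igraph::ego_size(g, order = h, mode = "out")
  stats::setNames(as.integer(sizes) - 1L, igraph::V(g)$name)[net$nodes]
}

# Full descendant set size (transitive closure row) via igraph reachability.
oracle_descendants_igraph <- function(net) {
  skip_if_not_installed("igraph")
  g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                     vertices = data.frame(name = net$nodes))
  sizes <- vapply(seq_along(net$nodes), function(i) {
    length(igraph::subcomponent(g, i, mode = "out")) - 1L
  }, 1L)
  stats::setNames(as.integer(sizes), net$nodes)
}

# Step-up FDR adjustment written straight from the definition:
# q_(i) = min over j >= i of p_(j) * m / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Hypergeometric upper tail P[X >= k] by direct summation of point masses.
oracle_hyper_tail <- function(N, K, n, k) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Running-sum enrichment score as an explicit position-by-position loop,
# returning the whole running sum plus the signed extremum (positive wins an
# exact tie between the maximal positive and negative deviations).
oracle_es <- function(genes, stat, gene_set, exponent) {
  L <- length(genes)
  hit <- genes %in% gene_set
  nh <- sum(hit)
  wsum <- sum(abs(stat[hit])^exponent)
  running <- numeric(L)
  acc <- 0
  for (i in seq_len(L)) {
    acc <- acc + if (hit[i]) {
      if (wsum > 0) abs(stat[i])^exponent / wsum else 1 / nh
    } else {
      -1 / (L - nh)
    }
    running[i] <- acc
  }
  es <- if (max(running) >= -min(running)) max(running) else min(running)
  list(running = running, es = es)
}

# Compare a package enrichment_score() result against the oracle. The two
# accumulate in different order/precision, so running sums are compared at
# 1e-12; at a mathematically exact tie between the positive and negative
# extremum the sign is a convention, so only the magnitude is asserted there.
expect_es_matches_oracle <- function(rk, gene_set, exponent) {
  got <- enrichment_score(rk, gene_set, exponent)
  ora <- oracle_es(rk$genes, rk$statistic, gene_set, exponent)
  expect_equal(got$running_sum, ora$running, tolerance = 1e-12)
  near_tie <- abs(max(ora$running) + min(ora$running)) < 1e-9
  if (near_tie) {
    expect_equal(abs(got$es), abs(ora$es), tolerance = 1e-12)
  } else {
    expect_equal(got$es, ora$es, tolerance = 1e-12)
  }
}

# Seeded Erdos-Renyi digraph over letter-number gene names.
random_digraph <- function(n, p, seed) {
  set.seed(seed)
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- stats::runif(nrow(pairs)) < p
  nm <- sprintf("n%02d", seq_len(n))
  suppressMessages(gene_network(nm[pairs$from[keep]], nm[pairs$to[keep]],
                                nodes = nm))
}
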