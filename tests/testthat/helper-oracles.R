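# Independent oracles and small fixture builders used across the suite.

# Naive quadratic Benjamini-Hochberg: for each p_i, the minimum over all
# thresholds p_j >= p_i of m * p_j / #{k: p_k <= p_j}, capped at 1.
naive_bh <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    cand <- p[p >= pi]
    min(1, min(vapply(cand, function(pj) m * pj / sum(p <= pj), numeric(1))))
  }, numeric(1))
}

# Counting-based average ranks (no calls to rank()): rank of x_i is
# #{j: x_j < x_i} + (ties including self + 1) / 2.
counting_ranks <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))
}

# Spearman rho as Pearson on counting ranks, written out long-hand.
oracle_spearman <- function(x, y) {
  rx <- counting_ranks(x)
  ry <- counting_ranks(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# All set partitions of 1..n (restricted-growth strings); returns a list of
# integer block labels, used to enumerate tie patterns exhaustively.
set_partitions <- function(n) {
  out <- list()
  rec <- function(labels, next_max) {
    k <- length(labels)
    if (k == n) {
      out[[length(out) + 1]] <<- labels
      return()
    }
    for (b in seq_len(next_max + 1))
      rec(c(labels, b), max(next_max, b))
  }
  rec(integer(0), 0L)
  out
}

# A tie pattern (block labels) becomes a data vector by assigning each block
# a distinct value; which value ordering is irrelevant for ranks up to
# monotone relabelling, so we use the labels themselves.
pattern_to_values <- function(pattern) as.numeric(pattern)

# Pooled-pipeline helper: filter -> relative abundance -> Spearman -> BH ->
# threshold -> network, over all samples at once.
pooled_network <- function(otu, policy = coocnet::threshold_policy()) {
  kept <- coocnet::filter_otus(otu)
  rel <- coocnet::relative_abundance(otu)[kept, , drop = FALSE]
  sp <- coocnet::spearman_matrix(rel)
  q <- sp$rho * NA
  ut <- upper.tri(sp$p)
  q[ut] <- coocnet::bh_fdr(sp$p[ut])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  coocnet::build_network(sp$rho, q, policy)
}

# Five toy graphs with hand-enumerated within-module degrees and
# participation coefficients under the given partitions.
toy_role_graphs <- function() {
  list(
    # 1: two triangles joined by one bridge; partition = the triangles.
    list(
      g = igraph::graph_from_edgelist(rbind(
        c("a1", "a2"), c("a2", "a3"), c("a1", "a3"),
        c("b1", "b2"), c("b2", "b3"), c("b1", "b3"),
        c("a1", "b1")), directed = FALSE),
      memb = c(a1 = 1, a2 = 1, a3 = 1, b1 = 2, b2 = 2, b3 = 2),
      # internal degrees all 2 -> sd 0 -> Z = 0 everywhere
      z = c(a1 = 0, a2 = 0, a3 = 0, b1 = 0, b2 = 0, b3 = 0),
      # a1: k=3, 2 internal + 1 external: 1 - (2/3)^2 - (1/3)^2 = 4/9
      c_ = c(a1 = 4 / 9, a2 = 0, a3 = 0, b1 = 4 / 9, b2 = 0, b3 = 0)
    ),
    # 2: star K1,4, all in one module: kappa = (4,1,1,1,1),
    # mu = 8/5, sd = sqrt(sum((k-mu)^2)/4) = sqrt(7.2/4)
    list(
      g = igraph::make_star(5, mode = "undirected", center = 1),
      memb = setNames(rep(1, 5), as.character(1:5)),
      z = setNames(c((4 - 8 / 5), rep(1 - 8 / 5, 4)) / sqrt(7.2 / 4),
                   as.character(1:5)),
      c_ = setNames(rep(0, 5), as.character(1:5))
    ),
    # 3: path a-b-c with singleton modules: all internal degrees 0, Z = 0;
    # b splits degree 2 over two foreign modules: C = 1 - 2*(1/2)^2 = 1/2;
    # a and c concentrate their single link in one module: C = 0
    list(
      g = igraph::graph_from_edgelist(rbind(c("a", "b"), c("b", "c")),
                                      directed = FALSE),
      memb = c(a = 1, b = 2, c = 3),
      z = c(a = 0, b = 0, c = 0),
      c_ = c(a = 0, b = 0.5, c = 0)
    ),
    # 4: node x with degree 4 split evenly over 4 modules -> C = 0.75
    list(
      g = igraph::graph_from_edgelist(rbind(
        c("x", "m1"), c("x", "m2"), c("x", "m3"), c("x", "m4")),
        directed = FALSE),
      memb = c(x = 1, m1 = 2, m2 = 3, m3 = 4, m4 = 5),
      z = c(x = 0, m1 = 0, m2 = 0, m3 = 0, m4 = 0),
      c_ = c(x = 0.75, m1 = 0, m2 = 0, m3 = 0, m4 = 0)
    ),
    # 5: triangle + pendant, one module: kappa = (3,2,2,1), mu = 2,
    # sd = sqrt((1+0+0+1)/3)
    list(
      g = igraph::graph_from_edgelist(rbind(
        c("p", "q"), c("q", "r"), c("p", "r"), c("p", "s")),
        directed = FALSE),
      memb = c(p = 1, q = 1, r = 1, s = 1),
      z = c(p = 1, q = 0, r = 0, s = -1) / sqrt(2 / 3),
      c_ = c(p = 0, q = 0, r = 0, s = 0)
    )
  )
}

# Small planted-module OTU table for fast pipeline tests.
quick_sim <- function(seed = 1, ...) {
  cfg <- coocnet::sim_config(fractions = "FL", seed = seed, ...)
  coocnet::simulate_survey(cfg)
}
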