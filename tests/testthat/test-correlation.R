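test_that("Spearman handles monotone, anti-monotone and tied data", {
  X <- rbind(x = c(1, 2, 3, 4), y = c(10, 20, 30, 40), z = c(4, 3, 2, 1))
  sp <- spearman_matrix(X)
  expect_equal(sp$rho["x", "y"], 1)
  expect_equal(sp$rho["x", "z"], -1)
  expect_equal(sp$p["x", "y"], 0)
  # tie case against the counting-rank oracle
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  sp2 <- spearman_matrix(rbind(a = x, b = y))
  expect_equal(sp2$rho["a", "b"], oracle_spearman(x, y))
  expect_equal(sp2$rho["a", "b"], cor(x, y, method = "spearman"))
})

test_that("Spearman matches the brute-force rank oracle across tie patterns", {
  # exhaustive over all set partitions (tie patterns) for n = 4, 5 on one
  # margin, against randomised partners; sampled patterns for n = 6..8
  for (n in 4:5) {
    parts <- set_partitions(n)
    set.seed(n)
    for (p in parts) {
      x <- pattern_to_values(p)
      y <- sample(pattern_to_values(parts[[sample(length(parts), 1)]]))
      if (length(unique(x)) == 1 || length(unique(y)) == 1) next
      got <- spearman_matrix(rbind(x = x, y = y))$rho["x", "y"]
      expect_equal(got, oracle_spearman(x, y), tolerance = 1e-12)
    }
  }
  set.seed(99)
  for (i in 1:200) {
    n <- sample(6:8, 1)
    x <- sample(1:3, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    got <- spearman_matrix(rbind(x = x, y = y))$rho["x", "y"]
    expect_equal(got, oracle_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("Spearman is invariant to strictly monotone transforms", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    r0 <- spearman_matrix(rbind(x = x, y = y))$rho["x", "y"]
    r1 <- spearman_matrix(rbind(x = exp(3 * x), y = y))$rho["x", "y"]
    r2 <- spearman_matrix(rbind(x = x, y = atan(y) + 10))$rho["x", "y"]
    expect_equal(r0, r1, tolerance = 1e-12)
    expect_equal(r0, r2, tolerance = 1e-12)
  }
})

test_that("Spearman matrix is symmetric, unit-diagonal, and guards inputs", {
  set.seed(4)
  X <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("v", 1:5), NULL))
  sp <- spearman_matrix(X)
  expect_equal(sp$rho, t(sp$rho))
  expect_equal(unname(diag(sp$rho)), rep(1, 5))
  expect_error(spearman_matrix(X[, 1:3]), "at least 4 samples")
  Xc <- rbind(X, const = rep(2, 10))
  spc <- spearman_matrix(Xc)
  expect_equal(spc$constant, "const")
  expect_true(all(is.na(spc$rho["const", ])))
})

test_that("BH q-values match the naive quadratic definition", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(rep(0.03, 7)), rep(0.03, 7))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_error(bh_fdr(c(0.1, NA)), "NA")
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(21)
  for (i in 1:50) {
    m <- sample(1:200, 1)
    p <- runif(m)^sample(1:3, 1)
    expect_equal(bh_fdr(p), naive_bh(p), tolerance = 1e-12)
  }
})

test_that("network thresholds are inclusive on rho and strict on Q", {
  ids <- c("a", "b", "c")
  rho <- diag(3); dimnames(rho) <- list(ids, ids)
  rho["a", "b"] <- rho["b", "a"] <- 0.7        # boundary rho, good Q
  rho["a", "c"] <- rho["c", "a"] <- 0.9        # boundary Q
  rho["b", "c"] <- rho["c", "b"] <- 0.2
  q <- matrix(1, 3, 3, dimnames = dimnames(rho))
  q["a", "b"] <- q["b", "a"] <- 0.005
  q["a", "c"] <- q["c", "a"] <- 0.01
  net <- build_network(rho, q)
  edges <- igraph::as_edgelist(net)
  expect_equal(nrow(edges), 1)
  expect_setequal(as.vector(edges), c("a", "b"))   # rho = 0.7 kept
  expect_equal(igraph::ecount(net), 1)             # q = 0.01 rejected
  # isolated variable c excluded from the node set
  expect_setequal(igraph::V(net)$name, c("a", "b"))
  expect_equal(igraph::E(net)$rho, 0.7)
})

test_that("negative correlations form edges unless positive_only", {
  ids <- c("a", "b")
  rho <- matrix(c(1, -0.8, -0.8, 1), 2, 2, dimnames = list(ids, ids))
  q <- matrix(1e-5, 2, 2, dimnames = list(ids, ids))
  net <- build_network(rho, q)
  expect_equal(igraph::E(net)$sign, "negative")
  expect_warning(
    net_pos <- build_network(rho, q, threshold_policy(positive_only = TRUE)),
    NA)
  expect_equal(igraph::ecount(net_pos), 0)
})

test_that("October override relaxes only October's Q threshold", {
  ids <- c("a", "b")
  rho <- matrix(c(1, 0.8, 0.8, 1), 2, 2, dimnames = list(ids, ids))
  q <- matrix(0.03, 2, 2, dimnames = list(ids, ids))
  pol <- threshold_policy()
  expect_equal(igraph::ecount(build_network(rho, q, pol, month = "Jul")), 0)
  oct <- build_network(rho, q, pol, month = "Oct")
  expect_equal(igraph::ecount(oct), 1)
  expect_equal(igraph::graph_attr(oct, "month"), "Oct")
})

test_that("monthly networks are built per month with per-fraction filtering", {
  cfg <- sim_config(seed = 8)
  sim <- simulate_survey(cfg)
  bundle <- join_tables(sim$otu, sim$meta, sim$env)
  nets <- monthly_networks(bundle)
  expect_equal(names(nets), c("Jul", "Aug", "Sept", "Oct", "Dec"))
  for (mo in names(nets)) {
    g <- nets[[mo]]
    expect_equal(igraph::graph_attr(g, "month"), mo)
    if (igraph::ecount(g) > 0)
      expect_true(all(abs(igraph::E(g)$rho) >= 0.7))
    kinds <- unique(igraph::V(g)$kind)
    expect_true(all(kinds %in% c("otu", "env", "phyto")))
  }
  # planted structure: within-module edges dominate between-module ones
  g <- nets$Jul
  tr <- sim$truth$otus
  va <- igraph::vertex_attr(g)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  mod <- tr$module[match(va$otu_id, tr$otu_id)]
  both_otu <- !is.na(mod[ends[, 1]]) & !is.na(mod[ends[, 2]])
  within <- sum(both_otu & mod[ends[, 1]] == mod[ends[, 2]])
  between <- sum(both_otu & mod[ends[, 1]] != mod[ends[, 2]])
  expect_gt(within, between)
})

test_that("independent data yield essentially no significant edges", {
  set.seed(31)
  frac_pass <- vapply(1:5, function(i) {
    X <- matrix(rlnorm(40 * 45), 40, 45,
                dimnames = list(paste0("o", 1:40), NULL))
    sp <- spearman_matrix(X)
    ut <- upper.tri(sp$p)
    q <- bh_fdr(sp$p[ut])
    mean(q < 0.01 & abs(sp$rho[ut]) >= 0.7)
  }, numeric(1))
  expect_lt(mean(frac_pass), 1e-3)
})
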