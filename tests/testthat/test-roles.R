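test_that("Louvain finds the obvious partitions with their modularity", {
  two_tri <- igraph::disjoint_union(igraph::make_full_graph(3),
                                    igraph::make_full_graph(3))
  part <- louvain_partition(two_tri, seed = 1)
  expect_equal(length(unique(part$membership)), 2)
  expect_equal(part$modularity, 0.5)
  k5 <- igraph::make_full_graph(5)
  pk <- louvain_partition(k5, seed = 1)
  expect_equal(length(unique(pk$membership)), 1)
  expect_equal(pk$modularity, 0)
  expect_error(louvain_partition(igraph::make_empty_graph(0, FALSE)),
               "empty")
  # seeded determinism
  sim <- quick_sim(seed = 2)
  net <- pooled_network(sim$otu)
  p1 <- louvain_partition(net, seed = 5)
  p2 <- louvain_partition(net, seed = 5)
  expect_identical(p1$membership, p2$membership)
})

test_that("Z and C match hand enumeration on the toy graphs", {
  for (toy in toy_role_graphs()) {
    z <- within_module_degree_z(toy$g, toy$memb)
    C <- participation_coefficient(toy$g, toy$memb)
    expect_equal(z[names(toy$z)], toy$z, tolerance = 1e-12)
    expect_equal(C[names(toy$c_)], toy$c_, tolerance = 1e-12)
  }
})

test_that("Z direct formula: kappa 5 against module mean 2 sd 1 gives 3", {
  # module of 3 nodes with internal degrees (5, 1, 0): build explicitly —
  # a hub h connected to 5 module mates, one of which links only to h
  edges <- rbind(c("h", "m1"), c("h", "m2"), c("h", "m3"), c("h", "m4"),
                 c("h", "m5"), c("m1", "m2"), c("m3", "m4"))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  memb <- setNames(rep(1, 6), c("h", paste0("m", 1:5)))
  z <- within_module_degree_z(g, memb)
  kappa <- c(5, 2, 2, 2, 2, 1)
  expect_equal(unname(z["h"]), (5 - mean(kappa)) / sd(kappa))
})

test_that("C respects its symmetry limits and bounds", {
  # even split across m modules gives 1 - 1/m
  for (m in c(2, 4, 5)) {
    edges <- cbind("x", paste0("n", 1:m))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    memb <- setNames(c(0, seq_len(m)), c("x", paste0("n", 1:m)))
    expect_equal(unname(participation_coefficient(g, memb)["x"]), 1 - 1 / m)
  }
})

test_that("Z standardises within modules and internal degrees are conserved", {
  sim <- quick_sim(seed = 7)
  net <- pooled_network(sim$otu)
  part <- louvain_partition(net, seed = 1)
  z <- within_module_degree_z(net, part)
  C <- participation_coefficient(net, part)
  memb <- part$membership[names(z)]
  n_modules <- length(unique(memb))
  expect_true(all(C >= 0 & C <= 1 - 1 / n_modules + 1e-12))
  for (s in unique(memb)) {
    zs <- z[memb == s]
    if (length(zs) > 1 && sd(zs) > 0) {
      expect_equal(mean(zs), 0, tolerance = 1e-10)
      expect_equal(sd(zs), 1, tolerance = 1e-10)
    }
  }
  # sum over modules of internal degree totals = 2 * internal edge count
  ends <- igraph::ends(net, igraph::E(net), names = TRUE)
  internal_edges <- sum(memb[ends[, 1]] == memb[ends[, 2]])
  adj <- igraph::as_adj_list(net)
  nm <- igraph::V(net)$name
  kappa_total <- sum(vapply(seq_along(adj), function(i)
    sum(memb[nm[as.integer(adj[[i]])]] == memb[nm[i]]), numeric(1)))
  expect_equal(kappa_total, 2 * internal_edges)
})

test_that("role classification partitions the Z-C plane exactly", {
  expect_equal(classify_role(2.0, 0.30), "module hub")
  expect_equal(classify_role(1.5, 0.62), "peripheral")  # both boundaries <=
  expect_equal(classify_role(0, 0.9), "connector")
  expect_equal(classify_role(3, 0.7), "network hub")
  grid <- expand.grid(z = seq(-2, 4, by = 0.25), c_ = seq(0, 1, by = 0.02))
  roles <- classify_role(grid$z, grid$c_)
  expect_true(all(roles %in% c("peripheral", "connector", "module hub",
                               "network hub")))
  manual <- ifelse(grid$z > 1.5 & grid$c_ <= 0.62, "module hub",
            ifelse(grid$z > 1.5, "network hub",
            ifelse(grid$c_ > 0.62, "connector", "peripheral")))
  expect_equal(roles, manual)
})

test_that("module depth profiles are normalised and labelled by rule", {
  counts <- matrix(0L, 3, 6, dimnames = list(
    c("surf_otu", "deep_otu", "even_otu"),
    paste0("s", 1:6)))
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     depth = rep(c("surface", "middle", "bottom"), each = 2))
  # equal column totals so relative abundances mirror the raw pattern
  counts["surf_otu", 1:2] <- 100L
  counts["deep_otu", 3:6] <- 100L
  counts["even_otu", ] <- 30L
  memb <- c(surf_otu = 1, deep_otu = 2, even_otu = 3, temperature = 4)
  prof <- module_depth_profile(memb, otu_table(counts), meta)
  expect_equal(prof$label[prof$module == 1], "S")
  expect_equal(prof$label[prof$module == 2], "MB")
  expect_equal(prof$label[prof$module == 3], "W")
  expect_equal(prof$label[prof$module == 4], "n/a")   # env-only module
  shares <- as.matrix(prof[prof$module != 4,
                           c("f_surface", "f_middle", "f_bottom")])
  expect_equal(unname(rowSums(shares)), rep(1, 3))
  # boundary example: (0.1, 0.4, 0.5) is MB since middle+bottom = 0.9;
  # a filler OTU keeps column totals equal so the shares are exact
  counts2 <- rbind(o = c(10L, 40L, 50L), filler = c(90L, 60L, 50L))
  colnames(counts2) <- paste0("u", 1:3)
  meta2 <- data.frame(sample_id = paste0("u", 1:3),
                      depth = c("surface", "middle", "bottom"))
  prof2 <- module_depth_profile(c(o = 1), otu_table(counts2), meta2)
  expect_equal(prof2$label, "MB")
  expect_equal(prof2$f_bottom, 0.5)
})

test_that("recurrence network keeps pairs seen in >= 3 months", {
  mk <- function(month, edges, rho) {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    igraph::E(g)$rho <- rho
    igraph::set_graph_attr(g, "month", month)
  }
  nets <- list(
    Jul = mk("Jul", rbind(c("a", "b"), c("c", "d"), c("e", "f")),
             c(0.8, 0.9, 0.75)),
    Aug = mk("Aug", rbind(c("a", "b"), c("c", "d")), c(0.85, -0.9)),
    Sept = mk("Sept", rbind(c("a", "b"), c("c", "d")), c(0.9, 0.95)),
    Oct = mk("Oct", rbind(c("a", "b"), c("e", "f")), c(0.7, 0.8)),
    Dec = mk("Dec", rbind(c("a", "b")), 0.9))
  rec <- recurrence_network(nets)
  expect_equal(igraph::ecount(rec), 2)      # a-b (5x), c-d (3x); e-f only 2x
  ed <- igraph::as_edgelist(rec)
  occ <- setNames(igraph::E(rec)$occurrence,
                  paste(ed[, 1], ed[, 2], sep = "-"))
  expect_equal(unname(occ["a-b"]), 5)
  expect_equal(unname(occ["c-d"]), 3)
  sgn <- setNames(igraph::E(rec)$sign_consistent,
                  paste(ed[, 1], ed[, 2], sep = "-"))
  expect_true(sgn[["a-b"]])
  expect_false(sgn[["c-d"]])                 # Aug flip recorded
  months <- setNames(igraph::E(rec)$months, paste(ed[, 1], ed[, 2], sep = "-"))
  expect_equal(months[["c-d"]], "Jul,Aug,Sept")
  # mean degree over the monthly networks a node appears in:
  # 'a' has degree 1 in each of 5 months
  expect_equal(igraph::V(rec)$mean_degree[igraph::V(rec)$name == "a"], 1)
  # strict reading is available
  rec4 <- recurrence_network(nets, min_occurrence = 4)
  expect_equal(igraph::ecount(rec4), 1)
  expect_error(recurrence_network(nets[1:2]), "at least 3")
})

test_that("recurrence network is invariant to the order of monthly networks", {
  sim <- quick_sim(seed = 10)
  bundle <- join_tables(sim$otu, sim$meta, sim$env)
  nets <- monthly_networks(bundle)
  r1 <- recurrence_network(nets)
  r2 <- recurrence_network(rev(nets))
  expect_gt(igraph::ecount(r1), 0)
  el1 <- igraph::as_data_frame(r1, "edges")
  el2 <- igraph::as_data_frame(r2, "edges")
  el1 <- el1[order(el1$from, el1$to), ]
  el2 <- el2[order(el2$from, el2$to), ]
  rownames(el1) <- rownames(el2) <- NULL
  expect_equal(el1, el2)
})

test_that("planted hubs earn module-hub Z scores through the full pipeline", {
  hub_ok <- vapply(1:4, function(s) {
    sim <- quick_sim(seed = s)
    net <- pooled_network(sim$otu)
    part <- louvain_partition(net, seed = s)
    z <- within_module_degree_z(net, part)
    hubs <- sim$truth$otus$otu_id[sim$truth$otus$hub]
    median(z[intersect(hubs, names(z))]) > 1.5
  }, logical(1))
  expect_true(all(hub_ok))
})
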