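#' Network density and average node degree
#'
#' Closed forms on the network's own node set: density `2E / (N (N - 1))`,
#' average degree `2E / N`.
#'
#' @param network igraph object.
#' @return A single number.
#' @export
net_density <- function(network) {
  n <- igraph::vcount(network)
  if (n < 2) return(0)
  2 * igraph::ecount(network) / (n * (n - 1))
}

#' @rdname net_density
#' @export
average_degree <- function(network) {
  n <- igraph::vcount(network)
  if (n == 0) return(0)
  2 * igraph::ecount(network) / n
}

#' Mean local clustering coefficient
#'
#' Average of the per-node local clustering coefficients; nodes of degree
#' < 2 contribute 0.
#'
#' @param network igraph object.
#' @return Mean local CC.
#' @export
clustering_coefficient <- function(network) {
  if (igraph::vcount(network) == 0) return(NaN)
  cc <- igraph::transitivity(network, type = "local", isolates = "zero")
  mean(cc)
}

# Largest connected component as an induced subgraph.
largest_component <- function(network) {
  comp <- igraph::components(network)
  keep <- which(comp$membership == which.max(comp$csize))
  igraph::induced_subgraph(network, keep)
}

#' Average shortest path length and diameter
#'
#' Both computed on the largest connected component (monthly networks are
#' typically multi-component), with unit edge lengths.
#'
#' @param network igraph object (may be disconnected).
#' @return `apl()`: mean pairwise shortest-path length; `net_diameter()`:
#'   the maximum (integer).
#' @export
apl <- function(network) {
  g <- largest_component(network)
  if (igraph::vcount(g) < 2) return(NaN)
  igraph::mean_distance(g, directed = FALSE, unconnected = FALSE)
}

#' @rdname apl
#' @export
net_diameter <- function(network) {
  g <- largest_component(network)
  if (igraph::vcount(g) < 2) return(0L)
  as.integer(igraph::diameter(g, directed = FALSE, unconnected = FALSE,
                              weights = NA))
}

#' Erdos-Renyi G(n, m) null ensemble
#'
#' Draws `n_reps` uniform random graphs with exactly the observed numbers of
#' nodes and edges and records, per replicate, the mean local clustering
#' coefficient, the APL on the largest component and the Louvain modularity.
#'
#' @param n Nodes.
#' @param m Edges (`m <= n (n - 1) / 2`).
#' @param n_reps Replicates (default 100).
#' @param seed RNG seed for the ensemble stream.
#' @param modularity_reps Louvain is costlier than CC/APL; modularity is
#'   computed on the first `modularity_reps` replicates (default: all).
#' @return An `er_null` list: per-rep vectors `cc`, `apl`, `modularity`,
#'   their means/sds, and `n`, `m`, `n_reps`, `seed`.
#' @export
er_null <- function(n, m, n_reps = 100, seed = 1,
                    modularity_reps = n_reps) {
  if (m > n * (n - 1) / 2) stop("more edges than unordered node pairs")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cc <- apl_v <- numeric(n_reps)
  mod <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    g <- igraph::sample_gnm(n, m)
    cc[r] <- clustering_coefficient(g)
    apl_v[r] <- apl(g)
    if (r <= modularity_reps)
      mod[r] <- igraph::modularity(igraph::cluster_louvain(g))
  }
  mod <- mod[!is.na(mod)]
  structure(list(n = n, m = m, n_reps = n_reps, seed = seed,
                 cc = cc, apl = apl_v, modularity = mod,
                 mean_cc = mean(cc), sd_cc = sd(cc),
                 mean_apl = mean(apl_v), sd_apl = sd(apl_v),
                 mean_modularity = mean(mod), sd_modularity = sd(mod)),
            class = "er_null")
}

#' @export
print.er_null <- function(x, ...) {
  cat(sprintf(
    "er_null: G(%d, %d), %d reps (seed %s)\n  CC %.4f +- %.4f  APL %.3f +- %.3f  modularity %.3f +- %.3f\n",
    x$n, x$m, x$n_reps, format(x$seed), x$mean_cc, x$sd_cc,
    x$mean_apl, x$sd_apl, x$mean_modularity, x$sd_modularity))
  invisible(x)
}

#' Small-world coefficient
#'
#' `sigma = (CC / CCr) / (APL / APLr)`; sigma > 1 indicates small-world
#' structure (more clustered, comparably short paths) relative to an
#' equally sized random graph.
#'
#' @param cc,ccr Observed and null-mean clustering coefficients.
#' @param apl,aplr Observed and null-mean average path lengths.
#' @return List: `sigma`, `cc_ratio`, `apl_ratio`.
#' @export
small_world_sigma <- function(cc, ccr, apl, aplr) {
  cc_ratio <- cc / ccr
  apl_ratio <- apl / aplr
  list(sigma = cc_ratio / apl_ratio,
       cc_ratio = cc_ratio, apl_ratio = apl_ratio)
}

#' R-squared of a log-log power-law fit to the degree distribution
#'
#' OLS of `log10(frequency of degree k)` on `log10(k)` over observed
#' degrees k >= 1 (raw frequencies, no binning, no CCDF). Needs at least 3
#' distinct degrees with nonzero variance; otherwise returns NaN with a
#' warning.
#'
#' @param network igraph object.
#' @return R-squared of the fit.
#' @export
degree_powerlaw_r2 <- function(network) {
  deg <- igraph::degree(network)
  tab <- table(deg[deg >= 1])
  k <- as.numeric(names(tab))
  f <- as.numeric(tab)
  if (length(k) < 3) {
    warning("degree distribution too degenerate for a power-law fit")
    return(NaN)
  }
  fit <- lm(log10(f) ~ log10(k))
  # summary.lm warns on numerically perfect fits; R^2 itself is fine
  suppressWarnings(summary(fit)$r.squared)
}

#' Edge share of the most highly connected nodes
#'
#' Fraction of all edges incident to at least one of the top
#' `ceiling(top_frac * N)` nodes by degree (ties broken by node id).
#'
#' @param network igraph object.
#' @param top_frac Fraction of nodes counted as hubs (default 0.1).
#' @return Share of edges in \[0, 1\].
#' @export
degree_concentration <- function(network, top_frac = 0.1) {
  n <- igraph::vcount(network)
  m <- igraph::ecount(network)
  if (m == 0) {
    warning("network has no edges")
    return(0)
  }
  deg <- igraph::degree(network)
  nm <- igraph::V(network)$name
  if (is.null(nm)) nm <- seq_len(n)
  ord <- order(-deg, nm)
  top <- ord[seq_len(ceiling(top_frac * n))]
  ends <- igraph::ends(network, igraph::E(network), names = FALSE)
  mean(ends[, 1] %in% top | ends[, 2] %in% top)
}

#' Edge composition by phylum, fraction and variable kind
#'
#' @param network igraph object with `kind`, `fraction` and `phylum` vertex
#'   attributes (as produced by [monthly_networks()]).
#' @return List: `phylum` (phylum x phylum edge-proportion matrix over
#'   OTU-OTU edges), `fraction_ratio` (per-fraction edge/node ratio, where a
#'   fraction's edges have both endpoints in it), `env_taxon` (edge counts
#'   between env variables and phyla; empty when no env nodes).
#' @export
edge_composition <- function(network) {
  va <- function(a) igraph::vertex_attr(network, a)
  if (is.null(va("kind"))) stop("network lacks a 'kind' vertex attribute")
  ends <- igraph::ends(network, igraph::E(network), names = FALSE)
  kind <- va("kind"); frac <- va("fraction"); phy <- va("phylum")

  ok <- kind[ends[, 1]] == "otu" & kind[ends[, 2]] == "otu"
  pp <- NULL
  if (any(ok)) {
    a <- phy[ends[ok, 1]]; b <- phy[ends[ok, 2]]
    a[is.na(a)] <- "unclassified"; b[is.na(b)] <- "unclassified"
    lev <- sort(unique(c(a, b)))
    pair <- cbind(pmin(a, b), pmax(a, b))
    pp <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
    for (i in seq_len(nrow(pair)))
      pp[pair[i, 1], pair[i, 2]] <- pp[pair[i, 1], pair[i, 2]] + 1
    pp <- pp + t(pp) - diag(diag(pp))
    pp <- pp / sum(ok)
  }

  fr_ratio <- NULL
  fr_levels <- sort(unique(frac[kind == "otu" & !is.na(frac)]))
  if (length(fr_levels) > 0) {
    fr_ratio <- vapply(fr_levels, function(fr) {
      nodes <- sum(kind == "otu" & !is.na(frac) & frac == fr)
      inner <- sum(!is.na(frac[ends[, 1]]) & !is.na(frac[ends[, 2]]) &
                     frac[ends[, 1]] == fr & frac[ends[, 2]] == fr)
      if (nodes == 0) NA_real_ else inner / nodes
    }, numeric(1))
  }

  env_edge <- (kind[ends[, 1]] == "env") != (kind[ends[, 2]] == "env")
  env_tab <- data.frame(env = character(), phylum = character(),
                        edges = integer())
  if (any(env_edge)) {
    nm <- igraph::V(network)$name
    e1 <- ends[env_edge, 1]; e2 <- ends[env_edge, 2]
    env_node <- ifelse(kind[e1] == "env", e1, e2)
    other <- ifelse(kind[e1] == "env", e2, e1)
    keep <- kind[other] == "otu"
    if (any(keep)) {
      ph <- phy[other[keep]]
      ph[is.na(ph)] <- "unclassified"
      env_tab <- as.data.frame(table(env = nm[env_node[keep]], phylum = ph),
                               stringsAsFactors = FALSE)
      names(env_tab)[3] <- "edges"
      env_tab <- env_tab[env_tab$edges > 0, ]
      rownames(env_tab) <- NULL
    }
  }
  list(phylum = pp, fraction_ratio = fr_ratio, env_taxon = env_tab)
}

#' Full topological summary of a network against its ER null
#'
#' One column of the monthly-comparison table: observed N, E, diameter,
#' density, average degree, modularity, CC and APL; null-ensemble means
#' (CCr, APLr, random modularity); the CC/CCr and APL/APLr ratios; and the
#' small-world coefficient sigma computed from the unrounded internal
#' values.
#'
#' @param network igraph object.
#' @param n_reps Null-ensemble replicates (default 100).
#' @param seed Seed for the null ensemble and Louvain restarts.
#' @return A `topology_summary` list (printable as a named column).
#' @export
topology_summary <- function(network, n_reps = 100, seed = 1) {
  n <- igraph::vcount(network)
  m <- igraph::ecount(network)
  part <- louvain_partition(network, seed = split_seed(seed, "louvain"))
  null <- er_null(n, m, n_reps = n_reps, seed = split_seed(seed, "null"))
  cc <- clustering_coefficient(network)
  apl_obs <- apl(network)
  sw <- small_world_sigma(cc, null$mean_cc, apl_obs, null$mean_apl)
  structure(list(
    nodes = n, edges = m,
    diameter = net_diameter(network),
    density = net_density(network),
    average_degree = average_degree(network),
    modularity = part$modularity,
    modularity_random = null$mean_modularity,
    cc = cc, cc_random = null$mean_cc, cc_ratio = sw$cc_ratio,
    apl = apl_obs, apl_random = null$mean_apl, apl_ratio = sw$apl_ratio,
    sigma = sw$sigma,
    largest_component_only = TRUE,
    null_seed = null$seed, n_reps = n_reps
  ), class = "topology_summary")
}

#' Tabulate topology summaries across months
#'
#' @param summaries Named list of [topology_summary()] results (one per
#'   month).
#' @return Data frame with the standard row labels and one column per month.
#' @export
topology_table <- function(summaries) {
  rows <- c("Nodes" = "nodes", "Edges" = "edges", "Diameter" = "diameter",
            "Network density" = "density",
            "Average node degree" = "average_degree",
            "Modularity" = "modularity",
            "Modularity, random" = "modularity_random",
            "Clustering coefficient (CC)" = "cc",
            "Clustering coefficient, random (CCr)" = "cc_random",
            "Ratio of CC/CCr" = "cc_ratio",
            "Average shortest path length (APL)" = "apl",
            "Average shortest path length, random (APLr)" = "apl_random",
            "Ratio of APL/APLr" = "apl_ratio",
            "Small-word coefficient σ, (CC/CCr)/(APL/APLr)" = "sigma")
  out <- data.frame(`Topological properties` = names(rows),
                    check.names = FALSE)
  for (mo in names(summaries))
    out[[mo]] <- vapply(rows, function(f) summaries[[mo]][[f]], numeric(1))
  out
}
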