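#' Spearman rank-correlation matrix with t-approximation P-values
#'
#' Ranks each variable with average-rank tie handling, then computes Pearson
#' correlations on the ranks. Two-sided P-values come from
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom;
#' `|rho| = 1` is assigned P = 0. Constant variables get NA rho/P and are
#' reported in `$constant` so callers can exclude them.
#'
#' @param X Variable x sample matrix (>= 4 samples).
#' @return List: `rho`, `p` (symmetric matrices, unit/zero diagonal), `n`
#'   (samples used), `constant` (ids of zero-variance variables).
#' @export
spearman_matrix <- function(X) {
  X <- as.matrix(X)
  n <- ncol(X)
  if (n < 4) stop("need at least 4 samples for rank correlation")
  if (is.null(rownames(X))) rownames(X) <- paste0("V", seq_len(nrow(X)))
  constant <- rownames(X)[apply(X, 1, function(r) length(unique(r)) == 1)]
  ranks <- t(apply(X, 1, rank, ties.method = "average"))
  rho <- suppressWarnings(cor(t(ranks)))
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  rho <- pmin(pmax(rho, -1), 1)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1 - 1e-12] <- 0
  diag(rho) <- 1
  diag(p) <- 0
  rho[constant, constant] <- NA_real_
  p[is.na(rho)] <- NA_real_
  list(rho = rho, p = p, n = n, constant = constant)
}

#' Benjamini-Hochberg Q-values
#'
#' Step-up FDR adjustment: `Q_(i) = min_{j >= i} m * P_(j) / j`, capped at 1,
#' returned in the original order.
#'
#' @param p Vector of P-values in \[0, 1\]; NA is rejected.
#' @return Q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p)) stop("P-values contain NA")
  if (any(p < 0 | p > 1)) stop("P-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Edge-retention policy for thresholded networks
#'
#' Default: retain a pair when Q < 0.01 and |rho| >= 0.7; October relaxes
#' the FDR cut to Q < 0.05 because its variance-poor profiles yield far
#' fewer significant pairs at the stricter cut. `positive_only = TRUE`
#' restricts to rho >= rho_min (literal positive co-occurrence).
#'
#' @param q_max FDR threshold (strict `<`).
#' @param rho_min Correlation-magnitude threshold (inclusive `>=`).
#' @param month_overrides Named list of per-month overrides, e.g.
#'   `list(Oct = list(q_max = 0.05))`.
#' @param positive_only Drop negative correlations entirely.
#' @return A `threshold_policy` list.
#' @export
threshold_policy <- function(q_max = 0.01, rho_min = 0.7,
                             month_overrides = list(Oct = list(q_max = 0.05)),
                             positive_only = FALSE) {
  stopifnot(q_max > 0, q_max <= 1, rho_min >= 0, rho_min <= 1)
  structure(list(q_max = q_max, rho_min = rho_min,
                 month_overrides = month_overrides,
                 positive_only = positive_only),
            class = "threshold_policy")
}

policy_for_month <- function(policy, month) {
  ov <- policy$month_overrides[[month]]
  if (!is.null(ov)) for (k in names(ov)) policy[[k]] <- ov[[k]]
  policy
}

#' Build a thresholded co-occurrence network
#'
#' Creates an undirected simple graph with an edge for every unordered pair
#' satisfying `Q < q_max` and `|rho| >= rho_min` (or `rho >= rho_min` under
#' `positive_only`). Edges store `rho`, `q` and `sign`; isolated variables
#' are excluded from the node set, so "nodes" counts connected variables.
#'
#' @param rho,q Symmetric matrices from [spearman_matrix()] / [bh_fdr()]
#'   (NA entries, e.g. constant variables, never form edges).
#' @param policy A [threshold_policy()]; per-month overrides are applied
#'   when `month` is given.
#' @param node_meta Optional data frame with `id` plus node attributes
#'   (`kind`, `fraction`, `phylum`, ...) copied onto vertices.
#' @param month Optional month tag stored as a graph attribute.
#' @return igraph object.
#' @export
build_network <- function(rho, q, policy = threshold_policy(),
                          node_meta = NULL, month = NULL) {
  stopifnot(all(dim(rho) == dim(q)))
  if (!is.null(month)) policy <- policy_for_month(policy, month)
  ids <- rownames(rho)
  ut <- upper.tri(rho)
  keep <- which(ut & !is.na(rho) & !is.na(q) & q < policy$q_max &
                  (if (policy$positive_only) rho >= policy$rho_min
                   else abs(rho) >= policy$rho_min),
                arr.ind = TRUE)
  if (nrow(keep) == 0) {
    cn_log("build_network: no pair passed the thresholds; empty network",
           level = "WARN")
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    edges <- data.frame(from = ids[keep[, 1]], to = ids[keep[, 2]],
                        rho = rho[keep], q = q[keep],
                        sign = ifelse(rho[keep] >= 0, "positive", "negative"),
                        stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  }
  if (!is.null(node_meta) && igraph::vcount(g) > 0) {
    idx <- match(igraph::V(g)$name, node_meta$id)
    for (col in setdiff(names(node_meta), "id"))
      g <- igraph::set_vertex_attr(g, col, value = node_meta[[col]][idx])
  }
  if (!is.null(month)) g <- igraph::set_graph_attr(g, "month", month)
  g
}

# Assemble the variable x unit matrix for one month: per-fraction filtered
# OTU relative abundances, environmental variables, filtered log10
# phytoplankton. Variables are rows; observation units are the month's
# water samples (station x depth).
month_variable_matrix <- function(bundle, month,
                                  max_relabund_min = 0.001,
                                  prevalence_min = 0.7) {
  meta <- bundle$meta[bundle$meta$month == month, ]
  if (nrow(meta) == 0) stop("no samples for month ", month)
  units <- unique(meta$unit_id)
  blocks <- list()
  node_meta <- list()
  for (fr in sort(unique(meta$fraction))) {
    sids <- meta$sample_id[meta$fraction == fr]
    sub <- bundle$otu$counts[, sids, drop = FALSE]
    kept <- filter_otus(sub, max_relabund_min, prevalence_min)
    if (length(kept) == 0) next
    rel <- relative_abundance(sub)[kept, , drop = FALSE]
    u <- meta$unit_id[match(colnames(rel), meta$sample_id)]
    rel <- rel[, match(units, u), drop = FALSE]
    rownames(rel) <- paste(fr, kept, sep = "|")
    blocks[[fr]] <- rel
    phylum <- if (!is.null(bundle$taxonomy))
      bundle$taxonomy$phylum[match(kept, bundle$taxonomy$otu_id)]
    else NA_character_
    node_meta[[fr]] <- data.frame(id = rownames(rel), kind = "otu",
                                  fraction = fr, otu_id = kept,
                                  phylum = phylum, stringsAsFactors = FALSE)
  }
  env <- bundle$env[match(units, bundle$env$unit_id), ]
  env_vars <- names(env)[vapply(env, is.numeric, logical(1))]
  if (length(env_vars) > 0) {
    em <- t(as.matrix(env[, env_vars, drop = FALSE]))
    colnames(em) <- units
    blocks[["env"]] <- em
    node_meta[["env"]] <- data.frame(id = env_vars, kind = "env",
                                     fraction = NA_character_,
                                     otu_id = NA_character_,
                                     phylum = NA_character_,
                                     stringsAsFactors = FALSE)
  }
  if (!is.null(bundle$phyto)) {
    ph <- bundle$phyto[, units, drop = FALSE]
    kept <- filter_phyto(ph, prevalence_min)
    if (length(kept) > 0) {
      pm <- log10_phyto(ph[kept, , drop = FALSE])
      rownames(pm) <- paste("phyto", kept, sep = "|")
      blocks[["phyto"]] <- pm
      node_meta[["phyto"]] <- data.frame(id = rownames(pm), kind = "phyto",
                                         fraction = NA_character_,
                                         otu_id = NA_character_,
                                         phylum = NA_character_,
                                         stringsAsFactors = FALSE)
    }
  }
  X <- do.call(rbind, blocks)
  list(X = X, node_meta = do.call(rbind, node_meta), units = units)
}

#' Monthly co-occurrence networks
#'
#' For each month: applies the abundance/prevalence filter within each size
#' fraction, pools the surviving fraction-specific OTU profiles with the
#' environmental (and, if present, phytoplankton) variables over the month's
#' water-sample units, computes the Spearman matrix, adjusts the pooled
#' P-value distribution with BH, and thresholds into a network (with the
#' per-month policy overrides, e.g. October's relaxed Q cut).
#'
#' @param bundle A `cooc_bundle` from [join_tables()] or
#'   [simulate_survey()]-derived tables.
#' @param policy A [threshold_policy()].
#' @param max_relabund_min,prevalence_min Filter thresholds passed through
#'   to [filter_otus()] / [filter_phyto()].
#' @return Named list of igraph networks, one per month in sampling order.
#' @export
monthly_networks <- function(bundle, policy = threshold_policy(),
                             max_relabund_min = 0.001,
                             prevalence_min = 0.7) {
  months <- intersect(MONTH_LEVELS, unique(bundle$meta$month))
  out <- list()
  for (mo in months) {
    vm <- month_variable_matrix(bundle, mo, max_relabund_min, prevalence_min)
    sp <- spearman_matrix(vm$X)
    ok <- setdiff(rownames(sp$rho), sp$constant)
    rho <- sp$rho[ok, ok, drop = FALSE]
    p <- sp$p[ok, ok, drop = FALSE]
    q <- rho * NA
    ut <- upper.tri(p)
    q[ut] <- bh_fdr(p[ut])
    q[lower.tri(q)] <- t(q)[lower.tri(q)]
    out[[mo]] <- build_network(rho, q, policy, vm$node_meta, month = mo)
    cn_log(sprintf("monthly_networks: %s -> %d nodes, %d edges (n = %d units)",
                   mo, igraph::vcount(out[[mo]]), igraph::ecount(out[[mo]]),
                   sp$n))
  }
  out
}
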