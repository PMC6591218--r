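#' Louvain module partition
#'
#' Runs the Louvain modularity-maximisation heuristic with seeded random
#' vertex orderings and returns the best of `restarts` runs (highest
#' modularity). Edge signs/weights are ignored: topology only, as for the
#' other network metrics.
#'
#' @param network Non-empty igraph object.
#' @param seed Seed controlling the restart orderings.
#' @param resolution Louvain resolution parameter (default 1).
#' @param restarts Number of seeded restarts (default 10).
#' @return A `module_partition` list: `membership` (named integer vector),
#'   `modularity`, `seed`, `resolution`.
#' @export
louvain_partition <- function(network, seed = 1, resolution = 1,
                              restarts = 10) {
  if (igraph::vcount(network) == 0) stop("cannot partition an empty network")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  best <- NULL
  best_q <- -Inf
  nm <- igraph::V(network)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(network)))
  for (r in seq_len(restarts)) {
    perm <- sample(igraph::vcount(network))
    gp <- igraph::permute(network, perm)
    cl <- igraph::cluster_louvain(gp, resolution = resolution, weights = NA)
    q <- igraph::modularity(cl)
    if (q > best_q) {
      best_q <- q
      memb <- igraph::membership(cl)
      best <- setNames(as.integer(memb[perm]), nm)
    }
  }
  structure(list(membership = best, modularity = best_q,
                 seed = seed, resolution = resolution),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d nodes in %d modules, modularity %.3f\n",
              length(x$membership), length(unique(x$membership)),
              x$modularity))
  invisible(x)
}

node_names <- function(network) {
  nm <- igraph::V(network)$name
  if (is.null(nm)) as.character(seq_len(igraph::vcount(network))) else nm
}

membership_vector <- function(network, partition) {
  memb <- if (inherits(partition, "module_partition"))
    partition$membership else partition
  nm <- node_names(network)
  if (!all(nm %in% names(memb)))
    stop("partition does not cover every network node")
  memb[nm]
}

#' Within-module degree z-score (Z)
#'
#' `Z_i = (kappa_i - mu_s) / sigma_s`, where `kappa_i` is node i's number of
#' links inside its own module s and `mu_s`/`sigma_s` are the mean/sd of
#' that internal link count over s's members. Modules with `sigma_s = 0`
#' (including singletons) give Z = 0.
#'
#' @param network igraph object.
#' @param partition A [louvain_partition()] result or named membership
#'   vector covering all nodes.
#' @return Named numeric vector of Z scores.
#' @export
within_module_degree_z <- function(network, partition) {
  memb <- membership_vector(network, partition)
  n <- igraph::vcount(network)
  adj <- igraph::as_adj_list(network, mode = "all")
  kappa <- vapply(seq_len(n), function(i)
    sum(memb[as.integer(adj[[i]])] == memb[i]), numeric(1))
  z <- numeric(n)
  for (s in unique(memb)) {
    idx <- which(memb == s)
    mu <- mean(kappa[idx])
    sig <- if (length(idx) > 1) sd(kappa[idx]) else 0
    z[idx] <- if (is.na(sig) || sig == 0) 0 else (kappa[idx] - mu) / sig
  }
  setNames(z, node_names(network))
}

#' Participation coefficient (C)
#'
#' `C_i = 1 - sum_t (kappa_it / k_i)^2` over modules t, where `kappa_it` is
#' the number of i's links into module t and `k_i` its total degree. C = 0
#' when all links stay inside the node's own module; C approaches 1 when
#' links spread evenly over many modules. Degree-0 nodes get C = 0.
#'
#' @inheritParams within_module_degree_z
#' @return Named numeric vector of C values in \[0, 1\].
#' @export
participation_coefficient <- function(network, partition) {
  memb <- membership_vector(network, partition)
  n <- igraph::vcount(network)
  adj <- igraph::as_adj_list(network, mode = "all")
  C <- vapply(seq_len(n), function(i) {
    k <- length(adj[[i]])
    if (k == 0) return(0)
    tab <- table(memb[as.integer(adj[[i]])])
    1 - sum((tab / k)^2)
  }, numeric(1))
  setNames(C, node_names(network))
}

#' Classify node roles in the Z-C plane
#'
#' Guimera-Amaral roles at thresholds Z = 1.5, C = 0.62:
#' module hubs (Z > 1.5, C <= 0.62), network hubs (Z > 1.5, C > 0.62),
#' connectors (Z <= 1.5, C > 0.62), peripherals (Z <= 1.5, C <= 0.62).
#' Both boundaries are inclusive on the <= side.
#'
#' @param z,c_ Z and C values (recycled to common length).
#' @param z_threshold,c_threshold Role thresholds (defaults 1.5 and 0.62).
#' @return Character vector of roles.
#' @export
classify_role <- function(z, c_, z_threshold = 1.5, c_threshold = 0.62) {
  ifelse(z > z_threshold,
         ifelse(c_ > c_threshold, "network hub", "module hub"),
         ifelse(c_ > c_threshold, "connector", "peripheral"))
}

#' Per-node role table for a network
#'
#' Convenience wrapper: Louvain partition (unless supplied), Z, C and role
#' per node.
#'
#' @param network igraph object.
#' @param partition Optional precomputed partition.
#' @param seed Seed for Louvain when `partition` is NULL.
#' @return Data frame: `id`, `module`, `z`, `c`, `role` (plus `kind` and
#'   `fraction` when the network carries them).
#' @export
node_roles <- function(network, partition = NULL, seed = 1) {
  if (is.null(partition)) partition <- louvain_partition(network, seed = seed)
  memb <- membership_vector(network, partition)
  z <- within_module_degree_z(network, partition)
  C <- participation_coefficient(network, partition)
  out <- data.frame(id = node_names(network),
                    module = as.integer(memb),
                    z = as.numeric(z), c = as.numeric(C),
                    role = classify_role(z, C),
                    stringsAsFactors = FALSE)
  for (a in c("kind", "fraction"))
    if (!is.null(igraph::vertex_attr(network, a)))
      out[[a]] <- igraph::vertex_attr(network, a)
  out
}

#' Module depth-preference profiles
#'
#' For each module, averages its member OTUs' relative abundances within
#' each depth layer, normalises the three layer means to sum 1, and labels
#' the module S (surface share >= 0.5), MB (middle + bottom share >= 0.75)
#' or W (whole column) — thresholds configurable. Modules without OTU
#' members (environment-only) are labelled "n/a".
#'
#' @param partition A [louvain_partition()] or membership vector over
#'   network node ids (fraction-qualified OTU ids of the form
#'   `"FL|OTU0001"` or plain OTU ids).
#' @param otu An [otu_table()].
#' @param meta Sample metadata with `sample_id` and `depth`.
#' @param s_threshold Surface share for an S label (default 0.5).
#' @param mb_threshold Middle+bottom share for an MB label (default 0.75).
#' @return Data frame per module: `module`, `f_surface`, `f_middle`,
#'   `f_bottom`, `label`.
#' @export
module_depth_profile <- function(partition, otu, meta,
                                 s_threshold = 0.5, mb_threshold = 0.75) {
  memb <- if (inherits(partition, "module_partition"))
    partition$membership else partition
  rel <- relative_abundance(otu)
  depth <- meta$depth[match(colnames(rel), meta$sample_id)]
  out <- lapply(sort(unique(memb)), function(s) {
    ids <- names(memb)[memb == s]
    otu_ids <- sub("^[^|]*\\|", "", ids)
    otu_ids <- intersect(otu_ids, rownames(rel))
    if (length(otu_ids) == 0)
      return(data.frame(module = s, f_surface = NA_real_,
                        f_middle = NA_real_, f_bottom = NA_real_,
                        label = "n/a", stringsAsFactors = FALSE))
    mean_ab <- vapply(DEPTH_LEVELS, function(d) {
      cols <- which(depth == d)
      if (length(cols) == 0) 0
      else mean(rel[otu_ids, cols, drop = FALSE])
    }, numeric(1))
    f <- if (sum(mean_ab) > 0) mean_ab / sum(mean_ab) else mean_ab
    lab <- if (f[["surface"]] >= s_threshold) "S"
           else if (f[["middle"]] + f[["bottom"]] >= mb_threshold) "MB"
           else "W"
    data.frame(module = s, f_surface = f[["surface"]],
               f_middle = f[["middle"]], f_bottom = f[["bottom"]],
               label = lab, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Recurrence network across monthly networks
#'
#' Collects every unordered variable pair that forms an edge in at least
#' `min_occurrence` of the monthly networks (sign ignored when counting;
#' a per-edge flag records whether the sign was consistent). Edge
#' attributes: `occurrence`, `months` (comma-joined), `mean_rho`,
#' `sign_consistent`. Node attribute `mean_degree` is the node's average
#' degree over the monthly networks in which it appears.
#'
#' @param monthly List of igraph networks (order irrelevant).
#' @param min_occurrence Minimum number of months a pair must recur in
#'   (default 3, counting an edge seen in exactly 3 months as recurrent).
#' @return igraph object (possibly empty).
#' @export
recurrence_network <- function(monthly, min_occurrence = 3) {
  if (length(monthly) < min_occurrence)
    stop("need at least ", min_occurrence, " monthly networks")
  tags <- names(monthly)
  if (is.null(tags)) tags <- vapply(monthly, function(g) {
    mo <- igraph::graph_attr(g, "month")
    if (is.null(mo)) NA_character_ else mo
  }, character(1))
  tags <- ifelse(is.na(tags) | tags == "", as.character(seq_along(monthly)),
                 tags)

  rec <- new.env(parent = emptyenv())
  for (i in seq_along(monthly)) {
    g <- monthly[[i]]
    if (igraph::ecount(g) == 0) next
    ends <- igraph::as_edgelist(g, names = TRUE)
    key <- paste(pmin(ends[, 1], ends[, 2]), pmax(ends[, 1], ends[, 2]),
                 sep = "\r")
    rho <- igraph::E(g)$rho
    for (j in seq_along(key)) {
      cur <- rec[[key[j]]]
      if (is.null(cur)) cur <- list(months = character(0), rho = numeric(0))
      cur$months <- c(cur$months, tags[i])
      cur$rho <- c(cur$rho, rho[j])
      rec[[key[j]]] <- cur
    }
  }
  keys <- ls(rec)
  occ <- vapply(keys, function(k) length(rec[[k]]$months), integer(1))
  keys <- keys[occ >= min_occurrence]
  if (length(keys) == 0) {
    cn_log("recurrence_network: no pair recurred often enough", level = "WARN")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  pairs <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  months_present <- lapply(keys, function(k) {
    mo <- rec[[k]]$months
    mo[order(match(mo, MONTH_LEVELS), mo)]
  })
  edges <- data.frame(
    from = pairs[, 1], to = pairs[, 2],
    occurrence = vapply(keys, function(k) length(rec[[k]]$months),
                        integer(1)),
    months = vapply(months_present, paste, character(1), collapse = ","),
    mean_rho = vapply(keys, function(k) mean(rec[[k]]$rho), numeric(1)),
    sign_consistent = vapply(keys, function(k)
      length(unique(sign(rec[[k]]$rho))) == 1, logical(1)),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), ]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)

  nm <- igraph::V(g)$name
  deg_sum <- setNames(numeric(length(nm)), nm)
  deg_n <- setNames(integer(length(nm)), nm)
  for (gm in monthly) {
    if (igraph::vcount(gm) == 0) next
    present <- intersect(nm, igraph::V(gm)$name)
    if (length(present) == 0) next
    d <- igraph::degree(gm)[present]
    deg_sum[present] <- deg_sum[present] + d
    deg_n[present] <- deg_n[present] + 1L
  }
  g <- igraph::set_vertex_attr(g, "mean_degree",
                               value = ifelse(deg_n > 0, deg_sum / deg_n, 0))
  g
}
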