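#' Per-sample relative abundance
#'
#' Closes each sample (column) to sum 1; all-zero samples stay all-zero.
#'
#' @param counts Count matrix (OTU x sample) or [otu_table()].
#' @return Real matrix with columns summing to 1 (or 0).
#' @export
relative_abundance <- function(counts) {
  if (inherits(counts, "otu_table")) counts <- counts$counts
  tot <- colSums(counts)
  tot[tot == 0] <- 1
  sweep(counts, 2, tot, "/")
}

#' Abundance + prevalence OTU filter
#'
#' Keeps an OTU iff, over the given samples (one size fraction's samples in
#' the intended use), its maximum per-sample relative abundance exceeds
#' `max_relabund_min` AND it is present (count > 0) in more than
#' `prevalence_min` of the samples. Both comparisons are strict, so an OTU
#' sitting exactly on a threshold is dropped.
#'
#' @param counts Count matrix (OTU x sample) or [otu_table()], already
#'   subset to the samples the filter should be judged on.
#' @param max_relabund_min Relative-abundance threshold (default 0.001, i.e.
#'   0.1%).
#' @param prevalence_min Prevalence threshold as a fraction of samples
#'   (default 0.7).
#' @return Character vector of retained OTU ids.
#' @export
filter_otus <- function(counts, max_relabund_min = 0.001,
                        prevalence_min = 0.7) {
  if (inherits(counts, "otu_table")) counts <- counts$counts
  if (ncol(counts) == 0) stop("no samples to filter on")
  rel <- relative_abundance(counts)
  max_rel <- apply(rel, 1, max)
  prev <- rowMeans(counts > 0)
  rownames(counts)[max_rel > max_relabund_min & prev > prevalence_min]
}

#' Prevalence filter for phytoplankton genera
#'
#' Keeps a genus iff it is observed (count > 0) in strictly more than
#' `prevalence_min` of the samples; no abundance clause.
#'
#' @param phyto Genus x sample count matrix.
#' @param prevalence_min Prevalence threshold (default 0.7).
#' @return Character vector of retained genus names (empty input gives an
#'   empty result, no error).
#' @export
filter_phyto <- function(phyto, prevalence_min = 0.7) {
  if (is.null(phyto) || nrow(phyto) == 0) return(character(0))
  rownames(phyto)[rowMeans(phyto > 0) > prevalence_min]
}

#' Arcsine square-root transform of a proportion
#'
#' `asin(sqrt(p))` in radians; the variance-stabilising transform used for
#' family-level relative abundances.
#'
#' @param p Proportions in \[0, 1\].
#' @return Transformed values in \[0, pi/2\].
#' @export
arcsine_transform <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("proportions must lie in [0, 1]")
  asin(sqrt(p))
}

#' log10(x + 1) transform for phytoplankton counts
#'
#' The pseudocount keeps zero counts representable (log10(0+1) = 0).
#'
#' @param x Non-negative counts.
#' @return Transformed values.
#' @export
log10_phyto <- function(x) {
  if (any(x < 0)) stop("counts must be non-negative")
  log10(x + 1)
}

#' Top-k most enriched families, averaged within fraction x depth groups
#'
#' Aggregates OTU relative abundances to family level, averages within each
#' fraction x depth group, ranks families by overall mean relative abundance
#' and returns the top `k` (all families when fewer than `k` exist).
#'
#' @param relabund Relative-abundance matrix (OTU x sample).
#' @param taxonomy Taxonomy table with `otu_id` and `family` columns.
#' @param meta Sample metadata with `sample_id`, `fraction`, `depth`.
#' @param k Number of families to keep (default 10).
#' @return List: `means` (family x group matrix of mean relative
#'   abundances), `arcsine` (same, arcsine-transformed), `overall` (named
#'   overall means used for ranking).
#' @export
top_families <- function(relabund, taxonomy, meta, k = 10) {
  fam <- taxonomy$family[match(rownames(relabund), taxonomy$otu_id)]
  fam[is.na(fam)] <- "unclassified"
  fam_mat <- rowsum(relabund, group = fam)
  grp <- paste(meta$fraction[match(colnames(relabund), meta$sample_id)],
               meta$depth[match(colnames(relabund), meta$sample_id)],
               sep = ".")
  means <- t(rowsum(t(fam_mat), group = grp) /
               as.vector(table(grp)[sort(unique(grp))]))
  overall <- rowMeans(fam_mat)
  top <- names(sort(overall, decreasing = TRUE))[seq_len(min(k, length(overall)))]
  means <- means[top, , drop = FALSE]
  list(means = means, arcsine = arcsine_transform(pmin(means, 1)),
       overall = overall[top])
}

#' Shannon diversity (natural log)
#'
#' `H = -sum p_i ln p_i` over taxa with positive counts.
#'
#' @param x Count vector for one sample, or matrix with samples in columns.
#' @return H per sample, in nats.
#' @export
shannon <- function(x) {
  if (is.matrix(x)) return(apply(x, 2, shannon))
  vegan::diversity(x, index = "shannon")
}

#' Chao1 richness estimator (bias-corrected)
#'
#' `S_obs + n1 (n1 - 1) / (2 (n2 + 1))` with `n1`/`n2` the singleton and
#' doubleton counts.
#'
#' @param x Count vector for one sample.
#' @return List: `chao1`, `s_obs`, `n1`, `n2`, `n_reads`.
#' @export
chao1 <- function(x) {
  if (any(x != round(x))) stop("Chao1 needs integer counts")
  s_obs <- sum(x > 0)
  n1 <- sum(x == 1)
  n2 <- sum(x == 2)
  list(chao1 = s_obs + n1 * (n1 - 1) / (2 * (n2 + 1)),
       s_obs = s_obs, n1 = n1, n2 = n2, n_reads = sum(x))
}

#' Simpson's evenness index
#'
#' `E = (1/D) / S_obs` with the unbiased Simpson concentration
#' `D = sum n_i (n_i - 1) / (N (N - 1))`. When D = 0 (all taxa singletons)
#' E is defined as 1. On very small samples E can exceed 1; values are
#' reported as computed, not clamped.
#'
#' @param x Count vector for one sample.
#' @return Evenness E.
#' @export
simpson_evenness <- function(x) {
  x <- x[x > 0]
  s_obs <- length(x)
  if (s_obs == 0) return(NA_real_)
  n <- sum(x)
  if (n < 2) return(1)
  d <- sum(x * (x - 1)) / (n * (n - 1))
  if (d == 0) return(1)
  (1 / d) / s_obs
}

#' Per-sample alpha-diversity summary
#'
#' @param otu An [otu_table()] or count matrix.
#' @return Data frame per sample: `shannon`, `chao1`, `simpson_evenness`,
#'   plus the raw ingredients `s_obs`, `n1`, `n2`, `n_reads`.
#' @export
diversity_summary <- function(otu) {
  counts <- if (inherits(otu, "otu_table")) otu$counts else otu
  rows <- lapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    ch <- chao1(x)
    data.frame(sample_id = colnames(counts)[j],
               shannon = shannon(x),
               chao1 = ch$chao1,
               simpson_evenness = simpson_evenness(x),
               s_obs = ch$s_obs, n1 = ch$n1, n2 = ch$n2,
               n_reads = ch$n_reads,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman correlations between diversity indices and environment
#'
#' @param div Output of [diversity_summary()] (uses shannon, chao1,
#'   simpson_evenness).
#' @param env Numeric matrix/data.frame of environmental variables aligned
#'   to the same samples (rows).
#' @return Data frame of index/variable pairs with `rho`, `p`, `q` (BH).
#' @export
diversity_env_correlation <- function(div, env) {
  idx <- as.matrix(div[, c("shannon", "chao1", "simpson_evenness")])
  env <- as.matrix(env)
  stopifnot(nrow(idx) == nrow(env))
  X <- t(cbind(idx, env))
  res <- spearman_matrix(X)
  pairs <- expand.grid(index = colnames(idx), variable = colnames(env),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs$rho <- res$rho[cbind(pairs$index, pairs$variable)]
  pairs$p <- res$p[cbind(pairs$index, pairs$variable)]
  pairs$q <- bh_fdr(pairs$p)
  pairs
}
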