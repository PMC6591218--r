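#' OTU count table
#'
#' Lightweight container for a non-negative integer count matrix with OTUs in
#' rows and samples in columns. Construction validates the invariants every
#' downstream step relies on: unique ids, finite non-negative integer counts.
#'
#' @param counts Numeric matrix (OTU x sample) with dimnames.
#' @return An `otu_table` object.
#' @export
otu_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry OTU ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate OTU id: ",
         rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ",
         colnames(counts)[duplicated(colnames(counts))][1])
  if (any(!is.finite(counts)))
    stop("counts contain non-finite values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 otu_ids = rownames(counts),
                 sample_ids = colnames(counts)),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples, %s total reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Read an OTU count table from TSV
#'
#' Canonical dialect: tab-separated, UTF-8, `.` decimal, no quoting; first
#' column holds OTU ids, header row holds sample ids. Cells must be
#' non-negative integers; violations are reported with their row and column.
#'
#' @param path Input TSV.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) stop("OTU table needs an id column plus samples: ", path)
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
  bad <- which(is.na(num) | !is.finite(num) | num != round(num) | num < 0,
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-integer count at OTU '%s', sample '%s' (value '%s')",
                 ids[bad[1, 1]], colnames(m)[bad[1, 2]],
                 m[bad[1, 1], bad[1, 2]]))
  dimnames(num) <- list(ids, colnames(m))
  otu_table(num)
}

#' Write an OTU count table as canonical TSV
#'
#' Inverse of [read_otu_table()]; output is byte-stable so round trips are
#' diffable.
#'
#' @param otu An [otu_table()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_otu_table <- function(otu, path) {
  df <- data.frame(otu_id = otu$otu_ids, otu$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `month`, `station`, `depth`, `fraction`
#' (and optionally `unit_id`). Vocabularies are closed: months
#' Jul/Aug/Sept/Oct/Dec, depths surface/middle/bottom, fractions FL/NP/MP.
#'
#' @param path Input TSV.
#' @return Data frame of metadata.
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "month", "station", "depth", "fraction")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  bad_month <- setdiff(unique(df$month), MONTH_LEVELS)
  if (length(bad_month)) stop("unknown month label: ", bad_month[1])
  bad_depth <- setdiff(unique(df$depth), DEPTH_LEVELS)
  if (length(bad_depth)) stop("unknown depth label: ", bad_depth[1])
  bad_frac <- setdiff(unique(df$fraction), FRACTION_LEVELS)
  if (length(bad_frac)) stop("unknown fraction label: ", bad_frac[1])
  if (!"unit_id" %in% names(df))
    df$unit_id <- paste(df$month, df$station, df$depth, sep = "_")
  df
}

#' Read an environmental-parameter table
#'
#' TSV keyed by `unit_id` (one row per water sample) with numeric columns;
#' missing values must be encoded as NA, not blanks-as-zero.
#'
#' @param path Input TSV.
#' @return Data frame.
#' @export
read_env_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"unit_id" %in% names(df)) stop("env table needs a unit_id column")
  if (anyDuplicated(df$unit_id)) stop("duplicate unit_id in env table")
  df
}

#' Read a Silva-style taxonomy lineage table
#'
#' TSV with columns `otu_id` and the ranked lineage `domain`, `phylum`,
#' `class`, `order`, `family`, `genus`. Empty ranks are normalised to
#' `"unclassified"`.
#'
#' @param path Input TSV.
#' @return Data frame of lineages.
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  miss <- setdiff(c("otu_id", ranks), names(df))
  if (length(miss)) stop("taxonomy missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$otu_id)) stop("duplicate otu_id in taxonomy")
  for (r in ranks) {
    x <- df[[r]]
    x[is.na(x) | x == ""] <- "unclassified"
    df[[r]] <- x
  }
  df[, c("otu_id", ranks)]
}

#' Bundle aligned OTU, metadata and environmental tables
#'
#' Aligns everything on sample ids (metadata) and unit ids (environment).
#' Samples missing from any table are dropped with a logged count, or raise
#' an error in strict mode.
#'
#' @param otu An [otu_table()].
#' @param meta Sample metadata (see [read_sample_metadata()]).
#' @param env Environmental table keyed by `unit_id`.
#' @param taxonomy Optional taxonomy table.
#' @param phyto Optional phytoplankton genus-count matrix (genus x unit).
#' @param strict Error instead of dropping misaligned samples.
#' @return A `cooc_bundle` list: `otu`, `meta`, `env`, `taxonomy`, `phyto`.
#' @export
join_tables <- function(otu, meta, env, taxonomy = NULL, phyto = NULL,
                        strict = FALSE) {
  stopifnot(inherits(otu, "otu_table"))
  keep <- intersect(otu$sample_ids, meta$sample_id)
  meta2 <- meta[match(keep, meta$sample_id), ]
  keep <- keep[meta2$unit_id %in% env$unit_id]
  if (length(keep) == 0) stop("no samples shared between tables")
  n_drop <- length(otu$sample_ids) - length(keep)
  if (n_drop > 0) {
    if (strict) stop(n_drop, " samples missing from metadata/env tables")
    cn_log(sprintf("join_tables: dropped %d of %d samples without full metadata/env",
                   n_drop, length(otu$sample_ids)), level = "WARN")
  }
  otu2 <- otu_table(otu$counts[, keep, drop = FALSE])
  meta2 <- meta[match(keep, meta$sample_id), ]
  rownames(meta2) <- NULL
  structure(list(otu = otu2, meta = meta2, env = env,
                 taxonomy = taxonomy, phyto = phyto),
            class = "cooc_bundle")
}

#' @export
print.cooc_bundle <- function(x, ...) {
  cat(sprintf("cooc_bundle: %d OTUs x %d samples; %d env units%s%s\n",
              nrow(x$otu$counts), ncol(x$otu$counts), nrow(x$env),
              if (is.null(x$taxonomy)) "" else "; taxonomy",
              if (is.null(x$phyto)) "" else "; phytoplankton"))
  invisible(x)
}

#' Export a network as GraphML
#'
#' Writes the igraph network with all node attributes (kind, fraction,
#' module if present) and edge attributes (rho, q, sign) so it can be
#' re-imported, e.g. into Cytoscape.
#'
#' @param network An igraph network as built by [build_network()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(network, path) {
  stopifnot(igraph::is_igraph(network))
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}

#' Export a network as a TSV edge list
#'
#' Columns `source`, `target`, `rho`, `q`, `sign` in a fixed order, suitable
#' for Cytoscape's table import.
#'
#' @inheritParams write_graphml
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(igraph::is_igraph(network))
  if (igraph::ecount(network) == 0) {
    df <- data.frame(source = character(), target = character(),
                     rho = numeric(), q = numeric(), sign = character())
  } else {
    ends <- igraph::as_edgelist(network, names = TRUE)
    df <- data.frame(source = ends[, 1], target = ends[, 2],
                     rho = igraph::E(network)$rho,
                     q = igraph::E(network)$q,
                     sign = igraph::E(network)$sign,
                     stringsAsFactors = FALSE)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are
#' auto-typed (numeric where possible, comma-split into vectors).
#'
#' @param path Input file.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stop("malformed config line: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}
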