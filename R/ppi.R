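#' Build a protein-protein interaction graph from an edge table
#'
#' Filters a STRING-style edge list to high-confidence interactions (score
#' strictly greater than the threshold), removes self-loops, collapses
#' duplicate/reversed rows into single undirected edges, and returns an
#' [igraph][igraph::graph_from_data_frame] graph. STRING publishes combined
#' scores on a 0-1000 scale; a threshold quoted as a probability (e.g. 0.9,
#' the "highest confidence" cut) corresponds to 900 on that scale. The scale
#' must be declared explicitly or left to `"auto"`, which picks `"raw"`
#' (0-1000) whenever any score exceeds 1.
#'
#' @param edge_table data.frame with columns `gene_a`, `gene_b`, `score`
#'   (extra columns ignored; STRING column names `protein1`, `protein2`,
#'   `combined_score` are also accepted).
#' @param score_threshold keep edges with `score > score_threshold`.
#' @param scale `"auto"`, `"raw"` (0-1000) or `"unit"` (0-1).
#' @return An undirected `igraph` object with a `score` edge attribute.
#' @export
build_ppi <- function(edge_table, score_threshold = 900,
                      scale = c("auto", "raw", "unit")) {
  scale <- match.arg(scale)
  cols <- names(edge_table)
  alias <- c(protein1 = "gene_a", protein2 = "gene_b", combined_score = "score")
  for (a in names(alias)) {
    if (a %in% cols && !(alias[[a]] %in% cols)) {
      names(edge_table)[names(edge_table) == a] <- alias[[a]]
    }
  }
  need <- c("gene_a", "gene_b", "score")
  if (!all(need %in% names(edge_table))) {
    stop_dtimoa("dtimoa_parse_error",
                "edge table must have columns gene_a, gene_b, score (or STRING names)")
  }
  bad <- which(is.na(edge_table$gene_a) | is.na(edge_table$gene_b) |
                 !is.finite(suppressWarnings(as.numeric(edge_table$score))))
  if (length(bad) > 0) {
    stop_dtimoa("dtimoa_parse_error", "malformed edge row(s) at line(s): %s",
                paste(utils::head(bad, 5), collapse = ", "))
  }
  edge_table$score <- as.numeric(edge_table$score)
  if (scale == "auto") {
    scale <- if (any(edge_table$score > 1)) "raw" else "unit"
  }
  max_scale <- if (scale == "raw") 1000 else 1
  if (score_threshold < 0 || score_threshold > max_scale) {
    stop_dtimoa("dtimoa_invalid_config",
                "threshold %s outside declared %s scale [0, %s]",
                format(score_threshold), scale, format(max_scale))
  }
  if (any(edge_table$score < 0 | edge_table$score > max_scale)) {
    stop_dtimoa("dtimoa_parse_error", "edge score outside declared %s scale", scale)
  }
  keep <- edge_table[edge_table$score > score_threshold &
                       edge_table$gene_a != edge_table$gene_b, , drop = FALSE]
  if (nrow(keep) > 0) {
    a <- pmin(keep$gene_a, keep$gene_b)
    b <- pmax(keep$gene_a, keep$gene_b)
    ord <- !duplicated(paste(a, b, sep = "\r"))
    keep <- data.frame(gene_a = a[ord], gene_b = b[ord],
                       score = keep$score[ord], stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(keep, directed = FALSE,
                                     vertices = unique(c(edge_table$gene_a,
                                                         edge_table$gene_b)))
  g
}

#' Neighbours of a gene in a PPI graph
#'
#' @param graph an igraph PPI graph from [build_ppi()].
#' @param gene gene symbol; must be a node of the graph.
#' @return Character vector of neighbouring gene symbols (never includes the
#'   gene itself).
#' @export
ppi_neighbors <- function(graph, gene) {
  if (!(gene %in% igraph::V(graph)$name)) {
    stop_dtimoa("dtimoa_lookup_error", "gene '%s' not in PPI graph", gene)
  }
  nb <- igraph::neighbors(graph, gene)$name
  setdiff(unique(nb), gene)
}

#' Infer a missing target vector from PPI neighbours
#'
#' Estimates the consensus target vector of a gene as the correlation-weighted
#' average ([weighted_average()]) of the measured vectors of its direct PPI
#' neighbours. Only one-hop neighbours are used, the gene's own measured
#' vector (if any) is always excluded, and at least `min_neighbors` covered
#' neighbours are required — otherwise the gene is not inferable and `NULL`
#' is returned.
#'
#' @param gene gene symbol (must be a node of `graph`).
#' @param graph igraph PPI graph.
#' @param store [target_store()] holding measured vectors.
#' @param min_neighbors minimum covered neighbours (default 3).
#' @param floor correlation floor for the weighted average.
#' @return List with `vector`, `provenance = "inferred"`, `n_support`,
#'   `neighbors`; or `NULL` when fewer than `min_neighbors` neighbours carry
#'   measured vectors.
#' @export
infer_vector <- function(gene, graph, store, min_neighbors = 3, floor = 0.01) {
  stopifnot(inherits(store, "target_store"))
  nb <- ppi_neighbors(graph, gene)
  covered <- nb[nb %in% store_genes(store, "measured")]
  if (length(covered) < min_neighbors) return(NULL)
  covered <- sort(covered)  # iteration-order independence
  vecs <- lapply(covered, function(g) store_get(store, g, "measured")$vector)
  agg <- weighted_average(vecs, floor = floor)
  list(vector = agg$vector, provenance = "inferred",
       n_support = length(covered), neighbors = covered,
       weights = agg$weights)
}

#' Infer vectors for all eligible genes of a PPI graph
#'
#' Runs [infer_vector()] over every node of the graph (optionally restricted
#' to `genes`) and adds the results to the store as inferred entries.
#' Measured entries are kept; a gene can hold both, and [store_get()] prefers
#' the measured one.
#'
#' @param graph igraph PPI graph.
#' @param store [target_store()] with measured entries.
#' @param genes optional character vector restricting the inference targets.
#' @param min_neighbors,floor passed to [infer_vector()].
#' @return The extended `target_store`.
#' @export
infer_all <- function(graph, store, genes = NULL, min_neighbors = 3, floor = 0.01) {
  nodes <- igraph::V(graph)$name
  if (!is.null(genes)) nodes <- intersect(nodes, genes)
  for (g in sort(nodes)) {
    res <- infer_vector(g, graph, store, min_neighbors = min_neighbors, floor = floor)
    if (!is.null(res)) {
      store <- store_set(store, g, res$vector, "inferred", n_support = res$n_support)
    }
  }
  store
}

#' Validate inferred vectors against measured ones
#'
#' For genes holding both a measured and an inferred vector, computes the
#' Spearman correlation between the two ("within-gene") and, for mismatched
#' gene pairs, between the inferred vector of one gene and the measured
#' vector of another ("between-gene"). If inference tracks real biology, the
#' within-gene distribution should stochastically dominate the between-gene
#' one; a one-sided Wilcoxon rank-sum test summarises the comparison.
#'
#' @param store_measured [target_store()] holding measured vectors.
#' @param store_inferred [target_store()] holding inferred vectors (may be
#'   the same object holding both provenances).
#' @param max_between cap on the number of between-gene pairs evaluated
#'   (pairs are enumerated deterministically row-major and truncated).
#' @return List with `within`, `between` (named numeric vectors),
#'   `median_within`, `median_between`, `p_value`, `statistic`.
#' @export
inference_validation <- function(store_measured, store_inferred,
                                 max_between = 5000) {
  genes <- intersect(store_genes(store_measured, "measured"),
                     store_genes(store_inferred, "inferred"))
  if (length(genes) == 0) {
    stop_dtimoa("dtimoa_invalid_input",
                "no genes hold both measured and inferred vectors")
  }
  genes <- sort(genes)
  meas <- lapply(genes, function(g) store_get(store_measured, g, "measured")$vector)
  infv <- lapply(genes, function(g) store_get(store_inferred, g, "inferred")$vector)
  names(meas) <- names(infv) <- genes
  within <- vapply(genes, function(g) spearman_correlation(infv[[g]], meas[[g]]),
                   numeric(1))
  pairs <- expand.grid(i = seq_along(genes), j = seq_along(genes))
  pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
  if (nrow(pairs) > max_between) pairs <- pairs[seq_len(max_between), , drop = FALSE]
  between <- vapply(seq_len(nrow(pairs)), function(k) {
    spearman_correlation(infv[[pairs$i[k]]], meas[[pairs$j[k]]])
  }, numeric(1))
  names(between) <- paste(genes[pairs$i], genes[pairs$j], sep = "~")
  wt <- stats::wilcox.test(within, between, alternative = "greater", exact = FALSE)
  list(within = within, between = between,
       median_within = stats::median(within),
       median_between = stats::median(between),
       p_value = wt$p.value, statistic = unname(wt$statistic))
}
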