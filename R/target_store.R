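#' Per-mode store of consensus target vectors
#'
#' Maps gene symbols to consensus target vectors for one mode of action
#' (activatory = overexpression-derived, inhibitory = knockdown-derived).
#' Each entry is tagged with its provenance: `"measured"` for vectors
#' aggregated from genetically perturbed signatures, `"inferred"` for vectors
#' imputed from PPI neighbours. Lookup prefers measured over inferred when a
#' gene carries both.
#'
#' @param mode `"activatory"` or `"inhibitory"`.
#' @param panel the [gene_panel()] all vectors are expressed on.
#' @return An object of class `target_store`.
#' @export
target_store <- function(mode = c("activatory", "inhibitory"), panel) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "gene_panel"))
  structure(list(mode = mode, panel = panel, entries = list()),
            class = "target_store")
}

#' Insert or replace a target vector
#'
#' @param store a [target_store()].
#' @param gene gene symbol.
#' @param vector numeric vector of panel length.
#' @param provenance `"measured"` or `"inferred"`.
#' @param n_support number of members behind the vector (replicates for
#'   measured entries, covered neighbours for inferred ones).
#' @return The updated store.
#' @export
store_set <- function(store, gene, vector, provenance = c("measured", "inferred"),
                      n_support = 1L) {
  stopifnot(inherits(store, "target_store"))
  provenance <- match.arg(provenance)
  assert_numeric_vector(vector, "vector")
  if (length(vector) != store$panel$size) {
    stop_dtimoa("dtimoa_invalid_input", "vector length %d != panel size %d",
                length(vector), store$panel$size)
  }
  store$entries[[paste0(provenance, "\r", gene)]] <-
    list(gene = as.character(gene), vector = as.numeric(vector),
         provenance = provenance, n_support = as.integer(n_support))
  store
}

#' Look up a target vector
#'
#' @param store a [target_store()].
#' @param gene gene symbol.
#' @param provenance `"any"` (measured preferred), `"measured"`, or
#'   `"inferred"`.
#' @return The entry (list with `vector`, `provenance`, `n_support`) or
#'   `NULL` if absent.
#' @export
store_get <- function(store, gene, provenance = c("any", "measured", "inferred")) {
  provenance <- match.arg(provenance)
  keys <- switch(provenance,
                 any      = paste0(c("measured", "inferred"), "\r", gene),
                 measured = paste0("measured\r", gene),
                 inferred = paste0("inferred\r", gene))
  for (k in keys) {
    if (!is.null(store$entries[[k]])) return(store$entries[[k]])
  }
  NULL
}

#' Genes present in a store
#'
#' @param store a [target_store()].
#' @param provenance filter: `"any"`, `"measured"` or `"inferred"`.
#' @return Character vector of gene symbols.
#' @export
store_genes <- function(store, provenance = c("any", "measured", "inferred")) {
  provenance <- match.arg(provenance)
  if (length(store$entries) == 0) return(character(0))
  prov <- vapply(store$entries, `[[`, character(1), "provenance")
  genes <- vapply(store$entries, `[[`, character(1), "gene")
  if (provenance != "any") genes <- genes[prov == provenance]
  unique(unname(genes))
}

#' @export
print.target_store <- function(x, ...) {
  cat("<target_store> mode=", x$mode, ", G=", x$panel$size,
      ", measured=", length(store_genes(x, "measured")),
      ", inferred=", length(store_genes(x, "inferred")), "\n", sep = "")
  invisible(x)
}

#' Build a measured target store from a set of signatures
#'
#' Groups signatures by perturbed gene for one perturbation kind and runs the
#' two-stage consensus aggregation ([aggregate_target()]) per gene.
#'
#' @param signatures list of [signature()] objects (mixed kinds allowed; only
#'   the requested kind is used).
#' @param kind `"overexpression"` or `"knockdown"`; determines the store mode.
#' @param floor correlation floor for [weighted_average()].
#' @return A `target_store` with measured entries.
#' @export
build_target_store <- function(signatures, kind = c("knockdown", "overexpression"),
                               floor = 0.01) {
  kind <- match.arg(kind)
  keep <- Filter(function(s) s$perturbation_kind == kind, signatures)
  if (length(keep) == 0) {
    stop_dtimoa("dtimoa_empty_input", "no %s signatures supplied", kind)
  }
  store <- target_store(perturbation_mode(kind), keep[[1]]$panel)
  by_gene <- split(keep, vapply(keep, `[[`, character(1), "perturbed_gene"))
  for (g in names(by_gene)) {
    agg <- aggregate_target(by_gene[[g]], floor = floor)
    store <- store_set(store, g, agg$vector, "measured",
                       n_support = length(by_gene[[g]]))
  }
  store
}
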