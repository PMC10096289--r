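#' Gene panel: the fixed gene axis of a signature study
#'
#' A gene panel fixes the identity and order of the genes over which every
#' signature in a study is expressed (the landmark panel of the L1000 assay
#' has 978 genes; synthetic studies use smaller panels). All signatures,
#' consensus vectors and inferred vectors in one study share one panel, and
#' readers re-order incoming matrices to it rather than imputing.
#'
#' @param gene_ids character vector of unique gene symbols/identifiers.
#' @return An object of class `gene_panel`.
#' @export
#' @examples
#' gene_panel(c("STAT3", "TP53", "MYC"))
gene_panel <- function(gene_ids) {
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) < 1 || anyDuplicated(gene_ids) > 0 || any(is.na(gene_ids))) {
    stop_dtimoa("dtimoa_invalid_input", "gene ids must be non-empty and unique")
  }
  structure(list(gene_ids = gene_ids, size = length(gene_ids)),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("<gene_panel> ", x$size, " genes: ",
      paste(utils::head(x$gene_ids, 4), collapse = ", "),
      if (x$size > 4) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' A single perturbational signature
#'
#' One z-score profile over a [gene_panel()], measured after a genetic
#' perturbation (cDNA overexpression or shRNA knockdown) of one gene in one
#' cell line under one experimental condition (dose/time combination).
#' Overexpression signatures represent activatory target states; knockdown
#' signatures represent inhibitory ones.
#'
#' @param values numeric z-score vector, same length and order as `panel`.
#' @param perturbed_gene gene symbol of the perturbed gene.
#' @param perturbation_kind `"overexpression"` or `"knockdown"`.
#' @param cell_line cell line label.
#' @param condition label encoding the perturbational dose/time.
#' @param signature_id unique identifier string.
#' @param panel a [gene_panel()].
#' @return An object of class `signature`.
#' @export
signature <- function(values, perturbed_gene, perturbation_kind,
                      cell_line, condition, signature_id, panel) {
  stopifnot(inherits(panel, "gene_panel"))
  assert_numeric_vector(values, "values")
  if (length(values) != panel$size) {
    stop_dtimoa("dtimoa_invalid_input",
                "signature length %d does not match panel size %d",
                length(values), panel$size)
  }
  perturbation_kind <- match.arg(perturbation_kind, c("overexpression", "knockdown"))
  structure(list(values = as.numeric(values),
                 perturbed_gene = as.character(perturbed_gene),
                 perturbation_kind = perturbation_kind,
                 cell_line = as.character(cell_line),
                 condition = as.character(condition),
                 signature_id = as.character(signature_id),
                 panel = panel),
            class = "signature")
}

#' Map a perturbation kind to its mode of action
#'
#' Overexpression signatures stand for activatory target states, knockdown
#' signatures for inhibitory ones.
#'
#' @param kind `"overexpression"` or `"knockdown"`.
#' @return `"activatory"` or `"inhibitory"`.
#' @export
perturbation_mode <- function(kind) {
  kind <- match.arg(kind, c("overexpression", "knockdown"))
  c(overexpression = "activatory", knockdown = "inhibitory")[[kind]]
}

# Accept either signature objects or bare numeric vectors and return the
# numeric matrix (columns = members) plus ids; enforces a shared panel.
#' @noRd
signature_values <- function(signatures) {
  if (length(signatures) == 0) {
    stop_dtimoa("dtimoa_empty_input", "no signatures supplied")
  }
  if (is.numeric(signatures)) signatures <- list(signatures)
  vecs <- lapply(signatures, function(s) if (inherits(s, "signature")) s$values else s)
  panels <- unique(vapply(signatures, function(s)
    if (inherits(s, "signature")) paste(s$panel$gene_ids, collapse = "\r") else NA_character_,
    character(1)))
  panels <- panels[!is.na(panels)]
  if (length(panels) > 1) {
    stop_dtimoa("dtimoa_invalid_input", "signatures reference different gene panels")
  }
  lens <- vapply(vecs, length, integer(1))
  if (length(unique(lens)) != 1) {
    stop_dtimoa("dtimoa_invalid_input", "signature vectors differ in length")
  }
  ids <- vapply(seq_along(signatures), function(i) {
    s <- signatures[[i]]
    if (inherits(s, "signature")) s$signature_id else paste0("v", i)
  }, character(1))
  list(mat = do.call(cbind, vecs), ids = ids)
}

#' Spearman rank correlation between two signature vectors
#'
#' Ranks (average ranks on ties) followed by the Pearson correlation of the
#' ranks. A pair involving a constant vector (zero rank variance) is defined
#' to have correlation 0, so that degenerate replicates neither attract nor
#' repel weight during aggregation.
#'
#' @param a,b numeric vectors of equal length `>= 2`.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
#' @examples
#' spearman_correlation(c(1, 2, 3, 4), c(4, 3, 2, 1))
spearman_correlation <- function(a, b) {
  assert_numeric_vector(a, "a"); assert_numeric_vector(b, "b")
  if (length(a) != length(b) || length(a) < 2) {
    stop_dtimoa("dtimoa_invalid_input",
                "inputs must have equal length >= 2 (got %d and %d)",
                length(a), length(b))
  }
  ra <- rank(a); rb <- rank(b)
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) return(0)
  stats::cor(ra, rb, method = "pearson")
}

#' Pairwise Spearman correlation matrix of a signature set
#'
#' @param signatures list of [signature()] objects (or bare numeric vectors)
#'   on a shared gene panel.
#' @return Symmetric n x n matrix with unit diagonal.
#' @export
correlation_matrix <- function(signatures) {
  sv <- signature_values(signatures)
  n <- ncol(sv$mat)
  R <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        R[i, j] <- R[j, i] <- spearman_correlation(sv$mat[, i], sv$mat[, j])
      }
    }
  }
  dimnames(R) <- list(sv$ids, sv$ids)
  R
}

#' Correlation-weighted average of replicate signatures
#'
#' The MODZ-style consensus: each replicate is weighted by the sum of its
#' Spearman correlations to the other replicates (self-correlation excluded),
#' weights are normalised to sum to one, and the consensus is the weighted
#' average. Off-diagonal correlations are floored at `floor` before the row
#' sums so that anti-correlated or degenerate replicates cannot produce
#' negative or zero weight mass; with `floor > 0` every weight is strictly
#' positive and the consensus lies in the convex hull of the inputs.
#'
#' Degenerate cases are forced by the formula and implemented as fast paths:
#' a single signature is returned unchanged with weight 1, and any pair gets
#' weights (1/2, 1/2) because both row sums equal the single mutual
#' correlation.
#'
#' @param signatures list of [signature()] objects or numeric vectors.
#' @param floor correlation floor applied to off-diagonal entries
#'   (default `0.01`).
#' @return An object of class `aggregation_result`: list with elements
#'   `vector`, `weights`, `n_inputs`, `member_ids`.
#' @export
#' @examples
#' weighted_average(list(c(1, 2, 3, 4, 5), c(1, 2, 3, 5, 4), c(5, 4, 3, 2, 1)))
weighted_average <- function(signatures, floor = 0.01) {
  sv <- signature_values(signatures)
  n <- ncol(sv$mat)
  if (n == 1) {
    w <- 1
    vec <- sv$mat[, 1]
  } else if (n == 2) {
    w <- c(0.5, 0.5)
    vec <- rowMeans(sv$mat)
  } else if (all(sv$mat == sv$mat[, 1])) {
    # identical replicates: weights are forced uniform and the consensus is
    # the replicate itself, bit-exactly
    w <- rep(1 / n, n)
    vec <- sv$mat[, 1]
  } else {
    R <- correlation_matrix(signatures)
    off <- pmax(R, floor)
    diag(off) <- 0
    raw <- rowSums(off)
    w <- raw / sum(raw)
    vec <- as.numeric(sv$mat %*% w)
  }
  structure(list(vector = as.numeric(vec), weights = as.numeric(w),
                 n_inputs = n, member_ids = sv$ids),
            class = "aggregation_result")
}

#' @export
print.aggregation_result <- function(x, ...) {
  cat("<aggregation_result> ", x$n_inputs, " member(s), G = ",
      length(x$vector), "; weights: ",
      paste(signif(x$weights, 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Two-stage consensus vector for one perturbed gene and mode
#'
#' Collapses all replicate signatures of one (gene, perturbation kind) pair
#' into a single consensus target vector in two weighted-averaging stages:
#' first over experimental conditions within each cell line, then over the
#' per-cell-line consensus vectors. The staging prevents a cell line with
#' many replicates from dominating the consensus, which single-stage pooling
#' of all replicates would allow.
#'
#' @param signatures list of [signature()] objects sharing `perturbed_gene`
#'   and `perturbation_kind`.
#' @param floor correlation floor passed to [weighted_average()].
#' @param single_stage if `TRUE`, pool all signatures in one stage
#'   (diagnostic only; not the default pipeline behaviour).
#' @return An `aggregation_result` whose `vector` is the consensus target
#'   vector; `member_ids` are cell-line labels (two-stage) or signature ids
#'   (single-stage).
#' @export
aggregate_target <- function(signatures, floor = 0.01, single_stage = FALSE) {
  if (length(signatures) == 0) {
    stop_dtimoa("dtimoa_empty_input", "no signatures to aggregate")
  }
  if (!all(vapply(signatures, inherits, logical(1), "signature"))) {
    stop_dtimoa("dtimoa_invalid_input", "aggregate_target expects signature objects")
  }
  genes <- unique(vapply(signatures, `[[`, character(1), "perturbed_gene"))
  kinds <- unique(vapply(signatures, `[[`, character(1), "perturbation_kind"))
  if (length(genes) != 1 || length(kinds) != 1) {
    stop_dtimoa("dtimoa_invalid_input",
                "signatures must share one perturbed gene and perturbation kind")
  }
  if (single_stage) {
    return(weighted_average(signatures, floor = floor))
  }
  cells <- vapply(signatures, `[[`, character(1), "cell_line")
  by_cell <- split(signatures, cells)
  inner <- lapply(by_cell, weighted_average, floor = floor)
  outer <- weighted_average(lapply(inner, `[[`, "vector"), floor = floor)
  outer$member_ids <- names(by_cell)
  outer
}
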