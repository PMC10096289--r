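#' Parse a curated DTI table into positive records by mode
#'
#' Maps free-text mode-of-action terms onto the two modes: activator/agonist
#' terms become activatory interactions, inhibitor/antagonist terms become
#' inhibitory ones. Matching is case-insensitive; rows with unmapped terms
#' are dropped (and counted); duplicate (compound, target, mode) triples are
#' collapsed.
#'
#' @param table data.frame with columns `compound_id`, `target_gene`,
#'   `moa_term`.
#' @param moa_vocabulary named character vector mapping lower-case terms to
#'   modes; the default implements the activator/agonist vs
#'   inhibitor/antagonist convention.
#' @return List with `records` (data.frame: compound_id, target_gene, mode,
#'   label = "positive", source = "known") and `n_dropped`.
#' @export
parse_dti_table <- function(table,
                            moa_vocabulary = c(activator = "activatory",
                                               agonist = "activatory",
                                               inhibitor = "inhibitory",
                                               antagonist = "inhibitory")) {
  need <- c("compound_id", "target_gene", "moa_term")
  if (!all(need %in% names(table))) {
    stop_dtimoa("dtimoa_parse_error", "DTI table must have columns: %s",
                paste(need, collapse = ", "))
  }
  mode <- unname(moa_vocabulary[tolower(trimws(as.character(table$moa_term)))])
  keep <- !is.na(mode)
  rec <- data.frame(compound_id = as.character(table$compound_id)[keep],
                    target_gene = as.character(table$target_gene)[keep],
                    mode = mode[keep],
                    label = "positive", source = "known",
                    stringsAsFactors = FALSE)
  rec <- rec[!duplicated(rec[c("compound_id", "target_gene", "mode")]), , drop = FALSE]
  rownames(rec) <- NULL
  list(records = rec, n_dropped = sum(!keep))
}

#' Assemble a featurized DTI dataset for one mode and tier
#'
#' Keeps the positive records whose compound has an embedding vector and
#' whose target has a consensus vector with provenance matching the tier:
#' `"original"` requires a measured vector, `"additional"` an inferred one,
#' `"integrated"` accepts either (measured preferred). Each surviving record
#' gets the feature row `compound vector (+) target vector` (compound first),
#' of width `d + G`.
#'
#' @param positives data.frame of positive records (see [parse_dti_table()]);
#'   only rows of `mode` are used.
#' @param compound_vectors numeric matrix, rows = compound ids.
#' @param store [target_store()] for the mode.
#' @param tier `"original"`, `"additional"` or `"integrated"`.
#' @param mode `"activatory"` or `"inhibitory"`.
#' @return An object of class `dti_dataset`: list with `records`, `X`,
#'   `tier`, `mode`, `d`, `G`, `n_filtered`.
#' @export
assemble_dataset <- function(positives, compound_vectors, store,
                             tier = c("original", "additional", "integrated"),
                             mode = c("activatory", "inhibitory")) {
  tier <- match.arg(tier); mode <- match.arg(mode)
  stopifnot(inherits(store, "target_store"))
  pos <- positives[positives$mode == mode, , drop = FALSE]
  prov <- switch(tier, original = "measured", additional = "inferred",
                 integrated = "any")
  d <- ncol(compound_vectors); G <- store$panel$size
  keep <- logical(nrow(pos))
  rows <- vector("list", nrow(pos))
  for (i in seq_len(nrow(pos))) {
    cv <- if (pos$compound_id[i] %in% rownames(compound_vectors))
      compound_vectors[pos$compound_id[i], ] else NULL
    tv <- store_get(store, pos$target_gene[i], prov)
    if (!is.null(cv) && !is.null(tv)) {
      keep[i] <- TRUE
      rows[[i]] <- c(as.numeric(cv), tv$vector)
    }
  }
  X <- do.call(rbind, rows[keep])
  if (is.null(X)) X <- matrix(numeric(0), nrow = 0, ncol = d + G)
  rec <- pos[keep, , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(records = rec, X = X, tier = tier, mode = mode,
                 d = d, G = G, n_filtered = sum(!keep)),
            class = "dti_dataset")
}

#' @export
print.dti_dataset <- function(x, ...) {
  cat("<dti_dataset> ", x$mode, "/", x$tier, ": ", nrow(x$records),
      " records, feature width ", x$d, " + ", x$G, " (", x$n_filtered,
      " filtered)\n", sep = "")
  invisible(x)
}

# The negative sampling universe: all compound x target cells over the
# compounds and targets seen in the positive set of this mode, minus the
# same-mode positives themselves.
#' @noRd
negative_universe <- function(positives) {
  compounds <- sort(unique(positives$compound_id))
  targets <- sort(unique(positives$target_gene))
  grid <- expand.grid(compound_id = compounds, target_gene = targets,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pos_key <- paste(positives$compound_id, positives$target_gene, sep = "\r")
  grid[!(paste(grid$compound_id, grid$target_gene, sep = "\r") %in% pos_key), ,
       drop = FALSE]
}

#' Sample negative DTI pairs
#'
#' Draws `ratio * nrow(positives)` unique (compound, target) pairs uniformly
#' without replacement from the universe of all pairs over the compounds and
#' targets appearing in the positive set, excluding the positives of the
#' same mode. Reproducible under `seed`.
#'
#' @param positives data.frame of same-mode positive records.
#' @param ratio negatives per positive (integer `>= 1`).
#' @param seed integer seed.
#' @param n_positives optionally override the positive count the ratio is
#'   applied to (used per-fold where negatives are matched to a fold subset
#'   but drawn from the full universe).
#' @return data.frame of records with `label = "negative"`,
#'   `source = "sampled"`.
#' @export
sample_negatives <- function(positives, ratio = 1, seed = 1,
                             n_positives = nrow(positives)) {
  if (ratio < 1 || ratio != round(ratio)) {
    stop_dtimoa("dtimoa_invalid_input", "ratio must be an integer >= 1")
  }
  universe <- negative_universe(positives)
  n_req <- ratio * n_positives
  if (nrow(universe) < n_req) {
    stop_dtimoa("dtimoa_capacity_error",
                "universe holds %d non-positive pairs; %d requested (short by %d)",
                nrow(universe), n_req, n_req - nrow(universe))
  }
  old <- .Random.seed_exists()
  set.seed(seed)
  idx <- sample.int(nrow(universe), n_req)
  restore_seed(old)
  neg <- universe[idx, , drop = FALSE]
  neg$mode <- positives$mode[1]
  neg$label <- "negative"; neg$source <- "sampled"
  rownames(neg) <- NULL
  neg
}

#' @noRd
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

#' @noRd
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Split positive records into k disjoint folds
#'
#' Random partition with fold sizes differing by at most one; reproducible
#' under `seed`. Positives never cross folds within one split.
#'
#' @param positives data.frame of positive records.
#' @param k number of folds (`>= 2`).
#' @param seed integer seed.
#' @return Integer vector of fold assignments (1..k) per row of `positives`.
#' @export
split_folds <- function(positives, k = 5, seed = 1) {
  n <- nrow(positives)
  if (k < 2) stop_dtimoa("dtimoa_invalid_input", "k must be >= 2")
  if (n < k) {
    stop_dtimoa("dtimoa_invalid_input", "%d positives cannot fill %d folds", n, k)
  }
  old <- .Random.seed_exists()
  set.seed(seed)
  folds <- sample(rep_len(seq_len(k), n))
  restore_seed(old)
  folds
}

#' Build a feature matrix for a set of records
#'
#' Concatenates the compound vector and the target vector (compound first)
#' for each record, using the tier's provenance rule. Records whose compound
#' or target lacks a vector raise an error: the caller is expected to have
#' filtered via [assemble_dataset()] or to be drawing negatives from a
#' covered universe.
#'
#' @param records data.frame with `compound_id`, `target_gene`.
#' @param compound_vectors matrix, rows = compound ids.
#' @param store [target_store()].
#' @param tier provenance rule (see [assemble_dataset()]).
#' @return Numeric matrix, one row per record.
#' @export
featurize_records <- function(records, compound_vectors, store,
                              tier = c("integrated", "original", "additional")) {
  tier <- match.arg(tier)
  prov <- switch(tier, original = "measured", additional = "inferred",
                 integrated = "any")
  X <- matrix(NA_real_, nrow = nrow(records),
              ncol = ncol(compound_vectors) + store$panel$size)
  for (i in seq_len(nrow(records))) {
    if (!(records$compound_id[i] %in% rownames(compound_vectors))) {
      stop_dtimoa("dtimoa_lookup_error", "no embedding for compound '%s'",
                  records$compound_id[i])
    }
    tv <- store_get(store, records$target_gene[i], prov)
    if (is.null(tv)) {
      stop_dtimoa("dtimoa_lookup_error", "no %s target vector for gene '%s'",
                  prov, records$target_gene[i])
    }
    X[i, ] <- c(as.numeric(compound_vectors[records$compound_id[i], ]), tv$vector)
  }
  X
}
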