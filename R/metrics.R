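#' Confusion counts at a score threshold
#'
#' A sample is called positive when its score is `>= threshold`; the four
#' counts partition the sample.
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels of the same length.
#' @param threshold decision threshold.
#' @return Named list `TP`, `FP`, `FN`, `TN` of class `confusion_counts`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold) {
  if (length(scores) != length(labels)) {
    stop_dtimoa("dtimoa_invalid_input", "scores and labels differ in length")
  }
  y <- check_labels_metric(labels)
  call_pos <- scores >= threshold
  structure(list(TP = sum(call_pos & y == 1), FP = sum(call_pos & y == 0),
                 FN = sum(!call_pos & y == 1), TN = sum(!call_pos & y == 0)),
            class = "confusion_counts")
}

#' @noRd
check_labels_metric <- function(labels) {
  y <- as.integer(labels)
  if (any(is.na(y)) || !all(y %in% c(0L, 1L))) {
    stop_dtimoa("dtimoa_invalid_input", "labels must be binary 0/1")
  }
  y
}

#' @noRd
require_both_classes <- function(y) {
  if (length(unique(y)) < 2) {
    stop_dtimoa("dtimoa_undefined_metric",
                "metric undefined: labels contain a single class")
  }
  invisible(y)
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic (probability that a
#' random positive outscores a random negative, ties counted half) via
#' midranks — exactly the area under the empirical ROC step curve.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary 0/1 labels.
#' @return AUROC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- check_labels_metric(labels); require_both_classes(y)
  if (length(scores) != length(y)) {
    stop_dtimoa("dtimoa_invalid_input", "scores and labels differ in length")
  }
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  r <- rank(scores)
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step integration of the empirical precision-recall curve over the
#' distinct score thresholds in decreasing order (tied scores enter
#' together): the sum of precision times the recall increment at each
#' threshold.
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels.
#' @return AUPR in `(0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  y <- check_labels_metric(labels); require_both_classes(y)
  if (length(scores) != length(y)) {
    stop_dtimoa("dtimoa_invalid_input", "scores and labels differ in length")
  }
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)  # counts at each distinct threshold
  tp <- tp[last]; fp <- fp[last]
  n_pos <- sum(y)
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  sum(precision * diff(c(0, recall)))
}

#' Enrichment factor at a fixed false positive rate
#'
#' EFx% measures how much the hit rate at the score threshold operating at an
#' x% false positive rate exceeds random picking: precision at the operating
#' point divided by the dataset's positive prevalence. The operating point is
#' the largest threshold whose FPR does not exceed `fpr_level`
#' (`policy = "le"`, the conservative side of the discrete ROC); with
#' `policy = "nearest"` the threshold with FPR closest to `fpr_level` is
#' used. When no threshold with positive calls satisfies FPR <= level (e.g. a
#' constant scorer, whose only informative operating point includes all
#' samples at FPR 1 and therefore scores at chance level, EF = 1), the
#' least-FPR operating point with positive calls is used and a warning is
#' emitted.
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels.
#' @param fpr_level target false positive rate in (0, 1).
#' @param policy `"le"` (default) or `"nearest"`.
#' @return EF value in `[0, 1/prevalence]`.
#' @export
enrichment_factor <- function(scores, labels, fpr_level = 0.01,
                              policy = c("le", "nearest")) {
  policy <- match.arg(policy)
  y <- check_labels_metric(labels); require_both_classes(y)
  if (fpr_level <= 0 || fpr_level >= 1) {
    stop_dtimoa("dtimoa_invalid_input", "fpr_level must be in (0, 1)")
  }
  thresholds <- sort(unique(scores), decreasing = TRUE)
  n_neg <- sum(y == 0)
  cm <- lapply(thresholds, function(th) confusion_at_threshold(scores, y, th))
  fpr <- vapply(cm, function(c) c$FP / n_neg, numeric(1))
  called <- vapply(cm, function(c) (c$TP + c$FP) > 0, logical(1))
  ok <- called & (fpr <= fpr_level)
  pick <- if (any(ok)) {
    if (policy == "le") max(which(ok)) else {
      cand <- which(called)
      cand[which.min(abs(fpr[cand] - fpr_level))]
    }
  } else if (any(called)) {
    warning("no operating point reaches FPR <= ", fpr_level,
            "; using the least-FPR point with positive calls")
    which(called)[which.min(fpr[called])]
  } else {
    warning("no operating point with positive calls; EF = 0")
    return(0)
  }
  enrichment_factor_counts(cm[[pick]])
}

#' Enrichment factor from confusion counts
#'
#' Closed form: `EF = (TP / (TP + FP)) / ((TP + FN) / N)` with
#' `N = TP + FP + FN + TN` — precision at the operating point over the
#' positive prevalence.
#'
#' @param counts a [confusion_at_threshold()] result or list with `TP`,
#'   `FP`, `FN`, `TN`.
#' @return EF value.
#' @export
enrichment_factor_counts <- function(counts) {
  n <- counts$TP + counts$FP + counts$FN + counts$TN
  if (n == 0) stop_dtimoa("dtimoa_invalid_input", "empty confusion counts")
  if (counts$TP + counts$FP == 0) return(0)
  precision <- counts$TP / (counts$TP + counts$FP)
  prevalence <- (counts$TP + counts$FN) / n
  precision / prevalence
}

#' Repeated cross-validation with asymmetric negative sampling
#'
#' The evaluation protocol for mode-of-action DTI prediction: per repeat,
#' the positives are split into `k` folds; per fold, the model trains on the
#' other folds' positives plus an equal number of sampled negatives (1:1)
#' and is tested on the held-out positives plus `test_negative_ratio` times
#' as many sampled negatives. Negatives are drawn from the non-positive
#' compound x target universe of the full positive set with a fresh seed per
#' (repeat, fold); train and test negatives may overlap across folds but
#' positives never cross folds within a repeat.
#'
#' @param positives data.frame of same-mode positive records.
#' @param compound_vectors matrix of compound embeddings (rows = ids).
#' @param store [target_store()] for the mode.
#' @param model_fitter function `(X, y, seed) -> model` answering
#'   [predict_scores()].
#' @param k folds per repeat.
#' @param repeats number of repeats (fresh split each).
#' @param test_negative_ratio negatives per positive in the test fold
#'   (1 for balanced, 10 for the sparse-positive screening setting).
#' @param master_seed integer; all fold/sampling/model seeds derive from it.
#' @param tier featurization provenance rule (see [featurize_records()]).
#' @param ef_levels FPR levels for enrichment factors.
#' @return An object of class `cv_result`: `folds` (data.frame: repeat,
#'   fold, auroc, aupr, ef columns), `summary` (mean and sd per metric),
#'   `protocol`.
#' @export
cross_validate <- function(positives, compound_vectors, store, model_fitter,
                           k = 5, repeats = 5, test_negative_ratio = 1,
                           master_seed = 1, tier = "integrated",
                           ef_levels = c(0.01, 0.05)) {
  if (nrow(positives) < k) {
    stop_dtimoa("dtimoa_invalid_input", "fewer positives than folds")
  }
  rows <- list()
  for (r in seq_len(repeats)) {
    folds <- split_folds(positives, k = k, seed = derive_seed(master_seed, "split", r))
    for (f in seq_len(k)) {
      te_pos <- positives[folds == f, , drop = FALSE]
      tr_pos <- positives[folds != f, , drop = FALSE]
      tr_neg <- sample_negatives(positives, ratio = 1,
                                 seed = derive_seed(master_seed, "train-neg", r, f),
                                 n_positives = nrow(tr_pos))
      te_neg <- sample_negatives(positives, ratio = test_negative_ratio,
                                 seed = derive_seed(master_seed, "test-neg", r, f),
                                 n_positives = nrow(te_pos))
      X_tr <- featurize_records(rbind(tr_pos[names(tr_neg)], tr_neg),
                                compound_vectors, store, tier)
      y_tr <- rep(c(1L, 0L), c(nrow(tr_pos), nrow(tr_neg)))
      X_te <- featurize_records(rbind(te_pos[names(te_neg)], te_neg),
                                compound_vectors, store, tier)
      y_te <- rep(c(1L, 0L), c(nrow(te_pos), nrow(te_neg)))
      m <- model_fitter(X_tr, y_tr, derive_seed(master_seed, "model", r, f))
      sc <- predict_scores(m, X_te)
      row <- data.frame(rep = r, fold = f,
                        auroc = roc_auc(sc, y_te), aupr = pr_auc(sc, y_te))
      for (lev in ef_levels) {
        row[[sprintf("ef%g", 100 * lev)]] <-
          suppressWarnings(enrichment_factor(sc, y_te, lev))
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  folds_df <- do.call(rbind, rows)
  metrics <- setdiff(names(folds_df), c("rep", "fold"))
  summ <- data.frame(metric = metrics,
                     mean = vapply(metrics, function(m) mean(folds_df[[m]]), numeric(1)),
                     sd = vapply(metrics, function(m) stats::sd(folds_df[[m]]), numeric(1)),
                     row.names = NULL)
  structure(list(folds = folds_df, summary = summ,
                 protocol = list(k = k, repeats = repeats,
                                 test_negative_ratio = test_negative_ratio,
                                 master_seed = master_seed, tier = tier)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$protocol$k, "-fold x ", x$protocol$repeats,
      " repeats, test ratio 1:", x$protocol$test_negative_ratio, "\n", sep = "")
  print(transform(x$summary, mean = signif(mean, 4), sd = signif(sd, 3)))
  invisible(x)
}

#' Rank a query score against a reference score distribution
#'
#' Ranks the predicted score of a query drug-target pair within the score
#' distribution over a reference drug library for the same target (the query
#' is taken to be a member of the reference pool). Rank is 1-based with
#' strictly-greater counting (ties take the optimistic rank) and the top
#' percentage is `100 * rank / reference_size`.
#'
#' @param query_score numeric scalar.
#' @param reference_scores numeric vector of reference scores.
#' @return List of class `rank_result`: `score`, `rank`, `top_percentage`,
#'   `reference_size`, `tie_rule`.
#' @export
#' @examples
#' rank_against_reference(0.99, c(1.0, 0.99, runif(2498)))
rank_against_reference <- function(query_score, reference_scores) {
  if (length(reference_scores) == 0) {
    stop_dtimoa("dtimoa_invalid_input", "reference scores are empty")
  }
  assert_numeric_vector(reference_scores, "reference_scores")
  rank <- 1L + sum(reference_scores > query_score)
  structure(list(score = query_score, rank = rank,
                 top_percentage = 100 * rank / length(reference_scores),
                 reference_size = length(reference_scores),
                 tie_rule = "strictly-greater (optimistic)"),
            class = "rank_result")
}

#' @export
print.rank_result <- function(x, ...) {
  cat(sprintf("<rank_result> score %.3g: rank %d / %d (top %.2f%%)\n",
              x$score, x$rank, x$reference_size, x$top_percentage))
  invisible(x)
}

#' Rediscovery calls at a score threshold
#'
#' A validated interaction counts as rediscovered when its predicted score
#' strictly exceeds the decision threshold (default 0.5, the model's natural
#' probability midpoint); a score exactly at the threshold is not a call.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param threshold decision threshold (default 0.5).
#' @return Logical vector.
#' @export
rediscover <- function(scores, threshold = 0.5) {
  assert_numeric_vector(scores, "scores")
  scores > threshold
}
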