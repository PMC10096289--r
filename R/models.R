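#' Cascade deep forest configuration
#'
#' A cascade deep forest stacks levels of forests; each level receives the
#' original features augmented with the class-probability outputs of the
#' previous level, and training stops when adding a level no longer improves
#' the out-of-fold validation metric. Half the forests of a level are random
#' forests (`split_criterion` splits), half are extremely randomized trees.
#'
#' The published optimum for the DTI task is 8 estimators per level and 500
#' trees per forest; the desk-scale defaults here (4 estimators, 100 trees)
#' keep synthetic benchmarks fast and are documented in the methods vignette.
#'
#' @param n_estimators_per_level forests per level (even, `>= 2`).
#' @param n_trees trees per forest.
#' @param split_criterion split rule for the RF half (`"gini"` or
#'   `"hellinger"`); the other half always uses extra-trees splits.
#' @param max_depth maximum tree depth (0 = unlimited).
#' @param min_samples_split minimum node size to split.
#' @param max_features features tried per split (`NULL` = sqrt(p)).
#' @param cv_folds_internal folds for the out-of-fold probability estimates.
#' @param stop_tolerance minimum metric improvement required to add a level.
#' @param max_levels hard cap on cascade depth.
#' @param metric out-of-fold metric driving level selection: `"aupr"`
#'   (default, the model-selection metric under class imbalance), `"auroc"`
#'   or `"accuracy"`.
#' @param seed integer seed; all forest/fold seeds derive from it.
#' @return An object of class `cascade_config`.
#' @export
cascade_config <- function(n_estimators_per_level = 4,
                           n_trees = 100,
                           split_criterion = "gini",
                           max_depth = 0,
                           min_samples_split = 2,
                           max_features = NULL,
                           cv_folds_internal = 3,
                           stop_tolerance = 1e-4,
                           max_levels = 20,
                           metric = c("aupr", "auroc", "accuracy"),
                           seed = 1) {
  metric <- match.arg(metric)
  if (n_estimators_per_level < 2 || n_estimators_per_level %% 2 != 0) {
    stop_dtimoa("dtimoa_invalid_config",
                "n_estimators_per_level must be even and >= 2")
  }
  if (n_trees < 1 || stop_tolerance < 0 || max_levels < 1) {
    stop_dtimoa("dtimoa_invalid_config", "invalid cascade configuration")
  }
  structure(list(n_estimators_per_level = as.integer(n_estimators_per_level),
                 n_trees = as.integer(n_trees),
                 split_criterion = split_criterion,
                 max_depth = as.integer(max_depth),
                 min_samples_split = as.integer(min_samples_split),
                 max_features = max_features,
                 cv_folds_internal = as.integer(cv_folds_internal),
                 stop_tolerance = stop_tolerance,
                 max_levels = as.integer(max_levels),
                 metric = metric,
                 seed = as.integer(seed)),
            class = "cascade_config")
}

#' @noRd
check_labels <- function(y) {
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) {
    stop_dtimoa("dtimoa_invalid_input", "labels must be binary 0/1")
  }
  if (length(unique(y)) < 2) {
    stop_dtimoa("dtimoa_degenerate_labels", "labels contain a single class")
  }
  y
}

#' @noRd
named_matrix <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  X
}

#' @noRd
fit_forest <- function(X, y, kind, config, seed) {
  ranger::ranger(
    x = X, y = factor(y, levels = c(0, 1)),
    num.trees = config$n_trees,
    mtry = if (is.null(config$max_features)) NULL else
      min(ncol(X), config$max_features),
    splitrule = if (kind == "etrees") "extratrees" else config$split_criterion,
    max.depth = config$max_depth,
    min.node.size = config$min_samples_split,
    probability = TRUE, seed = seed, num.threads = 1,
    verbose = FALSE)
}

#' @noRd
forest_prob <- function(forest, X) {
  p <- stats::predict(forest, data = X, num.threads = 1)$predictions
  p[, c("0", "1"), drop = FALSE]
}

#' @noRd
level_metric <- function(metric, scores, y) {
  switch(metric,
         aupr = pr_auc(scores, y),
         auroc = roc_auc(scores, y),
         accuracy = mean((scores >= 0.5) == (y == 1)))
}

# Fit the forests of one cascade level and return full-data fits plus
# out-of-fold class probabilities for every forest.
#' @noRd
fit_level <- function(X, y, config, level) {
  E <- config$n_estimators_per_level
  kinds <- rep(c("rf", "etrees"), each = E / 2)
  folds <- {
    old <- .Random.seed_exists()
    set.seed(derive_seed(config$seed, "cascade-folds", level))
    f <- sample(rep_len(seq_len(config$cv_folds_internal), length(y)))
    restore_seed(old)
    f
  }
  oof <- matrix(NA_real_, nrow = length(y), ncol = 2 * E)
  forests <- vector("list", E)
  for (e in seq_len(E)) {
    for (k in seq_len(config$cv_folds_internal)) {
      tr <- folds != k
      f <- fit_forest(X[tr, , drop = FALSE], y[tr], kinds[e], config,
                      derive_seed(config$seed, "cascade", level, e, k))
      oof[!tr, (2 * e - 1):(2 * e)] <- forest_prob(f, X[!tr, , drop = FALSE])
    }
    forests[[e]] <- fit_forest(X, y, kinds[e], config,
                               derive_seed(config$seed, "cascade", level, e, 0))
  }
  list(forests = forests, kinds = kinds, oof = oof)
}

#' Fit a cascade deep forest
#'
#' Trains levels of forests sequentially. Level 1 sees the raw features;
#' every later level sees the raw features augmented with the previous
#' level's per-forest out-of-fold class probabilities (width
#' `input_dim + 2 * n_estimators_per_level`). The out-of-fold validation
#' metric is recorded per level; training stops when a new level fails to
#' improve the running best by more than `stop_tolerance` (or at
#' `max_levels`), and the model keeps the best-scoring prefix of levels.
#'
#' @param X numeric feature matrix.
#' @param y binary labels (0/1).
#' @param config a [cascade_config()].
#' @return An object of class `cascade_forest` with elements `levels`,
#'   `level_scores`, `oof_scores` (out-of-fold positive-class scores of the
#'   kept final level), `oof_auroc`, `oof_aupr`, `config`, `input_dim`.
#' @export
fit_cascade <- function(X, y, config = cascade_config()) {
  X <- named_matrix(X)
  y <- check_labels(y)
  if (nrow(X) < config$cv_folds_internal) {
    stop_dtimoa("dtimoa_invalid_input", "need at least %d rows",
                config$cv_folds_internal)
  }
  levels_out <- list(); scores <- numeric(0); oof_by_level <- list()
  cur <- X
  best <- -Inf
  for (t in seq_len(config$max_levels)) {
    lv <- fit_level(cur, y, config, t)
    mean_pos <- rowMeans(lv$oof[, seq(2, ncol(lv$oof), by = 2), drop = FALSE])
    sc <- level_metric(config$metric, mean_pos, y)
    if (t > 1 && sc - best <= config$stop_tolerance) break
    levels_out[[t]] <- lv
    scores[t] <- sc
    oof_by_level[[t]] <- mean_pos
    best <- max(best, sc)
    cur <- cbind(X, lv$oof)
    colnames(cur) <- paste0("f", seq_len(ncol(cur)))
    if (is.infinite(config$stop_tolerance)) break
  }
  keep <- which.max(scores)
  levels_out <- levels_out[seq_len(keep)]
  scores <- scores[seq_len(keep)]
  final_oof <- oof_by_level[[keep]]
  structure(list(levels = levels_out, level_scores = scores,
                 oof_scores = final_oof,
                 oof_auroc = roc_auc(final_oof, y),
                 oof_aupr = pr_auc(final_oof, y),
                 config = config, input_dim = ncol(X)),
            class = "cascade_forest")
}

#' @export
print.cascade_forest <- function(x, ...) {
  cat("<cascade_forest> ", length(x$levels), " level(s), ",
      x$config$n_estimators_per_level, " forests x ", x$config$n_trees,
      " trees; oof ", x$config$metric, " trace: ",
      paste(signif(x$level_scores, 4), collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Predict interaction scores
#'
#' Scores are positive-class probabilities in `[0, 1]`. For a cascade,
#' features are propagated level by level (each level's forests append their
#' class probabilities to the raw features for the next level) and the final
#' score is the mean positive-class probability over the last level's
#' forests.
#'
#' @param model a fitted model (`cascade_forest` or a baseline from
#'   [fit_baseline()]).
#' @param X feature matrix with the training width.
#' @param ... unused.
#' @return Numeric score vector.
#' @export
predict_scores <- function(model, X, ...) UseMethod("predict_scores")

#' @export
predict_scores.cascade_forest <- function(model, X, ...) {
  X <- named_matrix(X)
  if (ncol(X) != model$input_dim) {
    stop_dtimoa("dtimoa_shape_error", "feature width %d != trained width %d",
                ncol(X), model$input_dim)
  }
  cur <- X
  for (t in seq_along(model$levels)) {
    lv <- model$levels[[t]]
    probs <- lapply(lv$forests, function(f) forest_prob(f, cur))
    if (t == length(model$levels)) {
      pos <- vapply(probs, function(p) p[, "1"], numeric(nrow(X)))
      if (nrow(X) == 1) pos <- matrix(pos, nrow = 1)
      return(rowMeans(pos))
    }
    cur <- cbind(X, do.call(cbind, probs))
    colnames(cur) <- paste0("f", seq_len(ncol(cur)))
  }
}

#' Fit a baseline classifier
#'
#' Logistic regression (`"logit"`), a single probability random forest
#' (`"rf"`), or a single-hidden-layer multilayer perceptron (`"mlp"`).
#' Logit and MLP features are z-scaled with statistics fitted on the
#' training data (leakage-safe); tree models are scale-free and left raw.
#'
#' @param kind `"logit"`, `"rf"` or `"mlp"`.
#' @param X feature matrix.
#' @param y binary 0/1 labels.
#' @param config optional list: `n_trees`, `mlp_size`, `mlp_decay`,
#'   `mlp_maxit`.
#' @param seed integer seed.
#' @return A model object answering [predict_scores()].
#' @export
fit_baseline <- function(kind = c("logit", "rf", "mlp"), X, y,
                         config = list(), seed = 1) {
  kind <- match.arg(kind)
  X <- named_matrix(X)
  y <- check_labels(y)
  scaler <- NULL
  if (kind %in% c("logit", "mlp")) {
    mu <- colMeans(X); sd <- apply(X, 2, stats::sd)
    sd[sd == 0] <- 1
    scaler <- list(mu = mu, sd = sd)
    X <- sweep(sweep(X, 2, mu), 2, sd, "/")
  }
  old <- .Random.seed_exists()
  set.seed(seed)
  fit <- switch(kind,
    logit = suppressWarnings(stats::glm.fit(cbind(1, X), y,
                                            family = stats::binomial())),
    rf = ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                        num.trees = config$n_trees %||% 500,
                        probability = TRUE, seed = seed, num.threads = 1,
                        verbose = FALSE),
    mlp = nnet::nnet(X, nnet::class.ind(factor(y, levels = c(0, 1))),
                     size = config$mlp_size %||% 32,
                     decay = config$mlp_decay %||% 1e-3,
                     maxit = config$mlp_maxit %||% 200,
                     softmax = TRUE, trace = FALSE,
                     MaxNWts = 100000))
  restore_seed(old)
  structure(list(kind = kind, fit = fit, scaler = scaler,
                 input_dim = ncol(X), seed = seed),
            class = c(paste0("baseline_", kind), "baseline_model"))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
predict_scores.baseline_model <- function(model, X, ...) {
  X <- named_matrix(X)
  if (ncol(X) != model$input_dim) {
    stop_dtimoa("dtimoa_shape_error", "feature width %d != trained width %d",
                ncol(X), model$input_dim)
  }
  if (!is.null(model$scaler)) {
    X <- sweep(sweep(X, 2, model$scaler$mu), 2, model$scaler$sd, "/")
  }
  switch(model$kind,
    logit = {
      beta <- model$fit$coefficients
      beta[is.na(beta)] <- 0  # aliased columns drop out of the score
      as.numeric(stats::plogis(cbind(1, X) %*% beta))
    },
    rf = forest_prob(model$fit, X)[, "1"],
    mlp = as.numeric(stats::predict(model$fit, X)[, 2]))
}

#' Greedy coordinate hyperparameter search
#'
#' Optimises one hyperparameter axis at a time in the declared order,
#' holding the others at their current best values, scoring each candidate
#' configuration by cross-validated AUPR of out-of-fold predictions. Ties
#' keep the first-listed value. The full evaluation trace is returned; the
#' number of evaluations is at most the sum of axis lengths (versus the
#' product for exhaustive search).
#'
#' @param config_grid named list of candidate vectors, in search order; names
#'   must be [cascade_config()] fields (or `fit_baseline` config fields when
#'   `fitter` is a baseline).
#' @param X,y training data.
#' @param k internal CV folds for scoring.
#' @param seed integer seed.
#' @param fitter function `(X, y, config_list, seed) -> model`; the default
#'   fits a cascade with the grid values spliced into [cascade_config()].
#' @return List with `best` (named list), `best_score`, `trace` (data.frame).
#' @export
grid_search <- function(config_grid, X, y, k = 3, seed = 1, fitter = NULL) {
  if (length(config_grid) == 0 || any(!nzchar(names(config_grid)))) {
    stop_dtimoa("dtimoa_invalid_config", "config_grid must be a non-empty named list")
  }
  X <- named_matrix(X); y <- check_labels(y)
  if (is.null(fitter)) {
    fitter <- function(X, y, cfg, seed) {
      fit_cascade(X, y, do.call(cascade_config, c(cfg, list(seed = seed))))
    }
  }
  score_cfg <- function(cfg) {
    folds <- split_folds(data.frame(i = seq_along(y)), k = k,
                         seed = derive_seed(seed, "grid-folds"))
    oof <- numeric(length(y))
    for (f in seq_len(k)) {
      tr <- folds != f
      m <- fitter(X[tr, , drop = FALSE], y[tr], cfg,
                  derive_seed(seed, "grid-fit", f))
      oof[!tr] <- predict_scores(m, X[!tr, , drop = FALSE])
    }
    pr_auc(oof, y)
  }
  best <- lapply(config_grid, `[[`, 1)
  trace <- list()
  best_score <- NA_real_
  for (axis in names(config_grid)) {
    axis_scores <- numeric(0)
    for (v in config_grid[[axis]]) {
      cand <- best; cand[[axis]] <- v
      s <- score_cfg(cand)
      axis_scores <- c(axis_scores, s)
      trace[[length(trace) + 1]] <- data.frame(axis = axis,
                                               value = as.character(v),
                                               aupr = s)
    }
    pick <- which.max(axis_scores)  # which.max keeps the first on ties
    best[[axis]] <- config_grid[[axis]][[pick]]
    best_score <- axis_scores[pick]
  }
  list(best = best, best_score = best_score, trace = do.call(rbind, trace))
}
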