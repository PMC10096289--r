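test_that("confusion counts partition the sample at any threshold", {
  scores <- c(0.9, 0.8, 0.4, 0.2)
  labels <- c(1, 1, 0, 0)
  cm <- confusion_at_threshold(scores, labels, 0.5)
  expect_equal(unclass(cm)[c("TP", "FP", "FN", "TN")],
               list(TP = 2L, FP = 0L, FN = 0L, TN = 2L))
  high <- confusion_at_threshold(scores, labels, 0.95)
  expect_equal(high$TP + high$FP, 0L)
  set.seed(10)
  s <- runif(20); y <- rbinom(20, 1, 0.4); th <- 0.37
  cm2 <- confusion_at_threshold(s, y, th)
  # brute-force loop oracle
  tp <- fp <- fn <- tn <- 0
  for (i in 1:20) {
    if (s[i] >= th && y[i] == 1) tp <- tp + 1
    if (s[i] >= th && y[i] == 0) fp <- fp + 1
    if (s[i] < th && y[i] == 1) fn <- fn + 1
    if (s[i] < th && y[i] == 0) tn <- tn + 1
  }
  expect_equal(unclass(cm2)[c("TP", "FP", "FN", "TN")],
               list(TP = tp, FP = fp, FN = fn, TN = tn))
  expect_equal(cm2$TP + cm2$FP + cm2$FN + cm2$TN, 20)
  expect_error(confusion_at_threshold(1:3, c(0, 1), 0.5),
               class = "dtimoa_invalid_input")
})

test_that("AUROC equals the pair-counting oracle and handles ties by midrank", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1.0)
  set.seed(11)
  for (i in 1:10) {
    s <- sample(seq(0, 1, by = 0.25), 12, TRUE)  # coarse grid forces ties
    y <- rbinom(12, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y), oracle_auc_paircount(s, y), tolerance = 1e-12)
  }
  # complement identity for tie-free scores
  s <- c(0.11, 0.52, 0.48, 0.9, 0.77, 0.05); y <- c(0, 1, 0, 1, 1, 0)
  expect_equal(roc_auc(s, y) + roc_auc(-s, y), 1.0)
  expect_error(roc_auc(s, rep(1, 6)), class = "dtimoa_undefined_metric")
  # null behaviour: labels independent of scores
  set.seed(12)
  s <- runif(4000); y <- rbinom(4000, 1, 0.5)
  expect_lt(abs(roc_auc(s, y) - 0.5), 0.05)
})

test_that("AUROC and AUPR agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  s <- runif(150); y <- rbinom(150, 1, 0.3)
  expect_equal(roc_auc(s, y),
               as.numeric(suppressMessages(pROC::auc(y, s, direction = "<"))),
               tolerance = 1e-10)
  # AUPR sanity: perfect ranking gives 1, prevalence is the random floor
  expect_equal(pr_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_gt(pr_auc(s, y), 0)
})

test_that("enrichment factor reproduces closed-form arithmetic and bounds", {
  expect_equal(enrichment_factor_counts(list(TP = 10, FP = 10, FN = 10, TN = 970)),
               25)
  # constant scorer operates at chance: EF = 1
  expect_warning(ef_const <- enrichment_factor(rep(0.3, 200),
                                               rep(c(1, 0), c(20, 180)), 0.01))
  expect_equal(ef_const, 1)
  # perfect classifier at an FPR level below 1/n_neg: the whole retrieved
  # head is positive, so EF reaches 1/prevalence exactly
  y <- rep(c(1, 0), c(10, 990)); s <- c(runif(10, 0.9, 1), runif(990, 0, 0.5))
  expect_equal(enrichment_factor(s, y, 0.0005), 100, tolerance = 1e-9)
  # EF <= 1/prevalence over random instances
  set.seed(14)
  for (i in 1:100) {
    n <- sample(50:200, 1)
    y <- rbinom(n, 1, runif(1, 0.05, 0.5))
    if (length(unique(y)) < 2) next
    s <- runif(n)
    ef <- suppressWarnings(enrichment_factor(s, y, runif(1, 0.01, 0.2)))
    expect_gte(ef, 0)
    expect_lte(ef, n / sum(y) + 1e-9)
  }
  expect_error(enrichment_factor(runif(5), c(1, 1, 0, 0, 1), 1.2),
               class = "dtimoa_invalid_input")
})

test_that("reference ranking arithmetic matches printed rank/percentage pairs", {
  # a reference pool of 2500 scores; query sits at known strict ranks
  ref <- seq(0.9999, 0.0001, length.out = 2500)
  for (case in list(c(2, 0.08), c(37, 1.48), c(2331, 93.24))) {
    q <- ref[case[1]]  # exactly case[1]-1 strictly greater members
    r <- rank_against_reference(q, ref)
    expect_equal(r$rank, case[1])
    expect_equal(r$top_percentage, case[2], tolerance = 1e-9)
  }
  top <- rank_against_reference(2, ref)
  expect_equal(top$rank, 1L)
  expect_equal(top$top_percentage, 100 / 2500)
  # monotone in rank, invariant to reference order
  set.seed(15)
  shuf <- sample(ref)
  expect_equal(rank_against_reference(ref[37], shuf)$rank, 37L)
  expect_error(rank_against_reference(1, numeric(0)),
               class = "dtimoa_invalid_input")
})

test_that("rediscovery uses a strict threshold", {
  expect_equal(rediscover(c(0.89, 0.17, 0.5, 0.501)),
               c(TRUE, FALSE, FALSE, TRUE))
})

test_that("repeated CV is reproducible and respects the protocol shape", {
  b <- small_bundle(seed = 6)
  pos <- b$benchmark$positives
  fitter <- function(X, y, seed) fit_baseline("logit", X, y, seed = seed)
  cv1 <- cross_validate(pos, b$compounds$vectors, b$store, fitter,
                        k = 3, repeats = 2, master_seed = 11)
  cv2 <- cross_validate(pos, b$compounds$vectors, b$store, fitter,
                        k = 3, repeats = 2, master_seed = 11)
  expect_identical(cv1, cv2)
  expect_equal(nrow(cv1$folds), 6)
  expect_equal(cv1$summary$mean[cv1$summary$metric == "auroc"],
               mean(cv1$folds$auroc))
  expect_equal(cv1$summary$sd[cv1$summary$metric == "aupr"],
               sd(cv1$folds$aupr))
  cv3 <- cross_validate(pos, b$compounds$vectors, b$store, fitter,
                        k = 3, repeats = 2, master_seed = 12)
  expect_false(identical(cv1$folds, cv3$folds))
})
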