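test_that("mode-of-action terms map to modes and duplicates collapse", {
  tbl <- data.frame(compound_id = c("c1", "c1", "c2", "c2", "c2"),
                    target_gene = c("G1", "G1", "G2", "G2", "G3"),
                    moa_term = c("Agonist", "agonist", "inhibitor",
                                 "Inhibitor", "binder"))
  res <- parse_dti_table(tbl)
  expect_equal(nrow(res$records), 2)
  expect_equal(res$n_dropped, 1)
  expect_equal(res$records$mode[res$records$compound_id == "c1"], "activatory")
  expect_equal(res$records$mode[res$records$compound_id == "c2"], "inhibitory")
  expect_true(all(res$records$label == "positive"))
  expect_error(parse_dti_table(data.frame(a = 1)), class = "dtimoa_parse_error")
})

test_that("dataset assembly filters by provenance tier and concatenates compound-first", {
  panel <- gene_panel(sprintf("g%d", 1:4))
  store <- target_store("inhibitory", panel)
  set.seed(6)
  tv1 <- rnorm(4); tv2 <- rnorm(4); tv3 <- rnorm(4)
  store <- store_set(store, "G1", tv1, "measured")
  store <- store_set(store, "G2", tv2, "measured")
  store <- store_set(store, "G3", tv3, "inferred", 3L)
  cmp <- matrix(rnorm(9), 3, 3, dimnames = list(c("c1", "c2", "c3"), NULL))
  pos <- data.frame(compound_id = c("c1", "c2", "c3", "c1"),
                    target_gene = c("G1", "G2", "G3", "G9"),
                    mode = "inhibitory", label = "positive", source = "known")
  orig <- assemble_dataset(pos, cmp, store, "original", "inhibitory")
  addl <- assemble_dataset(pos, cmp, store, "additional", "inhibitory")
  intg <- assemble_dataset(pos, cmp, store, "integrated", "inhibitory")
  expect_equal(nrow(orig$records), 2)   # measured targets only
  expect_equal(nrow(addl$records), 1)   # inferred target only
  expect_equal(nrow(intg$records), 3)   # either; G9 always filtered
  expect_equal(intg$n_filtered, 1)
  # tier partition: original U additional == integrated for disjoint stores
  key <- function(d) paste(d$records$compound_id, d$records$target_gene)
  expect_setequal(c(key(orig), key(addl)), key(intg))
  expect_equal(ncol(intg$X), 3 + 4)
  expect_equal(intg$X[1, 1:3], unname(cmp["c1", ]))
  expect_equal(intg$X[1, 4:7], tv1)
})

test_that("feature rows track record order under permutation", {
  b <- small_bundle(seed = 2)
  pos <- b$benchmark$positives
  X <- featurize_records(pos, b$compounds$vectors, b$store, "integrated")
  perm <- sample(nrow(pos))
  Xp <- featurize_records(pos[perm, ], b$compounds$vectors, b$store, "integrated")
  expect_equal(Xp, X[perm, ])
})

test_that("negative sampling is exact-count, disjoint and seed-reproducible", {
  pos <- data.frame(compound_id = c("c1", "c2", "c3"),
                    target_gene = c("G1", "G2", "G3"),
                    mode = "inhibitory", label = "positive", source = "known")
  neg <- sample_negatives(pos, ratio = 1, seed = 7)
  expect_equal(nrow(neg), 3)
  expect_length(intersect(paste(neg$compound_id, neg$target_gene),
                          paste(pos$compound_id, pos$target_gene)), 0)
  expect_identical(sample_negatives(pos, 1, seed = 7), neg)
  expect_false(identical(sample_negatives(pos, 1, seed = 8), neg))
  # ratio-2 request on the 6-cell universe fills it exactly; ratio 3 overflows
  expect_equal(nrow(sample_negatives(pos, 2, seed = 1)), 6)
  expect_error(sample_negatives(pos, 3, seed = 1), class = "dtimoa_capacity_error")
  expect_error(sample_negatives(pos, 1.5, seed = 1), class = "dtimoa_invalid_input")
  # enumeration oracle at ratio 10 on a larger universe (30 x 10 grid)
  set.seed(17)
  grid <- expand.grid(compound_id = sprintf("c%02d", 1:30),
                      target_gene = sprintf("G%02d", 1:10),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  bigpos <- grid[sample(nrow(grid), 20), ]
  bigpos$mode <- "inhibitory"; bigpos$label <- "positive"; bigpos$source <- "known"
  n5 <- sample_negatives(bigpos, 5, seed = 3)
  expect_equal(nrow(n5), 100)
  expect_equal(anyDuplicated(paste(n5$compound_id, n5$target_gene)), 0)
  expect_length(intersect(paste(n5$compound_id, n5$target_gene),
                          paste(bigpos$compound_id, bigpos$target_gene)), 0)
})

test_that("fold splitting partitions positives evenly and reproducibly", {
  pos <- data.frame(compound_id = sprintf("c%d", 1:10),
                    target_gene = "G1", mode = "inhibitory",
                    label = "positive", source = "known")
  f <- split_folds(pos, k = 5, seed = 1)
  expect_equal(unname(table(f)), rep(2L, 5), ignore_attr = TRUE)
  expect_identical(split_folds(pos, 5, 1), f)
  expect_false(identical(split_folds(pos, 5, 2), f))
  f3 <- split_folds(pos[1:7, ], k = 3, seed = 4)
  expect_true(all(abs(diff(sort(table(f3)))) <= 1))
  expect_setequal(unique(f3), 1:3)
  expect_error(split_folds(pos[1:3, ], k = 5, seed = 1),
               class = "dtimoa_invalid_input")
  expect_error(split_folds(pos, k = 1, seed = 1), class = "dtimoa_invalid_input")
})
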