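test_that("PPI construction filters, deduplicates and symmetrizes edges", {
  edges <- data.frame(gene_a = c("A", "A"), gene_b = c("B", "C"),
                      score = c(950, 800))
  g <- build_ppi(edges, 900)
  expect_equal(igraph::ecount(g), 1)
  expect_setequal(ppi_neighbors(g, "A"), "B")
  expect_setequal(ppi_neighbors(g, "C"), character(0))
  dup <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "A"),
                    score = c(950, 950))
  expect_equal(igraph::ecount(build_ppi(dup, 900)), 1)
  # counting oracle on random edges, strict-inequality semantics
  set.seed(13)
  nodes <- sprintf("n%02d", 1:20)
  tbl <- data.frame(gene_a = sample(nodes, 100, TRUE),
                    gene_b = sample(nodes, 100, TRUE),
                    score = sample(0:1000, 100, TRUE))
  tbl <- tbl[tbl$gene_a != tbl$gene_b, ]
  key <- paste(pmin(tbl$gene_a, tbl$gene_b), pmax(tbl$gene_a, tbl$gene_b))
  for (t in c(300, 700, 900)) {
    expect_equal(igraph::ecount(build_ppi(tbl, t)),
                 length(unique(key[tbl$score > t])))
  }
  expect_error(build_ppi(data.frame(x = 1), 900), class = "dtimoa_parse_error")
  expect_error(build_ppi(tbl, 2000, scale = "raw"), class = "dtimoa_invalid_config")
  expect_error(build_ppi(data.frame(gene_a = "A", gene_b = NA, score = 900), 800),
               class = "dtimoa_parse_error")
})

test_that("unit-scale scores are accepted with explicit or auto declaration", {
  tbl <- data.frame(gene_a = c("A", "A"), gene_b = c("B", "C"),
                    score = c(0.95, 0.7))
  expect_equal(igraph::ecount(build_ppi(tbl, 0.9, scale = "unit")), 1)
  expect_equal(igraph::ecount(build_ppi(tbl, 0.9)), 1)  # auto picks unit
})

test_that("neighbour inference enforces the minimum-coverage rule", {
  panel <- gene_panel(sprintf("g%02d", 1:10))
  store <- target_store("inhibitory", panel)
  set.seed(3)
  vecs <- replicate(3, rnorm(10), simplify = FALSE)
  store <- store_set(store, "N1", vecs[[1]], "measured")
  store <- store_set(store, "N2", vecs[[2]], "measured")
  store <- store_set(store, "N3", vecs[[3]], "measured")
  edges <- data.frame(gene_a = c("X", "X", "Y", "Y", "Y"),
                      gene_b = c("N1", "N2", "N1", "N2", "N3"),
                      score = 950)
  g <- build_ppi(edges, 900)
  expect_null(infer_vector("X", g, store))        # 2 covered < 3
  res <- infer_vector("Y", g, store)               # exactly 3 covered
  expect_equal(res$n_support, 3L)
  expect_equal(res$vector, weighted_average(vecs)$vector, tolerance = 1e-12)
  # idempotence: identical neighbour vectors return that vector
  store_id <- store
  for (n in c("N1", "N2", "N3")) store_id <- store_set(store_id, n, vecs[[1]], "measured")
  expect_equal(infer_vector("Y", g, store_id)$vector, vecs[[1]])
  expect_error(infer_vector("ZZ", g, store), class = "dtimoa_lookup_error")
  # support monotonicity: removing a neighbour never creates inference
  g2 <- build_ppi(edges[-5, ], 900)
  expect_null(infer_vector("Y", g2, store))
})

test_that("inference is deterministic and excludes the gene's own vector", {
  b <- small_bundle(seed = 5)
  ext1 <- infer_all(b$ppi$graph, b$store, genes = colnames(b$truths))
  ext2 <- infer_all(b$ppi$graph, b$store, genes = rev(colnames(b$truths)))
  genes <- store_genes(ext1, "inferred")
  expect_setequal(genes, store_genes(ext2, "inferred"))
  for (g in genes) {
    expect_equal(store_get(ext1, g, "inferred")$vector,
                 store_get(ext2, g, "inferred")$vector)
    # self-exclusion: inferred differs from the measured self vector
    expect_false(isTRUE(all.equal(store_get(ext1, g, "inferred")$vector,
                                  store_get(ext1, g, "measured")$vector)))
  }
  # the two low-degree targets stay uninferred
  expect_false(any(c("T001", "T002") %in% genes))
})

test_that("store lookup prefers measured entries over inferred ones", {
  panel <- gene_panel(c("a", "b"))
  st <- target_store("activatory", panel)
  st <- store_set(st, "G1", c(1, 2), "inferred", 3L)
  st <- store_set(st, "G1", c(3, 4), "measured")
  expect_equal(store_get(st, "G1")$provenance, "measured")
  expect_equal(store_get(st, "G1", "inferred")$vector, c(1, 2))
})

test_that("validation separates within-gene from between-gene correlations on planted structure", {
  b <- small_bundle(seed = 8)
  ext <- infer_all(b$ppi$graph, b$store, genes = colnames(b$truths))
  v <- inference_validation(b$store, ext)
  expect_gt(v$median_within, v$median_between)
  expect_lt(v$p_value, 0.01)
  # degenerate case: inferred == measured gives all within-correlations 1
  ident <- b$store
  for (g in store_genes(b$store, "measured")[1:5]) {
    ident <- store_set(ident, g, store_get(b$store, g)$vector, "inferred", 3L)
  }
  vi <- inference_validation(b$store, ident)
  expect_true(all(abs(vi$within - 1) < 1e-12))
  empty <- target_store("inhibitory", b$panel)
  expect_error(inference_validation(b$store, empty), class = "dtimoa_invalid_input")
})

test_that("permuted inferred vectors show no within/between separation", {
  b <- small_bundle(seed = 12)
  ext <- infer_all(b$ppi$graph, b$store, genes = colnames(b$truths))
  genes <- store_genes(ext, "inferred")
  perm <- target_store(b$store$mode, b$panel)
  shuffled <- genes[c(seq_along(genes)[-1], 1)]  # cyclic shift: no fixed point
  for (i in seq_along(genes)) {
    perm <- store_set(perm, genes[i],
                      store_get(ext, shuffled[i], "inferred")$vector,
                      "inferred", 3L)
  }
  for (g in store_genes(b$store, "measured")) {
    perm <- store_set(perm, g, store_get(b$store, g)$vector, "measured")
  }
  vp <- inference_validation(b$store, perm)
  expect_gt(vp$p_value, 0.05)
})
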