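#' Synthetic study configuration
#'
#' Defines the desk-scale synthetic study all tests and benchmarks run on:
#' replicate perturbational signatures over a gene panel (true target vector
#' plus Gaussian noise, laid out on a cell line x condition grid), a PPI
#' graph whose neighbourhoods carry correlated vectors, a random
#' substructure-embedding table, and interaction labels with a planted
#' learnable compound-target signal.
#'
#' @param G gene panel size.
#' @param n_targets number of perturbed target genes.
#' @param cells_per_target cell lines per target.
#' @param conditions_per_cell dose/time conditions per cell line.
#' @param noise_sd replicate noise standard deviation (z-score units).
#' @param ppi_degree planted PPI neighbours per target.
#' @param d compound embedding dimension.
#' @param n_compounds number of compounds.
#' @param n_positives number of positive interactions planted.
#' @param signal_strength scale of the planted interaction signal in
#'   `[0, 1]` (0 = pure noise labels).
#' @param seed master seed; every generator derives from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(G = 50, n_targets = 30, cells_per_target = 3,
                             conditions_per_cell = 3, noise_sd = 0.5,
                             ppi_degree = 4, d = 16, n_compounds = 200,
                             n_positives = 500, signal_strength = 1,
                             seed = 1) {
  counts <- c(G, n_targets, cells_per_target, conditions_per_cell,
              ppi_degree, d, n_compounds, n_positives)
  if (any(counts < 1) || noise_sd < 0 || signal_strength < 0 ||
      signal_strength > 1) {
    stop_dtimoa("dtimoa_invalid_config", "invalid synthetic configuration")
  }
  structure(list(G = as.integer(G), n_targets = as.integer(n_targets),
                 cells_per_target = as.integer(cells_per_target),
                 conditions_per_cell = as.integer(conditions_per_cell),
                 noise_sd = noise_sd, ppi_degree = as.integer(ppi_degree),
                 d = as.integer(d), n_compounds = as.integer(n_compounds),
                 n_positives = as.integer(n_positives),
                 signal_strength = signal_strength, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @noRd
with_seed <- function(seed, expr) {
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore_seed(old))
  force(expr)
}

#' Generate replicate perturbational signatures with known truths
#'
#' Per target gene, a true vector is drawn from `N(0, I_G)`; each
#' (cell line, condition) replicate equals the truth plus
#' `N(0, noise_sd^2 I)` noise. With `noise_sd = 0` every replicate equals
#' its truth and the two-stage consensus recovers it exactly.
#'
#' @param config a [synthetic_config()].
#' @param kind perturbation kind for the generated signatures.
#' @return List with `signatures` (list of [signature()]), `truths`
#'   (G x n_targets matrix, columns named by gene), `panel`.
#' @export
gen_signatures <- function(config, kind = c("knockdown", "overexpression")) {
  kind <- match.arg(kind)
  panel <- gene_panel(sprintf("g%03d", seq_len(config$G)))
  genes <- sprintf("T%03d", seq_len(config$n_targets))
  with_seed(derive_seed(config$seed, "signatures", kind), {
    truths <- matrix(stats::rnorm(config$G * config$n_targets),
                     nrow = config$G, dimnames = list(panel$gene_ids, genes))
    sigs <- list()
    for (g in genes) {
      for (c_i in seq_len(config$cells_per_target)) {
        for (k_i in seq_len(config$conditions_per_cell)) {
          vals <- truths[, g] + stats::rnorm(config$G, sd = config$noise_sd)
          sid <- sprintf("%s_cell%02d_cond%02d", g, c_i, k_i)
          sigs[[sid]] <- signature(vals, g, kind,
                                   cell_line = sprintf("cell%02d", c_i),
                                   condition = sprintf("cond%02d", k_i),
                                   signature_id = sid, panel = panel)
        }
      }
    }
    list(signatures = sigs, truths = truths, panel = panel)
  })
}

#' Generate a PPI graph with planted correlated neighbourhoods
#'
#' Each target gene is connected to `ppi_degree` dedicated neighbour genes
#' whose measured vectors are noisy copies of the target's truth, so that
#' one-hop inference can recover the target vector; the first two targets
#' get only two neighbours each (below the default coverage rule, hence not
#' inferable). Decoy edges connect neighbour genes to genes without vectors
#' and are given scores spanning the confidence scale, some below any
#' high-confidence threshold.
#'
#' @param config a [synthetic_config()].
#' @param truths G x n_targets truth matrix from [gen_signatures()].
#' @return List with `edges` (data.frame gene_a/gene_b/score on the 0-1000
#'   scale), `graph` (edges filtered at score > 900 via [build_ppi()]),
#'   `neighbor_vectors` (matrix, columns = neighbour genes).
#' @export
gen_ppi <- function(config, truths) {
  genes <- colnames(truths)
  with_seed(derive_seed(config$seed, "ppi"), {
    edges <- list(); nb_vecs <- list()
    for (gi in seq_along(genes)) {
      g <- genes[gi]
      deg <- if (gi <= 2) min(2L, config$ppi_degree) else config$ppi_degree
      for (j in seq_len(deg)) {
        nb <- sprintf("%s_nb%02d", g, j)
        nb_vecs[[nb]] <- truths[, g] + stats::rnorm(nrow(truths),
                                                    sd = config$noise_sd)
        edges[[length(edges) + 1]] <- data.frame(
          gene_a = g, gene_b = nb,
          score = sample(901:1000, 1), stringsAsFactors = FALSE)
      }
      # decoys: low- and mid-confidence edges that the threshold must drop
      edges[[length(edges) + 1]] <- data.frame(
        gene_a = g, gene_b = sprintf("decoy%03d", gi),
        score = sample(100:850, 1), stringsAsFactors = FALSE)
    }
    edges <- do.call(rbind, edges)
    list(edges = edges,
         graph = build_ppi(edges, score_threshold = 900, scale = "raw"),
         neighbor_vectors = do.call(cbind, nb_vecs))
  })
}

#' Generate a random embedding table and compound vectors
#'
#' Draws a token table of i.i.d. normal d-dimensional vectors and represents
#' each compound as a random token multiset (with repeats); compound vectors
#' are computed through [embed_compound()], so the generator exercises the
#' same summation path the real featurizer uses.
#'
#' @param config a [synthetic_config()].
#' @param n_tokens vocabulary size.
#' @param sentence_range min/max sentence length.
#' @return List with `table` ([embedding_table()]), `sentences`, `vectors`
#'   (n_compounds x d matrix, rows named by compound id).
#' @export
gen_compounds <- function(config, n_tokens = 64, sentence_range = c(5, 12)) {
  with_seed(derive_seed(config$seed, "compounds"), {
    tokens <- format(sample(1e6:9e6, n_tokens), scientific = FALSE)
    tab <- matrix(stats::rnorm(n_tokens * config$d), nrow = n_tokens,
                  dimnames = list(tokens, sprintf("v%02d", seq_len(config$d))))
    table <- embedding_table(tab)
    ids <- sprintf("C%04d", seq_len(config$n_compounds))
    sentences <- lapply(ids, function(i) {
      len <- sample(seq(sentence_range[1], sentence_range[2]), 1)
      sample(tokens, len, replace = TRUE)
    })
    names(sentences) <- ids
    vectors <- t(vapply(sentences, function(s)
      as.numeric(embed_compound(s, table)), numeric(config$d)))
    rownames(vectors) <- ids
    list(table = table, sentences = sentences, vectors = vectors)
  })
}

#' Generate a benchmark interaction dataset with a planted signal
#'
#' Plants a rank-one interaction surface: with compound projection
#' `p = a'c` and target projection `q = b't` (standardised over the pair
#' grid), the latent propensity is
#' `plogis(signal_strength * scale(p + q + 2*p*q) + noise)` and the
#' `n_positives` pairs with the highest propensity are labelled positive.
#' The main effects make the signal recoverable by a linear classifier (a
#' floor for any stronger model); the weighted product term rewards models
#' that can exploit compound-target interactions, which a linear model on
#' concatenated features cannot represent. With `signal_strength = 0` the
#' labels are pure noise and any classifier sits at chance.
#'
#' @param config a [synthetic_config()].
#' @param compound_vectors matrix from [gen_compounds()].
#' @param truths G x n_targets truth matrix from [gen_signatures()].
#' @return List with `positives` (records data.frame), `universe` (all
#'   pairs with latent propensity), `W` (the planted projections `a`, `b`).
#' @export
gen_dti_benchmark <- function(config, compound_vectors, truths) {
  ids <- rownames(compound_vectors); genes <- colnames(truths)
  with_seed(derive_seed(config$seed, "benchmark"), {
    a <- stats::rnorm(ncol(compound_vectors))
    b <- stats::rnorm(nrow(truths))
    p <- as.numeric(scale(compound_vectors %*% a))
    q <- as.numeric(scale(crossprod(truths, b)))
    grid <- expand.grid(ci = seq_along(ids), ti = seq_along(genes),
                        KEEP.OUT.ATTRS = FALSE)
    z <- p[grid$ci] + q[grid$ti] + 2 * p[grid$ci] * q[grid$ti]
    z <- as.numeric(scale(z))
    lat <- stats::plogis(config$signal_strength * z +
                           stats::rnorm(length(z), sd = config$noise_sd))
    if (config$n_positives > length(z)) {
      stop_dtimoa("dtimoa_invalid_config",
                  "n_positives exceeds the %d available pairs", length(z))
    }
    pos_idx <- order(lat, decreasing = TRUE)[seq_len(config$n_positives)]
    universe <- data.frame(compound_id = ids[grid$ci],
                           target_gene = genes[grid$ti],
                           propensity = lat, stringsAsFactors = FALSE)
    positives <- data.frame(compound_id = universe$compound_id[pos_idx],
                            target_gene = universe$target_gene[pos_idx],
                            mode = "inhibitory", label = "positive",
                            source = "known", stringsAsFactors = FALSE)
    list(positives = positives, universe = universe, W = list(a = a, b = b))
  })
}

#' Generate the full synthetic study bundle
#'
#' Runs all four generators coherently from one configuration: signatures
#' and truths, the planted PPI graph, the embedding table with compound
#' vectors, and the benchmark interaction labels. A measured
#' [target_store()] aggregated from the *noise-free truths* is also
#' returned, aligning the benchmark's planted signal with the featurization
#' path.
#'
#' @param config a [synthetic_config()].
#' @param kind perturbation kind for the signatures.
#' @return List with components `config`, `signatures`, `truths`, `panel`,
#'   `ppi`, `compounds`, `benchmark`, `store` (measured store holding the
#'   truth vectors).
#' @export
gen_bundle <- function(config = synthetic_config(),
                       kind = c("knockdown", "overexpression")) {
  kind <- match.arg(kind)
  sig <- gen_signatures(config, kind)
  ppi <- gen_ppi(config, sig$truths)
  # neighbour genes are themselves measured perturbations: one signature
  # each, so that file-based re-aggregation also covers the PPI neighbourhood
  for (nb in colnames(ppi$neighbor_vectors)) {
    sid <- paste0(nb, "_cell01_cond01")
    sig$signatures[[sid]] <- signature(ppi$neighbor_vectors[, nb], nb, kind,
                                       cell_line = "cell01",
                                       condition = "cond01",
                                       signature_id = sid, panel = sig$panel)
  }
  cmp <- gen_compounds(config)
  bench <- gen_dti_benchmark(config, cmp$vectors, sig$truths)
  store <- target_store(perturbation_mode(kind), sig$panel)
  for (g in colnames(sig$truths)) {
    store <- store_set(store, g, sig$truths[, g], "measured", n_support = 1L)
  }
  # planted neighbour vectors are measured entries too, so that one-hop
  # inference over the PPI graph has coverage
  for (nb in colnames(ppi$neighbor_vectors)) {
    store <- store_set(store, nb, ppi$neighbor_vectors[, nb], "measured",
                       n_support = 1L)
  }
  list(config = config, signatures = sig$signatures, truths = sig$truths,
       panel = sig$panel, ppi = ppi, compounds = cmp, benchmark = bench,
       store = store)
}
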