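#' Substructure embedding table
#'
#' Token-to-vector lookup table in the mol2vec scheme: tokens are Morgan
#' substructure identifiers (unsigned integers rendered as strings) and each
#' maps to a d-dimensional real vector. Training such a table is upstream of
#' this package; any token->vector table can be supplied (see
#' [read_embedding_table()]) and the synthetic generator produces random ones.
#'
#' @param vectors numeric matrix, one row per token (rownames = tokens), or a
#'   named list of equal-length numeric vectors.
#' @param unk unknown-token policy: `"skip"` (contribute nothing) or `"zero"`
#'   (contribute a zero vector). Both yield the same sum; they differ only in
#'   the reported unknown-token accounting.
#' @return An object of class `embedding_table`.
#' @export
embedding_table <- function(vectors, unk = c("skip", "zero")) {
  unk <- match.arg(unk)
  if (is.list(vectors)) {
    vectors <- do.call(rbind, vectors)
  }
  if (!is.matrix(vectors) || !is.numeric(vectors) || is.null(rownames(vectors))) {
    stop_dtimoa("dtimoa_invalid_input",
                "embedding table needs a numeric matrix with token rownames")
  }
  structure(list(vectors = vectors, d = ncol(vectors), unk = unk),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat("<embedding_table> ", nrow(x$vectors), " tokens, d = ", x$d,
      ", unk = ", x$unk, "\n", sep = "")
  invisible(x)
}

# 32-bit polynomial string hash; exact in double arithmetic.
#' @noRd
hash32 <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 4294967296
  h
}

# Parse a SMILES string into a heavy-atom molecular graph via
# ChemmineR/OpenBabel. Returns element symbols and a bond table
# (a1, a2, order) on canonical atom order; keeps the largest covalent
# fragment of a salt/mixture.
#' @noRd
smiles_graph <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) ||
      !nzchar(smiles)) {
    stop_dtimoa("dtimoa_parse_error", "cannot parse SMILES: '%s'", smiles)
  }
  can <- tryCatch(
    trimws(ChemmineOB::convertFormat("SMI", "CAN", source = smiles)),
    error = function(e) "")
  can <- sub("\t.*$", "", can)
  if (!nzchar(can)) {
    stop_dtimoa("dtimoa_parse_error", "cannot parse SMILES: '%s'", smiles)
  }
  frags <- strsplit(can, ".", fixed = TRUE)[[1]]
  parse_one <- function(smi) {
    sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smi)[[1]]),
                    error = function(e) NULL)
    if (is.null(sdf)) {
      stop_dtimoa("dtimoa_parse_error", "cannot parse SMILES: '%s'", smi)
    }
    ab <- ChemmineR::atomblock(sdf)
    elements <- sub("_.*$", "", rownames(ab))
    bb <- ChemmineR::bondblock(sdf)
    if (!is.null(bb) && is.null(dim(bb))) bb <- matrix(bb, nrow = 1)
    bonds <- if (is.null(bb) || nrow(bb) == 0 || ncol(bb) < 3) {
      data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
    } else {
      data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                 order = as.integer(bb[, 3]))
    }
    bonds <- bonds[bonds$a1 > 0 & bonds$a2 > 0, , drop = FALSE]
    heavy <- which(elements != "H")
    idx <- match(seq_along(elements), heavy)
    bonds <- bonds[bonds$a1 %in% heavy & bonds$a2 %in% heavy, , drop = FALSE]
    bonds$a1 <- idx[bonds$a1]; bonds$a2 <- idx[bonds$a2]
    list(elements = elements[heavy], bonds = bonds, smiles = smi)
  }
  if (length(frags) > 1) {
    parsed <- lapply(frags, parse_one)
    parsed[[which.max(vapply(parsed, function(p) length(p$elements), integer(1)))]]
  } else {
    parse_one(can)
  }
}

# Iterative Morgan-style environment identifiers: radius-0 ids hash the atom
# invariants (element, heavy degree, sum of bond orders); radius r ids hash
# the radius r-1 id together with the sorted (bond order, neighbour id)
# list, so identifiers are invariant to atom input order.
#' @noRd
morgan_ids <- function(graph, max_radius) {
  n <- length(graph$elements)
  deg <- integer(n); bsum <- integer(n)
  adj <- vector("list", n)
  if (nrow(graph$bonds) > 0) {
    for (k in seq_len(nrow(graph$bonds))) {
      i <- graph$bonds$a1[k]; j <- graph$bonds$a2[k]; o <- graph$bonds$order[k]
      deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
      bsum[i] <- bsum[i] + o; bsum[j] <- bsum[j] + o
      adj[[i]] <- rbind(adj[[i]], c(j, o))
      adj[[j]] <- rbind(adj[[j]], c(i, o))
    }
  }
  ids <- matrix(0, nrow = n, ncol = max_radius + 1)
  ids[, 1] <- vapply(seq_len(n), function(i)
    hash32(paste(graph$elements[i], deg[i], bsum[i], sep = "|")), numeric(1))
  if (max_radius >= 1) {
    for (r in seq_len(max_radius)) {
      ids[, r + 1] <- vapply(seq_len(n), function(i) {
        if (is.null(adj[[i]])) return(hash32(paste0("T|", ids[i, r])))
        nb <- apply(adj[[i]], 1, function(x) paste(x[2], ids[x[1], r], sep = ","))
        hash32(paste0("T|", ids[i, r], "|", paste(sort(nb), collapse = ";")))
      }, numeric(1))
    }
  }
  ids
}

#' Morgan substructure sentence of a compound
#'
#' Decomposes a molecule into the ordered list of Morgan environment
#' identifier tokens that the mol2vec scheme treats as "words": for each
#' heavy atom (canonical atom order), the environment identifier at each
#' requested radius in ascending order. Identifiers are 32-bit hashes of the
#' iteratively refined atom environments, deterministic for a given molecule
#' and invariant across equivalent SMILES spellings. Salts/mixtures keep the
#' largest covalent fragment.
#'
#' @param smiles SMILES string.
#' @param radii non-negative integer radii (default `c(0, 1)`, the mol2vec
#'   reference scheme).
#' @return Character vector of tokens, length `n_heavy_atoms * length(radii)`.
#' @export
#' @examples
#' \donttest{
#' mol_sentence("CCO")
#' }
mol_sentence <- function(smiles, radii = c(0, 1)) {
  radii <- sort(unique(as.integer(radii)))
  if (length(radii) == 0 || any(radii < 0)) {
    stop_dtimoa("dtimoa_invalid_input", "radii must be non-negative integers")
  }
  graph <- smiles_graph(smiles)
  ids <- morgan_ids(graph, max(radii))
  tokens <- character(0)
  for (i in seq_along(graph$elements)) {
    tokens <- c(tokens, format(ids[i, radii + 1], scientific = FALSE))
  }
  trimws(tokens)
}

#' Embed a compound sentence by summing substructure vectors
#'
#' The compound vector is the exact sum of the embedding vectors of its
#' sentence tokens, duplicates counted with multiplicity. Unknown tokens are
#' handled per the table's policy; a sentence with no known token yields a
#' zero vector with a warning.
#'
#' @param sentence character vector of tokens (from [mol_sentence()]).
#' @param table an [embedding_table()].
#' @return Numeric vector of length `table$d`, with attribute `n_unknown`.
#' @export
embed_compound <- function(sentence, table) {
  stopifnot(inherits(table, "embedding_table"))
  if (nrow(table$vectors) == 0) {
    stop_dtimoa("dtimoa_invalid_input", "embedding table is empty")
  }
  idx <- match(sentence, rownames(table$vectors))
  n_unknown <- sum(is.na(idx))
  known <- idx[!is.na(idx)]
  v <- if (length(known) == 0) {
    warning("no sentence token found in the embedding table; zero vector returned")
    numeric(table$d)
  } else if (length(known) == 1) {
    as.numeric(table$vectors[known, ])
  } else {
    as.numeric(colSums(table$vectors[known, , drop = FALSE]))
  }
  attr(v, "n_unknown") <- n_unknown
  v
}

#' Featurize a set of SMILES into compound vectors
#'
#' @param smiles named character vector (names = compound ids) or data.frame
#'   with columns `compound_id`, `smiles`.
#' @param table an [embedding_table()].
#' @param radii passed to [mol_sentence()].
#' @return List with `vectors` (matrix, rows = compounds), `sentences`,
#'   `unk_rate` per compound, and `failed` (unparseable SMILES ids).
#' @export
featurize_compounds <- function(smiles, table, radii = c(0, 1)) {
  if (is.data.frame(smiles)) {
    smi <- stats::setNames(as.character(smiles$smiles), smiles$compound_id)
  } else {
    smi <- smiles
  }
  if (is.null(names(smi))) names(smi) <- paste0("cmpd", seq_along(smi))
  sentences <- list(); failed <- character(0)
  for (id in names(smi)) {
    sentences[[id]] <- tryCatch(mol_sentence(smi[[id]], radii = radii),
                                error = function(e) NULL)
    if (is.null(sentences[[id]])) failed <- c(failed, id)
  }
  sentences <- sentences[!vapply(sentences, is.null, logical(1))]
  vecs <- matrix(0, nrow = length(sentences), ncol = table$d,
                 dimnames = list(names(sentences), colnames(table$vectors)))
  unk <- numeric(length(sentences)); names(unk) <- names(sentences)
  for (id in names(sentences)) {
    v <- suppressWarnings(embed_compound(sentences[[id]], table))
    vecs[id, ] <- v
    unk[id] <- attr(v, "n_unknown") / max(1L, length(sentences[[id]]))
  }
  list(vectors = vecs, sentences = sentences, unk_rate = unk, failed = failed)
}

#' Binary structural fingerprints
#'
#' Hashed Morgan bit vector (environment identifiers at radii `0..radius`
#' folded modulo `n_bits`) or MACCS structural keys (166 bits, computed by
#' OpenBabel). Deterministic for a given molecule.
#'
#' @param smiles SMILES string.
#' @param kind `"morgan"` or `"maccs"`.
#' @param n_bits fingerprint width for Morgan (default 2048).
#' @param radius maximum Morgan radius (default 2).
#' @return Integer 0/1 vector.
#' @export
fingerprint <- function(smiles, kind = c("morgan", "maccs"),
                        n_bits = 2048, radius = 2) {
  kind <- match.arg(kind)
  if (kind == "morgan") {
    graph <- smiles_graph(smiles)
    ids <- morgan_ids(graph, radius)
    bits <- integer(n_bits)
    bits[unique(as.numeric(ids) %% n_bits) + 1] <- 1L
    bits
  } else {
    graph <- smiles_graph(smiles)  # validates + canonicalizes/desalts
    sdf <- ChemmineR::smiles2sdf(graph$smiles)
    fp <- ChemmineR::fingerprintOB(sdf, "MACCS")
    # OpenBabel stores the 166 MACCS keys in a 256-bit container
    as.integer(as.vector(fp[[1]])[seq_len(166)])
  }
}

#' Tanimoto similarity of two binary fingerprints
#'
#' @param a,b 0/1 integer vectors of equal length.
#' @return Similarity in `[0, 1]`; 1 when both are empty.
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  inter <- sum(a & b); uni <- sum(a | b)
  if (uni == 0) return(1)
  inter / uni
}
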