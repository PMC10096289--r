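#' Read a GCT 1.2/1.3 text matrix
#'
#' Parses the text GCT dialect used for gene expression matrices: a version
#' line (`#1.2` or `#1.3`), a dimension line, then a header row and the data
#' block. For 1.3 files the per-row and per-column metadata blocks declared
#' on the dimension line are skipped; only the numeric matrix with row and
#' column identifiers is returned.
#'
#' @param path file path.
#' @return Numeric matrix with gene rownames and signature colnames.
#' @export
read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop_dtimoa("dtimoa_parse_error", "truncated GCT file")
  version <- trimws(lines[1])
  if (!version %in% c("#1.2", "#1.3")) {
    stop_dtimoa("dtimoa_parse_error", "unknown GCT version line '%s'", version)
  }
  dims <- suppressWarnings(as.integer(strsplit(trimws(lines[2]), "\t")[[1]]))
  if (version == "#1.2") {
    if (length(dims) < 2 || any(is.na(dims[1:2]))) {
      stop_dtimoa("dtimoa_parse_error", "bad GCT 1.2 dimension line")
    }
    nr <- dims[1]; nc <- dims[2]; nrmeta <- 0L; ncmeta <- 1L  # Description col
  } else {
    if (length(dims) < 4 || any(is.na(dims[1:4]))) {
      stop_dtimoa("dtimoa_parse_error", "bad GCT 1.3 dimension line")
    }
    nr <- dims[1]; nc <- dims[2]; nrmeta <- dims[4]; ncmeta <- dims[3]
  }
  header <- strsplit(lines[3], "\t")[[1]]
  body_start <- 4L + nrmeta  # 1.3: column-metadata rows precede the data
  if (length(lines) < body_start + nr - 1L) {
    stop_dtimoa("dtimoa_parse_error",
                "GCT declares %d data rows but file holds %d", nr,
                max(0L, length(lines) - body_start + 1L))
  }
  body <- lines[seq(body_start, length.out = nr)]
  if (any(!nzchar(body))) {
    stop_dtimoa("dtimoa_parse_error", "blank line inside GCT data block")
  }
  fields <- strsplit(body, "\t")
  expected <- 1L + ncmeta + nc
  if (any(vapply(fields, length, integer(1)) != expected)) {
    stop_dtimoa("dtimoa_parse_error",
                "GCT row width mismatch (expected %d fields)", expected)
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  mat <- t(vapply(fields, function(f)
    as.numeric(f[(2L + ncmeta):(1L + ncmeta + nc)]), numeric(nc)))
  if (nc == 1) mat <- matrix(mat, ncol = 1)
  if (any(is.na(mat))) stop_dtimoa("dtimoa_parse_error", "non-numeric GCT value")
  dimnames(mat) <- list(ids, header[(2L + ncmeta):(1L + ncmeta + nc)])
  mat
}

#' Write a matrix as GCT 1.2 text
#'
#' @param mat numeric matrix with row and column names.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_gct <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(mat), ncol(mat), sep = "\t"),
               paste(c("id", "Description", colnames(mat)), collapse = "\t")),
             con)
  for (i in seq_len(nrow(mat))) {
    writeLines(paste(c(rownames(mat)[i], "na",
                       format(mat[i, ], digits = 15, scientific = FALSE,
                              trim = TRUE)), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a typed TSV table
#'
#' Plain UTF-8 tab-separated tables with a header row, `NA` as the missing
#' token and no quoting (embedded tabs in fields are rejected upstream by
#' the writer). Column types may be declared and are enforced.
#'
#' @param path file path.
#' @param col_types optional named character vector, values in
#'   `c("character", "numeric", "integer")`.
#' @return data.frame.
#' @export
read_tsv_table <- function(path, col_types = NULL) {
  df <- utils::read.delim(path, sep = "\t", quote = "", na.strings = "NA",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  for (col in names(col_types)) {
    if (!col %in% names(df)) {
      stop_dtimoa("dtimoa_parse_error", "missing column '%s' in %s", col, path)
    }
    df[[col]] <- switch(col_types[[col]],
                        character = as.character(df[[col]]),
                        numeric = as.numeric(df[[col]]),
                        integer = as.integer(df[[col]]),
                        df[[col]])
  }
  df
}

#' Write a TSV table
#'
#' @param df data.frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  chr <- vapply(df, is.character, logical(1))
  if (any(vapply(df[chr], function(x) any(grepl("[\t\n]", x)), logical(1)))) {
    stop_dtimoa("dtimoa_invalid_input",
                "fields containing tabs or newlines cannot be written")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read signatures from a GCT matrix plus a metadata table
#'
#' Columns of the GCT are signature profiles; the metadata TSV must carry
#' `signature_id`, `perturbed_gene`, `perturbation_kind`, `cell_line`,
#' `condition`. Genes are re-ordered to `panel` when given; missing panel
#' genes are an error (no imputation).
#'
#' @param gct_path path to the signature GCT.
#' @param meta_path path to the metadata TSV.
#' @param panel optional [gene_panel()]; defaults to the GCT row order.
#' @return List of [signature()] objects.
#' @export
read_signatures <- function(gct_path, meta_path, panel = NULL) {
  mat <- read_gct(gct_path)
  meta <- read_tsv_table(meta_path,
                         col_types = c(signature_id = "character",
                                       perturbed_gene = "character",
                                       perturbation_kind = "character",
                                       cell_line = "character",
                                       condition = "character"))
  if (is.null(panel)) panel <- gene_panel(rownames(mat))
  missing <- setdiff(panel$gene_ids, rownames(mat))
  if (length(missing) > 0) {
    stop_dtimoa("dtimoa_invalid_input", "panel genes missing from GCT: %s",
                paste(utils::head(missing, 5), collapse = ", "))
  }
  mat <- mat[panel$gene_ids, , drop = FALSE]
  absent <- setdiff(meta$signature_id, colnames(mat))
  if (length(absent) > 0) {
    stop_dtimoa("dtimoa_invalid_input", "metadata signatures missing from GCT: %s",
                paste(utils::head(absent, 5), collapse = ", "))
  }
  sigs <- lapply(seq_len(nrow(meta)), function(i) {
    signature(mat[, meta$signature_id[i]], meta$perturbed_gene[i],
              meta$perturbation_kind[i], meta$cell_line[i],
              meta$condition[i], meta$signature_id[i], panel)
  })
  names(sigs) <- meta$signature_id
  sigs
}

#' Write a target store as a GCT consensus matrix plus provenance TSV
#'
#' @param store a [target_store()].
#' @param gct_path output GCT path (columns = genes).
#' @param meta_path output TSV path (gene, provenance, n_support).
#' @return Invisibly, the two paths.
#' @export
write_target_store <- function(store, gct_path, meta_path) {
  entries <- store$entries
  if (length(entries) == 0) stop_dtimoa("dtimoa_empty_input", "empty store")
  mat <- vapply(entries, `[[`, numeric(store$panel$size), "vector")
  colnames(mat) <- vapply(entries, function(e)
    paste(e$gene, e$provenance, sep = "|"), character(1))
  rownames(mat) <- store$panel$gene_ids
  write_gct(mat, gct_path)
  write_tsv_table(data.frame(
    gene = vapply(entries, `[[`, character(1), "gene"),
    provenance = vapply(entries, `[[`, character(1), "provenance"),
    n_support = vapply(entries, `[[`, integer(1), "n_support"),
    stringsAsFactors = FALSE), meta_path)
  invisible(c(gct_path, meta_path))
}

#' Read a target store written by [write_target_store()]
#'
#' @param gct_path consensus GCT path.
#' @param meta_path provenance TSV path.
#' @param mode store mode.
#' @return A [target_store()].
#' @export
read_target_store <- function(gct_path, meta_path,
                              mode = c("activatory", "inhibitory")) {
  mode <- match.arg(mode)
  mat <- read_gct(gct_path)
  meta <- read_tsv_table(meta_path, col_types = c(gene = "character",
                                                  provenance = "character",
                                                  n_support = "integer"))
  store <- target_store(mode, gene_panel(rownames(mat)))
  for (i in seq_len(nrow(meta))) {
    col <- paste(meta$gene[i], meta$provenance[i], sep = "|")
    store <- store_set(store, meta$gene[i], mat[, col], meta$provenance[i],
                       meta$n_support[i])
  }
  store
}

#' Read a STRING-style PPI edge table
#'
#' Expects columns `protein1`, `protein2`, `combined_score` (or the package
#' names `gene_a`, `gene_b`, `score`). An optional two-column identifier map
#' (`protein_id`, `gene_symbol`) translates protein identifiers to gene
#' symbols before the graph is built; unmapped proteins are dropped with a
#' count reported via message.
#'
#' @param path edge table TSV path.
#' @param id_map_path optional identifier map TSV path.
#' @param score_threshold,scale passed to [build_ppi()].
#' @return An igraph PPI graph.
#' @export
read_string_edges <- function(path, id_map_path = NULL, score_threshold = 900,
                              scale = "auto") {
  edges <- read_tsv_table(path)
  if (!is.null(id_map_path)) {
    map <- read_tsv_table(id_map_path, col_types = c(protein_id = "character",
                                                     gene_symbol = "character"))
    lut <- stats::setNames(map$gene_symbol, map$protein_id)
    a <- names(edges)[1]; b <- names(edges)[2]
    before <- nrow(edges)
    edges[[a]] <- unname(lut[as.character(edges[[a]])])
    edges[[b]] <- unname(lut[as.character(edges[[b]])])
    edges <- edges[!is.na(edges[[a]]) & !is.na(edges[[b]]), , drop = FALSE]
    if (before - nrow(edges) > 0) {
      message(before - nrow(edges), " edge(s) dropped: unmapped protein id")
    }
  }
  build_ppi(edges, score_threshold = score_threshold, scale = scale)
}

#' Read a substructure embedding table TSV
#'
#' First column `token`, remaining columns the vector components.
#'
#' @param path TSV path.
#' @param unk unknown-token policy.
#' @return An [embedding_table()].
#' @export
read_embedding_table <- function(path, unk = "skip") {
  df <- read_tsv_table(path, col_types = c(token = "character"))
  mat <- as.matrix(df[, setdiff(names(df), "token"), drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- df$token
  embedding_table(mat, unk = unk)
}

#' Write an embedding table TSV
#'
#' @param table an [embedding_table()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_embedding_table <- function(table, path) {
  df <- data.frame(token = rownames(table$vectors), table$vectors,
                   stringsAsFactors = FALSE, check.names = FALSE)
  write_tsv_table(df, path)
}

#' Write a run manifest
#'
#' Every artifact directory carries a JSON manifest recording the producing
#' command, its configuration echo, seeds, input checksums and record
#' counts, sufficient to re-run the command exactly.
#'
#' @param dir artifact directory.
#' @param command subcommand name.
#' @param config configuration list (echoed verbatim).
#' @param inputs character vector of input paths (md5-checksummed).
#' @param counts named list of record counts.
#' @return Path of the manifest, invisibly.
#' @export
write_manifest <- function(dir, command, config = list(), inputs = character(0),
                           counts = list()) {
  checksums <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else list()
  manifest <- list(command = command,
                   package_version = as.character(utils::packageVersion("dtimoa")),
                   r_version = as.character(getRversion()),
                   config = config, input_md5 = checksums, counts = counts,
                   written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a synthetic study bundle to disk
#'
#' Emits exactly the file formats the pipeline readers consume: signature
#' GCT + metadata TSV, truth GCT, PPI edge TSV, embedding-table TSV,
#' compound sentence TSV, DTI TSV, and a manifest.
#'
#' @param bundle a [gen_bundle()] result.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sigs <- bundle$signatures
  mat <- vapply(sigs, `[[`, numeric(bundle$config$G), "values")
  rownames(mat) <- bundle$panel$gene_ids
  write_gct(mat, file.path(dir, "signatures.gct"))
  write_tsv_table(data.frame(
    signature_id = vapply(sigs, `[[`, character(1), "signature_id"),
    perturbed_gene = vapply(sigs, `[[`, character(1), "perturbed_gene"),
    perturbation_kind = vapply(sigs, `[[`, character(1), "perturbation_kind"),
    cell_line = vapply(sigs, `[[`, character(1), "cell_line"),
    condition = vapply(sigs, `[[`, character(1), "condition"),
    stringsAsFactors = FALSE), file.path(dir, "signature_meta.tsv"))
  write_gct(bundle$truths, file.path(dir, "truths.gct"))
  write_tsv_table(bundle$ppi$edges, file.path(dir, "ppi_edges.tsv"))
  write_embedding_table(bundle$compounds$table,
                        file.path(dir, "embedding_table.tsv"))
  write_tsv_table(data.frame(
    compound_id = names(bundle$compounds$sentences),
    sentence = vapply(bundle$compounds$sentences, paste, character(1),
                      collapse = " "),
    stringsAsFactors = FALSE), file.path(dir, "compound_sentences.tsv"))
  pos <- bundle$benchmark$positives
  pos$moa_term <- "inhibitor"
  write_tsv_table(pos[c("compound_id", "target_gene", "moa_term")],
                  file.path(dir, "dti.tsv"))
  write_manifest(dir, "simulate", config = unclass(bundle$config),
                 counts = list(n_signatures = length(sigs),
                               n_positives = nrow(pos)))
  invisible(dir)
}
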