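# Readers and writers for the package's on-disk formats: MatrixMarket +
# TSV for layers, BED/GTF for feature coordinates, TSV edge lists for
# guidance edges, TSV for embeddings and regulatory tables, JSON run
# manifests.

#' Read an omics layer from MatrixMarket + annotation files
#'
#' Loads a cells x features sparse matrix (transposing if the feature
#' file matches the row count instead, as in gene x cell exports is NOT
#' assumed: dimensions must agree as cells x features), feature ids and
#' cell ids, validating dimensions and the integer constraint for NB
#' layers.
#'
#' @param matrix_path MatrixMarket (.mtx) file, cells x features.
#' @param features_path One feature id per line (first TSV column used).
#' @param cells_path One cell id per line; optional extra TSV columns,
#'   one of which may hold batch labels.
#' @param family `"NB"` or `"ZILN"`.
#' @param name Layer name.
#' @param batch_col Optional column index (2-based) in `cells_path`
#'   holding batch labels.
#' @return An [omics_layer()].
#' @export
read_layer <- function(matrix_path, features_path, cells_path,
                       family = "NB", name = "layer", batch_col = NULL) {
  X <- as(Matrix::readMM(matrix_path), "CsparseMatrix")
  feats <- read.table(features_path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
  cells_df <- read.table(cells_path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  cells <- cells_df[[1]]
  if (ncol(X) != length(feats) || nrow(X) != length(cells))
    stop("read_layer: matrix is ", nrow(X), " x ", ncol(X),
         " but annotations describe ", length(cells), " cells x ",
         length(feats), " features")
  dimnames(X) <- list(cells, feats)
  batches <- if (!is.null(batch_col)) {
    if (batch_col > ncol(cells_df))
      stop("read_layer: batch column ", batch_col, " not present")
    cells_df[[batch_col]]
  } else NULL
  omics_layer(X, features = feats, family = family, name = name,
              batches = batches)
}

#' Write an omics layer as MatrixMarket + annotation files
#'
#' @param layer An [omics_layer()].
#' @param dir Output directory (created if needed); files are
#'   `<name>.mtx`, `<name>_features.tsv`, `<name>_cells.tsv`.
#' @return Invisibly, the three file paths.
#' @export
write_layer <- function(layer, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, layer$name)
  mtx <- paste0(base, ".mtx")
  Matrix::writeMM(layer$X, mtx)
  ff <- paste0(base, "_features.tsv")
  writeLines(layer$features, ff)
  cf <- paste0(base, "_cells.tsv")
  cells <- rownames(layer$X) %||% sprintf("cell%d", seq_len(nrow(layer$X)))
  write.table(data.frame(cells, layer$batch_levels[layer$batches]),
              cf, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(c(matrix = mtx, features = ff, cells = cf))
}

#' Read genomic features from BED
#'
#' BED3+ / BED6; 0-based half-open coordinates are kept as-is. Column 4
#' supplies ids when present (generated otherwise), column 6 strands.
#'
#' @param path BED file path.
#' @param kind Feature kind recorded on the result.
#' @return A [genomic_features()] table.
#' @export
read_bed <- function(path, kind = "peak") {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  id <- if (ncol(df) >= 4) as.character(df[[4]])
    else sprintf("%s:%d-%d", df[[1]], df[[2]], df[[3]])
  strand <- if (ncol(df) >= 6) df[[6]] else "."
  genomic_features(id = id, chrom = df[[1]], start = df[[2]], end = df[[3]],
                   strand = strand, kind = kind)
}

#' Write genomic features as BED6
#'
#' @param features A [genomic_features()] table.
#' @param path Output path.
#' @export
write_bed <- function(features, path) {
  write.table(data.frame(features$chrom, features$start, features$end,
                         features$id, 0L, features$strand),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read gene features from GTF/GFF
#'
#' Parses records with feature type `gene` (falling back to `transcript`
#' when no gene records exist), extracting `gene_id` (or `ID=`) from the
#' attribute column. GTF 1-based inclusive coordinates are converted to
#' the package's 0-based half-open convention.
#'
#' @param path GTF/GFF file path.
#' @return A [genomic_features()] table of genes.
#' @export
read_gtf_genes <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  keep <- vapply(f, function(x) length(x) >= 9 && x[3] == "gene", TRUE)
  if (!any(keep))
    keep <- vapply(f, function(x) length(x) >= 9 && x[3] == "transcript",
                   TRUE)
  if (!any(keep)) stop("read_gtf_genes: no gene records found")
  f <- f[keep]
  attr_id <- vapply(f, function(x) {
    a <- x[9]
    m <- regmatches(a, regexec('gene_id[ =]+"?([^";]+)"?', a))[[1]]
    if (length(m) == 2) return(m[2])
    m <- regmatches(a, regexec("ID=([^;]+)", a))[[1]]
    if (length(m) == 2) return(m[2])
    NA_character_
  }, "")
  if (anyNA(attr_id)) stop("read_gtf_genes: records without gene_id/ID")
  genomic_features(
    id = attr_id,
    chrom = vapply(f, `[[`, "", 1),
    start = as.integer(vapply(f, `[[`, "", 4)) - 1L, # GTF is 1-based
    end = as.integer(vapply(f, `[[`, "", 5)),
    strand = vapply(f, `[[`, "", 7),
    kind = "gene")
}

#' Read / write guidance edges as a TSV edge list
#'
#' Columns: `source`, `target`, `weight`, `sign`, `tag` (header row).
#'
#' @param path TSV file path.
#' @return `read_edge_tsv` returns an edge data.frame suitable for
#'   [guidance_graph()].
#' @export
read_edge_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("source", "target", "weight", "sign")
  if (!all(need %in% names(df)))
    stop("read_edge_tsv: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  data.frame(i = as.character(df$source), j = as.character(df$target),
             sign = df$sign, weight = df$weight,
             tag = if ("tag" %in% names(df)) df$tag else "prior",
             stringsAsFactors = FALSE)
}

#' @rdname read_edge_tsv
#' @param g A [guidance_graph()] whose non-self-loop edges are written.
#' @export
write_edge_tsv <- function(g, path) {
  e <- cross_edges(g)
  write.table(data.frame(source = e$i, target = e$j,
                         weight = signif(e$weight, 9), sign = e$sign,
                         tag = e$tag),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an embedding matrix as TSV
#'
#' Rows are cells/features (ids in the first column), columns the
#' embedding dimensions; floats at 9 significant digits.
#'
#' @param emb Numeric matrix with rownames.
#' @param path Output path.
#' @return `read_embeddings_tsv` returns the matrix.
#' @export
write_embeddings_tsv <- function(emb, path) {
  df <- data.frame(id = rownames(emb) %||% seq_len(nrow(emb)),
                   signif(emb, 9))
  names(df)[-1] <- paste0("dim", seq_len(ncol(emb)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embeddings_tsv
#' @export
read_embeddings_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a regulatory table as TSV (and optionally BEDPE)
#'
#' @param table Output of [regulatory_scores()] /
#'   [regulatory_significance()].
#' @param path Output TSV path.
#' @param features Optional [genomic_features()] table; when given, a
#'   BEDPE file with paired intervals is written alongside
#'   (`<path>.bedpe`).
#' @export
write_regulatory_tsv <- function(table, path, features = NULL) {
  num <- vapply(table, is.numeric, TRUE)
  out <- table
  out[num] <- lapply(out[num], signif, 9)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(features)) {
    fi <- match(table$feature_i, features$id)
    fj <- match(table$feature_j, features$id)
    bedpe <- data.frame(features$chrom[fi], features$start[fi],
                        features$end[fi], features$chrom[fj],
                        features$start[fj], features$end[fj],
                        paste(table$feature_i, table$feature_j, sep = "|"),
                        signif(table$score, 9))
    write.table(bedpe, paste0(path, ".bedpe"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Run manifest for reproducibility
#'
#' JSON snapshot of a command's configuration, seeds, input file hashes
#' and package version — sufficient to re-run bit-identically.
#'
#' @param config Any list of configuration values.
#' @param inputs Character vector of input file paths (content-hashed).
#' @param path Output JSON path.
#' @return Invisibly, the manifest list.
#' @export
write_manifest <- function(config, inputs = character(0), path) {
  hash_file <- function(p) {
    con <- file(p, "rb")
    on.exit(close(con))
    raw <- as.integer(readBin(con, "raw", file.info(p)$size))
    # order-dependent polynomial hash in double precision; stable
    # across platforms and fast enough for manifest-sized inputs
    h <- 17
    for (b in raw) h <- (h * 31 + b) %% 2147483647
    sprintf("%08x", as.integer(h))
  }
  man <- list(
    package = "omicbridge",
    version = as.character(utils::packageVersion("omicbridge")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config[!vapply(config, is.function, TRUE)],
    inputs = if (length(inputs))
      stats::setNames(lapply(inputs, hash_file), inputs) else NULL)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(man)
}

#' Write a training history log as JSON
#'
#' @param model A fitted [glue_model()].
#' @param path Output JSON path.
#' @export
write_history_json <- function(model, path) {
  if (is.null(model$history)) stop("write_history_json: no history")
  jsonlite::write_json(model$history, path, digits = NA, dataframe = "rows")
  invisible(path)
}
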