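# TSV dialects used throughout: UTF-8, tab-delimited, "." decimal separator.
# Matrices carry the feature (or sample) id in the first column and the
# sample (or trait) ids in the header row.

#' Read a features x samples matrix from TSV
#'
#' First column = feature id, header = sample ids.
#'
#' @param path file path.
#' @return numeric matrix with rownames (features) and colnames (samples).
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate row ids in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("missing values in ", path)
  rownames(m) <- ids
  m
}

#' Write a matrix to TSV (row ids in the first column)
#'
#' @param m matrix with dimnames.
#' @param path output file path.
#' @param id_col header name for the id column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GEBV table (samples x traits) from TSV
#'
#' First column = sample id, header = trait ids.
#'
#' @param path file path.
#' @return numeric matrix, samples x traits.
#' @export
read_gebv_tsv <- function(path) read_matrix_tsv(path)

#' Read an attribute table from TSV
#'
#' Columns: `feature_id`, `kind` (one of `DEG`, `TF`, `cis_eqtl`,
#' `trans_eqtl`), `trait_id` (may be blank for TF/eQTL rows), `direction`
#' (`up`, `down` or `none`).
#'
#' @param path file path.
#' @return data.frame with those four columns; duplicate
#'   (feature_id, kind, trait_id) combinations are an error.
#' @export
read_attributes_tsv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  need <- c("feature_id", "kind", "trait_id", "direction")
  if (!all(need %in% names(df)))
    stop("attribute table must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  bad <- setdiff(unique(df$kind), c("DEG", "TF", "cis_eqtl", "trans_eqtl"))
  if (length(bad))
    stop("unknown attribute kind(s): ", paste(bad, collapse = ", "))
  df$direction[df$direction == ""] <- "none"
  key <- paste(df$feature_id, df$kind, df$trait_id)
  if (anyDuplicated(key))
    stop("duplicate (feature_id, kind, trait_id) rows in ", path)
  df
}

#' Write a data.frame to TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a PCIT result as an edge list plus node-role table
#'
#' @param result a `pcit_result`.
#' @param edge_path path for the edge TSV (`node_a`, `node_b`, `r`,
#'   `significant`, `source_run`).
#' @param node_path optional path for the node-role TSV.
#' @param source_run run label.
#' @param significant_only write only significant edges (default `TRUE`).
#' @export
write_pcit_edges <- function(result, edge_path, node_path = NULL,
                             source_run = "pcit", significant_only = TRUE) {
  e <- pcit_edges(result, significant_only = significant_only,
                  source_run = source_run)
  write_tsv(e[, c("node_a", "node_b", "r", "significant", "source_run")],
            edge_path)
  if (!is.null(node_path))
    write_tsv(data.frame(node_id = result$node_ids,
                         role = unname(result$roles),
                         stringsAsFactors = FALSE), node_path)
  invisible(edge_path)
}

#' Write a PCIT significance matrix
#'
#' Square 0/1 matrix, rows/columns in node order.
#'
#' @param result a `pcit_result`.
#' @param path output path.
#' @export
write_pcit_matrix <- function(result, path) {
  m <- result$sig * 1L
  write_matrix_tsv(m, path, id_col = "node_id")
}
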