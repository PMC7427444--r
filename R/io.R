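#' Read an adjacency matrix from CSV/TSV
#'
#' Expects a dense square matrix with a header row of node ids (and an
#' optional leading id column, detected automatically).
#'
#' @param path file path; `sep` inferred from the extension unless given
#' @param sep field separator
#' @return a [brain_graph()]
#' @export
read_adjacency <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  if (!is.numeric(df[[1]]) || ncol(df) == nrow(df) + 1) {
    ids <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
    rownames(df) <- ids
  }
  m <- as.matrix(df)
  brain_graph(m, node_ids = colnames(df))
}

#' Write an adjacency matrix as CSV/TSV
#' @param g a [brain_graph()]
#' @param path output path; `.tsv` extension switches to tab separation
#' @return `path`, invisibly
#' @export
write_adjacency <- function(g, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  m <- g$adjacency
  dimnames(m) <- list(g$node_ids, g$node_ids)
  write.table(m, path, sep = sep, quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a graph from GraphML
#' @param path GraphML file
#' @return a [brain_graph()]
#' @export
read_graphml <- function(path) {
  gi <- igraph::read_graph(path, format = "graphml")
  m <- as.matrix(igraph::as_adjacency_matrix(gi, type = "both"))
  m[m > 1] <- 1
  ids <- igraph::vertex_attr(gi, "name")
  if (is.null(ids)) ids <- paste0("n", seq_len(nrow(m)))
  brain_graph(unname(m), node_ids = ids)
}

#' Write a graph as GraphML
#' @param g a [brain_graph()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_graphml <- function(g, path) {
  m <- g$adjacency
  dimnames(m) <- list(g$node_ids, g$node_ids)
  gi <- igraph::graph_from_adjacency_matrix(m, mode = "undirected")
  igraph::write_graph(gi, path, format = "graphml")
  invisible(path)
}

#' Read a node attribute table (TSV)
#'
#' Columns: `node_id`, `rsn_label`, `cortical_group`, plus optional
#' covariate columns.
#'
#' @param path TSV file
#' @return a validated `node_attributes` data.frame
#' @export
read_attributes <- function(path) {
  validate_attrs(read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE))
}

#' Write a node attribute table (TSV)
#' @param attrs attribute table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_attributes <- function(attrs, path) {
  write.table(attrs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a fit as JSON
#'
#' One object per term: estimate, standard error, z, p, significance.
#'
#' @param fit an `ergm_fit`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fit_json <- function(fit, path) {
  x <- list(method = fit$method, spec = fit$spec$name,
            converged = fit$converged, alpha = fit$alpha,
            seed = fit$seed,
            terms = as.data.frame(fit))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Serialize a fit as CSV (one row per term)
#' @param fit an `ergm_fit`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fit_csv <- function(fit, path) {
  write.csv(as.data.frame(fit), path, row.names = FALSE)
  invisible(path)
}
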