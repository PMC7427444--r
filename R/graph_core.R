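#' Validate an adjacency matrix into a brain graph
#'
#' A brain graph is an undirected binary graph: a symmetric, hollow
#' (zero-diagonal) 0/1 adjacency matrix over a fixed node set.  This is the
#' observed network \eqn{y} whose probability an exponential random graph
#' model (ERGM) writes as \eqn{P(Y=y) \propto \exp(\theta^T g(y))}.
#'
#' @param adjacency square numeric/integer matrix with entries in `{0,1}`,
#'   symmetric, zero diagonal.
#' @param node_ids optional character vector of node identifiers; defaults to
#'   matrix dimnames, or `"n1".."nN"`.
#' @return an object of class `brain_graph` with fields `n_nodes`,
#'   `adjacency` (integer matrix) and `node_ids`.
#' @examples
#' g <- brain_graph(matrix(c(0,1,1, 1,0,1, 1,1,0), 3, 3))
#' graph_density(g)
#' @export
brain_graph <- function(adjacency, node_ids = NULL) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency))
    stop("adjacency must be a square matrix")
  n <- nrow(adjacency)
  a <- adjacency
  storage.mode(a) <- "double"
  bad <- which(!(a %in% c(0, 1)))
  if (length(bad) > 0) {
    ij <- arrayInd(bad[1], dim(a))
    stop(sprintf("non-binary entry %g at (%d, %d)", a[bad[1]], ij[1], ij[2]))
  }
  d <- which(diag(a) != 0)
  if (length(d) > 0)
    stop(sprintf("self-loop at node %d: diagonal must be zero", d[1]))
  asym <- which(a != t(a))
  if (length(asym) > 0) {
    ij <- arrayInd(asym[1], dim(a))
    stop(sprintf("asymmetric entries at (%d, %d) vs (%d, %d)",
                 ij[1], ij[2], ij[2], ij[1]))
  }
  if (is.null(node_ids)) {
    node_ids <- rownames(adjacency)
    if (is.null(node_ids)) node_ids <- paste0("n", seq_len(n))
  }
  if (length(node_ids) != n)
    stop("node_ids length does not match matrix dimension")
  a <- unname(a)
  storage.mode(a) <- "integer"
  structure(list(n_nodes = n, adjacency = a,
                 node_ids = as.character(node_ids)),
            class = "brain_graph")
}

#' @export
print.brain_graph <- function(x, ...) {
  cat(sprintf("brain_graph: %d nodes, %d edges (density %.4f)\n",
              x$n_nodes, edge_count(x), graph_density(x)))
  invisible(x)
}

#' Number of edges of a brain graph
#' @param g a [brain_graph()]
#' @return integer edge count
#' @export
edge_count <- function(g) {
  stopifnot(inherits(g, "brain_graph"))
  sum(g$adjacency) %/% 2L
}

#' Graph density
#'
#' Fraction of realized dyads, \eqn{E / \binom{n}{2}}.
#'
#' @param g a [brain_graph()]
#' @return density in `[0, 1]`
#' @export
graph_density <- function(g) {
  stopifnot(inherits(g, "brain_graph"))
  if (g$n_nodes < 2) stop("density undefined for graphs with fewer than 2 nodes")
  edge_count(g) / (g$n_nodes * (g$n_nodes - 1) / 2)
}

#' Edgewise shared partner (ESP) distribution
#'
#' For each edge (u, v), counts the common neighbours of u and v, and
#' histograms those counts: `counts[i]` is the number of edges with exactly
#' `i` shared partners (named `"0"`, `"1"`, ...).  The total over all bins
#' equals the edge count.
#'
#' @param g a [brain_graph()]
#' @return named integer vector of class `esp_distribution`, bins `0..n-2`
#' @export
esp_distribution <- function(g) {
  stopifnot(inherits(g, "brain_graph"))
  counts <- cpp_esp_counts(g$adjacency)
  names(counts) <- as.character(seq_along(counts) - 1L)
  structure(counts, class = "esp_distribution")
}

#' Fixed-decay GWESP statistic from an ESP distribution
#'
#' The geometrically weighted edgewise shared partner statistic
#' \deqn{v(y;\lambda) = e^{\lambda} \sum_{i \ge 1}
#'   \left[1 - (1 - e^{-\lambda})^i\right] EP_i(y)}
#' down-weights edges with many shared partners so the term stays
#' informative about triadic closure without the degeneracy of a raw
#' triangle count.
#'
#' @param esp named numeric vector of ESP counts; names are shared-partner
#'   counts (as from [esp_distribution()], or any named subset).
#' @param decay decay \eqn{\lambda \ge 0}.
#' @return the GWESP statistic (nonnegative real)
#' @export
gwesp_from_esp <- function(esp, decay) {
  if (!is.numeric(decay) || length(decay) != 1 || decay < 0)
    stop("decay must be a single nonnegative number")
  if (length(esp) == 0) return(0)
  i <- as.integer(names(esp))
  if (anyNA(i)) stop("esp must be named by shared-partner counts")
  u <- 1 - exp(-decay)
  keep <- i >= 1L
  sum(exp(decay) * (1 - u^i[keep]) * as.numeric(esp[keep]))
}

#' Selective-mixing edge counts
#'
#' Counts edges by the unordered pair of node labels they join.  All label
#' cells are reported, including cells with zero edges; the cell total
#' equals the edge count.
#'
#' @param g a [brain_graph()]
#' @param attrs a node attribute table (see [node_attributes()]) aligned
#'   with `g`
#' @param label column of `attrs` holding the categorical label
#'   (default `"rsn_label"`)
#' @return data.frame with columns `label_a`, `label_b` (label_a <= label_b)
#'   and `count`
#' @export
mixing_counts <- function(g, attrs, label = "rsn_label") {
  attrs <- check_attrs(g, attrs, require = label)
  lab <- as.character(attrs[[label]])
  lev <- sort(unique(lab))
  cells <- mixing_cells(lev)
  counts <- setNames(rep(0L, nrow(cells)),
                     paste(cells$label_a, cells$label_b, sep = "\r"))
  ij <- which(upper.tri(g$adjacency) & g$adjacency == 1L, arr.ind = TRUE)
  if (nrow(ij) > 0) {
    a <- pmin(lab[ij[, 1]], lab[ij[, 2]])
    b <- pmax(lab[ij[, 1]], lab[ij[, 2]])
    tab <- table(paste(a, b, sep = "\r"))
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  cells$count <- as.integer(counts)
  cells
}

# all unordered label cells {a, b}, a <= b, in lexicographic order
mixing_cells <- function(levels) {
  levels <- sort(levels)
  L <- length(levels)
  out <- do.call(rbind, lapply(seq_len(L), function(i)
    data.frame(label_a = levels[i], label_b = levels[i:L],
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Compute the ERGM sufficient statistic vector g(y)
#'
#' Concatenates, per the model specification: the edge count; the
#' selective-mixing cell counts (reference cell dropped, see
#' [model_spec()]); for structural specifications, the nodal covariate sums
#' \eqn{\sum_{(u,v) \in E} (x_u + x_v)} for degree, local efficiency and
#' clustering, and the count of edges joining nodes in the same latent
#' cluster; and the fixed-decay GWESP statistic.
#'
#' This is the reference (vectorised R) implementation; the estimation
#' engine uses an independent incremental C++ path, and the two are checked
#' against each other in the test suite.
#'
#' @param g a [brain_graph()]
#' @param attrs node attribute table aligned with `g`
#' @param spec a [model_spec()]
#' @return named numeric vector (a `statistic_vector`)
#' @export
compute_statistics <- function(g, attrs, spec) {
  stopifnot(inherits(g, "brain_graph"), inherits(spec, "ergm_model_spec"))
  attrs <- check_attrs(g, attrs, require = required_columns(spec))
  a <- g$adjacency
  nm <- term_names(spec, attrs)
  out <- setNames(numeric(length(nm)), nm)
  out["edges"] <- sum(a) / 2
  lab <- as.character(attrs$rsn_label)
  mix <- mixing_counts(g, attrs)
  key <- paste0("mix.", mix$label_a, ".", mix$label_b)
  keep <- key %in% nm
  out[key[keep]] <- mix$count[keep]
  if (spec$structural) {
    deg <- rowSums(a)
    for (v in struct_covariate_names()) {
      x <- as.numeric(attrs[[v]])
      out[paste0("nodecov.", v)] <- sum(x * deg)
    }
    cl <- attrs$latent_cluster
    ij <- which(upper.tri(a) & a == 1L, arr.ind = TRUE)
    out["nodematch.latent"] <- sum(cl[ij[, 1]] == cl[ij[, 2]])
  }
  if (spec$gwesp) {
    esp <- esp_distribution(g)
    out[gwesp_term_name(spec)] <- gwesp_from_esp(esp, spec$gwesp_decay)
  }
  out
}

struct_covariate_names <- function()
  c("struct_degree", "struct_efficiency", "struct_clustering")

#' Node attribute table constructor
#'
#' Builds and validates the per-node attribute table used by the mixing,
#' structural-covariate and latent-cluster ERGM terms.
#'
#' @param node_id character node identifiers
#' @param rsn_label categorical resting-state-network / subcortical label
#' @param cortical_group `"cortical"` or `"subcortical"` per node
#' @param ... optional further per-node columns (`struct_degree`,
#'   `struct_efficiency`, `struct_clustering`, `latent_cluster`)
#' @return a data.frame of class `node_attributes`
#' @export
node_attributes <- function(node_id, rsn_label, cortical_group, ...) {
  out <- data.frame(node_id = as.character(node_id),
                    rsn_label = as.character(rsn_label),
                    cortical_group = as.character(cortical_group),
                    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  validate_attrs(out)
}

validate_attrs <- function(attrs) {
  need <- c("node_id", "rsn_label", "cortical_group")
  miss <- setdiff(need, names(attrs))
  if (length(miss) > 0)
    stop("attribute table missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(attrs$rsn_label) || anyNA(attrs$cortical_group))
    stop("every node needs an rsn_label and a cortical_group")
  bad <- setdiff(unique(attrs$cortical_group), c("cortical", "subcortical"))
  if (length(bad) > 0)
    stop("cortical_group must be 'cortical' or 'subcortical', got: ",
         paste(bad, collapse = ", "))
  class(attrs) <- unique(c("node_attributes", class(attrs)))
  attrs
}

check_attrs <- function(g, attrs, require = character()) {
  attrs <- validate_attrs(attrs)
  if (nrow(attrs) != g$n_nodes)
    stop(sprintf("attribute table has %d rows but graph has %d nodes",
                 nrow(attrs), g$n_nodes))
  miss <- setdiff(require, names(attrs))
  if (length(miss) > 0)
    stop("attribute table missing required column(s): ",
         paste(miss, collapse = ", "))
  for (v in intersect(require, names(attrs)))
    if (anyNA(attrs[[v]]))
      stop("attribute column '", v, "' has missing values")
  attrs
}
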