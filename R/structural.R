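#' Per-node structural connectivity metrics
#'
#' Derives the nodal covariates entering the structural ERGM terms from a
#' binarized structural connectivity graph:
#' \describe{
#'   \item{struct_degree}{neighbour count.}
#'   \item{struct_clustering}{Watts-Strogatz local clustering coefficient:
#'     the fraction of neighbour pairs that are themselves connected
#'     (0 when degree < 2).}
#'   \item{struct_efficiency}{local efficiency: the mean of inverse
#'     shortest-path lengths between neighbour pairs within the subgraph
#'     induced by the node's neighbours (unreachable pairs contribute 0;
#'     0 when degree < 2).}
#' }
#'
#' @param s a [brain_graph()] holding the structural adjacency
#' @return data.frame with columns `node_id`, `struct_degree`,
#'   `struct_clustering`, `struct_efficiency`
#' @export
structural_metrics <- function(s) {
  stopifnot(inherits(s, "brain_graph"))
  a <- s$adjacency
  n <- s$n_nodes
  deg <- rowSums(a)
  clus <- numeric(n)
  eff <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(a[v, ] == 1L)
    k <- length(nb)
    if (k < 2) next
    sub <- a[nb, nb, drop = FALSE]
    npairs <- k * (k - 1) / 2
    clus[v] <- sum(sub) / 2 / npairs
    gi <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
    d <- igraph::distances(gi)
    inv <- 1 / d[upper.tri(d)]
    inv[!is.finite(inv)] <- 0
    eff[v] <- mean(inv)
  }
  data.frame(node_id = s$node_ids, struct_degree = deg,
             struct_clustering = clus, struct_efficiency = eff,
             stringsAsFactors = FALSE)
}

#' Latent structural clusters
#'
#' Stand-in for a latent-space community assignment: nodes are embedded in
#' a 2-D space by classical multidimensional scaling of geodesic distances
#' (disconnected pairs placed at the maximum finite distance + 1), then
#' partitioned by k-means.  With `k = "auto"` the cluster count is chosen
#' by the mean silhouette width over k = 2..6.
#'
#' @param s a [brain_graph()] structural graph
#' @param k integer cluster count, or `"auto"`
#' @param seed integer seed controlling the k-means initialisation
#' @return integer vector of cluster ids (1-based), one per node
#' @export
latent_clusters <- function(s, k = "auto", seed = 1L) {
  stopifnot(inherits(s, "brain_graph"))
  n <- s$n_nodes
  gi <- igraph::graph_from_adjacency_matrix(s$adjacency, mode = "undirected")
  d <- igraph::distances(gi)
  if (any(!is.finite(d))) {
    dmax <- max(d[is.finite(d)])
    d[!is.finite(d)] <- dmax + 1
  }
  xy <- cmdscale(d, k = min(2L, n - 1L))
  if (ncol(xy) < 2) xy <- cbind(xy, 0)
  fit_k <- function(kk) {
    if (kk > n) stop(sprintf("k = %d exceeds node count %d", kk, n))
    if (kk == 1L) return(rep(1L, n))
    with_seed(seed, {
      km <- suppressWarnings(kmeans(xy, centers = kk, nstart = 20L,
                                    iter.max = 50L))
      km$cluster
    })
  }
  if (identical(k, "auto")) {
    ks <- 2:min(6L, n - 1L)
    sil <- vapply(ks, function(kk) {
      cl <- fit_k(kk)
      if (length(unique(cl)) < 2) return(-Inf)
      mean(cluster::silhouette(cl, dmatrix = d)[, "sil_width"])
    }, numeric(1))
    k <- ks[which.max(sil)]
  }
  if (!is.numeric(k) || length(k) != 1 || k < 1)
    stop("k must be a positive integer or 'auto'")
  as.integer(fit_k(as.integer(k)))
}

#' Standardize structural covariates
#'
#' z-scores the structural covariate columns in place.  Raw degree and the
#' unit-interval clustering/efficiency metrics differ by orders of
#' magnitude; standardizing puts their ERGM coefficients on a comparable
#' scale.  Constant columns are set to zero.
#'
#' @param attrs node attribute table containing the structural covariates
#' @return the table with `struct_degree`, `struct_clustering`,
#'   `struct_efficiency` z-scored
#' @export
scale_struct_covariates <- function(attrs) {
  for (v in struct_covariate_names()) {
    if (!v %in% names(attrs)) next
    x <- as.numeric(attrs[[v]])
    s <- sd(x)
    attrs[[v]] <- if (is.na(s) || s == 0) x * 0 else (x - mean(x)) / s
  }
  attrs
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
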