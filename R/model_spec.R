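#' ERGM model specifications
#'
#' The four nested specifications fit to every graph:
#' \describe{
#'   \item{base}{edges + selective mixing (`nodemix` over resting-state
#'     network and subcortical labels).}
#'   \item{structural}{base + nodal covariates from structural connectivity
#'     (degree, local efficiency, clustering coefficient) + `nodematch` on
#'     latent structural clusters.}
#'   \item{gwesp}{base + fixed-decay GWESP triadic-closure term.}
#'   \item{complete}{all of the above.}
#' }
#'
#' One mixing cell — the lexicographically first within-category cell — is
#' dropped as the reference to avoid exact collinearity between the edges
#' term and the full set of mixing cells (their sum is the edge count).
#'
#' @param name one of `"base"`, `"structural"`, `"gwesp"`, `"complete"`
#' @param gwesp_decay fixed GWESP decay \eqn{\lambda \ge 0} (default 0.5);
#'   ignored by specifications without the GWESP term
#' @return an object of class `ergm_model_spec`
#' @examples
#' model_spec("complete", gwesp_decay = 0.45)
#' @export
model_spec <- function(name = c("base", "structural", "gwesp", "complete"),
                       gwesp_decay = 0.5) {
  name <- match.arg(name)
  if (!is.numeric(gwesp_decay) || length(gwesp_decay) != 1 || gwesp_decay < 0)
    stop("gwesp_decay must be a single nonnegative number")
  structure(list(
    name = name,
    structural = name %in% c("structural", "complete"),
    gwesp = name %in% c("gwesp", "complete"),
    gwesp_decay = gwesp_decay
  ), class = "ergm_model_spec")
}

#' @export
print.ergm_model_spec <- function(x, ...) {
  cat(sprintf("ergm_model_spec '%s'%s\n", x$name,
              if (x$gwesp) sprintf(" (gwesp decay %g)", x$gwesp_decay) else ""))
  invisible(x)
}

#' Is a specification dyad-independent?
#'
#' The base and structural specifications contain only terms whose change
#' statistics do not depend on the rest of the graph, so their maximum
#' pseudo-likelihood fit is the exact maximum likelihood fit.
#'
#' @param spec a [model_spec()]
#' @return logical
#' @export
is_dyad_independent <- function(spec) !spec$gwesp

required_columns <- function(spec) {
  cols <- "rsn_label"
  if (spec$structural) cols <- c(cols, struct_covariate_names(), "latent_cluster")
  cols
}

gwesp_term_name <- function(spec)
  sprintf("gwesp.fixed.%g", spec$gwesp_decay)

#' Term names of a specification
#'
#' @param spec a [model_spec()]
#' @param attrs node attribute table (determines the mixing cells)
#' @return character vector of statistic/term names, in canonical order:
#'   edges, mixing cells (reference dropped), nodal covariates, nodematch,
#'   GWESP
#' @export
term_names <- function(spec, attrs) {
  lab <- as.character(attrs$rsn_label)
  lev <- sort(unique(lab))
  cells <- mixing_cells(lev)
  keep <- !(cells$label_a == cells$label_b &
              cells$label_a == reference_cell(lab))
  nm <- c("edges", paste0("mix.", cells$label_a, ".", cells$label_b)[keep])
  if (spec$structural)
    nm <- c(nm, paste0("nodecov.", struct_covariate_names()), "nodematch.latent")
  if (spec$gwesp) nm <- c(nm, gwesp_term_name(spec))
  nm
}

# Reference mixing cell: the within-category cell of the most frequent
# label (ties broken lexicographically).  Using the largest cell as the
# baseline keeps the variance of every mixing contrast small; a tiny
# reference cell (few dyads) would dominate the standard error of every
# other mixing coefficient.
reference_cell <- function(labels) {
  tab <- table(labels)
  names(tab)[order(-tab, names(tab))][1]
}

#' Mixing term names of a fitted/targeted specification
#'
#' @param attrs node attribute table
#' @return character vector of `mix.a.b` term names (reference cell dropped)
#' @export
mixing_term_names <- function(attrs) {
  nm <- term_names(model_spec("base"), attrs)
  nm[startsWith(nm, "mix.")]
}

# Internal: layout handed to the C++ core.  Maps each active term to its
# column in the statistic vector (0-based for C++).
stat_layout <- function(attrs, spec) {
  nm <- term_names(spec, attrs)
  lab <- as.character(attrs$rsn_label)
  lev <- sort(unique(lab))
  L <- length(lev)
  mix_col <- matrix(-1L, L, L)
  cells <- mixing_cells(lev)
  for (r in seq_len(nrow(cells))) {
    key <- paste0("mix.", cells$label_a[r], ".", cells$label_b[r])
    col <- match(key, nm)
    if (!is.na(col)) {
      ia <- match(cells$label_a[r], lev); ib <- match(cells$label_b[r], lev)
      mix_col[ia, ib] <- col - 1L
      mix_col[ib, ia] <- col - 1L
    }
  }
  if (spec$structural) {
    cov <- as.matrix(attrs[struct_covariate_names()])
    storage.mode(cov) <- "double"
    cov_col <- match(paste0("nodecov.", struct_covariate_names()), nm) - 1L
    match_id <- as.integer(factor(attrs$latent_cluster))
    match_col <- match("nodematch.latent", nm) - 1L
  } else {
    cov <- matrix(0, nrow(attrs), 0)
    cov_col <- integer(0)
    match_id <- integer(0)
    match_col <- -1L
  }
  list(labels = match(lab, lev) - 1L,
       mix_col = mix_col,
       cov = cov, cov_col = as.integer(cov_col),
       match_id = match_id, match_col = as.integer(match_col),
       decay = if (spec$gwesp) spec$gwesp_decay else -1,
       gwesp_col = if (spec$gwesp) match(gwesp_term_name(spec), nm) - 1L else -1L,
       n_terms = length(nm),
       term_names = nm)
}
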