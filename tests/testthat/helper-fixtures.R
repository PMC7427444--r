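# Shared fixtures and independent oracles.  All expected values asserted in
# the tests are either closed forms or come from the naive loop-based
# implementations below, which deliberately share no code with the package's
# vectorised R path or its incremental C++ path.

rand_graph <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1L, p)
  adj <- adj + t(adj)
  brain_graph(adj)
}

rand_attrs <- function(n, labels = c("A", "B", "C"), seed = 1,
                       with_struct = TRUE) {
  set.seed(seed)
  groups <- c(A = "cortical", B = "cortical", C = "subcortical",
              D = "subcortical")[labels]
  lab <- sample(labels, n, replace = TRUE)
  extra <- if (with_struct) list(
    struct_degree = rnorm(n),
    struct_efficiency = runif(n),
    struct_clustering = runif(n),
    latent_cluster = sample(1:3, n, replace = TRUE)) else list()
  do.call(node_attributes,
          c(list(node_id = paste0("n", seq_len(n)), rsn_label = lab,
                 cortical_group = unname(groups[lab])), extra))
}

# naive edge-loop recomputation of the sufficient statistics
naive_stats <- function(g, attrs, spec) {
  a <- g$adjacency
  n <- nrow(a)
  nm <- term_names(spec, attrs)
  out <- setNames(numeric(length(nm)), nm)
  lam <- spec$gwesp_decay
  for (i in seq_len(n - 1)) for (j in (i + 1):n) if (a[i, j] == 1) {
    out["edges"] <- out["edges"] + 1
    la <- min(attrs$rsn_label[i], attrs$rsn_label[j])
    lb <- max(attrs$rsn_label[i], attrs$rsn_label[j])
    key <- paste0("mix.", la, ".", lb)
    if (key %in% nm) out[key] <- out[key] + 1
    if (spec$structural) {
      for (v in c("struct_degree", "struct_efficiency", "struct_clustering"))
        out[paste0("nodecov.", v)] <-
          out[paste0("nodecov.", v)] + attrs[[v]][i] + attrs[[v]][j]
      if (attrs$latent_cluster[i] == attrs$latent_cluster[j])
        out["nodematch.latent"] <- out["nodematch.latent"] + 1
    }
    if (spec$gwesp) {
      sp <- sum(a[i, ] == 1 & a[j, ] == 1)
      gk <- sprintf("gwesp.fixed.%g", lam)
      out[gk] <- out[gk] + exp(lam) * (1 - (1 - exp(-lam))^sp)
    }
  }
  out
}

# brute-force change statistic: recompute on both toggle states
naive_change <- function(g, attrs, spec, i, j) {
  a1 <- g$adjacency; a1[i, j] <- a1[j, i] <- 1L
  a0 <- g$adjacency; a0[i, j] <- a0[j, i] <- 0L
  naive_stats(brain_graph(a1), attrs, spec) -
    naive_stats(brain_graph(a0), attrs, spec)
}

adjusted_rand_index <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  ea <- b * cc / choose(n, 2)
  (a - ea) / ((b + cc) / 2 - ea)
}

# small attribute tables used across engine tests
tiny_attrs_ab <- function(n, seed = 1) {
  set.seed(seed)
  node_attributes(paste0("n", seq_len(n)),
                  sample(c("A", "B"), n, replace = TRUE),
                  rep("cortical", n))
}

# a cheap cohort configuration for pipeline tests: 24 nodes, 3 labels
small_census <- function() {
  data.frame(label = c("default", "frontoparietal", "thalamus"),
             count = c(10L, 8L, 6L),
             group = c("cortical", "cortical", "subcortical"),
             stringsAsFactors = FALSE)
}

small_cohort_config <- function(n_subjects = 2L, scenario = "patients",
                                seed = 1L) {
  cohort_config(n_subjects = n_subjects, scenario = scenario,
                label_census = small_census(),
                structural_density = c(0.15, 0.30),
                functional_density = c(0.20, 0.40),
                seed = seed)
}
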