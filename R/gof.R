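#' Two-sided Monte Carlo p-value
#'
#' Add-one-corrected two-sided Monte Carlo p-value:
#' \deqn{p = \min\!\left(1,\; 2 \min\left(\frac{\#\{sim \ge obs\} + 1}{n+1},
#'   \frac{\#\{sim \le obs\} + 1}{n+1}\right)\right)}
#' With few simulations the attainable values are coarse (e.g. 0.2 steps at
#' n = 9), matching the granularity of tabulated simulation-based fit
#' checks.
#'
#' @param observed observed statistic
#' @param sims numeric vector of simulated statistics
#' @return p-value in `(0, 1]`
#' @export
mc_pvalue <- function(observed, sims) {
  if (length(sims) == 0) stop("sims must be nonempty")
  n <- length(sims)
  up <- (sum(sims >= observed) + 1) / (n + 1)
  lo <- (sum(sims <= observed) + 1) / (n + 1)
  min(1, 2 * min(up, lo))
}

#' Simulation-based goodness of fit
#'
#' Simulates `n_sims` graphs at the fitted parameters and compares every
#' model term statistic and every edgewise-shared-partner (ESP) bin of the
#' observed graph against the simulated distribution (min, mean, max, and a
#' two-sided Monte Carlo p-value).  A model that reproduces the observed
#' graph's generative structure should leave all observed statistics well
#' inside the simulated envelopes.
#'
#' @param fit a converged `ergm_fit`
#' @param g_observed the observed [brain_graph()]
#' @param attrs node attribute table aligned with `g_observed`
#' @param spec the [model_spec()] that produced `fit`
#' @param n_sims number of simulated graphs (default 1000)
#' @param seed integer seed
#' @param burnin,thin chain control passed to [sample_graphs()]
#' @return a `gof_report` data.frame with columns `statistic`, `observed`,
#'   `min`, `mean`, `max`, `p_value`, plus attributes `n_sims` and `seed`
#' @export
gof_report <- function(fit, g_observed, attrs, spec, n_sims = 1000L,
                       seed = 1L, burnin = NULL, thin = NULL) {
  stopifnot(inherits(fit, "ergm_fit"))
  if (!isTRUE(fit$converged))
    stop("refusing goodness-of-fit for a non-converged fit")
  attrs <- check_attrs(g_observed, attrs, require = required_columns(spec))
  sim <- suppressWarnings(
    sample_graphs(fit$theta, attrs, spec, n_samples = n_sims,
                  burnin = burnin, thin = thin, seed = seed,
                  init = g_observed, collect = c("stats", "esp")))
  obs_terms <- compute_statistics(g_observed, attrs, spec)
  esp_obs <- as.numeric(esp_distribution(g_observed))
  # trim trailing ESP bins empty in both observed and simulated graphs
  occupied <- which(esp_obs > 0 | colSums(sim$esp) > 0)
  n_bins <- if (length(occupied) == 0) 1L else max(occupied)
  rows <- rbind(
    data.frame(statistic = names(obs_terms), observed = unname(obs_terms),
               stringsAsFactors = FALSE),
    data.frame(statistic = paste0("esp", seq_len(n_bins) - 1L),
               observed = esp_obs[seq_len(n_bins)], stringsAsFactors = FALSE))
  sims_mat <- cbind(sim$stats, sim$esp[, seq_len(n_bins), drop = FALSE])
  report <- cbind(rows, t(vapply(seq_len(nrow(rows)), function(r) {
    s <- sims_mat[, r]
    c(min = min(s), mean = mean(s), max = max(s),
      p_value = mc_pvalue(rows$observed[r], s))
  }, numeric(4))))
  attr(report, "n_sims") <- as.integer(n_sims)
  attr(report, "seed") <- as.integer(seed)
  class(report) <- c("gof_report", class(report))
  report
}

#' Write a goodness-of-fit report as CSV
#' @param report a [gof_report()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gof_csv <- function(report, path) {
  write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
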