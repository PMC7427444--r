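#' Change statistics for one dyad
#'
#' Returns \eqn{g(y^+_{ij}) - g(y^-_{ij})}: the difference in the sufficient
#' statistic vector between the graph with edge (i, j) present and absent,
#' all other dyads held fixed.  Computed incrementally (the edges term
#' contributes 1, a mixing cell 1, a nodal covariate \eqn{x_i + x_j},
#' nodematch an indicator, and GWESP a local shared-partner update), which
#' is what makes pseudo-likelihood and Metropolis sampling tractable.
#'
#' @param g a [brain_graph()]
#' @param attrs node attribute table aligned with `g`
#' @param spec a [model_spec()]
#' @param i,j node indices (1-based), `i != j`
#' @return named numeric vector aligned to [term_names()]
#' @export
change_statistics <- function(g, attrs, spec, i, j) {
  stopifnot(inherits(g, "brain_graph"))
  if (i == j) stop("change statistic undefined for a self-loop dyad")
  attrs <- check_attrs(g, attrs, require = required_columns(spec))
  lay <- stat_layout(attrs, spec)
  out <- cpp_change_stats(g$adjacency, i - 1L, j - 1L, lay)
  setNames(out, lay$term_names)
}

#' Estimation control parameters
#'
#' Defaults follow the sampler conventions used throughout the package:
#' burn-in \eqn{10 n^2} proposals and thinning \eqn{n^2} proposals between
#' retained samples, scaling with the dyad count.
#'
#' @param n_samples simulated graphs per MCMC-MLE iteration
#' @param burnin proposals discarded before sampling (`NULL` = \eqn{10n^2})
#' @param thin proposals between retained samples (`NULL` = \eqn{n^2})
#' @param max_iter maximum Monte Carlo refinement iterations
#' @param tol convergence tolerance on the relative parameter change
#' @param step_max trust-region cap on each parameter update (importance
#'   weights degrade for large steps)
#' @return list of class `ergm_control`
#' @export
control_ergm <- function(n_samples = 400L, burnin = NULL, thin = NULL,
                         max_iter = 20L, tol = 1e-3, step_max = 0.5) {
  structure(list(n_samples = as.integer(n_samples), burnin = burnin,
                 thin = thin, max_iter = as.integer(max_iter), tol = tol,
                 step_max = step_max),
            class = "ergm_control")
}

resolve_chain <- function(control, n) {
  list(burnin = if (is.null(control$burnin)) 10 * n^2 else control$burnin,
       thin = if (is.null(control$thin)) n^2 else control$thin)
}

#' Maximum pseudo-likelihood fit
#'
#' Logistic regression of each dyad's observed state on its change
#' statistics evaluated at the observed graph.  For dyad-independent
#' specifications (base, structural) this is the exact maximum likelihood
#' estimate; with a GWESP term it is the classical MPLE approximation and
#' the usual initializer for [mcmcmle_fit()].
#'
#' @param g a [brain_graph()]
#' @param attrs node attribute table aligned with `g`
#' @param spec a [model_spec()]
#' @param alpha two-sided significance level for the Wald tests
#' @return an `ergm_fit` object: `theta`, `std_err`, `z`, `p_value`,
#'   `significant`, `method`, `converged`, plus bookkeeping fields
#' @export
mple_fit <- function(g, attrs, spec, alpha = 0.05) {
  stopifnot(inherits(g, "brain_graph"))
  attrs <- check_attrs(g, attrs, require = required_columns(spec))
  lay <- stat_layout(attrs, spec)
  d <- cpp_mple_matrix(g$adjacency, lay)
  X <- d$X
  colnames(X) <- lay$term_names
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    stop("degenerate fit: design matrix rank deficient; aliased term(s): ",
         paste(lay$term_names[drop], collapse = ", "))
  }
  fit <- suppressWarnings(glm.fit(X, d$y, family = binomial()))
  theta <- fit$coefficients
  w <- fit$weights
  info <- crossprod(X * sqrt(w))
  vc <- tryCatch(solve(info), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, length(theta)) else sqrt(diag(vc))
  # flag separated terms (huge estimate with exploding SE) instead of
  # aborting: downstream audits must keep running and treat them as
  # non-significant
  sep <- !is.finite(se) | se > 1e3 | abs(theta) > 15
  if (any(sep))
    warning("possible separation in term(s): ",
            paste(lay$term_names[sep], collapse = ", "))
  new_ergm_fit(theta = theta, se = se, alpha = alpha, method = "MPLE",
               converged = fit$converged, spec = spec,
               term_names = lay$term_names, seed = NA_integer_,
               flagged = lay$term_names[sep])
}

new_ergm_fit <- function(theta, se, alpha, method, converged, spec,
                         term_names, seed, flagged = character(),
                         note = NULL) {
  z <- theta / se
  p <- 2 * pnorm(-abs(z))
  sig <- !is.na(p) & p < alpha
  if (length(flagged) > 0) sig[term_names %in% flagged] <- FALSE
  structure(list(
    theta = setNames(theta, term_names),
    std_err = setNames(se, term_names),
    z = setNames(z, term_names),
    p_value = setNames(p, term_names),
    significant = setNames(sig, term_names),
    alpha = alpha, method = method, converged = converged,
    spec = spec, seed = seed, flagged = flagged, note = note
  ), class = "ergm_fit")
}

#' @export
print.ergm_fit <- function(x, ...) {
  cat(sprintf("ergm_fit (%s, spec '%s', %sconverged)\n", x$method,
              x$spec$name, if (x$converged) "" else "NOT "))
  tab <- data.frame(estimate = round(x$theta, 4),
                    std_err = round(x$std_err, 4),
                    p_value = signif(x$p_value, 3),
                    sig = ifelse(x$significant, "*", ""))
  print(utils::head(tab, 12))
  if (length(x$theta) > 12) cat("... (", length(x$theta), "terms )\n")
  invisible(x)
}

#' @export
as.data.frame.ergm_fit <- function(x, ...) {
  data.frame(term = names(x$theta), estimate = unname(x$theta),
             std_err = unname(x$std_err), z = unname(x$z),
             p_value = unname(x$p_value),
             significant = unname(x$significant),
             stringsAsFactors = FALSE)
}

#' Simulate graphs from an ERGM by Metropolis edge toggles
#'
#' Metropolis-Hastings over uniformly proposed dyad toggles with acceptance
#' probability \eqn{\min(1, \exp(\pm\theta^T \Delta))}.  Reproducible under
#' `seed`; a sustained sampled density below 0.01 or above 0.99 triggers a
#' near-degeneracy warning.
#'
#' @param theta named parameter vector aligned to [term_names()]
#' @param attrs node attribute table (determines n and the term layout)
#' @param spec a [model_spec()]
#' @param n_samples number of graphs to retain
#' @param burnin,thin chain control (`NULL` = the \eqn{10n^2}/\eqn{n^2}
#'   defaults)
#' @param seed integer seed
#' @param init optional [brain_graph()] start state (default empty graph)
#' @param collect what to record per retained sample: `"stats"` always;
#'   add `"esp"` for ESP histograms, `"graphs"` for adjacency matrices,
#'   `"codes"` for dyad-bitmask graph codes (small n only)
#' @return list with `stats` (n_samples x n_terms matrix), optionally
#'   `esp`, `graphs` (list of [brain_graph()]), `codes`, plus `final`
#'   graph, `accept_rate` and `mean_density`
#' @export
sample_graphs <- function(theta, attrs, spec, n_samples = 100L,
                          burnin = NULL, thin = NULL, seed = 1L,
                          init = NULL, collect = "stats") {
  attrs <- validate_attrs(attrs)
  n <- nrow(attrs)
  lay <- stat_layout(attrs, spec)
  theta <- align_theta(theta, lay$term_names)
  if (is.null(burnin)) burnin <- 10 * n^2
  if (is.null(thin)) thin <- n^2
  if (is.null(init)) {
    adj <- matrix(0L, n, n)
  } else {
    stopifnot(inherits(init, "brain_graph"), init$n_nodes == n)
    adj <- init$adjacency
  }
  res <- cpp_sample(adj, lay, theta, burnin, thin, as.integer(n_samples),
                    as.integer(seed),
                    "esp" %in% collect, "codes" %in% collect,
                    "graphs" %in% collect)
  colnames(res$stats) <- lay$term_names
  out <- list(stats = res$stats,
              final = brain_graph(res$final_adj, node_ids = attrs$node_id),
              accept_rate = res$accept_rate,
              mean_density = res$mean_density)
  if (!is.null(res$esp)) {
    colnames(res$esp) <- paste0("esp", seq_len(ncol(res$esp)) - 1L)
    out$esp <- res$esp
  }
  if (!is.null(res$codes)) out$codes <- res$codes
  if (!is.null(res$graphs))
    out$graphs <- lapply(res$graphs, brain_graph, node_ids = attrs$node_id)
  if (out$mean_density < 0.01 || out$mean_density > 0.99)
    warning(sprintf("near-degenerate chain: mean sampled density %.4f",
                    out$mean_density))
  out
}

align_theta <- function(theta, term_names) {
  if (!is.null(names(theta))) {
    miss <- setdiff(term_names, names(theta))
    if (length(miss) > 0)
      stop("theta missing term(s): ", paste(miss, collapse = ", "))
    theta <- theta[term_names]
  } else if (length(theta) != length(term_names)) {
    stop(sprintf("theta has length %d but the specification has %d terms",
                 length(theta), length(term_names)))
  }
  unname(as.numeric(theta))
}

#' Monte Carlo maximum likelihood fit
#'
#' Importance-sampling refinement of the pseudo-likelihood estimate in the
#' Geyer-Thompson style: graphs are simulated at the current \eqn{\theta},
#' the sampled log-likelihood-ratio approximation
#' \eqn{(\theta'-\theta)^T g(y_{obs}) - \log \frac{1}{M}\sum_m
#' e^{(\theta'-\theta)^T g(y_m)}} is maximised by damped Newton steps, and
#' the cycle repeats until the parameter change falls below `tol`.  Wald
#' standard errors come from the inverse estimated Fisher information (the
#' weighted covariance of the simulated statistics).  Dyad-independent
#' specifications short-circuit to [mple_fit()], which is their exact MLE.
#'
#' @inheritParams mple_fit
#' @param seed integer seed governing all simulation
#' @param control an [control_ergm()] list
#' @return an `ergm_fit`; on non-convergence or degeneracy `converged` is
#'   `FALSE` and the inference columns are `NA`
#' @export
mcmcmle_fit <- function(g, attrs, spec, alpha = 0.05, seed = 1L,
                        control = control_ergm()) {
  stopifnot(inherits(g, "brain_graph"))
  attrs <- check_attrs(g, attrs, require = required_columns(spec))
  if (is_dyad_independent(spec)) {
    fit <- mple_fit(g, attrs, spec, alpha = alpha)
    fit$note <- "dyad-independent specification: MPLE is the exact MLE"
    fit$seed <- as.integer(seed)
    return(fit)
  }
  lay <- stat_layout(attrs, spec)
  g_obs <- cpp_full_stats(g$adjacency, lay)
  init <- mple_fit(g, attrs, spec, alpha = alpha)
  theta <- unname(init$theta)
  n <- g$n_nodes
  ch <- resolve_chain(control, n)
  converged <- FALSE
  degenerate <- FALSE
  sim <- NULL
  for (it in seq_len(control$max_iter)) {
    sim <- suppressWarnings(
      sample_graphs(theta, attrs, spec, n_samples = control$n_samples,
                    burnin = ch$burnin, thin = ch$thin,
                    seed = as.integer(seed + it), init = g))
    if (sim$mean_density < 0.005 || sim$mean_density > 0.995) {
      degenerate <- TRUE
      break
    }
    upd <- mcmcmle_step(theta, g_obs, sim$stats, control$step_max)
    theta <- theta + upd$step
    # stop when the relative change is below tol, or (after a couple of
    # refinements) the step is indistinguishable from Monte Carlo noise
    small <- max(abs(upd$step) / pmax(abs(theta), 1)) < control$tol
    noise <- it >= 3 && is.finite(upd$noise_stat) &&
      upd$noise_stat < qchisq(0.9, length(theta))
    if (small || noise) {
      converged <- TRUE
      break
    }
  }
  if (degenerate || !converged) {
    return(new_ergm_fit(theta = theta, se = rep(NA_real_, length(theta)),
                        alpha = alpha, method = "MCMC-MLE", converged = FALSE,
                        spec = spec, term_names = lay$term_names,
                        seed = as.integer(seed),
                        note = if (degenerate) "near-degenerate chain"
                               else "maximum iterations reached"))
  }
  # Fisher information estimated from a fresh simulation at the final theta
  sim <- suppressWarnings(
    sample_graphs(theta, attrs, spec, n_samples = control$n_samples,
                  burnin = ch$burnin, thin = ch$thin,
                  seed = as.integer(seed), init = g))
  info <- cov(sim$stats)
  vc <- tryCatch(solve(info), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, length(theta))
        else sqrt(pmax(diag(vc), 0))
  new_ergm_fit(theta = theta, se = se, alpha = alpha, method = "MCMC-MLE",
               converged = TRUE, spec = spec, term_names = lay$term_names,
               seed = as.integer(seed))
}

# one damped Newton step on the importance-sampled log-likelihood ratio
mcmcmle_step <- function(theta, g_obs, S, step_max) {
  obj <- function(d) {
    eta <- S %*% d
    m <- max(eta)
    as.numeric(crossprod(d, g_obs) - (m + log(mean(exp(eta - m)))))
  }
  grad_hess <- function(d) {
    eta <- as.numeric(S %*% d)
    w <- exp(eta - max(eta)); w <- w / sum(w)
    mu <- colSums(S * w)
    Sc <- sweep(S, 2, mu)
    H <- crossprod(Sc * sqrt(w))
    list(grad = g_obs - mu, hess = H)
  }
  d <- numeric(length(theta))
  for (k in 1:25) {
    gh <- grad_hess(d)
    step <- tryCatch(solve(gh$hess + diag(1e-8, ncol(S)), gh$grad),
                     error = function(e) gh$grad * 1e-3)
    # backtracking line search
    f0 <- obj(d)
    lam <- 1
    repeat {
      dn <- d + lam * step
      if (max(abs(dn)) <= step_max && obj(dn) >= f0 - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-6) { dn <- d; break }
    }
    if (max(abs(dn - d)) < 1e-10) { d <- dn; break }
    d <- dn
  }
  # Monte Carlo standard error of the step: cov of the importance-sampled
  # optimum is approximately H^{-1} / ESS, where ESS accounts for both the
  # importance weights and the chain autocorrelation of the statistics
  gh <- grad_hess(d)
  eta <- as.numeric(S %*% d)
  w <- exp(eta - max(eta)); w <- w / sum(w)
  ess_w <- 1 / sum(w^2)
  M <- nrow(S)
  rho <- vapply(seq_len(ncol(S)), function(k) {
    x <- S[, k]
    if (sd(x) == 0) return(0)
    r <- cor(x[-1], x[-M])
    if (!is.finite(r)) 0 else max(0, r)
  }, numeric(1))
  ess_ac <- M * min((1 - rho) / (1 + rho))
  ess <- max(1, min(ess_w, ess_ac))
  vc <- tryCatch(solve(gh$hess + diag(1e-8, ncol(S))),
                 error = function(e) diag(NA_real_, ncol(S)))
  # Hotelling-style statistic: is the step consistent with pure MC noise?
  noise_stat <- tryCatch(ess * sum(d * (gh$hess %*% d)),
                         error = function(e) Inf)
  list(step = d, step_se = sqrt(pmax(diag(vc), 0) / ess),
       noise_stat = noise_stat)
}

#' Select a GWESP decay by profile pseudo-likelihood
#'
#' The published fits use fixed per-subject decays without a stated
#' selection rule.  This helper profiles the maximum pseudo-likelihood
#' over a decay grid and returns the maximizer; the default grid is
#' 0.1, 0.2, ..., 1.0.
#'
#' @param g a [brain_graph()]
#' @param attrs node attribute table aligned with `g`
#' @param spec_name `"gwesp"` or `"complete"`
#' @param grid candidate decay values
#' @param alpha significance level passed to the fits
#' @return list with `decay` (selected value) and `logpl` (profile
#'   pseudo-log-likelihood per grid point)
#' @export
select_gwesp_decay <- function(g, attrs, spec_name = "gwesp",
                               grid = seq(0.1, 1, by = 0.1), alpha = 0.05) {
  stopifnot(spec_name %in% c("gwesp", "complete"))
  logpl <- vapply(grid, function(lam) {
    spec <- model_spec(spec_name, lam)
    lay <- stat_layout(check_attrs(g, attrs,
                                   require = required_columns(spec)), spec)
    d <- cpp_mple_matrix(g$adjacency, lay)
    fit <- suppressWarnings(glm.fit(d$X, d$y, family = binomial()))
    p <- pmin(pmax(fit$fitted.values, 1e-12), 1 - 1e-12)
    sum(d$y * log(p) + (1 - d$y) * log(1 - p))
  }, numeric(1))
  list(decay = grid[which.max(logpl)],
       logpl = setNames(logpl, as.character(grid)))
}

#' Exact ERGM distribution by enumeration
#'
#' Enumerates all \eqn{2^{\binom{n}{2}}} graphs on up to 5 nodes, computes
#' their sufficient statistics with [compute_statistics()] and returns the
#' exact probabilities \eqn{\exp(\theta^T g(y)) / c(\theta)}.  Serves as the
#' ground-truth oracle against which the Metropolis sampler and the change
#' statistics are tested.
#'
#' @inheritParams sample_graphs
#' @return list with `codes` (dyad-bitmask graph ids), `stats` (graph x
#'   term matrix), `prob`, `log_normalizer` and `expected` statistics
#' @export
enumerate_exact <- function(theta, attrs, spec) {
  attrs <- validate_attrs(attrs)
  n <- nrow(attrs)
  if (n > 5) stop("exact enumeration limited to n <= 5 nodes")
  nd <- n * (n - 1) / 2
  lay <- stat_layout(attrs, spec)
  theta <- align_theta(theta, lay$term_names)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  ngraph <- 2^nd
  stats <- matrix(0, ngraph, lay$n_terms)
  for (code in seq_len(ngraph) - 1) {
    adj <- matrix(0L, n, n)
    bits <- bitwAnd(bitwShiftR(code, seq_len(nd) - 1L), 1L)
    on <- which(bits == 1L)
    if (length(on) > 0) {
      adj[pairs[on, , drop = FALSE]] <- 1L
      adj[pairs[on, c(2, 1), drop = FALSE]] <- 1L
    }
    g <- brain_graph(adj, node_ids = attrs$node_id)
    stats[code + 1, ] <- compute_statistics(g, attrs, spec)
  }
  colnames(stats) <- lay$term_names
  eta <- as.numeric(stats %*% theta)
  m <- max(eta)
  logc <- m + log(sum(exp(eta - m)))
  prob <- exp(eta - logc)
  list(codes = seq_len(ngraph) - 1, stats = stats, prob = prob,
       log_normalizer = logc,
       expected = setNames(as.numeric(crossprod(stats, prob)),
                           lay$term_names))
}
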