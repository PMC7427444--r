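#' Multinomial logistic regression of error category on group
#'
#' Fits a baseline-category multinomial logit by Newton-Raphson on the full
#' likelihood.  Each non-reference outcome category \eqn{j} gets its own
#' coefficient vector \eqn{b_j} over an intercept plus dummy-coded group
#' effects; \eqn{P(y = j \mid x) = e^{x^T b_j} / \sum_k e^{x^T b_k}} with
#' \eqn{b_{ref} = 0}.  Coefficients are reported as odds ratios
#' (\eqn{e^{b}}) with Wald standard errors (on the log-odds scale) from the
#' inverse observed information, significance stars at 0.05 / 0.01 / 0.001,
#' and AIC \eqn{= 2k - 2\ell}.
#'
#' @param observations data.frame with columns `outcome` (category) and
#'   `group` (predictor), one row per audited term, or the output of
#'   [tally_errors()] (with a `count` column)
#' @param reference_outcome baseline outcome category (default `"none"`)
#' @param reference_group baseline predictor level
#' @param tol convergence tolerance on the gradient max-norm
#' @param max_iter Newton iteration cap
#' @return object of class `rate_model`: `coef` and `std_err` matrices
#'   (outcome x predictor), `odds_ratio`, `z`, `p_value`, `stars`,
#'   `log_likelihood`, `aic`, `n_observations`, `flagged` (separated
#'   coefficients)
#' @export
fit_multinomial <- function(observations, reference_outcome = "none",
                            reference_group = NULL, tol = 1e-8,
                            max_iter = 100L) {
  if ("count" %in% names(observations)) {
    counts <- observations
  } else {
    counts <- as.data.frame(table(outcome = observations$outcome,
                                  group = observations$group),
                            stringsAsFactors = FALSE)
    names(counts)[names(counts) == "Freq"] <- "count"
  }
  counts$outcome <- as.character(counts$outcome)
  counts$group <- as.character(counts$group)
  out_lev <- sort(unique(counts$outcome))
  grp_lev <- sort(unique(counts$group))
  if (!reference_outcome %in% out_lev)
    stop("reference outcome '", reference_outcome, "' not observed")
  if (is.null(reference_group)) reference_group <- grp_lev[1]
  if (!reference_group %in% grp_lev)
    stop("reference group '", reference_group, "' not observed")
  if (length(out_lev) < 2) stop("need at least 2 outcome categories")
  out_lev <- c(reference_outcome, setdiff(out_lev, reference_outcome))
  grp_lev <- c(reference_group, setdiff(grp_lev, reference_group))

  # aggregate to the (group x outcome) contingency table
  tab <- matrix(0, length(grp_lev), length(out_lev),
                dimnames = list(grp_lev, out_lev))
  for (r in seq_len(nrow(counts)))
    tab[counts$group[r], counts$outcome[r]] <-
      tab[counts$group[r], counts$outcome[r]] + counts$count[r]

  G <- length(grp_lev)
  X <- cbind(1, diag(G)[, -1, drop = FALSE])  # intercept + group dummies
  colnames(X) <- c("(Intercept)", grp_lev[-1])
  J <- length(out_lev)
  K <- ncol(X)
  npar <- (J - 1) * K
  B <- matrix(0, J - 1, K)  # row j-1: coefficients of category out_lev[j]

  probs <- function(B) {
    eta <- cbind(0, X %*% t(B))
    eta <- eta - apply(eta, 1, max)
    p <- exp(eta)
    p / rowSums(p)
  }
  loglik <- function(B) sum(tab * log(pmax(probs(B), 1e-300)))

  ll_old <- loglik(B)
  rowN <- rowSums(tab)
  for (it in seq_len(max_iter)) {
    P <- probs(B)
    grad <- numeric(npar)
    H <- matrix(0, npar, npar)
    for (j in 2:J) {
      idx <- (j - 2) * K + seq_len(K)
      grad[idx] <- colSums((tab[, j] - rowN * P[, j]) * X)
      for (l in 2:J) {
        idxl <- (l - 2) * K + seq_len(K)
        w <- rowN * (P[, j] * ((j == l) - P[, l]))
        H[idx, idxl] <- crossprod(X, X * w)
      }
    }
    if (max(abs(grad)) < tol) break
    step <- tryCatch(solve(H + diag(1e-10, npar), grad),
                     error = function(e) grad / max(1, max(abs(grad))))
    lam <- 1
    repeat {
      Bn <- B + lam * matrix(step, J - 1, K, byrow = TRUE)
      lln <- loglik(Bn)
      if (lln >= ll_old - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    B <- Bn
    ll_old <- lln
  }
  P <- probs(B)
  # observed information at the optimum
  H <- matrix(0, npar, npar)
  for (j in 2:J) {
    idx <- (j - 2) * K + seq_len(K)
    for (l in 2:J) {
      idxl <- (l - 2) * K + seq_len(K)
      w <- rowN * (P[, j] * ((j == l) - P[, l]))
      H[idx, idxl] <- crossprod(X, X * w)
    }
  }
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, npar, npar))
  se <- matrix(sqrt(pmax(diag(vc), 0)), J - 1, K, byrow = TRUE)
  dimnames(B) <- dimnames(se) <- list(out_lev[-1], colnames(X))
  flagged <- abs(B) > 20 | !is.finite(se) | se > 100
  if (any(flagged))
    warning("infinite/unstable estimate (empty cell separation) in: ",
            paste(paste(rownames(B)[row(B)[flagged]],
                        colnames(B)[col(B)[flagged]], sep = ":"),
                  collapse = ", "))
  z <- B / se
  p <- 2 * pnorm(-abs(z))
  stars <- matrix(cut(p, c(-Inf, 0.001, 0.01, 0.05, Inf),
                      labels = c("***", "**", "*", "")),
                  J - 1, K, dimnames = dimnames(B))
  ll <- loglik(B)
  structure(list(
    coef = B, std_err = se, odds_ratio = exp(B), z = z, p_value = p,
    stars = stars, log_likelihood = ll, aic = 2 * npar - 2 * ll,
    n_observations = sum(tab), table = tab,
    outcome_levels = out_lev, group_levels = grp_lev,
    flagged = flagged
  ), class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("rate_model: %d observations, logLik %.3f, AIC %.3f\n",
              x$n_observations, x$log_likelihood, x$aic))
  or <- format(round(x$odds_ratio, 4))
  se <- format(round(x$std_err, 3))
  for (j in seq_len(nrow(or))) {
    cat(rownames(or)[j], ":\n", sep = "")
    for (k in seq_len(ncol(or)))
      cat(sprintf("  %-14s OR %s%s (SE %s)\n", colnames(or)[k], or[j, k],
                  x$stars[j, k], se[j, k]))
  }
  invisible(x)
}

#' @export
as.data.frame.rate_model <- function(x, ...) {
  do.call(rbind, lapply(seq_len(nrow(x$coef)), function(j)
    data.frame(outcome = rownames(x$coef)[j],
               predictor = colnames(x$coef),
               odds_ratio = x$odds_ratio[j, ],
               std_err = x$std_err[j, ],
               coef = x$coef[j, ],
               p_value = x$p_value[j, ],
               stars = as.character(x$stars[j, ]),
               stringsAsFactors = FALSE, row.names = NULL)))
}
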