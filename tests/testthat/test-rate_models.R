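test_that("intercept-only closed form", {
  obs <- data.frame(outcome = c(rep("none", 90), rep("FP", 10)),
                    group = "g0")
  m <- fit_multinomial(obs)
  expect_equal(unname(m$coef["FP", "(Intercept)"]), log(10 / 90),
               tolerance = 1e-8)
  expect_equal(unname(m$odds_ratio["FP", "(Intercept)"]), 1 / 9,
               tolerance = 1e-8)
})

test_that("saturated two-group odds ratio is the cross-product ratio", {
  obs <- rbind(
    data.frame(outcome = c(rep("none", 40), rep("FP", 20)), group = "g0"),
    data.frame(outcome = c(rep("none", 60), rep("FP", 10)), group = "g1"))
  m <- fit_multinomial(obs, reference_group = "g0")
  expect_equal(unname(m$odds_ratio["FP", "g1"]), (10 / 60) / (20 / 40),
               tolerance = 1e-6)
})

test_that("saturated fits reproduce observed cell frequencies", {
  counts <- expand.grid(outcome = c("none", "FP", "FN"),
                        group = c("a", "b", "c"),
                        stringsAsFactors = FALSE)
  set.seed(90)
  counts$count <- sample(5:80, nrow(counts))
  m <- fit_multinomial(counts, reference_group = "a")
  # reconstruct fitted probabilities from the coefficients
  for (g in c("a", "b", "c")) {
    eta <- c(none = 0,
             sapply(rownames(m$coef), function(j)
               m$coef[j, "(Intercept)"] +
                 if (g == "a") 0 else m$coef[j, g]))
    p <- exp(eta) / sum(exp(eta))
    nobs <- counts$count[counts$group == g]
    names(nobs) <- counts$outcome[counts$group == g]
    expect_equal(p[names(nobs)], nobs / sum(nobs), tolerance = 1e-6)
  }
})

test_that("matches a generic-optimizer oracle on a 3-outcome design", {
  counts <- expand.grid(outcome = c("none", "FP", "FN"),
                        group = c("g0", "g1"),
                        stringsAsFactors = FALSE)
  set.seed(91)
  counts$count <- sample(10:100, nrow(counts))
  m <- fit_multinomial(counts, reference_group = "g0")

  # independent oracle: direct optimisation of the multinomial likelihood
  out_lev <- c("none", "FP", "FN")
  grp_lev <- c("g0", "g1")
  tab <- matrix(0, 2, 3, dimnames = list(grp_lev, out_lev))
  for (r in seq_len(nrow(counts)))
    tab[counts$group[r], counts$outcome[r]] <- counts$count[r]
  nll <- function(par) {
    B <- matrix(par, 2, 2)  # rows FP, FN; cols intercept, g1
    ll <- 0
    for (g in 1:2) {
      eta <- c(0, B[, 1] + (g - 1) * B[, 2])
      p <- exp(eta) / sum(exp(eta))
      ll <- ll + sum(tab[g, ] * log(p))
    }
    -ll
  }
  o <- optim(rep(0, 4), nll, method = "BFGS",
             control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(-o$value, m$log_likelihood, tolerance = 1e-4)
  oracle_B <- matrix(o$par, 2, 2)
  expect_equal(unname(m$coef[c("FP", "FN"), "(Intercept)"]), oracle_B[, 1],
               tolerance = 1e-4)
  expect_equal(unname(m$coef[c("FP", "FN"), "g1"]), oracle_B[, 2],
               tolerance = 1e-4)
  expect_equal(m$aic, 2 * 4 - 2 * m$log_likelihood)
})

test_that("category order does not change odds ratios", {
  counts <- expand.grid(outcome = c("none", "FP", "FN"),
                        group = c("g0", "g1"), stringsAsFactors = FALSE)
  set.seed(92)
  counts$count <- sample(10:60, nrow(counts))
  m1 <- fit_multinomial(counts, reference_group = "g0")
  m2 <- fit_multinomial(counts[sample(nrow(counts)), ],
                        reference_group = "g0")
  expect_equal(m1$odds_ratio[rownames(m2$odds_ratio), ],
               m2$odds_ratio, tolerance = 1e-8)
})

test_that("empty cells are flagged as separation", {
  counts <- data.frame(outcome = c("none", "FP", "none", "FP"),
                       group = c("g0", "g0", "g1", "g1"),
                       count = c(50, 10, 50, 0))
  expect_warning(m <- fit_multinomial(counts, reference_group = "g0"),
                 "separation|infinite")
  expect_true(any(m$flagged))
})

test_that("input validation", {
  expect_error(fit_multinomial(data.frame(outcome = "none", group = "g0",
                                          count = 5)),
               "at least 2")
  expect_error(fit_multinomial(data.frame(outcome = c("a", "b"),
                                          group = "g0", count = c(1, 2)),
                               reference_outcome = "none"),
               "not observed")
})
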