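test_that("change statistics match the brute-force toggle difference", {
  specs <- list(model_spec("base"), model_spec("structural"),
                model_spec("gwesp", 0.5), model_spec("complete", 0.45))
  for (s in 1:5) {
    n <- sample(6:10, 1)
    g <- rand_graph(n, runif(1, 0.2, 0.6), seed = 500 + s)
    attrs <- rand_attrs(n, seed = 500 + s)
    for (spec in specs) {
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        expect_equal(change_statistics(g, attrs, spec, i, j),
                     naive_change(g, attrs, spec, i, j),
                     tolerance = 1e-9)
      }
    }
  }
  g <- rand_graph(6, 0.5, seed = 1)
  expect_error(change_statistics(g, rand_attrs(6), model_spec("base"), 2, 2),
               "self-loop")
})

test_that("mple recovers closed-form logits for dyad-independent models", {
  # one label -> the reference cell is dropped -> pure edges model
  n <- 20
  attrs <- node_attributes(paste0("n", seq_len(n)), rep("A", n),
                           rep("cortical", n))
  g <- rand_graph(n, 0.3, seed = 21)
  d <- graph_density(g)
  f <- mple_fit(g, attrs, model_spec("base"))
  expect_equal(unname(f$theta[["edges"]]), qlogis(d), tolerance = 1e-8)

  # two labels: each mixing coefficient is that cell's logit minus the
  # reference cell's logit (reference = largest cell, here A.A)
  attrs2 <- node_attributes(paste0("n", 1:30),
                            rep(c("A", "B"), c(16, 14)),
                            rep("cortical", 30))
  g2 <- rand_graph(30, 0.35, seed = 22)
  f2 <- mple_fit(g2, attrs2, model_spec("base"))
  lab <- attrs2$rsn_label
  cell_dens <- function(la, lb) {
    sel <- outer(lab, lab, function(x, y)
      (pmin(x, y) == la) & (pmax(x, y) == lb))
    ut <- upper.tri(sel)
    sum(g2$adjacency[ut & sel]) / sum(sel[ut])
  }
  ref <- qlogis(cell_dens("A", "A"))
  expect_equal(unname(f2$theta[["edges"]]), ref, tolerance = 1e-7)
  expect_equal(unname(f2$theta[["mix.A.B"]]),
               qlogis(cell_dens("A", "B")) - ref, tolerance = 1e-7)
  expect_equal(unname(f2$theta[["mix.B.B"]]),
               qlogis(cell_dens("B", "B")) - ref, tolerance = 1e-7)
})

test_that("mple recovers known parameters of dyad-independent graphs", {
  # simulated at known theta; mean estimate within 2 MC standard errors
  n <- 100
  attrs <- tiny_attrs_ab(n, seed = 30)
  spec <- model_spec("base")
  truth <- c(edges = -1.2, mix.A.B = 0.5, mix.B.B = -0.4)
  ests <- matrix(NA_real_, 20, 3)
  for (r in 1:20) {
    sim <- sample_graphs(truth, attrs, spec, n_samples = 1,
                         burnin = 8 * n^2, thin = 1, seed = 600 + r)
    ests[r, ] <- mple_fit(sim$final, attrs, spec)$theta
  }
  bias <- colMeans(ests) - truth
  mcse <- apply(ests, 2, sd) / sqrt(20)
  expect_true(all(abs(bias) < 2.5 * mcse + 1e-3))
})

test_that("enumerate_exact: uniform case, expected edges, gwesp ratio", {
  attrs <- node_attributes(paste0("n", 1:3), rep("A", 3), rep("cortical", 3))
  ex0 <- enumerate_exact(c(edges = 0), attrs, model_spec("base"))
  expect_equal(ex0$prob, rep(1 / 8, 8))
  expect_equal(sum(ex0$prob), 1, tolerance = 1e-12)

  th <- 0.7
  ex <- enumerate_exact(c(edges = th), attrs, model_spec("base"))
  expect_equal(unname(ex$expected[["edges"]]), 3 * plogis(th),
               tolerance = 1e-10)

  # gwesp term: probability ratio of two equal-edge graphs is
  # exp(theta_gwesp * delta_gwesp)
  attrs4 <- node_attributes(paste0("n", 1:4), rep("A", 4), rep("cortical", 4))
  spec <- model_spec("gwesp", 0.5)
  thg <- c(0.3, 0.8)
  ex4 <- enumerate_exact(setNames(thg, c("edges", "gwesp.fixed.0.5")),
                         attrs4, spec)
  same_edges <- which(ex4$stats[, "edges"] == 3)
  gvals <- ex4$stats[same_edges, "gwesp.fixed.0.5"]
  tri <- same_edges[which.max(gvals)]   # a triangle (gwesp > 0)
  open <- same_edges[which.min(gvals)]  # a 3-edge path/star (gwesp = 0)
  expect_equal(ex4$prob[tri] / ex4$prob[open],
               exp(thg[2] * (max(gvals) - min(gvals))), tolerance = 1e-10)

  expect_error(enumerate_exact(c(edges = 0), rand_attrs(6), model_spec("base")),
               "n <= 5")
})

test_that("sampler hits uniform and degenerate limits", {
  attrs <- node_attributes(paste0("n", 1:4), rep("A", 4), rep("cortical", 4))
  spec <- model_spec("base")
  sim <- sample_graphs(c(edges = 0), attrs, spec, n_samples = 20000,
                       burnin = 500, thin = 3, seed = 31)
  expect_equal(mean(sim$stats[, "edges"]), 3, tolerance = 0.05)
  expect_warning(
    simlo <- sample_graphs(c(edges = -10), attrs, spec, n_samples = 200,
                           burnin = 500, thin = 3, seed = 32),
    "near-degenerate")
  expect_lt(simlo$mean_density, 0.01)
})

test_that("sampler matches exact enumeration in total variation", {
  attrs <- node_attributes(paste0("n", 1:4), c("A", "A", "B", "B"),
                           rep("cortical", 4))
  spec <- model_spec("gwesp", 0.5)
  th <- c(edges = -0.4, mix.A.B = 0.3, mix.B.B = 0.2)
  th[["gwesp.fixed.0.5"]] <- 0.5
  ex <- enumerate_exact(th, attrs, spec)
  sim <- sample_graphs(th, attrs, spec, n_samples = 120000, burnin = 2000,
                       thin = 4, seed = 33, collect = c("stats", "codes"))
  emp <- tabulate(sim$codes + 1, nbins = 64) / length(sim$codes)
  expect_lt(0.5 * sum(abs(emp - ex$prob)), 0.02)
})

test_that("sampler is reproducible under a fixed seed", {
  attrs <- tiny_attrs_ab(12, seed = 3)
  nm <- term_names(model_spec("base"), attrs)
  th <- setNames(c(-1, 0.2, 0.1), nm)
  s1 <- sample_graphs(th, attrs, model_spec("base"), n_samples = 50, seed = 99)
  s2 <- sample_graphs(th, attrs, model_spec("base"), n_samples = 50, seed = 99)
  expect_identical(s1$stats, s2$stats)
  expect_identical(s1$final$adjacency, s2$final$adjacency)
})

test_that("mcmcmle reduces to mple for dyad-independent specifications", {
  g <- rand_graph(25, 0.3, seed = 40)
  attrs <- rand_attrs(25, seed = 40)
  attrs <- scale_struct_covariates(attrs)
  for (sname in c("base", "structural")) {
    spec <- model_spec(sname)
    fm <- mple_fit(g, attrs, spec)
    fmc <- mcmcmle_fit(g, attrs, spec, seed = 5)
    expect_equal(fm$theta, fmc$theta, tolerance = 1e-6)
    expect_match(fmc$note, "dyad-independent")
  }
})

test_that("mcmcmle flags degeneracy on a near-complete graph", {
  n <- 12
  a <- 1 * !diag(n)
  a[1, 2] <- a[2, 1] <- 0  # one missing edge
  g <- brain_graph(a)
  attrs <- node_attributes(paste0("n", seq_len(n)), rep("A", n),
                           rep("cortical", n))
  spec <- model_spec("gwesp", 0.5)
  fit <- suppressWarnings(
    mcmcmle_fit(g, attrs, spec, seed = 6,
                control = control_ergm(n_samples = 50, max_iter = 3)))
  expect_false(fit$converged && all(is.finite(fit$std_err)))
})

test_that("mple errors on rank-deficient designs", {
  g <- rand_graph(20, 0.3, seed = 50)
  attrs <- rand_attrs(20, seed = 50)
  attrs$struct_efficiency <- attrs$struct_degree  # exact collinearity
  expect_error(mple_fit(g, attrs, model_spec("structural")),
               "rank deficient")
})

test_that("decay selection profiles the pseudo-likelihood", {
  # graph generated with decay 0.5: the profile should not prefer the
  # grid extremes
  attrs <- tiny_attrs_ab(40, seed = 60)
  spec <- model_spec("gwesp", 0.5)
  nm <- term_names(spec, attrs)
  th <- setNames(c(-2.2, 0.3, 0.2, 0.5), nm)
  sim <- sample_graphs(th, attrs, spec, n_samples = 1, burnin = 30000,
                       thin = 1, seed = 61)
  sel <- select_gwesp_decay(sim$final, attrs, "gwesp")
  expect_true(sel$decay %in% seq(0.1, 1, by = 0.1))
  expect_equal(length(sel$logpl), 10)
  # the selected decay attains the profile maximum by construction;
  # check the profile is finite and single-valued per grid point
  expect_true(all(is.finite(sel$logpl)))
  expect_equal(sel$logpl[[as.character(sel$decay)]], max(sel$logpl))
})
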