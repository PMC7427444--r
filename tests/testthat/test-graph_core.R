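test_that("brain_graph validates and rejects malformed adjacency", {
  a <- matrix(0L, 154, 154)
  a[1, 2] <- a[2, 1] <- 1L
  g <- brain_graph(a)
  expect_equal(g$n_nodes, 154)
  expect_equal(edge_count(g), 1L)

  asym <- matrix(0, 3, 3); asym[1, 2] <- 1
  expect_error(brain_graph(asym), "asymmetric")
  loop <- matrix(0, 3, 3); loop[3, 3] <- 1
  expect_error(brain_graph(loop), "self-loop")
  nb <- matrix(0, 3, 3); nb[1, 2] <- nb[2, 1] <- 2
  expect_error(brain_graph(nb), "non-binary")
  expect_error(brain_graph(matrix(0, 2, 3)), "square")
})

test_that("graph_density matches E / choose(n,2)", {
  k4 <- brain_graph(1 * !diag(4))
  expect_equal(graph_density(k4), 1)
  expect_equal(graph_density(brain_graph(matrix(0, 5, 5))), 0)
  a <- matrix(0L, 5, 5)
  a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- 1L
  a[3, 4] <- a[4, 3] <- a[4, 5] <- a[5, 4] <- 1L
  expect_equal(graph_density(brain_graph(a)), 0.4)
  expect_error(graph_density(brain_graph(matrix(0, 1, 1))), "undefined")
})

test_that("esp_distribution on canonical shapes and conservation", {
  tri <- brain_graph(1 * !diag(3))
  expect_equal(as.integer(esp_distribution(tri)), c(0L, 3L))

  star <- matrix(0L, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1L
  esp <- esp_distribution(brain_graph(star))
  expect_equal(unname(esp[["0"]]), 3L)
  expect_equal(sum(esp), 3L)

  k4 <- brain_graph(1 * !diag(4))
  expect_equal(unname(esp_distribution(k4)[["2"]]), 6L)

  for (s in 1:20) {
    g <- rand_graph(sample(4:15, 1), runif(1, 0.1, 0.8), seed = s)
    expect_equal(sum(esp_distribution(g)), edge_count(g))
  }
})

test_that("gwesp_from_esp: closed forms, monotonicity, bound", {
  for (lam in c(0, 0.3, 0.45, 1.2))
    expect_equal(gwesp_from_esp(c("1" = 3), lam), 3)
  expect_equal(gwesp_from_esp(setNames(integer(0), character(0)), 0.5), 0)
  expect_error(gwesp_from_esp(c("1" = 3), -0.1), "nonnegative")

  g <- rand_graph(12, 0.4, seed = 7)
  esp <- esp_distribution(g)
  lams <- seq(0.05, 2, by = 0.05)
  vals <- vapply(lams, function(l) gwesp_from_esp(esp, l), numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
  e_pos <- edge_count(g) - esp[["0"]]
  expect_true(all(vals <= exp(lams) * e_pos + 1e-9))
})

test_that("gwesp from esp agrees with the direct statistic path", {
  spec <- model_spec("gwesp", 0.45)
  for (s in 1:10) {
    g <- rand_graph(sample(5:14, 1), runif(1, 0.2, 0.7), seed = 100 + s)
    attrs <- tiny_attrs_ab(g$n_nodes, seed = s)
    direct <- compute_statistics(g, attrs, spec)[["gwesp.fixed.0.45"]]
    via_esp <- gwesp_from_esp(esp_distribution(g), 0.45)
    expect_equal(direct, via_esp, tolerance = 1e-9)
  }
})

test_that("mixing_counts: examples and conservation", {
  tri <- matrix(0L, 3, 3)
  tri[1, 2] <- tri[2, 1] <- tri[1, 3] <- tri[3, 1] <- 1L
  attrs <- node_attributes(paste0("n", 1:3), c("A", "A", "B"),
                           rep("cortical", 3))
  m <- mixing_counts(brain_graph(tri), attrs)
  expect_equal(m$count[m$label_a == "A" & m$label_b == "A"], 1L)
  expect_equal(m$count[m$label_a == "A" & m$label_b == "B"], 1L)
  expect_equal(m$count[m$label_a == "B" & m$label_b == "B"], 0L)

  k4 <- brain_graph(1 * !diag(4))
  attrs4 <- node_attributes(paste0("n", 1:4), c("A", "A", "B", "B"),
                            rep("cortical", 4))
  m4 <- mixing_counts(k4, attrs4)
  expect_equal(m4$count, c(1L, 4L, 1L))

  for (s in 1:10) {
    g <- rand_graph(sample(5:20, 1), runif(1, 0.1, 0.9), seed = 200 + s)
    attrs <- rand_attrs(g$n_nodes, seed = s, with_struct = FALSE)
    expect_equal(sum(mixing_counts(g, attrs)$count), edge_count(g))
  }
})

test_that("compute_statistics matches the naive loop oracle on all specs", {
  specs <- list(model_spec("base"), model_spec("structural"),
                model_spec("gwesp", 0.45), model_spec("complete", 0.6))
  for (s in 1:8) {
    g <- rand_graph(10, 0.4, seed = 300 + s)
    attrs <- rand_attrs(10, seed = 300 + s)
    for (spec in specs)
      expect_equal(compute_statistics(g, attrs, spec),
                   naive_stats(g, attrs, spec), tolerance = 1e-12)
  }
})

test_that("nodecov sums follow the x_u + x_v definition", {
  tri <- brain_graph(1 * !diag(3))
  attrs <- node_attributes(paste0("n", 1:3), c("A", "A", "B"),
                           rep("cortical", 3),
                           struct_degree = c(1, 2, 3),
                           struct_efficiency = c(0, 0, 0),
                           struct_clustering = c(0, 0, 0),
                           latent_cluster = c(1, 1, 2))
  st <- compute_statistics(tri, attrs, model_spec("structural"))
  expect_equal(st[["nodecov.struct_degree"]], 12)  # (1+2)+(1+3)+(2+3)
  expect_equal(st[["nodematch.latent"]], 1)
  expect_equal(st[["edges"]], 3)
})

test_that("attribute validation catches misalignment and missing labels", {
  g <- rand_graph(5, 0.5, seed = 1)
  attrs <- tiny_attrs_ab(4)
  expect_error(compute_statistics(g, attrs, model_spec("base")), "rows")
  attrs5 <- tiny_attrs_ab(5)
  attrs5$rsn_label[2] <- NA
  expect_error(compute_statistics(g, attrs5, model_spec("base")))
  expect_error(compute_statistics(g, tiny_attrs_ab(5),
                                  model_spec("structural")), "missing")
})
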