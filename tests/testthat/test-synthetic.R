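test_that("default parcellation matches the 154-node census", {
  cfg <- cohort_config(seed = 1)
  attrs <- gen_parcellation(cfg)
  expect_equal(nrow(attrs), 154)
  expect_equal(sum(attrs$rsn_label == "thalamus"), 14)
  expect_equal(sum(attrs$rsn_label == "basal_ganglia"), 6)
  expect_equal(sum(attrs$cortical_group == "cortical"), 134)
  expect_equal(length(unique(attrs$rsn_label[attrs$cortical_group ==
                                               "cortical"])), 7)
  expect_identical(gen_parcellation(cfg), gen_parcellation(cfg))
})

test_that("custom census scales the parcellation", {
  census <- data.frame(label = c("A", "B", "sub"),
                       count = c(5L, 5L, 4L),
                       group = c("cortical", "cortical", "subcortical"))
  cfg <- cohort_config(label_census = census,
                       structural_density = c(0.2, 0.4),
                       functional_density = c(0.2, 0.4), seed = 2)
  attrs <- gen_parcellation(cfg)
  expect_equal(nrow(attrs), 14)
})

test_that("structural graphs land in the target density range", {
  cfg <- cohort_config(seed = 3)
  for (s in 1:3) {
    g <- gen_structural_graph(cfg, subject_seed = 900 + s)
    d <- graph_density(g)
    expect_gte(d, 0.0531)
    expect_lte(d, 0.0632)
  }
  g1 <- gen_structural_graph(cfg, subject_seed = 42)
  g2 <- gen_structural_graph(cfg, subject_seed = 42)
  expect_identical(g1$adjacency, g2$adjacency)
})

test_that("functional cohorts respect densities, truth and determinism", {
  cfg <- small_cohort_config(n_subjects = 2L, scenario = "conscious_like",
                             seed = 11)
  co <- gen_functional_cohort(cfg)
  expect_equal(nrow(co$sessions), 4)
  expect_true(all(co$sessions$density >= cfg$functional_density[1] &
                    co$sessions$density <= cfg$functional_density[2]))
  # ground truth regenerates the exact cohort
  co2 <- gen_functional_cohort(cfg)
  for (key in names(co$graphs))
    expect_identical(co$graphs[[key]]$adjacency, co2$graphs[[key]]$adjacency)
  expect_equal(co$ground_truth, co2$ground_truth)
  # truth vector is a complete-model parameterization
  gt <- co$ground_truth[[1]]
  expect_setequal(names(gt$theta),
                  term_names(model_spec("complete", cfg$gwesp_decay),
                             co$attrs[[1]]))
})

test_that("patients scenario mirrors the study group layout", {
  cfg <- small_cohort_config(n_subjects = 4L, scenario = "patients",
                             seed = 12)
  co <- gen_functional_cohort(cfg)
  s <- co$sessions
  expect_true(all(s$group[s$session == "chronic"] == "conscious_chronic"))
  expect_true(all(s$scenario[s$group == "unconscious"] ==
                    "unconscious_like"))
  expect_true(all(c("gcs_v", "gcs_m") %in% names(s)))
  # the recorded GCS subscales reproduce the groups via the inference rule
  acute <- s[s$session == "acute", ]
  expect_equal(ifelse(infer_gose(acute$gcs_v, acute$gcs_m) == 2,
                      "unconscious", "conscious_acute"),
               acute$group)
})

test_that("dyad-independent generation matches logistic closed form", {
  # zero GWESP and covariates: empirical cell densities follow the logit
  cfg <- small_cohort_config(n_subjects = 1L, seed = 13)
  attrs <- gen_parcellation(cfg)
  attrs$struct_degree <- attrs$struct_efficiency <-
    attrs$struct_clustering <- rep(0, nrow(attrs))
  attrs$latent_cluster <- rep(1L, nrow(attrs))
  spec <- model_spec("complete", 0.5)
  nm <- term_names(spec, attrs)
  th <- setNames(rep(0, length(nm)), nm)
  th["edges"] <- -1
  th["mix.default.frontoparietal"] <- 0.8
  th["nodematch.latent"] <- 0  # all same cluster: matched on every dyad
  sim <- sample_graphs(th, attrs, spec, n_samples = 400, burnin = 4000,
                       thin = 300, seed = 14)
  lab <- attrs$rsn_label
  cell <- outer(lab, lab, function(x, y)
    pmin(x, y) == "default" & pmax(x, y) == "frontoparietal")
  n_cell_dyads <- sum(cell[upper.tri(cell)])
  exp_mix <- n_cell_dyads * plogis(-1 + 0.8)
  got <- mean(sim$stats[, "mix.default.frontoparietal"])
  expect_equal(got, exp_mix, tolerance = 0.05 * exp_mix + 1)
})

test_that("config validation", {
  expect_error(cohort_config(structural_density = c(0.5, 0.4)))
  bad <- data.frame(label = "A", count = -1L, group = "cortical")
  expect_error(cohort_config(label_census = bad), "census")
})
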