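test_that("sampled graphs satisfy the structural invariants", {
  set.seed(101)
  for (i in 1:10) {
    cfg <- sim_config(n_traits = sample(3:10, 1),
                      p_pleio = sample(c(0, 0.2), 1),
                      iv_per_trait_min = 3, iv_per_trait_max = 6)
    g <- sample_trait_graph(cfg)
    ig <- igraph::graph_from_data_frame(g$edges[, 1:2], directed = TRUE,
                                        vertices = g$trait_ids)
    expect_true(igraph::is_dag(ig))
    # every instrument has exactly one primary trait with nonzero effect
    expect_equal(anyDuplicated(g$instruments$iv_id), 0L)
    expect_true(all(g$instruments$effect != 0))
    expect_true(all(g$instruments$trait %in% g$trait_ids))
    # pleiotropic effects never land on the primary trait
    if (nrow(g$pleiotropy) > 0) {
      primary <- g$instruments$trait[match(g$pleiotropy$iv_id,
                                           g$instruments$iv_id)]
      expect_true(all(primary != g$pleiotropy$trait))
    }
  }
})

test_that("degenerate generator settings behave as specified", {
  set.seed(5)
  g0 <- sample_trait_graph(sim_config(n_traits = 2, mean_children = 0))
  expect_identical(nrow(g0$edges), 0L)
  g1 <- sample_trait_graph(sim_config(n_traits = 6, p_pleio = 0))
  expect_identical(nrow(g1$pleiotropy), 0L)
  expect_warning(sim_config(n_traits = 3, mean_children = 10),
                 "truncated")
})

test_that("mean total instrument count matches the closed-form expectation", {
  set.seed(202)
  cfg <- sim_config()
  counts <- replicate(1000, nrow(sample_trait_graph(cfg)$instruments))
  # per-trait count uniform on 10..20: mean 15, variance 10
  expected <- cfg$n_traits * 15
  se_mean <- sqrt(cfg$n_traits * 10 / 1000)
  expect_lt(abs(mean(counts) - expected), 3 * se_mean)
})

test_that("structural equations reproduce their coefficients", {
  # pure noise when there are no effects
  cfg <- sim_config(n_traits = 2, mean_children = 0, n_samples = 5000,
                    noise_sd = 1)
  set.seed(31)
  g <- sample_trait_graph(cfg)
  g$instruments$effect[] <- 0
  ds <- simulate_dataset(g, cfg)
  expect_lt(max(abs(colMeans(ds$traits))), 4 / sqrt(cfg$n_samples))
  expect_lt(max(abs(apply(ds$traits, 2, sd) - 1)), 0.06)

  # single instrument effect recovered by OLS within 3 s.e.
  cfg1 <- sim_config(n_traits = 2, mean_children = 0, n_samples = 3000,
                     iv_per_trait_min = 1, iv_per_trait_max = 1)
  set.seed(32)
  g1 <- sample_trait_graph(cfg1)
  ds1 <- simulate_dataset(g1, cfg1)
  iv <- g1$instruments[1, ]
  fit <- summary(lm(ds1$traits[, iv$trait] ~ ds1$genotypes[, iv$iv_id]))
  expect_lt(abs(coef(fit)[2, 1] - iv$effect), 3 * coef(fit)[2, 2])

  # chain effect: cov(A, B) / var(A) converges to the edge coefficient
  cfg2 <- sim_config(n_traits = 2, n_samples = 20000, mean_children = 0,
                     iv_per_trait_min = 1, iv_per_trait_max = 1)
  set.seed(33)
  g2 <- sample_trait_graph(cfg2)
  g2$edges <- data.frame(parent = "trait_01", child = "trait_02",
                         effect = 0.3, stringsAsFactors = FALSE)
  ds2 <- simulate_dataset(g2, cfg2)
  ratio <- cov(ds2$traits[, 1], ds2$traits[, 2]) / var(ds2$traits[, 1])
  expect_lt(abs(ratio - 0.3), 0.05)
})

test_that("marginal variance accumulates weakly along a causal chain", {
  # with equal instrument architecture and nonnegative effects, each
  # trait adds its parent's propagated variance on top of its own
  cfg <- sim_config(n_traits = 5, n_samples = 20000, iv_per_trait_min = 3,
                    iv_per_trait_max = 3)
  set.seed(88)
  g <- sample_trait_graph(cfg)
  g$instruments$effect <- 0.3
  g$instruments$freq <- 0.3
  g$edges <- data.frame(parent = sprintf("trait_%02d", 1:4),
                        child = sprintf("trait_%02d", 2:5),
                        effect = rep(0.6, 4), stringsAsFactors = FALSE)
  ds <- simulate_dataset(g, cfg)
  v <- apply(ds$traits, 2, var)
  # increments shrink geometrically toward the chain's fixed point, so
  # allow sampling noise around the late, near-zero increments
  expect_true(all(diff(v) > -0.05))
  expect_gt(v[5], v[1])
})

test_that("directed-path truth matrix equals a DFS oracle on random DAGs", {
  set.seed(404)
  for (i in 1:20) {
    g <- sample_trait_graph(sim_config(n_traits = 8, iv_per_trait_min = 1,
                                       iv_per_trait_max = 2))
    truth <- true_causal_matrix(g)
    expect_identical(truth, dfs_reachable(g$trait_ids, g$edges))
    # transitively closed and acyclic
    expect_true(all(!(truth & t(truth))))
    closure <- (truth %*% truth) > 0
    expect_true(all(truth[closure]))
    expect_false(any(diag(truth)))
  }
})

test_that("truth matrix handles boundary graphs", {
  set.seed(6)
  g <- sample_trait_graph(sim_config(n_traits = 3, mean_children = 0))
  expect_false(any(true_causal_matrix(g)))
  g$edges <- data.frame(parent = c("trait_01", "trait_02"),
                        child = c("trait_02", "trait_03"),
                        effect = c(0.2, 0.3), stringsAsFactors = FALSE)
  tm <- true_causal_matrix(g)
  expect_true(tm["trait_01", "trait_03"])
  expect_false(tm["trait_03", "trait_01"])
  # a cycle must be rejected
  g$edges <- rbind(g$edges, data.frame(parent = "trait_03",
                                       child = "trait_01", effect = 0.1))
  expect_error(true_causal_matrix(g), "cycle")
})

test_that("total effects equal brute-force path enumeration", {
  set.seed(7)
  g <- sample_trait_graph(sim_config(n_traits = 4, mean_children = 0))
  g$edges <- data.frame(
    parent = c("trait_01", "trait_02", "trait_01"),
    child = c("trait_02", "trait_03", "trait_03"),
    effect = c(0.5, 0.4, -0.2), stringsAsFactors = FALSE
  )
  te <- total_effect_matrix(g)
  expect_equal(te["trait_01", "trait_02"], 0.5)
  # two paths 1->3: direct (-0.2) and through 2 (0.5 * 0.4)
  expect_equal(te["trait_01", "trait_03"], -0.2 + 0.5 * 0.4)
  expect_equal(te["trait_03", "trait_01"], 0)
})

test_that("datasets round-trip through the TSV/JSON writer", {
  fx <- small_dataset(seed = 9, n_traits = 3, n_samples = 50, p_pleio = 0.2)
  dir <- withr::local_tempdir()
  write_dataset(fx$dataset, dir)
  back <- read_dataset(dir)
  expect_equal(unname(back$genotypes), unname(fx$dataset$genotypes))
  expect_equal(back$traits, fx$dataset$traits, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$graph$edges$effect, fx$dataset$graph$edges$effect)
  expect_equal(back$graph$instruments$freq,
               fx$dataset$graph$instruments$freq)
})

test_that("with no pleiotropy instruments only associate with their primary trait and its descendants", {
  fx <- small_dataset(seed = 21, n_traits = 5, n_samples = 4000, p_pleio = 0)
  gw <- run_gwas(fx$dataset)
  truth <- true_causal_matrix(fx$graph)
  # strongly significant associations must be with the primary trait or
  # one of its descendants
  sig <- which(gw$pval < 1e-8, arr.ind = TRUE)
  for (k in seq_len(nrow(sig))) {
    iv <- rownames(gw$pval)[sig[k, 1]]
    tr <- colnames(gw$pval)[sig[k, 2]]
    primary <- fx$graph$instruments$trait[fx$graph$instruments$iv_id == iv]
    expect_true(tr == primary || truth[primary, tr])
  }
})
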