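test_that("marginal GWAS matches per-pair lm() on a small fixture", {
  set.seed(11)
  n <- 6
  G <- cbind(iv_001 = c(0, 1, 0, 1, 1, 0), iv_002 = c(1, 1, 0, 0, 1, 0))
  Y <- cbind(trait_01 = rnorm(n), trait_02 = rnorm(n))
  ds <- structure(list(genotypes = G, traits = Y, graph = NULL),
                  class = "mr_dataset")
  gw <- run_gwas(ds)
  for (iv in colnames(G)) for (tr in colnames(Y)) {
    fit <- summary(lm(Y[, tr] ~ G[, iv]))
    expect_equal(gw$beta[iv, tr], unname(coef(fit)[2, 1]), tolerance = 1e-12)
    expect_equal(gw$se[iv, tr], unname(coef(fit)[2, 2]), tolerance = 1e-12)
    expect_equal(gw$pval[iv, tr], unname(coef(fit)[2, 4]), tolerance = 1e-12)
  }
  # hand closed form for one pair
  x <- G[, 1]; y <- Y[, 1]
  expect_equal(gw$beta["iv_001", "trait_01"],
               sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2))
})

test_that("perfect association and degenerate genotypes are flagged", {
  set.seed(12)
  G <- cbind(iv_001 = rep(c(0, 1), 10), iv_002 = rep(1, 20))
  Y <- cbind(trait_01 = as.numeric(G[, 1]))
  ds <- structure(list(genotypes = G, traits = Y, graph = NULL),
                  class = "mr_dataset")
  gw <- run_gwas(ds)
  expect_equal(gw$beta["iv_001", "trait_01"], 1)
  expect_lt(gw$pval["iv_001", "trait_01"], 1e-100)
  # zero-variance genotype: flagged, never selectable
  expect_equal(gw$beta["iv_002", "trait_01"], 0)
  expect_equal(gw$pval["iv_002", "trait_01"], 1)
})

test_that("GWAS p-values are uniform under the null", {
  set.seed(13)
  n <- 100
  reps <- 1000
  G <- matrix(rbinom(n * reps, 1, 0.3), n, reps,
              dimnames = list(NULL, sprintf("iv_%03d", 1:reps)))
  Y <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "trait_01"))
  ds <- structure(list(genotypes = G, traits = Y, graph = NULL),
                  class = "mr_dataset")
  gw <- run_gwas(ds)
  expect_gt(ks.test(gw$pval[, 1], "punif")$p.value, 0.01)
})

test_that("Bonferroni selection implements the stated rule and is monotone", {
  pv <- c(1e-6, 2e-4, 2.3e-4, 0.01, 1)
  gw <- fake_gwas(pv)
  # alpha = 0.05 over 225 tests: threshold 0.05/225 ~ 2.222e-4
  sel <- select_instruments(gw, "trait_01", alpha = 0.05, n_tests = 225)
  expect_identical(sel$instruments, sprintf("iv_%03d", c(1, 2)))
  expect_identical(names(sel$weights), sel$instruments)
  # all-null table selects nothing
  expect_length(select_instruments(fake_gwas(rep(1, 4)),
                                   "trait_01")$instruments, 0)
  # shrinking alpha never adds instruments
  prev <- select_instruments(gw, "trait_01", alpha = 0.05,
                             n_tests = 10)$instruments
  for (a in c(0.01, 0.001, 1e-4)) {
    cur <- select_instruments(gw, "trait_01", alpha = a,
                              n_tests = 10)$instruments
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("null selection count matches the binomial expectation", {
  set.seed(14)
  m <- 500
  reps <- 1000
  alpha <- 0.05
  n_sel <- replicate(reps, {
    gw <- fake_gwas(runif(m))
    length(select_instruments(gw, "trait_01", alpha = alpha,
                              n_tests = m)$instruments)
  })
  expected <- m * alpha / m
  se <- sqrt(m * (alpha / m) * (1 - alpha / m) / reps)
  expect_lt(abs(mean(n_sel) - expected), 3 * se)
})

test_that("UniqueIV filtering removes pleiotropic instruments and keeps clean ones", {
  # X with 6 instruments, one of which also directly affects Z
  set.seed(15)
  n <- 4000
  freq <- rep(0.3, 6)
  G <- sapply(freq, function(f) rbinom(n, 1, f))
  colnames(G) <- sprintf("iv_%03d", 1:6)
  X <- G %*% rep(0.35, 6) + rnorm(n)
  Z <- 0.4 * X + 0.4 * G[, 6] + rnorm(n)   # iv_006 is pleiotropic on Z
  ds <- structure(list(genotypes = G,
                       traits = cbind(trait_01 = as.numeric(X),
                                      trait_02 = as.numeric(Z)),
                       graph = NULL),
                  class = "mr_dataset")
  gw <- run_gwas(ds)
  base <- select_instruments(gw, "trait_01")
  expect_length(base$instruments, 6)
  filt <- unique_iv_filter(gw, ds, "trait_01", base)
  expect_false("iv_006" %in% filt$instruments)
  expect_true(all(sprintf("iv_%03d", 1:5) %in% filt$instruments))
  # always a subset of the Bonferroni set
  expect_true(all(filt$instruments %in% base$instruments))
  # excluding the outcome from the screen makes the filter an identity here
  ident <- unique_iv_filter(gw, ds, "trait_01", base,
                            exclude_traits = "trait_02")
  expect_identical(ident$instruments, base$instruments)
})

test_that("UniqueIV retains nearly all instruments of a source trait when pleiotropy is absent", {
  fx <- small_dataset(seed = 16, n_traits = 5, n_samples = 4000, p_pleio = 0,
                      iv_per_trait_min = 8, iv_per_trait_max = 10)
  gw <- run_gwas(fx$dataset)
  # pick a parentless trait (a source in the DAG)
  truth <- true_causal_matrix(fx$graph)
  src <- names(which(colSums(truth) == 0))[1]
  base <- select_instruments(gw, src)
  filt <- unique_iv_filter(gw, fx$dataset, src, base)
  expect_true(all(filt$instruments %in% base$instruments))
  expect_gte(length(filt$instruments), 0.6 * length(base$instruments))
})

test_that("filter is the identity in a single-trait system", {
  set.seed(17)
  n <- 200
  G <- matrix(rbinom(n * 3, 1, 0.4), n, 3,
              dimnames = list(NULL, sprintf("iv_%03d", 1:3)))
  Y <- matrix(G %*% rep(0.5, 3) + rnorm(n), n, 1,
              dimnames = list(NULL, "trait_01"))
  ds <- structure(list(genotypes = G, traits = Y, graph = NULL),
                  class = "mr_dataset")
  gw <- run_gwas(ds)
  base <- select_instruments(gw, "trait_01", alpha = 0.05, n_tests = 3)
  filt <- unique_iv_filter(gw, ds, "trait_01", base)
  expect_identical(filt$instruments, base$instruments)
})

test_that("weighted allele scores reproduce their defining sum", {
  # hand fixture: 4 samples, two instruments, weights (0.5, -0.2)
  G <- rbind(c(0, 1), c(1, 1), c(1, 0), c(0, 0))
  colnames(G) <- c("iv_001", "iv_002")
  ds <- structure(list(genotypes = G,
                       traits = matrix(0, 4, 1,
                                       dimnames = list(NULL, "trait_01")),
                       graph = NULL),
                  class = "mr_dataset")
  iset <- structure(list(exposure = "trait_01",
                         instruments = c("iv_001", "iv_002"),
                         weights = c(iv_001 = 0.5, iv_002 = -0.2)),
                    class = "instrument_set")
  sc <- weighted_allele_score(ds, iset)
  expect_equal(sc$values, c(-0.2, 0.3, 0.5, 0))
  # single unit-weight instrument: score equals the genotype column
  one <- structure(list(exposure = "trait_01", instruments = "iv_001",
                        weights = c(iv_001 = 1)), class = "instrument_set")
  expect_equal(weighted_allele_score(ds, one)$values, unname(G[, 1]))
  # zero weights give a constant-zero score
  zero <- iset; zero$weights[] <- 0
  expect_equal(weighted_allele_score(ds, zero)$values, rep(0, 4))
  # empty set is an error
  empty <- structure(list(exposure = "trait_01", instruments = character(0),
                          weights = numeric(0)), class = "instrument_set")
  expect_error(weighted_allele_score(ds, empty), "empty")
  # recomputation invariant on a simulated replicate
  fx <- small_dataset(seed = 18, n_traits = 3, n_samples = 300)
  gw <- run_gwas(fx$dataset)
  bs <- select_instruments(gw, "trait_01")
  if (length(bs$instruments) > 0) {
    sc2 <- weighted_allele_score(fx$dataset, bs)
    manual <- as.vector(fx$dataset$genotypes[, bs$instruments, drop = FALSE]
                        %*% bs$weights)
    expect_identical(sc2$values, manual)
  }
})
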