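test_that("genome models are reproducible simplices with exact G+C", {
  m1 <- sample_genome_model(0.65, 2, 0.5, seed = 1)
  m2 <- sample_genome_model(0.65, 2, 0.5, seed = 1)
  expect_identical(m1$trans, m2$trans)
  expect_equal(unname(rowSums(m1$trans)), rep(1, 16), tolerance = 1e-12)
  # stationary G+C hits the target (well within the 0.5 pp contract)
  expect_equal(model_gc(m1), 0.65, tolerance = 1e-9)

  # zero bias, order 0, target 0.5 -> uniform ACGT
  u <- sample_genome_model(0.5, 0, 0, seed = 2)
  expect_equal(unname(u$trans[1, ]), rep(0.25, 4))

  expect_error(sample_genome_model(0, 2, 0.5, 1))
})

test_that("model_word_probs is a distribution consistent with sampling", {
  m <- sample_genome_model(0.6, 1, 0.6, seed = 3)
  p3 <- model_word_probs(m, 3)
  expect_equal(sum(p3), 1, tolerance = 1e-9)
  # empirical trimer frequencies of a long sample track the analytic values
  sim <- generate_scaffolds(community_spec(list(m), n_scaffolds = 1,
                                           length_median = 2e5,
                                           length_sigma = 0, seed = 4))
  emp <- composition_vector(sim$records$seq[[1]], k_min = 3, k_max = 3)
  expect_lt(sum(abs(emp$frequencies - p3)), 0.02)
})

test_that("sampled scaffolds hit the target G+C", {
  m <- sample_genome_model(0.65, 2, 0.5, seed = 5)
  sim <- generate_scaffolds(community_spec(list(m), n_scaffolds = 100,
                                           length_median = 50000,
                                           length_sigma = 0, seed = 5))
  expect_gt(mean(gc_content(sim$records)), 0.64)
  expect_lt(mean(gc_content(sim$records)), 0.66)
})

test_that("generate_scaffolds honors abundances, lengths and truth labels", {
  ms <- list(sample_genome_model(0.4, 0, 0, seed = 6, label = "L"),
             sample_genome_model(0.6, 0, 0, seed = 7, label = "H"))
  spec <- community_spec(ms, abundances = c(0.5, 0.5), n_scaffolds = 2000,
                         length_median = 1000, length_sigma = 0, seed = 8)
  sim <- generate_scaffolds(spec)
  expect_equal(nrow(sim$truth), 2000)
  nl <- table(sim$truth$label)["L"]
  bounds <- qbinom(c(0.005, 0.995), 2000, 0.5) # binomial 99% oracle
  expect_gte(nl, bounds[1])
  expect_lte(nl, bounds[2])

  # byte-identical reproducibility
  sim2 <- generate_scaffolds(spec)
  expect_identical(as.character(sim$records$seq), as.character(sim2$records$seq))

  # exact per-model counts and length truncation
  spec3 <- community_spec(ms, n_scaffolds = c(10, 15), length_median = 4000,
                          length_sigma = 1.2, length_range = c(1000, 30000),
                          seed = 9)
  sim3 <- generate_scaffolds(spec3)
  expect_equal(as.integer(table(sim3$truth$label)[c("L", "H")]), c(10L, 15L))
  expect_true(all(sim3$truth$length >= 1000 & sim3$truth$length <= 30000))
})

test_that("N-injection masks bases without breaking parsing", {
  m <- sample_genome_model(0.5, 1, 0.2, seed = 10)
  sim <- generate_scaffolds(community_spec(list(m), n_scaffolds = 5,
                                           length_median = 2000,
                                           length_sigma = 0, n_rate = 0.02,
                                           seed = 10))
  freq <- Biostrings::alphabetFrequency(sim$records$seq)
  expect_gt(sum(freq[, "N"]), 0)
  expect_equal(sum(freq[, c("A", "C", "G", "T", "N")]), sum(freq))
})

test_that("models with distinct order-2 bias separate along PC1", {
  ma <- sample_genome_model(0.5, 2, 0.5, seed = 11, label = "a")
  mb <- sample_genome_model(0.5, 2, 0.5, seed = 12, label = "b")
  sim <- generate_scaffolds(community_spec(list(ma, mb),
                                           n_scaffolds = c(30, 30),
                                           length_median = 20000,
                                           length_sigma = 0, seed = 13))
  cm <- composition_matrix(sim$records)
  sc <- pca(cm$freq, 1)$scores[, 1]
  lab <- sim$truth$label
  centroid_gap <- abs(diff(tapply(sc, lab, mean)))
  within_sd <- sqrt(mean(tapply(sc, lab, var)))
  expect_gt(centroid_gap, 3 * within_sd)
})

test_that("generate_otu_counts: determinism, bounds, alpha recovery", {
  c1 <- generate_otu_counts(N = 200, abundance_model = "logseries",
                            alpha = 5, seed = 14)
  c2 <- generate_otu_counts(N = 200, abundance_model = "logseries",
                            alpha = 5, seed = 14)
  expect_identical(c1, c2)
  expect_equal(sum(c1), 200)

  ln <- generate_otu_counts(S_true = 50, N = 30,
                            abundance_model = "lognormal", seed = 15)
  expect_lte(sum(ln > 0), 30) # S_obs <= min(N, S_true)

  # parameter recovery: fisher_alpha over replicates, relative bias < 10%
  alphas <- vapply(1:60, function(i) {
    fisher_alpha(generate_otu_counts(N = 1000, abundance_model = "logseries",
                                     alpha = 10, seed = 1000 + i))
  }, 0)
  expect_lt(abs(mean(alphas) - 10) / 10, 0.1)
})

test_that("generate_env_matrix plants a detectable gradient", {
  env <- generate_env_matrix(12, n_numeric = 4, n_factor = 1,
                             effect_axis = 3, seed = 16)
  expect_equal(attr(env, "truth")$planted, "env01")
  # ordination representing the community response to the latent gradient
  g <- attr(env, "truth")$gradient
  scores <- cbind(Axis1 = g,
                  Axis2 = matbin:::with_seed(17, rnorm(12, 0, 0.2)))
  fit <- fit_env_variables(scores, env, n_permutations = 99, seed = 17)
  num <- fit[fit$type == "numeric", ]
  expect_equal(num$variable[which.max(num$r2)], "env01")
  expect_lte(fit$p_value[fit$variable == "env01"], 0.05)

  env0 <- generate_env_matrix(12, effect_axis = 0, seed = 18)
  expect_true(is.na(attr(env0, "truth")$planted))
})

test_that("generate_func_matrix plants recoverable site groups", {
  m <- generate_func_matrix(seed = 19)
  expect_identical(m, generate_func_matrix(seed = 19))
  expect_equal(dim(m), c(52L, 12L))
  truth <- attr(m, "truth")$groups
  std <- standardize_rows(relative_abundance(m))
  for (recipe in list(c("euclidean", "complete"), c("pearson", "average"))) {
    cut3 <- cut_dendrogram(hcluster(t(std), recipe[1], recipe[2]), 3)
    expect_gte(adjusted_rand_index(cut3, truth), 0.9)
  }
})
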