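test_that("gower_distance matches hand-computed coefficients", {
  env <- data.frame(a = c(0, 5, 10), b = c(1, 1, 3), f = c("x", "y", "x"),
                    row.names = c("s1", "s2", "s3"))
  D <- gower_distance(env)
  # ranges: a -> 10, b -> 2; categorical mismatch contributes 1
  expect_equal(D["s1", "s2"], (0.5 + 0 + 1) / 3)
  expect_equal(D["s1", "s3"], (1.0 + 1 + 0) / 3)
  expect_equal(D["s2", "s3"], (0.5 + 1 + 1) / 3)
  expect_equal(unname(diag(D)), rep(0, 3))

  # missing values drop a variable's weight for affected pairs
  env$b <- c(1, NA, 3)
  D2 <- gower_distance(env)
  expect_equal(D2["s1", "s2"], (0.5 + 1) / 2)

  # identical rows at distance 0; single differing categorical at 1
  expect_equal(gower_distance(data.frame(x = c(1, 1), f = c("u", "u")))[1, 2],
               0)
  expect_equal(gower_distance(data.frame(f = c("u", "v")))[1, 2], 1)

  # a pair with no comparable variable is an error naming the pair
  bad <- data.frame(a = c(1, NA, 2), b = c(NA, 1, 2),
                    row.names = c("p", "q", "r"))
  expect_error(gower_distance(bad), "p and q")
})

test_that("gower_distance is a pseudo-metric on complete data", {
  for (i in 1:5) {
    env <- matbin:::with_seed(i, data.frame(
      a = rnorm(6), b = runif(6), f = sample(c("u", "v", "w"), 6, TRUE)))
    D <- gower_distance(env)
    expect_equal(D, t(D))
    expect_true(all(D >= 0 & D <= 1))
    for (x in 1:6) for (y in 1:6) for (z in 1:6)
      expect_lte(D[x, z], D[x, y] + D[y, z] + 1e-12)
  }
})

test_that("fit_env_variables recovers exact and degenerate fits", {
  env <- generate_env_matrix(10, n_numeric = 2, n_factor = 0, seed = 2)
  ord <- pcoa(gower_distance(env), 2)
  env$axis1 <- ord$scores[, 1] # identical to the first axis
  env$const <- 5
  fit <- suppressMessages(
    fit_env_variables(ord$scores, env, n_permutations = 99, seed = 3))
  expect_equal(fit$r2[fit$variable == "axis1"], 1.0, tolerance = 1e-9)
  expect_equal(fit$p_value[fit$variable == "axis1"], 1 / 100)
  expect_equal(fit$r2[fit$variable == "const"], 0)
  expect_true(is.na(fit$p_value[fit$variable == "const"]))
  expect_true(all(fit$p_value >= 1 / 100, na.rm = TRUE))
})

test_that("fit_env_variables agrees with the vegan envfit oracle", {
  skip_if_not_installed("vegan")
  env <- generate_env_matrix(12, n_numeric = 3, n_factor = 1, seed = 4)
  ord <- pcoa(gower_distance(env), 2)
  mine <- fit_env_variables(ord$scores, env, n_permutations = 99, seed = 5)
  vg <- vegan::envfit(ord$scores, env[, 1:3], permutations = 99)
  expect_equal(mine$r2[1:3], unname(vg$vectors$r), tolerance = 1e-9)
  vf <- vegan::envfit(ord$scores, data.frame(f = factor(env$fac01)),
                      permutations = 99)
  expect_equal(mine$r2[4], unname(vf$factors$r), tolerance = 1e-9)
  # deterministic under a fixed seed
  mine2 <- fit_env_variables(ord$scores, env, n_permutations = 99, seed = 5)
  expect_identical(mine$p_value, mine2$p_value)
})

test_that("chao1 closed forms", {
  expect_equal(chao1(c(a = 1, b = 1, c = 2)), 5.0) # 3 + 2^2/(2*1)
  expect_equal(chao1(c(3, 4, 5)), 3) # no singletons
  expect_equal(chao1(c(1)), 1) # bias-corrected f2 = 0 branch
  expect_gte(chao1(c(1, 1, 1, 2, 5)), 5)
})

test_that("ace matches an independent textbook recomputation", {
  cnt <- c(1, 1, 1, 2, 2, 3, 4, 7, 9, 10, 12, 40, 80)
  got <- ace(cnt)
  # independent recomputation, written directly from the estimator
  rare <- cnt[cnt <= 10]
  f1 <- sum(rare == 1)
  Nr <- sum(rare)
  C <- 1 - f1 / Nr
  fi <- vapply(1:10, function(i) sum(rare == i), 0)
  g2 <- max(length(rare) / C * sum((1:10) * (0:9) * fi) / (Nr * (Nr - 1)) - 1,
            0)
  expect_equal(as.numeric(got), sum(cnt > 10) + length(rare) / C +
                 f1 / C * g2)
  expect_equal(attr(got, "method"), "ace")

  expect_equal(as.numeric(ace(c(11, 20, 30))), 3) # all abundant
  expect_message(fb <- ace(c(1, 1, 1)), "falling back")
  expect_equal(attr(fb, "method"), "chao1_fallback")
})

test_that("ace agrees with the vegan oracle on random samples", {
  skip_if_not_installed("vegan")
  for (i in 1:5) {
    cnt <- generate_otu_counts(N = 400, abundance_model = "logseries",
                               alpha = 15, seed = 40 + i)
    expect_equal(as.numeric(ace(cnt)),
                 unname(vegan::estimateR(cnt)["S.ACE"]), tolerance = 1e-8)
  }
})

test_that("shannon, simpson and fisher alpha closed forms", {
  expect_equal(shannon_index(rep(5, 4)), log(4))
  expect_equal(simpson_reciprocal(rep(5, 4)), 4)
  expect_equal(shannon_index(c(9)), 0)
  expect_equal(simpson_reciprocal(c(9)), 1)
  expect_equal(shannon_index(rep(1, 8), base = 2), 3)

  # S = 10, N = 100: alpha verified by back-substitution
  counts <- c(rep(1, 9), 91)
  a <- fisher_alpha(counts)
  expect_lt(abs(a * log1p(100 / a) - 10), 1e-9)
  expect_warning(expect_equal(fisher_alpha(c(1, 1, 1)), Inf), "singleton")
})

test_that("diversity indices are invariant to species labels", {
  cnt <- generate_otu_counts(N = 300, abundance_model = "logseries",
                             alpha = 8, seed = 6)
  perm <- matbin:::with_seed(7, sample(length(cnt)))
  for (f in list(chao1, function(x) as.numeric(ace(x)), shannon_index,
                 simpson_reciprocal, fisher_alpha))
    expect_equal(f(cnt), f(cnt[perm]))
})

test_that("rarefaction expectation matches its limits and Monte-Carlo", {
  cnt <- c(5, 3, 2, 1, 1)
  N <- sum(cnt)
  expect_equal(rarefaction(cnt, N)$expected_s, 5) # m = N recovers S_obs
  expect_equal(rarefaction(cnt, 1)$expected_s, 1)
  expect_error(rarefaction(cnt, N + 1), "depths")

  # subsampling oracle at m = 6
  reps <- 1e4
  pool <- rep(seq_along(cnt), cnt)
  sim <- matbin:::with_seed(8, vapply(seq_len(reps), function(i)
    length(unique(sample(pool, 6))), 0))
  se <- sd(sim) / sqrt(reps)
  expect_lt(abs(rarefaction(cnt, 6)$expected_s - mean(sim)), 3 * se)

  # monotone, bounded curve
  cur <- rarefaction(cnt, 1:N)$expected_s
  expect_true(all(diff(cur) >= -1e-12))
  expect_true(all(cur <= 5 + 1e-12))
})

test_that("diversity_report bundles consistent estimates", {
  cnt <- generate_otu_counts(N = 500, abundance_model = "logseries",
                             alpha = 12, seed = 9)
  rep_ <- diversity_report(cnt)
  expect_gte(rep_$chao1, rep_$s_obs)
  expect_gte(rep_$ace, rep_$s_obs)
  expect_gte(rep_$simpson_reciprocal, 1)
  expect_lte(rep_$simpson_reciprocal, rep_$s_obs)
  expect_true(all(diff(rep_$rarefaction$expected_s) >= -1e-12))
})

test_that("parse_env_values applies the below-detection rule", {
  v <- parse_env_values(c("117", "<3", "nd", "24"))
  expect_equal(as.numeric(v), c(117, 1.5, NA, 24))
  expect_equal(attr(v, "below_detection"), c(FALSE, TRUE, FALSE, FALSE))
})
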