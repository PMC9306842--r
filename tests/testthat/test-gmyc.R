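# single-threshold GMYC model: partition, likelihood, fits, LRT, support

test_that("threshold_partition boundary and fixture behaviour", {
  tr <- random_tree(9, seed = 2)
  depth <- max(attr(tr, "heights"))
  expect_length(threshold_partition(tr, depth), 1L)
  expect_length(threshold_partition(tr, 0), 9L)
  expect_error(threshold_partition(tr, depth * 1.01),
               class = "validation_error")

  fx <- figure1_fixture()
  part <- threshold_partition(fx$truth$tree, fx$threshold)
  expect_length(part, 6L)
  expect_true(any(vapply(part, function(s)
    setequal(s, c("sp1_1", "sp1_2", "sp2_1", "sp2_2", "sp3_1", "sp3_2")),
    TRUE)))
  expect_true(any(vapply(part, function(s) setequal(s, "spB_1"), TRUE)))
  expect_true(any(vapply(part, function(s)
    setequal(s, c("spW_1", "spY_1", "spY_2")), TRUE)))
})

test_that("single_class_rate closed forms", {
  expect_equal(single_class_rate(3, 1, 1, "coalescent"), 6)
  expect_equal(single_class_rate(7, 0.5, 0, "coalescent"), 0.5)
  expect_equal(single_class_rate(2, 1, 1, "diversification"), 2)
  expect_equal(single_class_rate(1, 1, 1, "coalescent"), 0) # no pair
  expect_equal(single_class_rate(1, 1, 0, "coalescent"), 0) # 0^0 stays 0
})

test_that("log-likelihood closed form on a single-interval schedule", {
  # one diversification event, k = 2, lambda_div = 1, p_div = 1, x = 0.5:
  # log(2) - 2 * 0.5
  tr <- as_ultrametric(ape::read.tree(text = "(a:0.5,b:0.5);"))
  s <- branching_events(tr, 0.25)
  expect_equal(nrow(s$events), 1L)
  ll <- gmyc_log_likelihood(s, list(lambda_div = 1, lambda_coal = 1,
                                    p_div = 1, p_coal = 1))
  expect_equal(ll, log(2) - 1, tolerance = 1e-12)

  # impossible coalescent event (lambda_coal -> 0) gives -Inf
  s2 <- branching_events(tr, 0.5)
  expect_true(all(s2$events$class == "coalescent"))
  ll2 <- gmyc_log_likelihood(s2, list(lambda_div = 1, lambda_coal = 0,
                                      p_div = 1, p_coal = 1))
  expect_equal(ll2, -Inf)
})

test_that("likelihood equals an independently coded per-interval summation", {
  fx <- figure1_fixture()
  tr <- fx$truth$tree
  params <- list(lambda_div = 0.8, lambda_coal = 40, p_div = 0.7,
                 p_coal = 1.3)
  for (Tc in c(0.5, 1.0, 2.2)) {
    s <- branching_events(tr, Tc)
    expect_equal(gmyc_log_likelihood(s, params),
                 oracle_loglik(tr, Tc, params$lambda_div, params$lambda_coal,
                               params$p_div, params$p_coal),
                 tolerance = 1e-10)
  }
  for (seed in 1:10) {
    tr <- random_tree(6 + seed %% 5, seed + 40)
    Tc <- stats::runif(1, 0, max(attr(tr, "heights")))
    s <- branching_events(tr, Tc)
    expect_equal(gmyc_log_likelihood(s, params),
                 oracle_loglik(tr, Tc, params$lambda_div, params$lambda_coal,
                               params$p_div, params$p_coal),
                 tolerance = 1e-10)
  }
})

test_that("profiled lambdas maximise the likelihood", {
  # closed form: one class, m events, exposure E -> lambda = m / E
  tr <- as_ultrametric(ape::read.tree(text = "((a:1,b:1):1,c:2);"))
  s <- branching_events(tr, max(attr(tr, "heights"))) # all coalescent
  pr <- profile_lambdas(s, 1, 0)
  # 2 events, unit factors at p = 0, E = x1 + x2 = 2 -> lambda = 1
  expect_equal(pr$lambda_coal, 1, tolerance = 1e-12)
  expect_equal(pr$lambda_div, 0)

  # profile beats +-10% lambda perturbations on random classified schedules
  for (seed in 1:100) {
    tr <- random_tree(4 + seed %% 7, seed + 900)
    set.seed(seed)
    Tc <- stats::runif(1, 0, max(attr(tr, "heights")))
    s <- branching_events(tr, Tc)
    p_div <- stats::runif(1, 0, 2); p_coal <- stats::runif(1, 0, 2)
    pr <- profile_lambdas(s, p_div, p_coal)
    expect_equal(pr$logL,
                 gmyc_log_likelihood(s, list(lambda_div = pr$lambda_div,
                                             lambda_coal = pr$lambda_coal,
                                             p_div = p_div, p_coal = p_coal)),
                 tolerance = 1e-9)
    for (fac in c(0.9, 1.1)) {
      pert <- list(lambda_div = if (pr$lambda_div > 0) pr$lambda_div * fac
                                else 1e-9,
                   lambda_coal = if (pr$lambda_coal > 0) pr$lambda_coal * fac
                                 else 1e-9,
                   p_div = p_div, p_coal = p_coal)
      expect_gte(pr$logL + 1e-9, gmyc_log_likelihood(s, pert))
    }
  }
})

test_that("null fit: closed form and grid oracle", {
  tr <- as_ultrametric(ape::read.tree(text = "((a:1,b:1):1,c:2);"))
  s <- branching_events(tr)
  # p0 = 0: lambda0 = m / sum(x) = 2 / 2 = 1
  pairs <- s$events$n_total * (s$events$n_total - 1)
  expect_equal(2 / sum(s$events$x), 1)

  # null logL equals the threshold likelihood of an all-coalescent schedule
  null <- fit_null(s)
  s_all <- branching_events(tr, max(attr(tr, "heights")))
  ll <- gmyc_log_likelihood(s_all, list(lambda_div = 0,
                                        lambda_coal = null$lambda0,
                                        p_div = 1, p_coal = null$p0))
  expect_equal(null$logL, ll, tolerance = 1e-8)

  # 20-tip tree: optimiser beats a 50 x 50 (lambda, p) grid
  tr20 <- simulate_species_tree(20, 1, seed = 99)
  s20 <- branching_events(tr20)
  null20 <- fit_null(s20)
  x <- s20$events$x
  pairs <- s20$events$n_total * (s20$events$n_total - 1)
  grid_ll <- function(lambda, p) {
    Fc <- pairs^p
    sum(log(lambda * Fc)) - lambda * sum(Fc * x)
  }
  lambdas <- seq(null20$lambda0 * 0.2, null20$lambda0 * 3, length.out = 50)
  ps <- seq(0, 10, length.out = 50)
  best_grid <- max(outer(lambdas, ps, Vectorize(grid_ll)))
  expect_gte(null20$logL + 1e-8, best_grid)
})

test_that("fit equals brute-force enumeration on small trees", {
  for (seed in 1:10) {
    tr <- random_tree(4 + seed %% 5, seed * 13)
    fit <- fit_single_threshold(tr)
    orc <- oracle_fit(tr)
    expect_equal(fit$logL, orc$logL, tolerance = 1e-4)
    expect_gte(fit$logL, fit$null_logL - 1e-9) # nesting
  }
})

test_that("fit recovers simulated species and is deterministic", {
  ts <- sim_clean(5, 4, seed = 1)
  fit <- fit_single_threshold(ts$tree)
  expect_equal(fit$n_entities, 5L)
  expect_equal(fit$n_entities, fit$n_clusters + fit$n_singletons)
  expect_setequal(unlist(fit$partition), ts$tree$tip.label)

  fit2 <- fit_single_threshold(ts$tree)
  expect_identical(fit[setdiff(names(fit), "tree")],
                   fit2[setdiff(names(fit2), "tree")])

  # single-class tree (pure coalescent): LR small, nesting always holds
  tr <- random_tree(12, seed = 77)
  f <- fit_single_threshold(tr)
  expect_gte(f$logL, f$null_logL - 1e-9)
  expect_true(f$p_value >= 0 && f$p_value <= 1)
})

test_that("likelihood-ratio test reference values", {
  expect_equal(likelihood_ratio_test(10, 10)$p_value, 1)
  expect_equal(likelihood_ratio_test(10, 10)$LR, 0)
  # chi-square quantile table: P(X2_3 > 7.815) ~ 0.05
  expect_equal(likelihood_ratio_test(10 + 7.815 / 2, 10, df = 3)$p_value,
               0.05, tolerance = 1e-3)
  expect_equal(likelihood_ratio_test(10 + 5.991 / 2, 10, df = 2)$p_value,
               0.05, tolerance = 1e-3)
})

test_that("entity counts", {
  fx <- figure1_fixture()
  expect_equal(entity_counts(fx$imposed_partition),
               c(entities = 6L, clusters = 5L, singletons = 1L))
  allsing <- species_partition(as.list(letters[1:5]))
  expect_equal(entity_counts(allsing),
               c(entities = 5L, clusters = 0L, singletons = 5L))
  one <- species_partition(list(letters[1:4]))
  expect_equal(entity_counts(one),
               c(entities = 1L, clusters = 1L, singletons = 0L))
})

test_that("node support is an Akaike-weight sum over candidate models", {
  tr <- as_ultrametric(ape::read.tree(text = "((a:1,b:1):2,(c:2,d:2):1);"))
  # two candidate models with equal logL: weights 0.5 each
  prof <- data.frame(threshold = c(1.5, 2.5), logL = c(-3, -3))
  sup <- node_support(tr, prof)
  h <- attr(tr, "heights")
  ab <- which(h == 1)  # cherry (a,b): species root under both models
  cd <- which(h == 2)  # cherry (c,d): species root only at T = 2.5
  expect_equal(sup$support[sup$node == ab], 1.0)
  expect_equal(sup$support[sup$node == cd], 0.5)
  expect_equal(sup$support[sup$node == 5], 0) # root never species-defining

  # supports lie in [0,1] on random fitted trees
  for (seed in 1:5) {
    tr <- random_tree(8, seed + 60)
    fit <- fit_single_threshold(tr)
    sup <- node_support(tr, fit$threshold_profile)
    expect_true(all(sup$support >= -1e-12 & sup$support <= 1 + 1e-12))
  }
})
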