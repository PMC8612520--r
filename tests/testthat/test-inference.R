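test_that("summarize_posterior matches the quantile oracle", {
  draws <- cbind(theta = (1:1000) / 100)
  s <- summarize_posterior(draws, level = 0.90)
  expect_equal(s$mean, mean(draws))
  expect_equal(s$lower, quantile(draws, 0.05, names = FALSE))
  expect_equal(s$upper, quantile(draws, 0.95, names = FALSE))

  const <- cbind(theta = rep(3.5, 100))
  sc <- summarize_posterior(const)
  expect_equal(c(sc$mean, sc$lower, sc$upper), rep(3.5, 3))

  wide <- summarize_posterior(cbind(x = rnorm(2000)), level = 0.9)
  narrow <- summarize_posterior(cbind(x = rnorm(2000)), level = 0.5)
  expect_lt(narrow$upper - narrow$lower, wide$upper - wide$lower)

  expect_error(summarize_posterior(draws, level = 1.2),
               class = "cg_contract_error")
})

test_that("waic matches closed forms and a naive implementation", {
  # constant draws: lppd = c, p_waic = 0, waic = -2c
  const <- matrix(-1.7, 50, 1)
  w <- waic(const)
  expect_equal(w$lppd, -1.7, tolerance = 1e-12)
  expect_equal(w$p_waic, 0, tolerance = 1e-12)
  expect_equal(w$waic, 3.4, tolerance = 1e-12)

  # two draws, one group
  two <- matrix(c(log(0.5), log(0.25)), 2, 1)
  w2 <- waic(two)
  expect_equal(w2$lppd, log(0.375), tolerance = 1e-12)
  expect_equal(w2$p_waic, var(c(log(0.5), log(0.25))), tolerance = 1e-12)

  # naive (unstable) route on well-scaled inputs
  set.seed(12)
  m <- matrix(rnorm(200, mean = -2, sd = 0.3), 20, 10)
  naive_lppd <- sum(log(colMeans(exp(m))))
  naive_p <- sum(apply(m, 2, var))
  w3 <- waic(m)
  expect_equal(w3$lppd, naive_lppd, tolerance = 1e-10)
  expect_equal(w3$waic, -2 * (naive_lppd - naive_p), tolerance = 1e-10)

  # stability: enormous negative log-likelihoods must not underflow to -Inf
  expect_true(is.finite(waic(matrix(c(-800, -801), 2, 1))$lppd))

  expect_error(waic(matrix(0, 1, 3)), class = "cg_contract_error")
})

test_that("model weights are normalized exp(-D/2) over the whole set", {
  cmp <- compare_models(c(a = 10, b = 12))
  expect_equal(cmp$D, c(0, 2))
  expect_equal(cmp$W, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)

  one <- compare_models(5)
  expect_equal(one$D, 0)
  expect_equal(one$W, 1)

  eq <- compare_models(c(5, 5, 5))
  expect_equal(eq$W, rep(1 / 3, 3))

  # invariants on an arbitrary set
  cmp2 <- compare_models(c(101.2, 99.4, 103.8, 99.4))
  expect_equal(min(cmp2$D), 0)
  expect_equal(sum(cmp2$W), 1, tolerance = 1e-9)
  expect_true(all(diff(cmp2$W[order(cmp2$D)]) <= 1e-12))
})

test_that("base-model posterior recovers pooled category proportions", {
  pooled <- count_matrix(matrix(c(23L, 85L, 60L), 1, 3,
                                dimnames = list("ALL", goal_categories())))
  cov <- covariates_df(group_id = "ALL")
  spec <- model_spec()
  dd <- build_design(cov, pooled, spec)
  fit <- suppressWarnings(sample_posterior(
    spec, dd$design, dd$counts,
    mcmc = mcmc_config(chains = 2, warmup = 600, iter = 1500, seed = 2)))
  eta <- cbind(solitary = fit$draws[, "alpha[solitary]"], competitive = 0,
               cooperative = fit$draws[, "alpha[cooperative]"])
  p_hat <- colMeans(softmax_rows(eta))
  expect_equal(unname(p_hat), c(23, 85, 60) / 168, tolerance = 0.02)
})

test_that("fixed seed and chains give identical posterior summaries", {
  counts <- count_matrix(matrix(c(3L, 9L, 6L, 1L, 5L, 2L), 2, 3,
                                byrow = TRUE,
                                dimnames = list(c("G01", "G02"),
                                                goal_categories())))
  cov <- covariates_df(group_id = c("G01", "G02"),
                       land_hunt = c("present", "absent"))
  spec <- model_spec("land_hunt")
  dd <- build_design(cov, counts, spec)
  mc <- mcmc_config(chains = 2, warmup = 200, iter = 200, seed = 77)
  f1 <- suppressWarnings(sample_posterior(spec, dd$design, dd$counts,
                                          mcmc = mc))
  f2 <- suppressWarnings(sample_posterior(spec, dd$design, dd$counts,
                                          mcmc = mc))
  expect_identical(f1$draws, f2$draws)
  expect_identical(summarize_posterior(f1), summarize_posterior(f2))
})

test_that("stored pointwise log-likelihood agrees with the model module", {
  fit <- small_phylo_fit()
  S <- nrow(fit$draws)
  nonref <- c("solitary", "cooperative")
  idx <- sort(sample.int(S, 25))
  for (s in idx) {
    d <- fit$draws[s, ]
    phi <- cbind(d[sprintf("phi[%s,solitary]", fit$design$group_ids)],
                 d[sprintf("phi[%s,cooperative]", fit$design$group_ids)])
    params <- model_params(
      alpha = setNames(d[sprintf("alpha[%s]", nonref)], nonref),
      beta = matrix(d[sprintf("beta[%s,land_hunt]", nonref)], 2, 1,
                    dimnames = list(nonref, "land_hunt")),
      sigma = setNames(d[sprintf("sigma[%s]", nonref)], nonref),
      phi = phi)
    eta <- linear_predictor(params, fit$design)
    ll <- log_likelihood(fit$counts, eta)
    expect_equal(unname(fit$pointwise_loglik[s, ]), ll$pointwise,
                 tolerance = 1e-10)
  }
})

test_that("posterior draws carry diagnostics and labeled parameters", {
  fit <- small_phylo_fit()
  expect_true(all(c("alpha[solitary]", "alpha[cooperative]",
                    "beta[cooperative,land_hunt]", "sigma[cooperative]") %in%
                    colnames(fit$draws)))
  expect_true(any(grepl("^phi\\[G01,", colnames(fit$draws))))
  expect_equal(nrow(fit$draws), 2 * 400)
  expect_equal(nrow(fit$diagnostics), ncol(fit$draws))
  expect_true(all(is.finite(fit$pointwise_loglik)))
  rh <- fit$diagnostics$rhat
  expect_true(all(rh[is.finite(rh)] > 0.8 & rh[is.finite(rh)] < 2))
})

test_that("contract violations in sample_posterior are rejected", {
  counts <- count_matrix(matrix(c(3L, 9L, 6L), 1, 3,
                                dimnames = list("G01", goal_categories())))
  cov <- covariates_df(group_id = "G01")
  dd <- build_design(cov, counts, model_spec())
  expect_error(
    sample_posterior(model_spec(use_phylo = TRUE), dd$design, dd$counts),
    class = "cg_contract_error")
  expect_error(
    sample_posterior(model_spec(), dd$design, dd$counts, C = diag(1)),
    class = "cg_contract_error")
})

test_that("effect_table lays out univariate and multivariate rows", {
  cfg <- sim_config(n_groups = 10, total_games_target = 60,
                    smallest_groups = 3, seed = 21)
  study <- simulate_study(cfg)
  battery <- list(
    base = model_spec(),
    land = model_spec("land_hunt"),
    mv = model_spec(c("intra_group_conflict", "land_hunt")))
  names(battery) <- vapply(battery, function(s) s$label, character(1))
  bat <- suppressWarnings(fit_battery(
    study$counts, study$covariates,
    mcmc = mcmc_config(chains = 2, warmup = 200, iter = 200, seed = 3),
    battery = battery))
  tab <- bat$table
  expect_equal(nrow(tab), 3)
  base_row <- tab[tab$model == "base", ]
  expect_true(is.na(base_row$predictor) && is.na(base_row$mean))
  expect_false(is.na(base_row$D) || is.na(base_row$W))
  uni <- tab[tab$model == "land_hunt", ]
  expect_false(is.na(uni$mean))
  expect_true(is.na(uni$predictor2))
  mv <- tab[tab$model == "intra_group_conflict+land_hunt", ]
  expect_equal(mv$predictor2, "land_hunt")
  expect_false(any(is.na(c(mv$mean, mv$mean2))))
  expect_equal(sum(bat$comparison$W), 1, tolerance = 1e-9)
  expect_equal(min(bat$comparison$D), 0)
})
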