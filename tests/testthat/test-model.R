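make_counts <- function(m, ids = sprintf("G%02d", seq_len(nrow(m)))) {
  dimnames(m) <- list(ids, goal_categories())
  count_matrix(m)
}

test_that("model_spec validates its arguments", {
  s <- model_spec("land_hunt", use_phylo = TRUE)
  expect_s3_class(s, "model_spec")
  expect_equal(s$reference_category, "competitive")
  expect_error(model_spec(c("a", "a")), class = "cg_validation_error")
  expect_error(model_spec(c("a", "b", "c")), class = "cg_validation_error")
  expect_error(model_spec(reference_category = "none"),
               class = "cg_validation_error")
  expect_error(model_spec(prior_scale_slope = -1),
               class = "cg_validation_error")
})

test_that("build_design recodes presence and drops incomplete cases", {
  counts <- make_counts(matrix(5L, 3, 3))
  cov <- covariates_df(group_id = sprintf("G%02d", 1:3),
                       land_hunt = c("present", "absent", "missing"))

  base <- build_design(cov, counts, model_spec())
  expect_equal(ncol(base$design$x), 0)
  expect_equal(base$design$group_ids, sprintf("G%02d", 1:3))
  expect_equal(nrow(base$design$dropped_groups), 0)

  uni <- build_design(cov, counts, model_spec("land_hunt"))
  expect_equal(as.vector(uni$design$x[, "land_hunt"]), c(1, 0))
  expect_equal(uni$design$dropped_groups$group_id, "G03")
  expect_match(uni$design$dropped_groups$reason, "land_hunt")
  expect_equal(rownames(uni$counts), uni$design$group_ids)

  allmiss <- covariates_df(group_id = sprintf("G%02d", 1:3),
                           land_hunt = "missing")
  expect_error(build_design(allmiss, counts, model_spec("land_hunt")),
               class = "cg_validation_error")
  expect_error(build_design(cov[1:2, ], counts, model_spec()),
               class = "cg_contract_error")
})

test_that("linear predictor pins the reference category at zero", {
  counts <- make_counts(matrix(2L, 2, 3))
  cov <- covariates_df(group_id = c("G01", "G02"),
                       land_hunt = c("present", "absent"))
  dd <- build_design(cov, counts, model_spec("land_hunt"))
  beta <- rbind(solitary = 0, cooperative = 0.92)
  colnames(beta) <- "land_hunt"
  p <- model_params(alpha = c(solitary = 0, cooperative = 0), beta = beta)
  eta <- linear_predictor(p, dd$design)
  expect_equal(eta[, "competitive"], c(G01 = 0, G02 = 0))
  # log-odds of cooperative vs competitive for an exposed group is beta
  expect_equal(eta["G01", "cooperative"] - eta["G01", "competitive"], 0.92)
  expect_equal(eta["G02", "cooperative"], 0)

  zero <- linear_predictor(
    model_params(alpha = c(solitary = 0, cooperative = 0),
                 beta = matrix(0, 2, 1)), dd$design)
  expect_equal(unname(softmax_rows(zero)),
               matrix(1 / 3, 2, 3))

  expect_error(
    linear_predictor(model_params(alpha = c(solitary = 0, cooperative = 0)),
                     dd$design),
    class = "cg_contract_error")
})

test_that("log-likelihood matches closed forms and the enumeration oracle", {
  y1 <- make_counts(matrix(c(2L, 0L, 0L), 1, 3), "A")
  ll <- log_likelihood(y1, matrix(0, 1, 3))
  expect_equal(ll$pointwise, log(1 / 9), tolerance = 1e-12)

  # probabilities (1/2, 1/2, ~0): mass of (1,1,0) is 2 * 1/4
  eta <- matrix(c(0, 0, -40), 1, 3)
  y2 <- make_counts(matrix(c(1L, 1L, 0L), 1, 3), "A")
  expect_equal(log_likelihood(y2, eta)$total, log(0.5), tolerance = 1e-8)

  set.seed(31)
  for (rep in 1:20) {
    N <- sample(0:5, 1)
    y <- as.vector(rmultinom(1, N, c(.2, .5, .3)))
    p <- rgamma(3, 1) + 0.05
    p <- p / sum(p)
    yc <- matrix(as.integer(y), 1, 3) # plain matrix: N = 0 is allowed here
    got <- log_likelihood(yc, matrix(log(p), 1, 3))$total
    expect_equal(got, enum_multinom_logmass(y, p), tolerance = 1e-10)
    expect_equal(got, dmultinom(y, prob = p, log = TRUE), tolerance = 1e-10)
  }

  expect_error(log_likelihood(matrix(-1L, 1, 3), matrix(0, 1, 3)),
               class = "cg_validation_error")
})

test_that("likelihood is invariant to shifting all scores of a group", {
  set.seed(8)
  y <- make_counts(matrix(as.integer(rmultinom(1, 30, c(.2, .5, .3))), 1, 3),
                   "A")
  eta <- matrix(rnorm(3), 1, 3)
  shifted <- eta + 7.3
  expect_equal(log_likelihood(y, eta)$total,
               log_likelihood(y, shifted)$total, tolerance = 1e-10)
  # stability contract: scores up to |40|
  expect_true(is.finite(log_likelihood(y, matrix(c(40, -40, 0), 1, 3))$total))
})

test_that("softmax rows sum to one", {
  set.seed(9)
  eta <- matrix(rnorm(300, sd = 10), 100, 3)
  expect_equal(rowSums(softmax_rows(eta)), rep(1, 100), tolerance = 1e-12)
})

test_that("log-prior matches closed forms and a dense MVN oracle", {
  spec <- model_spec("land_hunt")
  p0 <- model_params(alpha = c(solitary = 0, cooperative = 0),
                     beta = matrix(0, 2, 1))
  expect_equal(log_prior(p0, spec),
               4 * dnorm(0, 0, 2.5, log = TRUE), tolerance = 1e-12)

  tree <- read_newick(newick_file("((A:1,B:1):1,C:2);"))
  C <- phylo_covariance(tree)
  specp <- model_spec("land_hunt", use_phylo = TRUE)
  phi <- matrix(c(0.3, -0.2, 0.1, 0.05, -0.4, 0.2), 3, 2)
  pp <- model_params(alpha = c(solitary = 0.1, cooperative = -0.2),
                     beta = matrix(0.5, 2, 1),
                     sigma = c(0.7, 1.3), phi = phi)
  got <- log_prior(pp, specp, C)
  want <- sum(dnorm(pp$alpha, 0, 2.5, log = TRUE)) +
    sum(dnorm(pp$beta, 0, 2.5, log = TRUE)) +
    sum(log(2) + dnorm(pp$sigma, 0, 1, log = TRUE)) +
    dense_mvn_logpdf(phi[, 1], 0.7^2 * (C + diag(1e-8, 3))) +
    dense_mvn_logpdf(phi[, 2], 1.3^2 * (C + diag(1e-8, 3)))
  expect_equal(got, want, tolerance = 1e-6)

  # degenerate scale: zero sigma only supports zero effects
  pz <- pp
  pz$sigma <- c(0, 0)
  expect_equal(log_prior(pz, specp, C), -Inf)
  pz$phi <- matrix(0, 3, 2)
  expect_true(is.finite(log_prior(pz, specp, C)))
  pn <- pp
  pn$sigma <- c(-0.1, 1)
  expect_equal(log_prior(pn, specp, C), -Inf)
})

test_that("simulate_counts is seed-reproducible and law-of-large-numbers sane", {
  cov <- covariates_df(group_id = "G01")
  counts <- make_counts(matrix(1L, 1, 3))
  dd <- build_design(cov, counts, model_spec())
  p <- model_params(alpha = c(solitary = 0, cooperative = 0))

  big <- simulate_counts(p, dd$design, totals = 30000, seed = 4)
  expect_equal(as.vector(big) / 30000, rep(1 / 3, 3), tolerance = 0.01)

  a <- simulate_counts(p, dd$design, totals = 50, seed = 10)
  b <- simulate_counts(p, dd$design, totals = 50, seed = 10)
  expect_identical(a, b)

  none <- simulate_counts(p, dd$design, totals = 0, seed = 1)
  expect_equal(nrow(none), 0) # zero-total groups carry no information

  set.seed(123)
  simulate_counts(p, dd$design, totals = 10, seed = 99)
  after_sim <- runif(1)
  set.seed(123)
  expect_identical(runif(1), after_sim) # caller RNG untouched by seeded draw
})
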