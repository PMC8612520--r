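# Fixture builders shared across test files. Everything is generated in
# code; files only ever land in tempdirs.

games_df <- function(goal_structure = c("solitary", "competitive",
                                        "cooperative"),
                     group_id = "G01", abvd_linked = TRUE,
                     describable = TRUE, local_origin = TRUE,
                     period_start = 1880L, period_end = 1920L) {
  n <- length(goal_structure)
  data.frame(game_id = sprintf("g%03d", seq_len(n)),
             group_id = rep_len(group_id, n),
             goal_structure = goal_structure,
             abvd_linked = rep_len(abvd_linked, n),
             describable = rep_len(describable, n),
             local_origin = rep_len(local_origin, n),
             period_start = rep_len(period_start, n),
             period_end = rep_len(period_end, n))
}

covariates_df <- function(group_id = "G01", time_focus = 1900L, ...) {
  df <- data.frame(group_id = group_id)
  vals <- list(...)
  for (cv in covariate_names()) {
    df[[cv]] <- rep_len(if (is.null(vals[[cv]])) "present" else vals[[cv]],
                        length(group_id))
  }
  df$time_focus <- rep_len(time_focus, length(group_id))
  df
}

write_tmp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

newick_file <- function(text) {
  path <- tempfile(fileext = ".nwk")
  writeLines(text, path)
  path
}

# Exhaustive-enumeration oracle for the multinomial log-mass of a count
# triple: enumerates every outcome with the same total, checks the masses
# sum to 1, and returns the target outcome's log mass.
enum_multinom_logmass <- function(y, p) {
  N <- sum(y)
  grid <- expand.grid(a = 0:N, b = 0:N, c = 0:N)
  grid <- grid[rowSums(grid) == N, , drop = FALSE]
  mass <- apply(grid, 1, function(t) {
    factorial(N) / prod(factorial(t)) * prod(p^t)
  })
  stopifnot(abs(sum(mass) - 1) < 1e-9)
  unname(log(mass[grid$a == y[1] & grid$b == y[2] & grid$c == y[3]]))
}

# Dense multivariate-normal log-density oracle (direct determinant and
# quadratic form; independent of the Cholesky route used in log_prior).
dense_mvn_logpdf <- function(x, Sigma) {
  k <- length(x)
  -0.5 * (k * log(2 * pi) + log(det(Sigma)) +
            drop(t(x) %*% solve(Sigma) %*% x))
}

# A small cached phylo fit reused by several inference tests.
small_fit_cache <- new.env()
small_phylo_fit <- function() {
  if (is.null(small_fit_cache$fit)) {
    cfg <- sim_config(n_groups = 12, total_games_target = 80,
                      smallest_groups = 4,
                      true_beta = c(land_hunt = 1), seed = 42)
    study <- simulate_study(cfg)
    spec <- model_spec("land_hunt", use_phylo = TRUE)
    dd <- build_design(study$covariates, study$counts, spec)
    C <- phylo_covariance(study$tree)
    fit <- suppressWarnings(sample_posterior(
      spec, dd$design, dd$counts, C,
      mcmc_config(chains = 2, warmup = 400, iter = 400, seed = 5)))
    small_fit_cache$fit <- fit
  }
  small_fit_cache$fit
}
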