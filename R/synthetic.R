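#' Configuration of a synthetic study
#'
#' The defaults mirror the shape of the empirical study the pipeline is
#' built for: 25 ethnolinguistic groups on an ultrametric language tree,
#' 168 games in total, heavily skewed per-group totals with 11 groups
#' contributing only 1-3 games, three collapsed outcome categories, and
#' binary covariates with occasional missingness. True intercepts default
#' to the pooled analysis-sample proportions (23/85/60 over
#' solitary/competitive/cooperative, reference competitive).
#'
#' @param n_groups Number of groups / tree tips (default 25).
#' @param total_games_target Total number of games (default 168).
#' @param smallest_groups Number of groups forced to 1-3 games
#'   (default 11).
#' @param true_alpha Named length-2 vector of intercepts for the
#'   non-reference categories (`solitary`, `cooperative`), log-odds vs
#'   competitive.
#' @param true_beta Named vector of true effects of each covariate on the
#'   cooperative-vs-competitive log-odds (the solitary equation gets slope
#'   0); defaults to all zero.
#' @param true_sigma Scale of the phylogenetic random effects on both
#'   non-reference categories (default 0.5).
#' @param predictor_prevalence Probability a covariate is `present`
#'   (default 0.5).
#' @param missing_rate Probability a covariate value is masked as
#'   `missing` in the emitted table (default 0).
#' @param phylo_signal_predictors If `TRUE`, covariates are generated by
#'   thresholding a Brownian trait on the tree (phylogenetically
#'   autocorrelated) instead of iid coin flips.
#' @param plant_violations If `TRUE`, six extra games are added, each
#'   engineered to fail exactly one filtering step.
#' @param time_focus Covariate reference year (default 1900).
#' @param window_years Temporal filter half-width (default 50).
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_groups = 25, total_games_target = 168,
                       smallest_groups = 11,
                       true_alpha = c(solitary = log(23 / 85),
                                      cooperative = log(60 / 85)),
                       true_beta = setNames(rep(0, 6), covariate_names()),
                       true_sigma = 0.5,
                       predictor_prevalence = 0.5,
                       missing_rate = 0,
                       phylo_signal_predictors = FALSE,
                       plant_violations = FALSE,
                       time_focus = 1900, window_years = 50,
                       seed = 1) {
  if (n_groups < 2) cg_validation_error("n_groups must be >= 2")
  if (total_games_target < n_groups) {
    cg_validation_error("total_games_target must be >= n_groups")
  }
  if (smallest_groups < 0 || smallest_groups > n_groups) {
    cg_validation_error("smallest_groups out of range")
  }
  if (predictor_prevalence <= 0 || predictor_prevalence >= 1) {
    cg_validation_error("predictor_prevalence must be in (0, 1)")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    cg_validation_error("missing_rate must be in [0, 1)")
  }
  if (true_sigma < 0) cg_validation_error("true_sigma must be >= 0")
  tb <- setNames(rep(0, 6), covariate_names())
  tb[names(true_beta)] <- true_beta
  structure(list(n_groups = as.integer(n_groups),
                 total_games_target = as.integer(total_games_target),
                 smallest_groups = as.integer(smallest_groups),
                 true_alpha = true_alpha, true_beta = tb,
                 true_sigma = true_sigma,
                 predictor_prevalence = predictor_prevalence,
                 missing_rate = missing_rate,
                 phylo_signal_predictors = isTRUE(phylo_signal_predictors),
                 plant_violations = isTRUE(plant_violations),
                 time_focus = as.integer(time_focus),
                 window_years = as.integer(window_years),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a pure-birth (Yule) tree
#'
#' Birth-death simulation with zero extinction conditioned on the tip
#' count, rescaled to unit root-to-tip depth, tips relabeled `G01`,
#' `G02`, ...
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed.
#' @return An ultrametric `phylo` object with depth 1.
#' @export
simulate_tree <- function(n_tips, seed = NULL) {
  if (n_tips < 2) cg_validation_error("n_tips must be >= 2")
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree)[seq_len(n_tips)])
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("G%02d", seq_len(n_tips))
  tree
}

#' Simulate binary cultural covariates on a tree
#'
#' Each covariate is drawn either iid Bernoulli(prevalence) across tips
#' or, with `phylo_signal_predictors`, by simulating a Brownian trait on
#' the tree (MVN with the tree's covariance) and marking as `present` the
#' tips above the trait's (1 - prevalence) empirical quantile, giving
#' phylogenetically autocorrelated presence patterns. Missingness is then
#' applied iid at `missing_rate`.
#'
#' @param tree A `phylo` object whose tips are the groups.
#' @param config A [sim_config()].
#' @return A covariate data frame in the [read_covariates()] layout.
#' @export
simulate_covariates <- function(tree, config) {
  tips <- tree$tip.label
  J <- length(tips)
  with_seed(config$seed + 1L, {
    df <- data.frame(group_id = tips)
    if (config$phylo_signal_predictors) {
      L <- chol_lower(phylo_covariance(tree))
    }
    for (cv in covariate_names()) {
      if (config$phylo_signal_predictors) {
        z <- as.vector(L %*% rnorm(J))
        pres <- z > stats::quantile(z, 1 - config$predictor_prevalence)
      } else {
        pres <- runif(J) < config$predictor_prevalence
      }
      v <- ifelse(pres, "present", "absent")
      v[runif(J) < config$missing_rate] <- "missing"
      df[[cv]] <- v
    }
    df$time_focus <- config$time_focus
    df
  })
}

#' Simulate skewed per-group game totals
#'
#' `smallest_groups` randomly chosen groups get totals drawn uniformly
#' from 1-3 (clamped so the target stays feasible); the remaining games
#' are spread over the other groups by a gamma-weighted multinomial
#' allocation with every group guaranteed at least one game. Totals sum
#' exactly to `total_games_target`.
#'
#' @param config A [sim_config()].
#' @return Named integer vector of totals, one per group.
#' @export
simulate_group_totals <- function(config) {
  J <- config$n_groups
  total <- config$total_games_target
  with_seed(config$seed + 2L, {
    ids <- sprintf("G%02d", seq_len(J))
    small <- sample(ids, config$smallest_groups)
    big <- setdiff(ids, small)
    n <- setNames(rep(1L, J), ids)
    n[small] <- sample(1:3, length(small), replace = TRUE)
    # keep enough games for the non-small groups to get >= 1 each
    excess <- function() sum(n[small]) - (total - length(big))
    while (length(small) && excess() > 0) {
      i <- small[which.max(n[small])]
      n[i] <- n[i] - 1L
    }
    if (length(big)) {
      # non-small groups get at least 4 games when the target allows, so
      # the count of 1-3-game groups is exactly `smallest_groups`
      floor_big <- if (total - sum(n[small]) >= 4L * length(big)) 4L else 1L
      rest <- total - sum(n[small]) - floor_big * length(big)
      w <- rgamma(length(big), shape = 0.8)
      n[big] <- floor_big + if (rest > 0) {
        as.integer(rmultinom(1, rest, w / sum(w)))
      } else 0L
    }
    n
  })
}

# Split one group's collapsed-category counts uniformly across that
# category's fine-grained codes, emitting one game row per game.
emit_games <- function(counts, config) {
  members <- split(goal_codes(), collapse_goal_structure(goal_codes()))
  rows <- list()
  for (g in rownames(counts)) {
    for (k in goal_categories()) {
      n <- counts[g, k]
      if (n == 0) next
      codes <- members[[k]]
      alloc <- as.integer(rmultinom(1, n, rep(1, length(codes))))
      rows[[length(rows) + 1L]] <- data.frame(
        group_id = g, goal_structure = rep(codes, alloc))
    }
  }
  df <- do.call(rbind, rows)
  start <- config$time_focus - sample(0:40, nrow(df), replace = TRUE)
  data.frame(game_id = sprintf("game%04d", seq_len(nrow(df))),
             group_id = df$group_id, goal_structure = df$goal_structure,
             abvd_linked = TRUE, describable = TRUE, local_origin = TRUE,
             period_start = start,
             period_end = start + sample(0:30, nrow(df), replace = TRUE))
}

# One extra game per filtering step, each passing every earlier step and
# failing exactly its own. The step-v game uses an extra tip that is on
# the tree but absent from the covariate table.
planted_violations <- function(config, extra_tip) {
  tf <- config$time_focus
  base <- data.frame(
    game_id = sprintf("bad_%s", c("abvd", "describe", "origin", "tree",
                                  "covariates", "time")),
    group_id = c("G01", "G01", "G01", "not_a_tip", extra_tip, "G01"),
    goal_structure = "competitive",
    abvd_linked = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    describable = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    local_origin = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    period_start = tf, period_end = tf)
  base$period_start[6] <- tf + config$window_years + 1L
  base$period_end[6] <- tf + config$window_years + 10L
  base
}

#' Simulate a complete synthetic study
#'
#' Composes [simulate_tree()], [simulate_covariates()],
#' [simulate_group_totals()] and [simulate_counts()] (with phylogenetic
#' random effects drawn from MVN(0, sigma^2 C)), then emits a game table
#' at the fine-grained six-code granularity by splitting each collapsed
#' category uniformly across its member codes — so the full ingest path,
#' including the collapse, is exercised. All filter flags pass by
#' default; `plant_violations` adds one engineered failure per step.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_study`: `tree`, `covariates`, `games`,
#'   `counts` (the generator's internal [count_matrix()]), `totals`,
#'   `params` (the true [model_params()]), `design` (the true-model
#'   design over all covariates), and `config`.
#' @export
simulate_study <- function(config) {
  n_tips <- config$n_groups + as.integer(config$plant_violations)
  tree <- simulate_tree(n_tips, config$seed)
  groups <- sprintf("G%02d", seq_len(config$n_groups))
  covariates <- simulate_covariates(
    if (config$plant_violations) prune_tree(tree, groups) else tree, config)
  totals <- simulate_group_totals(config)

  # true design uses the pre-missingness binary values
  x_full <- with_seed(config$seed + 3L, {
    x <- matrix(0, config$n_groups, 6,
                dimnames = list(groups, covariate_names()))
    for (cv in covariate_names()) {
      v <- covariates[[cv]]
      v[v == "missing"] <- sample(c("present", "absent"),
                                  sum(v == "missing"), replace = TRUE)
      x[, cv] <- as.numeric(v == "present")
    }
    x
  })
  design <- structure(list(group_ids = groups, x = x_full,
                           dropped_groups = data.frame(
                             group_id = character(0),
                             reason = character(0))),
                      class = "design_matrix")
  beta <- rbind(solitary = rep(0, 6), cooperative = config$true_beta)
  colnames(beta) <- covariate_names()
  phi <- NULL
  if (config$true_sigma > 0) {
    C <- phylo_covariance(if (config$plant_violations)
      prune_tree(tree, groups) else tree)
    L <- chol_lower(C[groups, groups])
    phi <- with_seed(config$seed + 4L, {
      config$true_sigma * cbind(L %*% rnorm(length(groups)),
                                L %*% rnorm(length(groups)))
    })
    colnames(phi) <- c("solitary", "cooperative")
  }
  params <- model_params(alpha = config$true_alpha, beta = beta,
                         sigma = rep(config$true_sigma, 2), phi = phi)
  counts <- simulate_counts(params, design, totals, seed = config$seed + 5L)
  games <- with_seed(config$seed + 6L, emit_games(counts, config))
  if (config$plant_violations) {
    games <- rbind(games, planted_violations(
      config, sprintf("G%02d", n_tips)))
  }
  structure(list(tree = tree, covariates = covariates, games = games,
                 counts = counts, totals = totals, params = params,
                 design = design, config = config),
            class = "sim_study")
}

#' Write a synthetic study to disk
#'
#' Emits exactly the formats the ingest and phylogeny modules read:
#' `games.csv`, `covariates.csv`, and `tree.nwk`.
#'
#' @param study A `sim_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(games = file.path(dir, "games.csv"),
             covariates = file.path(dir, "covariates.csv"),
             tree = file.path(dir, "tree.nwk"))
  utils::write.csv(study$games, paths["games"], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(study$covariates, paths["covariates"], row.names = FALSE,
                   quote = FALSE)
  ape::write.tree(study$tree, paths["tree"])
  invisible(paths)
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates a study, fits the specified univariate model to
#' the simulated counts, and summarizes how well the posterior recovers
#' the generating effect: per-truth bias and RMSE of the posterior mean,
#' and empirical coverage of the 90% credible interval.
#'
#' @param config A [sim_config()]; its `seed` seeds replicate r as
#'   `seed + 1000 * r`.
#' @param replicates Number of simulated studies.
#' @param mcmc An [mcmc_config()].
#' @param predictor Covariate whose effect is estimated (default
#'   `land_hunt`).
#' @param true_betas Vector of generating effects cycled over replicates;
#'   default the single value in `config$true_beta[predictor]`.
#' @param use_phylo Fit with phylogenetic controls? Default `TRUE`.
#' @param level Credible level for the coverage check (default 0.90).
#' @return A list of class `recovery_report`: `replicates` (one row per
#'   fit: truth, posterior mean/sd/interval, coverage indicator) and
#'   `summary` (per-truth bias, RMSE, coverage).
#' @export
recovery_experiment <- function(config, replicates, mcmc = mcmc_config(),
                                predictor = "land_hunt", true_betas = NULL,
                                use_phylo = TRUE, level = 0.90) {
  if (replicates < 1) cg_contract_error("replicates must be >= 1")
  if (is.null(true_betas)) true_betas <- config$true_beta[predictor]
  spec <- model_spec(predictor, use_phylo = use_phylo)
  par_name <- sprintf("beta[cooperative,%s]", predictor)
  rows <- lapply(seq_len(replicates), function(r) {
    truth <- true_betas[(r - 1L) %% length(true_betas) + 1L]
    cfg <- config
    cfg$seed <- config$seed + 1000L * r
    cfg$true_beta[predictor] <- truth
    cfg$missing_rate <- 0 # recovery isolates estimation, not missingness
    study <- simulate_study(cfg)
    dd <- build_design(study$covariates, study$counts, spec)
    C <- if (use_phylo) phylo_covariance(study$tree)
    m <- mcmc
    m$seed <- cfg$seed
    fit <- suppressWarnings(
      sample_posterior(spec, dd$design, dd$counts, C = C, mcmc = m))
    dr <- fit$draws[, par_name]
    a <- (1 - level) / 2
    q <- stats::quantile(dr, c(a, 1 - a), names = FALSE)
    data.frame(replicate = r, truth = truth, mean = mean(dr),
               sd = stats::sd(dr), lower = q[1], upper = q[2],
               covered = q[1] <= truth & truth <= q[2])
  })
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(reps, reps$truth), function(d) {
    data.frame(truth = d$truth[1], n = nrow(d),
               bias = mean(d$mean - d$truth),
               rmse = sqrt(mean((d$mean - d$truth)^2)),
               coverage = mean(d$covered))
  }))
  rownames(summ) <- NULL
  structure(list(replicates = reps, summary = summ,
                 overall = data.frame(
                   n = nrow(reps),
                   bias = mean(reps$mean - reps$truth),
                   rmse = sqrt(mean((reps$mean - reps$truth)^2)),
                   coverage = mean(reps$covered))),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("recovery_report\n")
  print(x$summary, digits = 3, ...)
  cat("overall:\n")
  print(x$overall, digits = 3, ...)
  invisible(x)
}
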