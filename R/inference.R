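#' MCMC settings
#'
#' @param chains Number of chains (default 4).
#' @param warmup Iterations per chain used for adaptation + burn-in
#'   (default 1000).
#' @param iter Kept iterations per chain (default 1000).
#' @param seed Integer base seed; each chain gets a distinct RNG stream
#'   derived from it.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4, warmup = 1000, iter = 1000, seed = 1) {
  stopifnot(chains >= 1, warmup >= 2, iter >= 2)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), seed = as.integer(seed)),
            class = "mcmc_config")
}

cg_warn <- function(msg, class) {
  warning(warningCondition(paste0(msg, "\n"),
                           class = c(class, "coopgames_warning")))
}

# Build the JAGS model string for a given predictor count / phylo flag.
# The reference category's score is fixed at 0; m = 1, 2 indexes the
# non-reference categories in canonical order.
build_jags_model <- function(P, use_phylo, sigma_fixed = FALSE) {
  eta_term <- function(m, k) {
    t <- sprintf("    eta[j,%d] <- alpha[%d]", k, m)
    if (P > 0) t <- paste0(t, sprintf(" + inprod(beta[%d,1:P], x[j,1:P])", m))
    if (use_phylo) t <- paste0(t, sprintf(" + phi[j,%d]", m))
    t
  }
  lines <- c(
    "model {",
    "  for (j in 1:J) {",
    "    y[j,1:3] ~ dmulti(p[j,1:3], N[j])",
    "    for (k in 1:3) {",
    "      e[j,k] <- exp(eta[j,k])",
    "      p[j,k] <- e[j,k] / sum(e[j,1:3])",
    "    }",
    "    eta[j,ref] <- 0",
    eta_term(1, -1L), # placeholders replaced below
    eta_term(2, -2L),
    "  }",
    "  for (m in 1:2) {",
    "    alpha[m] ~ dnorm(0, prec_alpha)")
  if (P > 0) lines <- c(lines,
    "    for (q in 1:P) { beta[m,q] ~ dnorm(0, prec_beta) }")
  if (use_phylo) {
    lines <- c(lines,
    "    for (j in 1:J) {",
    "      z[j,m] ~ dnorm(0, 1)",
    "      phi[j,m] <- sigma[m] * inprod(L[j,1:J], z[1:J,m])",
    "    }")
    if (!sigma_fixed) lines <- c(lines,
    "    sigma[m] ~ dnorm(0, prec_sigma) T(0,)")
  }
  c(lines, "  }", "}")
}

#' Sample the posterior of a multinomial regression model
#'
#' Runs MCMC (via JAGS) on the posterior defined by the package's
#' multinomial likelihood ([log_likelihood()]) and priors ([log_prior()]).
#' Phylogenetic random effects use a non-centered parameterization
#' `phi = sigma L z` with `L` the (jittered) Cholesky factor of `C`.
#' Pointwise log-likelihoods per group per draw are recomputed in R from
#' the monitored draws and stored for WAIC.
#'
#' @param spec A [model_spec()].
#' @param design A `design_matrix` from [build_design()].
#' @param counts The matching [count_matrix()].
#' @param C Phylogenetic covariance ([phylo_covariance()]); required iff
#'   `spec$use_phylo`. Rows/columns must cover the design's groups.
#' @param mcmc An [mcmc_config()].
#' @param sigma_fixed Optional non-negative value(s) at which to fix the
#'   random-effect scales instead of sampling them (used for
#'   degenerate-limit checks).
#' @return An object of class `posterior_draws`: combined draw matrix
#'   (`draws`, columns like `beta[cooperative,land_hunt]`), the per-chain
#'   `coda` samples, `pointwise_loglik` (draws x groups), convergence
#'   `diagnostics` (split R-hat, effective sample size), and the inputs.
#'   Warns (class `cg_convergence_warning`) if any split R-hat exceeds
#'   1.01 or any ESS falls below 400.
#' @export
sample_posterior <- function(spec, design, counts, C = NULL,
                             mcmc = mcmc_config(), sigma_fixed = NULL) {
  J <- length(design$group_ids)
  if (!identical(rownames(counts), design$group_ids)) {
    cg_contract_error("counts and design group order differ")
  }
  if (spec$use_phylo && is.null(C)) {
    cg_contract_error("spec$use_phylo is TRUE but no covariance C given")
  }
  if (!spec$use_phylo && !is.null(C)) {
    cg_contract_error("C supplied for a non-phylogenetic model")
  }
  nonref <- nonref_categories(spec)
  ref_idx <- match(spec$reference_category, goal_categories())
  nonref_idx <- match(nonref, goal_categories())
  P <- length(spec$predictors)

  y <- unclass(counts)[, goal_categories(), drop = FALSE]
  dat <- list(y = y, N = rowSums(y), J = J, ref = ref_idx,
              prec_alpha = 1 / spec$prior_scale_intercept^2)
  if (P > 0) {
    dat$x <- design$x
    dat$P <- P
    dat$prec_beta <- 1 / spec$prior_scale_slope^2
  }
  if (spec$use_phylo) {
    missing_tips <- setdiff(design$group_ids, rownames(C))
    if (length(missing_tips)) {
      cg_contract_error(sprintf("groups absent from covariance: %s",
                                paste(missing_tips, collapse = ", ")))
    }
    dat$L <- chol_lower(C[design$group_ids, design$group_ids])
    if (is.null(sigma_fixed)) {
      dat$prec_sigma <- 1 / spec$prior_scale_sigma^2
    } else {
      if (any(sigma_fixed < 0)) cg_validation_error("sigma_fixed must be >= 0")
      dat$sigma <- rep(sigma_fixed, length.out = 2)
    }
  }

  code <- build_jags_model(P, spec$use_phylo, !is.null(sigma_fixed))
  code <- sub("eta\\[j,-1\\]", sprintf("eta[j,%d]", nonref_idx[1]), code)
  code <- sub("eta\\[j,-2\\]", sprintf("eta[j,%d]", nonref_idx[2]), code)

  inits <- lapply(seq_len(mcmc$chains), function(ch) {
    list(.RNG.name = "base::Wichmann-Hill",
         .RNG.seed = (mcmc$seed * 1009L + ch) %% 2147483629L)
  })
  adapt <- max(100L, mcmc$warmup %/% 2L)
  burn <- mcmc$warmup - adapt
  monitors <- c("alpha",
                if (P > 0) "beta",
                if (spec$use_phylo && is.null(sigma_fixed)) "sigma",
                if (spec$use_phylo) "phi")
  samples <- tryCatch({
    jm <- rjags::jags.model(textConnection(paste(code, collapse = "\n")),
                            data = dat, inits = inits,
                            n.chains = mcmc$chains, n.adapt = adapt,
                            quiet = TRUE)
    if (burn > 0) update(jm, burn)
    rjags::coda.samples(jm, variable.names = monitors, n.iter = mcmc$iter)
  }, error = function(e) cg_inference_error(
    sprintf("sampling failed: %s", conditionMessage(e))))

  rename <- jags_name_map(coda::varnames(samples), spec, design)
  samples <- lapply(samples, function(m) {
    colnames(m) <- rename[colnames(m)]
    m[, order(match(colnames(m), rename)), drop = FALSE]
  })
  class(samples) <- "mcmc.list"
  draws <- do.call(rbind, lapply(samples, as.matrix))

  diagnostics <- data.frame(
    parameter = colnames(draws),
    rhat = vapply(colnames(draws), function(p) {
      split_rhat(sapply(samples, function(m) as.numeric(m[, p])))
    }, numeric(1)),
    ess = tryCatch(as.numeric(coda::effectiveSize(samples)),
                   error = function(e) rep(NA_real_, ncol(draws))),
    row.names = NULL)

  fit <- structure(list(draws = draws, samples = samples, spec = spec,
                        design = design, counts = counts,
                        chains = mcmc$chains, mcmc = mcmc,
                        sigma_fixed = sigma_fixed),
                   class = "posterior_draws")
  fit$pointwise_loglik <- pointwise_loglik_matrix(fit)
  fit$diagnostics <- diagnostics

  bad_rhat <- diagnostics$rhat[is.finite(diagnostics$rhat)] > 1.01
  low_ess <- diagnostics$ess[is.finite(diagnostics$ess)] < 400
  if (any(bad_rhat) || any(low_ess)) {
    cg_warn(sprintf(
      "convergence: %d parameter(s) with split R-hat > 1.01, %d with ESS < 400",
      sum(bad_rhat), sum(low_ess)), "cg_convergence_warning")
  }
  fit
}

# Map JAGS variable names (alpha[1], beta[1,2], phi[3,1], sigma[2]) to
# labeled names (alpha[solitary], beta[solitary,water_hunt], ...).
jags_name_map <- function(vars, spec, design) {
  nonref <- nonref_categories(spec)
  out <- setNames(vars, vars)
  for (v in vars) {
    m <- regmatches(v, regexec("^([a-z]+)\\[([0-9]+)(,([0-9]+))?\\]$", v))[[1]]
    if (!length(m)) next
    base <- m[2]; i <- as.integer(m[3])
    j <- if (nzchar(m[5])) as.integer(m[5]) else NA_integer_
    out[v] <- switch(base,
      alpha = sprintf("alpha[%s]", nonref[i]),
      sigma = sprintf("sigma[%s]", nonref[i]),
      beta  = sprintf("beta[%s,%s]", nonref[i], spec$predictors[j]),
      phi   = sprintf("phi[%s,%s]", design$group_ids[i], nonref[j]),
      v)
  }
  out
}

# Split-half R-hat (rank-free version of the standard split statistic).
# x: iterations x chains matrix. NA when draws are constant.
split_rhat <- function(x) {
  x <- as.matrix(x)
  half <- nrow(x) %/% 2L
  if (half < 2L) return(NA_real_)
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[nrow(x) - half + seq_len(half), , drop = FALSE])
  W <- mean(apply(sub, 2, stats::var))
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- half * stats::var(colMeans(sub))
  sqrt(((half - 1) / half * W + B / half) / W)
}

# Pointwise log-likelihood (draws x groups), vectorized over draws; agrees
# with looping linear_predictor() + log_likelihood() over draws (tested).
pointwise_loglik_matrix <- function(fit) {
  spec <- fit$spec; design <- fit$design
  draws <- fit$draws
  y <- unclass(fit$counts)
  S <- nrow(draws); J <- nrow(y)
  nonref <- nonref_categories(spec)
  E <- setNames(vector("list", 3), goal_categories())
  E[[spec$reference_category]] <- matrix(0, S, J)
  for (k in nonref) {
    Ek <- matrix(draws[, sprintf("alpha[%s]", k)], S, J)
    for (q in spec$predictors) {
      Ek <- Ek + outer(draws[, sprintf("beta[%s,%s]", k, q)],
                       design$x[, q])
    }
    if (spec$use_phylo) {
      Ek <- Ek + draws[, sprintf("phi[%s,%s]", design$group_ids, k),
                       drop = FALSE]
    }
    E[[k]] <- Ek
  }
  M <- pmax(E[[1]], E[[2]], E[[3]])
  logZ <- M + log(exp(E[[1]] - M) + exp(E[[2]] - M) + exp(E[[3]] - M))
  ll <- matrix(rep(lgamma(rowSums(y) + 1) - rowSums(lgamma(y + 1)),
                   each = S), S, J)
  for (k in goal_categories()) {
    ll <- ll + (E[[k]] - logZ) * rep(y[, k], each = S)
  }
  colnames(ll) <- rownames(y)
  ll
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("posterior_draws: model '%s', %d chains x %d draws, %d groups\n",
              x$spec$label, x$chains, nrow(x$draws) / x$chains,
              nrow(x$counts)))
  print(head(summarize_posterior(x), 10), ...)
  invisible(x)
}

#' Posterior summaries: means and central credible intervals
#'
#' @param fit A `posterior_draws` object (or a plain draw matrix).
#' @param level Credible-interval mass in (0, 1); default 0.90
#'   (equal-tailed, 5th-95th percentiles).
#' @param pars Optional regular expression selecting parameters.
#' @return Data frame with columns `parameter`, `mean`, `lower`, `upper`.
#' @export
summarize_posterior <- function(fit, level = 0.90, pars = NULL) {
  if (!(is.numeric(level) && length(level) == 1L && level > 0 && level < 1)) {
    cg_contract_error("level must be in (0, 1)")
  }
  draws <- if (inherits(fit, "posterior_draws")) fit$draws else as.matrix(fit)
  if (!is.null(pars)) {
    draws <- draws[, grepl(pars, colnames(draws)), drop = FALSE]
  }
  a <- (1 - level) / 2
  q <- apply(draws, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  data.frame(parameter = colnames(draws),
             mean = unname(colMeans(draws)),
             lower = q[1, ], upper = q[2, ], row.names = NULL)
}

#' Watanabe-Akaike information criterion
#'
#' `lppd = sum_j log mean_d exp(loglik[d, j])` (computed via log-sum-exp),
#' `p_waic = sum_j var_d(loglik[d, j])` (sample variance, denominator
#' d - 1), `waic = -2 (lppd - p_waic)`.
#'
#' @param pointwise_loglik Matrix of log-likelihoods, draws x observation
#'   units (groups), or a `posterior_draws` object.
#' @return List with `waic`, `lppd`, `p_waic`.
#' @export
waic <- function(pointwise_loglik) {
  if (inherits(pointwise_loglik, "posterior_draws")) {
    pointwise_loglik <- pointwise_loglik$pointwise_loglik
  }
  m <- as.matrix(pointwise_loglik)
  if (nrow(m) < 2L) cg_contract_error("waic needs at least 2 draws")
  lppd <- sum(apply(m, 2, logsumexp) - log(nrow(m)))
  p_waic <- sum(apply(m, 2, stats::var))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

#' Compare models by WAIC
#'
#' Computes, for each model, the WAIC difference from the best model
#' (`D = waic - min(waic)`) and the normalized weight
#' `W = exp(-D/2) / sum exp(-D/2)` over the whole supplied set.
#'
#' @param waics Numeric vector of WAIC values (optionally named), or a
#'   list of [waic()] results.
#' @param labels Optional model labels.
#' @return Data frame with columns `model`, `waic`, `D`, `W`, sorted in
#'   input order.
#' @export
compare_models <- function(waics, labels = NULL) {
  if (is.list(waics) && !is.data.frame(waics)) {
    waics <- vapply(waics, function(w) if (is.list(w)) w$waic else w,
                    numeric(1))
  }
  if (!length(waics)) cg_contract_error("need at least one model")
  if (is.null(labels)) {
    labels <- if (!is.null(names(waics))) names(waics)
              else sprintf("model_%d", seq_along(waics))
  }
  D <- waics - min(waics)
  W <- exp(-D / 2)
  W <- W / sum(W)
  data.frame(model = labels, waic = unname(waics), D = unname(D),
             W = unname(W), row.names = NULL)
}
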