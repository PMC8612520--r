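#' Specify a multinomial regression model variant
#'
#' A model is defined by which binary cultural covariates enter as
#' predictors (0, 1 or 2 of them), whether phylogenetically correlated
#' random effects are included, the reference category of the multinomial
#' logit, and the prior scales. With reference category `competitive`
#' (the default), the slope on the `cooperative` equation is the change in
#' log-odds of cooperative relative to competitive games — the contrast
#' reported throughout.
#'
#' Priors are weakly regularizing: Normal(0, `prior_scale_intercept`) on
#' intercepts, Normal(0, `prior_scale_slope`) on slopes, and
#' half-Normal(`prior_scale_sigma`) on the phylogenetic random-effect
#' scales.
#'
#' @param predictors Character vector of 0-2 distinct covariate names.
#' @param use_phylo Include phylogenetically correlated random effects?
#' @param reference_category One of [goal_categories()]; default
#'   `"competitive"`.
#' @param prior_scale_intercept,prior_scale_slope,prior_scale_sigma
#'   Positive prior standard deviations (defaults 2.5, 2.5, 1).
#' @param label Optional display label; defaults to a label built from the
#'   predictors.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(predictors = character(), use_phylo = FALSE,
                       reference_category = "competitive",
                       prior_scale_intercept = 2.5,
                       prior_scale_slope = 2.5,
                       prior_scale_sigma = 1.0,
                       label = NULL) {
  predictors <- as.character(predictors)
  if (anyDuplicated(predictors)) {
    cg_validation_error("predictors must be distinct")
  }
  if (length(predictors) > 2L) {
    cg_validation_error("at most two predictors per model")
  }
  if (!reference_category %in% goal_categories()) {
    cg_validation_error(sprintf("reference_category must be one of: %s",
                                paste(goal_categories(), collapse = ", ")))
  }
  for (s in c(prior_scale_intercept, prior_scale_slope, prior_scale_sigma)) {
    if (!is.numeric(s) || length(s) != 1L || s <= 0) {
      cg_validation_error("prior scales must be positive numbers")
    }
  }
  if (is.null(label)) {
    label <- if (length(predictors)) paste(predictors, collapse = "+")
             else "base"
    if (use_phylo) label <- paste0(label, " (phylo)")
  }
  structure(list(predictors = predictors,
                 use_phylo = isTRUE(use_phylo),
                 reference_category = reference_category,
                 prior_scale_intercept = prior_scale_intercept,
                 prior_scale_slope = prior_scale_slope,
                 prior_scale_sigma = prior_scale_sigma,
                 label = label),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec '%s': predictors = [%s], phylo = %s, ref = %s\n",
              x$label, paste(x$predictors, collapse = ", "),
              x$use_phylo, x$reference_category))
  invisible(x)
}

# Non-reference categories in canonical order; their order defines the
# category index m used in parameter names and the JAGS model.
nonref_categories <- function(spec) {
  setdiff(goal_categories(), spec$reference_category)
}

#' Build the design matrix for a model
#'
#' Recodes predictor values `present` -> 1, `absent` -> 0. Any group with
#' a `missing` value on a predictor used by the model is dropped from both
#' the design and the count matrix (complete-case analysis per model); the
#' drops are recorded.
#'
#' @param covariates Data frame from [read_covariates()].
#' @param counts A [count_matrix()]; every group must have a covariate row.
#' @param spec A [model_spec()].
#' @return A list with `design` (class `design_matrix`: `group_ids`, the
#'   0/1 matrix `x`, and a `dropped_groups` data frame) and `counts` (the
#'   possibly reduced count matrix, same group order as the design).
#' @export
build_design <- function(covariates, counts, spec) {
  groups <- rownames(counts)
  missing_rows <- setdiff(groups, covariates$group_id)
  if (length(missing_rows)) {
    cg_contract_error(sprintf("groups without covariate rows: %s",
                              paste(missing_rows, collapse = ", ")))
  }
  cov <- covariates[match(groups, covariates$group_id), , drop = FALSE]
  P <- length(spec$predictors)
  dropped <- data.frame(group_id = character(0), reason = character(0))
  keep <- rep(TRUE, length(groups))
  if (P > 0L) {
    unknown <- setdiff(spec$predictors, names(cov))
    if (length(unknown)) {
      cg_schema_error(sprintf("predictor(s) not in covariate table: %s",
                              paste(unknown, collapse = ", ")))
    }
    for (p in spec$predictors) {
      miss <- cov[[p]] == "missing"
      if (any(miss & keep)) {
        dropped <- rbind(dropped, data.frame(
          group_id = groups[miss & keep],
          reason = sprintf("missing %s", p)))
      }
      keep <- keep & !miss
    }
  }
  if (!any(keep)) {
    cg_validation_error("all groups dropped: no complete cases for model")
  }
  groups <- groups[keep]
  x <- matrix(0, length(groups), P,
              dimnames = list(groups, spec$predictors))
  if (P > 0L) {
    cov <- cov[keep, , drop = FALSE]
    for (p in spec$predictors) {
      x[, p] <- as.numeric(cov[[p]] == "present")
    }
  }
  design <- structure(list(group_ids = groups, x = x,
                           dropped_groups = dropped),
                      class = "design_matrix")
  list(design = design, counts = counts[groups, , drop = FALSE])
}

#' Bundle model parameters
#'
#' @param alpha Named numeric of length 2: intercepts for the two
#'   non-reference categories (log-odds vs the reference).
#' @param beta Matrix (2 x P) of slopes, rows named by the non-reference
#'   categories, columns by predictors; may be NULL when P = 0.
#' @param sigma Named non-negative numeric of length 2: phylogenetic
#'   random-effect scales; NULL for non-phylo models.
#' @param phi Matrix (J x 2) of group-level random effects, columns named
#'   by the non-reference categories; NULL for non-phylo models.
#' @return A list of class `model_params`.
#' @export
model_params <- function(alpha, beta = NULL, sigma = NULL, phi = NULL) {
  if (length(alpha) != 2L || is.null(names(alpha))) {
    cg_contract_error("alpha must be a named length-2 vector")
  }
  if (!is.null(sigma) && any(sigma < 0)) {
    cg_validation_error("sigma must be non-negative")
  }
  structure(list(alpha = alpha, beta = beta, sigma = sigma, phi = phi),
            class = "model_params")
}

#' Per-group category scores (linear predictor)
#'
#' Computes the J x 3 matrix of category scores eta. The reference
#' category's column is identically zero (the identifiability constraint);
#' each non-reference category k gets
#' `alpha[k] + sum_p beta[k, p] x[j, p] + phi[j, k]`.
#'
#' @param params A [model_params()]; the non-reference categories are read
#'   from `names(params$alpha)`.
#' @param design A `design_matrix` from [build_design()].
#' @return Numeric matrix, rows = groups, columns = [goal_categories()].
#' @export
linear_predictor <- function(params, design) {
  cats <- goal_categories()
  nonref <- names(params$alpha)
  if (!all(nonref %in% cats) || length(unique(nonref)) != 2L) {
    cg_contract_error("alpha names must be two distinct goal categories")
  }
  J <- length(design$group_ids)
  eta <- matrix(0, J, 3, dimnames = list(design$group_ids, cats))
  P <- ncol(design$x)
  if (!is.null(params$beta)) {
    if (!is.matrix(params$beta) || ncol(params$beta) != P ||
        nrow(params$beta) != 2L) {
      cg_contract_error("beta must be a 2 x P matrix matching the design")
    }
  } else if (P > 0L) {
    cg_contract_error("design has predictors but params$beta is NULL")
  }
  if (!is.null(params$phi) &&
      (!is.matrix(params$phi) || nrow(params$phi) != J ||
       ncol(params$phi) != 2L)) {
    cg_contract_error("phi must be a J x 2 matrix matching the design")
  }
  for (m in 1:2) {
    k <- nonref[m]
    v <- rep(params$alpha[m], J)
    if (P > 0L) v <- v + as.vector(design$x %*% params$beta[m, ])
    if (!is.null(params$phi)) v <- v + params$phi[, m]
    eta[, k] <- v
  }
  eta
}

#' Row-wise softmax
#'
#' Numerically stable: subtracts the row maximum before exponentiating.
#'
#' @param eta Numeric matrix of scores.
#' @return Matrix of the same shape whose rows are probabilities summing
#'   to 1.
#' @export
softmax_rows <- function(eta) {
  m <- apply(eta, 1, max)
  e <- exp(eta - m)
  e / rowSums(e)
}

#' Multinomial log-likelihood of a count matrix
#'
#' Each group's count triple is scored against the softmax of its row of
#' `eta`, including the multinomial coefficient. Stable for scores up to
#' |eta| ~ 40 via log-sum-exp.
#'
#' @param counts A [count_matrix()] (or plain non-negative integer
#'   matrix).
#' @param eta J x 3 score matrix aligned with `counts` rows.
#' @return List with `total` (sum) and `pointwise` (per-group log
#'   densities).
#' @export
log_likelihood <- function(counts, eta) {
  y <- unclass(counts)
  if (any(y < 0) || anyNA(y)) cg_validation_error("negative counts")
  if (!all(dim(y) == dim(eta))) {
    cg_contract_error("counts and eta must have identical dimensions")
  }
  if (any(!is.finite(eta))) cg_contract_error("non-finite eta")
  m <- apply(eta, 1, max)
  logZ <- m + log(rowSums(exp(eta - m)))
  logp <- eta - logZ
  pointwise <- lgamma(rowSums(y) + 1) - rowSums(lgamma(y + 1)) +
    rowSums(y * logp)
  list(total = sum(pointwise), pointwise = unname(pointwise))
}

#' Log prior density of model parameters
#'
#' Sum of Normal(0, scale) log-densities on intercepts and slopes, a
#' half-Normal(scale) on each phylogenetic random-effect scale sigma, and,
#' for phylo models, a mean-zero multivariate normal with covariance
#' `sigma[k]^2 C` on each category's random-effect vector.
#'
#' @param params A [model_params()].
#' @param spec The matching [model_spec()].
#' @param C Phylogenetic covariance from [phylo_covariance()]; required
#'   when `spec$use_phylo`.
#' @return The log prior density (`-Inf` outside the support).
#' @export
log_prior <- function(params, spec, C = NULL) {
  lp <- sum(stats::dnorm(params$alpha, 0, spec$prior_scale_intercept,
                         log = TRUE))
  if (!is.null(params$beta) && length(params$beta)) {
    lp <- lp + sum(stats::dnorm(params$beta, 0, spec$prior_scale_slope,
                                log = TRUE))
  }
  if (spec$use_phylo) {
    if (is.null(C)) cg_contract_error("phylo model needs a covariance C")
    sigma <- params$sigma
    if (is.null(sigma)) cg_contract_error("phylo model needs sigma")
    if (any(sigma < 0)) return(-Inf)
    # half-Normal: 2 * dnorm on [0, Inf)
    lp <- lp + sum(log(2) + stats::dnorm(sigma, 0, spec$prior_scale_sigma,
                                         log = TRUE))
    phi <- params$phi
    if (is.null(phi)) cg_contract_error("phylo model needs phi")
    L <- chol_lower(C)
    J <- nrow(C)
    for (m in 1:2) {
      if (sigma[m] == 0) {
        if (any(phi[, m] != 0)) return(-Inf)
        next
      }
      # MVN(0, sigma^2 C) via the Cholesky factor of C
      z <- forwardsolve(L, phi[, m]) / sigma[m]
      logdet <- 2 * sum(log(diag(L))) + 2 * J * log(sigma[m])
      lp <- lp - 0.5 * (J * log(2 * pi) + logdet + sum(z^2))
    }
  }
  lp
}

#' Simulate count data from the model
#'
#' Draws each group's category triple from
#' Multinomial(N_j, softmax(eta[j, ])).
#'
#' @param params A [model_params()].
#' @param design A `design_matrix`.
#' @param totals Per-group game totals N_j (non-negative integers),
#'   aligned with `design$group_ids`.
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @return A [count_matrix()] (groups with N_j = 0 are dropped by
#'   construction).
#' @export
simulate_counts <- function(params, design, totals, seed = NULL) {
  if (length(totals) != length(design$group_ids) || any(totals < 0)) {
    cg_contract_error("totals must be non-negative, one per design group")
  }
  eta <- linear_predictor(params, design)
  p <- softmax_rows(eta)
  y <- with_seed(seed, {
    t(vapply(seq_along(totals), function(j) {
      if (totals[j] == 0) return(c(0L, 0L, 0L))
      as.integer(rmultinom(1, totals[j], p[j, ]))
    }, integer(3)))
  })
  dimnames(y) <- list(design$group_ids, goal_categories())
  count_matrix(y)
}
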