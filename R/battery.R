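#' The default battery of model variants
#'
#' The standard comparison set: an intercept-only base model, one
#' univariate model per cultural covariate, and two multivariate models
#' pairing each conflict predictor of interest with land-based hunting
#' interdependence — each fitted with and without phylogenetic controls
#' (18 models in all). Non-phylo models come first, mirroring the usual
#' two-block presentation.
#'
#' @param predictors Covariates for the univariate block; defaults to
#'   [covariate_names()].
#' @param multivariate List of length-2 predictor vectors; the second
#'   element is conventionally `land_hunt`, whose effect gets its own
#'   column in [effect_table()].
#' @return Named list of [model_spec()] objects.
#' @export
default_battery <- function(predictors = covariate_names(),
                            multivariate = list(
                              c("intra_group_conflict", "land_hunt"),
                              c("inter_cultural_conflict", "land_hunt"))) {
  specs <- list()
  for (phylo in c(FALSE, TRUE)) {
    specs <- c(specs, list(model_spec(use_phylo = phylo)))
    for (p in predictors) {
      specs <- c(specs, list(model_spec(p, use_phylo = phylo)))
    }
    for (mv in multivariate) {
      specs <- c(specs, list(model_spec(mv, use_phylo = phylo)))
    }
  }
  names(specs) <- vapply(specs, function(s) s$label, character(1))
  specs
}

#' Fit a battery of models on one data set
#'
#' Builds each model's design (complete-case per model), samples its
#' posterior, and assembles the WAIC comparison and effect table. Models
#' whose sampler fails are kept in the output with an error flag rather
#' than dropped.
#'
#' @param counts A [count_matrix()].
#' @param covariates Covariate data frame covering the count groups.
#' @param C Phylogenetic covariance; needed if any spec uses phylo
#'   controls.
#' @param mcmc An [mcmc_config()].
#' @param battery Named list of [model_spec()]s; default
#'   [default_battery()].
#' @return A list of class `battery_fit`: `fits` (named list of
#'   `posterior_draws` or error conditions), `comparison`
#'   ([compare_models()] output over the successful fits), and `table`
#'   (the [effect_table()]).
#' @export
fit_battery <- function(counts, covariates, C = NULL,
                        mcmc = mcmc_config(), battery = default_battery()) {
  fits <- vector("list", length(battery))
  names(fits) <- names(battery)
  for (i in seq_along(battery)) {
    spec <- battery[[i]]
    fits[[i]] <- tryCatch({
      dd <- build_design(covariates, counts, spec)
      sample_posterior(spec, dd$design, dd$counts,
                       C = if (spec$use_phylo) C, mcmc = mcmc)
    }, error = function(e) e)
  }
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok)) cg_inference_error("every model in the battery failed")
  comparison <- compare_models(lapply(fits[ok], waic), labels = names(fits)[ok])
  structure(list(fits = fits, comparison = comparison,
                 table = effect_table(fits, comparison, battery)),
            class = "battery_fit")
}

#' Table of per-model effects and WAIC comparison
#'
#' One row per model: the first predictor's effect on the log-odds of
#' cooperative relative to competitive games (posterior mean and 90%
#' interval), the land-hunting effect for multivariate models, the phylo
#' flag, and the WAIC comparison columns `D` and `W`.
#'
#' @param fits Named list of `posterior_draws` fits (error conditions
#'   allowed; their rows are flagged).
#' @param comparison Output of [compare_models()] covering the successful
#'   fits.
#' @param battery The list of [model_spec()]s (used to label failed
#'   fits); defaults to the specs stored in `fits`.
#' @return A data frame with columns `model`, `phylo`, `predictor`,
#'   `mean`, `q05`, `q95`, `predictor2`, `mean2`, `q05_2`, `q95_2`, `D`,
#'   `W`, `converged`.
#' @export
effect_table <- function(fits, comparison, battery = NULL) {
  rows <- lapply(seq_along(fits), function(i) {
    fit <- fits[[i]]
    if (inherits(fit, "error")) {
      spec <- if (!is.null(battery)) battery[[i]] else NULL
      return(data.frame(
        model = names(fits)[i],
        phylo = if (!is.null(spec)) spec$use_phylo else NA,
        predictor = NA_character_, mean = NA_real_, q05 = NA_real_,
        q95 = NA_real_, predictor2 = NA_character_, mean2 = NA_real_,
        q05_2 = NA_real_, q95_2 = NA_real_, D = NA_real_, W = NA_real_,
        converged = FALSE))
    }
    spec <- fit$spec
    contrast <- setdiff(nonref_categories(spec), "solitary")[1]
    eff <- function(p) {
      s <- summarize_posterior(fit, 0.90,
                               pars = sprintf("^beta\\[%s,%s\\]", contrast, p))
      c(s$mean, s$lower, s$upper)
    }
    p1 <- if (length(spec$predictors)) spec$predictors[1] else NA_character_
    p2 <- if (length(spec$predictors) > 1) spec$predictors[2] else NA_character_
    e1 <- if (!is.na(p1)) eff(p1) else rep(NA_real_, 3)
    e2 <- if (!is.na(p2)) eff(p2) else rep(NA_real_, 3)
    cmp <- comparison[comparison$model == names(fits)[i], ]
    rhat <- fit$diagnostics$rhat
    data.frame(
      model = names(fits)[i], phylo = spec$use_phylo,
      predictor = p1, mean = e1[1], q05 = e1[2], q95 = e1[3],
      predictor2 = p2, mean2 = e2[1], q05_2 = e2[2], q95_2 = e2[3],
      D = if (nrow(cmp)) cmp$D else NA_real_,
      W = if (nrow(cmp)) cmp$W else NA_real_,
      converged = all(rhat[is.finite(rhat)] < 1.05))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.battery_fit <- function(x, ...) {
  cat(sprintf("battery_fit: %d models\n", length(x$fits)))
  print(x$table[, c("model", "phylo", "predictor", "mean", "q05", "q95",
                    "D", "W")], digits = 3, ...)
  invisible(x)
}
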