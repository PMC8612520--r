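#' Read a run configuration
#'
#' YAML configuration shared by the pipeline runners. Recognized keys
#' (all optional unless a runner needs them): `games`, `covariates`,
#' `newick`, `output_dir`, `columns` (games/covariates column-name
#' mappings), `window_years`, `seed`, `mcmc` (chains/warmup/iter),
#' `battery` (list of `{predictors, use_phylo}`), `sim`
#' ([sim_config()] fields), `replicates`, `predictor`.
#'
#' @param path Path to a YAML file.
#' @return A list of class `run_config`; `config_id` carries the file's
#'   MD5 digest for the audit trail.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) cg_io_error(sprintf("config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) cg_schema_error("config must be a YAML mapping")
  defaults <- list(window_years = 50, seed = 1, output_dir = ".",
                   mcmc = list(), sim = list(), replicates = 10,
                   predictor = "land_hunt", columns = list())
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  known_cov <- covariate_names()
  if (!is.null(cfg$battery)) {
    for (b in cfg$battery) {
      bad <- setdiff(unlist(b$predictors), known_cov)
      if (length(bad)) {
        cg_schema_error(sprintf("battery refers to unknown covariate(s): %s",
                                paste(bad, collapse = ", ")))
      }
    }
  }
  cfg$config_id <- unname(tools::md5sum(path))
  structure(cfg, class = "run_config")
}

config_mcmc <- function(cfg) {
  do.call(mcmc_config, c(cfg$mcmc[intersect(names(cfg$mcmc),
                                            c("chains", "warmup", "iter"))],
                         list(seed = cfg$seed)))
}

config_battery <- function(cfg) {
  if (is.null(cfg$battery)) return(default_battery())
  specs <- lapply(cfg$battery, function(b) {
    model_spec(unlist(b$predictors), use_phylo = isTRUE(b$use_phylo))
  })
  names(specs) <- vapply(specs, function(s) s$label, character(1))
  specs
}

# Seed- and config-stamped CSV writer: a `#` comment header that the
# package's own readers skip.
write_stamped_csv <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %d", cfg$seed), con)
  writeLines(sprintf("# config_id: %s", cfg$config_id), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

load_inputs <- function(cfg, need = c("games", "covariates", "newick")) {
  out <- list()
  if ("games" %in% need) {
    out$games <- read_games(cfg$games, columns = unlist(cfg$columns$games))
  }
  if ("covariates" %in% need) {
    out$covariates <- read_covariates(
      cfg$covariates, columns = unlist(cfg$columns$covariates))
  }
  if ("newick" %in% need) out$tree <- read_newick(cfg$newick)
  out
}

#' Run the filtering stage
#'
#' Reads games, covariates and the tree, applies [filter_games()], and
#' writes `filtered_games.csv` and `filter_report.csv` to the output
#' directory.
#'
#' @param cfg A [read_run_config()] result.
#' @return Paths of the written files, invisibly.
#' @export
run_filter <- function(cfg) {
  inp <- load_inputs(cfg)
  res <- filter_games(inp$games, inp$covariates, inp$tree$tip.label,
                      cfg$window_years)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(games = file.path(cfg$output_dir, "filtered_games.csv"),
             report = file.path(cfg$output_dir, "filter_report.csv"))
  write_stamped_csv(res$games, paths["games"], cfg)
  write_stamped_csv(res$report, paths["report"], cfg)
  for (i in seq_len(nrow(res$report))) {
    message(sprintf("filter %-14s %4d -> %4d", res$report$step[i],
                    res$report$n_before[i], res$report$n_after[i]))
  }
  invisible(paths)
}

#' Run the model battery
#'
#' Filters the data, tabulates counts, prunes the tree to the analysis
#' groups, builds the phylogenetic covariance, fits the configured
#' battery, and writes the effect table, the WAIC comparison, per-model
#' draws, and a diagnostics log.
#'
#' @param cfg A [read_run_config()] result.
#' @return The `battery_fit`, invisibly; files land in `output_dir`.
#' @export
run_fit <- function(cfg) {
  inp <- load_inputs(cfg)
  res <- filter_games(inp$games, inp$covariates, inp$tree$tip.label,
                      cfg$window_years)
  counts <- tabulate_counts(res$games)
  if (nrow(counts) < 2) cg_validation_error("fewer than 2 groups after filtering")
  tree <- prune_tree(inp$tree, rownames(counts))
  C <- phylo_covariance(tree)
  bat <- suppressWarnings(
    fit_battery(counts, inp$covariates, C, config_mcmc(cfg),
                config_battery(cfg)))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_stamped_csv(bat$table, file.path(cfg$output_dir, "effect_table.csv"),
                    cfg)
  write_stamped_csv(bat$comparison,
                    file.path(cfg$output_dir, "model_comparison.csv"), cfg)
  diag <- do.call(rbind, lapply(names(bat$fits), function(nm) {
    f <- bat$fits[[nm]]
    if (inherits(f, "error")) {
      return(data.frame(model = nm, parameter = NA, rhat = NA, ess = NA,
                        error = conditionMessage(f)))
    }
    cbind(model = nm, f$diagnostics, error = "")
  }))
  write_stamped_csv(diag, file.path(cfg$output_dir, "diagnostics.csv"), cfg)
  draws_dir <- file.path(cfg$output_dir, "draws")
  dir.create(draws_dir, showWarnings = FALSE)
  for (nm in names(bat$fits)) {
    f <- bat$fits[[nm]]
    if (inherits(f, "error")) next
    fn <- file.path(draws_dir, paste0(gsub("[^A-Za-z0-9_+-]", "_", nm),
                                      ".csv"))
    write_stamped_csv(as.data.frame(f$draws), fn, cfg)
  }
  invisible(bat)
}

#' Generate and write a synthetic study
#'
#' @param cfg A [read_run_config()] result; `sim` fields override
#'   [sim_config()] defaults, `seed` seeds the generator.
#' @return The `sim_study`, invisibly; files land in `output_dir`.
#' @export
run_simulate <- function(cfg) {
  sim <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
  study <- simulate_study(sim)
  paths <- write_study(study, cfg$output_dir)
  # stamp the CSV outputs in place
  for (p in paths[c("games", "covariates")]) {
    txt <- readLines(p)
    writeLines(c(sprintf("# seed: %d", cfg$seed),
                 sprintf("# config_id: %s", cfg$config_id), txt), p)
  }
  invisible(study)
}

#' Run a parameter-recovery experiment
#'
#' @param cfg A [read_run_config()] result; uses `sim`, `replicates`,
#'   `predictor`, and `mcmc`.
#' @return The `recovery_report`, invisibly; `recovery.csv` and
#'   `recovery_summary.csv` land in `output_dir`.
#' @export
run_recover <- function(cfg) {
  sim <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
  rep <- recovery_experiment(sim, cfg$replicates, config_mcmc(cfg),
                             predictor = cfg$predictor)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  write_stamped_csv(rep$replicates,
                    file.path(cfg$output_dir, "recovery.csv"), cfg)
  write_stamped_csv(rep$summary,
                    file.path(cfg$output_dir, "recovery_summary.csv"), cfg)
  invisible(rep)
}
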