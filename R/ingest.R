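#' Read a table of game records
#'
#' Each row describes one game: an identifier, the ethnolinguistic group it
#' belongs to (the key linking games to covariates and phylogeny tips), its
#' six-level goal-structure code, the boolean flags consumed by
#' [filter_games()], and the time frame of the ethnographic description.
#'
#' @param path Path to a CSV file with a header row. Lines starting with
#'   `#` are ignored.
#' @param columns Optional named character vector mapping the canonical
#'   column names (`game_id`, `group_id`, `goal_structure`, `abvd_linked`,
#'   `describable`, `local_origin`, `period_start`, `period_end`) to the
#'   names used in the file. Unmapped columns default to their canonical
#'   names.
#' @return A data frame with the canonical columns, one row per game.
#' @export
read_games <- function(path, columns = NULL) {
  canonical <- c("game_id", "group_id", "goal_structure", "abvd_linked",
                 "describable", "local_origin", "period_start", "period_end")
  df <- read_mapped_csv(path, canonical, columns)
  if (nrow(df) == 0L) return(df)

  df$game_id  <- as.character(df$game_id)
  df$group_id <- as.character(df$group_id)
  df$goal_structure <- as.character(df$goal_structure)
  bad <- which(!df$goal_structure %in% goal_codes())
  if (length(bad)) {
    cg_validation_error(sprintf(
      "unknown goal_structure '%s' at row %d (valid codes: %s)",
      df$goal_structure[bad[1]], bad[1], paste(goal_codes(), collapse = ", ")))
  }
  for (fl in c("abvd_linked", "describable", "local_origin")) {
    df[[fl]] <- as_flag(df[[fl]], fl)
  }
  for (pc in c("period_start", "period_end")) {
    v <- suppressWarnings(as.integer(df[[pc]]))
    if (anyNA(v)) {
      cg_validation_error(sprintf("non-integer %s at row %d", pc,
                                  which(is.na(v))[1]))
    }
    df[[pc]] <- v
  }
  bad <- which(df$period_start > df$period_end)
  if (length(bad)) {
    cg_validation_error(sprintf("period_start > period_end at row %d", bad[1]))
  }
  df
}

#' Read a table of per-group cultural covariates
#'
#' One row per ethnolinguistic group, with the six binary cultural
#' covariates (see [covariate_names()]) coded `present` / `absent` /
#' `missing` (blank cells are read as `missing`), and `time_focus`, the
#' reference year of the ethnographic coding used for temporal filtering.
#'
#' @inheritParams read_games
#' @return A data frame with columns `group_id`, the six covariates, and
#'   `time_focus`.
#' @export
read_covariates <- function(path, columns = NULL) {
  canonical <- c("group_id", covariate_names(), "time_focus")
  df <- read_mapped_csv(path, canonical, columns)
  if (nrow(df) == 0L) return(df)

  df$group_id <- as.character(df$group_id)
  dup <- duplicated(df$group_id)
  if (any(dup)) {
    cg_validation_error(sprintf("duplicate group_id '%s'",
                                df$group_id[which(dup)[1]]))
  }
  for (cv in covariate_names()) {
    v <- as.character(df[[cv]])
    v[is.na(v) | trimws(v) == ""] <- "missing"
    bad <- which(!v %in% c("present", "absent", "missing"))
    if (length(bad)) {
      cg_validation_error(sprintf(
        "invalid value '%s' for %s at row %d (use present/absent/missing)",
        v[bad[1]], cv, bad[1]))
    }
    df[[cv]] <- v
  }
  tf <- suppressWarnings(as.integer(df$time_focus))
  if (anyNA(tf)) {
    cg_validation_error(sprintf("non-integer time_focus at row %d",
                                which(is.na(tf))[1]))
  }
  df$time_focus <- tf
  df
}

read_mapped_csv <- function(path, canonical, columns) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    cg_io_error(sprintf("file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        check.names = FALSE)
  map <- setNames(canonical, canonical)
  if (!is.null(columns)) {
    unknown <- setdiff(names(columns), canonical)
    if (length(unknown)) {
      cg_schema_error(sprintf("column mapping refers to unknown field(s): %s",
                              paste(unknown, collapse = ", ")))
    }
    map[names(columns)] <- columns
  }
  miss <- canonical[!map %in% names(df)]
  if (length(miss)) {
    cg_schema_error(sprintf("missing required column(s): %s",
                            paste(map[miss], collapse = ", ")))
  }
  out <- df[, unname(map), drop = FALSE]
  names(out) <- canonical
  out
}

as_flag <- function(x, name) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[v %in% c("false", "f", "0", "no", "n")] <- FALSE
  if (anyNA(out)) {
    cg_validation_error(sprintf("non-boolean value '%s' in column %s at row %d",
                                x[which(is.na(out))[1]], name,
                                which(is.na(out))[1]))
  }
  out
}

#' Apply the six game-filtering steps
#'
#' Filters game records in a fixed order: (i) the game is linked to a
#' basic-vocabulary language code (`abvd_linked`); (ii) it is described in
#' enough detail to code (`describable`); (iii) it is of local origin
#' (`local_origin`); (iv) its group is a tip of the analysis phylogeny;
#' (v) its group has a covariate row; (vi) its description time frame
#' overlaps the covariate reference period `time_focus` +/-
#' `window_years` (closed intervals, any overlap).
#'
#' @param games Data frame from [read_games()].
#' @param covariates Data frame from [read_covariates()].
#' @param tree_tips Character vector of phylogeny tip labels.
#' @param window_years Non-negative half-width of the temporal window in
#'   years (default 50).
#' @return A list with `games` (the surviving rows) and `report`, a data
#'   frame with one row per step (`step`, `n_before`, `n_after`).
#' @export
filter_games <- function(games, covariates, tree_tips, window_years = 50) {
  if (!is.numeric(window_years) || length(window_years) != 1L ||
      window_years < 0) {
    cg_contract_error("window_years must be a single non-negative number")
  }
  focus <- setNames(covariates$time_focus, covariates$group_id)
  steps <- list(
    abvd_linked    = function(g) g$abvd_linked,
    describable    = function(g) g$describable,
    local_origin   = function(g) g$local_origin,
    on_tree        = function(g) g$group_id %in% tree_tips,
    has_covariates = function(g) g$group_id %in% covariates$group_id,
    time_overlap   = function(g) {
      tf <- focus[g$group_id]
      g$period_start <= tf + window_years & g$period_end >= tf - window_years
    }
  )
  report <- data.frame(step = names(steps),
                       n_before = NA_integer_, n_after = NA_integer_)
  for (i in seq_along(steps)) {
    report$n_before[i] <- nrow(games)
    keep <- if (nrow(games)) steps[[i]](games) else logical(0)
    games <- games[keep, , drop = FALSE]
    report$n_after[i] <- nrow(games)
  }
  rownames(games) <- NULL
  list(games = games, report = report)
}

#' Collapse six goal-structure codes into three analysis categories
#'
#' Games with any cooperative interaction (`cooperative`,
#' `cooperative_group_vs_cooperative_group`,
#' `competitive_vs_cooperative_group`) become `cooperative`; games with
#' competitive but no cooperative interactions (`competitive`,
#' `competitive_vs_solitary`) become `competitive`; `solitary` stays
#' `solitary`.
#'
#' @param code Character vector of goal-structure codes.
#' @return Character vector of collapsed categories, same length.
#' @export
collapse_goal_structure <- function(code) {
  map <- c(solitary = "solitary",
           competitive = "competitive",
           competitive_vs_solitary = "competitive",
           competitive_vs_cooperative_group = "cooperative",
           cooperative_group_vs_cooperative_group = "cooperative",
           cooperative = "cooperative")
  bad <- which(!code %in% names(map))
  if (length(bad)) {
    cg_validation_error(sprintf("unknown goal-structure code '%s'",
                                code[bad[1]]))
  }
  unname(map[code])
}

#' Construct or validate a per-group count matrix
#'
#' The multinomial outcome: one row per ethnolinguistic group, columns in
#' the fixed order `solitary`, `competitive`, `cooperative`. Groups with a
#' zero row total are dropped (they carry no likelihood information).
#'
#' @param counts Integer matrix (or coercible) with group ids as row names
#'   and the three category names as column names.
#' @return An integer matrix of class `count_matrix`, rows sorted by group
#'   id.
#' @export
count_matrix <- function(counts) {
  m <- as.matrix(counts)
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    cg_validation_error("count matrix needs unique group ids as row names")
  }
  if (is.null(colnames(m)) || !setequal(colnames(m), goal_categories())) {
    cg_validation_error(sprintf("count matrix columns must be: %s",
                                paste(goal_categories(), collapse = ", ")))
  }
  m <- m[, goal_categories(), drop = FALSE]
  storage.mode(m) <- "integer"
  if (anyNA(m) || any(m < 0)) {
    cg_validation_error("counts must be non-negative integers")
  }
  m <- m[rowSums(m) > 0, , drop = FALSE]
  if (nrow(m)) m <- m[order(rownames(m)), , drop = FALSE]
  class(m) <- c("count_matrix", class(m))
  m
}

#' @export
`[.count_matrix` <- function(x, i, j, ..., drop = FALSE) {
  cl <- oldClass(x)
  oldClass(x) <- NULL
  out <- x[i, j, drop = drop]
  if (is.matrix(out)) oldClass(out) <- cl
  out
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d groups, %d games\n", nrow(x), sum(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Tabulate collapsed category counts per group
#'
#' @param games Data frame of (already filtered) game records.
#' @return A [count_matrix()] with one row per group present in `games`,
#'   sorted by group id.
#' @export
tabulate_counts <- function(games) {
  cats <- goal_categories()
  if (nrow(games) == 0L) {
    m <- matrix(integer(0), 0, 3, dimnames = list(character(0), cats))
    class(m) <- c("count_matrix", class(m))
    return(m)
  }
  collapsed <- collapse_goal_structure(games$goal_structure)
  tab <- table(factor(games$group_id), factor(collapsed, levels = cats))
  m <- matrix(as.integer(tab), nrow(tab), 3,
              dimnames = list(rownames(tab), cats))
  count_matrix(m)
}

#' Descriptive statistics of a count matrix
#'
#' @param counts A [count_matrix()].
#' @return A list with `n_games`, `n_groups`, `category_totals`,
#'   `n_competitive_majority` and `n_cooperative_majority` (groups where
#'   that category makes up at least half of the group's games), and
#'   `n_small_sample` (groups with 1-3 games).
#' @export
descriptive_summary <- function(counts) {
  if (nrow(counts) == 0L) cg_contract_error("empty count matrix")
  tot <- rowSums(counts)
  list(
    n_games = sum(counts),
    n_groups = nrow(counts),
    category_totals = colSums(counts),
    n_competitive_majority = sum(counts[, "competitive"] >= tot / 2),
    n_cooperative_majority = sum(counts[, "cooperative"] >= tot / 2),
    n_small_sample = sum(tot >= 1 & tot <= 3)
  )
}

#' Write a filter report to CSV
#'
#' @param report The `report` element returned by [filter_games()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
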