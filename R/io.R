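# Canonical factor levels of the study design; configs are validated against
# these unless allow_nonstandard is set.
.paper_levels <- list(
  ratios = list(c(100L, 100L), c(200L, 100L), c(300L, 100L),
                c(400L, 100L), c(500L, 100L)),
  deltas = c(0, 0.25, 0.5, 1.0),
  n_items = c(5L, 10L),
  n_categories = c(3L, 5L, 7L),
  conditions = 1:13
)

.config_defaults <- function() {
  list(base_seed = 1L,
       reps = 1000L,
       alpha = 0.05,
       ratios = .paper_levels$ratios,
       deltas = c(0.5, 1.0),
       n_items = c(5L, 10L),
       n_categories = c(3L, 5L, 7L),
       conditions = 1:13,
       studied_item = 1L,
       retry_budget = 5L,
       alpha_item_policy = "all_dif_free",
       alpha_source = "matched_null",
       allow_nonstandard = FALSE,
       out = NULL)
}

#' Load and validate a simulation run configuration
#'
#' Reads a YAML configuration (or one of the shipped presets
#' `"paper_grid"`, `"condition13"`, `"small_dif"`) and fills unset fields
#' with defaults: nominal level 0.05, 1000 replications, the full factorial
#' factor levels, retry budget 5. Factor levels outside the canonical study
#' design are rejected unless the config sets `allow_nonstandard: true`.
#'
#' @param path Path to a YAML file, or a preset name.
#' @return A validated list of class `run_config`.
#' @export
load_config <- function(path) {
  presets <- c("paper_grid", "condition13", "small_dif")
  if (is.character(path) && length(path) == 1L && path %in% presets) {
    path <- system.file("extdata", paste0(path, ".yaml"),
                        package = "mimicsim", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  cfg <- utils::modifyList(.config_defaults(), raw)
  if (!is.null(cfg$ratios)) {
    cfg$ratios <- lapply(cfg$ratios, function(r) as.integer(unlist(r)))
  }

  fail <- function(field, msg) {
    stop(sprintf("config field '%s': %s", field, msg), call. = FALSE)
  }
  if (!is.numeric(cfg$alpha) || length(cfg$alpha) != 1L ||
      cfg$alpha <= 0 || cfg$alpha >= 1) {
    fail("alpha", "must lie strictly between 0 and 1")
  }
  cfg$reps <- as.integer(cfg$reps)
  if (is.na(cfg$reps) || cfg$reps < 1L) fail("reps", "must be >= 1")
  cfg$base_seed <- as.integer(cfg$base_seed)
  if (is.na(cfg$base_seed)) fail("base_seed", "must be an integer")
  cfg$retry_budget <- as.integer(cfg$retry_budget)
  if (is.na(cfg$retry_budget) || cfg$retry_budget < 0L) {
    fail("retry_budget", "must be >= 0")
  }
  if (!cfg$alpha_item_policy %in% c("all_dif_free", "item2_only")) {
    fail("alpha_item_policy", "must be 'all_dif_free' or 'item2_only'")
  }
  if (!cfg$alpha_source %in% c("matched_null", "same_dataset")) {
    fail("alpha_source", "must be 'matched_null' or 'same_dataset'")
  }
  if (!isTRUE(cfg$allow_nonstandard)) {
    if (!all(vapply(cfg$ratios, function(r) {
      any(vapply(.paper_levels$ratios, identical, logical(1), r))
    }, logical(1)))) {
      fail("ratios", "outside the canonical design (set allow_nonstandard)")
    }
    if (!all(cfg$deltas %in% .paper_levels$deltas)) {
      fail("deltas", "outside the canonical design (set allow_nonstandard)")
    }
    if (!all(cfg$n_items %in% .paper_levels$n_items)) {
      fail("n_items", "outside the canonical design (set allow_nonstandard)")
    }
    if (!all(cfg$n_categories %in% .paper_levels$n_categories)) {
      fail("n_categories", "outside the canonical design (set allow_nonstandard)")
    }
    if (!all(cfg$conditions %in% .paper_levels$conditions)) {
      fail("conditions", "outside the canonical design (set allow_nonstandard)")
    }
  }
  structure(cfg, class = "run_config")
}

#' Expand a run configuration into its scenario grid
#'
#' @param config A `run_config` from [load_config()].
#' @return The scenario grid data frame (see [scenario_grid()]).
#' @export
config_scenarios <- function(config) {
  stopifnot(inherits(config, "run_config"))
  scenario_grid(ratios = config$ratios, deltas = config$deltas,
                n_items = config$n_items, n_categories = config$n_categories,
                conditions = config$conditions,
                studied_item = config$studied_item)
}

#' @export
print.run_config <- function(x, ...) {
  cat("simulation run configuration\n")
  cat(sprintf("  base_seed %d, reps %d, alpha %g, retry budget %d\n",
              x$base_seed, x$reps, x$alpha, x$retry_budget))
  cat(sprintf("  grid: %d ratios x %d deltas x %d lengths x %d category counts x %d conditions = %d scenarios\n",
              length(x$ratios), length(x$deltas), length(x$n_items),
              length(x$n_categories), length(x$conditions),
              nrow(config_scenarios(x))))
  invisible(x)
}

#' Write / read a grid results table
#'
#' Results are stored as plain CSV (diffable, portable) with one row per
#' scenario. `read_results` validates the table on load: required columns,
#' rates in [0, 1], and `n_converged` not exceeding the requested
#' replications; violations are reported with their row numbers.
#'
#' @param results A `grid_results` data frame.
#' @param path CSV file path.
#' @return `write_results` invisibly returns `path`; `read_results` returns
#'   a `grid_results` data frame.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("n_ref", "n_focal", "delta", "n_items", "n_categories",
            "condition_id", "reps", "n_converged", "power", "type1_error")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("results file lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  num_cols <- intersect(c("power", "type1_error", "mean_rmsea", "mean_cfi",
                          "mean_tli", "mean_gfi", "mean_rmr", "delta"),
                        names(df))
  for (cn in num_cols) df[[cn]] <- as.numeric(df[[cn]])
  bad <- which(df$n_converged > df$reps)
  if (length(bad)) {
    stop("invalid results rows (n_converged > reps): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.na(df$power) & (df$power < 0 | df$power > 1))
  if (length(bad)) {
    stop("invalid results rows (power outside [0, 1]): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  class(df) <- c("grid_results", class(df))
  df
}

#' Serialize a MIMIC fit as a JSON-ready record
#'
#' @param fit A `mimic_fit`.
#' @return A plain named list (estimates, standard errors, Wald test,
#'   chi-square, fit indices, flags) suitable for `jsonlite::toJSON()`.
#' @export
fit_report <- function(fit) {
  stopifnot(inherits(fit, "mimic_fit"))
  if (!is.null(fit$error)) {
    return(list(converged = FALSE, error = fit$error))
  }
  wt <- if (is.finite(fit$se_beta) && fit$se_beta > 0) {
    wald_dif_test(fit$beta, fit$se_beta)
  } else list(z = NA_real_, p_value = NA_real_)
  list(n_obs = fit$n_obs,
       studied_item = fit$studied_item,
       loadings = fit$loadings,
       intercepts = fit$intercepts,
       residual_variances = fit$residual_variances,
       gamma = fit$gamma, se_gamma = fit$se_gamma,
       beta = fit$beta, se_beta = fit$se_beta,
       z = wt$z, p_value = wt$p_value,
       zeta_variance = fit$zeta_variance,
       fml = fit$fml, chi_square = fit$chi_square, df = fit$df,
       converged = fit$converged, heywood = fit$heywood,
       fit_indices = fit$fit_indices[c("rmsea", "rmr", "tli", "cfi", "gfi")])
}
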