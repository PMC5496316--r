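#' Run all replications of one simulation cell
#'
#' For each replication a fresh dataset is generated from the scenario (new
#' item bank, new latent traits) under a deterministic child seed, every
#' requested item is tested for uniform DIF, and the rejection indicators
#' are accumulated. A replication whose studied-item fit fails to converge
#' or yields a Heywood solution is redrawn with the next child seed (up to
#' `retry_budget` redraws) and dropped if none succeeds; failed fits of
#' individual DIF-free items are excluded from both numerator and
#' denominator of the false-positive rate. Power and Type I error are
#' therefore computed over converged fits only.
#'
#' @param scn A [scenario()]; its `seed` drives every child seed, so a cell
#'   can be reproduced in isolation.
#' @param n_reps Number of replications requested.
#' @param alpha Nominal significance level.
#' @param items `"all"` tests every item (power from the studied item, Type
#'   I error from the DIF-free items); `"studied_only"` fits only the
#'   studied item, which is enough for power and about k times faster.
#' @param alpha_item_policy With `"all_dif_free"`, the per-replication false
#'   positive rate averages over every DIF-free item; `"item2_only"`
#'   restricts it to item 2.
#' @param alpha_source Where the Type-I-error decisions come from when the
#'   scenario injects DIF. `"matched_null"` (default) tests the DIF-free
#'   items in a companion dataset generated from the same child seed with
#'   the threshold shift set to zero, so false-positive rates are measured
#'   on data that actually satisfy the null for every item; with common
#'   random numbers the companion shares its item bank and latent traits
#'   with the power dataset. `"same_dataset"` tests the DIF-free items in
#'   the DIF dataset itself, where the shifted item sits among the anchors;
#'   this inflates the false-positive rate increasingly with the DIF
#'   magnitude (anchor contamination) and is provided for studying exactly
#'   that effect. Scenarios with `delta = 0` are their own null.
#' @param retry_budget Redraws allowed per replication on nonconvergence.
#' @return An object of class `scenario_result`: the scenario, replication
#'   bookkeeping (`n_reps_requested`, `n_converged`, `n_retries`,
#'   `n_alpha_dropped` individual DIF-free-item fits excluded), `power`,
#'   `type1_error` (NA under `"studied_only"`) and `mean_fit_indices` from
#'   the studied-item fits.
#' @export
run_scenario <- function(scn, n_reps, alpha = 0.05,
                         items = c("all", "studied_only"),
                         alpha_item_policy = c("all_dif_free", "item2_only"),
                         alpha_source = c("matched_null", "same_dataset"),
                         retry_budget = 5L) {
  stopifnot(inherits(scn, "dif_scenario"))
  items <- match.arg(items)
  alpha_item_policy <- match.arg(alpha_item_policy)
  alpha_source <- match.arg(alpha_source)
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L) stop("'n_reps' must be >= 1", call. = FALSE)
  retry_budget <- as.integer(retry_budget)

  tested <- if (items == "studied_only") scn$studied_item else seq_len(scn$n_items)
  alpha_items <- if (scn$delta > 0) setdiff(tested, scn$studied_item) else tested
  if (alpha_item_policy == "item2_only") {
    alpha_items <- intersect(alpha_items, 2L)
  }
  # companion no-DIF scenario for matched-null Type I error estimation
  use_null <- scn$delta > 0 && length(alpha_items) > 0 &&
    alpha_source == "matched_null"
  scn_null <- if (use_null) {
    scenario(scn$n_ref, scn$n_focal, 0, scn$n_items, scn$n_categories,
             scn$condition_id, scn$studied_item, scn$seed)
  }

  set.seed(scn$seed)
  rep_seeds <- matrix(sample.int(2147483646L, n_reps * (retry_budget + 1L)),
                      nrow = n_reps)

  reject_studied <- logical(0)
  fp_rate <- numeric(0)
  fi_sum <- c(rmsea = 0, rmr = 0, tli = 0, cfi = 0, gfi = 0)
  n_converged <- 0L
  n_retries <- 0L

  n_alpha_dropped <- 0L
  for (r in seq_len(n_reps)) {
    # A replication stands or falls with the studied-item fit: on
    # nonconvergence or a Heywood solution the dataset is redrawn with the
    # next child seed. Failed fits of individual DIF-free items are excluded
    # from both numerator and denominator of the false-positive rate instead
    # of discarding the replication, since with long coarse scales a single
    # near-degenerate item would otherwise veto almost every replication.
    ok <- FALSE
    for (attempt in seq_len(retry_budget + 1L)) {
      data <- generate_dataset(scn, seed = rep_seeds[r, attempt])
      d <- test_item(data, scn$studied_item, alpha)
      if (d$converged && !d$heywood) { ok <- TRUE; break }
      n_retries <- n_retries + 1L
    }
    if (!ok) next
    n_converged <- n_converged + 1L
    studied_fit <- attr(d, "fit")
    reject_studied <- c(reject_studied, d$rejected)
    fi <- studied_fit$fit_indices
    fi_sum <- fi_sum + c(fi$rmsea, fi$rmr, fi$tli, fi$cfi, fi$gfi)

    if (length(alpha_items)) {
      data_alpha <- if (use_null) {
        generate_dataset(scn_null, seed = rep_seeds[r, attempt])
      } else {
        data
      }
      fp <- logical(0)
      for (j in alpha_items) {
        da <- if (!use_null && j == scn$studied_item) {
          d          # delta = 0: the studied fit already is a null fit
        } else {
          test_item(data_alpha, j, alpha)
        }
        if (da$converged && !da$heywood) {
          fp <- c(fp, da$rejected)
        } else {
          n_alpha_dropped <- n_alpha_dropped + 1L
        }
      }
      if (length(fp)) fp_rate <- c(fp_rate, mean(fp))
    }
  }

  if (n_converged == 0L) {
    warning("no replication converged for this scenario", call. = FALSE)
  }
  structure(
    list(scenario = scn,
         n_reps_requested = n_reps,
         n_converged = n_converged,
         n_retries = n_retries,
         n_alpha_dropped = n_alpha_dropped,
         alpha = alpha,
         power = if (n_converged > 0L) mean(reject_studied) else NA_real_,
         type1_error = if (n_converged > 0L && length(alpha_items))
           mean(fp_rate) else NA_real_,
         mean_fit_indices = if (n_converged > 0L)
           as.list(fi_sum / n_converged) else
             as.list(fi_sum * NA_real_)),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  print(x$scenario)
  cat(sprintf("  replications: %d requested, %d converged (%d retries)\n",
              x$n_reps_requested, x$n_converged, x$n_retries))
  cat(sprintf("  power = %.3f   type I error = %.3f\n",
              x$power, x$type1_error))
  invisible(x)
}

# Flatten a scenario_result into one results-table row.
.result_row <- function(res) {
  scn <- res$scenario
  fi <- res$mean_fit_indices
  data.frame(n_ref = scn$n_ref, n_focal = scn$n_focal, delta = scn$delta,
             n_items = scn$n_items, n_categories = scn$n_categories,
             condition_id = scn$condition_id, seed = scn$seed,
             reps = res$n_reps_requested, n_converged = res$n_converged,
             power = res$power, type1_error = res$type1_error,
             mean_rmsea = fi$rmsea, mean_cfi = fi$cfi, mean_tli = fi$tli,
             mean_gfi = fi$gfi, mean_rmr = fi$rmr)
}

#' Run a factorial grid of scenarios
#'
#' Executes [run_scenario()] for every row of a scenario grid. Each cell's
#' seed is derived deterministically from `base_seed` and the cell's factor
#' levels, so rerunning any subset of the grid (or running scenarios in
#' parallel) reproduces exactly the same rows as the full serial run.
#'
#' @param grid Data frame from [scenario_grid()] (or [config_scenarios()]).
#' @param n_reps Replications per cell.
#' @param base_seed Base seed for the whole grid.
#' @param alpha Nominal significance level.
#' @param items,alpha_item_policy,alpha_source,retry_budget Passed to
#'   [run_scenario()].
#' @param jobs Number of worker processes (scenario-level parallelism via
#'   the parallel package; results are scheduling-independent).
#' @param out Optional CSV path; in serial runs rows are appended as each
#'   scenario completes, in parallel runs the full table is written at the
#'   end.
#' @param verbose Log per-scenario progress and retry counts.
#' @return A data frame of class `grid_results`, one row per scenario with
#'   columns n_ref, n_focal, delta, n_items, n_categories, condition_id,
#'   seed, reps, n_converged, power, type1_error and the mean fit indices.
#' @export
run_grid <- function(grid, n_reps, base_seed = 1L, alpha = 0.05,
                     items = "all", alpha_item_policy = "all_dif_free",
                     alpha_source = "matched_null",
                     retry_budget = 5L, jobs = 1L, out = NULL,
                     verbose = FALSE) {
  stopifnot(is.data.frame(grid), nrow(grid) > 0L)
  need <- c("n_ref", "n_focal", "delta", "n_items", "n_categories",
            "condition_id")
  if (!all(need %in% names(grid))) {
    stop("grid must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"studied_item" %in% names(grid)) grid$studied_item <- 1L

  one <- function(i) {
    g <- grid[i, ]
    scn <- scenario(g$n_ref, g$n_focal, g$delta, g$n_items, g$n_categories,
                    g$condition_id, g$studied_item,
                    seed = scenario_seed(base_seed, g$n_ref, g$n_focal,
                                         g$delta, g$n_items, g$n_categories,
                                         g$condition_id, g$studied_item))
    res <- run_scenario(scn, n_reps, alpha = alpha, items = items,
                        alpha_item_policy = alpha_item_policy,
                        alpha_source = alpha_source,
                        retry_budget = retry_budget)
    if (verbose) {
      message(sprintf(
        "[%d/%d] R%d/F%d delta=%g k=%d J=%d cond=%d: power=%.3f alpha=%.3f (%d/%d converged, %d retries)",
        i, nrow(grid), g$n_ref, g$n_focal, g$delta, g$n_items,
        g$n_categories, g$condition_id, res$power, res$type1_error,
        res$n_converged, n_reps, res$n_retries))
    }
    .result_row(res)
  }

  if (jobs > 1L) {
    rows <- parallel::mclapply(seq_len(nrow(grid)), one,
                               mc.cores = jobs, mc.preschedule = TRUE)
    bad <- vapply(rows, function(r) inherits(r, "try-error") || is.null(r),
                  logical(1))
    if (any(bad)) stop("grid workers failed for ", sum(bad), " scenario(s)",
                       call. = FALSE)
    results <- do.call(rbind, rows)
    if (!is.null(out)) write_results(results, out)
  } else {
    rows <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
      rows[[i]] <- one(i)
      if (!is.null(out)) {
        utils::write.table(rows[[i]], out, sep = ",", row.names = FALSE,
                           col.names = i == 1L, append = i > 1L)
      }
    }
    results <- do.call(rbind, rows)
  }
  rownames(results) <- NULL
  class(results) <- c("grid_results", class(results))
  results
}

#' Aggregate grid results along one design factor
#'
#' Groups scenario-level power and Type I error by one factor and reports
#' unweighted means per level together with all pairwise level differences
#' in percentage points. `distribution_class` maps condition 13 to
#' `"normal"`, odd conditions 1-11 to `"moderate"` skew and even conditions
#' 2-12 to `"high"` skew.
#'
#' @param results A `grid_results` data frame.
#' @param factor One of `"distribution_class"`, `"delta"`, `"n_items"`,
#'   `"n_categories"`, `"ratio"`.
#' @return A data frame with one row per factor level (columns `level`,
#'   `n_scenarios`, `mean_power`, `mean_type1_error`); the pairwise
#'   percentage-point differences are attached as attribute `"pairwise"`.
#' @export
aggregate_contrast <- function(results,
                               factor = c("distribution_class", "delta",
                                          "n_items", "n_categories", "ratio")) {
  stopifnot(is.data.frame(results), nrow(results) > 0L)
  factor <- match.arg(factor)
  key <- switch(factor,
    distribution_class = distribution_class(results$condition_id),
    delta = as.character(results$delta),
    n_items = as.character(results$n_items),
    n_categories = as.character(results$n_categories),
    ratio = sprintf("R%d/F%d", results$n_ref, results$n_focal))
  lev <- switch(factor,
    distribution_class = intersect(c("normal", "moderate", "high"), key),
    unique(key))
  agg <- do.call(rbind, lapply(lev, function(l) {
    sub <- results[key == l, ]
    data.frame(level = l, n_scenarios = nrow(sub),
               mean_power = mean(sub$power, na.rm = TRUE),
               mean_type1_error = mean(sub$type1_error, na.rm = TRUE))
  }))
  rownames(agg) <- NULL
  if (nrow(agg) > 1L) {
    pairs <- utils::combn(nrow(agg), 2L)
    pw <- data.frame(
      level_a = agg$level[pairs[1, ]],
      level_b = agg$level[pairs[2, ]],
      power_diff_pp = 100 * (agg$mean_power[pairs[1, ]] -
                               agg$mean_power[pairs[2, ]]),
      type1_diff_pp = 100 * (agg$mean_type1_error[pairs[1, ]] -
                               agg$mean_type1_error[pairs[2, ]]))
    attr(agg, "pairwise") <- pw
  }
  agg
}
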