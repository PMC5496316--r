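#' One cell of the simulation design
#'
#' Bundles the factors that define a simulation condition: group sample
#' sizes, uniform-DIF magnitude, scale length, number of response categories,
#' latent trait distribution condition, the studied item, and the base seed
#' driving all replications of the cell.
#'
#' @param n_ref,n_focal Reference and focal group sample sizes.
#' @param delta Uniform-DIF threshold shift for the studied item in the focal
#'   group (0 means no DIF).
#' @param n_items Scale length k.
#' @param n_categories Number of ordered response categories J.
#' @param condition_id Latent trait distribution condition (1..13, see
#'   [trait_condition()]).
#' @param studied_item Index of the item carrying the DIF effect (default 1).
#' @param seed Integer base seed for the cell.
#' @return An object of class `dif_scenario`.
#' @export
scenario <- function(n_ref, n_focal, delta, n_items, n_categories,
                     condition_id = 13L, studied_item = 1L, seed = 1L) {
  n_ref <- as.integer(n_ref); n_focal <- as.integer(n_focal)
  n_items <- as.integer(n_items); n_categories <- as.integer(n_categories)
  studied_item <- as.integer(studied_item)
  if (any(is.na(c(n_ref, n_focal, n_items, n_categories, studied_item)))) {
    stop("scenario fields must be integer-valued", call. = FALSE)
  }
  if (n_ref < 1L || n_focal < 1L) stop("group sizes must be positive", call. = FALSE)
  if (n_items < 2L) stop("'n_items' must be >= 2", call. = FALSE)
  if (n_categories < 2L) stop("'n_categories' must be >= 2", call. = FALSE)
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta < 0) {
    stop("'delta' must be a nonnegative scalar", call. = FALSE)
  }
  if (studied_item < 1L || studied_item > n_items) {
    stop("'studied_item' out of range", call. = FALSE)
  }
  trait_condition(condition_id)   # validates condition_id
  structure(
    list(n_ref = n_ref, n_focal = n_focal, delta = as.numeric(delta),
         n_items = n_items, n_categories = n_categories,
         condition_id = as.integer(condition_id),
         studied_item = studied_item, seed = as.integer(seed)),
    class = "dif_scenario"
  )
}

#' @export
print.dif_scenario <- function(x, ...) {
  cat(sprintf(
    "scenario: R%d/F%d, delta = %g, %d items, %d categories, condition %d (%s), seed %d\n",
    x$n_ref, x$n_focal, x$delta, x$n_items, x$n_categories,
    x$condition_id, distribution_class(x$condition_id), x$seed))
  invisible(x)
}

#' Enumerate a factorial scenario grid
#'
#' Expands factor levels into one row per simulation cell, in a fixed
#' deterministic order (conditions vary fastest, then categories, scale
#' length, DIF magnitude, and sample-size ratio). The default levels
#' reproduce the full 780-cell study grid: 5 sample-size ratios x 2 DIF
#' magnitudes x 2 scale lengths x 3 category counts x 13 distribution
#' conditions.
#'
#' @param ratios List of `c(n_ref, n_focal)` pairs.
#' @param deltas Uniform-DIF magnitudes.
#' @param n_items Scale lengths.
#' @param n_categories Category counts.
#' @param conditions Distribution condition ids.
#' @param studied_item Studied item index (recycled over the grid).
#' @return A data frame with columns n_ref, n_focal, delta, n_items,
#'   n_categories, condition_id, studied_item.
#' @export
scenario_grid <- function(ratios = list(c(100, 100), c(200, 100), c(300, 100),
                                        c(400, 100), c(500, 100)),
                          deltas = c(0.5, 1.0),
                          n_items = c(5L, 10L),
                          n_categories = c(3L, 5L, 7L),
                          conditions = 1:13,
                          studied_item = 1L) {
  g <- expand.grid(condition_id = as.integer(conditions),
                   n_categories = as.integer(n_categories),
                   n_items = as.integer(n_items),
                   delta = as.numeric(deltas),
                   ratio = seq_along(ratios),
                   KEEP.OUT.ATTRS = FALSE)
  nr <- vapply(ratios, `[`, numeric(1), 1L)
  nf <- vapply(ratios, `[`, numeric(1), 2L)
  out <- data.frame(n_ref = as.integer(nr[g$ratio]),
                    n_focal = as.integer(nf[g$ratio]),
                    delta = g$delta,
                    n_items = g$n_items,
                    n_categories = g$n_categories,
                    condition_id = g$condition_id,
                    studied_item = as.integer(studied_item))
  out[order(out$n_ref, out$delta, out$n_items, out$n_categories,
            out$condition_id), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

# Deterministic per-scenario seed: folds the cell's factor levels and a base
# seed with a multiplicative hash mod 2^31 - 1, so any subset of a grid rerun
# in isolation gets the same seed as in the full run. All intermediates stay
# below 2^53 and results below 2^31.
scenario_seed <- function(base_seed, n_ref, n_focal, delta, n_items,
                          n_categories, condition_id, studied_item = 1L) {
  m <- 2147483647
  h <- as.numeric(base_seed) %% m
  for (v in c(n_ref, n_focal, round(100 * delta), n_items,
              n_categories, condition_id, studied_item)) {
    h <- (h * 131 + as.numeric(v) + 1) %% m
  }
  as.integer(h) + 1L
}
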