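#' Generate one simulated dataset
#'
#' Draws a fresh item bank, samples latent traits for the reference and focal
#' groups from the scenario's distribution condition, shifts the studied
#' item's thresholds by `delta` for the focal group only, and samples ordinal
#' responses from the graded response model. Group coding is 0 (reference)
#' and 1 (focal); because a positive threshold shift makes the studied item
#' harder for the focal group, the expected MIMIC direct-path coefficient is
#' negative.
#'
#' @param scn A [scenario()].
#' @param seed Integer seed for this dataset (defaults to the scenario seed).
#' @param bank Optional fixed [item_bank()]; by default a fresh bank is drawn
#'   per call, so replications average over item-parameter draws.
#' @return An object of class `dif_dataset`: list with `responses`
#'   (n x k integer matrix, categories 1..J), `group` (0/1 vector),
#'   `item_bank`, `true_dif_item` (NA when `delta` is 0) and `scenario`.
#' @export
generate_dataset <- function(scn, seed = scn$seed, bank = NULL) {
  stopifnot(inherits(scn, "dif_scenario"))
  set.seed(as.integer(seed))
  if (is.null(bank)) {
    bank <- draw_item_bank(scn$n_items, scn$n_categories)
  } else {
    stopifnot(inherits(bank, "item_bank"))
    if (bank$n_items != scn$n_items || bank$n_categories != scn$n_categories) {
      stop("'bank' dimensions do not match the scenario", call. = FALSE)
    }
  }
  cond <- trait_condition(scn$condition_id)
  theta_ref <- sample_latent(cond$reference, scn$n_ref)
  theta_focal <- sample_latent(cond$focal, scn$n_focal)
  bank_focal <- apply_uniform_dif(bank, scn$studied_item, scn$delta)

  n <- scn$n_ref + scn$n_focal
  k <- scn$n_items
  responses <- matrix(NA_integer_, n, k,
                      dimnames = list(NULL, paste0("item_", seq_len(k))))
  ref_rows <- seq_len(scn$n_ref)
  for (i in seq_len(k)) {
    responses[ref_rows, i] <-
      grm_sample_item(theta_ref, bank$discriminations[i], bank$thresholds[i, ])
    responses[-ref_rows, i] <-
      grm_sample_item(theta_focal, bank_focal$discriminations[i],
                      bank_focal$thresholds[i, ])
  }
  structure(
    list(responses = responses,
         group = rep(c(0L, 1L), c(scn$n_ref, scn$n_focal)),
         item_bank = bank,
         true_dif_item = if (scn$delta > 0) scn$studied_item else NA_integer_,
         scenario = scn),
    class = "dif_dataset"
  )
}

#' @export
print.dif_dataset <- function(x, ...) {
  cat(sprintf(
    "simulated dataset: %d subjects (%d reference, %d focal), %d items, %d categories\n",
    nrow(x$responses), sum(x$group == 0L), sum(x$group == 1L),
    ncol(x$responses), x$scenario$n_categories))
  if (!is.na(x$true_dif_item)) {
    cat(sprintf("uniform DIF: item %d, threshold shift %g\n",
                x$true_dif_item, x$scenario$delta))
  } else {
    cat("uniform DIF: none\n")
  }
  invisible(x)
}

#' Write / read a dataset as CSV
#'
#' The CSV dialect has columns `item_1` .. `item_k` (integer categories
#' 1..J) and `group` (0 = reference, 1 = focal). Item parameters and scenario
#' metadata are not serialized; a re-read dataset supports DIF testing but
#' not parameter-truth comparisons.
#'
#' @param data A `dif_dataset`.
#' @param path File path.
#' @return `write_dataset` invisibly returns `path`; `read_dataset` returns a
#'   `dif_dataset` with `item_bank`, `true_dif_item` and `scenario` set to NA.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "dif_dataset"))
  df <- as.data.frame(data$responses)
  df$group <- data$group
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path)
  if (!"group" %in% names(df)) {
    stop("dataset CSV must contain a 'group' column", call. = FALSE)
  }
  item_cols <- grep("^item_", names(df), value = TRUE)
  if (length(item_cols) < 2L) {
    stop("dataset CSV must contain at least two 'item_*' columns", call. = FALSE)
  }
  item_cols <- item_cols[order(as.integer(sub("^item_", "", item_cols)))]
  responses <- as.matrix(df[item_cols])
  storage.mode(responses) <- "integer"
  dimnames(responses) <- list(NULL, item_cols)
  group <- as.integer(df$group)
  if (!all(group %in% c(0L, 1L))) {
    stop("'group' must be coded 0 (reference) / 1 (focal)", call. = FALSE)
  }
  structure(
    list(responses = responses, group = group,
         item_bank = NULL, true_dif_item = NA_integer_, scenario = NULL),
    class = "dif_dataset"
  )
}
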