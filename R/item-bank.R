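#' Item bank for a graded response scale
#'
#' Holds the graded response model (GRM) parameters of a k-item scale with J
#' ordered response categories: one discrimination a_i per item and J - 1
#' ascending thresholds b_ij per item.
#'
#' @param discriminations Numeric vector of k discriminations.
#' @param thresholds k x (J - 1) numeric matrix of thresholds; each row must
#'   be strictly ascending.
#' @return An object of class `item_bank`.
#' @export
item_bank <- function(discriminations, thresholds) {
  thresholds <- as.matrix(thresholds)
  k <- length(discriminations)
  if (k < 1L || nrow(thresholds) != k) {
    stop("'thresholds' must have one row per discrimination", call. = FALSE)
  }
  if (any(!is.finite(discriminations)) || any(!is.finite(thresholds))) {
    stop("item parameters must be finite", call. = FALSE)
  }
  if (ncol(thresholds) >= 2L &&
      any(apply(thresholds, 1L, function(b) any(diff(b) <= 0)))) {
    stop("each item's thresholds must be strictly ascending", call. = FALSE)
  }
  structure(
    list(n_items = k,
         n_categories = ncol(thresholds) + 1L,
         discriminations = as.numeric(discriminations),
         thresholds = unname(thresholds)),
    class = "item_bank"
  )
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("item bank: %d items, %d response categories\n",
              x$n_items, x$n_categories))
  tab <- cbind(a = x$discriminations, x$thresholds)
  colnames(tab) <- c("a", paste0("b", seq_len(x$n_categories - 1L)))
  print(round(tab, 3))
  invisible(x)
}

#' Draw a random item bank
#'
#' Discriminations are drawn independently from Uniform(1.5, 2); each item's
#' J - 1 thresholds are i.i.d. standard normal draws sorted ascending. Uses
#' the global random number stream.
#'
#' @param k Number of items (>= 2).
#' @param J Number of ordered response categories (>= 2).
#' @return An [item_bank()].
#' @export
draw_item_bank <- function(k, J) {
  k <- as.integer(k); J <- as.integer(J)
  if (is.na(k) || k < 2L) stop("'k' must be an integer >= 2", call. = FALSE)
  if (is.na(J) || J < 2L) stop("'J' must be an integer >= 2", call. = FALSE)
  a <- stats::runif(k, 1.5, 2)
  b <- matrix(stats::rnorm(k * (J - 1L)), nrow = k)
  b <- t(apply(b, 1L, sort))
  if (J == 2L) b <- matrix(b, nrow = k)   # apply() drops to a vector
  item_bank(a, b)
}

#' Inject uniform DIF into one item
#'
#' Adds a constant `delta` to every threshold of the studied item, leaving
#' all other items untouched. Applied to the focal group only, this shifts
#' the item's difficulty uniformly across the latent trait range, which is
#' the defining mechanism of uniform DIF.
#'
#' @param bank An [item_bank()].
#' @param item Index of the studied item.
#' @param delta Nonnegative threshold shift (0.25, 0.5 and 1.0 correspond to
#'   small, medium and severe DIF).
#' @return A modified copy of `bank`.
#' @export
apply_uniform_dif <- function(bank, item, delta) {
  stopifnot(inherits(bank, "item_bank"))
  item <- as.integer(item)
  if (is.na(item) || item < 1L || item > bank$n_items) {
    stop("'item' is not a valid item index", call. = FALSE)
  }
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta)) {
    stop("'delta' must be a numeric scalar", call. = FALSE)
  }
  bank$thresholds[item, ] <- bank$thresholds[item, ] + delta
  bank
}

#' GRM response category probabilities
#'
#' Category probabilities of the graded response model for a single item.
#' The cumulative probability of responding in category j + 1 or above is
#' plogis(a * (theta - b_j)); category probabilities are the adjacent
#' differences, with the implicit boundaries 1 (above category 0) and 0
#' (above category J).
#'
#' @param theta Scalar latent trait value.
#' @param a Item discrimination.
#' @param thresholds Ascending vector of J - 1 thresholds.
#' @return Probability vector of length J summing to 1.
#' @examples
#' grm_category_probs(0, 2, c(-1, 1))
#' @export
grm_category_probs <- function(theta, a, thresholds) {
  if (length(thresholds) >= 2L && any(diff(thresholds) <= 0)) {
    stop("'thresholds' must be strictly ascending", call. = FALSE)
  }
  pstar <- stats::plogis(a * (theta - thresholds))
  -diff(c(1, pstar, 0))
}

# Sample ordinal responses for one item across many subjects at once.
# P(Y >= j + 1 | theta) = plogis(a (theta - b_j)) and the cumulative
# probabilities are decreasing in j, so a single uniform draw per subject
# thresholded against all J - 1 curves yields a GRM-distributed category.
grm_sample_item <- function(theta, a, thresholds) {
  n <- length(theta)
  u <- stats::runif(n)
  y <- rep(1L, n)
  for (b in thresholds) {
    y <- y + (u < stats::plogis(a * (theta - b)))
  }
  y
}
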