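#' Latent trait distribution specification
#'
#' Describes the distribution of the latent trait (theta) for one group:
#' either standard normal or a Beta(shape1, shape2) distribution standardized
#' to population mean 0 and variance 1. Standardized Beta draws retain the
#' skewness of the underlying Beta, which is how skewed quality-of-life-type
#' constructs are emulated.
#'
#' @param family `"normal"` or `"beta"`.
#' @param shape1,shape2 Positive Beta shape parameters; ignored for
#'   `family = "normal"`.
#' @return An object of class `latent_trait_spec`.
#' @examples
#' latent_trait_spec("beta", 1, 4)
#' @export
latent_trait_spec <- function(family = c("normal", "beta"),
                              shape1 = NA_real_, shape2 = NA_real_) {
  family <- match.arg(family)
  if (family == "beta") {
    if (!is.numeric(shape1) || !is.numeric(shape2) ||
        is.na(shape1) || is.na(shape2) || shape1 <= 0 || shape2 <= 0) {
      stop("Beta latent trait requires positive 'shape1' and 'shape2'",
           call. = FALSE)
    }
  }
  structure(
    list(family = family,
         shape1 = as.numeric(shape1),
         shape2 = as.numeric(shape2),
         standardized = TRUE),
    class = "latent_trait_spec"
  )
}

#' @export
print.latent_trait_spec <- function(x, ...) {
  if (x$family == "normal") {
    cat("latent trait: N(0, 1)\n")
  } else {
    cat(sprintf("latent trait: standardized Beta(%g, %g)\n",
                x$shape1, x$shape2))
  }
  invisible(x)
}

#' Analytic moments used to standardize a Beta distribution
#'
#' Population mean and standard deviation of Beta(shape1, shape2), used to
#' transform raw Beta draws x to (x - mean) / sd so that every simulated
#' latent trait has population mean 0 and variance 1 regardless of skewness.
#'
#' @param shape1,shape2 Positive Beta shape parameters.
#' @return A list with components `mean` and `sd`.
#' @examples
#' standardized_beta_params(1, 4)   # mean 0.2, sd ~0.1633
#' @export
standardized_beta_params <- function(shape1, shape2) {
  if (!is.numeric(shape1) || !is.numeric(shape2) ||
      length(shape1) != 1L || length(shape2) != 1L ||
      is.na(shape1) || is.na(shape2) || shape1 <= 0 || shape2 <= 0) {
    stop("'shape1' and 'shape2' must be positive scalars", call. = FALSE)
  }
  s <- shape1 + shape2
  list(mean = shape1 / s,
       sd = sqrt(shape1 * shape2 / (s^2 * (s + 1))))
}

#' Sample latent trait values
#'
#' Draws `n` latent trait values from the distribution described by `spec`,
#' using R's global random number stream (set a seed beforehand for
#' reproducibility). Beta draws are standardized with the analytic population
#' moments from [standardized_beta_params()].
#'
#' @param spec A [latent_trait_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_latent <- function(spec, n) {
  stopifnot(inherits(spec, "latent_trait_spec"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer", call. = FALSE)
  if (spec$family == "normal") {
    stats::rnorm(n)
  } else {
    m <- standardized_beta_params(spec$shape1, spec$shape2)
    (stats::rbeta(n, spec$shape1, spec$shape2) - m$mean) / m$sd
  }
}

# Distribution conditions: which latent trait distribution each group gets.
# Conditions 1-4 pair a normal reference with a skewed focal group, 5-8 give
# both groups the same skewed distribution, 9-12 oppose the skew directions,
# and 13 is the normal/normal benchmark.
.trait_condition_table <- function() {
  b <- function(a, bb) list(family = "beta", shape1 = a, shape2 = bb)
  nrm <- list(family = "normal", shape1 = NA_real_, shape2 = NA_real_)
  list(
    list(ref = nrm,         focal = b(1, 4)),
    list(ref = nrm,         focal = b(0.5, 4)),
    list(ref = nrm,         focal = b(4, 1)),
    list(ref = nrm,         focal = b(4, 0.5)),
    list(ref = b(1, 4),     focal = b(1, 4)),
    list(ref = b(0.5, 4),   focal = b(0.5, 4)),
    list(ref = b(4, 1),     focal = b(4, 1)),
    list(ref = b(4, 0.5),   focal = b(4, 0.5)),
    list(ref = b(1, 4),     focal = b(4, 1)),
    list(ref = b(0.5, 4),   focal = b(4, 0.5)),
    list(ref = b(4, 1),     focal = b(1, 4)),
    list(ref = b(4, 0.5),   focal = b(0.5, 4)),
    list(ref = nrm,         focal = nrm)
  )
}

#' Latent trait specifications for a distribution condition
#'
#' Maps a condition id (1..13) to the pair of latent trait distributions for
#' the reference and focal groups. Condition 13 is normal/normal; conditions
#' 1-12 involve standardized Beta distributions with shapes drawn from
#' \{0.5, 1, 4\}.
#'
#' @param condition_id Integer in 1..13.
#' @return A list with elements `reference` and `focal`, both
#'   [latent_trait_spec()] objects.
#' @export
trait_condition <- function(condition_id) {
  condition_id <- as.integer(condition_id)
  if (is.na(condition_id) || condition_id < 1L || condition_id > 13L) {
    stop("'condition_id' must be an integer in 1..13", call. = FALSE)
  }
  row <- .trait_condition_table()[[condition_id]]
  mk <- function(x) latent_trait_spec(x$family, x$shape1, x$shape2)
  list(reference = mk(row$ref), focal = mk(row$focal))
}

#' Skewness class of a distribution condition
#'
#' Classifies a condition id by the skewness of the latent trait
#' distributions involved: `"normal"` (condition 13), `"moderate"`
#' (conditions 1, 3, 5, 7, 9, 11, which use Beta shapes 1 and 4) or `"high"`
#' (conditions 2, 4, 6, 8, 10, 12, which use shapes 0.5 and 4).
#'
#' @param condition_id Integer vector with entries in 1..13.
#' @return Character vector of class labels.
#' @export
distribution_class <- function(condition_id) {
  condition_id <- as.integer(condition_id)
  if (any(is.na(condition_id)) || any(condition_id < 1L | condition_id > 13L)) {
    stop("'condition_id' entries must be integers in 1..13", call. = FALSE)
  }
  ifelse(condition_id == 13L, "normal",
         ifelse(condition_id %% 2L == 1L, "moderate", "high"))
}
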