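#' Balancing hyperparameters
#'
#' @param beta effective-sample-size growth control, in `[0, 1)`.  Larger
#'   values let the effective size track the raw count more closely; at
#'   `beta = 0` every class has effective size 1.  Default 0.99.
#' @param rho prior-flexibility exponent, >= 0.  `rho = 0` gives a uniform
#'   class prior, `rho = 1` the normalized inverse class frequency.
#'   Default 0.25.
#' @return An object of class `"balance_params"`.
#' @export
balance_params <- function(beta = 0.99, rho = 0.25) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta < 0 || beta >= 1)
    stop("beta must be a single number in [0, 1)")
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho < 0)
    stop("rho must be a single non-negative number")
  structure(list(beta = beta, rho = rho), class = "balance_params")
}

#' Effective number of samples per class
#'
#' The effective sample size of a class with n samples is
#' `E_n = (1 - beta^n) / (1 - beta)`, a saturating count that models the
#' diminishing information carried by additional samples whose features
#' overlap those already seen.  `E_n` runs from 1 (at `beta = 0`, or n = 1)
#' up to n (as `beta -> 1`).  `beta^n` is evaluated in log space so that
#' large counts neither overflow nor underflow silently.
#'
#' @param counts a [class_counts()] object.
#' @param beta growth-control hyperparameter in `[0, 1)`.
#' @return Numeric vector of per-class effective sizes, in `[1, n_i]`.
#' @examples
#' effective_sample_sizes(class_counts(c(838, 224, 305)), 0.99)
#' @export
effective_sample_sizes <- function(counts, beta) {
  counts <- as_class_counts(counts)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta < 0 || beta >= 1)
    stop("beta must be a single number in [0, 1)")
  n <- counts$counts
  if (beta == 0) return(rep(1, length(n)))
  # (1 - exp(n log beta)) / (1 - beta); -expm1 keeps precision as beta -> 1
  (-expm1(n * log(beta))) / (1 - beta)
}

#' Sample-size balance factors
#'
#' Normalized inverse effective sample sizes:
#' `alpha_i = (1/E_i) / sum_j (1/E_j)`.  Classes with fewer effective
#' samples receive larger factors; the factors sum to one.
#'
#' @inheritParams effective_sample_sizes
#' @return Numeric vector summing to 1, one entry per class.
#' @export
balance_factors <- function(counts, beta) {
  e <- 1 / effective_sample_sizes(counts, beta)
  e / sum(e)
}

#' Class prior probabilities
#'
#' Normalized inverse class frequencies with flexibility exponent `rho`:
#' `pp_i = n_i^{-rho} / sum_j n_j^{-rho}`.  `rho = 0` yields the uniform
#' prior; `rho = 1` the inverse-frequency prior; intermediate values
#' interpolate in between.
#'
#' @param counts a [class_counts()] object.
#' @param rho flexibility exponent, >= 0.
#' @return Numeric vector summing to 1, one entry per class.
#' @export
prior_probabilities <- function(counts, rho) {
  counts <- as_class_counts(counts)
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho < 0)
    stop("rho must be a single non-negative number")
  # n^-rho in log space for large n
  w <- exp(-rho * log(counts$counts))
  w / sum(w)
}

#' Precompute the per-class weight table
#'
#' Bundles every per-class quantity the double-balanced loss needs —
#' effective sizes, their inverses, the size-balance factors `alpha`, and
#' the prior probabilities `pp` — into one record computed once from the
#' global training counts and frozen for the run.
#'
#' @param counts a [class_counts()] object.
#' @param params a [balance_params()] object.
#' @return An object of class `"weight_table"` with fields
#'   `effective_sizes`, `inverse_effective`, `alpha`, `prior`, `params`,
#'   `counts`.
#' @examples
#' weight_table(lesion_counts(), balance_params(0.99, 0.25))
#' @export
weight_table <- function(counts, params = balance_params()) {
  counts <- as_class_counts(counts)
  if (!inherits(params, "balance_params"))
    stop("params must be a balance_params object")
  E <- effective_sample_sizes(counts, params$beta)
  structure(list(
    effective_sizes   = E,
    inverse_effective = 1 / E,
    alpha             = balance_factors(counts, params$beta),
    prior             = prior_probabilities(counts, params$rho),
    params            = params,
    counts            = counts
  ), class = "weight_table")
}

#' @export
print.weight_table <- function(x, digits = 4, ...) {
  cat(sprintf("Weight table (beta = %g, rho = %g)\n",
              x$params$beta, x$params$rho))
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], round, digits)
  print(df)
  invisible(x)
}

#' @export
as.data.frame.weight_table <- function(x, ...) {
  data.frame(label = x$counts$labels, n = x$counts$counts,
             E = x$effective_sizes, alpha = x$alpha, prior = x$prior,
             stringsAsFactors = FALSE)
}

#' Write a weight table to CSV
#'
#' Columns: `label, n, E, alpha, prior`.
#'
#' @param table a [weight_table()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_weight_table <- function(table, path) {
  stopifnot(inherits(table, "weight_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

# Coerce bare integer vectors for convenience; insist on validity.
as_class_counts <- function(x) {
  if (inherits(x, "class_counts")) return(x)
  if (is.numeric(x)) return(class_counts(x))
  stop("expected a class_counts object or an integer vector of counts")
}
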