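#' Numerically stable softmax
#'
#' Maps a vector of logits to a probability vector via
#' `exp(z_i) / sum_j exp(z_j)`, computed with max-subtraction so that large
#' logits do not overflow.  Shift-invariant: `softmax(z + c) = softmax(z)`.
#'
#' @param logits finite numeric vector.
#' @return Probability vector of the same length, summing to 1.
#' @examples
#' softmax(c(log(2), 0))  # c(2/3, 1/3)
#' @export
softmax <- function(logits) {
  if (!is.numeric(logits) || any(!is.finite(logits)))
    stop("logits must be finite numeric")
  z <- logits - max(logits)
  e <- exp(z)
  e / sum(e)
}

# Row-wise softmax for an n x k logit matrix.
softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Loss configuration
#'
#' Selects a per-sample loss and its hyperparameters.  Kinds:
#' \describe{
#'   \item{`ce`}{plain cross-entropy `-log p_true`.}
#'   \item{`wce`}{weighted cross-entropy; default weights are the
#'     normalized inverse class frequencies rescaled to mean 1.}
#'   \item{`focal`}{focal loss `(1 - p_true)^gamma * (-log p_true)`.}
#'   \item{`cb`}{class-balanced cross-entropy, weighting by the inverse
#'     effective sample size `(1 - beta) / (1 - beta^n)`.}
#'   \item{`db`}{the double-balanced loss; see [loss_db()].}
#' }
#'
#' @param kind one of `"ce"`, `"wce"`, `"focal"`, `"cb"`, `"db"`.
#' @param gamma focal modulation exponent, >= 0 (default 2).
#' @param variant `"printed"` or `"derived"` double-balanced form; see
#'   [loss_db()].
#' @param eps clamp floor applied to probabilities before any logarithm,
#'   in `(0, 1e-6]`.  The squared-log term of the DB loss diverges
#'   quadratically as p -> 0, so unclamped zero probabilities would
#'   produce non-finite losses.
#' @param reduction `"mean"`, `"sum"` or `"none"` for batch reduction.
#' @return An object of class `"loss_config"`.
#' @export
loss_config <- function(kind = c("ce", "wce", "focal", "cb", "db"),
                        gamma = 2, variant = c("printed", "derived"),
                        eps = 1e-12, reduction = c("mean", "sum", "none")) {
  kind <- match.arg(kind)
  variant <- match.arg(variant)
  reduction <- match.arg(reduction)
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma < 0)
    stop("gamma must be a single non-negative number")
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0 || eps > 1e-6)
    stop("eps must be in (0, 1e-6]")
  structure(list(kind = kind, gamma = gamma, variant = variant,
                 eps = eps, reduction = reduction),
            class = "loss_config")
}

#' @export
print.loss_config <- function(x, ...) {
  cat(sprintf("Loss config: kind=%s gamma=%g variant=%s eps=%g reduction=%s\n",
              x$kind, x$gamma, x$variant, x$eps, x$reduction))
  invisible(x)
}

clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1)

check_prob_vector <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0))
    stop("p must be a non-negative finite probability vector")
  if (abs(sum(p) - 1) > 1e-6)
    stop("p must sum to 1")
  invisible(p)
}

check_label <- function(y, k) {
  if (length(y) != 1L || y != round(y) || y < 1L || y > k)
    stop("label must be a single integer in 1..k")
  as.integer(y)
}

#' Cross-entropy loss for one sample
#'
#' `-log p[y]` with the natural logarithm on the clamped probability.
#' Only the true-class probability enters the value.
#'
#' @param p probability vector over the k classes (softmax output).
#' @param y true class index in `1..k`.
#' @param eps clamp floor before the logarithm.
#' @return Non-negative scalar loss.
#' @export
loss_ce <- function(p, y, eps = 1e-12) {
  check_prob_vector(p); y <- check_label(y, length(p))
  -log(clamp_prob(p[y], eps))
}

#' Default weighted cross-entropy weights
#'
#' Normalized inverse class frequencies (priors at `rho = 1`) rescaled to
#' mean 1, so that the weighted loss stays on the same scale as plain
#' cross-entropy.
#'
#' @param counts a [class_counts()] object.
#' @return Positive numeric weight vector with mean 1.
#' @export
wce_weights <- function(counts) {
  pp <- prior_probabilities(counts, rho = 1)
  pp / mean(pp)
}

#' Weighted cross-entropy loss for one sample
#'
#' @inheritParams loss_ce
#' @param class_weights positive per-class weights; see [wce_weights()] for
#'   the count-derived default.
#' @return `class_weights[y] * (-log p[y])`.
#' @export
loss_wce <- function(p, y, class_weights, eps = 1e-12) {
  check_prob_vector(p); y <- check_label(y, length(p))
  if (length(class_weights) != length(p) || any(class_weights <= 0))
    stop("class_weights must be positive, one per class")
  class_weights[y] * -log(clamp_prob(p[y], eps))
}

#' Focal loss for one sample
#'
#' `(1 - p_true)^gamma * (-log p_true)`: down-weights well-classified
#' (easy) samples so that hard samples dominate the gradient.  At
#' `gamma = 0` it reduces to cross-entropy.
#'
#' @inheritParams loss_ce
#' @param gamma modulation exponent, >= 0.
#' @return Non-negative scalar loss.
#' @export
loss_focal <- function(p, y, gamma = 2, eps = 1e-12) {
  check_prob_vector(p); y <- check_label(y, length(p))
  if (gamma < 0) stop("gamma must be >= 0")
  pt <- clamp_prob(p[y], eps)
  (1 - pt)^gamma * -log(pt)
}

#' Class-balanced cross-entropy loss for one sample
#'
#' Weights the cross-entropy by the inverse effective sample size of the
#' true class, `(1 - beta) / (1 - beta^{n_y})`.  At `beta = 0` (or
#' `n_y = 1`) the weight is 1 and the loss reduces to cross-entropy.
#'
#' @inheritParams loss_ce
#' @param counts a [class_counts()] object giving per-class training counts.
#' @param beta effective-size hyperparameter in `[0, 1)`.
#' @return Non-negative scalar loss.
#' @export
loss_cb <- function(p, y, counts, beta, eps = 1e-12) {
  check_prob_vector(p); y <- check_label(y, length(p))
  e <- 1 / effective_sample_sizes(counts, beta)
  if (length(e) != length(p)) stop("counts and p disagree on k")
  e[y] * -log(clamp_prob(p[y], eps))
}

#' Difficulty weight of one sample
#'
#' The prior-weighted cross-entropy distance between the class prior and
#' the predicted probability for the true class:
#' `-prior_y * log(p_true)`.  It is 0 for a perfectly confident correct
#' prediction and grows as the prediction drifts from the prior's class.
#'
#' @param prior_y prior probability of the true class, in `(0, 1]`.
#' @param p_true predicted probability of the true class, in `(0, 1]`.
#' @param eps clamp floor.
#' @return Non-negative scalar, strictly decreasing in `p_true`.
#' @export
difficulty_weight <- function(prior_y, p_true, eps = 1e-12) {
  if (prior_y <= 0 || prior_y > 1) stop("prior_y must be in (0, 1]")
  if (p_true < 0 || p_true > 1) stop("p_true must be in [0, 1]")
  -prior_y * log(clamp_prob(p_true, eps))
}

# Multiplier on (log p)^2 for the double-balanced loss.
db_factor <- function(alpha_y, prior_y, variant) {
  switch(variant,
         printed = 1 + alpha_y * prior_y,
         derived = (1 + alpha_y) * prior_y,
         stop("unknown variant '", variant, "'"))
}

#' Double-balanced loss for one sample
#'
#' Combines the size-balance factor `alpha` and the difficulty weight
#' (prior times log-probability distance) into one loss on the squared
#' log probability of the true class.  Two published forms exist and both
#' are provided:
#' \describe{
#'   \item{`printed`}{`(1 + alpha_y * pp_y) * (log p_true)^2` — both
#'     weights inside the `(1 + .)` term (the default).}
#'   \item{`derived`}{`(1 + alpha_y) * pp_y * (log p_true)^2` — the literal
#'     composition of the size-balanced loss with the difficulty weight.}
#' }
#' Both are non-negative, vanish only at `p_true = 1`, and strictly
#' decrease as `p_true` grows.
#'
#' @inheritParams loss_ce
#' @param table a [weight_table()] built from the training counts, with k
#'   matching `length(p)`.
#' @param variant `"printed"` (default) or `"derived"`.
#' @return Non-negative scalar loss.
#' @examples
#' tab <- weight_table(class_counts(c(5, 5, 5)))
#' loss_db(c(exp(-1), 1 - exp(-1) - 0.1, 0.1), 1, tab)  # (1 + 1/9) * 1
#' @export
loss_db <- function(p, y, table, variant = c("printed", "derived"),
                    eps = 1e-12) {
  check_prob_vector(p); y <- check_label(y, length(p))
  variant <- match.arg(variant)
  if (!inherits(table, "weight_table"))
    stop("table must be a weight_table")
  if (length(table$alpha) != length(p))
    stop("weight table and probability vector disagree on k")
  L <- -log(clamp_prob(p[y], eps))
  db_factor(table$alpha[y], table$prior[y], variant) * L^2
}

# ---- batch evaluation --------------------------------------------------

# Per-sample loss values for an n x k probability matrix (no reduction).
# cfg decides the kind; table supplies counts/alpha/prior where needed.
loss_values <- function(cfg, P, y, table = NULL) {
  stopifnot(inherits(cfg, "loss_config"))
  P <- as.matrix(P)
  n <- nrow(P); k <- ncol(P)
  y <- as.integer(y)
  if (length(y) != n) stop("labels must match rows of the probability matrix")
  if (n > 0L && (any(y < 1L) || any(y > k))) stop("labels out of range 1..k")
  if (n > 0L && any(abs(rowSums(P) - 1) > 1e-6))
    stop("rows must be probability vectors summing to 1")
  if (cfg$kind %in% c("wce", "cb", "db")) {
    if (is.null(table) || !inherits(table, "weight_table"))
      stop("loss kind '", cfg$kind, "' needs a weight_table")
    if (length(table$alpha) != k) stop("weight table k mismatch")
  }
  if (n == 0L) return(numeric(0))
  pt <- clamp_prob(P[cbind(seq_len(n), y)], cfg$eps)
  L <- -log(pt)
  switch(cfg$kind,
    ce    = L,
    wce   = wce_weights(table$counts)[y] * L,
    focal = (1 - pt)^cfg$gamma * L,
    cb    = table$inverse_effective[y] * L,
    db    = db_factor(table$alpha[y], table$prior[y], cfg$variant) * L^2)
}

#' Batch loss
#'
#' Applies the configured per-sample loss row-wise to a probability matrix
#' and reduces per `cfg$reduction` (`"mean"`, `"sum"` or `"none"`).
#'
#' @param cfg a [loss_config()].
#' @param P n x k matrix whose rows are probability vectors.
#' @param y integer labels in `1..k`, length n.
#' @param table a [weight_table()]; required for kinds `wce`, `cb`, `db`.
#' @return A scalar (mean/sum) or length-n vector (none).
#' @export
batch_loss <- function(cfg, P, y, table = NULL) {
  v <- loss_values(cfg, P, y, table)
  switch(cfg$reduction, mean = mean(v), sum = sum(v), none = v)
}

# ---- gradients ---------------------------------------------------------

# dL/dp_true for each loss kind, vectorized over samples.
dloss_dptrue <- function(cfg, pt, y, table) {
  switch(cfg$kind,
    ce    = -1 / pt,
    wce   = -wce_weights(table$counts)[y] / pt,
    focal = {
      g <- cfg$gamma
      if (g == 0) -1 / pt
      else g * (1 - pt)^(g - 1) * log(pt) - (1 - pt)^g / pt
    },
    cb    = -table$inverse_effective[y] / pt,
    db    = db_factor(table$alpha[y], table$prior[y], cfg$variant) *
              2 * log(pt) / pt)
}

# Gradient of the reduced batch loss with respect to an n x k logit matrix.
# Chain rule through softmax: dL/dz_j = dL/dp_t * p_t * (1[j==y] - p_j).
grad_logits_batch <- function(cfg, Z, y, table = NULL) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  P <- softmax_rows(Z)
  y <- as.integer(y)
  pt <- clamp_prob(P[cbind(seq_len(n), y)], cfg$eps)
  s <- dloss_dptrue(cfg, pt, y, table) * pt
  G <- -s * P
  G[cbind(seq_len(n), y)] <- G[cbind(seq_len(n), y)] + s
  if (cfg$reduction == "mean") G <- G / n
  G
}

#' Gradient of a loss with respect to the logits
#'
#' Analytic gradient of the selected per-sample loss composed with softmax,
#' differentiating through the full loss (including the squared-log term of
#' the double-balanced loss).  For cross-entropy this is the classical
#' `p - onehot(y)`.
#'
#' @param cfg a [loss_config()].
#' @param logits finite numeric vector of k logits.
#' @param y true class index in `1..k`.
#' @param table a [weight_table()]; required for kinds `wce`, `cb`, `db`.
#' @return Numeric gradient vector of length k.
#' @examples
#' grad_logits(loss_config("ce"), c(0, 0, 0), 1)  # c(-2/3, 1/3, 1/3)
#' @export
grad_logits <- function(cfg, logits, y, table = NULL) {
  stopifnot(inherits(cfg, "loss_config"))
  if (!is.numeric(logits) || any(!is.finite(logits)))
    stop("logits must be finite numeric")
  y <- check_label(y, length(logits))
  if (cfg$kind %in% c("wce", "cb", "db")) {
    if (is.null(table) || !inherits(table, "weight_table"))
      stop("loss kind '", cfg$kind, "' needs a weight_table")
    if (length(table$alpha) != length(logits)) stop("weight table k mismatch")
  }
  cfg_none <- cfg; cfg_none$reduction <- "none"
  drop(grad_logits_batch(cfg_none, matrix(logits, nrow = 1L), y, table))
}

#' Effective weighting curve of the double-balanced loss
#'
#' The multiplier the double-balanced loss places on plain cross-entropy as
#' a function of the predicted probability:
#' `W(p) = loss_db(p) / (-log p) = factor * (-log p)`, evaluated on a grid.
#' For each class the curve decreases in p (easy samples are suppressed),
#' and across classes the curves are ordered opposite to the class counts.
#'
#' @param table a [weight_table()].
#' @param class_index class whose curve to evaluate, in `1..k`.
#' @param p_grid probabilities strictly inside `(0, 1)`.
#' @param variant `"printed"` or `"derived"`.
#' @return Numeric vector `W(p)` over the grid.
#' @export
weight_curve <- function(table, class_index, p_grid,
                         variant = c("printed", "derived")) {
  stopifnot(inherits(table, "weight_table"))
  variant <- match.arg(variant)
  class_index <- check_label(class_index, length(table$alpha))
  if (any(p_grid <= 0) || any(p_grid >= 1))
    stop("p_grid must lie strictly inside (0, 1)")
  db_factor(table$alpha[class_index], table$prior[class_index], variant) *
    -log(p_grid)
}
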