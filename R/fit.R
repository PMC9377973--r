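#' Training control parameters
#'
#' Mini-batch SGD schedule for [db_fit()].  The defaults mirror the
#' reference schedule: momentum 0.9, initial learning rate 0.005, and the
#' learning rate multiplied by `lr_decay` every `decay_every` epochs (so
#' after six epochs two decays have been applied and the rate is
#' `0.005 / 9` under the default `lr_decay = 1/3`).
#'
#' @param lr initial learning rate, > 0.
#' @param momentum momentum coefficient in `[0, 1)`.
#' @param lr_decay multiplicative decay factor applied every
#'   `decay_every` epochs (default 1/3).
#' @param decay_every epochs between decays (default 3).
#' @param epochs number of passes over the training data.
#' @param batch_size mini-batch size.
#' @param seed integer seed controlling initialization and shuffling.
#' @return An object of class `"train_control"`.
#' @export
train_control <- function(lr = 0.005, momentum = 0.9, lr_decay = 1 / 3,
                          decay_every = 3L, epochs = 12L, batch_size = 64L,
                          seed = 1L) {
  if (lr < 0) stop("lr must be >= 0")
  if (momentum < 0 || momentum >= 1) stop("momentum must be in [0, 1)")
  if (lr_decay <= 0 || lr_decay > 1) stop("lr_decay must be in (0, 1]")
  structure(list(lr = lr, momentum = momentum, lr_decay = lr_decay,
                 decay_every = as.integer(decay_every),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_control")
}

# Stepped decay: lr is multiplied by lr_decay after every decay_every
# epochs, so epoch 7 under the defaults runs at 0.005 / 9.
lr_at_epoch <- function(control, epoch) {
  control$lr * control$lr_decay^((epoch - 1L) %/% control$decay_every)
}

#' Fit a linear-softmax classifier with a pluggable balanced loss
#'
#' Trains a multinomial linear model `z = W x + b`, `p = softmax(z)` by
#' mini-batch gradient descent with momentum, using any of the package's
#' loss functions ([loss_config()]) and their analytic gradients.  The
#' linear model isolates the effect of the loss: the balancing mechanism
#' under study lives entirely in the loss, not in the architecture.
#'
#' For the weighted losses (`wce`, `cb`, `db`) the per-class weight table
#' is built once from the training-set class tallies and frozen for the
#' run.
#'
#' @param x an n x d feature matrix, a `labeled_dataset`, or a formula.
#' @param y integer (`1..k`) or factor labels, length n (ignored when `x`
#'   is a `labeled_dataset`).
#' @param loss a [loss_config()]; default double-balanced.
#' @param params a [balance_params()] used to build the weight table for
#'   the weighted losses.
#' @param control a [train_control()].
#' @param ... passed between methods.
#' @return An object of class `"db_fit"` with components `W` (k x d),
#'   `b` (k), `loss_history` (mean per-sample training loss per epoch),
#'   `loss`, `params`, `control`, `table`, `levels`.
#' @examples
#' ds <- generate_dataset(dataset_spec(class_counts(c(60, 25, 30)), seed = 3))
#' fit <- db_fit(ds, control = train_control(epochs = 5, seed = 3))
#' predict(fit, ds$features[1:3, ], type = "prob")
#' @export
db_fit <- function(x, ...) UseMethod("db_fit")

#' @rdname db_fit
#' @export
db_fit.labeled_dataset <- function(x, ...) {
  db_fit.default(x$features, x$labels, labels = x$spec$counts$labels, ...)
}

#' @rdname db_fit
#' @param data data frame holding the formula's variables.
#' @export
db_fit.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  db_fit.default(X, y, ...)
}

#' @rdname db_fit
#' @param labels optional class names (defaults to factor levels or
#'   `class1..classk`).
#' @export
db_fit.default <- function(x, y, loss = loss_config("db"),
                           params = balance_params(),
                           control = train_control(), labels = NULL, ...) {
  X <- as.matrix(x)
  if (is.factor(y)) {
    if (is.null(labels)) labels <- levels(y)
    y <- as.integer(y)
  }
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("x and y disagree on n")
  k <- max(y)
  if (k < 2L) stop("need at least 2 classes")
  tallies <- tabulate(y, k)
  if (any(tallies == 0L)) stop("every class in 1..k must be present in y")
  if (is.null(labels)) labels <- paste0("class", seq_len(k))
  counts <- class_counts(tallies, labels)
  table <- weight_table(counts, params)
  stopifnot(inherits(loss, "loss_config"), inherits(control, "train_control"))

  n <- nrow(X); d <- ncol(X)
  cfg_none <- loss; cfg_none$reduction <- "none"

  fit <- with_seed(control$seed, {
    W <- matrix(stats::rnorm(k * d, sd = 0.01), k, d)
    b <- numeric(k)
    vW <- matrix(0, k, d); vb <- numeric(k)
    history <- numeric(control$epochs)
    for (epoch in seq_len(control$epochs)) {
      lr <- lr_at_epoch(control, epoch)
      ord <- sample.int(n)
      total <- 0
      for (start in seq(1L, n, by = control$batch_size)) {
        idx <- ord[start:min(start + control$batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
        Z <- Xb %*% t(W) + matrix(b, length(idx), k, byrow = TRUE)
        if (any(!is.finite(Z)))
          stop("training diverged (non-finite logits) at epoch ", epoch)
        vals <- loss_values(cfg_none, softmax_rows(Z), yb, table)
        if (any(!is.finite(vals)))
          stop("training diverged (non-finite loss) at epoch ", epoch)
        total <- total + sum(vals)
        G <- grad_logits_batch(cfg_none, Z, yb, table) / length(idx)
        gW <- t(G) %*% Xb
        gb <- colSums(G)
        vW <- control$momentum * vW - lr * gW
        vb <- control$momentum * vb - lr * gb
        W <- W + vW
        b <- b + vb
      }
      history[epoch] <- total / n
    }
    list(W = W, b = b, history = history)
  })

  structure(list(W = fit$W, b = fit$b, loss_history = fit$history,
                 loss = loss, params = params, control = control,
                 table = table, levels = labels, dim = d,
                 call = match.call()),
            class = "db_fit")
}

#' @export
print.db_fit <- function(x, ...) {
  cat("Linear-softmax classifier (", x$loss$kind, " loss)\n", sep = "")
  cat(sprintf("  %d classes, %d features, %d epochs; final training loss %.4f\n",
              length(x$levels), x$dim, x$control$epochs,
              utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' @export
coef.db_fit <- function(object, ...) {
  m <- cbind(object$b, object$W)
  dimnames(m) <- list(object$levels,
                      c("(Intercept)", paste0("x", seq_len(object$dim))))
  m
}

#' @export
summary.db_fit <- function(object, ...) {
  structure(list(fit = object, coef = coef(object)),
            class = "summary.db_fit")
}

#' @export
print.summary.db_fit <- function(x, ...) {
  print(x$fit)
  cat("Weight table:\n")
  print(x$fit$table)
  cat("Coefficients:\n")
  print(round(x$coef, 4))
  invisible(x)
}

new_features <- function(object, newdata) {
  if (inherits(newdata, "labeled_dataset")) newdata <- newdata$features
  X <- as.matrix(newdata)
  if (ncol(X) != object$dim) stop("newdata has wrong feature dimension")
  X
}

#' Predict from a fitted classifier
#'
#' @param object a [db_fit()] result.
#' @param newdata feature matrix or `labeled_dataset`.
#' @param type `"class"` (integer labels), `"prob"` (softmax matrix) or
#'   `"link"` (logit matrix).
#' @param ... unused.
#' @return Per `type`: integer vector, or an n x k matrix.
#' @export
predict.db_fit <- function(object, newdata,
                           type = c("class", "prob", "link"), ...) {
  type <- match.arg(type)
  X <- new_features(object, newdata)
  Z <- X %*% t(object$W) +
    matrix(object$b, nrow(X), length(object$b), byrow = TRUE)
  colnames(Z) <- object$levels
  switch(type,
         link = Z,
         prob = softmax_rows(Z),
         class = max.col(Z, ties.method = "first"))
}

#' @export
residuals.db_fit <- function(object, newdata, y = NULL, ...) {
  if (inherits(newdata, "labeled_dataset")) {
    y <- newdata$labels; newdata <- newdata$features
  }
  if (is.null(y)) stop("true labels are required for residuals")
  P <- predict(object, newdata, type = "prob")
  1 - P[cbind(seq_along(y), as.integer(y))]
}

#' @export
plot.db_fit <- function(x, ...) {
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "b",
                 xlab = "epoch", ylab = "mean training loss",
                 main = paste0("Training loss (", x$loss$kind, ")"), ...)
  invisible(x)
}

#' @export
simulate.db_fit <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  X <- new_features(object, newdata)
  P <- predict(object, X, type = "prob")
  draw <- function() apply(P, 1L, function(p) sample.int(length(p), 1L, prob = p))
  sims <- if (is.null(seed)) replicate(nsim, draw())
          else with_seed(seed, replicate(nsim, draw()))
  matrix(sims, nrow = nrow(X), ncol = nsim)
}

#' Evaluate a fitted classifier on held-out data
#'
#' @param fit a [db_fit()] result.
#' @param test_ds a `labeled_dataset` with matching feature dimension.
#' @return List with `confusion` ([confusion()] matrix) and `report`
#'   ([per_class_report()]).
#' @export
evaluate <- function(fit, test_ds) {
  stopifnot(inherits(fit, "db_fit"), inherits(test_ds, "labeled_dataset"))
  pred <- predict(fit, test_ds$features, type = "class")
  cm <- confusion(test_ds$labels, pred, length(fit$levels), fit$levels)
  list(confusion = cm, report = per_class_report(cm))
}
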