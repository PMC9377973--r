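# Independent oracles used across the suite.

# Partial geometric sum: the effective sample size written out term by term.
geom_sum_oracle <- function(n, beta) sum(beta^(0:(n - 1)))

# Per-sample loss evaluated one row at a time through the scalar functions.
loop_loss_oracle <- function(cfg, P, y, table) {
  vapply(seq_len(nrow(P)), function(i) {
    p <- P[i, ]; yi <- y[i]
    switch(cfg$kind,
      ce    = loss_ce(p, yi, cfg$eps),
      wce   = loss_wce(p, yi, wce_weights(table$counts), cfg$eps),
      focal = loss_focal(p, yi, cfg$gamma, cfg$eps),
      cb    = loss_cb(p, yi, table$counts, table$params$beta, cfg$eps),
      db    = loss_db(p, yi, table, cfg$variant, cfg$eps))
  }, numeric(1))
}

# Central finite differences of the loss as a function of the logits.
fd_grad_oracle <- function(cfg, z, y, table, h = 1e-5) {
  f <- function(zz) {
    cfg_none <- cfg; cfg_none$reduction <- "none"
    batch_loss(cfg_none, matrix(softmax(zz), nrow = 1), y, table)
  }
  vapply(seq_along(z), function(j) {
    zp <- z; zp[j] <- zp[j] + h
    zm <- z; zm[j] <- zm[j] - h
    (f(zp) - f(zm)) / (2 * h)
  }, numeric(1))
}

# Random probability vector strictly inside the simplex.
random_prob <- function(k) {
  p <- stats::runif(k, 0.05, 1)
  p / sum(p)
}

# Nearest-center classifier, the Bayes rule for equal isotropic spreads.
nearest_center <- function(X, centers) {
  d2 <- sapply(seq_len(nrow(centers)), function(i) {
    rowSums((X - matrix(centers[i, ], nrow(X), ncol(X), byrow = TRUE))^2)
  })
  max.col(-d2, ties.method = "first")
}

small_table <- function(counts = c(838, 224, 305), beta = 0.99, rho = 0.25,
                        labels = NULL) {
  weight_table(class_counts(counts, labels), balance_params(beta, rho))
}
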