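test_that("softmax is stable, shift-invariant and normalized", {
  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(softmax(c(log(2), 0)), c(2 / 3, 1 / 3))
  p <- softmax(c(1000, 0, 0))
  expect_true(all(is.finite(p)))
  expect_equal(p[1], 1, tolerance = 1e-9)
  set.seed(5)
  z <- rnorm(4)
  expect_equal(softmax(z + 17.3), softmax(z), tolerance = 1e-12)
  expect_equal(sum(softmax(z)), 1, tolerance = 1e-12)
  expect_error(softmax(c(1, NA)), "finite")
  expect_error(softmax(c(1, Inf)), "finite")
})

test_that("cross-entropy depends only on the true-class probability", {
  expect_equal(loss_ce(c(1 - 2e-13, 1e-13, 1e-13), 1), 0, tolerance = 1e-9)
  p <- c(exp(-1), 1 - exp(-1) - 0.1, 0.1)
  expect_equal(loss_ce(p, 1), 1)
  expect_equal(loss_ce(p[c(1, 3, 2)], 1), loss_ce(p, 1))
  expect_error(loss_ce(c(0.5, 0.2), 1), "sum to 1")
  expect_error(loss_ce(c(0.5, 0.5), 3), "1..k")
})

test_that("weighted cross-entropy scales by the true-class weight", {
  p <- c(exp(-1), 1 - exp(-1))
  expect_equal(loss_wce(p, 1, c(1, 1)), loss_ce(p, 1))
  expect_equal(loss_wce(p, 1, c(2, 7)), 2)
  expect_error(loss_wce(p, 1, c(-1, 1)), "positive")
})

test_that("focal loss modulates cross-entropy by confidence", {
  p <- c(0.5, 0.3, 0.2)
  expect_equal(loss_focal(p, 1, gamma = 0), loss_ce(p, 1))
  expect_equal(loss_focal(p, 1, gamma = 2), 0.25 * log(2))
  expect_equal(loss_focal(c(1 - 2e-13, 1e-13, 1e-13), 1, 2), 0,
               tolerance = 1e-9)
  # harder samples keep more of their loss
  easy <- loss_focal(c(0.9, 0.1), 1, 2) / loss_ce(c(0.9, 0.1), 1)
  hard <- loss_focal(c(0.2, 0.8), 1, 2) / loss_ce(c(0.2, 0.8), 1)
  expect_true(hard > easy)
})

test_that("class-balanced CE weights by inverse effective size", {
  p <- c(0.4, 0.6)
  cc <- class_counts(c(1, 50))
  expect_equal(loss_cb(p, 1, cc, 0.9), loss_ce(p, 1))   # n = 1 -> weight 1
  expect_equal(loss_cb(p, 2, cc, 0), loss_ce(p, 2))     # beta = 0 -> CE
  tabcnt <- lesion_counts()
  w_cancer <- 1 / effective_sample_sizes(tabcnt, 0.99)[2]
  w_adenoma <- 1 / effective_sample_sizes(tabcnt, 0.99)[1]
  p3 <- c(0.5, 0.3, 0.2)
  expect_true(loss_cb(p3, 2, tabcnt, 0.99) > loss_cb(p3, 1, tabcnt, 0.99))
  expect_equal(loss_cb(p3, 2, tabcnt, 0.99), w_cancer * -log(0.3))
  expect_equal(loss_cb(p3, 1, tabcnt, 0.99), w_adenoma * -log(0.5))
})

test_that("difficulty weight is the prior-scaled log distance", {
  expect_equal(difficulty_weight(0.3, 1), 0)
  expect_equal(difficulty_weight(1, exp(-1)), 1)
  expect_equal(difficulty_weight(0.4, 0.5), 0.4 * log(2))
  # strictly decreasing in the predicted probability
  g <- seq(0.05, 0.95, by = 0.05)
  vals <- vapply(g, function(p) difficulty_weight(0.5, p), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(difficulty_weight(0, 0.5), "prior_y")
})

test_that("double-balanced loss matches hand-computed values", {
  tab_eq <- small_table(c(5, 5, 5))
  p <- c(exp(-1), 1 - exp(-1) - 0.1, 0.1)
  # uniform counts: alpha = prior = 1/3, printed factor 1 + 1/9
  expect_equal(loss_db(p, 1, tab_eq, "printed"), (1 + 1 / 9))
  expect_equal(loss_db(p, 1, tab_eq, "derived"), (1 + 1 / 3) * (1 / 3))
  expect_equal(loss_db(c(1 - 2e-13, 1e-13, 1e-13), 1, tab_eq), 0,
               tolerance = 1e-9)
  # rarer class carries the larger loss at identical confidence
  tab <- small_table()
  p_fix <- c(0.5, 0.3, 0.2)
  l_cancer <- loss_db(c(0.3, 0.5, 0.2), 2, tab)
  l_adenoma <- loss_db(c(0.5, 0.3, 0.2), 1, tab)
  expect_true(l_cancer > l_adenoma)
  expect_error(loss_db(c(0.5, 0.5), 1, tab), "disagree on k")
})

test_that("db loss decreases strictly as the true-class probability grows", {
  tab <- small_table()
  for (variant in c("printed", "derived")) {
    vals <- vapply(seq(0.05, 0.95, 0.05), function(pt) {
      loss_db(c(pt, (1 - pt) / 2, (1 - pt) / 2), 1, tab, variant)
    }, numeric(1))
    expect_true(all(diff(vals) < 0))
    expect_true(all(vals >= 0))
  }
})

test_that("batch losses equal the scalar-function loop oracle", {
  set.seed(31)
  tab <- small_table(c(17, 5, 9, 3), labels = letters[1:4])
  for (kind in c("ce", "wce", "focal", "cb", "db")) {
    for (variant in c("printed", "derived")) {
      cfg <- loss_config(kind, gamma = 1.7, variant = variant,
                         reduction = "none")
      n <- 23
      P <- t(replicate(n, random_prob(4)))
      y <- sample(4, n, replace = TRUE)
      v <- batch_loss(cfg, P, y, tab)
      expect_equal(v, loop_loss_oracle(cfg, P, y, tab), tolerance = 1e-12)
      cfg$reduction <- "mean"
      expect_equal(batch_loss(cfg, P, y, tab), mean(v), tolerance = 1e-12)
      cfg$reduction <- "sum"
      expect_equal(batch_loss(cfg, P, y, tab), sum(v), tolerance = 1e-12)
    }
  }
})

test_that("batch loss handles edge shapes and validates inputs", {
  cfg <- loss_config("ce", reduction = "none")
  p <- c(0.2, 0.8)
  expect_equal(batch_loss(cfg, matrix(p, 1), 2L), loss_ce(p, 2))
  # duplicating a sample leaves the mean unchanged
  cfgm <- loss_config("ce")
  P <- rbind(p, p, c(0.6, 0.4))
  expect_equal(batch_loss(cfgm, rbind(P, p), c(1L, 1L, 2L, 1L)) *
                 4, batch_loss(cfgm, P, c(1L, 1L, 2L)) * 3 + loss_ce(p, 1))
  expect_error(batch_loss(cfg, matrix(p, 1), c(1L, 2L)), "match rows")
  expect_error(batch_loss(loss_config("db"), matrix(p, 1), 1L), "weight_table")
  expect_length(batch_loss(cfg, matrix(numeric(0), 0, 2), integer(0)), 0)
})

test_that("weight curves decrease in p and order opposite to counts", {
  grid <- seq(0.05, 0.95, by = 0.05)
  tab_eq <- small_table(c(10, 10, 10))
  curves_eq <- sapply(1:3, function(i) weight_curve(tab_eq, i, grid))
  expect_equal(curves_eq[, 1], curves_eq[, 2])
  expect_equal(curves_eq[, 1], curves_eq[, 3])

  tab <- small_table()  # adenoma 838, cancer 224, polyp 305
  for (i in 1:3) expect_true(all(diff(weight_curve(tab, i, grid)) < 0))
  w_ad <- weight_curve(tab, 1, grid)
  w_ca <- weight_curve(tab, 2, grid)
  w_po <- weight_curve(tab, 3, grid)
  expect_true(all(w_ad < w_po) && all(w_po < w_ca))
  # W(p) -> 0 as p -> 1
  expect_lt(weight_curve(tab, 1, 1 - 1e-12), 1e-10)
  expect_error(weight_curve(tab, 1, c(0.5, 1)), "strictly inside")
})

test_that("loss_config validates hyperparameters", {
  expect_error(loss_config("db", gamma = -1), "non-negative")
  expect_error(loss_config("db", eps = 0.5), "eps")
  expect_error(loss_config("nope"), "arg")
})
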