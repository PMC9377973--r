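test_that("class_counts validates its inputs", {
  cc <- class_counts(c(2, 1), c("a", "b"))
  expect_s3_class(cc, "class_counts")
  expect_error(class_counts(integer(0)), "at least one")
  expect_error(class_counts(c(0, 1)), "positive integers")
  expect_error(class_counts(c(1.5, 1)), "positive integers")
  expect_error(class_counts(c(1, 1), c("a", "a")), "unique")
  expect_error(class_counts(1:3, c("a", "b")), "same length")
})

test_that("effective sample sizes follow the geometric-series form", {
  expect_equal(effective_sample_sizes(class_counts(c(1, 1, 1)), 0.5),
               c(1, 1, 1))
  expect_equal(effective_sample_sizes(class_counts(2), 0.5), 1.5)
  # at beta = 0 every class collapses to effective size 1
  expect_equal(effective_sample_sizes(class_counts(c(5, 1000)), 0), c(1, 1))
  # lesion profile at beta = 0.9 saturates at 1/(1-beta) = 10 for all classes
  E <- effective_sample_sizes(lesion_counts(), 0.9)
  expect_true(all(abs(E - 10) < 1e-6))
  expect_error(effective_sample_sizes(class_counts(5), 1), "\\[0, 1\\)")
  expect_error(effective_sample_sizes(class_counts(5), -0.1), "\\[0, 1\\)")
})

test_that("effective sizes match the partial geometric sum oracle", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(1:1000, 4)
    beta <- runif(1, 0, 0.999)
    E <- effective_sample_sizes(class_counts(n), beta)
    expect_equal(E, vapply(n, geom_sum_oracle, numeric(1), beta = beta),
                 tolerance = 1e-9)
  }
})

test_that("effective sizes interpolate between 1 and n across beta", {
  n <- c(10, 100, 10000)
  E_hi <- effective_sample_sizes(class_counts(n), 1 - 1e-9)
  expect_true(all(abs(E_hi - n) / n < 1e-4))
  E_lo <- effective_sample_sizes(class_counts(n), 1e-12)
  expect_equal(E_lo, c(1, 1, 1), tolerance = 1e-9)
  expect_equal(balance_factors(class_counts(n), 1e-12), rep(1 / 3, 3),
               tolerance = 1e-9)
  # huge counts neither overflow nor underflow
  expect_true(all(is.finite(effective_sample_sizes(class_counts(c(1, 1e6)), 0.9))))
})

test_that("balance factors normalize, respect symmetry and count order", {
  expect_equal(balance_factors(class_counts(c(100, 100, 100)), 0.7),
               rep(1 / 3, 3))
  a <- balance_factors(lesion_counts(), 0.99)  # adenoma, cancer, polyp
  expect_equal(sum(a), 1, tolerance = 1e-12)
  expect_true(a[2] > a[3] && a[3] > a[1])  # rarest class weighted most
  a2 <- balance_factors(class_counts(c(1, 1000000)), 0.9)
  expect_equal(sum(a2), 1, tolerance = 1e-12)
  expect_true(all(a2 > 0) && a2[1] > a2[2])
})

test_that("alpha and prior are permutation-equivariant and monotone", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(1:5000, 5)
    beta <- runif(1, 0.5, 0.999); rho <- runif(1, 0.1, 2)
    a <- balance_factors(class_counts(n), beta)
    pp <- prior_probabilities(class_counts(n), rho)
    expect_equal(sum(a), 1, tolerance = 1e-12)
    expect_equal(sum(pp), 1, tolerance = 1e-12)
    perm <- sample(5)
    expect_equal(balance_factors(class_counts(n[perm]), beta), a[perm])
    expect_equal(prior_probabilities(class_counts(n[perm]), rho), pp[perm])
    ord <- order(n)
    expect_true(all(diff(a[ord]) <= 1e-15))    # more samples, smaller alpha
    expect_true(all(diff(pp[ord]) < 0))        # strictly for rho > 0
    expect_true(all(diff(effective_sample_sizes(class_counts(n[ord]), beta)) >= 0))
  }
})

test_that("tied counts give exactly equal weights", {
  a <- balance_factors(class_counts(c(50, 50, 7)), 0.95)
  expect_identical(a[1], a[2])
  pp <- prior_probabilities(class_counts(c(50, 50, 7)), 0.6)
  expect_identical(pp[1], pp[2])
})

test_that("prior probabilities cover the uniform and inverse-frequency poles", {
  expect_equal(prior_probabilities(class_counts(c(7, 900, 33)), 0),
               rep(1 / 3, 3))
  expect_equal(prior_probabilities(class_counts(c(2, 1, 1)), 1),
               c(0.2, 0.4, 0.4))
  pp <- prior_probabilities(lesion_counts(), 1)
  expect_equal(pp, (1 / c(838, 224, 305)) / sum(1 / c(838, 224, 305)))
  expect_error(prior_probabilities(class_counts(5), -1), "non-negative")
})

test_that("weight_table bundles consistent components", {
  expect_error(balance_params(1, 0.5), "\\[0, 1\\)")
  expect_error(balance_params(0.5, -1), "non-negative")
  tab <- weight_table(class_counts(c(5, 5)), balance_params(0.9, 0.5))
  expect_equal(tab$alpha, c(0.5, 0.5))
  expect_equal(tab$prior, c(0.5, 0.5))
  tab2 <- weight_table(class_counts(c(10, 1)), balance_params(0.5, 1))
  expect_equal(tab2$prior, c(1 / 11, 10 / 11))
  tab3 <- weight_table(lesion_counts(), balance_params(0.99, 0.25))
  expect_equal(sum(tab3$alpha), 1, tolerance = 1e-12)
  expect_equal(sum(tab3$prior), 1, tolerance = 1e-12)
  expect_true(all(tab3$effective_sizes >= 1 &
                  tab3$effective_sizes <= tab3$counts$counts))
  expect_equal(tab3$inverse_effective, 1 / tab3$effective_sizes)
})

test_that("class counts and weight tables round-trip through CSV", {
  tmp <- tempfile(fileext = ".csv")
  cc <- lesion_counts()
  utils::write.csv(as.data.frame(cc), tmp, row.names = FALSE)
  cc2 <- read_class_counts(tmp)
  expect_equal(cc2, cc)

  tmp2 <- tempfile(fileext = ".csv")
  write_weight_table(weight_table(cc), tmp2)
  df <- utils::read.csv(tmp2)
  expect_named(df, c("label", "n", "E", "alpha", "prior"))
  expect_equal(sum(df$alpha), 1, tolerance = 1e-9)
  expect_equal(sum(df$prior), 1, tolerance = 1e-9)
})

test_that("wce default weights are inverse-frequency with mean one", {
  w <- wce_weights(class_counts(c(2, 1, 1)))
  expect_equal(mean(w), 1)
  expect_equal(w, c(0.2, 0.4, 0.4) / mean(c(0.2, 0.4, 0.4)))
})
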