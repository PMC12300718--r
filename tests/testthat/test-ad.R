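test_that("cosine similarity has its geometric anchors", {
  expect_equal(cos_alpha(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cos_alpha(c(1, 0), c(0, 1)), 0)
  expect_equal(cos_alpha(c(1, -2), c(-1, 2)), -1)
  expect_error(cos_alpha(c(0, 0), c(1, 1)), "zero vector")
})

test_that("Shannon entropy matches the closed form in nats", {
  expect_equal(shannon_entropy(c(1, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), log(2))
  expect_equal(shannon_entropy(c(0.75, 0.25)), 0.5623, tolerance = 1e-4)
  expect_error(shannon_entropy(c(0.6, 0.6)), "sum to 1")
})

test_that("posterior band and entropy checks agree for two classes", {
  h75 <- shannon_entropy(c(0.75, 0.25))
  for (p in seq(0.01, 0.99, by = 0.01)) {
    in_band <- p > 0.25 && p < 0.75
    expect_identical(shannon_entropy(c(p, 1 - p)) > h75 + 1e-12, in_band)
  }
})

test_that("structural AD threshold leaves the configured training coverage inside", {
  d <- gen_classification_dataset(n_per_class = c(40, 40), p = 4,
                                  separation = 2, seed = 51)
  ad <- fit_classification_ad(d$x, k = 3, coverage = 0.95)
  inside <- mean(ad$train_knn_sim >= ad$threshold)
  expect_gte(inside, 0.95 - 1 / nrow(d$x))
  expect_lte(inside, 0.95 + 2 / nrow(d$x))
  expect_error(fit_classification_ad(d$x[1:3, ], k = 3), "more than k")
})

test_that("classification verdicts flag uncertain, far-field and training queries correctly", {
  d <- gen_classification_dataset(n_per_class = c(40, 40), p = 4,
                                  separation = 3, seed = 52)
  fit <- qsar_lda(d$x, d$y)
  ad <- fit_classification_ad(d$x, model = fit)
  # training compounds: at least coverage fraction inside the structural AD
  inside <- vapply(seq_len(nrow(d$x)), function(i)
    assess_classification(d$x[i, ], fit, ad)$structural == "inside",
    logical(1))
  expect_gte(mean(inside), 0.95 - 1 / nrow(d$x))
  # far-field check: training vectors confined to one orientation, query
  # pointing the opposite way has negative similarity to every neighbour
  xd <- matrix(runif(200, 1, 2), 50, 4,
               dimnames = list(NULL, paste0("D", 1:4)))
  yd <- factor(rep(c("A", "I"), 25))
  xd[yd == "A", 1] <- xd[yd == "A", 1] + 1
  fit2 <- qsar_lda(xd, yd)
  ad2 <- fit_classification_ad(xd, model = fit2, autoscale = FALSE)
  far <- assess_classification(c(-1.5, -1.5, -1.5, -1.5), fit2, ad2)
  expect_identical(far$structural, "outside")
  expect_identical(far$overall, "unreliable")
  expect_lt(far$knn_sim, ad2$threshold)
  expect_true(all(c("knn_sim", "max_posterior", "entropy") %in% names(far)))
  # a midpoint query is endpoint-uncertain
  mid <- (colMeans(d$x[d$y == "A", ]) + colMeans(d$x[d$y == "I", ])) / 2
  v <- assess_classification(mid, fit, ad)
  expect_identical(v$endpoint, "uncertain")
  expect_identical(v$overall, "unreliable")
})

test_that("leverage matches the hat matrix and its published cutoff", {
  expect_equal(round(h_star(3, 43), 4), 0.2791)
  d <- gen_regression_dataset(n = 30, p = 3, seed = 53)
  fit <- qsar_mlr(d$x, d$y)
  h <- leverage(d$x, fit)
  expect_equal(sum(h), fit$p + 1, tolerance = 1e-8)          # trace of H
  ref <- hatvalues(lm(d$y ~ d$x))
  expect_equal(unname(h), unname(ref), tolerance = 1e-8)
  # centroid of the training design attains the minimum leverage 1/n
  expect_equal(leverage(colMeans(d$x), fit), 1 / fit$n, tolerance = 1e-8)
  expect_true(all(h >= 1 / fit$n - 1e-10))
})

test_that("standardized residuals flag planted outliers", {
  d <- gen_regression_dataset(n = 40, p = 2, sigma = 0.5, seed = 54)
  y <- d$y
  y[7] <- y[7] + 10 * 0.5   # plant a gross response outlier
  fit <- qsar_mlr(d$x, y)
  z <- standardized_residuals(fit)
  expect_true(z$outlier[7])
  expect_equal(z$std_residual, unname(fit$residuals / fit$sigma))
  # unit residual scales to one
  expect_equal(standardized_residuals(fit, truth = 1 + fit$sigma,
                                      predictions = 1)$std_residual, 1)
})

test_that("prediction intervals widen with leverage and vanish without noise", {
  d <- gen_regression_dataset(n = 30, p = 2, sigma = 1, seed = 55)
  fit <- qsar_mlr(d$x, d$y)
  ctr <- prediction_interval(colMeans(d$x), fit)
  outp <- prediction_interval(colMeans(d$x) + 8, fit)
  expect_lt(ctr$width, outp$width)
  exact <- qsar_mlr(d$x, 2 + d$x %*% c(1, -1))
  expect_equal(prediction_interval(colMeans(d$x), exact)$width, 0,
               tolerance = 1e-8)
})

test_that("regression verdicts combine leverage, range and uncertainty checks", {
  d <- gen_regression_dataset(n = 40, p = 3, sigma = 0.5, seed = 56)
  fit <- qsar_mlr(d$x, d$y)
  ad <- fit_regression_ad(fit)
  ok <- assess_regression(colMeans(d$x), fit, ad)
  expect_identical(ok$structural, "inside")
  expect_identical(ok$overall, "reliable")
  # find a direction giving about twice the cutoff leverage
  dir <- rep(1, 3) / sqrt(3)
  f <- uniroot(function(s) leverage(colMeans(d$x) + s * dir, fit) -
                 2 * ad$h_star, c(0.1, 50))$root
  far <- assess_regression(colMeans(d$x) + f * dir, fit, ad)
  expect_identical(far$structural, "outside")
  expect_identical(far$overall, "unreliable")
  # a prediction beyond the training response range is out of range
  big <- assess_regression(colMeans(d$x) + 100 * dir, fit, ad)
  expect_identical(big$endpoint, "out_of_range")
  expect_identical(big$overall, "unreliable")
})

test_that("Williams plot data carries both cutoffs", {
  d <- gen_regression_dataset(n = 25, p = 2, seed = 57)
  fit <- qsar_mlr(d$x, d$y)
  w <- williams_plot_data(fit)
  expect_equal(nrow(w$points), 25)
  expect_equal(w$cutoffs$h_star, h_star(2, 25))
  expect_equal(w$cutoffs$residual_bound, 2.5)
})
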