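test_that("LDA separates well-separated clouds and is symmetric at the midpoint", {
  d <- gen_classification_dataset(n_per_class = c(30, 30), p = 3,
                                  separation = 8, seed = 2)
  fit <- qsar_lda(d$x, d$y)
  expect_equal(mean(predict(fit)$class == d$y), 1)
  # midpoint of the class means with equal priors: posterior (0.5, 0.5)
  sym <- qsar_lda(d$x, d$y, prior = c(A = 0.5, I = 0.5), autoscale = FALSE)
  mid <- (sym$means["A", ] + sym$means["I", ]) / 2
  pr <- predict(sym, matrix(mid, 1, dimnames = list(NULL, sym$descriptors)))
  expect_equal(unname(pr$posterior[1, ]), c(0.5, 0.5), tolerance = 1e-10)
  # exact score tie resolves to the active class
  expect_identical(as.character(pr$class), "A")
})

test_that("empirical priors are the class frequencies", {
  d <- gen_classification_dataset(n_per_class = c(74, 49), p = 3,
                                  separation = 2, seed = 3)
  fit <- qsar_lda(d$x, d$y)
  expect_equal(unname(fit$prior), c(74, 49) / 123, tolerance = 1e-12)
  expect_equal(round(unname(fit$prior), 3), c(0.602, 0.398))
  expect_equal(sum(fit$prior), 1)
})

test_that("LDA posteriors sum to one and are invariant to common score shifts", {
  d <- gen_classification_dataset(n_per_class = c(25, 20), p = 4,
                                  separation = 2, seed = 4)
  fit <- qsar_lda(d$x, d$y)
  pr <- predict(fit, d$x)
  expect_equal(unname(rowSums(pr$posterior)), rep(1, nrow(d$x)))
  shifted <- fit
  for (k in shifted$levels) {
    shifted$coefficients[[k]][["intercept"]] <-
      shifted$coefficients[[k]][["intercept"]] + 7.3
  }
  pr2 <- predict(shifted, d$x)
  expect_equal(pr2$posterior, pr$posterior)
  expect_identical(pr2$class, pr$class)
})

test_that("LDA agrees with the reference implementation to 1e-8", {
  skip_if_not_installed("MASS")
  set.seed(5)
  worst <- 0
  for (r in 1:50) {
    n1 <- sample(10:30, 1); n2 <- sample(10:30, 1); p <- sample(2:5, 1)
    x <- matrix(rnorm((n1 + n2) * p), n1 + n2, p)
    x[seq_len(n1), 1] <- x[seq_len(n1), 1] + 1.5
    colnames(x) <- paste0("D", seq_len(p))
    y <- factor(rep(c("A", "I"), c(n1, n2)))
    fit <- qsar_lda(x, y, autoscale = FALSE)
    ref <- MASS::lda(x, grouping = y)
    pref <- predict(ref, as.data.frame(x))
    pr <- predict(fit, x)
    worst <- max(worst,
                 max(abs(pr$posterior[, "A"] - pref$posterior[, "A"])),
                 mean(pr$class != pref$class))
  }
  expect_lt(worst, 1e-8)
})

test_that("OLS recovers exact linear data and matches lm to 1e-8", {
  set.seed(6)
  x <- matrix(rnorm(40 * 2), 40, 2, dimnames = list(NULL, c("x1", "x2")))
  y <- 1 + 2 * x[, 1] - 3 * x[, 2]
  fit <- qsar_mlr(x, y)
  expect_equal(unname(coef(fit)), c(1, 2, -3), tolerance = 1e-8)
  expect_equal(fit$r_squared, 1)
  worst <- 0
  for (r in 1:50) {
    n <- sample(15:60, 1); p <- sample(1:5, 1)
    xr <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("D", 1:p)))
    yr <- rnorm(n) + xr %*% rnorm(p)
    f1 <- qsar_mlr(xr, yr)
    f2 <- lm(yr ~ xr)
    sm <- summary(f2)
    worst <- max(worst,
                 max(abs(unname(coef(f1)) - unname(coef(f2)))),
                 max(abs(unname(f1$se) - unname(sm$coefficients[, 2]))),
                 abs(f1$sigma - sm$sigma),
                 abs(f1$r_squared - sm$r.squared))
  }
  expect_lt(worst, 1e-8)
})

test_that("constant response yields zero slopes and a flagged R-squared", {
  x <- matrix(rnorm(30), 15, 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(fit <- qsar_mlr(x, rep(2, 15)), "constant response")
  expect_equal(unname(coef(fit))[-1], c(0, 0), tolerance = 1e-10)
  expect_equal(fit$r_squared, 0)
})

test_that("coefficient estimates fall within 3 SE of truth at the nominal rate", {
  beta <- c(1.5, -2, 0.5)
  hits <- 0
  for (r in 1:200) {
    d <- gen_regression_dataset(n = 43, p = 3, beta = beta, sigma = 1,
                                seed = 1000 + r)
    fit <- qsar_mlr(d$x, d$y)
    ok <- abs(coef(fit)[-1] - beta) <= 3 * fit$se[-1]
    hits <- hits + all(ok)
  }
  expect_gte(hits / 200, 0.95)
})

test_that("classification metrics match hand arithmetic", {
  m <- classification_metrics(
    truth = rep(c("A", "I"), c(10, 10)),
    predictions = c(rep("A", 9), "I", rep("I", 8), "A", "A"))
  expect_equal(unname(m$confusion), c(9, 2, 8, 1))  # TP FP TN FN
  expect_equal(m$SN, 0.9)
  expect_equal(m$SP, 0.8)
  expect_equal(m$ACC, 0.85)
  expect_equal(m$P, 9 / 11)
  expect_equal(m$ACC + m$MR, 1)

  perfect <- classification_metrics(c("A", "I"), c("A", "I"), c(0.9, 0.1))
  expect_equal(perfect$ACC, 1)
  expect_equal(perfect$MR, 0)
  expect_equal(perfect$AUC, 1)
})

test_that("AUC equals the reference ROC implementation, ties included", {
  skip_if_not_installed("pROC")
  set.seed(8)
  truth <- rep(c("A", "I"), c(25, 25))
  scores <- round(runif(50), 1)  # deliberate ties
  m <- classification_metrics(truth, ifelse(scores >= 0.5, "A", "I"), scores)
  ref <- as.numeric(pROC::auc(pROC::roc(response = truth, predictor = scores,
                                        levels = c("I", "A"), quiet = TRUE,
                                        direction = "<")))
  expect_equal(m$AUC, ref, tolerance = 1e-10)
})

test_that("single-class truth degrades to NaN with a warning", {
  expect_warning(m <- classification_metrics(c("A", "A"), c("A", "I")), "SP")
  expect_true(is.nan(m$SP))
})

test_that("regression metrics match their formula oracles", {
  set.seed(9)
  x <- matrix(rnorm(24), 12, 2, dimnames = list(NULL, c("a", "b")))
  y <- 1 + x[, 1] - x[, 2]
  fit <- qsar_mlr(x, y)
  # noiseless: perfect internal and external metrics
  m <- regression_metrics(fit, x, y)
  expect_equal(m$R2, 1)
  expect_equal(m$MAE, 0, tolerance = 1e-10)
  expect_equal(m$Q2_LOO, 1, tolerance = 1e-8)
  expect_equal(m$Q2_F3, 1, tolerance = 1e-10)
  expect_equal(m$MAE_test, 0, tolerance = 1e-10)
})

test_that("Q2_F3 matches the hand-computed value when predicting the training mean", {
  # 4-point external fixture, predictions forced to the training mean by an
  # intercept-only-like model on orthogonal test data
  xtr <- matrix(c(-1, 1, -1, 1, -2, 2, 2, -2), 4, 2,
                dimnames = list(NULL, c("a", "b")))
  ytr <- c(1, 3, 5, 7)
  fit <- qsar_mlr(xtr, ytr)
  xte <- matrix(0, 4, 2, dimnames = list(NULL, c("a", "b")))
  # at the origin the fit predicts the training mean exactly (centered design)
  yte <- c(0, 2, 6, 8)
  # 4 points cannot support a leave-one-out refit; Q2_LOO degrades to NaN
  expect_warning(m <- regression_metrics(fit, xte, yte), "Q2_LOO")
  expect_true(is.nan(m$Q2_LOO))
  press <- sum((yte - mean(ytr))^2)
  tss <- sum((ytr - mean(ytr))^2)
  expect_equal(m$Q2_F3, 1 - (press / 4) / (tss / 4))
})
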