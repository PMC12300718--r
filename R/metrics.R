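#' Classification performance metrics
#'
#' Computes the confusion-matrix metrics used to judge the activity model,
#' with the active class `"A"` as positive: accuracy (ACC), misclassification
#' rate (MR), sensitivity (SN), specificity (SP), precision (P), and the area
#' under the ROC curve (AUC) over the posterior score for the positive class.
#' AUC is computed as the Mann-Whitney statistic (rank-average tie handling),
#' which equals the trapezoidal area under the ROC curve.
#'
#' @param truth True classes (factor or character; `"A"` = positive).
#' @param predictions Predicted classes.
#' @param scores Optional numeric score for the positive class (posterior
#'   probability); required for AUC/ROC.
#' @param positive Positive class label (default `"A"`).
#' @return A list with `ACC`, `MR`, `SN`, `SP`, `P`, `AUC`, `confusion`
#'   (named counts TP/FP/TN/FN), and `roc` (data frame of ROC points, when
#'   scores are given).
#' @examples
#' classification_metrics(c("A","A","I","I"), c("A","I","I","I"),
#'                        scores = c(.9, .4, .2, .1))
#' @export
classification_metrics <- function(truth, predictions, scores = NULL,
                                   positive = "A") {
  truth <- as.character(truth); predictions <- as.character(predictions)
  stopifnot(length(truth) == length(predictions))
  pos <- truth == positive
  tp <- sum(pos & predictions == positive)
  fn <- sum(pos & predictions != positive)
  tn <- sum(!pos & predictions != positive)
  fp <- sum(!pos & predictions == positive)
  n <- length(truth)
  warn_na <- function(metric) {
    warning(metric, " undefined (single-class truth or no positive calls); NaN")
    NaN
  }
  sn <- if (tp + fn == 0) warn_na("SN") else tp / (tp + fn)
  sp <- if (tn + fp == 0) warn_na("SP") else tn / (tn + fp)
  pr <- if (tp + fp == 0) NaN else tp / (tp + fp)
  auc <- NA_real_
  roc <- NULL
  if (!is.null(scores) && any(pos) && any(!pos)) {
    r <- rank(scores)
    n1 <- sum(pos); n0 <- sum(!pos)
    auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
    roc <- data.frame(
      threshold = thr,
      tpr = vapply(thr, function(t) sum(pos & scores >= t) / n1, numeric(1)),
      fpr = vapply(thr, function(t) sum(!pos & scores >= t) / n0, numeric(1)))
  }
  list(ACC = (tp + tn) / n, MR = (fp + fn) / n, SN = sn, SP = sp, P = pr,
       AUC = auc, confusion = c(TP = tp, FP = fp, TN = tn, FN = fn), roc = roc)
}

#' Regression performance metrics
#'
#' Fitting, internal-robustness and external-predictivity metrics for the
#' potency model: training R-squared and MAE, leave-one-out cross-validated
#' Q2 (each training compound predicted by the model refit without it), and
#' for an external test set the test MAE and the external predictive
#' squared correlation
#' \deqn{Q^2_{F3} = 1 - \frac{PRESS_{test}/n_{test}}{TSS_{train}/n_{train}}.}
#'
#' @param model A fitted [qsar_mlr()] model.
#' @param test_x,test_y Optional external test descriptors and responses.
#' @return A list with `R2`, `MAE`, `Q2_LOO`, and, when a test set is given,
#'   `MAE_test` and `Q2_F3`.
#' @export
regression_metrics <- function(model, test_x = NULL, test_y = NULL) {
  stopifnot(inherits(model, "qsar_mlr"))
  y <- model$train_y
  out <- list(R2 = model$r_squared, MAE = mean(abs(model$residuals)))
  out$Q2_LOO <- q2_loo(model)
  if (!is.null(test_x)) {
    if (is.null(test_y)) stop("test_y required with test_x")
    pred <- predict(model, test_x)
    press <- sum((test_y - pred)^2)
    tss_tr <- sum((y - mean(y))^2)
    if (tss_tr == 0) {
      warning("zero training response variance; Q2_F3 undefined")
      out$Q2_F3 <- NaN
    } else {
      out$Q2_F3 <- 1 - (press / length(test_y)) / (tss_tr / length(y))
    }
    out$MAE_test <- mean(abs(test_y - pred))
  }
  out
}

#' Leave-one-out cross-validated Q2
#'
#' Refits the OLS model without each training compound in turn, predicts the
#' left-out compound, and returns
#' \eqn{1 - PRESS / TSS} on the training responses.
#'
#' @param model A fitted [qsar_mlr()] model.
#' @return Q2_LOO value.
#' @export
q2_loo <- function(model) {
  x <- model$train_x; y <- model$train_y
  n <- model$n
  if (n - 1 <= model$p + 1) {
    warning("too few compounds to refit without one; Q2_LOO undefined")
    return(NaN)
  }
  press <- 0
  for (i in seq_len(n)) {
    fit_i <- qsar_mlr(x[-i, , drop = FALSE], y[-i])
    press <- press + (y[i] - predict(fit_i, x[i, , drop = FALSE]))^2
  }
  tss <- sum((y - mean(y))^2)
  if (tss == 0) { warning("zero response variance; Q2_LOO undefined"); return(NaN) }
  unname(1 - press / tss)
}
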