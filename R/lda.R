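#' Fit a two-class linear discriminant QSAR
#'
#' Canonical two-class linear discriminant analysis with pooled within-class
#' covariance, the classification algorithm of the activity model. Each class
#' k gets the linear score
#' \deqn{g_k(x) = x^T \Sigma^{-1} \mu_k - \tfrac12 \mu_k^T \Sigma^{-1} \mu_k
#'   + \log \pi_k}
#' and a compound is assigned to the class with the higher score; posteriors
#' are the softmax of the scores. Descriptors are autoscaled on the training
#' set by default and the scaler is stored in the model so new compounds are
#' placed on the same scale. Score ties go to the active class `"A"`
#' (precautionary).
#'
#' @param x Numeric matrix or data frame of descriptors (named columns).
#' @param y Class labels with exactly two levels; level `"A"` is treated as
#'   the positive (active) class when present.
#' @param prior Class priors: `"empirical"` (default, class frequencies) or a
#'   named numeric vector summing to 1.
#' @param autoscale Center and scale descriptors before fitting (default
#'   `TRUE`).
#' @return An object of class `qsar_lda` with components `means` (per-class
#'   mean vectors on the fitting scale), `pooled_cov`, `prior`, `coefficients`
#'   (per-class intercepts and weights of the linear scoring equations),
#'   `scaler`, `levels`, `descriptors`, `train_ids`.
#' @seealso [predict.qsar_lda()], [frozen_lda()] for the published
#'   fixed-coefficient model.
#' @examples
#' set.seed(1)
#' d <- gen_classification_dataset(n_per_class = c(30, 30), p = 3,
#'                                 separation = 4, seed = 1)
#' fit <- qsar_lda(d$x, d$y)
#' table(predict(fit)$class, d$y)
#' @export
qsar_lda <- function(x, y, prior = "empirical", autoscale = TRUE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("D", seq_len(ncol(x)))
  y <- factor(y)
  if (nlevels(y) != 2) stop("qsar_lda models exactly two classes")
  lv <- levels(y)
  if ("A" %in% lv) lv <- c("A", setdiff(lv, "A"))  # active class first
  y <- factor(y, levels = lv)
  if (any(table(y) < 2)) stop("each class needs at least 2 training compounds")

  scaler <- NULL
  if (autoscale) {
    ctr <- colMeans(x); scl <- apply(x, 2, stats::sd)
    if (any(scl == 0)) stop("constant descriptor column; run filter_descriptors() first")
    x <- scale(x, center = ctr, scale = scl)
    scaler <- list(center = ctr, scale = scl)
  }
  n <- nrow(x); p <- ncol(x)
  means <- rbind(colMeans(x[y == lv[1], , drop = FALSE]),
                 colMeans(x[y == lv[2], , drop = FALSE]))
  rownames(means) <- lv
  S <- ((sum(y == lv[1]) - 1) * stats::cov(x[y == lv[1], , drop = FALSE]) +
        (sum(y == lv[2]) - 1) * stats::cov(x[y == lv[2], , drop = FALSE])) / (n - 2)
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("pooled covariance is singular; remove collinear descriptors ",
         "with filter_descriptors()"))
  if (identical(prior, "empirical")) {
    pri <- as.numeric(table(y)) / n
    names(pri) <- lv
  } else {
    if (abs(sum(prior) - 1) > 1e-8) stop("priors must sum to 1")
    pri <- prior[lv]
  }
  coefs <- lapply(lv, function(k) {
    w <- drop(Sinv %*% means[k, ])
    b <- -0.5 * drop(means[k, ] %*% Sinv %*% means[k, ]) + log(pri[[k]])
    c(intercept = b, w)
  })
  names(coefs) <- lv
  structure(list(means = means, pooled_cov = S, pooled_cov_inv = Sinv,
                 prior = pri, coefficients = coefs, scaler = scaler,
                 levels = lv, descriptors = colnames(x),
                 train_x = x, train_y = y,
                 train_ids = rownames(x) %||% as.character(seq_len(n)),
                 n = n, p = p),
            class = "qsar_lda")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.lda_scores <- function(object, x) {
  x <- as.matrix(x)
  if (!is.null(object$scaler)) {
    x <- scale(x, center = object$scaler$center, scale = object$scaler$scale)
  }
  sapply(object$levels, function(k) {
    cf <- object$coefficients[[k]]
    drop(x %*% cf[-1]) + cf[[1]]
  }) |> matrix(nrow = nrow(x), dimnames = list(rownames(x), object$levels))
}

#' Predict method for qsar_lda models
#'
#' @param object A fitted [qsar_lda()] model.
#' @param newdata Descriptor matrix/data frame with the model's descriptor
#'   columns; the training set when omitted.
#' @param ... Unused.
#' @return A list with `class` (factor), `posterior` (matrix, rows sum to 1),
#'   `scores` (linear discriminant scores per class).
#' @export
predict.qsar_lda <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    sc <- .lda_scores_raw(object, object$train_x)
  } else {
    newdata <- as.matrix(newdata)
    if (!is.null(colnames(newdata)) &&
        all(object$descriptors %in% colnames(newdata))) {
      newdata <- newdata[, object$descriptors, drop = FALSE]
    }
    sc <- .lda_scores(object, newdata)
  }
  post <- t(apply(sc, 1, function(s) { e <- exp(s - max(s)); e / sum(e) }))
  colnames(post) <- object$levels
  # argmax; numerically exact ties go to the first (active) level
  tol <- sqrt(.Machine$double.eps)
  pick <- apply(sc, 1, function(s) {
    top <- max(s)
    which(s >= top - tol * max(1, abs(top)))[1]
  })
  cls <- factor(object$levels[pick], levels = object$levels)
  list(class = cls, posterior = post, scores = sc)
}

# scores for data already on the fitting scale (training matrix is stored
# scaled)
.lda_scores_raw <- function(object, xs) {
  sapply(object$levels, function(k) {
    cf <- object$coefficients[[k]]
    drop(xs %*% cf[-1]) + cf[[1]]
  }) |> matrix(nrow = nrow(xs), dimnames = list(rownames(xs), object$levels))
}

#' @export
print.qsar_lda <- function(x, ...) {
  cat("Two-class LDA QSAR (", paste(x$levels, collapse = " vs "), ")\n", sep = "")
  cat("  n =", x$n, " descriptors:", paste(x$descriptors, collapse = ", "), "\n")
  cat("  priors:", paste(sprintf("%s = %.3f", names(x$prior), x$prior),
                         collapse = ", "), "\n")
  for (k in x$levels) {
    cf <- x$coefficients[[k]]
    cat(sprintf("  score_%s = %.4g %s\n", k, cf[[1]],
                paste(sprintf("%+.4g*%s", cf[-1], x$descriptors), collapse = " ")))
  }
  invisible(x)
}

#' @export
summary.qsar_lda <- function(object, ...) {
  pr <- predict(object)
  m <- classification_metrics(object$train_y, pr$class, pr$posterior[, 1])
  out <- list(model = object, training_metrics = m)
  class(out) <- "summary.qsar_lda"
  out
}

#' @export
print.summary.qsar_lda <- function(x, ...) {
  print(x$model)
  m <- x$training_metrics
  cat(sprintf("  training: ACC %.2f  MR %.2f  SN %.2f  SP %.2f  P %.2f  AUC %.2f\n",
              m$ACC, m$MR, m$SN, m$SP, m$P, m$AUC))
  invisible(x)
}

#' @export
coef.qsar_lda <- function(object, ...) {
  do.call(rbind, object$coefficients)
}
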