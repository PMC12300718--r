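#' Fit an ordinary-least-squares regression QSAR
#'
#' Multiple linear regression by ordinary least squares, the algorithm of the
#' potency (Log RP) model. The fit stores everything the applicability-domain
#' machinery needs: the inverse cross-product of the intercept-augmented
#' design matrix (for leverages and prediction intervals), the residual
#' standard deviation, and the training response range.
#'
#' @param x Numeric matrix or data frame of descriptors (named columns).
#' @param y Numeric response (e.g. Log RP).
#' @return An object of class `qsar_mlr` with components `coefficients`,
#'   `se`, `sigma` (residual SD), `xtx_inv`, `fitted`, `residuals`,
#'   `response_range`, `r_squared`, `n`, `p`, `descriptors`, `train_ids`.
#' @examples
#' d <- gen_regression_dataset(n = 43, p = 3, seed = 7)
#' fit <- qsar_mlr(d$x, d$y)
#' coef(fit)
#' @export
qsar_mlr <- function(x, y) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("D", seq_len(ncol(x)))
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (n <= p + 1) stop("need n > p + 1 compounds to fit (residual df > 0)")
  X <- cbind("(Intercept)" = 1, x)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient; ",
                               "remove collinear descriptors")
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  df <- n - p - 1
  sigma2 <- sum(res^2) / df
  xtx_inv <- solve(crossprod(X))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  se <- sqrt(sigma2 * diag(xtx_inv))
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) { warning("constant response; R^2 undefined, reported as 0"); 0 }
        else 1 - sum(res^2) / tss
  structure(list(coefficients = beta, se = se, sigma = sqrt(sigma2),
                 xtx_inv = xtx_inv, fitted = fitted, residuals = res,
                 response_range = range(y), r_squared = r2,
                 train_x = x, train_y = y,
                 train_ids = rownames(x) %||% as.character(seq_len(n)),
                 n = n, p = p, df_residual = df,
                 descriptors = colnames(x)),
            class = "qsar_mlr")
}

#' Predict method for qsar_mlr models
#'
#' @param object A fitted [qsar_mlr()] model.
#' @param newdata Descriptor matrix/data frame; the training set when
#'   omitted.
#' @param interval `"none"` or `"prediction"` for a new-observation interval
#'   \eqn{\hat y \pm t_{1-\alpha/2,\,n-p-1}\, s \sqrt{1 + h}}.
#' @param level Interval coverage (default 0.95).
#' @param ... Unused.
#' @return Numeric vector of predictions, or (with an interval) a data frame
#'   with columns `fit`, `lwr`, `upr`, `leverage`.
#' @export
predict.qsar_mlr <- function(object, newdata = NULL,
                             interval = c("none", "prediction"),
                             level = 0.95, ...) {
  interval <- match.arg(interval)
  x <- if (is.null(newdata)) object$train_x else as.matrix(newdata)
  if (!is.null(colnames(x)) && all(object$descriptors %in% colnames(x))) {
    x <- x[, object$descriptors, drop = FALSE]
  }
  X <- cbind(1, x)
  fit <- drop(X %*% object$coefficients)
  if (interval == "none") return(fit)
  h <- rowSums((X %*% object$xtx_inv) * X)
  tq <- stats::qt(1 - (1 - level) / 2, object$df_residual)
  half <- tq * object$sigma * sqrt(1 + h)
  data.frame(fit = fit, lwr = fit - half, upr = fit + half, leverage = h)
}

#' @export
residuals.qsar_mlr <- function(object, ...) object$residuals

#' @export
coef.qsar_mlr <- function(object, ...) object$coefficients

#' @export
print.qsar_mlr <- function(x, ...) {
  cat("OLS regression QSAR\n")
  cat(sprintf("  n = %d, p = %d, R^2 = %.2f, s = %.3g\n",
              x$n, x$p, x$r_squared, x$sigma))
  cat("  ", paste(sprintf("%s = %.3g (+/- %.2g)", names(x$coefficients),
                          x$coefficients, x$se), collapse = "\n   "), "\n")
  invisible(x)
}

#' @export
summary.qsar_mlr <- function(object, ...) {
  tval <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = tval,
               `Pr(>|t|)` = 2 * stats::pt(-abs(tval), object$df_residual))
  out <- list(model = object, coefficients = tab,
              mae = mean(abs(object$residuals)))
  class(out) <- "summary.qsar_mlr"
  out
}

#' @export
print.summary.qsar_mlr <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training MAE = %.3g\n", x$mae))
  stats::printCoefmat(x$coefficients)
  invisible(x)
}

#' Simulate responses from a fitted regression QSAR
#'
#' Draws new responses at the training design points from the fitted model,
#' \eqn{y^* = X\hat\beta + \epsilon}, \eqn{\epsilon \sim N(0, s^2)}.
#'
#' @param object A fitted [qsar_mlr()] model.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data frame with `nsim` columns.
#' @export
simulate.qsar_mlr <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- replicate(nsim, object$fitted +
                     stats::rnorm(object$n, 0, object$sigma))
  as.data.frame(out)
}
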