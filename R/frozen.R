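#' The published classification model (fixed coefficients)
#'
#' The linear scoring equations of the activity model recalibrated on the
#' full 121-compound dataset, with the coefficients exactly as published:
#' \deqn{score_A = -47 + 37\,GATS3e + 79\,ATSC6p + 10\,GATS8m + 39\,MIC2
#'   + \log(0.61)}
#' \deqn{score_I = -38 + 30\,GATS3e + 73\,ATSC6p + 8.1\,GATS8m + 32\,MIC2
#'   + \log(0.39)}
#' A compound is assigned to the class with the higher score (ties to the
#' active class); posteriors are the softmax of the scores. The prior terms
#' use the natural log (the canonical LDA form); `log_base = 10` is
#' available for sensitivity analysis.
#'
#' @param log_base Base of the prior log terms, `exp(1)` (default) or 10.
#' @return An object of class `frozen_lda` (also usable by
#'   [assess_classification()]).
#' @examples
#' m <- frozen_lda()
#' frozen_classify(c(GATS3e = 0, ATSC6p = 0, GATS8m = 0, MIC2 = 0))$class
#' @export
frozen_lda <- function(log_base = exp(1)) {
  logf <- function(p) log(p, base = log_base)
  coefs <- list(
    A = c(intercept = -47 + logf(0.61),
          GATS3e = 37, ATSC6p = 79, GATS8m = 10, MIC2 = 39),
    I = c(intercept = -38 + logf(0.39),
          GATS3e = 30, ATSC6p = 73, GATS8m = 8.1, MIC2 = 32))
  structure(list(coefficients = coefs, prior = c(A = 0.61, I = 0.39),
                 levels = c("A", "I"),
                 descriptors = c("GATS3e", "ATSC6p", "GATS8m", "MIC2"),
                 scaler = NULL, version = "full-dataset, n = 121"),
            class = c("frozen_lda", "qsar_lda"))
}

#' Classify a compound with the published classification model
#'
#' @param descriptors Named numeric vector (or one-row data frame) with
#'   `GATS3e`, `ATSC6p`, `GATS8m`, `MIC2`.
#' @param model A [frozen_lda()] object (default built fresh).
#' @return A list with `class` (`"A"` or `"I"`), `scores` and `posterior`.
#' @export
frozen_classify <- function(descriptors, model = frozen_lda()) {
  d <- unlist(descriptors)[model$descriptors]
  if (anyNA(d)) stop("descriptors must supply finite ",
                     paste(model$descriptors, collapse = ", "))
  sc <- vapply(model$levels, function(k) {
    cf <- model$coefficients[[k]]
    cf[["intercept"]] + sum(cf[model$descriptors] * d)
  }, numeric(1))
  e <- exp(sc - max(sc))
  post <- e / sum(e)
  cls <- model$levels[[which.max(sc)]]  # which.max ties -> first (= "A")
  list(class = cls, scores = sc, posterior = post)
}

#' @export
predict.frozen_lda <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(colnames(x)) && all(object$descriptors %in% colnames(x))) {
    x <- x[, object$descriptors, drop = FALSE]
  }
  res <- apply(x, 1, function(r) frozen_classify(stats::setNames(r, object$descriptors),
                                                 model = object),
               simplify = FALSE)
  list(class = factor(vapply(res, `[[`, character(1), "class"),
                      levels = object$levels),
       posterior = do.call(rbind, lapply(res, `[[`, "posterior")),
       scores = do.call(rbind, lapply(res, `[[`, "scores")))
}

#' @export
print.frozen_lda <- function(x, ...) {
  cat("Published LDA-QSAR (", x$version, ")\n", sep = "")
  for (k in x$levels) {
    cf <- x$coefficients[[k]]
    cat(sprintf("  score_%s = %.4g %s\n", k, cf[["intercept"]],
                paste(sprintf("%+.4g*%s", cf[x$descriptors], x$descriptors),
                      collapse = " ")))
  }
  invisible(x)
}

#' The published regression model (fixed coefficients)
#'
#' The potency model recalibrated on the full 63-compound dataset, with the
#' published coefficients:
#' \deqn{Log\,RP = -2.7 + 1.6\,piPC5 - 3.3\,GGI9 - 11\,AATSC0e}
#' (standard errors 1.3, 0.26, 0.79, 2.7). The strong-binder threshold
#' Log RP >= -1.26 is carried with the model.
#'
#' @param strong_threshold Strong hTTR-binder threshold on Log RP
#'   (default -1.26).
#' @return An object of class `frozen_mlr`.
#' @examples
#' frozen_predict_logrp(c(piPC5 = 0, GGI9 = 0, AATSC0e = 0))  # intercept: -2.7
#' @export
frozen_mlr <- function(strong_threshold = -1.26) {
  structure(list(
    coefficients = c("(Intercept)" = -2.7, piPC5 = 1.6, GGI9 = -3.3,
                     AATSC0e = -11),
    se = c("(Intercept)" = 1.3, piPC5 = 0.26, GGI9 = 0.79, AATSC0e = 2.7),
    descriptors = c("piPC5", "GGI9", "AATSC0e"),
    strong_threshold = strong_threshold,
    version = "full-dataset, n = 63"),
    class = "frozen_mlr")
}

#' Predict Log RP with the published regression model
#'
#' @param descriptors Named numeric vector (or one-row data frame) with
#'   `piPC5`, `GGI9`, `AATSC0e`.
#' @param model A [frozen_mlr()] object (default built fresh).
#' @return Predicted Log RP.
#' @export
frozen_predict_logrp <- function(descriptors, model = frozen_mlr()) {
  d <- unlist(descriptors)[model$descriptors]
  if (anyNA(d)) stop("descriptors must supply finite ",
                     paste(model$descriptors, collapse = ", "))
  unname(model$coefficients[["(Intercept)"]] +
           sum(model$coefficients[model$descriptors] * d))
}

#' @export
print.frozen_mlr <- function(x, ...) {
  cat("Published MLR-QSAR (", x$version, ")\n", sep = "")
  cat(sprintf("  Log RP = %.4g %s\n", x$coefficients[["(Intercept)"]],
              paste(sprintf("%+.4g*%s", x$coefficients[x$descriptors],
                            x$descriptors), collapse = " ")))
  cat("  strong-binder threshold: Log RP >=", x$strong_threshold, "\n")
  invisible(x)
}
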