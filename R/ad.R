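#' Cosine similarity between descriptor vectors
#'
#' The cos-alpha similarity used by the structural applicability domain of
#' the classification model: the inner product of the two vectors over the
#' product of their Euclidean norms, in \[-1, 1\].
#'
#' @param u,v Numeric vectors of equal length, both nonzero.
#' @return Cosine of the angle between `u` and `v`.
#' @examples
#' cos_alpha(c(1, 0), c(0, 1))  # orthogonal: 0
#' @export
cos_alpha <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cos_alpha is undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Fit the structural applicability domain of the classification model
#'
#' For every training compound the mean cos-alpha similarity to its `k`
#' nearest (most similar) training neighbours is computed, self excluded, on
#' autoscaled model descriptors. The domain threshold is the quantile of
#' that distribution leaving `coverage` of the training compounds at or
#' above it; a query whose k-NN mean similarity falls below the threshold is
#' outside the structural domain. The maximum training Shannon entropy of
#' the class posteriors (the uncertainty reference) is stored when a fitted
#' model is supplied.
#'
#' @param x Training descriptor matrix (model descriptors).
#' @param k Number of neighbours (default 3).
#' @param coverage Training coverage retained inside the domain (default
#'   0.95, i.e. the threshold sits at the 5th percentile of training
#'   similarities).
#' @param model Optional fitted [qsar_lda()]; its training posteriors set
#'   the maximum-entropy reference.
#' @param autoscale Autoscale descriptors before computing similarities
#'   (default `TRUE`).
#' @return An object of class `classification_ad` with the scaled training
#'   matrix, `threshold`, `train_knn_sim`, `k`, `coverage`, `max_entropy`,
#'   and the scaler.
#' @export
fit_classification_ad <- function(x, k = 3, coverage = 0.95, model = NULL,
                                  autoscale = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n <= k) stop("need more than k training compounds")
  scaler <- NULL
  if (autoscale) {
    ctr <- colMeans(x); scl <- apply(x, 2, stats::sd)
    scl[scl == 0] <- 1
    x <- scale(x, center = ctr, scale = scl)
    scaler <- list(center = ctr, scale = scl)
  }
  sims <- .knn_cos_sim(x, x, k, self_exclude = TRUE)
  threshold <- unname(stats::quantile(sims, 1 - coverage))
  max_entropy <- log(2)
  if (!is.null(model)) {
    post <- predict(model)$posterior
    max_entropy <- max(apply(post, 1, shannon_entropy))
  }
  structure(list(train = x, scaler = scaler, k = k, coverage = coverage,
                 threshold = threshold, train_knn_sim = sims,
                 max_entropy = max_entropy),
            class = "classification_ad")
}

# mean cos-alpha of the k most similar rows of `train` for each row of `q`
.knn_cos_sim <- function(q, train, k, self_exclude = FALSE) {
  qn <- q / sqrt(rowSums(q^2))
  tn <- train / sqrt(rowSums(train^2))
  if (any(!is.finite(qn)) || any(!is.finite(tn))) {
    stop("zero descriptor vector encountered in cos-alpha domain")
  }
  S <- qn %*% t(tn)
  vapply(seq_len(nrow(S)), function(i) {
    s <- S[i, ]
    if (self_exclude) s <- s[-i]
    mean(sort(s, decreasing = TRUE)[seq_len(k)])
  }, numeric(1))
}

#' Shannon entropy of a posterior vector
#'
#' \eqn{-\sum_k p_k \ln p_k} in nats, with \eqn{0 \ln 0 = 0}; the
#' prediction-uncertainty measure of the classification model. For two
#' classes the maximum is \eqn{\ln 2} at (0.5, 0.5).
#'
#' @param p Probability vector (non-negative, sums to 1).
#' @return Entropy in nats.
#' @examples
#' shannon_entropy(c(0.75, 0.25))
#' @export
shannon_entropy <- function(p) {
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-8) {
    stop("posteriors must be non-negative and sum to 1")
  }
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Assess the reliability of a classification prediction
#'
#' Applies the three reliability checks of the classification model to a
#' query compound: structural (k-NN mean cos-alpha at or above the domain
#' threshold), endpoint (maximum posterior at or above `post_threshold`,
#' i.e. outside the uncertain band), and uncertainty (Shannon entropy of the
#' posteriors not exceeding the maximum training entropy). The prediction is
#' reliable only when all three pass.
#'
#' @param query Descriptor vector or one-row matrix (model descriptors, raw
#'   scale).
#' @param model A fitted [qsar_lda()] or [frozen_lda()] model.
#' @param ad A fitted [fit_classification_ad()] object.
#' @param post_threshold Posterior band edge (default 0.75; posteriors in
#'   (1 - 0.75, 0.75) are uncertain).
#' @return A list (class `ad_verdict`) with `structural`, `endpoint`,
#'   `uncertainty`, `overall` flags and the numeric evidence
#'   (`knn_sim`, `max_posterior`, `entropy`).
#' @export
assess_classification <- function(query, model, ad, post_threshold = 0.75) {
  q <- matrix(as.numeric(query), nrow = 1)
  colnames(q) <- model$descriptors
  pred <- predict(model, q)
  qs <- q
  if (!is.null(ad$scaler)) {
    qs <- scale(q, center = ad$scaler$center, scale = ad$scaler$scale)
  }
  sim <- .knn_cos_sim(qs, ad$train, ad$k)
  post <- pred$posterior[1, ]
  ent <- shannon_entropy(post)
  structural <- sim >= ad$threshold
  endpoint <- max(post) >= post_threshold
  uncertainty <- ent <= ad$max_entropy + 1e-12
  structure(list(
    class = as.character(pred$class), posterior = post,
    structural = if (structural) "inside" else "outside",
    endpoint = if (endpoint) "certain" else "uncertain",
    uncertainty = if (uncertainty) "reliable" else "unreliable",
    overall = if (structural && endpoint && uncertainty) "reliable" else "unreliable",
    knn_sim = unname(sim), max_posterior = max(post), entropy = ent),
    class = "ad_verdict")
}

#' Leverage of a query compound
#'
#' Hat-matrix value \eqn{h = x_0^T (X^T X)^{-1} x_0} of a query with respect
#' to the intercept-augmented training design of an OLS model; the
#' structural distance measure of the regression applicability domain.
#'
#' @param query Descriptor vector or matrix of queries (model descriptors).
#' @param model A fitted [qsar_mlr()] or [frozen_mlr()] model.
#' @return Leverage value(s).
#' @export
leverage <- function(query, model) {
  q <- if (is.null(dim(query))) matrix(as.numeric(query), nrow = 1)
       else as.matrix(query)
  X <- cbind(1, q)
  drop(rowSums((X %*% model$xtx_inv) * X))
}

#' Leverage cutoff of the regression domain
#'
#' \eqn{h^* = 3 (p + 1) / n} for a model with `p` descriptors fit on `n`
#' training compounds; queries with leverage above it are structural
#' outliers.
#'
#' @param p Number of model descriptors.
#' @param n Training-set size.
#' @return The cutoff value.
#' @examples
#' h_star(3, 43)  # 0.2791
#' @export
h_star <- function(p, n) 3 * (p + 1) / n

#' Standardized residuals of a regression QSAR
#'
#' Residuals divided by the residual standard deviation; values beyond
#' `bound` standard-deviation units flag response outliers (the y-axis of
#' the Williams plot).
#'
#' @param model A fitted [qsar_mlr()] model.
#' @param truth,predictions Optional external truth/prediction pairs; the
#'   training residuals are used when omitted.
#' @param bound Outlier bound in SD units (default 2.5).
#' @return A data frame with `std_residual` and logical `outlier`.
#' @export
standardized_residuals <- function(model, truth = NULL, predictions = NULL,
                                   bound = 2.5) {
  res <- if (is.null(truth)) model$residuals else truth - predictions
  z <- res / model$sigma
  data.frame(std_residual = z, outlier = abs(z) > bound)
}

#' Prediction interval of a regression QSAR
#'
#' New-observation interval
#' \eqn{\hat y \pm t_{1-\alpha/2,\,n-p-1}\, s \sqrt{1 + h}}; its width grows
#' with the query's leverage and is compared against the maximum training
#' interval width by the uncertainty check of the regression domain.
#'
#' @param query Descriptor vector or matrix.
#' @param model A fitted [qsar_mlr()] model.
#' @param alpha Significance level (default 0.05 for 95% intervals).
#' @return A data frame with `fit`, `lwr`, `upr`, `width`, `leverage`.
#' @export
prediction_interval <- function(query, model, alpha = 0.05) {
  q <- if (is.null(dim(query))) matrix(as.numeric(query), nrow = 1)
       else as.matrix(query)
  pr <- predict(model, q, interval = "prediction", level = 1 - alpha)
  pr$width <- pr$upr - pr$lwr
  pr
}

#' Fit the applicability domain of the regression model
#'
#' Stores the leverage cutoff \eqn{h^*}, the maximum training
#' prediction-interval width (the uncertainty reference) and the training
#' response range used by [assess_regression()].
#'
#' @param model A fitted [qsar_mlr()] model.
#' @param alpha Significance level of the prediction intervals.
#' @return An object of class `regression_ad`.
#' @export
fit_regression_ad <- function(model, alpha = 0.05) {
  pr <- prediction_interval(model$train_x, model, alpha)
  structure(list(h_star = h_star(model$p, model$n),
                 train_leverage = leverage(model$train_x, model),
                 max_pi_width = max(pr$width),
                 response_range = model$response_range,
                 alpha = alpha),
            class = "regression_ad")
}

#' Assess the reliability of a regression prediction
#'
#' Applies the three reliability checks of the potency model to a query:
#' structural (leverage at most \eqn{h^*}), response range (prediction
#' within the training Log RP range), and uncertainty (prediction-interval
#' width not exceeding the maximum training width). The prediction is
#' reliable only when all three pass.
#'
#' @param query Descriptor vector (model descriptors, raw scale).
#' @param model A fitted [qsar_mlr()] model.
#' @param ad A fitted [fit_regression_ad()] object.
#' @return A list (class `ad_verdict`) with `structural`, `endpoint`,
#'   `uncertainty`, `overall` flags and numeric evidence (`prediction`,
#'   `leverage`, `pi_width`).
#' @export
assess_regression <- function(query, model, ad) {
  pr <- prediction_interval(query, model, ad$alpha)
  h <- pr$leverage[[1]]
  inside <- h <= ad$h_star
  in_range <- pr$fit[[1]] >= ad$response_range[1] &&
    pr$fit[[1]] <= ad$response_range[2]
  certain <- pr$width[[1]] <= ad$max_pi_width + 1e-12
  structure(list(
    prediction = pr$fit[[1]],
    structural = if (inside) "inside" else "outside",
    endpoint = if (in_range) "in_range" else "out_of_range",
    uncertainty = if (certain) "reliable" else "unreliable",
    overall = if (inside && in_range && certain) "reliable" else "unreliable",
    leverage = h, pi_width = pr$width[[1]],
    pi = c(lwr = pr$lwr[[1]], upr = pr$upr[[1]])),
    class = "ad_verdict")
}

#' @export
print.ad_verdict <- function(x, ...) {
  cat("AD verdict:", x$overall, "\n")
  cat("  structural:", x$structural,
      " endpoint:", x$endpoint,
      " uncertainty:", x$uncertainty, "\n")
  invisible(x)
}

#' Williams plot coordinates
#'
#' Returns the leverage / standardized-residual coordinates and cutoff lines
#' of the Williams plot as plain data, for plotting or export.
#'
#' @param model A fitted [qsar_mlr()] model.
#' @param bound Standardized-residual bound (default 2.5).
#' @return A list with `points` (id, leverage, std_residual) and `cutoffs`
#'   (`h_star`, `residual_bound`).
#' @export
williams_plot_data <- function(model, bound = 2.5) {
  list(points = data.frame(id = model$train_ids,
                           leverage = leverage(model$train_x, model),
                           std_residual = model$residuals / model$sigma),
       cutoffs = list(h_star = h_star(model$p, model$n),
                      residual_bound = bound))
}
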