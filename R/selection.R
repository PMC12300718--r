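# Internal fast fitting/criterion evaluation used by the selection and
# randomization machinery. The criterion is training MR for LDA (minimized)
# and training R^2 for OLS (maximized).

.fit_criterion <- function(x, y, algorithm) {
  if (algorithm == "lda") {
    fit <- tryCatch(qsar_lda(x, y, autoscale = FALSE), error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    mean(predict(fit)$class != fit$train_y)
  } else {
    fit <- tryCatch(qsar_mlr(x, y), error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    fit$r_squared
  }
}

.better <- function(algorithm) {
  # ordering function: TRUE when a is better than b
  if (algorithm == "lda") function(a, b) a < b else function(a, b) a > b
}

#' Step-up variable subset selection
#'
#' Forward beam selection of descriptor subsets: the size-1 population holds
#' the best `beam` single-descriptor models by the training criterion
#' (misclassification rate for LDA, R-squared for OLS); the size-k population
#' is formed by augmenting every retained size-(k-1) subset with each unused
#' descriptor, merging duplicates, and keeping the best `beam`. Optionally
#' each retained population is annotated with its leave-one-out bootstrap
#' error so the growth of model complexity can be checked for overfitting
#' (see [overfit_knee()]).
#'
#' @param x Descriptor matrix (named columns).
#' @param y Response (classes for `"lda"`, numeric for `"ols"`).
#' @param algorithm `"lda"` or `"ols"`.
#' @param beam Population size retained at each model size (default 25);
#'   `Inf` keeps everything (exhaustive search).
#' @param max_size Largest subset size to explore.
#' @param bootstrap Also compute the bootstrap error of the best subset of
#'   each size (default `FALSE`; adds [loo_bootstrap()] cost).
#' @param B Bootstrap resamples when `bootstrap = TRUE`.
#' @param seed Seed for the bootstrap stage.
#' @return An object of class `selection_trace`: a list with one element per
#'   model size, each a list of `subsets` (list of descriptor-name vectors,
#'   best first), `criterion` (sorted values), and optionally `boot_error`,
#'   `boot_spread` for the best subset.
#' @export
step_up_select <- function(x, y, algorithm = c("lda", "ols"), beam = 25,
                           max_size = 3, bootstrap = FALSE, B = 100,
                           seed = 1) {
  algorithm <- match.arg(algorithm)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("D", seq_len(ncol(x)))
  vars <- colnames(x)
  if (max_size >= length(vars) + 1) stop("max_size must not exceed the descriptor count")
  better <- .better(algorithm)
  decreasing <- algorithm != "lda"
  trace <- vector("list", max_size)
  pop <- list()  # list of character vectors
  for (k in seq_len(max_size)) {
    cand <- list()
    if (k == 1) {
      cand <- as.list(vars)
    } else {
      for (s in pop) {
        for (v in setdiff(vars, s)) cand[[length(cand) + 1L]] <- sort(c(s, v))
      }
      cand <- unique(cand)
    }
    crit <- vapply(cand, function(s)
      .fit_criterion(x[, s, drop = FALSE], y, algorithm), numeric(1))
    ok <- !is.na(crit)
    cand <- cand[ok]; crit <- crit[ok]
    ord <- order(crit, decreasing = decreasing)
    keep <- ord[seq_len(min(length(ord), if (is.finite(beam)) beam else length(ord)))]
    pop <- cand[keep]
    entry <- list(size = k, subsets = pop, criterion = crit[keep])
    if (bootstrap && length(pop) > 0) {
      bt <- loo_bootstrap(x, y, subset = pop[[1]], algorithm = algorithm,
                          B = B, seed = seed + k)
      entry$boot_error <- bt$estimate
      entry$boot_spread <- bt$spread
    }
    trace[[k]] <- entry
  }
  structure(trace, class = "selection_trace", algorithm = algorithm)
}

#' @export
print.selection_trace <- function(x, ...) {
  alg <- attr(x, "algorithm")
  cat("Step-up selection trace (", alg, ")\n", sep = "")
  for (e in x) {
    best <- e$subsets[[1]]
    cat(sprintf("  size %d: best = {%s}, criterion = %.4f", e$size,
                paste(best, collapse = ", "), e$criterion[[1]]))
    if (!is.null(e$boot_error)) cat(sprintf(", bootstrap error = %.4f", e$boot_error))
    cat("\n")
  }
  invisible(x)
}

#' Leave-one-out bootstrap error
#'
#' Out-of-bag error estimation used to control the optimism of the step-up
#' selection: for each of `B` bootstrap resamples the model is refit on the
#' resample and the compounds left out of that resample are predicted; each
#' compound's error is averaged over the resamples in which it was
#' out-of-bag, and the compound-level errors are averaged. The procedure is
#' repeated `repeats` times and the spread (standard deviation over repeats)
#' of the estimate is reported alongside its mean. The error is the
#' misclassification rate for LDA and the mean absolute error for OLS.
#'
#' @param x Descriptor matrix.
#' @param y Response.
#' @param subset Descriptor names to use (default all columns).
#' @param algorithm `"lda"` or `"ols"`.
#' @param B Number of bootstrap resamples per run (default 100).
#' @param repeats Whole-procedure repetitions for the spread (default 5).
#' @param seed Integer seed.
#' @return A list with `estimate` (mean over repeats), `spread` (SD over
#'   repeats), and `runs` (the per-repeat estimates).
#' @export
loo_bootstrap <- function(x, y, subset = colnames(x),
                          algorithm = c("lda", "ols"), B = 100, repeats = 5,
                          seed = 1) {
  algorithm <- match.arg(algorithm)
  stopifnot(B >= 10)
  x <- as.matrix(x)[, subset, drop = FALSE]
  n <- nrow(x)
  is_cls <- algorithm == "lda"
  if (is_cls) y <- factor(y)
  runs <- numeric(repeats)
  set.seed(seed)
  for (r in seq_len(repeats)) {
    err_sum <- err_cnt <- numeric(n)
    for (b in seq_len(B)) {
      for (try in seq_len(100)) {
        idx <- sample.int(n, n, replace = TRUE)
        if (!is_cls || length(unique(y[idx])) == nlevels(y)) break
        if (try == 100) stop("could not draw a resample containing both classes")
      }
      oob <- setdiff(seq_len(n), unique(idx))
      if (length(oob) == 0) next
      if (is_cls) {
        fit <- tryCatch(qsar_lda(x[idx, , drop = FALSE], y[idx],
                                 autoscale = FALSE),
                        error = function(e) NULL)
        if (is.null(fit)) next
        pred <- predict(fit, x[oob, , drop = FALSE])$class
        e <- as.numeric(pred != y[oob])
      } else {
        fit <- tryCatch(qsar_mlr(x[idx, , drop = FALSE], y[idx]),
                        error = function(e) NULL)
        if (is.null(fit)) next
        e <- abs(predict(fit, x[oob, , drop = FALSE]) - y[oob])
      }
      err_sum[oob] <- err_sum[oob] + e
      err_cnt[oob] <- err_cnt[oob] + 1
    }
    seen <- err_cnt > 0
    runs[r] <- mean(err_sum[seen] / err_cnt[seen])
  }
  list(estimate = mean(runs), spread = stats::sd(runs), runs = runs)
}

#' Suggest a model size from a bootstrap-error trace
#'
#' Scans the bootstrap error of the best model at each size and returns the
#' smallest size after which adding a descriptor no longer improves the
#' bootstrap error by more than `tol` (flattening) or makes it worse
#' (increase) - the overfitting signature. Advisory: the final choice
#' belongs to the modeller.
#'
#' @param trace A [step_up_select()] trace fitted with `bootstrap = TRUE`,
#'   or a plain numeric vector of bootstrap errors indexed by model size.
#' @param tol Minimum absolute improvement that counts (default 0.005).
#' @return Suggested model size (integer).
#' @export
overfit_knee <- function(trace, tol = 0.005) {
  err <- if (is.numeric(trace)) trace
         else vapply(trace, function(e) e$boot_error %||% NA_real_, numeric(1))
  if (anyNA(err)) stop("trace lacks bootstrap errors; rerun with bootstrap = TRUE")
  K <- length(err)
  for (k in seq_len(K - 1)) {
    if (err[k] - err[k + 1] <= tol) return(k)
  }
  K
}

#' Probability of coincidental relationship via descriptor randomization
#'
#' Reruns the whole step-up selection on randomized descriptor matrices and
#' compares the best criterion achievable from noise with the real model's.
#' Each run replaces every descriptor column with values drawn uniformly
#' within its observed range (`mode = "range"`), or resampled respecting the
#' column's detected nature (`mode = "nature"`): binary columns as Bernoulli
#' draws at the observed frequency, integer-valued columns as uniform
#' integers in range, continuous columns as uniform. Two probabilities are
#' returned: the empirical fraction of runs reaching or beating the real
#' criterion, and the tail probability of the real criterion under a normal
#' fit to the run criteria (the headline number, resolving below 1/runs).
#'
#' @param x Descriptor matrix.
#' @param y Response.
#' @param algorithm `"lda"` or `"ols"`.
#' @param real_criterion Criterion of the real model (training MR for LDA,
#'   R-squared for OLS).
#' @param runs Number of randomized reruns (default 100).
#' @param mode `"range"` or `"nature"`.
#' @param beam,max_size Passed to [step_up_select()].
#' @param seed Integer seed.
#' @return A list with `probability` (normal-tail), `empirical` (exceedance
#'   fraction), and `criteria` (the per-run best criteria).
#' @export
randomization_probability <- function(x, y, algorithm = c("lda", "ols"),
                                      real_criterion, runs = 100,
                                      mode = c("range", "nature"),
                                      beam = 25, max_size = 3, seed = 1) {
  algorithm <- match.arg(algorithm)
  mode <- match.arg(mode)
  stopifnot(runs >= 10)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("D", seq_len(ncol(x)))
  n <- nrow(x)
  set.seed(seed)
  rand_col <- function(v) {
    if (mode == "nature") {
      uv <- unique(v)
      if (length(uv) <= 2) return(sample(uv, n, replace = TRUE,
                                         prob = tabulate(match(v, uv)) / n))
      if (all(v == round(v))) {
        rng <- seq(min(v), max(v))
        if (length(rng) == 1L) return(rep(rng, n))
        return(sample(rng, n, replace = TRUE))
      }
    }
    stats::runif(n, min(v), max(v))
  }
  best <- numeric(runs)
  for (r in seq_len(runs)) {
    xr <- apply(x, 2, rand_col)
    colnames(xr) <- colnames(x)
    tr <- step_up_select(xr, y, algorithm = algorithm, beam = beam,
                         max_size = max_size)
    best[r] <- tr[[max_size]]$criterion[[1]]
  }
  if (algorithm == "lda") {
    empirical <- mean(best <= real_criterion)
    tail_p <- stats::pnorm(real_criterion, mean(best), stats::sd(best))
  } else {
    empirical <- mean(best >= real_criterion)
    tail_p <- stats::pnorm(real_criterion, mean(best), stats::sd(best),
                           lower.tail = FALSE)
  }
  list(probability = tail_p, empirical = empirical, criteria = best)
}

#' Y-scrambling chance-correlation check
#'
#' Refits the OLS model on random permutations of the response with the
#' descriptors fixed and returns the average training R-squared over the
#' permutations. Values near zero indicate the real fit is not a chance
#' correlation.
#'
#' @param x Descriptor matrix.
#' @param y Numeric response.
#' @param subset Descriptor names to use (default all).
#' @param iters Number of permutations (default 50).
#' @param seed Integer seed.
#' @return A list with `r2_ys` (mean scrambled R-squared) and `r2_runs`.
#' @export
y_scramble <- function(x, y, subset = colnames(x), iters = 50, seed = 1) {
  stopifnot(iters >= 2)
  x <- as.matrix(x)[, subset, drop = FALSE]
  if (nrow(x) == ncol(x) + 1) {
    warning("n = p + 1: scrambled fits interpolate and R2_YS is trivially 1")
    return(list(r2_ys = 1, r2_runs = rep(1, iters)))
  }
  set.seed(seed)
  r2 <- vapply(seq_len(iters), function(i) {
    qsar_mlr(x, sample(y))$r_squared
  }, numeric(1))
  list(r2_ys = mean(r2), r2_runs = r2)
}
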