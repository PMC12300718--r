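#' Structure-ranked training/test split
#'
#' Splits a descriptor matrix into training and test sets "by structure":
#' within each stratum (each activity class when `labels` is given, the whole
#' set otherwise) the descriptors are autoscaled, the first principal
#' component is computed, compounds are ranked by their PC1 score, and every
#' third compound in rank order (ranks 3, 6, 9, ...) is assigned to the test
#' set. This keeps the structural diversity of the dataset represented in
#' both sets and yields a deterministic 2/3 : 1/3 split (within one compound
#' per stratum).
#'
#' @param x Numeric matrix or data frame of descriptors (rownames are
#'   compound ids; row indices are used when absent).
#' @param labels Optional class labels defining the strata.
#' @param every Assign every `every`-th ranked compound to the test set
#'   (default 3, i.e. a two-thirds training fraction).
#' @return A list with `train` and `test` (vectors of compound ids).
#' @export
split_by_structure <- function(x, labels = NULL, every = 3) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  strata <- if (is.null(labels)) factor(rep("all", nrow(x))) else factor(labels)
  train <- test <- character(0)
  for (s in levels(strata)) {
    idx <- which(strata == s)
    if (length(idx) < 3) stop("stratum '", s, "' has fewer than 3 compounds")
    xs <- x[idx, , drop = FALSE]
    keep <- apply(xs, 2, function(v) stats::sd(v) > 0)
    if (!any(keep)) stop("all descriptors constant within stratum '", s, "'")
    xs <- scale(xs[, keep, drop = FALSE])
    pca <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
    # canonical PC1 sign: dominant loading positive, so the ranking does not
    # depend on the SVD's sign convention
    v1 <- pca$rotation[, 1]
    if (v1[which.max(abs(v1))] < 0) pca$x[, 1] <- -pca$x[, 1]
    pc1 <- pca$x[, 1]
    rk <- order(pc1)  # ties broken by input order (order() is stable)
    ranked_ids <- rownames(x)[idx][rk]
    is_test <- seq_along(ranked_ids) %% every == 0
    test <- c(test, ranked_ids[is_test])
    train <- c(train, ranked_ids[!is_test])
  }
  list(train = train, test = test)
}
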