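#' Generate a synthetic two-class descriptor dataset
#'
#' Draws two multivariate-normal descriptor clouds with identity covariance
#' whose means are `separation` Mahalanobis units apart along the first
#' axis. Under these conditions the Bayes accuracy is known in closed form,
#' \eqn{\Phi(\delta/2)}, so classifier behaviour can be checked against an
#' analytic reference. Defaults emulate the geometry of the modelled
#' activity dataset: 74 active and 49 weak/not-active compounds with four
#' descriptors, and a separation of 2.5 (Bayes accuracy about 0.89,
#' matching the accuracy range the activity model operates in).
#'
#' @param n_per_class Integer vector of class sizes `(A, I)`.
#' @param p Number of descriptors.
#' @param separation Mahalanobis distance between the class means.
#' @param seed Integer seed; same spec + seed reproduces the dataset
#'   bit-identically.
#' @return A list with `x` (matrix, columns `D1..Dp`), `y` (factor `A`/`I`),
#'   `bayes_accuracy`.
#' @export
gen_classification_dataset <- function(n_per_class = c(74, 49), p = 4,
                                       separation = 2.5, seed = 1) {
  set.seed(seed)
  n1 <- n_per_class[[1]]; n2 <- n_per_class[[2]]
  mu <- rep(0, p); mu[1] <- separation
  x <- rbind(matrix(stats::rnorm(n1 * p), n1, p) +
               matrix(mu, n1, p, byrow = TRUE),
             matrix(stats::rnorm(n2 * p), n2, p))
  colnames(x) <- paste0("D", seq_len(p))
  rownames(x) <- paste0("c", seq_len(n1 + n2))
  y <- factor(rep(c("A", "I"), c(n1, n2)), levels = c("A", "I"))
  list(x = x, y = y, bayes_accuracy = stats::pnorm(separation / 2))
}

#' Generate a synthetic regression descriptor dataset
#'
#' Draws descriptors from a standard normal and a response
#' \eqn{y = X\beta + \epsilon}, \eqn{\epsilon \sim N(0, \sigma^2)}. When
#' `sigma` is omitted it is set so the expected R-squared,
#' \eqn{\|\beta\|^2 / (\|\beta\|^2 + \sigma^2)}, equals `target_r2`.
#' Defaults emulate the geometry of the modelled potency dataset: 63
#' compounds, three descriptors, R-squared about 0.8.
#'
#' @param n Number of compounds.
#' @param p Number of descriptors.
#' @param beta True coefficient vector (length `p`; default `rep(1, p)`).
#' @param intercept True intercept.
#' @param sigma Noise standard deviation; derived from `target_r2` when
#'   `NULL`.
#' @param target_r2 Expected R-squared used to set `sigma` (default 0.8).
#' @param seed Integer seed.
#' @return A list with `x`, `y`, `beta`, `intercept`, `sigma`,
#'   `expected_r2`.
#' @export
gen_regression_dataset <- function(n = 63, p = 3, beta = rep(1, p),
                                   intercept = 0, sigma = NULL,
                                   target_r2 = 0.8, seed = 1) {
  stopifnot(length(beta) == p)
  if (is.null(sigma)) {
    signal_var <- sum(beta^2)
    sigma <- if (signal_var == 0) 1 else
      sqrt(signal_var * (1 - target_r2) / target_r2)
  }
  set.seed(seed)
  x <- matrix(stats::rnorm(n * p), n, p)
  colnames(x) <- paste0("D", seq_len(p))
  rownames(x) <- paste0("c", seq_len(n))
  y <- intercept + drop(x %*% beta) + stats::rnorm(n, 0, sigma)
  signal_var <- sum(beta^2)
  list(x = x, y = y, beta = beta, intercept = intercept, sigma = sigma,
       expected_r2 = signal_var / (signal_var + sigma^2))
}

#' Generate random fluoroalkyl SMILES
#'
#' Constructs valid, curation-passing SMILES of the chemotypes of the
#' modelled dataset: perfluoroalkyl carboxylic and sulfonic acids,
#' fluorotelomer alcohols, perfluoroalkyl ethers, amides, and neutral
#' perfluoroalkanes, with perfluorinated chain lengths drawn uniformly from
#' `chain_range`.
#'
#' @param n Number of SMILES to generate.
#' @param chain_range Integer range (min, max) of perfluorinated carbons.
#' @param head_groups Character vector of head-group keys to draw from:
#'   `"cooh"` (carboxylic acid), `"so3h"` (sulfonic acid), `"ftoh"`
#'   (fluorotelomer alcohol), `"ether"` (methyl perfluoroalkyl ether),
#'   `"amide"` (primary amide), `"h"` (perfluoroalkane).
#' @param seed Integer seed.
#' @return Character vector of SMILES, named `pfas1..pfasN`.
#' @examples
#' gen_fluoroalkyl_smiles(3, chain_range = c(4, 8), seed = 42)
#' @export
gen_fluoroalkyl_smiles <- function(n, chain_range = c(3, 11),
                                   head_groups = c("cooh", "so3h", "ftoh",
                                                   "ether", "amide", "h"),
                                   seed = 1) {
  set.seed(seed)
  heads <- list(cooh = "C(=O)O", so3h = "S(=O)(=O)O", ftoh = "CCO",
                ether = "OC", amide = "C(=O)N", h = "F")
  bad <- setdiff(head_groups, names(heads))
  if (length(bad) > 0) stop("unknown head group(s): ", paste(bad, collapse = ", "))
  grid <- expand.grid(len = seq(chain_range[1], chain_range[2]),
                      head = head_groups, stringsAsFactors = FALSE)
  # distinct structures whenever the (chain length x head group) grid allows,
  # so a generated batch curates without duplicate exclusions
  pick_n <- function(x, size, replace) {
    if (length(x) == 1L) rep(x, size) else sample(x, size, replace = replace)
  }
  rows <- if (n <= nrow(grid)) pick_n(seq_len(nrow(grid)), n, FALSE)
          else pick_n(seq_len(nrow(grid)), n, TRUE)
  smi <- vapply(rows, function(k) {
    chain <- paste(rep("C(F)(F)", grid$len[k]), collapse = "")
    paste0("F", chain, heads[[grid$head[k]]])
  }, character(1))
  names(smi) <- paste0("pfas", seq_len(n))
  smi
}
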