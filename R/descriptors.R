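#' @name autocorrelation
#' @title 2D autocorrelation descriptors
#'
#' @description
#' Topological (2D) autocorrelation descriptors over a molecular graph,
#' weighted by an atomic property: `atsc()` is the centered Broto-Moreau
#' autocorrelation, `aatsc()` its average over the contributing terms, and
#' `gats()` the Geary autocorrelation coefficient. Atom pairs contribute at
#' the topological lag equal to their graph distance; the weighting property
#' is one of atomic mass (`"m"`), Sanderson electronegativity (`"e"`) or
#' polarizability (`"p"`), taken from [element_properties()].
#'
#' With centered weights \eqn{w_i - \bar w}:
#' \itemize{
#'   \item \eqn{ATSC_d = \sum_{\{i,j\}: d(i,j)=d} (w_i-\bar w)(w_j-\bar w)}
#'     over unordered pairs, and \eqn{ATSC_0 = \sum_i (w_i-\bar w)^2};
#'   \item \eqn{AATSC_d = ATSC_d / \Delta_d} with \eqn{\Delta_d} the number of
#'     contributing terms (atoms at lag 0, unordered pairs at lag > 0);
#'   \item \eqn{GATS_d} is the Geary coefficient: the mean squared weight
#'     difference over ordered pairs at distance d (halved), divided by the
#'     sample variance of the weights.
#' }
#' All three are computed on the hydrogen-explicit graph.
#'
#' @param graph A `molgraph` from [build_graph()].
#' @param lag Topological distance (non-negative integer; `gats` requires
#'   `lag >= 1`).
#' @param prop Weighting property: `"m"`, `"e"` or `"p"`.
#' @param degenerate Value returned by `gats` when the weight variance is
#'   zero (homoatomic graph); default 0.
#' @return A single numeric descriptor value.
#' @examples
#' g <- build_graph("OCC(F)(F)F")
#' atsc(g, 6, "p")   # ATSC6p
#' gats(g, 3, "e")   # GATS3e
#' aatsc(g, 0, "e")  # AATSC0e = population variance of electronegativities
NULL

.atom_weights <- function(graph, prop) {
  col <- switch(prop,
                m = "mass", e = "electronegativity", p = "polarizability",
                stop("prop must be one of 'm', 'e', 'p'"))
  w <- graph$atoms[[col]]
  if (anyNA(w)) stop("atomic properties missing for some atoms; ",
                     "graph contains elements outside the property table")
  w
}

#' @rdname autocorrelation
#' @export
atsc <- function(graph, lag, prop) {
  stopifnot(inherits(graph, "molgraph"), lag >= 0)
  w <- .atom_weights(graph, prop)
  wc <- w - mean(w)
  if (lag == 0) return(sum(wc^2))
  d <- .topo_dist(graph)
  sel <- d == lag & upper.tri(d)
  if (!any(sel)) return(0)
  sum((wc %o% wc)[sel])
}

#' @rdname autocorrelation
#' @export
aatsc <- function(graph, lag, prop) {
  stopifnot(inherits(graph, "molgraph"), lag >= 0)
  if (lag == 0) return(atsc(graph, 0, prop) / nrow(graph$atoms))
  d <- .topo_dist(graph)
  npairs <- sum(d == lag & upper.tri(d))
  if (npairs == 0) return(0)
  atsc(graph, lag, prop) / npairs
}

#' @rdname autocorrelation
#' @export
gats <- function(graph, lag, prop, degenerate = 0) {
  stopifnot(inherits(graph, "molgraph"), lag >= 1)
  n <- nrow(graph$atoms)
  if (n < 2) stop("Geary autocorrelation needs at least 2 atoms")
  w <- .atom_weights(graph, prop)
  denom <- sum((w - mean(w))^2) / (n - 1)
  if (denom == 0) return(degenerate)
  d <- .topo_dist(graph)
  sel <- d == lag  # ordered pairs: both triangles
  diag(sel) <- FALSE
  delta <- sum(sel)
  if (delta == 0) return(0)
  diffs <- (matrix(w, n, n) - matrix(w, n, n, byrow = TRUE))^2
  num <- sum(diffs[sel]) / (2 * delta)
  num / denom
}

#' Modified information content index (MIC)
#'
#' Information-content descriptor of the neighborhood symmetry of a given
#' order: atoms are partitioned into equivalence classes by iterated rooted
#' neighborhood signatures (element, degree and sorted incident bond orders,
#' refined `order` times), and the Shannon information of the partition is
#' computed with each atom's term weighted by its atomic-mass fraction
#' (King's modification):
#' \eqn{MIC_k = -\sum_i (m_i/M) \log_2 (n_{c(i)}/n)} where \eqn{n_{c(i)}}
#' is the size of atom i's class. A single-class partition gives 0.
#'
#' @param graph A `molgraph`.
#' @param order Neighborhood radius (non-negative integer).
#' @return Descriptor value in bits.
#' @examples
#' mic(build_graph("C"), 0)  # methane: classes {C}, {H x 4}
#' @export
mic <- function(graph, order = 2) {
  stopifnot(inherits(graph, "molgraph"), order >= 0)
  n <- nrow(graph$atoms)
  cls <- .symmetry_classes(graph, order)
  sizes <- table(cls)
  p_cls <- as.numeric(sizes[as.character(cls)]) / n
  m <- graph$atoms$mass
  if (anyNA(m)) stop("atomic masses missing for some atoms")
  -sum((m / sum(m)) * log2(p_cls))
}

# Iterated neighborhood-symmetry refinement. Round 0 classes: (element,
# heavy-atom degree, sorted incident bond orders). Each further round
# appends the sorted multiset of (neighbor class, connecting bond order).
.symmetry_classes <- function(graph, order) {
  n <- nrow(graph$atoms)
  nbr <- vector("list", n)
  if (nrow(graph$bonds) > 0) {
    for (b in seq_len(nrow(graph$bonds))) {
      i <- graph$bonds$i[b]; j <- graph$bonds$j[b]; o <- graph$bonds$order[b]
      nbr[[i]] <- rbind(nbr[[i]], c(j, o))
      nbr[[j]] <- rbind(nbr[[j]], c(i, o))
    }
  }
  heavy_deg <- vapply(seq_len(n), function(i) {
    if (is.null(nbr[[i]])) return(0L)
    sum(graph$atoms$element[nbr[[i]][, 1]] != "H")
  }, integer(1))
  sig <- vapply(seq_len(n), function(i) {
    orders <- if (is.null(nbr[[i]])) numeric(0) else sort(nbr[[i]][, 2])
    paste(graph$atoms$element[i], heavy_deg[i], paste(orders, collapse = ","))
  }, character(1))
  cls <- as.integer(factor(sig))
  if (order == 0) return(cls)
  for (r in seq_len(order)) {
    sig <- vapply(seq_len(n), function(i) {
      if (is.null(nbr[[i]])) return(paste0(cls[i], "|"))
      nb <- paste(cls[nbr[[i]][, 1]], nbr[[i]][, 2], sep = ":")
      paste0(cls[i], "|", paste(sort(nb), collapse = ";"))
    }, character(1))
    new_cls <- as.integer(factor(sig))
    if (length(unique(new_cls)) == length(unique(cls))) { cls <- new_cls; break }
    cls <- new_cls
  }
  cls
}

#' Conventional bond-order path count (piPC)
#'
#' Enumerates all simple paths of exactly `order` bonds in the
#' hydrogen-suppressed molecular skeleton (each undirected path counted
#' once), weights each path by the product of its conventional bond orders
#' (aromatic = 1.5), and returns the natural log of one plus the weighted
#' sum. Molecules too small to contain such a path return 0.
#'
#' @param graph A `molgraph`.
#' @param order Path length in bonds (positive integer).
#' @param suppress_h Compute on the heavy-atom skeleton (default `TRUE`,
#'   the path-count convention).
#' @return Descriptor value, `ln(1 + sum of path weights)`.
#' @examples
#' pipc(build_graph("CCCCCC"), 5)  # one 5-bond path: log(2)
#' @export
pipc <- function(graph, order = 5, suppress_h = TRUE) {
  stopifnot(inherits(graph, "molgraph"), order >= 1)
  keep <- if (suppress_h) which(graph$atoms$element != "H")
          else seq_len(nrow(graph$atoms))
  n <- length(keep)
  if (n < order + 1) return(0)
  remap <- match(seq_len(nrow(graph$atoms)), keep)
  adj <- vector("list", n)
  wts <- vector("list", n)
  sel <- graph$bonds$i %in% keep & graph$bonds$j %in% keep
  bb <- graph$bonds[sel, , drop = FALSE]
  for (b in seq_len(nrow(bb))) {
    i <- remap[bb$i[b]]; j <- remap[bb$j[b]]; o <- bb$order[b]
    adj[[i]] <- c(adj[[i]], j); wts[[i]] <- c(wts[[i]], o)
    adj[[j]] <- c(adj[[j]], i); wts[[j]] <- c(wts[[j]], o)
  }
  total <- 0
  visited <- logical(n)
  dfs <- function(v, depth, wprod) {
    if (depth == order) { total <<- total + wprod; return(invisible()) }
    visited[v] <<- TRUE
    nb <- adj[[v]]
    for (k in seq_along(nb)) {
      u <- nb[k]
      if (!visited[u]) dfs(u, depth + 1L, wprod * wts[[v]][k])
    }
    visited[v] <<- FALSE
  }
  for (s in seq_len(n)) dfs(s, 0L, 1)
  log(1 + total / 2)  # each undirected path found from both ends
}

#' Galvez topological charge index (GGI)
#'
#' Charge-transfer index of a given order over the hydrogen-suppressed
#' skeleton: with A the bond-order-weighted adjacency matrix and D* the
#' inverse-square topological distance matrix (off-diagonal entries
#' \eqn{1/d^2}, zero diagonal), the charge-transfer term between atoms i and
#' j is \eqn{CT_{ij} = M_{ij} - M_{ji}} where \eqn{M = A D^*}. The index of
#' order k sums \eqn{|CT_{ij}|} over unordered pairs at topological distance
#' exactly k. Graphs with diameter below `order` return 0.
#'
#' @param graph A `molgraph`.
#' @param order Topological distance (positive integer).
#' @param suppress_h Compute on the heavy-atom skeleton (default `TRUE`,
#'   the charge-index convention).
#' @return Descriptor value (non-negative).
#' @export
ggi <- function(graph, order = 9, suppress_h = TRUE) {
  stopifnot(inherits(graph, "molgraph"), order >= 1)
  keep <- if (suppress_h) which(graph$atoms$element != "H")
          else seq_len(nrow(graph$atoms))
  n <- length(keep)
  if (n < 2) return(0)
  d <- .topo_dist(graph, suppress_h = suppress_h)
  if (!any(d == order & upper.tri(d))) return(0)
  A <- matrix(0, n, n)
  remap <- match(seq_len(nrow(graph$atoms)), keep)
  sel <- graph$bonds$i %in% keep & graph$bonds$j %in% keep
  bb <- graph$bonds[sel, , drop = FALSE]
  for (b in seq_len(nrow(bb))) {
    i <- remap[bb$i[b]]; j <- remap[bb$j[b]]
    A[i, j] <- A[j, i] <- bb$order[b]
  }
  Dstar <- ifelse(d == 0 | is.infinite(d), 0, 1 / d^2)
  M <- A %*% Dstar
  CT <- M - t(M)
  sum(abs(CT)[d == order & upper.tri(d)])
}

#' Compute the seven modelling descriptors from a SMILES
#'
#' Computes the descriptor vector used by the two published models:
#' `GATS3e`, `ATSC6p`, `GATS8m`, `MIC2` (classification) and `piPC5`,
#' `GGI9`, `AATSC0e` (regression).
#'
#' @param smiles A single SMILES string, or a character vector of them.
#' @return For one SMILES a named numeric vector of length 7; for several a
#'   data frame with one row per compound (rownames = input ids, if named).
#' @examples
#' compute_model_descriptors("OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F")
#' @export
compute_model_descriptors <- function(smiles) {
  if (length(smiles) > 1) {
    m <- t(vapply(smiles, compute_model_descriptors, numeric(7)))
    out <- as.data.frame(m)
    if (!is.null(names(smiles))) rownames(out) <- names(smiles)
    return(out)
  }
  g <- build_graph(smiles)
  c(GATS3e = gats(g, 3, "e"),
    ATSC6p = atsc(g, 6, "p"),
    GATS8m = gats(g, 8, "m"),
    MIC2 = mic(g, 2),
    piPC5 = pipc(g, 5),
    GGI9 = ggi(g, 9),
    AATSC0e = aatsc(g, 0, "e"))
}

#' Filter a descriptor matrix
#'
#' Removes useless and redundant descriptors before modelling:
#' (a) near-constant descriptors whose modal value covers more than
#' `constancy_frac` of the compounds; (b) from each pair with absolute
#' Pearson correlation above `corr_max`, the member that comes later in
#' alphabetical order; (c) descriptors whose value range (max - min) spans
#' more than `range_decades` orders of magnitude.
#'
#' @param x Numeric matrix or data frame, compounds in rows, named
#'   descriptors in columns, no missing values.
#' @param constancy_frac Modal-value fraction above which a descriptor is
#'   dropped as (near-)constant (default 0.8).
#' @param corr_max Absolute pairwise correlation threshold (default 0.95).
#' @param range_decades Maximum admissible range in orders of magnitude
#'   (default 2, i.e. max - min must not exceed 100).
#' @return A list with `matrix` (the surviving columns) and `removed`
#'   (data frame `descriptor`, `reason` in
#'   `low_variance`/`correlation`/`wide_range`).
#' @export
filter_descriptors <- function(x, constancy_frac = 0.8, corr_max = 0.95,
                               range_decades = 2) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("descriptor matrix must not contain missing values")
  if (is.null(colnames(x))) colnames(x) <- paste0("D", seq_len(ncol(x)))
  removed <- data.frame(descriptor = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  drop_cols <- function(cols, reason) {
    if (length(cols) == 0) return(invisible())
    removed <<- rbind(removed, data.frame(descriptor = cols, reason = reason,
                                          stringsAsFactors = FALSE))
    x <<- x[, setdiff(colnames(x), cols), drop = FALSE]
  }
  modal_frac <- apply(x, 2, function(v) max(table(v)) / length(v))
  drop_cols(colnames(x)[modal_frac > constancy_frac], "low_variance")
  span <- apply(x, 2, function(v) max(v) - min(v))
  drop_cols(colnames(x)[span > 10^range_decades], "wide_range")
  if (ncol(x) >= 2) {
    ord <- order(colnames(x))
    xo <- x[, ord, drop = FALSE]
    cm <- suppressWarnings(stats::cor(xo))
    cm[is.na(cm)] <- 0
    drop <- character(0)
    nm <- colnames(xo)
    for (a in seq_len(ncol(xo) - 1)) {
      if (nm[a] %in% drop) next
      for (b in seq((a + 1), ncol(xo))) {
        if (nm[b] %in% drop) next
        if (abs(cm[a, b]) > corr_max) drop <- c(drop, nm[b])
      }
    }
    drop_cols(drop, "correlation")
  }
  if (ncol(x) == 0) warning("all descriptors removed by filtering")
  list(matrix = x, removed = removed)
}

#' Read an externally computed descriptor matrix
#'
#' Reads a CSV whose first column is the compound id and whose header names
#' the descriptors, as produced by external descriptor software.
#'
#' @param path CSV path.
#' @return Numeric matrix with compound ids as rownames.
#' @export
read_descriptor_matrix <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}
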