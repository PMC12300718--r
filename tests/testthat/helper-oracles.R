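# Independent brute-force oracles for the descriptor engines, plus small
# graph-construction helpers. The oracles deliberately avoid the package's
# code paths: distances come from Floyd-Warshall instead of igraph BFS,
# autocorrelations from explicit double loops, path counts from ordered-path
# enumeration deduplicated by endpoint ordering, and charge indices from
# scalar triple loops.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Construct a molgraph-like object directly (bypasses SMILES parsing) so
# arbitrary weighted graphs can be fed to the descriptor functions.
make_graph <- function(elements, bonds_ij, orders = rep(1, nrow(bonds_ij))) {
  tab <- pfasttr::element_properties()
  idx <- match(elements, tab$element)
  atoms <- data.frame(element = elements,
                      aromatic = FALSE, charge = 0,
                      mass = tab$mass[idx],
                      electronegativity = tab$electronegativity[idx],
                      polarizability = tab$polarizability[idx],
                      stringsAsFactors = FALSE)
  g <- list(atoms = atoms,
            bonds = data.frame(i = bonds_ij[, 1], j = bonds_ij[, 2],
                               order = orders),
            smiles = "<synthetic>")
  class(g) <- "molgraph"
  g
}

# Floyd-Warshall topological distances (independent of igraph)
oracle_dist <- function(g, suppress_h = FALSE) {
  keep <- if (suppress_h) which(g$atoms$element != "H") else seq_len(nrow(g$atoms))
  n <- length(keep)
  d <- matrix(Inf, n, n); diag(d) <- 0
  remap <- match(seq_len(nrow(g$atoms)), keep)
  for (b in seq_len(nrow(g$bonds))) {
    i <- remap[g$bonds$i[b]]; j <- remap[g$bonds$j[b]]
    if (!is.na(i) && !is.na(j)) d[i, j] <- d[j, i] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

oracle_weights <- function(g, prop) {
  switch(prop, m = g$atoms$mass, e = g$atoms$electronegativity,
         p = g$atoms$polarizability)
}

oracle_atsc <- function(g, lag, prop) {
  w <- oracle_weights(g, prop)
  wc <- w - mean(w)
  if (lag == 0) return(sum(wc^2))
  d <- oracle_dist(g)
  total <- 0
  n <- length(w)
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    if (d[i, j] == lag) total <- total + wc[i] * wc[j]
  }
  total
}

oracle_aatsc <- function(g, lag, prop) {
  if (lag == 0) return(oracle_atsc(g, 0, prop) / nrow(g$atoms))
  d <- oracle_dist(g)
  n <- nrow(g$atoms)
  cnt <- 0
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    if (d[i, j] == lag) cnt <- cnt + 1
  }
  if (cnt == 0) return(0)
  oracle_atsc(g, lag, prop) / cnt
}

oracle_gats <- function(g, lag, prop) {
  w <- oracle_weights(g, prop)
  n <- length(w)
  denom <- sum((w - mean(w))^2) / (n - 1)
  if (denom == 0) return(0)
  d <- oracle_dist(g)
  num <- 0; cnt <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && d[i, j] == lag) { num <- num + (w[i] - w[j])^2; cnt <- cnt + 1 }
  }
  if (cnt == 0) return(0)
  (num / (2 * cnt)) / denom
}

# enumerate ordered simple paths, keep those whose first endpoint index is
# below the last (counts each undirected path exactly once)
oracle_pipc <- function(g, order, suppress_h = TRUE) {
  keep <- if (suppress_h) which(g$atoms$element != "H") else seq_len(nrow(g$atoms))
  n <- length(keep)
  if (n < order + 1) return(0)
  remap <- match(seq_len(nrow(g$atoms)), keep)
  W <- matrix(0, n, n)
  for (b in seq_len(nrow(g$bonds))) {
    i <- remap[g$bonds$i[b]]; j <- remap[g$bonds$j[b]]
    if (!is.na(i) && !is.na(j)) W[i, j] <- W[j, i] <- g$bonds$order[b]
  }
  total <- 0
  extend <- function(path, wprod) {
    v <- path[length(path)]
    if (length(path) == order + 1) {
      if (path[1] < v) total <<- total + wprod
      return(invisible())
    }
    for (u in seq_len(n)) {
      if (W[v, u] > 0 && !(u %in% path)) extend(c(path, u), wprod * W[v, u])
    }
  }
  for (s in seq_len(n)) extend(s, 1)
  log(1 + total)
}

oracle_ggi <- function(g, order, suppress_h = TRUE) {
  keep <- if (suppress_h) which(g$atoms$element != "H") else seq_len(nrow(g$atoms))
  n <- length(keep)
  if (n < 2) return(0)
  remap <- match(seq_len(nrow(g$atoms)), keep)
  A <- matrix(0, n, n)
  for (b in seq_len(nrow(g$bonds))) {
    i <- remap[g$bonds$i[b]]; j <- remap[g$bonds$j[b]]
    if (!is.na(i) && !is.na(j)) A[i, j] <- A[j, i] <- g$bonds$order[b]
  }
  d <- oracle_dist(g, suppress_h)
  total <- 0
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    if (d[i, j] == order) {
      mij <- 0; mji <- 0
      for (k in seq_len(n)) {
        dk_j <- if (d[k, j] > 0 && is.finite(d[k, j])) 1 / d[k, j]^2 else 0
        dk_i <- if (d[k, i] > 0 && is.finite(d[k, i])) 1 / d[k, i]^2 else 0
        mij <- mij + A[i, k] * dk_j
        mji <- mji + A[j, k] * dk_i
      }
      total <- total + abs(mij - mji)
    }
  }
  total
}

# All non-isomorphic connected graphs with 2..max_n vertices, from the igraph
# atlas, dressed with cyclically assigned elements and bond orders.
atlas_graphs <- function(max_n = 7) {
  elements <- c("C", "O", "N", "F", "S")
  orders <- c(1, 2, 1, 1.5, 3, 1)
  out <- list()
  for (i in 0:1252) {
    ig <- suppressWarnings(igraph::graph_from_atlas(i))
    n <- igraph::vcount(ig)
    if (n < 2 || n > max_n) next
    if (!igraph::is_connected(ig)) next
    el <- igraph::as_edgelist(ig)
    if (nrow(el) == 0) next
    g <- make_graph(elements[(seq_len(n) - 1) %% length(elements) + 1],
                    el,
                    orders[(seq_len(nrow(el)) - 1) %% length(orders) + 1])
    out[[length(out) + 1L]] <- g
  }
  out
}

# random permutation of atom labels; descriptor values must be unchanged
permute_graph <- function(g, perm) {
  g2 <- g
  g2$atoms <- g$atoms[order(perm), , drop = FALSE]
  rownames(g2$atoms) <- NULL
  g2$bonds$i <- perm[g$bonds$i]
  g2$bonds$j <- perm[g$bonds$j]
  g2
}
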