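# chain of n carbons with single bonds, no hydrogens (synthetic skeleton)
carbon_chain <- function(n) {
  make_graph(rep("C", n), cbind(seq_len(n - 1), seq(2, n)))
}

test_that("centered autocorrelations vanish for homoatomic graphs and beyond the diameter", {
  g <- carbon_chain(5)
  for (lag in 0:4) expect_equal(atsc(g, lag, "e"), 0)
  het <- build_graph("OCC(F)(F)F")
  expect_equal(atsc(het, 50, "p"), 0)   # lag beyond any diameter
  expect_equal(aatsc(het, 50, "p"), 0)
  expect_equal(gats(het, 50, "m"), 0)
})

test_that("AATSC at lag 0 equals the population variance of the weights", {
  g <- build_graph("OCC(F)(F)F")  # trifluoroethanol
  e <- g$atoms$electronegativity
  expect_equal(aatsc(g, 0, "e"), mean((e - mean(e))^2))
  expect_equal(atsc(g, 0, "e"), sum((e - mean(e))^2))
})

test_that("Geary coefficient matches the two-atom closed form and degenerates safely", {
  g <- make_graph(c("C", "O"), cbind(1, 2))
  w <- c(2.55, 3.44)
  num <- (w[1] - w[2])^2 / 2          # ordered pairs: 2 terms / (2 * 2)
  den <- sum((w - mean(w))^2) / 1
  expect_equal(gats(g, 1, "e"), num / den)
  # homoatomic: zero variance hits the degenerate branch, never NaN/Inf
  expect_identical(gats(carbon_chain(3), 1, "e"), 0)
  expect_true(is.nan(gats(carbon_chain(3), 1, "e", degenerate = NaN)))
})

test_that("MIC matches the two-class closed form on methane and is zero for one class", {
  g <- build_graph("C")
  m <- c(12.011, rep(1.008, 4)); M <- sum(m)
  p <- c(1 / 5, rep(4 / 5, 4))
  expect_equal(mic(g, 0), -sum(m / M * log2(p)))
  # all atoms equivalent: cyclohexane skeleton without hydrogens
  ring <- make_graph(rep("C", 6), cbind(1:6, c(2:6, 1)))
  for (ord in 0:3) expect_equal(mic(ring, ord), 0)
})

test_that("path counts follow the bond-order product convention", {
  expect_equal(pipc(carbon_chain(4), 5), 0)           # no 5-bond path
  expect_equal(pipc(carbon_chain(6), 5), log(2))      # exactly one, weight 1
  # one double bond in a 6-chain doubles the single path weight
  g <- make_graph(rep("C", 6), cbind(1:5, 2:6), c(2, 1, 1, 1, 1))
  expect_equal(pipc(g, 5), log(1 + 2))
  # branched fluorotelomer-like fixture vs exhaustive enumeration oracle
  ft <- build_graph("OCCC(F)(F)C(F)(F)C(F)(F)C(F)(F)F")
  for (ord in 2:6) expect_equal(pipc(ft, ord), oracle_pipc(ft, ord))
})

test_that("Galvez charge index vanishes below the order and on symmetric pairs", {
  expect_equal(ggi(build_graph("OCC(F)(F)F"), 9), 0)  # diameter < 9
  two <- make_graph(c("C", "C"), cbind(1, 2))
  for (k in 1:3) expect_equal(ggi(two, k), 0)
  # long perfluoroalkyl chain has nonzero GGI9; matches the dense-matrix oracle
  c14 <- build_graph(paste0("OC(=O)", paste(rep("C(F)(F)", 12), collapse = ""), "F"))
  expect_gt(ggi(c14, 9), 0)
  expect_equal(ggi(c14, 9), oracle_ggi(c14, 9))
})

test_that("the seven-descriptor vector is canonical-notation invariant and finite", {
  v1 <- compute_model_descriptors("OC(=O)C(F)(F)F")
  v2 <- compute_model_descriptors("C(F)(F)(F)C(O)=O")
  expect_equal(v1, v2)
  expect_true(all(is.finite(v1)))
  expect_named(v1, c("GATS3e", "ATSC6p", "GATS8m", "MIC2", "piPC5", "GGI9",
                     "AATSC0e"))
  # a 3-bond molecule cannot host a 5-bond path nor a distance-9 pair
  v3 <- compute_model_descriptors("OCO")
  expect_equal(unname(v3["piPC5"]), 0)
  expect_equal(unname(v3["GGI9"]), 0)
})

test_that("all seven descriptors are graph-isomorphism invariants", {
  g <- build_graph("OCC(F)(F)C(F)(F)C(=O)N")
  vals <- function(gr) c(gats(gr, 3, "e"), atsc(gr, 6, "p"), gats(gr, 8, "m"),
                         mic(gr, 2), pipc(gr, 5), ggi(gr, 9), aatsc(gr, 0, "e"))
  ref <- vals(g)
  set.seed(11)
  for (rep in 1:5) {
    perm <- sample(nrow(g$atoms))
    expect_equal(vals(permute_graph(g, perm)), ref)
  }
})

test_that("descriptor engines equal brute-force oracles on all connected graphs up to 6 atoms", {
  graphs <- atlas_graphs(6)
  expect_gt(length(graphs), 100)
  worst <- 0
  for (g in graphs) {
    for (lag in 0:3) {
      worst <- max(worst,
                   abs(atsc(g, lag, "e") - oracle_atsc(g, lag, "e")),
                   abs(aatsc(g, lag, "p") - oracle_aatsc(g, lag, "p")))
      if (lag >= 1) {
        worst <- max(worst, abs(gats(g, lag, "m") - oracle_gats(g, lag, "m")))
      }
    }
    for (ord in 1:3) {
      worst <- max(worst,
                   abs(pipc(g, ord) - oracle_pipc(g, ord)),
                   abs(ggi(g, ord) - oracle_ggi(g, ord)))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("descriptor filtering removes constant, duplicated and wide-range columns", {
  set.seed(3)
  n <- 40
  base <- matrix(rnorm(n * 6), n, 6)
  x <- cbind(base,
             const1 = rep(1, n),
             const2 = rep(-2.5, n),
             dupof1 = base[, 1],
             wide = runif(n, 0, 500))
  colnames(x)[1:6] <- paste0("d", 1:6)
  filt <- filter_descriptors(x)
  expect_equal(ncol(filt$matrix), 6)
  got <- setNames(filt$removed$reason, filt$removed$descriptor)
  expect_identical(got[["const1"]], "low_variance")
  expect_identical(got[["const2"]], "low_variance")
  expect_identical(got[["wide"]], "wide_range")
  expect_identical(got[["dupof1"]], "correlation")
  # exactly one member of an identical pair is dropped
  expect_true("d1" %in% colnames(filt$matrix))
})

test_that("near-constant columns fall to the modal-value rule", {
  x <- cbind(a = c(rep(0, 33), 1:7), b = rnorm(40))
  filt <- filter_descriptors(x)   # modal value covers 33/40 > 0.8
  expect_identical(filt$removed$descriptor, "a")
  expect_identical(filt$removed$reason, "low_variance")
})
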