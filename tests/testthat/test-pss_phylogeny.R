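# Simple-matching distances, neighbor joining and group Fst matrices.

test_that("simple matching distance counts mismatches over co-called sites", {
  gm <- rbind(a = c(rep(0, 10)), b = c(rep(0, 7), 1, 1, 1),
              c = rep(1, 10))
  d <- simple_matching_distance(gm)
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "b"], 0.3)
  expect_equal(d["a", "c"], 1)
  # missing entries shrink the denominator
  gm2 <- rbind(a = c(NA, NA, rep(0, 10)), b = c(1, 1, rep(0, 9), 1))
  d2 <- simple_matching_distance(gm2)
  expect_equal(d2["a", "b"], 0.1)
  # overlap floor enforced with the offending pair named
  gm3 <- rbind(a = c(rep(NA, 8), 0, 0), b = c(rep(0, 10)))
  expect_error(simple_matching_distance(gm3), "a / b")
})

test_that("simple matching distance is a metric on complete matrices", {
  set.seed(41)
  for (i in 1:10) {
    gm <- matrix(rbinom(5 * 30, 1, 0.5), nrow = 5,
                 dimnames = list(paste0("t", 1:5), NULL))
    d <- simple_matching_distance(gm)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    for (a in 1:5) for (b in 1:5) for (c in 1:5)
      expect_lte(d[a, b], d[a, c] + d[c, b] + 1e-12)
  }
})

test_that("neighbor joining recovers additive trees", {
  # 4 taxa from tree ((A:1,B:2):1,C:3,D:4)
  D4 <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(D4)
  ref <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref)),
               structure(0, names = "PH85"), ignore_attr = TRUE)
  # path lengths reproduce the input distances on additive data
  pd <- ape::cophenetic.phylo(tr)[rownames(D4), colnames(D4)]
  expect_equal(pd, D4, tolerance = 1e-8)

  # 5 taxa, additive by construction
  ref5 <- ape::read.tree(text = "((A:1,B:2):1,(C:1.5,D:0.5):2,E:3);")
  D5 <- ape::cophenetic.phylo(ref5)
  tr5 <- neighbor_joining(D5)
  expect_equal(ape::dist.topo(ape::unroot(tr5), ape::unroot(ref5)),
               structure(0, names = "PH85"), ignore_attr = TRUE)

  # agreement with the classical implementation in ape on random matrices
  set.seed(43)
  m <- matrix(runif(36, 0.1, 1), 6, 6)
  D6 <- (m + t(m)) / 2; diag(D6) <- 0
  dimnames(D6) <- list(paste0("t", 1:6), paste0("t", 1:6))
  expect_equal(ape::dist.topo(ape::unroot(neighbor_joining(D6)),
                              ape::unroot(ape::nj(D6))),
               structure(0, names = "PH85"), ignore_attr = TRUE)
})

test_that("three taxa give the closed-form star branch lengths", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  bl <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                 tr$tip.label)
  expect_equal(unname(bl["a"]), (2 + 3 - 4) / 2, tolerance = 1e-10)
  expect_equal(unname(bl["b"]), (2 + 4 - 3) / 2, tolerance = 1e-10)
  expect_equal(unname(bl["c"]), (3 + 4 - 2) / 2, tolerance = 1e-10)
})

test_that("ties break deterministically and bad matrices are rejected", {
  D <- matrix(1, 4, 4); diag(D) <- 0
  dimnames(D) <- list(letters[1:4], letters[1:4])
  t1 <- ape::write.tree(neighbor_joining(D))
  t2 <- ape::write.tree(neighbor_joining(D))
  expect_identical(t1, t2)
  bad <- D; bad[1, 2] <- 5
  expect_error(neighbor_joining(bad), "symmetric")
  neg <- D; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(neighbor_joining(neg), "negative")
})

test_that("group Fst matrices recover simulated differentiation", {
  # two groups with identical frequencies: zero
  set.seed(44)
  g <- matrix(rbinom(40 * 50, 1, 0.4), nrow = 40,
              dimnames = list(paste0("s", 1:40), NULL))
  assign <- setNames(rep(c("G1", "G2"), each = 20), paste0("s", 1:40))
  dupg <- rbind(g[1:20, ], g[1:20, ])
  rownames(dupg) <- paste0("s", 1:40)   # two groups, identical frequencies
  m0 <- group_fst_matrix(dupg, assign)
  expect_equal(m0["G1", "G2"], 0)
  expect_true(is.na(m0["G1", "G1"]))

  # three groups at known pairwise F: recovered within 0.03 over 2000 sites
  nsite <- 2000
  p <- runif(nsite, 0.2, 0.8)
  draw <- function(f) {
    q <- rbeta(nsite, p * (1 - f) / f, (1 - p) * (1 - f) / f)
    matrix(rbinom(30 * nsite, 1, rep(q, each = 30)), nrow = 30)
  }
  gg <- rbind(draw(0.05), draw(0.05), draw(0.4))
  rownames(gg) <- paste0("x", 1:90)
  asn <- setNames(rep(c("A", "B", "C"), each = 30), rownames(gg))
  mf <- group_fst_matrix(gg, asn)
  expect_equal(mf, t(mf))
  expect_lt(mf["A", "B"], mf["A", "C"])
  expect_lt(mf["A", "B"], mf["B", "C"])
  # self-consistency against the per-site estimator on raw frequencies
  fa <- colMeans(gg[asn[rownames(gg)] == "A", ])
  fb <- colMeans(gg[asn[rownames(gg)] == "B", ])
  expect_equal(mf["A", "B"], mean(fst_site(fa, fb), na.rm = TRUE))
})

test_that("missingness filter drops sites sparse in any group", {
  g <- matrix(0L, nrow = 10, ncol = 3,
              dimnames = list(paste0("s", 1:10), NULL))
  g[1:5, 2] <- NA                       # 100% missing in group 1
  g[1, 3] <- NA                         # 20% missing in group 1
  asn <- setNames(rep(c("G1", "G2"), each = 5), rownames(g))
  kept <- filter_sites_by_missingness(g, asn, max_missing = 0.2)
  expect_equal(ncol(kept), 2)
})
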