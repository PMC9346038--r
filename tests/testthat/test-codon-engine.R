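test_that("MG94xREV rate matrix has the required structure", {
  # multi-nucleotide changes are exactly zero for any parameters
  set.seed(1)
  p <- random_mg94()
  Qm <- mg94_rate_matrix(p)
  code <- universal_genetic_code()
  cmat <- do.call(rbind, strsplit(code$codons, ""))
  ndiff <- outer(1:61, 1:61, Vectorize(function(i, j)
    sum(cmat[i, ] != cmat[j, ])))
  expect_true(all(Qm$Q[ndiff > 1] == 0))
  expect_lt(max(abs(rowSums(Qm$Q))), 1e-10)

  # omega = 1, equal exchangeabilities, uniform frequencies: all single-step
  # off-diagonals equal
  u <- mg94_rate_matrix(mg94_params(omega = 1))
  offd <- u$Q[ndiff == 1]
  expect_lt(diff(range(offd)), 1e-12)
})

test_that("detailed balance holds for random parameter draws", {
  set.seed(2)
  for (k in 1:20) {
    p <- random_mg94()
    Qm <- mg94_rate_matrix(p)
    flux <- Qm$freqs * Qm$Q
    expect_lt(max(abs(flux - t(flux))), 1e-10)
  }
})

test_that("normalization gives one expected substitution per unit length at omega 1", {
  set.seed(3)
  p <- random_mg94()
  p1 <- mg94_params(p$rev_rates, omega = 1, nuc_freqs = p$nuc_freqs)
  Qm <- mg94_rate_matrix(p1)
  expect_equal(-sum(Qm$freqs * diag(Qm$Q)), 1, tolerance = 1e-10)
})

test_that("transition matrices are stochastic and match series/expm oracles", {
  set.seed(4)
  Qm <- mg94_rate_matrix(random_mg94())
  expect_equal(transition_matrix(Qm, 0), diag(61), tolerance = 1e-10)
  for (t in c(0.05, 0.7, 3)) {
    P <- transition_matrix(Qm, t)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_true(all(P >= 0))
  }
  # first-order series at small t
  t <- 1e-4
  expect_lt(max(abs(transition_matrix(Qm, t) - (diag(61) + Qm$Q * t))), 1e-6)
  # independent matrix exponential
  expect_lt(max(abs(transition_matrix(Qm, 0.4) -
                    as.matrix(Matrix::expm(Qm$Q * 0.4)))), 1e-10)
  expect_error(transition_matrix(Qm, -1), ">= 0")
})

test_that("pruning equals closed forms on degenerate trees", {
  Qm <- mg94_rate_matrix(mg94_params(omega = 0.5))
  code <- universal_genetic_code()
  tr <- ape::read.tree(text = "(a:0.1,b:0.2,c:0.3);")
  # all leaves missing: probability one
  col <- c(a = NA, b = NA, c = NA)
  expect_equal(site_log_likelihood(tr, col, Qm), 0)
  # single observed leaf: log equilibrium frequency
  col2 <- c(a = "ATG", b = NA, c = NA)
  atg <- code$codon_index[["ATG"]]
  expect_equal(site_log_likelihood(tr, col2, Qm), log(Qm$freqs[atg]),
               tolerance = 1e-10)
})

test_that("pruning matches exhaustive enumeration on small random instances", {
  set.seed(5)
  for (k in 1:6) {
    ntax <- sample(4:5, 1)
    tr <- ape::rtree(ntax, rooted = FALSE)
    tr$edge.length <- runif(nrow(tr$edge), 0.02, 0.8)
    Qm <- mg94_rate_matrix(random_mg94())
    col <- random_column(tr$tip.label, n_missing = sample(0:1, 1))
    got <- site_log_likelihood(tr, col, Qm)
    want <- oracle_site_loglik(tr, Qm$Q, Qm$freqs, col)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to re-rooting under the reversible model", {
  set.seed(6)
  tr <- ape::rtree(6, rooted = FALSE)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.5)
  Qm <- mg94_rate_matrix(random_mg94())
  col <- random_column(tr$tip.label)
  base <- site_log_likelihood(tr, col, Qm)
  for (og in c(2, 4)) {
    rr <- ape::root(tr, outgroup = tr$tip.label[og], resolve.root = TRUE)
    expect_equal(site_log_likelihood(rr, col, Qm), base, tolerance = 1e-8)
  }
})

test_that("neighbor joining recovers additive trees exactly", {
  # additive 4-taxon metric from a known tree:
  # ((a:1,b:2):1.5,(c:1,d:3));
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 3
  d["a", "c"] <- d["c", "a"] <- 3.5
  d["a", "d"] <- d["d", "a"] <- 5.5
  d["b", "c"] <- d["c", "b"] <- 4.5
  d["b", "d"] <- d["d", "b"] <- 6.5
  d["c", "d"] <- d["d", "c"] <- 4
  tr <- nj_tree(d)
  expect_equal(as.matrix(stats::cophenetic(tr))[rownames(d), colnames(d)], d,
               tolerance = 1e-9)
  # generating topology: a,b form a cherry
  pair <- tr$edge[tr$edge[, 2] %in% match(c("a", "b"), tr$tip.label), 1]
  expect_equal(pair[1], pair[2])

  # 3 taxa: the unique unrooted topology
  expect_equal(length(nj_tree(d[1:3, 1:3])$tip.label), 3L)
  # ultrametric equidistant: path lengths reproduce the input
  de <- matrix(2, 4, 4, dimnames = dimnames(d)); diag(de) <- 0
  te <- nj_tree(de)
  expect_lt(max(abs(as.matrix(stats::cophenetic(te))[rownames(de), ] - de)), 1e-9)
  expect_true(all(te$edge.length >= 0))
  # validation
  dbad <- d; dbad[1, 2] <- 99
  expect_error(nj_tree(dbad), "symmetric")
})
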