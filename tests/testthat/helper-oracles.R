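# Independent oracles and shared fixtures for the test suite. The oracles
# deliberately avoid the package's computational paths: alignment scores by
# exhaustive enumeration of all alignments, likelihoods by explicit summation
# over internal-state assignments with Matrix::expm transition matrices.

# exhaustive global alignment score: every monotone alignment, affine gaps
# (a run of length L costs open + extend * L), end gaps penalized
oracle_align_score <- function(a, b, mat, open = 10, extend = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, sc, last) {
    if (i > length(A) && j > length(B)) {
      best <<- max(best, sc)
      return(invisible())
    }
    if (i <= length(A) && j <= length(B))
      rec(i + 1L, j + 1L, sc + mat[A[i], B[j]], "m")
    if (i <= length(A))
      rec(i + 1L, j, sc - extend - if (last != "u") open else 0, "u")
    if (j <= length(B))
      rec(i, j + 1L, sc - extend - if (last != "l") open else 0, "l")
  }
  rec(1L, 1L, 0, "s")
  best
}

# brute-force pruning likelihood: sum over all internal-state assignments,
# P(t) via Matrix::expm; missing leaves marginalize out (their edge factor
# sums to one and is skipped)
oracle_site_loglik <- function(tree, Qmat, pi, column) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  P <- lapply(seq_len(nrow(tr$edge)), function(e)
    as.matrix(Matrix::expm(Qmat * tr$edge.length[e])))
  grid <- as.matrix(expand.grid(rep(list(1:61), nnode)))
  pr <- pi[grid[, 1]]  # root is node ntip + 1, first internal column
  for (e in seq_len(nrow(tr$edge))) {
    pnode <- tr$edge[e, 1]
    cnode <- tr$edge[e, 2]
    sp <- grid[, pnode - ntip]
    if (cnode <= ntip) {
      scol <- column[tr$tip.label[cnode]]
      if (is.na(scol)) next
      pr <- pr * P[[e]][cbind(sp, scol)]
    } else {
      pr <- pr * P[[e]][cbind(sp, grid[, cnode - ntip])]
    }
  }
  log(sum(pr))
}

random_mg94 <- function() {
  nf <- matrix(rgamma(12, 8, 1), 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  nf <- sweep(nf, 2, colSums(nf), "/")
  mg94_params(rev_rates = c(AC = runif(1, .3, 3), AG = runif(1, .5, 6),
                            AT = runif(1, .3, 3), CG = runif(1, .3, 3),
                            CT = runif(1, .5, 6), GT = 1),
              omega = runif(1, 0.1, 2), nuc_freqs = nf)
}

random_column <- function(taxa, n_missing = 0) {
  col <- sample.int(61L, length(taxa), replace = TRUE)
  names(col) <- taxa
  if (n_missing > 0) col[sample(seq_along(col), n_missing)] <- NA
  col
}

# shared simulated dataset + global fit, reused across test files (built once
# per test run; 12 taxa x 60 codons keeps every consumer fast)
.fixture_env <- new.env()

shared_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    prof <- make_site_profile(c("1-30" = 0.2, "31-60" = 0.8), 60,
                              invariant_start_met = TRUE)
    .fixture_env$sim <- simulate_codon_alignment(prof, n_taxa = 12, seed = 42,
                                                 tree_length = 4)
  }
  .fixture_env$sim
}

shared_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    sim <- shared_sim()
    .fixture_env$fit <- fit_global_model(sim$alignment, sim$tree)
  }
  .fixture_env$fit
}

shared_scan <- function() {
  if (is.null(.fixture_env$scan)) {
    .fixture_env$scan <- fel_scan(shared_sim()$alignment, shared_fit())
  }
  .fixture_env$scan
}

random_protein <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
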