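test_that("site profiles are built from blocks exactly", {
  prof <- make_site_profile(c("1-40" = 0.8, "41-120" = 0.1, "121-160" = 0.9),
                            160)
  expect_equal(nrow(prof), 160)
  expect_equal(unique(prof$omega[1:40]), 0.8)
  expect_equal(unique(prof$omega[41:120]), 0.1)
  expect_equal(unique(prof$omega[121:160]), 0.9)
  expect_true(all(prof$alpha == 1))
  expect_false(any(prof$planted_positive))

  neutral <- make_site_profile(c("1-30" = 1), 30)
  expect_true(all(neutral$omega == 1))

  pos <- make_site_profile(data.frame(start = c(1, 2), end = c(1, 30),
                                      omega = c(2, 0.5)), 30)
  expect_true(pos$planted_positive[1])
  expect_false(any(pos$planted_positive[-1]))

  expect_error(make_site_profile(c("1-20" = 1, "15-30" = 1), 30),
               "overlapping")
  expect_error(make_site_profile(c("1-20" = 1), 30), "tile")
})

test_that("simulation is deterministic given the seed", {
  prof <- make_site_profile(c("1-20" = 0.5), 20)
  s1 <- simulate_codon_alignment(prof, n_taxa = 8, seed = 5)
  s2 <- simulate_codon_alignment(prof, n_taxa = 8, seed = 5)
  expect_identical(s1$alignment$sequences, s2$alignment$sequences)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  f1 <- tempfile(); f2 <- tempfile()
  write_codon_alignment(s1$alignment, f1)
  write_codon_alignment(s2$alignment, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  s3 <- simulate_codon_alignment(prof, n_taxa = 8, seed = 6)
  expect_false(identical(s1$alignment$sequences, s3$alignment$sequences))
  expect_error(simulate_codon_alignment(prof, n_taxa = 8), "seed")
})

test_that("omega zero forbids amino-acid change; invariant Met stays pinned", {
  prof <- make_site_profile(c("1-30" = 0), 30, invariant_start_met = TRUE)
  sim <- simulate_codon_alignment(prof, n_taxa = 16, seed = 11,
                                  tree_length = 10)
  chars <- sim$alignment$codon_chars
  code <- universal_genetic_code()
  gc <- Biostrings::GENETIC_CODE
  for (s in seq_len(ncol(chars))) {
    aas <- unique(unname(gc[chars[, s]]))
    expect_length(aas, 1)
  }
  expect_true(all(chars[, 1] == "ATG"))
  # truth table and alignment agree on shape
  expect_equal(nrow(sim$truth), sim$alignment$n_col)
})

test_that("substitution counts scale with branch length as the model predicts", {
  prof <- make_site_profile(c("1-1000" = 1), 1000)
  Qm <- mg94_rate_matrix(mg94_params(c(AC = 1, AG = 4, AT = 1, CG = 1,
                                       CT = 4, GT = 1), omega = 1))
  p_prev <- 0
  for (t in c(0.05, 0.1, 0.2)) {
    tr <- ape::read.tree(text = sprintf("(a:%g,b:0);", t))
    sim <- simulate_codon_alignment(prof, seed = 31 + round(1000 * t),
                                    tree = tr)
    chars <- sim$alignment$codon_chars
    obs <- mean(chars[1, ] != chars[2, ])
    expected <- 1 - sum(Qm$freqs * diag(transition_matrix(Qm, t)))
    se <- sqrt(expected * (1 - expected) / 1000)
    expect_lt(abs(obs - expected), 3 * se)
    expect_gt(obs, p_prev)  # monotone in t
    p_prev <- obs
  }
})

test_that("long-branch simulation preserves the equilibrium distribution", {
  prof <- make_site_profile(c("1-2000" = 1), 2000)
  tr <- ape::read.tree(text = "(a:20,b:0);")
  sim <- simulate_codon_alignment(prof, seed = 99, tree = tr)
  Qm <- mg94_rate_matrix(mg94_params(c(AC = 1, AG = 4, AT = 1, CG = 1,
                                       CT = 4, GT = 1), omega = 1))
  code <- universal_genetic_code()
  counts <- table(factor(sim$alignment$codon_chars[1, ],
                         levels = code$codons))
  gof <- suppressWarnings(stats::chisq.test(as.numeric(counts), p = Qm$freqs))
  expect_gt(gof$p.value, 0.001)
})

test_that("curation fixtures hit their identity/similarity targets", {
  targets <- data.frame(identity = c(100, 45, 55, 65),
                        similarity = c(100, 60, 70, 80))
  fx <- make_curation_fixture(targets, ref_length = 120, seed = 17)
  expect_equal(fx$truth$achieved_identity[1], 100)
  expect_equal(fx$records[[1]]$sequence, fx$reference$sequence)
  expect_true(all(abs(fx$truth$achieved_identity -
                      fx$truth$target_identity) <= 2))
  expect_true(all(abs(fx$truth$achieved_similarity -
                      fx$truth$target_similarity) <= 2))
  # planted 45/55 straddle the 50 percent identity rule as intended
  expect_equal(fx$truth$expected_included, c(TRUE, FALSE, TRUE, TRUE))
  # matched CDS translates back to the mutant proteins
  expect_true(all(vapply(fx$records, function(r) !is.null(r$source_cds), TRUE)))
  expect_error(make_curation_fixture(data.frame(identity = 101,
                                                similarity = 101), seed = 1),
               "within")
  expect_error(make_curation_fixture(data.frame(identity = 80,
                                                similarity = 70), seed = 1),
               "below identity")
})
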