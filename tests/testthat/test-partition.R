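test_that("a single-site partition reduces to that site's FEL omega", {
  sim <- shared_sim()
  fit <- shared_fit()
  scan <- shared_scan()
  # pick an interior defined site
  cand <- scan$site[scan$omega_status == "defined" & scan$omega > 0 &
                    is.finite(scan$omega)]
  site <- cand[1]
  agg <- fit_aggregate_omega(sim$alignment, fit,
                             partition(paste0("s", site), site))
  expect_equal(agg$omega_bar, scan$omega[scan$site == site], tolerance = 1e-6)
  expect_equal(agg$n_sites_used, 1L)
})

test_that("undefined (invariant) sites are excluded from aggregate fits", {
  sim <- shared_sim()
  fit <- shared_fit()
  scan <- shared_scan()
  p <- partition("FL", 1:60, "full_length")
  agg <- fit_aggregate_omega(sim$alignment, fit, p)
  n_undef <- sum(scan$omega_status == "undefined_0_over_0")
  expect_gt(n_undef, 0)  # at least the invariant initiator Met
  expect_equal(agg$n_sites_used, 60L - n_undef)
  # counts reconcile: used + undefined = all mapped sites
  expect_equal(agg$n_sites_used + n_undef, nrow(scan))
  # a partition of only invariant sites cannot be fit
  undef_sites <- scan$site[scan$omega_status == "undefined_0_over_0"]
  expect_error(fit_aggregate_omega(sim$alignment, fit,
                                   partition("bad", undef_sites)),
               "no usable sites")
})

test_that("aggregate omega lies within the band of its sites' defined estimates", {
  sim <- shared_sim()
  fit <- shared_fit()
  scan <- shared_scan()
  agg <- fit_aggregate_omega(sim$alignment, fit, partition("low", 2:30))
  defined <- scan[scan$site %in% 2:30 & scan$omega_status == "defined", ]
  expect_gte(agg$omega_bar, min(defined$omega) - 1e-6)
  expect_lte(agg$omega_bar, max(pmin(defined$omega, 1e4)) + 1e-6)
  expect_true(agg$ci_lower <= agg$omega_bar && agg$omega_bar <= agg$ci_upper)
})

test_that("comparisons: identical partitions give LRT 0, disjoint planted ones differ", {
  sim <- shared_sim()
  fit <- shared_fit()
  a <- fit_aggregate_omega(sim$alignment, fit, partition("A", 2:30))
  a2 <- fit_aggregate_omega(sim$alignment, fit, partition("A2", 2:30))
  # same site set: the separate fit cannot beat the joint one
  same <- compare_aggregate(a, a2)
  expect_equal(same$lrt, 0, tolerance = 1e-6)
  expect_gt(same$p_value, 0.99)

  b <- fit_aggregate_omega(sim$alignment, fit, partition("B", 31:60))
  cmp <- compare_aggregate(a, b)
  expect_gt(cmp$lrt, 0)
  expect_lt(cmp$p_value, 0.05)
  expect_equal(cmp$higher, "B")
  # symmetric in the labels
  rev <- compare_aggregate(b, a)
  expect_equal(rev$lrt, cmp$lrt, tolerance = 1e-9)
  expect_equal(rev$p_value, cmp$p_value, tolerance = 1e-9)
  expect_equal(rev$higher, cmp$higher)

  # overlap is rejected with the shared sites named
  expect_error(compare_aggregate(a,
    fit_aggregate_omega(sim$alignment, fit, partition("C", 25:40))),
    "overlap")
})

test_that("partition validation rejects bad configurations", {
  sim <- shared_sim()
  fit <- shared_fit()
  expect_error(partition("x", integer()), ">= 1")
  expect_error(fit_aggregate_omega(sim$alignment, fit, partition("x", 50:70)),
               "outside reference")
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("name\tcategory\tranges", "A\tregion\t1-10", "A\tregion\t11-20"),
             tmp)
  expect_error(read_partitions(tmp), "duplicate")
  tmp2 <- tempfile(fileext = ".tsv")
  writeLines(c("name\tcategory\tranges", "NTR\tregion\t2-20,31-40",
               "FL\tfull_length\t1-60"), tmp2)
  parts <- read_partitions(tmp2)
  expect_equal(parts$NTR$sites, c(2:20, 31:40))
  expect_equal(parts$FL$category, "full_length")
})

test_that("hasse diagrams are reduced, acyclic and follow the arrow convention", {
  res <- data.frame(name = c("p1", "p2", "p3"),
                    omega_bar = c(0.05, 0.3, 0.8))
  cmp_all <- data.frame(a = c("p1", "p1", "p2"), b = c("p2", "p3", "p3"),
                        p_value = c(0.01, 0.001, 0.02),
                        higher = c("p2", "p3", "p3"))
  h <- build_hasse(res, cmp_all, alpha = 0.05)
  # all-significant ladder collapses to a 2-edge chain, arrows to higher omega
  expect_equal(nrow(h$edges), 2)
  expect_equal(h$edges$from, c("p1", "p2"))
  expect_equal(h$edges$to, c("p2", "p3"))

  # nothing significant: edgeless
  cmp_ns <- transform(cmp_all, p_value = 0.5)
  expect_equal(nrow(build_hasse(res, cmp_ns, alpha = 0.05)$edges), 0)

  # missing pair is an error
  expect_error(build_hasse(res, cmp_all[1:2, ]), "missing pairwise")

  # DOT writer round-trip contains all edges
  tmp <- tempfile(fileext = ".dot")
  write_hasse_dot(h, tmp)
  txt <- readLines(tmp)
  expect_true(any(grepl("\"p1\" -> \"p2\"", txt)))
  expect_true(any(grepl("digraph", txt)))
})
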