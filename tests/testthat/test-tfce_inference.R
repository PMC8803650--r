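test_that("TFCE of an isolated element matches the discrete hand sum", {
  iso <- isolated_domain()
  # sum_{k=1..10} 1^E (0.1 k)^2 * 0.1 = 0.385
  expect_equal(tfce_enhance(1.0, iso, tfce_params(dh = 0.1))$enhanced,
               0.385, tolerance = 1e-12)
  # dh -> 0 limit: integral of h^2 over [0, 1] = 1/3
  fine <- tfce_enhance(1.0, iso, tfce_params(dh = 1e-4))$enhanced
  expect_equal(fine, 1 / 3, tolerance = 1e-3)
  # all-zero map stays zero
  d <- build_mesh_domain(0)
  expect_equal(tfce_enhance(numeric(12), d)$enhanced, numeric(12))
})

test_that("incremental TFCE equals brute-force recomputation", {
  set.seed(321)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    dom <- random_graph_domain(n, p = runif(1, 0.05, 0.3), seed = 500 + i)
    stat <- rnorm(n)
    dh <- max(abs(stat)) / 37
    got <- tfce_enhance(stat, dom, tfce_params(dh = dh))$enhanced
    want <- tfce_brute(stat, dom, dh = dh)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("raising one element's statistic never decreases enhancement", {
  set.seed(77)
  for (i in 1:10) {
    n <- 30
    dom <- random_graph_domain(n, 0.15, seed = 700 + i)
    stat <- abs(rnorm(n))
    dh <- 0.05
    base <- tfce_enhance(stat, dom, tfce_params(dh = dh))$enhanced
    j <- sample.int(n, 1)
    stat2 <- stat
    stat2[j] <- stat2[j] + runif(1, 0.1, 1)
    up <- tfce_enhance(stat2, dom, tfce_params(dh = dh))$enhanced
    expect_true(all(up >= base - 1e-12))
  }
})

test_that("permutation p-values obey the max-statistic convention", {
  dom <- build_mesh_domain(1)
  parc <- make_parcellation(dom, 4, rng_seed = 1)
  cfg <- simulation_config(group_sizes = c(CON = 8, AUD = 8),
                           element_noise_sd_mm = 0.05,
                           effect_table = data.frame(
                             group = "AUD",
                             parcel_id = 1:2,
                             thinning_mm = 0.8)) # massive planted effect
  coh <- simulate_cohort(cfg, dom, parc, rng_seed = 3)
  des <- make_design(coh$covariates, c(CON = 1, AUD = -1),
                     groups = c("CON", "AUD"))
  inf <- permutation_fwe(coh, des, dom, n_perm = 99, alpha = 0.05,
                         rng_seed = 4)
  # observed max exceeds all 99 permuted maxima -> min p = 1/100
  expect_equal(min(inf$p_fwe), 0.01)
  expect_gt(sum(inf$sig_mask), 0)
  # p values are multiples of 1/(n_perm + 1), bounded below by it
  expect_true(all(inf$p_fwe >= 1 / 100))
  expect_true(all(abs(inf$p_fwe * 100 - round(inf$p_fwe * 100)) < 1e-9))
  expect_error(permutation_fwe(coh, des, dom, n_perm = 9, alpha = 1.5),
               "alpha")
})

test_that("permutation inference is deterministic under a fixed seed", {
  dom <- build_mesh_domain(1)
  parc <- make_parcellation(dom, 4, rng_seed = 1)
  cfg <- simulation_config(group_sizes = c(CON = 6, AUD = 6))
  coh <- simulate_cohort(cfg, dom, parc, rng_seed = 8)
  des <- make_design(coh$covariates, c(CON = 1, AUD = -1),
                     groups = c("CON", "AUD"))
  a <- permutation_fwe(coh, des, dom, n_perm = 50, rng_seed = 31)
  b <- permutation_fwe(coh, des, dom, n_perm = 50, rng_seed = 31)
  expect_identical(a$p_fwe, b$p_fwe)
  expect_identical(a$max_dist, b$max_dist)
})

test_that("null min-p distribution is roughly uniform", {
  # exchangeable labels under a true null: min p_fwe should not pile up
  # near 0 or 1 (coarse Kolmogorov-Smirnov sanity on a small replicate set)
  dom <- build_mesh_domain(1)
  parc <- make_parcellation(dom, 4, rng_seed = 1)
  cfg <- simulation_config(group_sizes = c(CON = 8, AUD = 8))
  pmin_all <- numeric(40)
  for (s in 1:40) {
    coh <- simulate_cohort(cfg, dom, parc, rng_seed = 3000 + s)
    des <- make_design(coh$covariates, c(CON = 1, AUD = -1),
                       groups = c("CON", "AUD"))
    inf <- permutation_fwe(coh, des, dom, n_perm = 60, rng_seed = 4000 + s)
    pmin_all[s] <- min(inf$p_fwe)
  }
  ks <- suppressWarnings(stats::ks.test(pmin_all, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("Benjamini-Hochberg step-up matches hand evaluation", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06)
  expect_equal(bh_fdr(p, 0.05), c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(bh_fdr(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_equal(bh_fdr(rep(0, 5), 0.05), rep(TRUE, 5))
  expect_error(bh_fdr(p, 0), "q outside")
  expect_error(bh_fdr(p, 1), "q outside")
})
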