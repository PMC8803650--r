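make_pm <- function(values, parc) {
  pm <- parcel_means(matrix(2.5, nrow(values),
                            length(parc$element_to_parcel)), parc)
  pm$values <- values
  pm
}

test_that("subject centering zeroes row means and is idempotent", {
  dom <- build_mesh_domain(1)
  parc <- make_parcellation(dom, 4, rng_seed = 1)
  v <- rbind(c(2.4, 2.6, 2.5, 2.5), c(2.2, 2.2, 2.4, 2.4))
  pm <- make_pm(v, parc)
  cc <- center_subjects(pm)
  expect_equal(cc$values[1, 1:2], c(-0.1, 0.1))
  expect_true(all(abs(rowMeans(cc$values)) < 1e-12))
  expect_equal(center_subjects(cc)$values, cc$values)

  # column correlations invariant to subject-specific constants
  set.seed(4)
  v2 <- matrix(rnorm(10 * 4), 10, 4)
  pm2 <- make_pm(v2, parc)
  pm3 <- make_pm(v2 + rnorm(10), parc) # add per-subject constants
  expect_equal(cor(center_subjects(pm2)$values),
               cor(center_subjects(pm3)$values), tolerance = 1e-10)
})

test_that("age residualization removes age from every parcel column", {
  dom <- build_mesh_domain(1)
  parc <- make_parcellation(dom, 4, rng_seed = 1)
  set.seed(6)
  age <- rnorm(12, 45, 9)
  v <- matrix(rnorm(12 * 4), 12, 4)
  v[, 2] <- 2 * age
  pm <- age_residualize(make_pm(v, parc), age)
  expect_true(all(abs(pm$values[, 2]) < 1e-10))
  for (k in c(1, 3, 4))
    expect_lt(abs(cor(pm$values[, k], age)), 1e-10)
  # invariant to affine rescaling of age
  pm2 <- age_residualize(make_pm(v, parc), 3 * age - 100)
  expect_equal(pm$values, pm2$values, tolerance = 1e-9)
  expect_error(age_residualize(make_pm(v, parc), rep(45, 12)),
               "constant age")
})

test_that("correlation matrices behave on duplicated and null columns", {
  dom <- build_mesh_domain(1)
  parc <- make_parcellation(dom, 4, rng_seed = 1)
  set.seed(8)
  v <- matrix(rnorm(20 * 4), 20, 4)
  v[, 2] <- v[, 1]
  v[, 3] <- -v[, 1]
  cv <- covariance_matrix(make_pm(v, parc), "g")
  expect_equal(cv$corr[1, 2], 1)
  expect_equal(cv$corr[1, 3], -1)
  expect_true(isSymmetric(cv$corr))
  expect_true(all(diag(cv$corr) == 1))
  expect_true(all(cv$corr >= -1 - 1e-12 & cv$corr <= 1 + 1e-12))

  # zero-variance column flagged undefined
  v0 <- v; v0[, 4] <- 5
  cv0 <- covariance_matrix(make_pm(v0, parc), "g")
  expect_equal(cv0$undefined, 4L)
  expect_true(anyNA(cv0$corr[, 4][-4]))

  # independent Gaussian columns: mean |r| near its null expectation
  n <- 65
  dom2 <- shared_mesh()
  parc2 <- shared_parcellation()
  ms <- replicate(20, {
    vv <- matrix(rnorm(n * 20), n, 20)
    pm <- parcel_means(matrix(2.5, n, dom2$n_elements), parc2)
    pm$values <- vv
    pm$parcels <- pm$parcels[1:20, ]
    r <- covariance_matrix(pm, "null")$corr
    mean(abs(r[upper.tri(r)]))
  })
  expect_lt(abs(mean(ms) - sqrt(2 / (pi * (n - 1)))),
            3 * sd(ms) / sqrt(20) + 0.01)
})

test_that("peak seeds name one parcel per cluster with lowest-id ties", {
  dom <- build_lattice_domain(c(1, 1, 9), array(TRUE, c(1, 1, 9)))
  parc <- ctcov:::new_parcellation(
    rep(1:3, each = 3),
    data.frame(parcel_id = 1:3,
               name = c("DMNa_Region_1", "ECNa_Region_1", "SMNa_Region_1"),
               hemisphere = c("L", "L", "R"),
               network = c("DMNa", "ECNa", "SMNa"),
               subnetwork = c("a", "a", "a"),
               network_family = c("DMN", "ECN", "SMN"),
               stringsAsFactors = FALSE))
  # fabricate an inference result with two separated clusters
  res <- structure(list(
    enhanced = c(5, 6, 5, 0, 0, 0, 3, 3, 0),
    sig_mask = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE)),
    class = "ctcov_inference")
  seeds <- peak_seed(res, dom, parc, n_seeds = 2)
  expect_length(seeds, 2)
  expect_equal(seeds[1], parc$element_to_parcel[2]) # peak of big cluster
  # exact tie inside the second cluster resolves to the lowest element id
  expect_equal(seeds[2], parc$element_to_parcel[7])
  expect_true(seeds[1] != seeds[2] ||
                parc$element_to_parcel[2] == parc$element_to_parcel[7])

  empty <- structure(list(enhanced = numeric(9),
                          sig_mask = rep(FALSE, 9)),
                     class = "ctcov_inference")
  expect_error(peak_seed(empty, dom, parc), "no significant peak")
})

test_that("seed maps apply the one-sided positive-correlation rule", {
  # synthetic correlation structure with known entries
  K <- 5; n <- 21
  corr <- diag(K)
  corr[1, 2] <- corr[2, 1] <- 0.6   # t = 3.27, one-sided p ~ 0.002
  corr[1, 3] <- corr[3, 1] <- -0.9  # excluded: negative
  corr[1, 4] <- corr[4, 1] <- 0     # excluded: p = 0.5
  corr[1, 5] <- corr[5, 1] <- 0.2   # excluded at alpha = 0.05 (p ~ 0.19)
  cv <- structure(list(group = "g", corr = corr, n_subjects = n,
                       undefined = integer(0)),
                  class = "ctcov_covariance")
  smap <- seed_map(cv, 1, alpha = 0.05)
  expect_equal(smap$members, 2L)
  expect_false(1L %in% smap$members) # seed self-excluded

  # membership grows monotonically with alpha
  s1 <- seed_map(cv, 1, alpha = 0.01)
  s2 <- seed_map(cv, 1, alpha = 0.25)
  expect_true(all(s1$members %in% s2$members))

  cv$n_subjects <- 3
  expect_error(seed_map(cv, 1), "too few subjects")
})

test_that("latent-factor cohorts yield network-faithful seed maps", {
  dom <- shared_mesh()
  parc <- shared_parcellation()
  cfg <- simulation_config(group_sizes = c(AUD = 65),
                           latent_factor = list(network_family = "DMN",
                                                sd_mm = 0.1))
  coh <- simulate_cohort(cfg, dom, parc, rng_seed = 51)
  pm <- center_subjects(parcel_means(coh, parc))
  pm <- age_residualize(pm, coh$covariates$age)
  cv <- covariance_matrix(pm, "AUD")
  dmn <- parc$parcels$parcel_id[parc$parcels$network_family == "DMN"]
  smap <- seed_map(cv, dmn[1], alpha = 0.05)
  fams <- split(parc$parcels$parcel_id, parc$parcels$network_family)
  frac <- vapply(fams, function(p)
    mean(setdiff(p, dmn[1]) %in% smap$members), 0)
  expect_equal(names(which.max(frac)), "DMN")
})
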