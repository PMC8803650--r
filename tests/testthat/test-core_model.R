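test_that("lattice domains implement 6-connectivity over the mask", {
  d <- build_lattice_domain(c(1, 1, 3), array(TRUE, c(1, 1, 3)))
  expect_equal(d$n_elements, 3L)
  expect_equal(nrow(d$edges), 2L) # path graph forced by 6-connectivity

  d8 <- build_lattice_domain(c(2, 2, 2), array(TRUE, c(2, 2, 2)))
  expect_equal(d8$n_elements, 8L)
  expect_equal(nrow(d8$edges), 12L) # cube edge count

  # two voxels touching only diagonally are not neighbors
  m <- array(FALSE, c(2, 2, 1))
  m[1, 1, 1] <- TRUE; m[2, 2, 1] <- TRUE
  dd <- build_lattice_domain(c(2, 2, 1), m)
  expect_equal(dd$n_elements, 2L)
  expect_equal(nrow(dd$edges), 0L)

  expect_error(build_lattice_domain(c(2, 2, 2), array(FALSE, c(2, 2, 2))),
               "empty domain")
})

test_that("mesh domains have the icosphere vertex and edge counts", {
  d0 <- build_mesh_domain(0)
  expect_equal(d0$n_elements, 12L)
  expect_equal(nrow(d0$edges), 30L)
  expect_equal(build_mesh_domain(1)$n_elements, 42L)  # 10*4^1 + 2
  expect_equal(build_mesh_domain(2)$n_elements, 162L) # 10*4^2 + 2
  expect_error(build_mesh_domain(7))
})

test_that("adjacency is symmetric, irreflexive, and within range", {
  check_domain <- function(d) {
    e <- d$edges
    expect_true(all(e[, 1] != e[, 2]))
    expect_true(all(e >= 1) && all(e <= d$n_elements))
    # canonical storage u < v with no duplicates encodes symmetry
    expect_true(all(e[, 1] < e[, 2]))
    expect_false(any(duplicated(e)))
  }
  check_domain(build_mesh_domain(2))
  set.seed(42)
  for (i in 1:5) {
    m <- array(runif(4 * 4 * 4) < 0.6, c(4, 4, 4))
    if (!any(m)) m[1, 1, 1] <- TRUE
    check_domain(build_lattice_domain(c(4, 4, 4), m))
  }
})

test_that("parcel labels parse, classify, and round-trip", {
  i <- parse_label("SAL/VANb_Insula_2", "R")
  expect_equal(i$network_family, "SAL/VAN")
  expect_equal(i$subnetwork, "b")
  i2 <- parse_label("DMNb_PrefrontalCortex_dorsal_4", "L")
  expect_equal(i2$network_family, "DMN")
  expect_equal(parse_label("Temporparietal_Region_4", "R")$network_family,
               "TemporoParietal")
  expect_equal(parse_label("Temporoparietal_Region_1", "R")$network_family,
               "TemporoParietal")
  expect_error(parse_label("XYZ_Foo_1", "L"), "unknown network label")

  # identity on every published thinning label
  lab <- ct_reduction_labels()
  for (k in seq_len(nrow(lab))) {
    info <- parse_label(lab$name[k], lab$hemisphere[k])
    expect_identical(format_label(info), lab$name[k])
  }
})

test_that("smoothing is mean-preserving, variance-contracting averaging", {
  d <- build_mesh_domain(2)
  const <- rep(3.14, d$n_elements)
  expect_equal(smooth_field(const, d, iterations = 3), const)

  set.seed(7)
  x <- rnorm(d$n_elements)
  y <- smooth_field(x, d, fwhm_mm = 15)
  expect_lt(abs(mean(y) - mean(x)), 1e-10 * max(1, abs(mean(x))))
  expect_lte(var(y), var(x))

  # impulse on a path graph: one iteration is the (1/4, 1/2, 1/4) stencil
  p <- build_lattice_domain(c(1, 1, 5), array(TRUE, c(1, 1, 5)))
  imp <- c(0, 0, 1, 0, 0)
  expect_equal(smooth_field(imp, p, iterations = 1),
               c(0, 0.25, 0.5, 0.25, 0))
})

test_that("empirical smoothing FWHM tracks the requested kernel width", {
  # impulse response on a long path with unit spacing: after the derived
  # number of iterations the fitted Gaussian FWHM is close to requested
  n <- 201
  p <- build_lattice_domain(c(1, 1, n), array(TRUE, c(1, 1, n)))
  imp <- numeric(n); imp[101] <- 1
  for (fw in c(6, 10)) {
    y <- smooth_field(imp, p, fwhm_mm = fw)
    pos <- seq_len(n) - 101
    sig <- sqrt(sum(y * pos^2) / sum(y))
    expect_lt(abs(2.3548 * sig - fw) / fw, 0.25)
  }
})

test_that("domains, parcellations and fields survive a TSV round-trip", {
  d <- build_mesh_domain(1)
  dir <- file.path(tempdir(), "dom_io")
  write_domain(d, dir)
  d2 <- read_domain(dir)
  expect_equal(d2$n_elements, d$n_elements)
  expect_equal(d2$edges, d$edges)
  expect_equal(d2$mode, d$mode)

  pc <- make_parcellation(d, 6, rng_seed = 1)
  write_parcellation(pc, dir)
  pc2 <- read_parcellation(dir)
  expect_equal(pc2$element_to_parcel, pc$element_to_parcel)
  expect_equal(pc2$parcels$name, pc$parcels$name)

  f <- rnorm(d$n_elements)
  path <- file.path(dir, "field.tsv")
  write_field(f, path)
  expect_equal(read_field(path), f)
})

test_that("synthetic parcellations cover the domain with valid labels", {
  d <- shared_mesh()
  pc <- shared_parcellation()
  expect_equal(length(pc$element_to_parcel), d$n_elements)
  expect_true(all(tabulate(pc$element_to_parcel, n_parcels(pc)) > 0))
  for (k in seq_len(n_parcels(pc))) {
    info <- parse_label(pc$parcels$name[k], pc$parcels$hemisphere[k])
    expect_equal(info$network_family, pc$parcels$network_family[k])
  }
})
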