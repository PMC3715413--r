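test_that("closed-form loading matches the equilibrium-root oracle", {
  # the frozen enzyme case: equal concentrations, Table-constant affinities
  ld <- load_vesicle(c(1, 1, 1), K = c(1.4, 2.5, 5), n_sites = 1)
  or <- oracle_loading(c(1, 1, 1), c(1.4, 2.5, 5))
  expect_equal(ld$v, or$v, tolerance = 1e-12)
  expect_equal(ld$free_sites, or$free_sites, tolerance = 1e-12)
  expect_equal(unname(ld$v), c(0.3086420, 0.1728395, 0.0864198),
    tolerance = 1e-6)
  expect_equal(ld$free_sites, 0.4320988, tolerance = 1e-6)

  set.seed(421)
  for (i in 1:200) {
    n_sp <- sample(1:6, 1)
    C <- runif(n_sp, 0, 5) * rbinom(n_sp, 1, 0.9) # include zeros
    K <- runif(n_sp, 0.05, 10)
    n <- runif(1, 0.1, 3)
    ld <- load_vesicle(C, K, n)
    or <- oracle_loading(C, K, n)
    expect_equal(ld$v, or$v, tolerance = 1e-10)
    # site conservation to machine precision
    expect_equal(sum(ld$v) + ld$free_sites, n, tolerance = 1e-14)
    expect_true(all(ld$v >= 0) && ld$free_sites >= 0)
  }
})

test_that("single-species loading reduces to the saturating form", {
  for (C in c(0, 0.3, 1, 7)) {
    ld <- load_vesicle(C, K = 2, n_sites = 1.5)
    expect_equal(unname(ld$v), 1.5 * C / (2 + C), tolerance = 1e-14)
  }
  # half-saturation symmetry
  ld <- load_vesicle(1, K = 1, n_sites = 1)
  expect_equal(unname(ld$v), 0.5)
  expect_equal(ld$free_sites, 0.5)
})

test_that("empty cisterna loads nothing", {
  ld <- load_vesicle(c(0, 0), K = c(1, 2), n_sites = 3)
  expect_equal(unname(ld$v), c(0, 0))
  expect_equal(ld$free_sites, 3)
})

test_that("loading is homogeneous in the site concentration", {
  C <- c(0.5, 2, 0.1)
  K <- c(1.4, 2.5, 5)
  base <- load_vesicle(C, K, n_sites = 1)
  scaled <- load_vesicle(C, K, n_sites = 3.7)
  expect_equal(scaled$v, 3.7 * base$v, tolerance = 1e-14)
  expect_equal(scaled$free_sites, 3.7 * base$free_sites, tolerance = 1e-14)
})

test_that("stronger binders win shared sites; scaling concentrations fills sites", {
  rep1 <- loading_ordering_report(c(1, 1), K = c(0.4, 5))
  expect_true(rep1$ordered)
  expect_gt(rep1$load$v[1], rep1$load$v[2])

  rep2 <- loading_ordering_report(c(1, 1), K = c(2, 2))
  expect_equal(rep2$load$v[1], rep2$load$v[2])

  lo <- load_vesicle(c(1, 1, 1), K = c(1.4, 2.5, 5))
  hi <- load_vesicle(10 * c(1, 1, 1), K = c(1.4, 2.5, 5))
  expect_true(all(hi$v > lo$v))
  expect_lt(hi$free_sites, lo$free_sites)
})

test_that("loading rejects invalid input", {
  expect_error(load_vesicle(-1, K = 1), "nonnegative")
  expect_error(load_vesicle(1, K = 0), "positive")
  expect_error(load_vesicle(1, K = 1, n_sites = 0), "positive")
  expect_error(loading_ordering_report(1, K = 1), "two competing")
})
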