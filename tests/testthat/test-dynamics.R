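single_pair <- function(kappa_t = 0.2, n = 8, omega = 2, ...) {
  list(
    species = golgi_species(
      name = c("t", "v"), role = c("t_snare_alpha", "v_snare_alpha"),
      K = 1, kappa = c(kappa_t, 0), C_init = 1
    ),
    params = golgi_parameters(n_cisternae = n, omega = omega,
      site_sharing = "by_class", ...)
  )
}

test_that("fusion weights are proportional to target t-SNARE and normalized", {
  sp <- single_pair(n = 3)
  st <- golgi_state(sp$species, sp$params)
  st$C["t", ] <- c(0.9, 0.6, 0.3)
  fw <- fusion_weights(2, st, sp$species, sp$params)
  expect_equal(unname(fw$w), c(0.5, 1 / 3, 1 / 6))
  expect_equal(fw$w_er, 0)
  expect_equal(sum(fw$w) + fw$w_er, 1)

  # flat t-SNARE: uniform over the three compartment slots
  st$C["t", ] <- 1
  fw2 <- fusion_weights(2, st, sp$species, sp$params)
  expect_equal(unname(fw2$w), rep(1 / 3, 3))
})

test_that("a dead beta pair leaves weights identical to the pure-alpha case", {
  sp2 <- list(
    species = golgi_species(
      name = c("t", "v", "bt", "bv"),
      role = c("t_snare_alpha", "v_snare_alpha", "t_snare_beta",
        "v_snare_beta"),
      K = 1, kappa = 0, C_init = c(1, 1, 0, 0)
    ),
    params = golgi_parameters(n_cisternae = 4, omega = 2,
      site_sharing = "by_class")
  )
  sp1 <- single_pair(kappa_t = 0, n = 4)
  st2 <- golgi_state(sp2$species, sp2$params)
  st1 <- golgi_state(sp1$species, sp1$params)
  st2$C["t", ] <- st1$C["t", ] <- c(1, 0.7, 0.5, 0.2)
  for (d in 1:4) {
    expect_equal(
      fusion_weights(d, st2, sp2$species, sp2$params)$w,
      fusion_weights(d, st1, sp1$species, sp1$params)$w
    )
  }
})

test_that("all-zero affinities give all-zero weights and no transport", {
  sp <- single_pair(kappa_t = 0, n = 3)
  st <- golgi_state(sp$species, sp$params)
  st$C[] <- 0
  fw <- fusion_weights(1, st, sp$species, sp$params)
  expect_equal(unname(fw$w), rep(0, 3))
  d <- flux_derivatives(st, sp$params, sp$species)
  expect_equal(max(abs(d)), 0)
})

test_that("omega = 0 reduces the flux to pure first-order decay", {
  sp <- single_pair(kappa_t = 0.25, omega = 0, n = 5)
  st <- golgi_state(sp$species, sp$params)
  st$C["t", ] <- runif(5, 0.2, 1)
  d <- flux_derivatives(st, sp$params, sp$species)
  expect_equal(unclass(d), -sp$species$kappa * st$C, ignore_attr = TRUE)
})

test_that("closed boundary with no decay conserves total stack content", {
  sp <- single_pair(kappa_t = 0, omega = 3, n = 6)
  set.seed(7)
  for (rep in 1:5) {
    st <- golgi_state(sp$species, sp$params)
    st$C["t", ] <- runif(6, 0.1, 1.5)
    st$C["v", ] <- runif(6, 0.1, 1.5)
    d <- flux_derivatives(st, sp$params, sp$species)
    expect_equal(rowSums(unclass(d)), c(t = 0, v = 0), tolerance = 1e-14)
  }
})

test_that("a flat profile is stationary when no loss acts", {
  sp <- single_pair(kappa_t = 0, omega = 2, n = 7)
  st <- golgi_state(sp$species, sp$params) # uniform C_init everywhere
  d <- flux_derivatives(st, sp$params, sp$species)
  expect_equal(max(abs(d)), 0, tolerance = 1e-15)
})

test_that("euler step advances decay accurately and clamps overshoot", {
  sp <- single_pair(kappa_t = 0.2, omega = 0, n = 4)
  st <- golgi_state(sp$species, sp$params)
  st2 <- euler_step(st, sp$params, sp$species, dt = 1e-3)
  expect_equal(unname(st2$C["t", 1]), 1 - 0.2 * 1e-3)
  expect_equal(st2$t_in_period, 1e-3)

  # overshoot: decay rate so large one step crosses zero
  spx <- single_pair(kappa_t = 2000, omega = 0, n = 4)
  stx <- golgi_state(spx$species, spx$params)
  expect_warning(
    stx2 <- euler_step(stx, spx$params, spx$species, dt = 1e-3),
    "clamped"
  )
  expect_true(all(stx2$C >= 0))
  expect_gt(stx2$clamp_count, 0)
})

test_that("halving the step size shows second-order local error (Richardson)", {
  sp <- single_pair(kappa_t = 0.2, omega = 3, n = 5)
  st <- golgi_state(sp$species, sp$params)
  st$C["t", ] <- c(1, 0.8, 0.6, 0.4, 0.2)
  dt <- 2e-3
  one <- euler_step(st, sp$params, sp$species, dt)
  half <- euler_step(euler_step(st, sp$params, sp$species, dt / 2),
    sp$params, sp$species, dt / 2)
  err1 <- max(abs(one$C - half$C))
  dt <- 1e-3
  one <- euler_step(st, sp$params, sp$species, dt)
  half <- euler_step(euler_step(st, sp$params, sp$species, dt / 2),
    sp$params, sp$species, dt / 2)
  err2 <- max(abs(one$C - half$C))
  expect_gt(err1 / err2, 3) # halving dt quarters the Richardson defect
})

test_that("maturation shift moves, flushes and reloads", {
  sp <- single_pair(n = 3)
  st <- golgi_state(sp$species, sp$params)
  st$C["t", ] <- c(0.5, 0.4, 0.3)
  st <- maturation_shift(st, sp$species)
  expect_equal(unname(st$C["t", ]), c(1, 0.5, 0.4))
  expect_equal(unname(st$flushed_last["t"]), 0.3)
  expect_equal(st$n_shifts, 1L)
  expect_equal(st$t_in_period, 0)

  # pure conveyor: after N shifts the stack is C_init everywhere
  sp0 <- single_pair(kappa_t = 0, omega = 0, n = 4)
  st <- golgi_state(sp0$species, sp0$params, init = "denovo")
  for (k in 1:4) st <- maturation_shift(st, sp0$species)
  expect_equal(unname(st$C["t", ]), rep(1, 4))
})

test_that("compiled and reference integrators agree step for step", {
  for (scen in c("single_snare", "enzymes_open", "enzymes_open_decoupled",
                 "full_mammalian", "unrestricted_yeast")) {
    sc <- build_scenario(sub("_decoupled$", "", scen))
    if (scen == "enzymes_open_decoupled") sc$params$er_cargo_only <- TRUE
    sc$params$n_cisternae <- 5L
    sc$params$max_periods <- 2L
    sc$params$tol <- 1e-300 # force both periods
    r_cpp <- suppressWarnings(
      run_to_steady_state(sc$species, sc$params, engine = "cpp"))
    r_ref <- suppressWarnings(
      run_to_steady_state(sc$species, sc$params, engine = "r"))
    expect_equal(r_cpp$profiles, r_ref$profiles, tolerance = 1e-13)
    expect_equal(r_cpp$er_delivered, r_ref$er_delivered, tolerance = 1e-13)
    expect_equal(r_cpp$decayed, r_ref$decayed, tolerance = 1e-13)
  }
})
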