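test_that("every preset validates and carries the published constants", {
  for (nm in list_scenarios()) {
    sc <- build_scenario(nm)
    expect_silent(validate_config(sc$species, sc$params))
    expect_equal(sc$params$period, 1)
    expect_true(all(sc$species$C_init == 1))
  }
  fm <- build_scenario("full_mammalian")
  K <- setNames(fm$species$K, fm$species$name)
  expect_equal(K[c("er_v", "alpha_t", "alpha_v", "beta_t", "beta_v",
                   "enz_cis", "enz_med", "enz_trans")],
               c(er_v = 0.2, alpha_t = 0.4, alpha_v = 0.4, beta_t = 1,
                 beta_v = 5, enz_cis = 1.4, enz_med = 2.5, enz_trans = 5))
  expect_equal(fm$params$T_ER, 0.7)
  # only the beta t-SNARE carries an explicit decay term
  expect_true(all(fm$species$kappa[fm$species$name != "beta_t"] == 0))
  expect_gt(fm$species$kappa[fm$species$name == "beta_t"], 0)

  eo <- build_scenario("enzymes_open")
  expect_equal(sort(eo$species$K[eo$species$role == "passive_cargo"]),
               c(1.4, 2.5, 5))
  expect_equal(eo$params$er_access, "first_cisterna_only")

  to <- build_scenario("single_snare_transport_only")
  expect_true(all(to$species$kappa == 0))
  expect_gt(to$params$omega, 0)

  lo <- build_scenario("single_snare_loss_only")
  expect_equal(lo$params$omega, 0)
})

test_that("unknown scenario names are rejected with the preset list", {
  expect_error(build_scenario("bogus"), "single_snare")
  expect_error(build_scenario("bogus"), "full_mammalian")
})

# rebuilding a parameter list through the constructor re-runs every check
assert_parameters_public <- function(p) {
  do.call(golgi_parameters, unclass(p))
}

test_that("validation rejects inconsistent configurations", {
  sc <- build_scenario("single_snare")
  p_bad <- sc$params
  p_bad$dt <- p_bad$period # integrator guard: dt must be << period
  expect_error(assert_parameters_public(p_bad), "dt")

  p_bad2 <- sc$params
  p_bad2$er_access <- "all_cisternae" # boundary stays closed
  expect_error(validate_config(sc$species, p_bad2), "closed")

  sp_dup <- sc$species
  sp_dup$name[2] <- sp_dup$name[1]
  expect_error(validate_config(sp_dup, sc$params), "duplicate")

  # fusion-active transport without a v-SNARE role
  sp_t_only <- golgi_species("t", "t_snare_alpha", K = 1)
  expect_error(
    validate_config(sp_t_only, sc$params),
    "v-SNARE"
  )
  expect_error(golgi_species("x", "t_snare_alpha", K = -1), "positive")
  expect_error(golgi_species("x", "nonsense", K = 1), "role")
})

test_that("configurations round-trip exactly through the YAML format", {
  for (nm in c("single_snare", "enzymes_open", "full_mammalian")) {
    sc <- build_scenario(nm)
    path <- withr::local_tempfile(fileext = ".yaml")
    write_config(sc, path)
    back <- read_config(path)
    expect_identical(back$species, sc$species)
    expect_identical(back$params, sc$params)
    expect_identical(back$name, nm)
  }
})

test_that("unknown configuration keys are rejected", {
  sc <- build_scenario("single_snare")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(sc, path)
  txt <- readLines(path)
  writeLines(c(txt, "mystery_key: 1"), path)
  expect_error(read_config(path), "unknown top-level")

  writeLines(sub("omega:", "omege:", txt), path)
  expect_error(read_config(path), "unknown parameter")
})
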