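test_that("the default network has exactly 21 species and 21 reactions", {
  net <- fx_network()
  expect_length(net$species, 21L)
  expect_length(net$reactions, 21L)
  ids <- vapply(net$reactions, `[[`, integer(1), "id")
  expect_identical(sort(ids), 1:21)
  expect_identical(dim(net$stoichiometry), c(21L, 21L))
})

test_that("PINK1 dimer degradation is slower than monomer degradation", {
  p <- default_parameters()
  expect_lt(p[["r3_k"]], p[["r2_k"]])
  bad <- p
  bad["r3_k"] <- p[["r2_k"]] * 2
  expect_error(build_default_network(params = bad), "slower")
})

test_that("parameters outside the printed class bounds are rejected", {
  p <- default_parameters()
  p["r12_kon"] <- 50 # above the diffusion limit
  expect_error(build_default_network(params = p), "bounds")
  p <- default_parameters()
  p["r7_km"] <- 0.5 # below the Km range
  expect_error(build_default_network(params = p), "bounds")
  # variant zeroing is only legal with the override flag
  p <- default_parameters()
  p["r13_kon"] <- 0
  expect_error(build_default_network(params = p), "bounds")
  expect_silent(build_default_network(params = p, allow_zero = TRUE))
})

test_that("conserved moiety vectors lie in the left null space of S", {
  net <- fx_network()
  for (m in names(net$moieties)) {
    resid <- drop(net$moieties[[m]] %*% net$stoichiometry)
    expect_equal(unname(resid), rep(0, 21), tolerance = 1e-12,
                 info = paste("moiety:", m))
  }
})

test_that("every conversion has a nonzero reverse rate constant in the WT set", {
  p <- default_parameters()
  # mass-action reversibility
  for (nm in grep("_koff$", names(p), value = TRUE)) expect_gt(p[[nm]], 0)
  # each forward enzymatic conversion has a nonzero opposing reaction
  opposing <- list(c("r5_kc", "r6_kc"), c("r7_kc", "r8_kc"),
                   c("r11_kc", "r10_kc"), c("r14_kc", "r15_kc"),
                   c("r16_kc", "r17_kc"), c("r18_kc", "r19_kc"))
  for (pair in opposing) {
    expect_gt(p[[pair[1]]], 0)
    expect_gt(p[[pair[2]]], 0)
  }
})

test_that("moiety totals have zero time derivative at random states", {
  net <- fx_network()
  for (x in random_states(100)) {
    dx <- derivatives(net, x)
    for (m in names(net$moieties)) {
      expect_equal(unname(sum(net$moieties[[m]] * dx)), 0, tolerance = 1e-9)
    }
  }
})

test_that("compiled and data-driven derivative evaluations agree", {
  net <- fx_network()
  f <- mitoamp:::.ode_func(net)
  for (x in random_states(50, seed = 11)) {
    expect_equal(f(0, x, NULL)[[1]], unname(derivatives(net, x)),
                 tolerance = 1e-12)
  }
})

test_that("variant networks zero exactly the prescribed constants", {
  net <- fx_network()
  lir <- apply_variant(net, "LIR_V136S")
  expect_identical(unname(lir$params[c("r13_kon", "r20_kon")]), c(0, 0))
  same <- setdiff(names(net$params), c("r13_kon", "r20_kon"))
  expect_identical(lir$params[same], net$params[same])

  ubd <- apply_variant(net, "UBD_C443K")
  expect_identical(unname(ubd$params[["r12_kon"]]), 0)

  wt <- apply_variant(net, "WT")
  expect_identical(wt$params, net$params)

  expect_error(apply_variant(net, "NOT_A_VARIANT"), "unknown variant")
  expect_error(apply_variant(lir, "UBD_C443K"), "wild-type")
})

test_that("PI3K inhibition silences PtdIns(3)P production at any state", {
  pi3k <- apply_variant(fx_network(), "PI3K_INHIBITED")
  for (x in random_states(20, seed = 3)) {
    v <- reaction_rates(pi3k, x)
    expect_identical(unname(v[c("r14", "r15", "r16", "r17")]), rep(0, 4))
  }
})

test_that("network YAML round trip is lossless and stoichiometry exports", {
  net <- fx_network()
  path <- withr::local_tempfile(fileext = ".yaml")
  network_to_yaml(net, path)
  back <- network_from_yaml(path)
  expect_equal(back$params, net$params)
  expect_equal(back$initial, net$initial)
  expect_identical(back$variant, net$variant)
  expect_identical(back$stoichiometry, net$stoichiometry)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_stoichiometry_csv(net, csv)
  S <- read.csv(csv, check.names = FALSE)
  expect_identical(S$species, net$species)
  expect_equal(as.matrix(S[-1]), net$stoichiometry, ignore_attr = TRUE)
})
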