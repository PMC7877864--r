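test_that("built-in mechanisms map drugs to their published targets", {
  m <- builtin_mechanisms()
  expect_setequal(m$ustekinumab$targets, c("IL12", "IL23"))
  expect_equal(m$brazikumab$targets, "IL23")
  expect_equal(m$risankizumab$targets, "IL23")
  expect_equal(m$infliximab$targets, "TNFa")
  expect_equal(m$`PF-04236921`$targets, "IL6")
  expect_error(get_mechanism("adalimumab"), "unknown drug")
})

test_that("free fraction solves the binding quadratic", {
  # no drug and weak-binding limits
  expect_equal(free_fraction(5, 0, 0.1), 1)
  expect_equal(free_fraction(2, 50, Kd = 1e9 * 2), 1, tolerance = 1e-6)
  # grid-search oracle on the mass balance
  set.seed(31)
  for (i in 1:5) {
    Ttot <- runif(1, 0.2, 1)
    B <- runif(1, 0, 5)
    Kd <- runif(1, 0.05, 2)
    L <- Ttot * free_fraction(Ttot, B / 2, Kd, stoichiometry = 2)
    expect_lt(abs(L - grid_free_ligand(Ttot, B, Kd)), 1e-6)
  }
})

test_that("free fraction is monotone in drug and Kd, and mass balance holds", {
  set.seed(13)
  Ttot <- runif(1000, 0, 10)
  drug <- runif(1000, 0, 50)
  Kd <- runif(1000, 0.01, 10)
  ff <- free_fraction(Ttot, drug, Kd)
  # more drug never raises the free fraction
  ff_more <- free_fraction(Ttot, drug * 1.5, Kd)
  expect_true(all(ff_more <= ff + 1e-12))
  # weaker binding never lowers it
  ff_weak <- free_fraction(Ttot, drug, Kd * 1.5)
  expect_true(all(ff_weak >= ff - 1e-12))
  # free + bound = total
  L <- ff * Ttot
  bound <- 2 * drug * L / (Kd + L)
  ok <- Ttot > 1e-8
  expect_lt(max(abs(L + bound - Ttot)[ok] / Ttot[ok]), 1e-9)
})

test_that("apply_mechanisms suppresses exactly the dosed drugs' targets", {
  st <- nominal_state()
  expect_equal(unname(apply_mechanisms(list(), c(), st)), rep(1, 4))
  m <- builtin_mechanisms()
  ff <- apply_mechanisms(m["ustekinumab"], c(ustekinumab = 10), st)
  expect_lt(ff[["IL12"]], 1)
  expect_lt(ff[["IL23"]], 1)
  expect_equal(ff[["TNFa"]], 1)
  expect_equal(ff[["IL6"]], 1)
  ffc <- apply_mechanisms(m[c("infliximab", "ustekinumab")],
                          c(infliximab = 20, ustekinumab = 10), st)
  expect_true(all(ffc[c("TNFa", "IL12", "IL23")] < 1))
  expect_equal(ffc[["IL6"]], 1)
})

test_that("binding exposure accumulates regimens and rejects shared targets", {
  defs <- make_study_defaults()
  expo <- binding_exposure(list(defs$regimens$infliximab_5mgkg,
                                defs$regimens$ustekinumab_6mgkg), 84)
  expect_true(all(expo$B[, "TNFa"] >= 0))
  expect_gt(max(expo$B[, "IL12"]), 0)
  expect_equal(max(expo$B[, "IL6"]), 0)
  expect_error(
    binding_exposure(list(defs$regimens$ustekinumab_6mgkg,
                          defs$regimens$risankizumab_200mg), 84),
    "share target")
})

test_that("mechanism config files override Kd but keep defaults otherwise", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("infliximab:", "  targets: [TNFa]", "  Kd: 0.05"), path)
  tab <- mechanisms_from_config(path)
  expect_equal(tab$infliximab$Kd, 0.05)
  expect_equal(tab$ustekinumab$Kd, 0.1)
})
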