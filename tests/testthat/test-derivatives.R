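test_that("zero state with zero sources and floors is absorbing", {
  p <- nominal_parameters()
  p[grep("^(b|s)_", names(p))] <- 0
  st <- setNames(rep(0, 22), cd_species())
  d <- cd_derivatives(st, p)
  expect_equal(unname(d), rep(0, 22))
})

test_that("full TNFa neutralisation reduces activation to its TNFa-independent part", {
  p <- nominal_parameters()
  st <- nominal_state()
  d0 <- cd_derivatives(st, p, free_fraction = c(TNFa = 0))
  # expected activation fluxes with only the co-activator arms live
  H <- function(x, Km) x / (Km + x)
  a_dc <- p[["kact_DC"]] * p[["a_IL6_DC"]] * H(st[["IL6"]], p[["Km_IL6_DC"]]) * st[["iDC"]]
  a_m <- p[["kact_M"]] * p[["a_IFN_M"]] * H(st[["IFNg"]], p[["Km_IFN_M"]]) * st[["M0"]]
  a_n <- p[["kact_Neu"]] * p[["a_IL17_Neu"]] * H(st[["IL17"]], p[["Km_IL17_Neu"]]) * st[["Neu"]]
  expect_equal(d0[["eDC"]], a_dc - p[["kdeg_eDC"]] * st[["eDC"]], tolerance = 1e-12)
  expect_equal(d0[["M1"]], a_m - p[["kdeg_M1"]] * st[["M1"]], tolerance = 1e-12)
  expect_equal(d0[["Neu_a"]], a_n - p[["kdeg_Neua"]] * st[["Neu_a"]], tolerance = 1e-12)
})

test_that("rate vector matches a centred finite difference of the trajectory", {
  p <- nominal_parameters()
  set.seed(42)
  st <- nominal_state() * exp(rnorm(22, 0, 0.3))
  names(st) <- cd_species()
  h <- 1e-4
  tr <- cd_simulate(p, st, c(0, h, 2 * h))
  fd <- (unlist(tr[3, cd_species()]) - st) / (2 * h)
  d <- cd_derivatives(unlist(tr[2, cd_species()]), p)
  expect_equal(unname(fd), unname(d), tolerance = 1e-6)
})

test_that("rate laws agree with the independent oracle on 100 random states", {
  p <- nominal_parameters()
  base <- nominal_state()
  set.seed(101)
  for (i in 1:100) {
    st <- base * exp(rnorm(22, 0, 1))
    names(st) <- cd_species()
    ff <- c(TNFa = runif(1), IL6 = runif(1), IL12 = runif(1), IL23 = runif(1))
    expect_equal(unname(cd_derivatives(st, p, ff)),
                 unname(oracle_rates(st, p, ff)), tolerance = 1e-10)
  }
})

test_that("compiled and pure-R solver paths produce the same trajectory", {
  p <- nominal_parameters()
  set.seed(9)
  st <- nominal_state() * exp(rnorm(22, 0, 0.4))
  names(st) <- cd_species()
  ffconst <- c(TNFa = 0.3, IL6 = 0.8, IL12 = 1, IL23 = 0.5)
  trC <- cd_simulate(p, st, seq(0, 28, by = 7),
                     free_fraction = constant_ff_exposure(ffconst, 28))
  trR <- cd_simulate(p, st, seq(0, 28, by = 7),
                     free_fraction = function(t, y) ffconst)
  expect_equal(as.matrix(trC[cd_species()]), as.matrix(trR[cd_species()]),
               tolerance = 1e-6)
})

test_that("invalid states and free fractions are rejected", {
  p <- nominal_parameters()
  st <- nominal_state()
  bad <- st; bad["IL6"] <- -1
  expect_error(cd_derivatives(bad, p), "negative")
  expect_error(cd_derivatives(st, p, free_fraction = c(TNFa = 1.2)), "0, 1")
  expect_error(cd_derivatives(st, p, free_fraction = c(IL8 = 0.5)), "untargetable")
})

test_that("states stay non-negative from random starts under random parameters", {
  base_p <- nominal_parameters()
  vp <- variability_parameters()
  set.seed(77)
  for (i in 1:12) {
    p <- base_p
    p[vp] <- p[vp] * exp(runif(length(vp), -log(10), log(10)))
    st <- nominal_state() * exp(rnorm(22, 0, 1))
    names(st) <- cd_species()
    tr <- cd_simulate(p, st, seq(0, 120, by = 10))
    expect_true(all(as.matrix(tr[cd_species()]) >= 0))
  }
})
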