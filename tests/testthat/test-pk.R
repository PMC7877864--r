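test_that("mg/kg doses resolve against the standard 70 kg body weight", {
  reg <- regimen("ustekinumab",
                 data.frame(time = 0, route = "iv", amount_per_kg = 6))
  expect_equal(resolve_doses(reg)$events$amount, 420)
  reg5 <- regimen("infliximab",
                  data.frame(time = c(0, 14, 42), route = "iv", amount_per_kg = 5))
  expect_equal(resolve_doses(reg5)$events$amount, rep(350, 3))
  expect_error(regimen("x", data.frame(time = 0, route = "iv", amount_per_kg = 0)),
               "> 0")
  bad <- regimen("x", data.frame(time = 0, route = "iv", amount = 100))
  bad$body_weight <- -1
  expect_error(resolve_doses(bad), "body weight")
})

test_that("an IV bolus starts at dose over central volume and is zero before dosing", {
  pk <- builtin_pk_table()$infliximab
  reg <- regimen("infliximab", data.frame(time = 2, route = "iv", amount = 350))
  expect_equal(pk_concentration(pk, reg, 2), 350 / pk$V1)
  expect_equal(pk_concentration(pk, reg, c(0, 1, 1.99)), c(0, 0, 0))
})

test_that("closed-form profiles match numerical integration of the 2-compartment ODE", {
  for (case in list(
    list(pk = builtin_pk_table()$infliximab,
         reg = regimen("infliximab",
                       data.frame(time = c(0, 14, 42), route = "iv", amount = 350))),
    list(pk = builtin_pk_table()$`PF-04236921`,
         reg = regimen("PF-04236921",
                       data.frame(time = c(1, 28), route = "sc", amount = 200))))) {
    # grid avoids the dose instants, where the bolus discontinuity makes
    # the pre/post-event convention of the two methods differ
    t <- seq(0.25, 84, by = 0.5)
    cf <- pk_concentration(case$pk, case$reg, t)
    num <- pk_ode_conc(case$pk, case$reg, t)
    expect_lt(max(abs(cf - num) / pmax(num, 1e-8)), 1e-6)
  }
})

test_that("dose superposition is exactly linear", {
  pk <- builtin_pk_table()$brazikumab
  t <- seq(0, 120, by = 1)
  r1 <- regimen("brazikumab", data.frame(time = 0, route = "iv", amount = 700))
  r2 <- regimen("brazikumab", data.frame(time = 28, route = "sc", amount = 210))
  r12 <- regimen("brazikumab",
                 data.frame(time = c(0, 28), route = c("iv", "sc"),
                            amount = c(700, 210)))
  expect_equal(pk_concentration(pk, r12, t),
               pk_concentration(pk, r1, t) + pk_concentration(pk, r2, t),
               tolerance = 1e-12)
})

test_that("single-dose AUC equals F x Dose / CL", {
  for (route in c("iv", "sc")) {
    pk <- builtin_pk_table()$ustekinumab
    reg <- regimen("ustekinumab",
                   data.frame(time = 0, route = route, amount = 420))
    auc <- stats::integrate(function(t) pk_concentration(pk, reg, t),
                            0, Inf, rel.tol = 1e-10)$value
    f <- if (route == "iv") 1 else pk$F
    expect_equal(auc, f * 420 / pk$CL, tolerance = 1e-3)
  }
})

test_that("molar conversion is exact and invertible", {
  pk <- pk_parameters(CL = 0.2, V1 = 3.5, V2 = 3, Q = 0.4,
                      molecular_weight = 150000)
  expect_equal(to_molar(0, pk), 0)
  expect_equal(to_molar(15, pk), 100)
  x <- c(0.01, 1, 50)
  expect_equal(from_molar(to_molar(x, pk), pk), x, tolerance = 1e-12)
})

test_that("regimen CSV round-trips through read/write", {
  defs <- make_study_defaults()
  regs <- defs$regimens[c("infliximab_5mgkg", "PF-04236921_200mg")]
  names(regs) <- vapply(regs, function(r) r$drug, character(1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_regimens(regs, path)
  back <- read_regimens(path)
  expect_setequal(names(back), c("infliximab", "PF-04236921"))
  expect_equal(back$infliximab$events$time, c(0, 14, 42))
  expect_equal(resolve_doses(back$infliximab)$events$amount, rep(350, 3))
})
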