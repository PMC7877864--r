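test_that("the drug-free trajectory stays at the patient's steady state", {
  p <- nominal_parameters()
  st <- nominal_state()
  tr <- cd_simulate(p, st, seq(0, 84, by = 7))
  drift <- max(abs(t(as.matrix(tr[cd_species()])) - st) / pmax(st, 1e-6))
  expect_lt(drift, 1e-4)
})

test_that("complete IL-6 neutralisation drives CRP far below baseline", {
  p <- nominal_parameters()
  st <- nominal_state()
  tr <- cd_simulate(p, st, seq(0, 84, by = 7),
                    free_fraction = constant_ff_exposure(c(IL6 = 0), 84))
  expect_lt(tr$CRP[nrow(tr)], 0.5 * st[["CRP"]])
})

test_that("trajectory endpoint agrees with an independent nonlinear root-finder", {
  skip_if_not_installed("pracma")
  p <- nominal_parameters()
  p["kdeg_TNF"] <- p["kdeg_TNF"] * 0.4   # perturbed patient, nontrivial root
  end <- steady_state(p)
  f <- function(x) {
    y <- stats::setNames(pmax(as.numeric(x), 0), cd_species())
    unname(cd_derivatives(y, p))
  }
  root <- pracma::fsolve(f, unname(end) * 1.05, tol = 1e-12)$x
  expect_equal(unname(end), root, tolerance = 1e-5)
})

test_that("steady_state matches a long-horizon integration endpoint", {
  p <- nominal_parameters()
  p["p_IL6"] <- p["p_IL6"] * 2.5
  ss <- steady_state(p)
  tr <- cd_simulate(p, nominal_state(), c(0, 1500, 3000))
  expect_equal(unname(ss), unname(unlist(tr[3, cd_species()])),
               tolerance = 1e-5)
})

test_that("a sourceless, floorless system settles to the zero state", {
  p <- nominal_parameters()
  p[grep("^(b|s)_", names(p))] <- 0
  st <- setNames(rep(0.5, 22), cd_species())
  ss <- steady_state(p, init = st)
  expect_equal(max(ss), 0, tolerance = 1e-6)
})

test_that("steady-state CRP responds to the IL-6 production gain", {
  p <- nominal_parameters()
  ss1 <- steady_state(p)
  p2 <- p
  p2["p_IL6"] <- p2["p_IL6"] * 2
  ss2 <- steady_state(p2)
  expect_gt(ss2[["CRP"]], ss1[["CRP"]])
})

test_that("steady-state CRP is monotone in each drug target's free fraction", {
  base_p <- nominal_parameters()
  vp <- variability_parameters()
  set.seed(55)
  for (i in 1:50) {
    p <- base_p
    p[vp] <- p[vp] * exp(runif(length(vp), -log(4), log(4)))
    tgt <- sample(cd_targetable_cytokines(), 1)
    crp <- vapply(c(1, 0.3, 0), function(f) {
      ss_under_ff(p, setNames(f, tgt))[["CRP"]]
    }, numeric(1))
    expect_true(all(diff(crp) <= 1e-6),
                label = sprintf("set %d target %s: %s", i, tgt,
                                paste(signif(crp, 4), collapse = " >= ")))
  }
})

test_that("invalid grids and non-convergence are reported", {
  p <- nominal_parameters()
  st <- nominal_state()
  expect_error(cd_simulate(p, st, c(5, 1)), "sorted")
  slow <- solver_settings(ss_max_days = 1, ss_window = 1, ss_tol = 1e-14)
  expect_error(steady_state(p, settings = slow), class = "cdqsp_nonconvergence")
})
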