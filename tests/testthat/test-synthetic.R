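test_that("trial fixtures are reproducible from their seed and marked synthetic", {
  f1 <- make_trial_fixture(seed = 3)
  f2 <- make_trial_fixture(seed = 3)
  expect_identical(f1, f2)
  expect_identical(f1$provenance, "synthetic")
  f3 <- make_trial_fixture(seed = 4)
  expect_false(identical(f1$baseline, f3$baseline))
})

test_that("lognormal fixture medians agree with the stated law by direct sampling", {
  law <- default_baseline_law()
  set.seed(12)
  draws <- rlnorm(10000, law$CRP[["meanlog"]], law$CRP[["sdlog"]])
  # Monte Carlo error of the sample median at n = 10,000, gsd 2.5
  expect_lt(abs(median(draws) - exp(law$CRP[["meanlog"]])) /
              exp(law$CRP[["meanlog"]]), 0.05)
  fx <- make_trial_fixture(seed = 5, n_per_arm = 400)
  expect_lt(abs(fx$baseline$CRP$median - 10) / 10, 0.25)
  expect_lt(abs(fx$baseline$FCP$median - 600) / 600, 0.25)
})

test_that("fixtures can mirror heterogeneous trial reporting kinds", {
  fx <- make_trial_fixture(seed = 6,
                           stat_kind = c(CRP = "median_iqr", FCP = "mean_sd"))
  expect_equal(fx$baseline$CRP$kind, "median_iqr")
  expect_equal(fx$baseline$FCP$kind, "mean_sd")
  expect_gte(fx$baseline$FCP$sd, 0)
  expect_lte(fx$baseline$CRP$q1, fx$baseline$CRP$q3)
  # targets constructed from the fixture are consumable by the matcher
  tg <- fixture_targets(fx, tolerance = 0.2)
  expect_s3_class(tg, "baseline_targets")
  # longitudinal summaries carry the statistic their kind implies
  expect_setequal(unique(fx$longitudinal$statistic[fx$longitudinal$marker == "FCP"]),
                  "mean")
})

test_that("suppression profiles outside [0,1] are rejected", {
  expect_error(
    make_trial_fixture(effect_profile = list(bad = function(day) day / 10)),
    "0, 1")
})

test_that("the printed regimen library encodes the five induction schedules", {
  defs <- make_study_defaults()
  r <- defs$regimens
  expect_equal(resolve_doses(r$ustekinumab_6mgkg)$events$amount, 420)
  expect_equal(r$ustekinumab_130mg$events$amount, 130)
  expect_equal(r$risankizumab_200mg$events$time, c(0, 28, 56))
  expect_equal(r$`PF-04236921_200mg`$events$time, c(1, 28))
  expect_equal(r$`PF-04236921_200mg`$events$route, c("sc", "sc"))
  expect_equal(r$infliximab_5mgkg$events$time, c(0, 14, 42))
  expect_equal(r$infliximab_5mgkg_fcp$events$time, c(0, 56))
  braz <- r$brazikumab_700mg$events
  expect_equal(braz$time[braz$route == "iv"], c(0, 28))
  expect_true(all(braz$time[braz$route == "sc"] >= 84))
})

test_that("the criterion library holds exactly the four printed thresholds", {
  crits <- make_study_defaults()$criteria
  expect_length(crits, 4)
  thr <- vapply(crits, `[[`, numeric(1), "threshold")
  expect_setequal(unname(thr), c(60, 3, 5, 250))
  expect_equal(crits$crp_pct60$kind, "percent_decrease")
  expect_true(all(vapply(crits, `[[`, numeric(1), "day") == 42))
  expect_equal(crits$fcp_abs250$marker, "FCP")
})
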