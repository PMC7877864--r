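small_pop <- function(n = 40) cohort_subset(shared_cohort(), seq_len(n))

test_that("a placebo arm stays flat at baseline for every patient", {
  pop <- small_pop(20)
  spec <- trial_spec(horizon = 42, grid = seq(0, 42, by = 14))
  arm <- simulate_arm(pop, list(), spec)
  for (mk in c("CRP", "FCP", "IL6")) {
    s <- arm_summary(arm, mk, "percent_change")
    expect_lt(max(abs(s$median)), 0.05)
    expect_lt(max(abs(s$max)), 0.05)
  }
})

test_that("anti-IL-6 CRP suppression is ordered by dose", {
  pop <- small_pop(30)
  defs <- make_study_defaults()
  spec <- trial_spec()
  pc <- vapply(c("PF-04236921_10mg", "PF-04236921_50mg", "PF-04236921_200mg"),
               function(id) {
                 arm <- simulate_arm(pop, list(defs$regimens[[id]]), spec)
                 arm_summary(arm, "CRP", "percent_change")$median[13]
               }, numeric(1))
  expect_true(pc[3] <= pc[2] && pc[2] <= pc[1])  # more negative with dose
})

test_that("summary curves are recomputable from the per-patient series", {
  pop <- small_pop(25)
  defs <- make_study_defaults()
  spec <- trial_spec(horizon = 56, grid = seq(0, 56, by = 14))
  arm <- simulate_arm(pop, list(defs$regimens$infliximab_5mgkg), spec)
  s <- arm_summary(arm, "CRP", "absolute")
  manual <- apply(arm$series[, , "CRP"], 2, median)
  expect_equal(s$median, unname(manual))
  # and through the persisted long CSV
  path <- withr::local_tempfile(fileext = ".csv")
  write_arm_result(arm, path)
  long <- read.csv(path)
  crp42 <- long$value[long$marker == "CRP" & long$time_days == 42]
  expect_equal(median(crp42), s$median[s$time == 42])
})

test_that("responder classification follows the cutoff arithmetic", {
  # synthetic two-arm results with hand-computable outcomes
  mk_arm <- function(base, wk6) {
    series <- array(NA_real_, c(length(base), 2, 1),
                    dimnames = list(NULL, NULL, "CRP"))
    series[, 1, 1] <- base
    series[, 2, 1] <- wk6
    bl <- matrix(rep(nominal_state(), each = length(base)),
                 length(base), 22, dimnames = list(NULL, cd_species()))
    bl[, "CRP"] <- base
    structure(list(time = c(0, 42), markers = "CRP",
                   id = seq_along(base), series = series, baselines = bl,
                   failed = integer(0), drugs = "x"),
              class = "arm_result")
  }
  # patient 1: 10 -> 2.5 = 75% decrease (responder at >= 60%, and < 3)
  # patient 2: 10 -> 4.5 = 55% (non-responder); patient 3: 2 -> 1.9
  A <- mk_arm(c(10, 10, 2), c(2.5, 4.5, 1.9))
  B <- mk_arm(c(10, 10, 2), c(9, 3.9, 1.9))
  pct <- classify_responders(A, B, response_criterion("CRP", "percent_decrease", 60))
  expect_equal(unname(pct$counts), c(0, 1, 1, 1))  # both, A only, B only, neither
  expect_equal(pct$n_excluded, 0)
  abs3 <- classify_responders(A, B, response_criterion("CRP", "absolute_below", 3))
  expect_equal(abs3$n_excluded, 1)  # the baseline-2 patient is excluded
  expect_equal(abs3$n_included, 2)
  expect_equal(unname(abs3$counts), c(0, 1, 0, 1))
})

test_that("partition counts conserve the population over random outcomes", {
  set.seed(21)
  n <- 1000
  base <- rlnorm(n, log(8), 0.6)
  mk <- function(v) {
    series <- array(c(base, v), c(n, 2, 1), dimnames = list(NULL, NULL, "CRP"))
    bl <- matrix(rep(nominal_state(), each = n), n, 22,
                 dimnames = list(NULL, cd_species()))
    bl[, "CRP"] <- base
    structure(list(time = c(0, 42), markers = "CRP", id = seq_len(n),
                   series = series, baselines = bl, failed = integer(0),
                   drugs = "x"), class = "arm_result")
  }
  A <- mk(base * runif(n))
  B <- mk(base * runif(n))
  for (crit in list(response_criterion("CRP", "percent_decrease", 60),
                    response_criterion("CRP", "absolute_below", 3),
                    response_criterion("CRP", "absolute_below", 5))) {
    part <- classify_responders(A, B, crit)
    expect_equal(sum(part$counts), part$n_included)
    expect_equal(part$n_included + part$n_excluded, n)
    expect_equal(sum(part$fractions), 1, tolerance = 1e-9)
  }
})

test_that("percent criteria are scale-invariant; absolute criteria are not", {
  set.seed(33)
  n <- 400
  base <- rlnorm(n, log(8), 0.5)
  post <- base * runif(n)
  mk <- function(b, v) {
    series <- array(c(b, v), c(n, 2, 1), dimnames = list(NULL, NULL, "CRP"))
    bl <- matrix(rep(nominal_state(), each = n), n, 22,
                 dimnames = list(NULL, cd_species()))
    bl[, "CRP"] <- b
    structure(list(time = c(0, 42), markers = "CRP", id = seq_len(n),
                   series = series, baselines = bl, failed = integer(0),
                   drugs = "x"), class = "arm_result")
  }
  crit_pct <- response_criterion("CRP", "percent_decrease", 60)
  crit_abs <- response_criterion("CRP", "absolute_below", 3)
  p1 <- classify_responders(mk(base, post), mk(base, post), crit_pct)
  p2 <- classify_responders(mk(3 * base, 3 * post), mk(3 * base, 3 * post), crit_pct)
  expect_identical(p1$counts, p2$counts)
  a1 <- classify_responders(mk(base, post), mk(base, post), crit_abs)
  a2 <- classify_responders(mk(3 * base, 3 * post), mk(3 * base, 3 * post), crit_abs)
  expect_false(identical(a1$counts, a2$counts))
})

test_that("placebo correction subtracts rates", {
  expect_equal(placebo_corrected(30.4, 15.7), 14.7)
  expect_equal(placebo_corrected(42, 0), 42)
  expect_equal(placebo_corrected(30.9, 5.6), 25.3)
  expect_error(placebo_corrected(120, 10), "0, 100")
})

test_that("combination with an empty second regimen equals the monotherapy", {
  pop <- small_pop(10)
  defs <- make_study_defaults()
  spec <- trial_spec(horizon = 56, grid = seq(0, 56, by = 28))
  res <- simulate_combination(pop, defs$regimens$infliximab_5mgkg,
                              empty_regimen(), spec)
  expect_equal(res$AB$series, res$A$series, tolerance = 1e-10)
})

test_that("the combination dominates both monotherapies patient by patient", {
  pop <- small_pop(40)
  defs <- make_study_defaults()
  spec <- trial_spec(horizon = 56, grid = seq(0, 56, by = 14))
  res <- simulate_combination(pop, defs$regimens$infliximab_5mgkg,
                              defs$regimens$ustekinumab_6mgkg, spec)
  cA <- arm_values_at(res$A, "CRP", 56)
  cB <- arm_values_at(res$B, "CRP", 56)
  cAB <- arm_values_at(res$AB, "CRP", 56)
  expect_lte(median(cAB), min(median(cA), median(cB)))
  expect_gte(mean(cAB <= pmin(cA, cB) + 1e-9), 0.95)
})

test_that("arm simulation is deterministic", {
  pop <- small_pop(8)
  defs <- make_study_defaults()
  spec <- trial_spec(horizon = 42, grid = c(0, 42))
  a1 <- simulate_arm(pop, list(defs$regimens$ustekinumab_6mgkg), spec)
  a2 <- simulate_arm(pop, list(defs$regimens$ustekinumab_6mgkg), spec)
  expect_identical(a1$series, a2$series)
})
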