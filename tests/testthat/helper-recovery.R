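# Parameter-recovery machinery shared by the calibration and acceptance
# suites: a single-patient surrogate, absolute steady-state marker targets
# generated from a known parameter vector, and a seeded 3-fold perturbation
# to recover from.

recovery_params <- c("p_TNF", "p_IL6", "p_IL17", "p_CRP", "p_FCP")
recovery_markers <- c("CRP", "FCP", "IL6", "TNFa", "IL17")

recovery_targets <- function(truth) {
  ss <- steady_state(truth)
  calibration_targets(
    description = paste("baseline", recovery_markers),
    regimen_id = "placebo", marker = recovery_markers,
    statistic = "median", day = 42, transform = "absolute",
    value = unname(ss[recovery_markers]))
}
recovery_lib <- list(placebo = empty_regimen())

recovery_trial <- function(seed, maxit = 400) {
  truth <- nominal_parameters()
  set.seed(3000 + seed)
  pert <- exp(runif(length(recovery_params), -log(3), log(3)))
  start <- truth
  start[recovery_params] <- start[recovery_params] * pert
  fit <- calibrate(recovery_targets(truth), recovery_params, nominal = start,
                   regimen_library = recovery_lib, population_size = 1,
                   seed = 1, priors = NULL, n_starts = 0, maxit = maxit,
                   rederive = FALSE)
  max(abs(log(fit$params[recovery_params] / truth[recovery_params])))
}

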