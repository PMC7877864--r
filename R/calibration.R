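#' Calibration target table
#'
#' One row per observed quantity the nominal model is fitted to: which
#' regimen produces it, which marker/statistic/timepoint/transform extracts
#' it from an arm result, the observed value and a weight.
#'
#' @param description,regimen_id,marker,statistic,day,transform,value,weight
#'   Vectors (recycled) defining the targets; `statistic` is `median` or
#'   `mean`; `transform` is `absolute`, `change` or `percent_change`.
#' @return Data frame of class `calibration_targets`.
#' @export
calibration_targets <- function(description, regimen_id, marker, statistic,
                                day, transform, value, weight = 1) {
  df <- data.frame(description = description, regimen_id = regimen_id,
                   marker = marker, statistic = statistic, day = day,
                   transform = transform, value = value, weight = weight,
                   stringsAsFactors = FALSE)
  stopifnot(all(df$statistic %in% c("median", "mean")),
            all(df$transform %in% c("absolute", "change", "percent_change")),
            all(df$weight > 0))
  class(df) <- c("calibration_targets", "data.frame")
  df
}

#' Default calibration target set: anti-IL-6 CRP dose-response
#'
#' Week-12 median percent change in CRP for the three subcutaneous
#' PF-04236921 induction arms (10/50/200 mg on days 1 and 28), the
#' published pharmacodynamic readout of IL-6 suppression: -65.6, -86.3 and
#' -95 percent.
#'
#' @return A [calibration_targets()] table.
#' @export
default_calibration_targets <- function() {
  calibration_targets(
    description = c("anti-IL-6 10 mg week-12 median CRP % change",
                    "anti-IL-6 50 mg week-12 median CRP % change",
                    "anti-IL-6 200 mg week-12 median CRP % change"),
    regimen_id = c("PF-04236921_10mg", "PF-04236921_50mg", "PF-04236921_200mg"),
    marker = "CRP", statistic = "median", day = 84,
    transform = "percent_change",
    value = c(-65.6, -86.3, -95))
}

#' Read / write calibration target CSV files
#' @param path CSV path.
#' @return `read_calibration_targets`: a [calibration_targets()] table.
#' @export
read_calibration_targets <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  do.call(calibration_targets, df[c("description", "regimen_id", "marker",
                                    "statistic", "day", "transform",
                                    "value", "weight")])
}

#' @rdname read_calibration_targets
#' @param targets Target table to write.
#' @export
write_calibration_targets <- function(targets, path) {
  utils::write.csv(as.data.frame(targets), path, row.names = FALSE)
  invisible(path)
}

# Shared machinery: a frozen surrogate population (per-patient multipliers)
# plus precomputed binding exposures per regimen. Everything downstream of
# the candidate nominal parameters is deterministic.
calibration_setup <- function(targets, regimen_library, population_size,
                              seed, priors = default_priors(),
                              settings = solver_settings(),
                              mechanisms = builtin_mechanisms(),
                              pk_table = builtin_pk_table()) {
  stopifnot(nrow(targets) >= 1)
  missing <- setdiff(unique(targets$regimen_id), names(regimen_library))
  if (length(missing)) stop("regimen_library lacks: ", paste(missing, collapse = ", "))
  set.seed(as.integer(seed))
  if (is.null(priors)) {
    mult <- matrix(1, nrow = 1, ncol = 0)
    population_size <- 1L
  } else {
    k <- nrow(priors)
    mult <- matrix(exp(stats::runif(population_size * k,
                                    log(priors$lower), log(priors$upper))),
                   nrow = population_size, byrow = TRUE)
    colnames(mult) <- priors$parameter
  }
  horizon <- max(targets$day)
  grid <- sort(unique(c(0, targets$day)))
  expos <- lapply(regimen_library[unique(targets$regimen_id)], function(r) {
    regs <- if (inherits(r, "regimen")) list(r) else r
    binding_exposure(regs, horizon, mechanisms, pk_table)
  })
  list(targets = targets, mult = mult, grid = grid, expos = expos,
       settings = settings, seed = seed)
}

simulate_targets <- function(nominal, setup) {
  tg <- setup$targets
  n <- nrow(setup$mult)
  init <- nominal_state()
  sims <- list()
  ok <- rep(TRUE, n)
  base_mat <- matrix(NA_real_, n, length(cd_species()),
                     dimnames = list(NULL, cd_species()))
  for (i in seq_len(n)) {
    pp <- nominal
    if (ncol(setup$mult)) {
      vp <- colnames(setup$mult)
      pp[vp] <- pp[vp] * setup$mult[i, ]
    }
    ss <- tryCatch(steady_state(pp, init = init, settings = setup$settings),
                   error = function(e) NULL)
    if (is.null(ss)) { ok[i] <- FALSE; next }
    base_mat[i, ] <- ss
    for (rid in names(setup$expos)) {
      tr <- tryCatch(
        cd_simulate(pp, ss, setup$grid, free_fraction = setup$expos[[rid]],
                    settings = setup$settings),
        error = function(e) NULL)
      if (is.null(tr)) { ok[i] <- FALSE; next }
      sims[[rid]][[i]] <- tr
    }
  }
  if (!any(ok)) return(NULL)
  sim_value <- numeric(nrow(tg))
  for (j in seq_len(nrow(tg))) {
    rid <- tg$regimen_id[j]
    at <- which(setup$grid == tg$day[j])
    vals <- vapply(which(ok), function(i) {
      v <- sims[[rid]][[i]][[tg$marker[j]]][at]
      b <- base_mat[i, tg$marker[j]]
      switch(tg$transform[j],
             absolute = v, change = v - b,
             percent_change = 100 * (v - b) / b)
    }, numeric(1))
    sim_value[j] <- if (tg$statistic[j] == "median") stats::median(vals) else mean(vals)
  }
  list(sim = sim_value, n_ok = sum(ok))
}

target_residuals <- function(sim, targets) {
  mapply(function(s, o, tr) {
    if (tr == "absolute") {
      if (s <= 0 || o <= 0) (s - o) / abs(o) else log(s / o)
    } else {
      (s - o) / abs(o)
    }
  }, sim, targets$value, targets$transform)
}

#' Calibration loss for a candidate nominal parameter set
#'
#' Simulates every regimen the targets reference over a frozen seeded
#' surrogate population, extracts each target's statistic and returns the
#' weighted sum of squared relative residuals (log-scale for absolute
#' concentrations, linear for changes). Simulation failures are penalised.
#'
#' @param nominal Candidate nominal parameter vector.
#' @param targets A [calibration_targets()] table.
#' @param regimen_library Named list mapping `regimen_id` to a [regimen()]
#'   (or list of concurrent regimens).
#' @param population_size Surrogate population size.
#' @param seed Integer seed freezing the surrogate population.
#' @param priors Variability priors; `NULL` collapses the population to the
#'   single nominal patient.
#' @param setup Optional precomputed [calibration_setup()] (internal reuse).
#' @return Scalar loss.
#' @export
objective <- function(nominal, targets, regimen_library = make_study_defaults()$regimens,
                      population_size = 100, seed = 1,
                      priors = default_priors(), setup = NULL) {
  if (is.null(setup)) {
    setup <- calibration_setup(targets, regimen_library, population_size,
                               seed, priors)
  }
  res <- tryCatch(simulate_targets(validate_params(nominal), setup),
                  error = function(e) NULL)
  if (is.null(res)) return(1e6)
  r <- target_residuals(res$sim, setup$targets)
  sum(setup$targets$weight * r^2) +
    10 * (nrow(setup$mult) - res$n_ok) / nrow(setup$mult)
}

#' Fit nominal parameters to calibration targets
#'
#' Derivative-free strategy over log-multipliers of the chosen parameters:
#' an optional Latin-hypercube multistart within the bounds picks the best
#' starting point, then Nelder-Mead polishes it. The surrogate population
#' and all randomness are frozen by `seed`; re-simulating with the returned
#' parameters reproduces the stored residuals exactly.
#'
#' @param targets A [calibration_targets()] table.
#' @param param_names Parameters to fit (subset of [cd_param_names()]).
#' @param nominal Starting nominal vector.
#' @param regimen_library As in [objective()].
#' @param lower,upper Multiplier bounds around `nominal` (default 100-fold
#'   either way).
#' @param population_size,seed,priors As in [objective()].
#' @param n_starts Latin-hypercube starting points (0 = start from
#'   `nominal` only).
#' @param maxit Nelder-Mead iteration budget; 0 returns the starting
#'   parameters unchanged.
#' @param rederive Re-derive the production gains after every structural
#'   parameter move (see [rederive_gains()]) so the reference disease
#'   baseline stays anchored; multipliers on `p_*` gains themselves are
#'   re-applied afterwards.
#' @param baseline Baseline anchor used when `rederive` is TRUE.
#' @return List of class `fit_result`: `params` (fitted nominal),
#'   `multipliers`, `value`, `residuals` (per-target data frame),
#'   `trace`, `seed`.
#' @export
calibrate <- function(targets, param_names,
                      nominal = nominal_parameters(),
                      regimen_library = make_study_defaults()$regimens,
                      lower = 0.01, upper = 100,
                      population_size = 100, seed = 1,
                      priors = default_priors(),
                      n_starts = 8, maxit = 150, rederive = TRUE,
                      baseline = cd_reference_baseline()) {
  stopifnot(all(param_names %in% cd_param_names()), lower > 0, upper > lower)
  nominal <- validate_params(nominal)
  setup <- calibration_setup(targets, regimen_library, population_size,
                             seed, priors)
  gains <- grep("^p_", param_names, value = TRUE)
  apply_theta <- function(theta) {
    ## hard box: Nelder-Mead proposals outside the bounds are projected
    theta <- pmin(pmax(theta, log(lower)), log(upper))
    pp <- nominal
    pp[param_names] <- pp[param_names] * exp(theta)
    if (rederive) {
      pp <- rederive_gains(pp, baseline)
      pp[gains] <- pp[gains] * exp(theta[match(gains, param_names)])
    }
    validate_params(pp)
  }
  fn <- function(theta) objective(apply_theta(theta), targets, setup = setup)
  k <- length(param_names)
  f0 <- fn(rep(0, k))
  if (!is.finite(f0)) stop("objective is non-finite at the initial nominal")

  best_theta <- rep(0, k)
  best_val <- f0
  trace <- data.frame(stage = "init", value = f0)
  if (n_starts > 0) {
    set.seed(as.integer(seed) + 1L)
    lo <- log(lower); hi <- log(upper)
    grid <- lhs::randomLHS(n_starts, k) * (hi - lo) + lo
    for (s in seq_len(n_starts)) {
      v <- fn(grid[s, ])
      trace <- rbind(trace, data.frame(stage = "lhs", value = v))
      if (v < best_val) { best_val <- v; best_theta <- grid[s, ] }
    }
  }
  if (maxit > 0) {
    opt <- stats::optim(best_theta, fn, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-6))
    if (opt$value < best_val) { best_val <- opt$value; best_theta <- opt$par }
    trace <- rbind(trace, data.frame(stage = "nelder-mead", value = opt$value))
  }
  ## clamp into bounds (Nelder-Mead is unconstrained)
  best_theta <- pmin(pmax(best_theta, log(lower)), log(upper))
  fitted <- apply_theta(best_theta)
  sim <- simulate_targets(fitted, setup)
  resid <- data.frame(setup$targets,
                      simulated = sim$sim,
                      residual = target_residuals(sim$sim, setup$targets))
  structure(list(params = fitted,
                 multipliers = stats::setNames(exp(best_theta), param_names),
                 value = best_val, residuals = resid, trace = trace,
                 seed = seed, population_size = nrow(setup$mult)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Calibration fit: objective", signif(x$value, 4), "\n")
  cat("fitted multipliers:\n")
  print(signif(x$multipliers, 3))
  print(x$residuals[c("description", "value", "simulated")])
  invisible(x)
}

#' Persist a fit result (JSON + fitted-parameter CSV)
#'
#' @param fit A [calibrate()] result.
#' @param path JSON path; the fitted parameter vector is also written to
#'   `<path basename>_params.csv`.
#' @return The path, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  jsonlite::write_json(
    list(value = fit$value, multipliers = as.list(fit$multipliers),
         residuals = fit$residuals, seed = fit$seed,
         population_size = fit$population_size),
    path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(parameter = names(fit$params),
                              value = unname(fit$params)),
                   sub("\\.json$", "_params.csv", path), row.names = FALSE)
  invisible(path)
}
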