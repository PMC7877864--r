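#' Solver settings for the stiff network ODE
#'
#' @param rtol,atol Relative/absolute integration tolerances.
#' @param method deSolve integrator; `lsoda` switches automatically between
#'   stiff and non-stiff phases.
#' @param ss_tol Steady-state criterion: max over species of
#'   |dy/dt| / max(|y|, ss_floor) must fall below this (per day).
#' @param ss_floor Concentration floor used in the relative criterion.
#' @param ss_window Integration window (days) between steady-state checks.
#' @param ss_max_days Give up (non-convergence) after this many days.
#' @return List of solver settings.
#' @export
solver_settings <- function(rtol = 1e-8, atol = 1e-10, method = "lsoda",
                            ss_tol = 1e-7, ss_floor = 1e-6,
                            ss_window = 400, ss_max_days = 6000) {
  list(rtol = rtol, atol = atol, method = method, ss_tol = ss_tol,
       ss_floor = ss_floor, ss_window = ss_window, ss_max_days = ss_max_days)
}

# Assemble the parms vector for the compiled RHS: mechanistic parameters in
# canonical order + per-target Kd (nM) + molecular weights (g/mol).
c_parms <- function(params, Kd = NULL, mw = cd_cytokine_mw()) {
  tg <- cd_targetable_cytokines()
  kd <- rep(1, 4)
  names(kd) <- tg
  if (!is.null(Kd)) kd[names(Kd)] <- Kd
  mwv <- mw[tg]
  unname(c(params[cd_param_names()], kd[tg], mwv))
}

zero_exposure <- function(horizon) {
  tg <- cd_targetable_cytokines()
  B <- matrix(0, nrow = 2, ncol = 4, dimnames = list(NULL, tg))
  list(times = c(0, max(horizon, 1)), B = B,
       Kd = stats::setNames(rep(1, 4), tg))
}

#' Integrate the network ODE
#'
#' Two solver paths share one interface. With `free_fraction` `NULL` or an
#' [binding_exposure()] object, the compiled right-hand side is used (drug
#' action supplied as per-target binding-site forcing functions). With
#' `free_fraction` given as an R function `function(t, state)` returning a
#' named multiplier vector, the pure-R rate laws are integrated instead;
#' this path is slower and intended for small studies and cross-checks.
#'
#' @param params Named parameter vector over [cd_param_names()].
#' @param init Named non-negative initial state over [cd_species()].
#' @param times Sorted non-negative output time grid (days).
#' @param free_fraction `NULL` (no drug), a [binding_exposure()] object, or a
#'   function of `(t, state)`.
#' @param settings [solver_settings()].
#' @return Data frame: `time` plus one column per species; attribute
#'   `"free_fraction"` holds the per-target free-fraction time course when
#'   the compiled path is used.
#' @export
cd_simulate <- function(params, init, times, free_fraction = NULL,
                        settings = solver_settings()) {
  params <- validate_params(params)
  init <- validate_state(init, "init")
  if (is.unsorted(times) || any(times < 0)) {
    stop("times must be sorted and non-negative")
  }
  if (length(times) < 2) stop("need at least two output times")

  if (is.function(free_fraction)) {
    rhs <- function(t, y, parms) {
      ff <- free_fraction(t, y)
      list(unname(cd_derivatives(pmax(y, 0), parms, ff)))
    }
    out <- deSolve::ode(y = init, times = times, func = rhs, parms = params,
                        method = settings$method, maxsteps = 50000,
                        rtol = settings$rtol, atol = settings$atol)
  } else {
    expo <- if (is.null(free_fraction)) zero_exposure(max(times)) else free_fraction
    forc <- lapply(seq_len(4), function(j) cbind(expo$times, expo$B[, j]))
    out <- deSolve::ode(y = init, times = times,
                        func = "cd_derivs", initfunc = "cd_initmod",
                        initforc = "cd_initforc", forcings = forc,
                        dllname = "cdqsp",
                        parms = c_parms(params, expo$Kd),
                        nout = 4, outnames = paste0("ff_", cd_targetable_cytokines()),
                        method = settings$method, maxsteps = 50000,
                        rtol = settings$rtol, atol = settings$atol)
  }
  if (attr(out, "istate")[1] < 0) {
    stop(sprintf("integration failed near t = %.3f days", max(out[, "time"])))
  }
  res <- as.data.frame(out)
  sp <- cd_species()
  spmat <- as.matrix(res[sp])
  too_neg <- spmat < -1e-6
  if (any(too_neg)) {
    stop("integration produced substantially negative concentrations")
  }
  res[sp] <- pmax(spmat, 0)
  ffcols <- grep("^ff_", names(res), value = TRUE)
  ffattr <- if (length(ffcols)) res[c("time", ffcols)] else NULL
  res <- res[c("time", sp)]
  attr(res, "free_fraction") <- ffattr
  res
}

#' Drug-free steady state of a parameter set
#'
#' Integrates the undrugged system in windows until the relative rate
#' criterion in [solver_settings()] is met. Non-convergence within
#' `ss_max_days` raises a condition of class `cdqsp_nonconvergence`
#' (virtual-patient generation treats such draws as implausible and rejects
#' them).
#'
#' @param params Named parameter vector.
#' @param init Optional starting state; defaults to the analytic nominal
#'   fixed point, which is a good basin guess for perturbed parameters.
#' @param settings [solver_settings()].
#' @return Named state vector at steady state.
#' @export
steady_state <- function(params, init = NULL, settings = solver_settings()) {
  params <- validate_params(params)
  if (is.null(init)) init <- nominal_state()
  y <- validate_state(init, "init")
  elapsed <- 0
  repeat {
    traj <- cd_simulate(params, y, c(0, settings$ss_window / 2, settings$ss_window),
                        settings = settings)
    y <- unlist(traj[nrow(traj), cd_species()])
    elapsed <- elapsed + settings$ss_window
    dy <- cd_derivatives(y, params)
    rel <- max(abs(dy) / pmax(abs(y), settings$ss_floor))
    if (rel < settings$ss_tol) break
    if (elapsed >= settings$ss_max_days) {
      cond <- structure(
        class = c("cdqsp_nonconvergence", "error", "condition"),
        list(message = sprintf(
          "no steady state within %d days (residual %.3g)", elapsed, rel),
          call = sys.call(-1)))
      stop(cond)
    }
  }
  y
}
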