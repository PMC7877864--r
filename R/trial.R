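#' Trial simulation specification
#'
#' @param horizon Simulation horizon (days); must cover the last dose.
#' @param grid Output time grid (days) within the horizon; must contain any
#'   responder assessment day.
#' @param markers Biomarkers to retain per patient.
#' @return List of class `trial_spec`.
#' @export
trial_spec <- function(horizon = 84, grid = seq(0, 84, by = 7),
                       markers = c("CRP", "FCP", "IL6", "IL8", "IL17",
                                   "IL22", "TNFa", "Treg")) {
  if (is.unsorted(grid) || any(grid < 0) || max(grid) > horizon) {
    stop("grid must be sorted and lie within [0, horizon]")
  }
  stopifnot(all(markers %in% cd_species()))
  structure(list(horizon = horizon, grid = grid, markers = markers),
            class = "trial_spec")
}

#' Simulate one dosing arm over a virtual population
#'
#' Every patient shares the arm's drug concentration-time profile (computed
#' once from the closed-form PK and converted to binding-site forcings);
#' between-patient differences come only from the mechanistic parameter
#' vector. Patients whose integration fails are flagged and skipped; more
#' than 5\% failures aborts the arm.
#'
#' @param population A cohort (see [generate_cohort()]).
#' @param regimens List of [regimen()] dosed concurrently (empty list or
#'   empty regimens = placebo: no drug, patients stay at baseline).
#' @param spec A [trial_spec()].
#' @param mechanisms,pk_table Mechanism/PK tables.
#' @param settings [solver_settings()].
#' @return List of class `arm_result`: `time`, `markers`, `id`, `series`
#'   (array patients x times x markers), `baselines`, `failed` (ids).
#' @export
simulate_arm <- function(population, regimens, spec = trial_spec(),
                         mechanisms = builtin_mechanisms(),
                         pk_table = builtin_pk_table(),
                         settings = solver_settings()) {
  stopifnot(inherits(population, "cohort"), inherits(spec, "trial_spec"))
  if (length(population$id) == 0) stop("population is empty")
  if (inherits(regimens, "regimen")) regimens <- list(regimens)
  regimens <- lapply(regimens, resolve_doses)
  last_dose <- max(c(0, unlist(lapply(regimens, function(r) r$events$time))))
  if (spec$horizon < last_dose) stop("horizon must cover the last dose")
  expo <- binding_exposure(regimens, spec$horizon, mechanisms, pk_table)
  grid <- spec$grid
  if (grid[1] != 0) grid <- c(0, grid)
  n <- length(population$id)
  series <- array(NA_real_, dim = c(n, length(spec$grid), length(spec$markers)),
                  dimnames = list(NULL, NULL, spec$markers))
  failed <- logical(n)
  keep <- match(spec$grid, grid)
  for (i in seq_len(n)) {
    pp <- cohort_params(population, i)
    init <- population$baselines[i, ]
    tr <- tryCatch(
      cd_simulate(pp, init, grid, free_fraction = expo, settings = settings),
      error = function(e) NULL)
    if (is.null(tr)) {
      failed[i] <- TRUE
    } else {
      series[i, , ] <- as.matrix(tr[keep, spec$markers])
    }
  }
  if (mean(failed) > 0.05) {
    stop(sprintf("%d of %d patient integrations failed", sum(failed), n))
  }
  structure(list(time = spec$grid, markers = spec$markers,
                 id = population$id, series = series,
                 baselines = population$baselines,
                 failed = population$id[failed],
                 drugs = vapply(regimens, function(r) r$drug, character(1))),
            class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat("Arm result:", length(x$id), "patients,",
      if (length(x$drugs)) paste(x$drugs, collapse = " + ") else "placebo",
      "|", length(x$time), "timepoints\n")
  invisible(x)
}

marker_matrix <- function(arm, marker) {
  if (!marker %in% arm$markers) stop("marker not retained in arm: ", marker)
  m <- arm$series[, , marker, drop = FALSE]
  dim(m) <- dim(arm$series)[1:2]
  ok <- !arm$id %in% arm$failed
  m[ok, , drop = FALSE]
}

#' Summary curves of an arm
#'
#' @param arm An [simulate_arm()] result.
#' @param marker Marker name.
#' @param transform `"absolute"`, `"change"` (from baseline) or
#'   `"percent_change"` (100 x (value - baseline) / baseline).
#' @return Data frame: `time`, `median`, `q1`, `q3`, `mean`, `sd`, `min`,
#'   `max`, `n`.
#' @export
arm_summary <- function(arm, marker, transform = c("absolute", "change",
                                                   "percent_change")) {
  transform <- match.arg(transform)
  m <- marker_matrix(arm, marker)
  base <- m[, 1]
  m <- switch(transform,
              absolute = m,
              change = m - base,
              percent_change = 100 * (m - base) / base)
  data.frame(
    time = arm$time,
    median = apply(m, 2, stats::median),
    q1 = apply(m, 2, stats::quantile, 0.25),
    q3 = apply(m, 2, stats::quantile, 0.75),
    mean = colMeans(m),
    sd = apply(m, 2, stats::sd),
    min = apply(m, 2, min),
    max = apply(m, 2, max),
    n = nrow(m))
}

#' Extract per-patient marker values at one timepoint
#' @param arm An arm result.
#' @param marker Marker name.
#' @param day Assessment day; must match a grid point (nearest within 0.5
#'   days is used).
#' @return Numeric vector (non-failed patients, cohort order).
#' @export
arm_values_at <- function(arm, marker, day) {
  j <- which.min(abs(arm$time - day))
  if (abs(arm$time[j] - day) > 0.5) {
    stop("assessment day ", day, " not on the output grid")
  }
  marker_matrix(arm, marker)[, j]
}

#' Biomarker response criterion
#'
#' Two kinds of surrogate-response definitions: a percent decrease from
#' baseline of at least `threshold` percent, or an absolute value strictly
#' below `threshold` at the assessment day. Absolute criteria exclude
#' patients already below the cutoff at baseline.
#'
#' @param marker `"CRP"` or `"FCP"`.
#' @param kind `"percent_decrease"` or `"absolute_below"`.
#' @param threshold Positive threshold: percent for `percent_decrease`,
#'   marker units for `absolute_below`.
#' @param day Assessment day (default week 6 = day 42).
#' @return List of class `response_criterion`.
#' @export
response_criterion <- function(marker = "CRP",
                               kind = c("percent_decrease", "absolute_below"),
                               threshold = 60, day = 42) {
  kind <- match.arg(kind)
  stopifnot(marker %in% c("CRP", "FCP"), threshold > 0, day >= 0)
  structure(list(marker = marker, kind = kind, threshold = threshold,
                 day = day),
            class = "response_criterion")
}

criterion_eval <- function(values, baselines, criterion) {
  if (criterion$kind == "percent_decrease") {
    list(responder = 100 * (baselines - values) / baselines >= criterion$threshold,
         included = rep(TRUE, length(values)))
  } else {
    list(responder = values < criterion$threshold,
         included = baselines >= criterion$threshold)
  }
}

#' Partition a population by response to two treatments
#'
#' Patients excluded at baseline (absolute criteria only) are removed
#' before counting; the four classes partition the included patients.
#'
#' @param results_A,results_B [simulate_arm()] results over the same
#'   population.
#' @param criterion A [response_criterion()].
#' @return List of class `responder_partition`: `counts`, `fractions`
#'   (both/only_A/only_B/neither), `n_included`, `n_excluded`, `labels`
#'   (per included patient), `included_ids`, `criterion`.
#' @export
classify_responders <- function(results_A, results_B, criterion) {
  stopifnot(inherits(criterion, "response_criterion"))
  if (!identical(results_A$id, results_B$id)) {
    stop("the two arms cover different populations")
  }
  ok <- !(results_A$id %in% c(results_A$failed, results_B$failed))
  base <- results_A$baselines[ok, criterion$marker]
  vA <- arm_values_at(results_A, criterion$marker, criterion$day)
  vB <- arm_values_at(results_B, criterion$marker, criterion$day)
  eA <- criterion_eval(vA, base, criterion)
  eB <- criterion_eval(vB, base, criterion)
  inc <- eA$included  # exclusion depends on baseline only, same both arms
  rA <- eA$responder[inc]
  rB <- eB$responder[inc]
  labels <- ifelse(rA & rB, "both",
                   ifelse(rA, "only_A", ifelse(rB, "only_B", "neither")))
  counts <- c(both = sum(rA & rB), only_A = sum(rA & !rB),
              only_B = sum(!rA & rB), neither = sum(!rA & !rB))
  structure(list(counts = counts, fractions = counts / sum(counts),
                 n_included = sum(inc), n_excluded = sum(!inc),
                 labels = labels,
                 included_ids = results_A$id[ok][inc],
                 criterion = criterion),
            class = "responder_partition")
}

#' @export
print.responder_partition <- function(x, ...) {
  cat(sprintf("Responder partition (%s %s %s at day %g): ",
              x$criterion$marker, x$criterion$kind, x$criterion$threshold,
              x$criterion$day))
  cat(sprintf("%s %.1f%%", names(x$fractions), 100 * x$fractions),
      sep = ", ")
  cat(sprintf("\n(%d included, %d excluded at baseline)\n",
              x$n_included, x$n_excluded))
  invisible(x)
}

#' Single-arm responder rate
#'
#' @param arm An arm result.
#' @param criterion A [response_criterion()].
#' @return Percent of included patients responding.
#' @export
responder_rate <- function(arm, criterion) {
  ok <- !(arm$id %in% arm$failed)
  base <- arm$baselines[ok, criterion$marker]
  v <- arm_values_at(arm, criterion$marker, criterion$day)
  e <- criterion_eval(v, base, criterion)
  100 * mean(e$responder[e$included])
}

#' Placebo-corrected response rate
#'
#' @param observed_rate,placebo_rate Rates in percent, within [0, 100].
#' @return Difference (percentage points).
#' @export
placebo_corrected <- function(observed_rate, placebo_rate) {
  if (any(c(observed_rate, placebo_rate) < 0) ||
      any(c(observed_rate, placebo_rate) > 100)) {
    stop("rates must lie in [0, 100]")
  }
  observed_rate - placebo_rate
}

#' Simulate two monotherapies and their combination on one population
#'
#' @param population A cohort.
#' @param regimen_A,regimen_B [regimen()] for the two drugs.
#' @param spec A [trial_spec()].
#' @param ... Passed to [simulate_arm()].
#' @return Named list of three `arm_result`s: `A`, `B`, `AB`.
#' @export
simulate_combination <- function(population, regimen_A, regimen_B,
                                 spec = trial_spec(), ...) {
  list(A = simulate_arm(population, list(regimen_A), spec, ...),
       B = simulate_arm(population, list(regimen_B), spec, ...),
       AB = simulate_arm(population, list(regimen_A, regimen_B), spec, ...))
}

#' Persist an arm result as tidy long CSV (+ summary CSV)
#'
#' @param arm An arm result.
#' @param path Per-patient long CSV path (`patient_id, time_days, marker,
#'   value`); summaries written to `<path basename>_summary.csv` with one
#'   row per marker x timepoint.
#' @return The path, invisibly.
#' @export
write_arm_result <- function(arm, path) {
  long <- expand.grid(patient_id = arm$id, time_days = arm$time,
                      marker = arm$markers, stringsAsFactors = FALSE)
  long$value <- as.vector(arm$series)
  long <- long[!long$patient_id %in% arm$failed, ]
  utils::write.csv(long, path, row.names = FALSE)
  summ <- do.call(rbind, lapply(arm$markers, function(m) {
    s <- arm_summary(arm, m)
    s$marker <- m
    s
  }))
  utils::write.csv(summ, sub("\\.csv$", "_summary.csv", path),
                   row.names = FALSE)
  invisible(path)
}
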