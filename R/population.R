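#' Parameters carrying inter-subject variability
#'
#' The designated variability subset: per-subject multipliers are sampled
#' for these parameters only, the rest of the parameter vector being shared
#' across the population. The subset is production gains, cell sources and
#' turnover rates — quantities that genuinely differ between subjects —
#' plus the TNFa-on-IL-6 half-maximum constant, which the responder
#' analysis examines; the remaining half-maximum constants and basal floors
#' are treated as conserved molecular properties. The subset spans the
#' TNFa axis, the IL-6/CRP axis, the neutrophil/IL-8/FCP axis and the
#' Th17/IL-23 axis, which together drive the between-patient spread in
#' baseline CRP/FCP and in treatment response.
#'
#' @return Character vector of parameter names.
#' @export
variability_parameters <- function() {
  c("kdeg_TNF", "Km_TNF_IL6", "p_TNF",
    "p_IL6", "kdeg_IL6", "p_CRP", "kdeg_CRP",
    "p_FCP", "kdeg_FCP", "p_IL8",
    "s_Neu", "kact_Neu", "kact_M", "p_IL17", "p_IL23")
}

#' Default log-uniform sampling priors
#'
#' Each varied parameter gets an independent log-uniform multiplier on
#' \code{[1/fold, fold]} around its nominal value.
#'
#' @param fold Fold-range half-width (default 10).
#' @param parameters Which parameters vary; default
#'   [variability_parameters()].
#' @return Data frame: `parameter`, `lower`, `upper` (multipliers).
#' @export
default_priors <- function(fold = 10, parameters = variability_parameters()) {
  stopifnot(fold > 1, all(parameters %in% cd_param_names()))
  data.frame(parameter = parameters, lower = 1 / fold, upper = fold,
             stringsAsFactors = FALSE)
}

#' Plausibility window applied to candidate steady states
#'
#' @return Named list of c(min, max) windows.
#' @export
plausibility_window <- function() {
  list(CRP = c(0.1, 200), FCP = c(10, 5000), cytokine_max = 1e4)
}

is_plausible <- function(baseline, window = plausibility_window()) {
  baseline[["CRP"]] >= window$CRP[1] && baseline[["CRP"]] <= window$CRP[2] &&
    baseline[["FCP"]] >= window$FCP[1] && baseline[["FCP"]] <= window$FCP[2] &&
    all(baseline[cd_cytokine_species()] < window$cytokine_max)
}

#' Generate a plausible virtual-patient cohort
#'
#' Draws per-patient multipliers from `priors`, computes each candidate's
#' drug-free steady state, and retains patients that converge and whose
#' baseline lies inside [plausibility_window()]. Rejected draws are counted
#' in the provenance record. Deterministic given `seed`.
#'
#' @param n Number of retained patients (the full plausible-patient
#'   database of the study design is 40,000; smaller cohorts are used for
#'   desk-scale work).
#' @param priors [default_priors()]-shaped data frame.
#' @param seed Integer RNG seed.
#' @param nominal Nominal parameter vector the multipliers perturb.
#' @param settings [solver_settings()].
#' @param probe Size of the initial acceptance-rate probe batch.
#' @return List of class `cohort`: `id`, `multipliers` (n x k matrix),
#'   `baselines` (n x 22 matrix), `nominal`, `priors`, `seed`, `provenance`.
#' @export
generate_cohort <- function(n = 40000, priors = default_priors(), seed = 1,
                            nominal = nominal_parameters(),
                            settings = solver_settings(), probe = 50) {
  stopifnot(n >= 1)
  nominal <- validate_params(nominal)
  if (any(priors$lower <= 0) || any(priors$upper <= priors$lower)) {
    stop("priors must satisfy 0 < lower < upper")
  }
  set.seed(as.integer(seed))
  k <- nrow(priors)
  init <- nominal_state()
  sp <- cd_species()

  draw_batch <- function(m) {
    mult <- matrix(exp(stats::runif(m * k, log(priors$lower), log(priors$upper))),
                   nrow = m, byrow = TRUE)
    colnames(mult) <- priors$parameter
    mult
  }
  eval_patient <- function(mult_row) {
    pp <- nominal
    pp[colnames(mult_row)] <- pp[colnames(mult_row)] * as.numeric(mult_row)
    ss <- tryCatch(steady_state(pp, init = init, settings = settings),
                   cdqsp_nonconvergence = function(e) NULL,
                   error = function(e) NULL)
    if (is.null(ss) || !is_plausible(ss)) return(NULL)
    ss
  }

  kept_mult <- matrix(numeric(0), ncol = k, dimnames = list(NULL, priors$parameter))
  kept_base <- matrix(numeric(0), ncol = length(sp), dimnames = list(NULL, sp))
  tried <- 0L
  first_batch <- TRUE
  while (nrow(kept_mult) < n) {
    m <- if (first_batch) max(probe, min(n, 200)) else
      max(50, ceiling((n - nrow(kept_mult)) * 1.3))
    mult <- draw_batch(m)
    for (i in seq_len(m)) {
      if (nrow(kept_mult) >= n) break
      tried <- tried + 1L
      ss <- eval_patient(mult[i, , drop = FALSE])
      if (!is.null(ss)) {
        kept_mult <- rbind(kept_mult, mult[i, , drop = FALSE])
        kept_base <- rbind(kept_base, ss)
      }
    }
    if (first_batch) {
      rate <- nrow(kept_mult) / tried
      if (rate < 0.01) {
        stop("prior misspecification: acceptance rate ",
             sprintf("%.2f%%", 100 * rate), " in probe batch")
      }
      first_batch <- FALSE
    }
  }
  rownames(kept_mult) <- rownames(kept_base) <- NULL
  structure(list(
    id = seq_len(n),
    multipliers = kept_mult[seq_len(n), , drop = FALSE],
    baselines = kept_base[seq_len(n), , drop = FALSE],
    nominal = nominal, priors = priors, seed = as.integer(seed),
    provenance = list(tried = tried, rejected = tried - n,
                      generated = format(Sys.time(), "%Y-%m-%d"),
                      note = "synthetic virtual patients")),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Virtual cohort:", length(x$id), "patients,",
      ncol(x$multipliers), "varied parameters (seed", x$seed, ")\n")
  cat("baseline CRP median", signif(stats::median(x$baselines[, "CRP"]), 3),
      "mg/L; FCP median", signif(stats::median(x$baselines[, "FCP"]), 3), "mg/kg\n")
  invisible(x)
}

#' Full parameter vector of one cohort member
#'
#' @param cohort A [generate_cohort()] object.
#' @param i Patient index (position in the cohort, not id).
#' @return Named parameter vector.
#' @export
cohort_params <- function(cohort, i) {
  pp <- cohort$nominal
  vp <- colnames(cohort$multipliers)
  pp[vp] <- pp[vp] * cohort$multipliers[i, ]
  pp
}

#' Subset a cohort by position
#' @param cohort A cohort.
#' @param idx Integer positions to keep.
#' @return A cohort containing the selected patients (ids preserved).
#' @export
cohort_subset <- function(cohort, idx) {
  out <- cohort
  out$id <- cohort$id[idx]
  out$multipliers <- cohort$multipliers[idx, , drop = FALSE]
  out$baselines <- cohort$baselines[idx, , drop = FALSE]
  out
}

#' Baseline summary-statistic targets for trial matching
#'
#' Clinical trials report baseline CRP/FCP with heterogeneous statistics;
#' each marker's target states its kind and values, mirroring that
#' reporting.
#'
#' @param CRP,FCP Lists: `list(kind = "median_iqr", median=, q1=, q3=)`,
#'   `list(kind = "mean_sd", mean=, sd=)`, or
#'   `list(kind = "median_range", median=, min=, max=)`.
#' @param tolerance Relative matching tolerance in (0, 0.5].
#' @return List of class `baseline_targets`.
#' @export
baseline_targets <- function(CRP, FCP, tolerance = 0.1) {
  check <- function(t, marker) {
    kinds <- c("median_iqr", "mean_sd", "median_range")
    if (!t$kind %in% kinds) stop(marker, ": unknown statistic kind ", t$kind)
    vals <- unlist(t[setdiff(names(t), "kind")])
    if (any(vals <= 0)) stop(marker, ": target values must be positive")
    t
  }
  if (tolerance <= 0 || tolerance > 0.5) stop("tolerance must lie in (0, 0.5]")
  structure(list(CRP = check(CRP, "CRP"), FCP = check(FCP, "FCP"),
                 tolerance = tolerance),
            class = "baseline_targets")
}

# log-normal approximation of a target for importance weighting
target_log_law <- function(t) {
  if (t$kind == "median_iqr") {
    list(meanlog = log(t$median),
         sdlog = (log(t$q3) - log(t$q1)) / (2 * stats::qnorm(0.75)))
  } else if (t$kind == "mean_sd") {
    s2 <- log(1 + (t$sd / t$mean)^2)
    list(meanlog = log(t$mean) - s2 / 2, sdlog = sqrt(s2))
  } else {
    list(meanlog = log(t$median),
         sdlog = (log(t$max) - log(t$min)) / (2 * stats::qnorm(0.995)))
  }
}

# evaluate a statistic of the target's kind on a sample
achieved_stat <- function(x, t) {
  if (t$kind == "median_iqr") {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    c(q1 = q[1], median = q[2], q3 = q[3])
  } else if (t$kind == "mean_sd") {
    c(mean = mean(x), sd = stats::sd(x))
  } else {
    c(median = stats::median(x), min = min(x), max = max(x))
  }
}

stat_mismatch <- function(achieved, t) {
  tv <- unlist(t[setdiff(names(t), "kind")])
  cmp <- intersect(names(tv), names(achieved))
  if (t$kind == "median_range") cmp <- "median"  # sample extremes are noise
  max(abs(achieved[cmp] - tv[cmp]) / tv[cmp])
}

#' Select a trial-matched virtual population
#'
#' Importance-weighted sampling without replacement toward the target's
#' log-normal marginals in baseline CRP and FCP, followed by accept/reject
#' on the achieved joint statistic (recomputed on the candidate
#' subpopulation in the target's own statistic kind). The CRP-FCP
#' correlation is left as the mechanism induces it. Deterministic given
#' `seed`.
#'
#' @param cohort Source cohort (must be larger than `n_out`).
#' @param targets A [baseline_targets()].
#' @param n_out Patients to select.
#' @param seed Integer seed.
#' @param max_iter Resampling attempts before giving up.
#' @return A cohort of `n_out` patients (ids preserved from the source);
#'   attribute `"achieved"` records the achieved statistics.
#' @export
select_trial_population <- function(cohort, targets, n_out, seed = 1,
                                    max_iter = 60) {
  stopifnot(inherits(cohort, "cohort"), inherits(targets, "baseline_targets"))
  if (length(cohort$id) <= n_out) stop("cohort must be larger than n_out")
  set.seed(as.integer(seed))
  lc <- log(cohort$baselines[, "CRP"])
  lf <- log(cohort$baselines[, "FCP"])
  lawC <- target_log_law(targets$CRP)
  lawF <- target_log_law(targets$FCP)
  ## importance weights: target density over kernel-smoothed source density
  ## (per-marker product approximation)
  src_dens <- function(x) {
    d <- stats::density(x, n = 512)
    pmax(stats::approx(d$x, d$y, xout = x, rule = 2)$y, 1e-12)
  }
  w <- stats::dnorm(lc, lawC$meanlog, lawC$sdlog) *
    stats::dnorm(lf, lawF$meanlog, lawF$sdlog) /
    (src_dens(lc) * src_dens(lf))
  if (targets$CRP$kind == "median_range") {
    w[cohort$baselines[, "CRP"] < targets$CRP$min * (1 - targets$tolerance) |
        cohort$baselines[, "CRP"] > targets$CRP$max * (1 + targets$tolerance)] <- 0
  }
  if (targets$FCP$kind == "median_range") {
    w[cohort$baselines[, "FCP"] < targets$FCP$min * (1 - targets$tolerance) |
        cohort$baselines[, "FCP"] > targets$FCP$max * (1 + targets$tolerance)] <- 0
  }
  if (sum(w > 0) < n_out) stop("too few cohort members carry selection weight")

  joint_err <- function(idx) {
    max(stat_mismatch(achieved_stat(cohort$baselines[idx, "CRP"], targets$CRP),
                      targets$CRP),
        stat_mismatch(achieved_stat(cohort$baselines[idx, "FCP"], targets$FCP),
                      targets$FCP))
  }
  best <- NULL
  best_err <- Inf
  for (it in seq_len(max_iter)) {
    idx <- sample(seq_along(w), n_out, replace = FALSE, prob = w)
    err <- joint_err(idx)
    if (err < best_err) {
      best_err <- err
      best <- idx
    }
    if (err <= targets$tolerance) break
  }
  ## greedy swap refinement: exchange members against weighted outsiders
  ## while that reduces the joint mismatch
  if (best_err > targets$tolerance) {
    for (sw in seq_len(40L * n_out)) {
      if (best_err <= targets$tolerance) break
      cand <- best
      cand[sample.int(n_out, 1)] <-
        sample(seq_along(w), 1, prob = w * !(seq_along(w) %in% best))
      err <- joint_err(cand)
      if (err < best_err) {
        best_err <- err
        best <- cand
      }
    }
  }
  if (best_err > targets$tolerance) {
    stop(sprintf(
      paste0("no subpopulation matched within tolerance %.2f after %d ",
             "attempts; best mismatch %.3f (CRP achieved: %s; FCP achieved: %s)"),
      targets$tolerance, max_iter, best_err,
      paste(signif(achieved_stat(cohort$baselines[best, "CRP"], targets$CRP), 3),
            collapse = "/"),
      paste(signif(achieved_stat(cohort$baselines[best, "FCP"], targets$FCP), 3),
            collapse = "/")))
  }
  out <- cohort_subset(cohort, best)
  attr(out, "achieved") <- list(
    CRP = achieved_stat(out$baselines[, "CRP"], targets$CRP),
    FCP = achieved_stat(out$baselines[, "FCP"], targets$FCP),
    mismatch = best_err, iterations = it)
  out
}

#' Per-group baseline summaries
#'
#' Median and IQR of every baseline species and every varied parameter,
#' split by a per-patient grouping label (e.g. responder partition class).
#' Empty groups are flagged with `n = 0` rows, not an error.
#'
#' @param cohort A cohort.
#' @param grouping Character/factor vector, one label per patient.
#' @return Long data frame: `group`, `variable`, `kind` (species/parameter),
#'   `n`, `median`, `q1`, `q3`.
#' @export
compare_groups <- function(cohort, grouping) {
  stopifnot(length(grouping) == length(cohort$id))
  grouping <- as.character(grouping)
  vals <- cbind(as.data.frame(cohort$baselines),
                as.data.frame(sweep(cohort$multipliers, 2,
                                    cohort$nominal[colnames(cohort$multipliers)],
                                    `*`)))
  kind <- c(rep("species", ncol(cohort$baselines)),
            rep("parameter", ncol(cohort$multipliers)))
  out <- list()
  for (g in unique(grouping)) {
    rows <- grouping == g
    if (!any(rows)) next
    for (j in seq_along(vals)) {
      x <- vals[rows, j]
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      out[[length(out) + 1]] <- data.frame(
        group = g, variable = names(vals)[j], kind = kind[j],
        n = sum(rows), median = q[2], q1 = q[1], q3 = q[3])
    }
  }
  do.call(rbind, out)
}

#' Persist / restore a cohort as CSV + JSON metadata
#'
#' The CSV holds one row per patient (id, parameter multipliers, baseline
#' species); the JSON sidecar records seed, priors and provenance so the
#' cohort is regenerable.
#'
#' @param cohort A cohort.
#' @param path CSV path; metadata written next to it as `<path>.json`.
#' @return `read_cohort`: the restored cohort.
#' @export
write_cohort <- function(cohort, path) {
  df <- data.frame(id = cohort$id)
  mult <- cohort$multipliers
  colnames(mult) <- paste0("mult.", colnames(mult))
  base <- cohort$baselines
  colnames(base) <- paste0("base.", colnames(base))
  utils::write.csv(cbind(df, mult, base), path, row.names = FALSE)
  meta <- list(seed = cohort$seed, priors = cohort$priors,
               nominal = as.list(cohort$nominal),
               provenance = cohort$provenance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mult <- as.matrix(df[grep("^mult\\.", names(df))])
  colnames(mult) <- sub("^mult\\.", "", colnames(mult))
  base <- as.matrix(df[grep("^base\\.", names(df))])
  colnames(base) <- sub("^base\\.", "", colnames(base))
  structure(list(id = df$id, multipliers = mult, baselines = base,
                 nominal = validate_params(unlist(meta$nominal)),
                 priors = as.data.frame(meta$priors), seed = meta$seed,
                 provenance = meta$provenance),
            class = "cohort")
}
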