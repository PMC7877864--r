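#' Default baseline laws for synthetic trial reports
#'
#' Log-normal baseline distributions bracketing the CRP/FCP ranges seen
#' across Crohn's disease induction trials: CRP median 10 mg/L, FCP median
#' 600 mg/kg, geometric SD 2.5 for both.
#'
#' @return List with `CRP` and `FCP`, each `c(meanlog, sdlog)`.
#' @export
default_baseline_law <- function() {
  list(CRP = c(meanlog = log(10), sdlog = log(2.5)),
       FCP = c(meanlog = log(600), sdlog = log(2.5)))
}

#' Generate a fully synthetic trial "report"
#'
#' Emulates the published artefact the pipeline consumes: per-arm baseline
#' CRP/FCP summary statistics of a stated kind, and longitudinal observed
#' biomarker summaries equal to a true suppression curve plus seeded
#' sampling noise. No real clinical values are embedded; the provenance
#' field marks every fixture synthetic.
#'
#' @param seed Integer seed (fixture is regenerable from it).
#' @param n_per_arm Patients per arm.
#' @param baseline_law As [default_baseline_law()].
#' @param effect_profile Named list (one entry per arm) of functions
#'   `f(day)` returning the true fractional suppression in [0, 1].
#' @param stat_kind Named character: statistic kind per marker
#'   (`median_iqr`, `mean_sd` or `median_range`), recycled.
#' @param days Observation days for the longitudinal summaries.
#' @param noise_cv Coefficient of variation of the additive sampling noise
#'   on observed summaries.
#' @param trial Trial name label.
#' @return List of class `trial_fixture`: `trial`, `n_per_arm`,
#'   `baseline` (per-marker kind + values), `longitudinal` (data frame:
#'   arm, marker, day, statistic, value, lo, hi), `seed`, `provenance`.
#' @export
make_trial_fixture <- function(seed = 1, n_per_arm = 100,
                               baseline_law = default_baseline_law(),
                               effect_profile = list(
                                 treated = function(day) 0.6 * (1 - exp(-day / 14))),
                               stat_kind = c(CRP = "median_iqr", FCP = "median_iqr"),
                               days = c(0, 14, 28, 42, 56, 84),
                               noise_cv = 0.05, trial = "synthetic-trial") {
  for (law in baseline_law) {
    if (any(!is.finite(law)) || law[["sdlog"]] <= 0) stop("invalid lognormal law")
  }
  for (f in effect_profile) {
    s <- f(days)
    if (any(s < 0 | s > 1)) stop("suppression must lie in [0, 1]")
  }
  set.seed(as.integer(seed))
  markers <- names(baseline_law)
  stat_kind <- rep(stat_kind, length.out = length(markers))
  names(stat_kind) <- markers

  summarise <- function(x, kind) {
    if (kind == "median_iqr") {
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      list(kind = kind, median = q[2], q1 = q[1], q3 = q[3])
    } else if (kind == "mean_sd") {
      list(kind = kind, mean = mean(x), sd = stats::sd(x))
    } else {
      list(kind = kind, median = stats::median(x), min = min(x), max = max(x))
    }
  }

  baseline <- list()
  long <- list()
  for (mk in markers) {
    law <- baseline_law[[mk]]
    draws <- stats::rlnorm(n_per_arm, law[["meanlog"]], law[["sdlog"]])
    baseline[[mk]] <- summarise(draws, stat_kind[[mk]])
    centre <- stats::median(draws)
    for (arm in names(effect_profile)) {
      supp <- effect_profile[[arm]](days)
      truth <- centre * (1 - supp)
      noise <- stats::rnorm(length(days), 0, noise_cv * centre)
      value <- pmax(truth + noise, 0)
      spread <- 0.35 * value
      long[[length(long) + 1]] <- data.frame(
        arm = arm, marker = mk, day = days,
        statistic = if (stat_kind[[mk]] == "mean_sd") "mean" else "median",
        value = value, lo = pmax(value - spread, 0), hi = value + spread)
    }
  }
  structure(list(trial = trial, n_per_arm = n_per_arm, baseline = baseline,
                 longitudinal = do.call(rbind, long), seed = as.integer(seed),
                 provenance = "synthetic"),
            class = "trial_fixture")
}

#' Baseline-matching targets from a trial fixture
#'
#' @param fixture A [make_trial_fixture()].
#' @param tolerance Matching tolerance passed to [baseline_targets()].
#' @return A [baseline_targets()] object.
#' @export
fixture_targets <- function(fixture, tolerance = 0.1) {
  stopifnot(inherits(fixture, "trial_fixture"))
  baseline_targets(CRP = fixture$baseline$CRP, FCP = fixture$baseline$FCP,
                   tolerance = tolerance)
}

#' Library of the study's printed dosing regimens and response criteria
#'
#' Encodes the five induction regimens simulated by the analysis
#' (weeks converted to days, 70 kg standard weight for mg/kg doses) and the
#' four biomarker response criteria (>= 60 percent CRP decrease;
#' normalised CRP < 3 mg/L; normalised CRP < 5 mg/L; normalised FCP
#' < 250 mg/kg; all assessed at week 6).
#'
#' @return List with elements `regimens` (named list of [regimen()] /
#'   lists of regimens) and `criteria` (named list of
#'   [response_criterion()]).
#' @export
make_study_defaults <- function() {
  iv <- function(days, mg = NA, mgkg = NA) {
    data.frame(time = days, route = "iv", amount = mg, amount_per_kg = mgkg)
  }
  sc <- function(days, mg) {
    data.frame(time = days, route = "sc", amount = mg, amount_per_kg = NA)
  }
  regimens <- list(
    ustekinumab_130mg = regimen("ustekinumab", iv(0, mg = 130)),
    ustekinumab_6mgkg = regimen("ustekinumab", iv(0, mgkg = 6)),
    brazikumab_700mg = regimen(
      "brazikumab", rbind(iv(c(0, 28), mg = 700), sc(c(84, 112), mg = 210))),
    risankizumab_200mg = regimen("risankizumab", iv(c(0, 28, 56), mg = 200)),
    risankizumab_600mg = regimen("risankizumab", iv(c(0, 28, 56), mg = 600)),
    infliximab_5mgkg = regimen("infliximab", iv(c(0, 14, 42), mgkg = 5)),
    infliximab_5mgkg_fcp = regimen("infliximab", iv(c(0, 56), mgkg = 5)),
    `PF-04236921_10mg` = regimen("PF-04236921", sc(c(1, 28), mg = 10)),
    `PF-04236921_50mg` = regimen("PF-04236921", sc(c(1, 28), mg = 50)),
    `PF-04236921_200mg` = regimen("PF-04236921", sc(c(1, 28), mg = 200))
  )
  criteria <- list(
    crp_pct60 = response_criterion("CRP", "percent_decrease", 60, day = 42),
    crp_abs3 = response_criterion("CRP", "absolute_below", 3, day = 42),
    crp_abs5 = response_criterion("CRP", "absolute_below", 5, day = 42),
    fcp_abs250 = response_criterion("FCP", "absolute_below", 250, day = 42)
  )
  list(regimens = regimens, criteria = criteria)
}
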