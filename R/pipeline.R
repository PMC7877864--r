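#' Run configuration for the end-to-end pipeline
#'
#' Either a YAML file path or a list. Recognised fields (all optional,
#' defaults in parentheses): `out_dir` ("cdqsp-run"), `seed` (1),
#' `cohort_size` (500), `population_size` (200), `body_weight` (70),
#' `baseline` (fixture lognormal laws, see [default_baseline_law()]),
#' `regimen_a` ("infliximab_5mgkg"), `regimen_b` ("ustekinumab_6mgkg"),
#' `criterion` ("crp_pct60"), `calibrate_params`
#' (c("Km_IL6_CRP","b_CRP")), `calibration_population` (60),
#' `calibration_maxit` (60), `horizon` (84).
#'
#' @param config List or YAML path.
#' @return Normalised config list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    out_dir = "cdqsp-run", seed = 1, cohort_size = 500,
    population_size = 200, body_weight = 70,
    baseline = NULL, regimen_a = "infliximab_5mgkg",
    regimen_b = "ustekinumab_6mgkg", criterion = "crp_pct60",
    calibrate_params = c("Km_IL6_CRP", "b_CRP"),
    calibration_population = 60, calibration_maxit = 60, horizon = 84)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  config
}

#' Run the analysis pipeline end to end
#'
#' Stages: `generate` (plausible cohort), `select` (trial-matched
#' population), `calibrate` (nominal fit to the anti-IL-6 CRP targets),
#' `simulate` (the two monotherapy arms), `classify` (responder
#' partition), `combine` (combination arm). Later stages consume earlier
#' ones; requesting a stage whose dependency is neither requested nor
#' already produced in `out_dir` is an error naming the missing stage.
#' Every artifact is listed in a manifest with its md5 hash, the seed and
#' a config snapshot, so a rerun with the same config reproduces identical
#' hashes for the deterministic stages.
#'
#' @param config A [run_config()] list or YAML path.
#' @param stages Character subset of
#'   `c("generate","select","calibrate","simulate","classify","combine")`.
#' @return Invisible list with the manifest (also written to
#'   `manifest.json` in `out_dir`) and the in-memory stage outputs.
#' @export
run_pipeline <- function(config = list(),
                         stages = c("generate", "select", "simulate",
                                    "classify", "combine")) {
  all_stages <- c("generate", "select", "calibrate", "simulate",
                  "classify", "combine")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg <- run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  deps <- list(select = "generate", simulate = "select",
               classify = "simulate", combine = "select")
  artifact_of <- list(generate = "cohort.csv", select = "population.csv",
                      calibrate = "fit.json", simulate = "arm_A.csv",
                      classify = "partition.json", combine = "combo_AB.csv")
  for (st in stages) {
    d <- deps[[st]]
    if (!is.null(d) && !d %in% stages &&
        !file.exists(file.path(cfg$out_dir, artifact_of[[d]]))) {
      stop("stage '", st, "' requires prior stage '", d, "'")
    }
  }

  defaults <- make_study_defaults()
  state <- list()
  artifacts <- character(0)
  add <- function(path) artifacts <<- c(artifacts, path)
  pathto <- function(f) file.path(cfg$out_dir, f)

  nominal <- nominal_parameters()
  if ("calibrate" %in% stages) {
    fit <- calibrate(default_calibration_targets(), cfg$calibrate_params,
                     nominal = nominal,
                     population_size = cfg$calibration_population,
                     seed = cfg$seed, n_starts = 4,
                     maxit = cfg$calibration_maxit)
    nominal <- fit$params
    write_fit_result(fit, pathto("fit.json"))
    add(pathto("fit.json")); add(pathto("fit_params.csv"))
    state$fit <- fit
  }
  if ("generate" %in% stages) {
    cohort <- generate_cohort(cfg$cohort_size, seed = cfg$seed,
                              nominal = nominal)
    write_cohort(cohort, pathto("cohort.csv"))
    add(pathto("cohort.csv")); add(pathto("cohort.csv.json"))
    state$cohort <- cohort
  } else if (any(c("select", "simulate", "classify", "combine") %in% stages)) {
    state$cohort <- read_cohort(pathto("cohort.csv"))
  }
  if ("select" %in% stages) {
    law <- if (is.null(cfg$baseline)) default_baseline_law() else
      list(CRP = unlist(cfg$baseline$CRP), FCP = unlist(cfg$baseline$FCP))
    fixture <- make_trial_fixture(seed = cfg$seed, baseline_law = law)
    pop <- select_trial_population(state$cohort, fixture_targets(fixture),
                                   cfg$population_size, seed = cfg$seed)
    write_cohort(pop, pathto("population.csv"))
    add(pathto("population.csv")); add(pathto("population.csv.json"))
    state$population <- pop
  } else if (any(c("simulate", "classify", "combine") %in% stages)) {
    state$population <- read_cohort(pathto("population.csv"))
  }

  spec <- trial_spec(horizon = cfg$horizon,
                     grid = seq(0, cfg$horizon, by = 7))
  regA <- defaults$regimens[[cfg$regimen_a]]
  regB <- defaults$regimens[[cfg$regimen_b]]
  if ("simulate" %in% stages) {
    state$arm_A <- simulate_arm(state$population, list(regA), spec)
    state$arm_B <- simulate_arm(state$population, list(regB), spec)
    write_arm_result(state$arm_A, pathto("arm_A.csv"))
    write_arm_result(state$arm_B, pathto("arm_B.csv"))
    add(pathto("arm_A.csv")); add(pathto("arm_A_summary.csv"))
    add(pathto("arm_B.csv")); add(pathto("arm_B_summary.csv"))
  }
  if ("classify" %in% stages) {
    part <- classify_responders(state$arm_A, state$arm_B,
                                defaults$criteria[[cfg$criterion]])
    jsonlite::write_json(
      list(criterion = cfg$criterion, counts = as.list(part$counts),
           fractions = as.list(part$fractions),
           n_included = part$n_included, n_excluded = part$n_excluded),
      pathto("partition.json"), auto_unbox = TRUE, digits = NA)
    add(pathto("partition.json"))
    state$partition <- part
  }
  if ("combine" %in% stages) {
    combo <- simulate_arm(state$population, list(regA, regB), spec)
    write_arm_result(combo, pathto("combo_AB.csv"))
    add(pathto("combo_AB.csv")); add(pathto("combo_AB_summary.csv"))
    state$combo <- combo
  }

  manifest <- list(
    seed = cfg$seed, stages = stages,
    config = cfg[setdiff(names(cfg), "out_dir")],
    artifacts = lapply(unique(artifacts), function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, pathto("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(list(manifest = manifest), state))
}
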