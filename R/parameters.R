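#' Canonical parameter ordering of the Crohn's disease model
#'
#' Order matters: the compiled right-hand side indexes parameters by
#' position. Any new parameter must be appended in both places.
#'
#' @return Character vector of parameter names.
#' @export
cd_param_names <- function() {
  c(
    ## naive T cells and differentiation
    "s_Th0", "kdeg_Th0",
    "kdif_Th1", "Km_IL12_Th1", "kdeg_Th1",
    "kdif_Th17", "Km_IL23_Th17", "a_IL6_Th17", "Km_IL6_Th17", "kdeg_Th17",
    ## regulatory T cells (homeostatic; inhibit differentiation)
    "s_Treg", "kdeg_Treg", "Km_Treg",
    ## NK1 cells (IL-12 driven)
    "s_NK1", "kact_NK1", "Km_IL12_NK1", "kdeg_NK1",
    ## dendritic cells
    "s_iDC", "kdeg_iDC", "kact_DC", "Km_TNF_DC", "a_IL6_DC", "Km_IL6_DC", "kdeg_eDC",
    ## macrophages
    "s_M0", "kdeg_M0", "kact_M", "Km_TNF_M", "a_IFN_M", "Km_IFN_M", "kdeg_M1",
    ## neutrophils
    "s_Neu", "kdeg_Neu", "kact_Neu", "Km_TNF_Neu", "a_IL17_Neu", "Km_IL17_Neu", "kdeg_Neua",
    ## cytokines: basal floor, production gain, producer weights, degradation
    "b_TNF", "p_TNF", "w_M1_TNF", "w_Neu_TNF", "kdeg_TNF",
    "b_IL6", "p_IL6", "w_M1_IL6", "w_Neu_IL6", "c0_IL6", "Km_TNF_IL6",
    "a_IL17_IL6", "Km_IL17_IL6", "kdeg_IL6",
    "b_IL8", "p_IL8", "w_M1_IL8", "w_Neu_IL8", "kdeg_IL8",
    "b_IL12", "p_IL12", "w_M1_IL12", "w_Neu_IL12", "kdeg_IL12",
    "b_IL17", "p_IL17", "kdeg_IL17",
    "b_IL22", "p_IL22", "kdeg_IL22",
    "b_IL23", "p_IL23", "w_M1_IL23", "w_Neu_IL23", "kdeg_IL23",
    "b_IFN", "p_IFN", "w_NK_IFN", "kdeg_IFN",
    "b_GM", "p_GM", "w_M1_GM", "w_Neu_GM", "kdeg_GM",
    ## clinical markers
    "b_CRP", "p_CRP", "Km_IL6_CRP", "kdeg_CRP",
    "b_FCP", "p_FCP", "Km_Neua_FCP", "Km_IL8_FCP", "c0_FCP", "kdeg_FCP",
    ## global Hill coefficient for every modifier arrow
    "n_hill"
  )
}

#' Reference untreated Crohn's disease baseline
#'
#' Serum-equivalent concentrations typical of moderate-to-severe active
#' disease; the nominal parameterisation is anchored so that these values are
#' an exact steady state of the network.
#'
#' @return Named numeric vector: cytokines pg/mL, CRP mg/L, FCP mg/kg.
#' @export
cd_reference_baseline <- function() {
  c(TNFa = 15, IL6 = 10, IL8 = 30, IL12 = 5, IL17 = 8, IL22 = 20,
    IL23 = 5, IFNg = 10, GMCSF = 5, CRP = 10, FCP = 600)
}

hill_act <- function(x, Km, n = 1) {
  x <- pmax(x, 0)
  x^n / (Km^n + x^n)
}

#' Nominal mechanistic parameter set
#'
#' Structural constants (sources, degradation rates, half-maximum constants,
#' producer weights, basal floors) are fixed design values; the production
#' gains \code{p_*} are derived in closed form so that
#' \code{\link{cd_reference_baseline}} (plus the implied cell densities) is an
#' exact fixed point of the network. This plays the role of the trained
#' disease-state parameterisation that virtual-patient sampling and
#' calibration subsequently perturb.
#'
#' @param baseline Named vector of target cytokine/marker steady-state values;
#'   defaults to [cd_reference_baseline()].
#' @return Named numeric vector over [cd_param_names()].
#' @export
nominal_parameters <- function(baseline = cd_reference_baseline()) {
  b <- baseline
  p <- c(
    s_Th0 = 1, kdeg_Th0 = 1,
    kdif_Th1 = 0.5, Km_IL12_Th1 = 5, kdeg_Th1 = 0.2,
    kdif_Th17 = 0.5, Km_IL23_Th17 = 5, a_IL6_Th17 = 0.3, Km_IL6_Th17 = 10,
    kdeg_Th17 = 0.2,
    s_Treg = 0.5, kdeg_Treg = 0.5, Km_Treg = 2,
    s_NK1 = 0.05, kact_NK1 = 0.45, Km_IL12_NK1 = 5, kdeg_NK1 = 0.25,
    s_iDC = 1, kdeg_iDC = 0.5, kact_DC = 1, Km_TNF_DC = 10,
    a_IL6_DC = 0.5, Km_IL6_DC = 10, kdeg_eDC = 0.5,
    s_M0 = 1, kdeg_M0 = 0.5, kact_M = 1, Km_TNF_M = 10,
    a_IFN_M = 0.8, Km_IFN_M = 10, kdeg_M1 = 0.5,
    s_Neu = 2, kdeg_Neu = 0.5, kact_Neu = 1, Km_TNF_Neu = 10,
    a_IL17_Neu = 0.8, Km_IL17_Neu = 8, kdeg_Neua = 0.5,
    b_TNF = 5, p_TNF = NA, w_M1_TNF = 1, w_Neu_TNF = 1, kdeg_TNF = 10,
    b_IL6 = 0.5, p_IL6 = NA, w_M1_IL6 = 1, w_Neu_IL6 = 0.5,
    c0_IL6 = 0.05, Km_TNF_IL6 = 10, a_IL17_IL6 = 0.5, Km_IL17_IL6 = 8,
    kdeg_IL6 = 8,
    b_IL8 = 5, p_IL8 = NA, w_M1_IL8 = 1, w_Neu_IL8 = 2, kdeg_IL8 = 8,
    b_IL12 = 1, p_IL12 = NA, w_M1_IL12 = 1, w_Neu_IL12 = 0.1, kdeg_IL12 = 5,
    b_IL17 = 3, p_IL17 = NA, kdeg_IL17 = 5,
    b_IL22 = 5, p_IL22 = NA, kdeg_IL22 = 5,
    b_IL23 = 1, p_IL23 = NA, w_M1_IL23 = 1, w_Neu_IL23 = 0.1, kdeg_IL23 = 5,
    b_IFN = 1, p_IFN = NA, w_NK_IFN = 0.5, kdeg_IFN = 5,
    b_GM = 1, p_GM = NA, w_M1_GM = 1, w_Neu_GM = 1, kdeg_GM = 5,
    b_CRP = 0.15, p_CRP = NA, Km_IL6_CRP = 8, kdeg_CRP = 0.8,
    b_FCP = 20, p_FCP = NA, Km_Neua_FCP = 2.5, Km_IL8_FCP = 15,
    c0_FCP = 0.2, kdeg_FCP = 1,
    n_hill = 1
  )
  rederive_gains(p, b)
}

#' Re-derive production gains so a stated baseline is an exact fixed point
#'
#' Given any full parameter vector (its `p_*` entries are ignored) and a
#' target cytokine/marker baseline, recomputes the implied cell steady
#' states and solves each cytokine's production balance for its gain.
#' [nominal_parameters()] is this applied to the structural defaults;
#' calibration applies it after every structural-parameter move so that
#' fitting dose-response curvature never un-anchors the disease baseline.
#'
#' @param p Named parameter vector over [cd_param_names()] (gains may be NA).
#' @param baseline As [cd_reference_baseline()].
#' @return Parameter vector with all `p_*` gains re-derived.
#' @export
rederive_gains <- function(p, baseline = cd_reference_baseline()) {
  b <- baseline
  cells <- implied_cells(p, b)
  n <- p[["n_hill"]]
  H <- function(x, Km) hill_act(x, Km, n)

  derive_gain <- function(target, b_basal, kdeg, producer) {
    prod_needed <- kdeg * target - b_basal
    if (prod_needed <= 0) stop("basal floor exceeds target production for a cytokine")
    prod_needed / producer
  }
  S <- function(w_M1, w_Neu) {
    cells[["eDC"]] + w_M1 * cells[["M1"]] + w_Neu * cells[["Neu_a"]]
  }
  p[["p_TNF"]] <- derive_gain(b[["TNFa"]], p[["b_TNF"]], p[["kdeg_TNF"]],
                              S(p[["w_M1_TNF"]], p[["w_Neu_TNF"]]))
  f_IL6 <- p[["c0_IL6"]] + (1 - p[["c0_IL6"]]) *
    (H(b[["TNFa"]], p[["Km_TNF_IL6"]]) +
       p[["a_IL17_IL6"]] * H(b[["IL17"]], p[["Km_IL17_IL6"]])) /
    (1 + p[["a_IL17_IL6"]])
  p[["p_IL6"]] <- derive_gain(b[["IL6"]], p[["b_IL6"]], p[["kdeg_IL6"]],
                              S(p[["w_M1_IL6"]], p[["w_Neu_IL6"]]) * f_IL6)
  p[["p_IL8"]] <- derive_gain(b[["IL8"]], p[["b_IL8"]], p[["kdeg_IL8"]],
                              S(p[["w_M1_IL8"]], p[["w_Neu_IL8"]]))
  p[["p_IL12"]] <- derive_gain(b[["IL12"]], p[["b_IL12"]], p[["kdeg_IL12"]],
                               S(p[["w_M1_IL12"]], p[["w_Neu_IL12"]]))
  p[["p_IL23"]] <- derive_gain(b[["IL23"]], p[["b_IL23"]], p[["kdeg_IL23"]],
                               S(p[["w_M1_IL23"]], p[["w_Neu_IL23"]]))
  p[["p_IL17"]] <- derive_gain(b[["IL17"]], p[["b_IL17"]], p[["kdeg_IL17"]],
                               cells[["Th17"]])
  p[["p_IL22"]] <- derive_gain(b[["IL22"]], p[["b_IL22"]], p[["kdeg_IL22"]],
                               cells[["Th17"]])
  p[["p_IFN"]] <- derive_gain(b[["IFNg"]], p[["b_IFN"]], p[["kdeg_IFN"]],
                              cells[["Th1"]] + p[["w_NK_IFN"]] * cells[["NK1"]])
  p[["p_GM"]] <- derive_gain(b[["GMCSF"]], p[["b_GM"]], p[["kdeg_GM"]],
                             S(p[["w_M1_GM"]], p[["w_Neu_GM"]]))
  p[["p_CRP"]] <- derive_gain(b[["CRP"]], p[["b_CRP"]], p[["kdeg_CRP"]],
                              H(b[["IL6"]], p[["Km_IL6_CRP"]]))
  f_FCP <- p[["c0_FCP"]] + (1 - p[["c0_FCP"]]) * H(b[["IL8"]], p[["Km_IL8_FCP"]])
  p[["p_FCP"]] <- derive_gain(b[["FCP"]], p[["b_FCP"]], p[["kdeg_FCP"]],
                              H(cells[["Neu_a"]], p[["Km_Neua_FCP"]]) * f_FCP)
  validate_params(p[cd_param_names()])
}

# Cell steady states implied by fixed cytokine concentrations (closed form:
# with cytokines clamped, each cell lineage is a linear chain).
implied_cells <- function(p, b) {
  n <- p[["n_hill"]]
  H <- function(x, Km) hill_act(x, Km, n)
  Treg <- p[["s_Treg"]] / p[["kdeg_Treg"]]
  Itreg <- p[["Km_Treg"]]^n / (p[["Km_Treg"]]^n + Treg^n)
  NK1 <- (p[["s_NK1"]] + p[["kact_NK1"]] * H(b[["IL12"]], p[["Km_IL12_NK1"]])) /
    p[["kdeg_NK1"]]
  A_DC <- H(b[["TNFa"]], p[["Km_TNF_DC"]]) +
    p[["a_IL6_DC"]] * H(b[["IL6"]], p[["Km_IL6_DC"]])
  iDC <- p[["s_iDC"]] / (p[["kdeg_iDC"]] + p[["kact_DC"]] * A_DC)
  eDC <- p[["kact_DC"]] * A_DC * iDC / p[["kdeg_eDC"]]
  A_M <- H(b[["TNFa"]], p[["Km_TNF_M"]]) +
    p[["a_IFN_M"]] * H(b[["IFNg"]], p[["Km_IFN_M"]])
  M0 <- p[["s_M0"]] / (p[["kdeg_M0"]] + p[["kact_M"]] * A_M)
  M1 <- p[["kact_M"]] * A_M * M0 / p[["kdeg_M1"]]
  A_N <- H(b[["TNFa"]], p[["Km_TNF_Neu"]]) +
    p[["a_IL17_Neu"]] * H(b[["IL17"]], p[["Km_IL17_Neu"]])
  Neu <- p[["s_Neu"]] / (p[["kdeg_Neu"]] + p[["kact_Neu"]] * A_N)
  Neu_a <- p[["kact_Neu"]] * A_N * Neu / p[["kdeg_Neua"]]
  d1 <- p[["kdif_Th1"]] * H(b[["IL12"]], p[["Km_IL12_Th1"]]) * Itreg
  d17 <- p[["kdif_Th17"]] *
    (H(b[["IL23"]], p[["Km_IL23_Th17"]]) +
       p[["a_IL6_Th17"]] * H(b[["IL6"]], p[["Km_IL6_Th17"]])) * Itreg
  Th0 <- p[["s_Th0"]] / p[["kdeg_Th0"]]
  Th1 <- d1 * Th0 / p[["kdeg_Th1"]]
  Th17 <- d17 * Th0 / p[["kdeg_Th17"]]
  c(Th0 = Th0, Th1 = Th1, Th17 = Th17, Treg = Treg, NK1 = NK1,
    iDC = iDC, eDC = eDC, M0 = M0, M1 = M1, Neu = Neu, Neu_a = Neu_a)
}

#' The exact analytic fixed point anchored by the nominal parameterisation
#'
#' Only valid for a parameter vector freshly produced by
#' [nominal_parameters()] with the same baseline; perturbed parameter sets
#' must use [steady_state()] instead.
#'
#' @inheritParams nominal_parameters
#' @return Named state vector over [cd_species()].
#' @export
nominal_state <- function(baseline = cd_reference_baseline()) {
  p <- nominal_parameters(baseline)
  cells <- implied_cells(p, baseline)
  st <- c(cells, baseline[c("TNFa", "IL6", "IL8", "IL12", "IL17", "IL22",
                            "IL23", "IFNg", "GMCSF", "CRP", "FCP")])
  st[cd_species()]
}

#' Validate a mechanistic parameter vector
#'
#' Enforces positivity of every rate constant, source and half-maximum
#' constant, fractional floors in [0, 1), and a Hill coefficient in [1, 4].
#'
#' @param params Named numeric vector over [cd_param_names()].
#' @return The validated vector, canonically ordered.
#' @export
validate_params <- function(params) {
  nm <- cd_param_names()
  if (is.null(names(params)) || !all(nm %in% names(params))) {
    missing <- setdiff(nm, names(params))
    stop("parameter vector is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  params <- params[nm]
  if (any(!is.finite(params))) stop("non-finite parameter value", call. = FALSE)
  frac <- c("c0_IL6", "c0_FCP")
  if (any(params[frac] < 0 | params[frac] >= 1)) {
    stop("fractional production floors must lie in [0, 1)", call. = FALSE)
  }
  if (params[["n_hill"]] < 1 || params[["n_hill"]] > 4) {
    stop("Hill coefficient must lie in [1, 4]", call. = FALSE)
  }
  strict <- grep("^(kdeg|Km|kdif|kact|p)_", nm, value = TRUE)
  if (any(params[strict] <= 0)) {
    stop("rate constants, gains and Km values must be > 0", call. = FALSE)
  }
  nonneg <- grep("^(b|s|w|a)_", nm, value = TRUE)
  if (any(params[nonneg] < 0)) {
    stop("basal floors, sources and weights must be >= 0", call. = FALSE)
  }
  params
}
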