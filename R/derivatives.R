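#' Right-hand side of the Crohn's disease network ODE
#'
#' Reference (pure-R) implementation of the rate laws: first-order
#' degradation for every species, Michaelis-Menten/Hill activation for every
#' modifier arrow, additive basal production floors. Drug action enters
#' exclusively through \code{free_fraction}: wherever a targetable cytokine
#' acts as a modifier, its concentration is replaced by
#' \code{free_fraction * concentration} (the antibody-unbound part).
#'
#' The compiled solver path (`src/cd_rhs.c`) implements the identical
#' equations; the two are cross-checked in the test suite.
#'
#' @param state Named non-negative state vector over [cd_species()].
#' @param params Named parameter vector over [cd_param_names()].
#' @param free_fraction Named multiplier in [0, 1] for each of
#'   [cd_targetable_cytokines()]; missing entries default to 1 (no drug).
#' @return Named rate vector (d/dt, per day) over [cd_species()].
#' @export
cd_derivatives <- function(state, params,
                           free_fraction = c(TNFa = 1, IL6 = 1, IL12 = 1, IL23 = 1)) {
  y <- validate_state(state)
  p <- validate_params(params)
  ff <- c(TNFa = 1, IL6 = 1, IL12 = 1, IL23 = 1)
  if (length(free_fraction)) {
    bad <- setdiff(names(free_fraction), names(ff))
    if (length(bad)) stop("free_fraction for untargetable species: ",
                          paste(bad, collapse = ", "))
    if (any(free_fraction < 0 | free_fraction > 1)) {
      stop("free_fraction values must lie in [0, 1]")
    }
    ff[names(free_fraction)] <- free_fraction
  }
  n <- p[["n_hill"]]
  H <- function(x, Km) hill_act(x, Km, n)

  ## effective (drug-unbound) modifier concentrations
  TNF_e <- ff[["TNFa"]] * y[["TNFa"]]
  IL6_e <- ff[["IL6"]] * y[["IL6"]]
  IL12_e <- ff[["IL12"]] * y[["IL12"]]
  IL23_e <- ff[["IL23"]] * y[["IL23"]]

  Itreg <- p[["Km_Treg"]]^n / (p[["Km_Treg"]]^n + max(y[["Treg"]], 0)^n)

  d1 <- p[["kdif_Th1"]] * H(IL12_e, p[["Km_IL12_Th1"]]) * Itreg
  d17 <- p[["kdif_Th17"]] *
    (H(IL23_e, p[["Km_IL23_Th17"]]) +
       p[["a_IL6_Th17"]] * H(IL6_e, p[["Km_IL6_Th17"]])) * Itreg
  A_DC <- H(TNF_e, p[["Km_TNF_DC"]]) +
    p[["a_IL6_DC"]] * H(IL6_e, p[["Km_IL6_DC"]])
  A_M <- H(TNF_e, p[["Km_TNF_M"]]) +
    p[["a_IFN_M"]] * H(y[["IFNg"]], p[["Km_IFN_M"]])
  A_N <- H(TNF_e, p[["Km_TNF_Neu"]]) +
    p[["a_IL17_Neu"]] * H(y[["IL17"]], p[["Km_IL17_Neu"]])

  ## the naive pool is homeostatically maintained: differentiation drives
  ## Th1/Th17 production at a rate proportional to Th0 without depleting it
  ## (keeps the response to blocking one axis monotone; no precursor
  ## competition between the axes)
  dTh0 <- p[["s_Th0"]] - p[["kdeg_Th0"]] * y[["Th0"]]
  dTh1 <- d1 * y[["Th0"]] - p[["kdeg_Th1"]] * y[["Th1"]]
  dTh17 <- d17 * y[["Th0"]] - p[["kdeg_Th17"]] * y[["Th17"]]
  dTreg <- p[["s_Treg"]] - p[["kdeg_Treg"]] * y[["Treg"]]
  dNK1 <- p[["s_NK1"]] + p[["kact_NK1"]] * H(IL12_e, p[["Km_IL12_NK1"]]) -
    p[["kdeg_NK1"]] * y[["NK1"]]
  diDC <- p[["s_iDC"]] - (p[["kdeg_iDC"]] + p[["kact_DC"]] * A_DC) * y[["iDC"]]
  deDC <- p[["kact_DC"]] * A_DC * y[["iDC"]] - p[["kdeg_eDC"]] * y[["eDC"]]
  dM0 <- p[["s_M0"]] - (p[["kdeg_M0"]] + p[["kact_M"]] * A_M) * y[["M0"]]
  dM1 <- p[["kact_M"]] * A_M * y[["M0"]] - p[["kdeg_M1"]] * y[["M1"]]
  dNeu <- p[["s_Neu"]] - (p[["kdeg_Neu"]] + p[["kact_Neu"]] * A_N) * y[["Neu"]]
  dNeua <- p[["kact_Neu"]] * A_N * y[["Neu"]] - p[["kdeg_Neua"]] * y[["Neu_a"]]

  innate <- function(w_M1, w_Neu) {
    y[["eDC"]] + w_M1 * y[["M1"]] + w_Neu * y[["Neu_a"]]
  }
  dTNF <- p[["b_TNF"]] + p[["p_TNF"]] * innate(p[["w_M1_TNF"]], p[["w_Neu_TNF"]]) -
    p[["kdeg_TNF"]] * y[["TNFa"]]
  f6 <- p[["c0_IL6"]] + (1 - p[["c0_IL6"]]) *
    (H(TNF_e, p[["Km_TNF_IL6"]]) +
       p[["a_IL17_IL6"]] * H(y[["IL17"]], p[["Km_IL17_IL6"]])) /
    (1 + p[["a_IL17_IL6"]])
  dIL6 <- p[["b_IL6"]] +
    p[["p_IL6"]] * innate(p[["w_M1_IL6"]], p[["w_Neu_IL6"]]) * f6 -
    p[["kdeg_IL6"]] * y[["IL6"]]
  dIL8 <- p[["b_IL8"]] + p[["p_IL8"]] * innate(p[["w_M1_IL8"]], p[["w_Neu_IL8"]]) -
    p[["kdeg_IL8"]] * y[["IL8"]]
  dIL12 <- p[["b_IL12"]] + p[["p_IL12"]] * innate(p[["w_M1_IL12"]], p[["w_Neu_IL12"]]) -
    p[["kdeg_IL12"]] * y[["IL12"]]
  dIL17 <- p[["b_IL17"]] + p[["p_IL17"]] * y[["Th17"]] - p[["kdeg_IL17"]] * y[["IL17"]]
  dIL22 <- p[["b_IL22"]] + p[["p_IL22"]] * y[["Th17"]] - p[["kdeg_IL22"]] * y[["IL22"]]
  dIL23 <- p[["b_IL23"]] + p[["p_IL23"]] * innate(p[["w_M1_IL23"]], p[["w_Neu_IL23"]]) -
    p[["kdeg_IL23"]] * y[["IL23"]]
  dIFN <- p[["b_IFN"]] +
    p[["p_IFN"]] * (y[["Th1"]] + p[["w_NK_IFN"]] * y[["NK1"]]) -
    p[["kdeg_IFN"]] * y[["IFNg"]]
  dGM <- p[["b_GM"]] + p[["p_GM"]] * innate(p[["w_M1_GM"]], p[["w_Neu_GM"]]) -
    p[["kdeg_GM"]] * y[["GMCSF"]]
  dCRP <- p[["b_CRP"]] + p[["p_CRP"]] * H(IL6_e, p[["Km_IL6_CRP"]]) -
    p[["kdeg_CRP"]] * y[["CRP"]]
  fF <- p[["c0_FCP"]] + (1 - p[["c0_FCP"]]) * H(y[["IL8"]], p[["Km_IL8_FCP"]])
  dFCP <- p[["b_FCP"]] +
    p[["p_FCP"]] * H(y[["Neu_a"]], p[["Km_Neua_FCP"]]) * fF -
    p[["kdeg_FCP"]] * y[["FCP"]]

  out <- c(dTh0, dTh1, dTh17, dTreg, dNK1, diDC, deDC, dM0, dM1, dNeu, dNeua,
           dTNF, dIL6, dIL8, dIL12, dIL17, dIL22, dIL23, dIFN, dGM, dCRP, dFCP)
  names(out) <- cd_species()
  out
}
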