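# Independent oracles used across the suite. Each re-derives its quantity
# by a different route than the implementation it checks.

# --- independent re-implementation of the network rate laws ----------------
# Written as explicit production/loss bookkeeping per species (vs the
# implementation's inline vector arithmetic and the compiled C path).
oracle_rates <- function(state, params, ff = c(TNFa = 1, IL6 = 1, IL12 = 1, IL23 = 1)) {
  y <- as.list(state)
  p <- as.list(params)
  n <- p$n_hill
  hill <- function(x, Km) if (x <= 0) 0 else x^n / (Km^n + x^n)
  inh <- function(x, Km) Km^n / (Km^n + max(x, 0)^n)
  eTNF <- ff[["TNFa"]] * y$TNFa
  eIL6 <- ff[["IL6"]] * y$IL6
  eIL12 <- ff[["IL12"]] * y$IL12
  eIL23 <- ff[["IL23"]] * y$IL23

  prod <- loss <- stats::setNames(numeric(22), cd_species())
  treg_block <- inh(y$Treg, p$Km_Treg)
  r_th1 <- p$kdif_Th1 * hill(eIL12, p$Km_IL12_Th1) * treg_block * y$Th0
  r_th17 <- p$kdif_Th17 * (hill(eIL23, p$Km_IL23_Th17) +
                             p$a_IL6_Th17 * hill(eIL6, p$Km_IL6_Th17)) *
    treg_block * y$Th0
  r_dc <- p$kact_DC * (hill(eTNF, p$Km_TNF_DC) +
                         p$a_IL6_DC * hill(eIL6, p$Km_IL6_DC)) * y$iDC
  r_m <- p$kact_M * (hill(eTNF, p$Km_TNF_M) +
                       p$a_IFN_M * hill(y$IFNg, p$Km_IFN_M)) * y$M0
  r_n <- p$kact_Neu * (hill(eTNF, p$Km_TNF_Neu) +
                         p$a_IL17_Neu * hill(y$IL17, p$Km_IL17_Neu)) * y$Neu

  prod["Th0"] <- p$s_Th0
  loss["Th0"] <- p$kdeg_Th0 * y$Th0
  prod["Th1"] <- r_th1;  loss["Th1"] <- p$kdeg_Th1 * y$Th1
  prod["Th17"] <- r_th17; loss["Th17"] <- p$kdeg_Th17 * y$Th17
  prod["Treg"] <- p$s_Treg; loss["Treg"] <- p$kdeg_Treg * y$Treg
  prod["NK1"] <- p$s_NK1 + p$kact_NK1 * hill(eIL12, p$Km_IL12_NK1)
  loss["NK1"] <- p$kdeg_NK1 * y$NK1
  prod["iDC"] <- p$s_iDC; loss["iDC"] <- p$kdeg_iDC * y$iDC + r_dc
  prod["eDC"] <- r_dc; loss["eDC"] <- p$kdeg_eDC * y$eDC
  prod["M0"] <- p$s_M0; loss["M0"] <- p$kdeg_M0 * y$M0 + r_m
  prod["M1"] <- r_m; loss["M1"] <- p$kdeg_M1 * y$M1
  prod["Neu"] <- p$s_Neu; loss["Neu"] <- p$kdeg_Neu * y$Neu + r_n
  prod["Neu_a"] <- r_n; loss["Neu_a"] <- p$kdeg_Neua * y$Neu_a

  innate <- function(wm, wn) y$eDC + wm * y$M1 + wn * y$Neu_a
  prod["TNFa"] <- p$b_TNF + p$p_TNF * innate(p$w_M1_TNF, p$w_Neu_TNF)
  loss["TNFa"] <- p$kdeg_TNF * y$TNFa
  f6 <- p$c0_IL6 + (1 - p$c0_IL6) *
    (hill(eTNF, p$Km_TNF_IL6) + p$a_IL17_IL6 * hill(y$IL17, p$Km_IL17_IL6)) /
    (1 + p$a_IL17_IL6)
  prod["IL6"] <- p$b_IL6 + p$p_IL6 * innate(p$w_M1_IL6, p$w_Neu_IL6) * f6
  loss["IL6"] <- p$kdeg_IL6 * y$IL6
  prod["IL8"] <- p$b_IL8 + p$p_IL8 * innate(p$w_M1_IL8, p$w_Neu_IL8)
  loss["IL8"] <- p$kdeg_IL8 * y$IL8
  prod["IL12"] <- p$b_IL12 + p$p_IL12 * innate(p$w_M1_IL12, p$w_Neu_IL12)
  loss["IL12"] <- p$kdeg_IL12 * y$IL12
  prod["IL17"] <- p$b_IL17 + p$p_IL17 * y$Th17
  loss["IL17"] <- p$kdeg_IL17 * y$IL17
  prod["IL22"] <- p$b_IL22 + p$p_IL22 * y$Th17
  loss["IL22"] <- p$kdeg_IL22 * y$IL22
  prod["IL23"] <- p$b_IL23 + p$p_IL23 * innate(p$w_M1_IL23, p$w_Neu_IL23)
  loss["IL23"] <- p$kdeg_IL23 * y$IL23
  prod["IFNg"] <- p$b_IFN + p$p_IFN * (y$Th1 + p$w_NK_IFN * y$NK1)
  loss["IFNg"] <- p$kdeg_IFN * y$IFNg
  prod["GMCSF"] <- p$b_GM + p$p_GM * innate(p$w_M1_GM, p$w_Neu_GM)
  loss["GMCSF"] <- p$kdeg_GM * y$GMCSF
  prod["CRP"] <- p$b_CRP + p$p_CRP * hill(eIL6, p$Km_IL6_CRP)
  loss["CRP"] <- p$kdeg_CRP * y$CRP
  fF <- p$c0_FCP + (1 - p$c0_FCP) * hill(y$IL8, p$Km_IL8_FCP)
  prod["FCP"] <- p$b_FCP + p$p_FCP * hill(y$Neu_a, p$Km_Neua_FCP) * fF
  loss["FCP"] <- p$kdeg_FCP * y$FCP
  prod - loss
}

# --- two-compartment PK by numerical integration ---------------------------
pk_ode_conc <- function(pk, reg, times) {
  reg <- resolve_doses(reg)
  k10 <- pk$CL / pk$V1; k12 <- pk$Q / pk$V1; k21 <- pk$Q / pk$V2
  rhs <- function(t, y, parms) {
    # y: depot (mg), central (mg), peripheral (mg)
    list(c(-pk$ka * y[1],
           pk$ka * y[1] - (k10 + k12) * y[2] + k21 * y[3],
           k12 * y[2] - k21 * y[3]))
  }
  ev <- do.call(rbind, lapply(seq_len(nrow(reg$events)), function(i) {
    e <- reg$events[i, ]
    if (e$route == "iv") {
      data.frame(var = "C", time = e$time, value = e$amount, method = "add")
    } else {
      data.frame(var = "A", time = e$time, value = e$amount * pk$F, method = "add")
    }
  }))
  tt <- sort(unique(c(times, ev$time)))
  out <- deSolve::ode(c(A = 0, C = 0, P = 0), tt, rhs, NULL,
                      events = list(data = ev), rtol = 1e-11, atol = 1e-13)
  out[match(times, tt), "C"] / pk$V1
}

# --- grid-search solution of the binding mass balance ----------------------
grid_free_ligand <- function(Ttot, B, Kd, npts = 1e6) {
  L <- seq(0, Ttot, length.out = npts + 1)
  resid <- abs(L + B * L / (Kd + L) - Ttot)
  L[which.min(resid)]
}

# --- compiled-path exposure forcing a constant free fraction ---------------
# With Kd and binding sites both huge relative to the cytokine, the
# quadratic's solution tends to Kd / (Kd + B), independent of the state.
constant_ff_exposure <- function(ff, horizon) {
  tg <- cd_targetable_cytokines()
  f <- stats::setNames(rep(1, 4), tg)
  f[names(ff)] <- ff
  Kd <- stats::setNames(rep(1e7, 4), tg)
  Bv <- ifelse(f >= 1, 0, 1e7 * (1 - f) / pmax(f, 1e-12))
  B <- matrix(rep(Bv, each = 2), nrow = 2, dimnames = list(NULL, tg))
  list(times = c(0, horizon), B = B, Kd = Kd)
}

# steady state under a constant per-target free fraction
ss_under_ff <- function(params, ff, days = 600) {
  tr <- cd_simulate(params, nominal_state(), c(0, days / 2, days),
                    free_fraction = constant_ff_exposure(ff, days))
  unlist(tr[nrow(tr), cd_species()])
}

# small shared cohort (built once per test run)
shared_cohort <- local({
  co <- NULL
  function(n = 120, seed = 7) {
    if (is.null(co)) co <<- suppressWarnings(generate_cohort(n, seed = seed))
    co
  }
})
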