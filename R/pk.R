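#' Two-compartment pharmacokinetic parameters
#'
#' @param CL Clearance (L/day).
#' @param V1,V2 Central / peripheral volumes (L).
#' @param Q Inter-compartmental clearance (L/day).
#' @param ka First-order subcutaneous absorption rate (1/day).
#' @param F Subcutaneous bioavailability fraction in (0, 1].
#' @param molecular_weight Antibody molecular weight (g/mol).
#' @return List of class `pk_parameters`.
#' @export
pk_parameters <- function(CL, V1, V2, Q, ka = 0.25, F = 0.7,
                          molecular_weight = 150000) {
  vals <- c(CL = CL, V1 = V1, V2 = V2, Q = Q, ka = ka,
            molecular_weight = molecular_weight)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all PK parameters must be positive and finite")
  }
  if (F <= 0 || F > 1) stop("bioavailability F must lie in (0, 1]")
  structure(list(CL = CL, V1 = V1, V2 = V2, Q = Q, ka = ka, F = F,
                 molecular_weight = molecular_weight),
            class = "pk_parameters")
}

#' Repository default PK parameter table
#'
#' Literature-typical monoclonal-antibody disposition values per drug
#' (linear two-compartment; no target-mediated disposition). These are repo
#' defaults, overridable via [pk_table_from_config()].
#'
#' @return Named list of [pk_parameters()], keyed by drug name.
#' @export
builtin_pk_table <- function() {
  list(
    infliximab   = pk_parameters(CL = 0.27, V1 = 3.3, V2 = 2.7, Q = 0.38,
                                 ka = 0.25, F = 0.7, molecular_weight = 149100),
    ustekinumab  = pk_parameters(CL = 0.22, V1 = 3.0, V2 = 2.5, Q = 0.35,
                                 ka = 0.26, F = 0.7, molecular_weight = 148600),
    brazikumab   = pk_parameters(CL = 0.30, V1 = 3.5, V2 = 3.0, Q = 0.45,
                                 ka = 0.25, F = 0.65, molecular_weight = 148000),
    risankizumab = pk_parameters(CL = 0.30, V1 = 3.4, V2 = 2.9, Q = 0.45,
                                 ka = 0.25, F = 0.72, molecular_weight = 149000),
    `PF-04236921` = pk_parameters(CL = 0.20, V1 = 3.5, V2 = 3.0, Q = 0.40,
                                  ka = 0.22, F = 0.75, molecular_weight = 150000)
  )
}

#' Read a PK parameter table from a YAML config file
#'
#' The file maps drug name to the fields of [pk_parameters()]; drugs absent
#' from the file fall back to [builtin_pk_table()].
#'
#' @param path YAML file path.
#' @return Named list of [pk_parameters()].
#' @export
pk_table_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  tab <- builtin_pk_table()
  for (drug in names(cfg)) {
    tab[[drug]] <- do.call(pk_parameters, cfg[[drug]])
  }
  tab
}

#' Dosing regimen for one drug
#'
#' Each dose event has a time (days), a route (`"iv"` or `"sc"`), and exactly
#' one of `amount` (mg) or `amount_per_kg` (mg/kg).
#'
#' @param drug Drug name.
#' @param events Data frame with columns `time`, `route`, and `amount`
#'   and/or `amount_per_kg` (use NA for the unused one).
#' @param body_weight Body weight (kg) used to resolve mg/kg doses.
#' @return List of class `regimen`.
#' @export
regimen <- function(drug, events, body_weight = 70) {
  stopifnot(is.data.frame(events))
  if (!"amount" %in% names(events)) events$amount <- NA_real_
  if (!"amount_per_kg" %in% names(events)) events$amount_per_kg <- NA_real_
  req <- c("time", "route", "amount", "amount_per_kg")
  if (!all(c("time", "route") %in% names(events))) {
    stop("events needs columns time and route")
  }
  events <- events[req]
  if (any(events$time < 0)) stop("dose times must be >= 0")
  if (!all(events$route %in% c("iv", "sc"))) stop("route must be 'iv' or 'sc'")
  one <- xor(!is.na(events$amount), !is.na(events$amount_per_kg))
  if (!all(one)) stop("each event needs exactly one of amount / amount_per_kg")
  amt <- ifelse(is.na(events$amount), events$amount_per_kg, events$amount)
  if (any(amt <= 0)) stop("dose amounts must be > 0")
  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(drug = drug, events = events, body_weight = body_weight),
            class = "regimen")
}

#' An empty (placebo / no-drug) regimen
#' @param drug Label, default "placebo".
#' @return A `regimen` with zero events.
#' @export
empty_regimen <- function(drug = "placebo") {
  structure(list(drug = drug,
                 events = data.frame(time = numeric(), route = character(),
                                     amount = numeric(), amount_per_kg = numeric()),
                 body_weight = 70),
            class = "regimen")
}

#' Resolve weight-based doses to absolute milligrams
#'
#' @param reg A [regimen()].
#' @return The regimen with every event's `amount` filled in (mg) and
#'   `amount_per_kg` cleared.
#' @export
resolve_doses <- function(reg) {
  stopifnot(inherits(reg, "regimen"))
  if (!is.finite(reg$body_weight) || reg$body_weight <= 0) {
    stop("body weight must be > 0")
  }
  ev <- reg$events
  wb <- !is.na(ev$amount_per_kg)
  ev$amount[wb] <- ev$amount_per_kg[wb] * reg$body_weight
  ev$amount_per_kg <- rep(NA_real_, nrow(ev))
  reg$events <- ev
  reg
}

# macro rate constants and hybrid exponents of the 2-compartment model
pk_hybrid <- function(pk) {
  k10 <- pk$CL / pk$V1
  k12 <- pk$Q / pk$V1
  k21 <- pk$Q / pk$V2
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  list(k10 = k10, k12 = k12, k21 = k21, alpha = alpha, beta = beta)
}

# unit-dose concentration (mg/L per mg) at time t >= 0 after one dose
pk_unit_profile <- function(pk, t, route) {
  h <- pk_hybrid(pk)
  a <- h$alpha; b <- h$beta; k21 <- h$k21
  t <- pmax(t, 0)
  if (route == "iv") {
    (1 / pk$V1) * (((a - k21) / (a - b)) * exp(-a * t) +
                     ((k21 - b) / (a - b)) * exp(-b * t))
  } else {
    ka <- pk$ka
    if (any(abs(c(ka - a, ka - b)) < 1e-10)) {
      ka <- ka * (1 + 1e-8)  # avoid the degenerate ka == alpha/beta case
    }
    pk$F * ka / pk$V1 * (
      (k21 - a) / ((ka - a) * (b - a)) * exp(-a * t) +
        (k21 - b) / ((ka - b) * (a - b)) * exp(-b * t) +
        (k21 - ka) / ((a - ka) * (b - ka)) * exp(-ka * t))
  }
}

#' Serum drug concentration under a dosing regimen
#'
#' Closed-form linear two-compartment kinetics: biexponential decline after
#' an IV bolus, first-order absorption for SC doses, and superposition over
#' all dose events at or before `t`. Every subject in an arm shares this
#' profile; between-subject variability enters only through the mechanistic
#' model parameters.
#'
#' @param pk [pk_parameters()].
#' @param reg A [regimen()]; mg/kg doses are resolved internally.
#' @param t Vector of times (days).
#' @return Concentration (mg/L) at each time.
#' @export
pk_concentration <- function(pk, reg, t) {
  stopifnot(inherits(pk, "pk_parameters"), inherits(reg, "regimen"))
  if (any(t < 0)) stop("t must be >= 0")
  reg <- resolve_doses(reg)
  conc <- numeric(length(t))
  for (i in seq_len(nrow(reg$events))) {
    ev <- reg$events[i, ]
    after <- t >= ev$time
    if (any(after)) {
      conc[after] <- conc[after] +
        ev$amount * pk_unit_profile(pk, t[after] - ev$time, ev$route)
    }
  }
  conc
}

#' Convert drug serum concentration between mg/L and nM
#'
#' @param conc_mg_per_L,conc_nM Concentration to convert.
#' @param pk [pk_parameters()] supplying the molecular weight.
#' @return Converted concentration.
#' @export
to_molar <- function(conc_mg_per_L, pk) {
  if (any(conc_mg_per_L < 0)) stop("concentration must be >= 0")
  if (pk$molecular_weight <= 0) stop("molecular weight must be > 0")
  conc_mg_per_L / pk$molecular_weight * 1e6
}

#' @rdname to_molar
#' @export
from_molar <- function(conc_nM, pk) {
  if (any(conc_nM < 0)) stop("concentration must be >= 0")
  conc_nM * pk$molecular_weight / 1e6
}

#' Read / write regimen CSV files
#'
#' Columns: `drug, time_days, amount, unit (mg | mg_per_kg), route`.
#'
#' @param path CSV file path.
#' @param body_weight Body weight used for mg/kg events.
#' @return `read_regimens`: named list of [regimen()] (one per drug).
#' @export
read_regimens <- function(path, body_weight = 70) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("drug", "time_days", "amount", "unit", "route")
  if (!all(req %in% names(df))) {
    stop("regimen CSV needs columns: ", paste(req, collapse = ", "))
  }
  lapply(split(df, df$drug), function(d) {
    ev <- data.frame(
      time = d$time_days, route = d$route,
      amount = ifelse(d$unit == "mg", d$amount, NA_real_),
      amount_per_kg = ifelse(d$unit == "mg_per_kg", d$amount, NA_real_))
    regimen(d$drug[1], ev, body_weight = body_weight)
  })
}

#' @rdname read_regimens
#' @param regimens Named list of [regimen()].
#' @export
write_regimens <- function(regimens, path) {
  rows <- lapply(regimens, function(r) {
    if (nrow(r$events) == 0) return(NULL)
    data.frame(drug = r$drug, time_days = r$events$time,
               amount = ifelse(is.na(r$events$amount),
                               r$events$amount_per_kg, r$events$amount),
               unit = ifelse(is.na(r$events$amount), "mg_per_kg", "mg"),
               route = r$events$route)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
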