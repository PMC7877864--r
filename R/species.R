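#' Species of the Crohn's disease immune-network model
#'
#' The model tracks 11 cell populations (arbitrary consistent tissue-density
#' units), 9 cytokines (pg/mL serum-equivalent), serum C-reactive protein
#' (CRP, mg/L) and fecal calprotectin (FCP, mg/kg stool). The ordering
#' returned here is the canonical state ordering used by every solver path.
#'
#' @return Character vector of the 22 species names in canonical order.
#' @export
cd_species <- function() {
  c(
    "Th0", "Th1", "Th17", "Treg", "NK1",
    "iDC", "eDC", "M0", "M1", "Neu", "Neu_a",
    "TNFa", "IL6", "IL8", "IL12", "IL17", "IL22", "IL23", "IFNg", "GMCSF",
    "CRP", "FCP"
  )
}

#' @rdname cd_species
#' @export
cd_cell_species <- function() cd_species()[1:11]

#' @rdname cd_species
#' @export
cd_cytokine_species <- function() cd_species()[12:20]

#' Cytokines that can be neutralised by a therapeutic antibody
#' @return Character vector of targetable cytokine names.
#' @export
cd_targetable_cytokines <- function() c("TNFa", "IL6", "IL12", "IL23")

#' Molecular weights used to convert cytokine pg/mL to nM
#'
#' TNFa is treated as the soluble homotrimer, IL-12 as the p70 heterodimer
#' and IL-23 as the p19/p40 heterodimer.
#'
#' @return Named numeric vector, g/mol, for the four targetable cytokines.
#' @export
cd_cytokine_mw <- function() {
  c(TNFa = 51000, IL6 = 21000, IL12 = 70000, IL23 = 55000)
}

# pg/mL -> nM given molecular weight in g/mol
pgml_to_nM <- function(pg_per_ml, mw) pg_per_ml / mw

#' Validate a model state vector
#'
#' @param state Named numeric vector over [cd_species()].
#' @param what Label used in error messages.
#' @return The state, reordered canonically.
#' @keywords internal
validate_state <- function(state, what = "state") {
  sp <- cd_species()
  if (is.null(names(state)) || !all(sp %in% names(state))) {
    stop(what, " must be a named vector containing all of: ",
         paste(sp, collapse = ", "), call. = FALSE)
  }
  state <- state[sp]
  if (any(!is.finite(state))) stop(what, " contains non-finite values", call. = FALSE)
  if (any(state < 0)) stop(what, " contains negative values", call. = FALSE)
  state
}
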