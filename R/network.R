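#' Structural definition of the Crohn's disease immune network
#'
#' Returns the model wiring as an explicit reaction table: one row per
#' reaction with reactants, products, modifier species, rate-law kind
#' (`source`, `linear_decay`, `hill_conversion`, `hill_production`,
#' `modulated_production`) and the parameters each references. The table is
#' the single human-readable account of every modifier arrow the rate laws
#' implement; structural tests and the CSV export consume it.
#'
#' Key wiring: IL-12 drives Th0->Th1 differentiation and hence IFNg; IL-23
#' (and IL-6) drive Th0->Th17 and hence IL-17 and IL-22; TNFa activates
#' dendritic cells, macrophages and neutrophils (with IL-6, IFNg and IL-17
#' as respective co-activators); the activated innate cells produce TNFa,
#' IL-6, IL-8, IL-12, IL-23 and GM-CSF; TNFa additionally amplifies IL-6
#' production; IL-6 drives hepatic CRP; activated neutrophils and IL-8
#' drive FCP. IL-17 carries a constant IL-23-independent basal source.
#' Treg (homeostatic) inhibits Th differentiation; NK1 (IL-12 driven)
#' contributes IFNg. Every species has a first-order turnover reaction.
#'
#' @return List of class `cd_network` with elements `species` and
#'   `reactions` (data frame).
#' @export
build_network <- function() {
  rx <- function(id, reactants, products, modifiers, rate_law, parameters) {
    data.frame(id = id, reactants = reactants, products = products,
               modifiers = modifiers, rate_law = rate_law,
               parameters = parameters, stringsAsFactors = FALSE)
  }
  reactions <- rbind(
    rx("src_Th0", "", "Th0", "", "source", "s_Th0"),
    rx("dif_Th1", "", "Th1", "Th0;IL12;Treg", "hill_production",
       "kdif_Th1;Km_IL12_Th1;Km_Treg;n_hill"),
    rx("dif_Th17", "", "Th17", "Th0;IL23;IL6;Treg", "hill_production",
       "kdif_Th17;Km_IL23_Th17;a_IL6_Th17;Km_IL6_Th17;Km_Treg;n_hill"),
    rx("src_Treg", "", "Treg", "", "source", "s_Treg"),
    rx("src_NK1", "", "NK1", "IL12", "hill_production",
       "s_NK1;kact_NK1;Km_IL12_NK1;n_hill"),
    rx("src_iDC", "", "iDC", "", "source", "s_iDC"),
    rx("act_DC", "iDC", "eDC", "TNFa;IL6", "hill_conversion",
       "kact_DC;Km_TNF_DC;a_IL6_DC;Km_IL6_DC;n_hill"),
    rx("src_M0", "", "M0", "", "source", "s_M0"),
    rx("act_M", "M0", "M1", "TNFa;IFNg", "hill_conversion",
       "kact_M;Km_TNF_M;a_IFN_M;Km_IFN_M;n_hill"),
    rx("src_Neu", "", "Neu", "", "source", "s_Neu"),
    rx("act_Neu", "Neu", "Neu_a", "TNFa;IL17", "hill_conversion",
       "kact_Neu;Km_TNF_Neu;a_IL17_Neu;Km_IL17_Neu;n_hill"),
    rx("prod_TNF", "", "TNFa", "eDC;M1;Neu_a", "modulated_production",
       "b_TNF;p_TNF;w_M1_TNF;w_Neu_TNF"),
    rx("prod_IL6", "", "IL6", "eDC;M1;Neu_a;TNFa;IL17", "modulated_production",
       "b_IL6;p_IL6;w_M1_IL6;w_Neu_IL6;c0_IL6;Km_TNF_IL6;a_IL17_IL6;Km_IL17_IL6;n_hill"),
    rx("prod_IL8", "", "IL8", "eDC;M1;Neu_a", "modulated_production",
       "b_IL8;p_IL8;w_M1_IL8;w_Neu_IL8"),
    rx("prod_IL12", "", "IL12", "eDC;M1;Neu_a", "modulated_production",
       "b_IL12;p_IL12;w_M1_IL12;w_Neu_IL12"),
    rx("prod_IL17", "", "IL17", "Th17", "modulated_production",
       "b_IL17;p_IL17"),
    rx("prod_IL22", "", "IL22", "Th17", "modulated_production",
       "b_IL22;p_IL22"),
    rx("prod_IL23", "", "IL23", "eDC;M1;Neu_a", "modulated_production",
       "b_IL23;p_IL23;w_M1_IL23;w_Neu_IL23"),
    rx("prod_IFN", "", "IFNg", "Th1;NK1", "modulated_production",
       "b_IFN;p_IFN;w_NK_IFN"),
    rx("prod_GM", "", "GMCSF", "eDC;M1;Neu_a", "modulated_production",
       "b_GM;p_GM;w_M1_GM;w_Neu_GM"),
    rx("prod_CRP", "", "CRP", "IL6", "hill_production",
       "b_CRP;p_CRP;Km_IL6_CRP;n_hill"),
    rx("prod_FCP", "", "FCP", "Neu_a;IL8", "hill_production",
       "b_FCP;p_FCP;Km_Neua_FCP;Km_IL8_FCP;c0_FCP;n_hill")
  )
  decay <- do.call(rbind, lapply(cd_species(), function(sp) {
    kdeg <- switch(sp,
      Th0 = "kdeg_Th0", Th1 = "kdeg_Th1", Th17 = "kdeg_Th17",
      Treg = "kdeg_Treg", NK1 = "kdeg_NK1", iDC = "kdeg_iDC",
      eDC = "kdeg_eDC", M0 = "kdeg_M0", M1 = "kdeg_M1", Neu = "kdeg_Neu",
      Neu_a = "kdeg_Neua", TNFa = "kdeg_TNF", IL6 = "kdeg_IL6",
      IL8 = "kdeg_IL8", IL12 = "kdeg_IL12", IL17 = "kdeg_IL17",
      IL22 = "kdeg_IL22", IL23 = "kdeg_IL23", IFNg = "kdeg_IFN",
      GMCSF = "kdeg_GM", CRP = "kdeg_CRP", FCP = "kdeg_FCP")
    rx(paste0("deg_", sp), sp, "", "", "linear_decay", kdeg)
  }))
  reactions <- rbind(reactions, decay)
  drug_points <- data.frame(
    cytokine = cd_targetable_cytokines(),
    effect = c(
      "free TNFa drives DC/macrophage/neutrophil activation and IL-6 amplification",
      "free IL-6 drives Th17 differentiation, DC activation and CRP production",
      "free IL-12 drives Th1 differentiation and NK1 activity",
      "free IL-23 drives Th17 differentiation"),
    stringsAsFactors = FALSE)
  structure(list(species = cd_species(), reactions = reactions,
                 drug_effect_points = drug_points),
            class = "cd_network")
}

#' Export the reaction table to CSV
#'
#' @param network A [build_network()] object.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
network_to_csv <- function(network, path) {
  stopifnot(inherits(network, "cd_network"))
  utils::write.csv(network$reactions, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.cd_network <- function(x, ...) {
  cat("Crohn's disease immune-network model:", length(x$species),
      "species,", nrow(x$reactions), "reactions\n")
  invisible(x)
}

#' Check a parameter vector against the network's parameter references
#'
#' Every parameter named in the reaction table must resolve to a field of
#' the parameter vector.
#'
#' @param network A [build_network()] object.
#' @param params Named parameter vector.
#' @return TRUE invisibly; unresolved references are an error.
#' @export
check_network_params <- function(network, params = nominal_parameters()) {
  refs <- unique(unlist(strsplit(network$reactions$parameters, ";")))
  refs <- refs[nzchar(refs)]
  missing <- setdiff(refs, names(params))
  if (length(missing)) {
    stop("unresolved parameter references: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
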