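#' Carbon fate: marine sequestration and avoided emissions
#'
#' Three pathways convert kelp carbon into climate benefit, all reported in
#' kg CO2e per year:
#' * passive sequestration of detrital DOC/POC shed during growth;
#' * active sequestration of biomass purposefully left near the farm or
#'   transported and sunk in deep water;
#' * avoided emissions where seaweed-based food, animal feed or biofuel
#'   replaces a more emissions-intensive conventional product.
#'
#' The marine sequestration terms carry an air-sea uptake correction
#' (`atm_uptake_efficiency`): respiration and upwelling replace part of the
#' CO2 removed from surface waters, so carbon locked in seaweed tissue maps
#' to less than one-to-one atmospheric drawdown. Avoided emissions are
#' already expressed in CO2e by their replacement factors and take no such
#' correction. The sinking and release pathways additionally discount for
#' the fraction of biomass lost in handling before it reaches its
#' destination (`sink_retention`, `release_retention`).
#'
#' @name carbon-fate
NULL

#' Passive sequestration of detrital carbon (kg CO2e per year)
#'
#' `C_SeqP = (DOC * doc_seq_fraction + POC * poc_seq_fraction) *
#' (44/12) * atm_uptake_efficiency`. Linear in both fluxes.
#'
#' @param doc,poc detrital fluxes, kg C per year.
#' @param draws draw matrix/vector.
#' @return kg CO2e per year.
#' @export
passive_sequestration <- function(doc, poc, draws) {
  if (any(doc < 0) || any(poc < 0)) stop("DOC and POC must be >= 0")
  (doc * draw_col(draws, "doc_seq_fraction") +
     poc * draw_col(draws, "poc_seq_fraction")) *
    draw_col(draws, "c_to_co2") * draw_col(draws, "atm_uptake_efficiency")
}

#' Active sequestration of released or sunk biomass (kg CO2e per year)
#'
#' Biomass directed to `near_farm_release` or `deep_sink` is converted to
#' carbon with the harvest-weighted dry-weight and carbon-content factors,
#' discounted by the pathway's retention and long-term sequestration
#' fractions, and by the air-sea correction.
#'
#' @param b_h per-species harvest matrix (kg ww per year).
#' @param fates named fate vector (proportions summing to 1).
#' @param draws draw matrix/vector.
#' @return kg CO2e per year.
#' @export
active_sequestration <- function(b_h, fates, draws) {
  total <- rowSums(b_h)
  dwc <- ifelse(total > 0, harvested_carbon_cols(b_h, draws) / pmax(total, 1e-300), 0)
  rel <- total * fates[["near_farm_release"]] *
    draw_col(draws, "release_retention") *
    draw_col(draws, "nearfarm_seq_fraction")
  snk <- total * fates[["deep_sink"]] *
    draw_col(draws, "sink_retention") *
    draw_col(draws, "deepsink_seq_fraction")
  (rel + snk) * dwc * draw_col(draws, "c_to_co2") *
    draw_col(draws, "atm_uptake_efficiency")
}

# biomass-weighted kg C per kg ww
harvested_carbon_cols <- function(b_h, draws) {
  acc <- 0
  for (s in colnames(b_h)) {
    acc <- acc + unname(b_h[, s]) * draw_col(draws, param_id("dw_frac", s)) *
      draw_col(draws, param_id("c_frac", s))
  }
  acc
}

#' Avoided emissions from product replacement (kg CO2e per year)
#'
#' `C_Avoid = sum_p B_H_total * fate_p * yield_p * repl_factor_p` over the
#' product fates (food, animal feed, biofuel); `yield_p` is product mass
#' per kg ww and `repl_factor_p` is kg CO2e avoided per kg product.
#'
#' @param b_h per-species harvest matrix (kg ww per year).
#' @param fates named fate vector.
#' @param draws draw matrix/vector.
#' @return kg CO2e per year.
#' @export
avoided_emissions <- function(b_h, fates, draws) {
  total <- rowSums(b_h)
  acc <- numeric(length(total))
  for (p in PRODUCT_FATES) {
    if (fates[[p]] == 0) next
    tag <- product_tag(p)
    acc <- acc + total * fates[[p]] *
      draw_col(draws, paste0("yield_", tag)) *
      draw_col(draws, paste0("repl_factor_", tag))
  }
  acc
}

# fate name -> parameter suffix
product_tag <- function(p) c(food = "food", animal_feed = "feed",
                             biofuel = "biofuel")[[p]]

#' Total climate pathways (kg CO2e per year)
#'
#' Sum of passive sequestration, active sequestration and avoided
#' emissions.
#'
#' @param c_seq_p,c_seq_a,c_avoid pathway components.
#' @return kg CO2e per year.
#' @export
total_climate_pathways <- function(c_seq_p, c_seq_a, c_avoid) {
  c_seq_p + c_seq_a + c_avoid
}
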