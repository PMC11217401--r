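#' Industry emissions: the seven-term ledger
#'
#' Total emissions from building and running the farms and handling the
#' harvest are the sum of seven terms, all in kg CO2e per year:
#' nursery operations (`E_Nurs`), production of capital equipment
#' amortized over its lifetime (`E_Cap`), transport of materials to the
#' farm (`E_MatTrans`), farm maintenance including gear replacement
#' (`E_Maint`), active sinking of kelp (`E_Seq`), transport of harvested
#' kelp to port (`E_SWtrans`), and processing into final products
#' (`E_Proc`). Waste management, product storage and product distribution
#' are outside the model boundary and have no ledger slots.
#'
#' Capital, maintenance-trip and transport-distance parameters are zoned
#' (shallow vs deep strata): deeper sites carry heavier anchoring and
#' longer transits, so per-area emissions rise with the deep share of a
#' scenario's footprint. Zoned terms are resolved with area weights from
#' the scenario's zone table.
#'
#' @name emissions
NULL

EMISSION_TERMS <- c("E_Nurs", "E_Cap", "E_MatTrans", "E_Maint",
                    "E_Seq", "E_SWtrans", "E_Proc")

# per-scenario zone rows (zone, area_km2)
scenario_zones <- function(zone_table, scenario) {
  zt <- zone_table[zone_table$scenario == scenario$name, , drop = FALSE]
  if (nrow(zt) == 0L)
    stop("no zone entries for scenario: ", scenario$name)
  zt
}

#' Farm-phase emission terms
#'
#' Computes `E_Nurs`, `E_Cap`, `E_MatTrans` and `E_Maint` for a scenario.
#' All four scale with cultivated area; capital and maintenance use
#' zone-specific factors, and transport terms use zone-specific distances.
#'
#' @param scenario a `kelp_scenario`.
#' @param draws draw matrix/vector.
#' @param zone_table zone table with the scenario's shallow/deep areas.
#' @return list of four vectors (kg CO2e per year).
#' @export
farm_phase_emissions <- function(scenario, draws, zone_table) {
  zt <- scenario_zones(zone_table, scenario)
  n <- if (is.matrix(draws)) nrow(draws) else 1L
  e_nurs <- e_cap <- e_mat <- e_maint <- numeric(n)
  elec <- draw_col(draws, "elec_em_intensity")
  fuel <- draw_col(draws, "fuel_em_intensity")
  amort <- draw_col(draws, "capital_amort_years")
  for (k in seq_len(nrow(zt))) {
    z <- zt$zone[k]
    a_m2 <- zt$area_km2[k] * M2_PER_KM2
    if (a_m2 == 0) next
    zc <- function(nm) draw_col(draws, param_id(nm, zone = z))
    e_nurs <- e_nurs + a_m2 * draw_col(draws, "seed_line_density") *
      (draw_col(draws, "nursery_energy_per_m") * elec +
         draw_col(draws, "nursery_material_per_m"))
    embodied <- zc("capital_concrete") + zc("capital_steel") +
      zc("capital_lines") + zc("capital_buoys")
    e_cap <- e_cap + a_m2 * embodied / amort
    e_mat <- e_mat + a_m2 * zc("mattrans_per_m2_km") * zc("port_distance")
    e_maint <- e_maint +
      zt$area_km2[k] * zc("maint_trips_per_km2") * 2 * zc("farm_distance") *
        draw_col(draws, "vessel_fuel_per_km") * fuel +
      a_m2 * (zc("capital_lines") + zc("capital_buoys")) *
        draw_col(draws, "buoy_replacement_rate")
  }
  list(E_Nurs = e_nurs, E_Cap = e_cap, E_MatTrans = e_mat, E_Maint = e_maint)
}

#' Post-harvest emission terms
#'
#' Computes `E_Seq` (transport and handling of biomass sunk in deep
#' water), `E_SWtrans` (harvest and transport of product-bound biomass to
#' port, area-weighted over zones) and `E_Proc` (per-product processing
#' energy). Biomass left as near-farm release is neither transported nor
#' processed, so a no-harvest scenario has all three terms equal to zero.
#'
#' @param scenario a `kelp_scenario`.
#' @param draws draw matrix/vector.
#' @param b_h per-species harvest matrix (kg ww per year).
#' @param zone_table zone table for port-distance weighting.
#' @return list of three vectors (kg CO2e per year).
#' @export
postharvest_emissions <- function(scenario, draws, b_h, zone_table) {
  zt <- scenario_zones(zone_table, scenario)
  total <- rowSums(b_h)
  fates <- scenario$fates
  fuel <- draw_col(draws, "fuel_em_intensity")
  elec <- draw_col(draws, "elec_em_intensity")
  harvest_em <- draw_col(draws, "harvest_fuel_per_kg") * fuel

  sink_ww <- total * fates[["deep_sink"]]
  e_seq <- sink_ww * (draw_col(draws, "sink_trans_em_per_kg_km") *
                        draw_col(draws, "sink_distance") + harvest_em)

  product_ww <- total * sum(fates[PRODUCT_FATES])
  port_dist <- if (sum(zt$area_km2) > 0)
    zonal_average(zt, NULL, "port_distance", draws) else 0
  e_swt <- product_ww * (draw_col(draws, "swtrans_em_per_kg_km") * port_dist +
                           harvest_em +
                           draw_col(draws, "port_handling_em_per_kg"))

  e_proc <- numeric(length(total))
  for (p in PRODUCT_FATES) {
    if (fates[[p]] == 0) next
    e_proc <- e_proc + total * fates[[p]] *
      draw_col(draws, paste0("proc_energy_", product_tag(p))) * elec
  }
  list(E_Seq = e_seq, E_SWtrans = e_swt, E_Proc = e_proc)
}

#' Total emissions
#'
#' Arithmetic sum of the seven emission terms.
#'
#' @param terms named list (or data frame) holding the seven terms.
#' @return kg CO2e per year.
#' @export
total_emissions <- function(terms) {
  Reduce(`+`, lapply(EMISSION_TERMS, function(t) terms[[t]]))
}
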