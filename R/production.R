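#' Production sub-model: harvest, NPP and detrital export
#'
#' Harvested biomass per species is the product of the area-based
#' production rate, the cultivated area, the species' share of that area,
#' and the number of annual harvests. Net primary production (NPP) is then
#' back-calculated from harvested carbon, recognising that a fraction of
#' the carbon fixed by the kelp is shed before harvest as dissolved and
#' particulate organic carbon (DOC, POC). Internal units are kg (wet
#' weight) and kg C per year; teragrams appear only at reporting.
#'
#' @name production
NULL

KG_PER_TG <- 1e9
M2_PER_KM2 <- 1e6

#' Harvested biomass per species (kg ww per year)
#'
#' `B_H[i] = rate[i] * area_m2 * mix[i] * harvests_per_year`, with the rate
#' set selected by the scenario's `rate_source`. Linear in area and in each
#' species' rate.
#'
#' @param scenario a `kelp_scenario`.
#' @param draws a `kelp_draws` matrix (or single named vector).
#' @return matrix of kg ww per year, one row per draw, one column per
#'   species in the mix.
#' @export
harvested_biomass <- function(scenario, draws) {
  rate_name <- if (scenario$rate_source == "literature") "rate_literature" else "rate_farmer"
  area_m2 <- scenario$area_km2 * M2_PER_KM2
  sp <- names(scenario$species_mix)
  cols <- lapply(sp, function(s) {
    draw_col(draws, param_id(rate_name, s)) * area_m2 *
      scenario$species_mix[[s]] * scenario$harvests_per_year
  })
  m <- do.call(cbind, cols)
  colnames(m) <- sp
  m
}

#' Back-calculate NPP from harvested biomass (kg C per year)
#'
#' `NPP = sum_i(B_H[i] * DW[i] * C[i]) / (1 - FL_DOC - FL_POC)` where `DW`
#' converts wet to dry weight, `C` is carbon content of dry weight, and
#' `FL_DOC`, `FL_POC` are the fractions of fixed carbon lost as dissolved
#' and particulate detritus before harvest.
#'
#' @param b_h per-species harvest matrix from [harvested_biomass()].
#' @param draws draw matrix/vector.
#' @param scenario the scenario (names the species in `b_h`).
#' @return numeric vector of NPP, kg C per year.
#' @export
npp_from_harvest <- function(b_h, draws, scenario = NULL) {
  if (is.null(dim(b_h))) b_h <- matrix(b_h, nrow = 1,
                                       dimnames = list(NULL, names(b_h)))
  fl <- draw_col(draws, "fl_doc") + draw_col(draws, "fl_poc")
  if (any(fl >= 1))
    stop("FL_DOC + FL_POC must be < 1 (got ", max(fl), ")")
  hc <- 0
  for (s in colnames(b_h)) {
    hc <- hc + unname(b_h[, s]) * draw_col(draws, param_id("dw_frac", s)) *
      draw_col(draws, param_id("c_frac", s))
  }
  hc / (1 - fl)
}

#' Detrital carbon fluxes (kg C per year)
#'
#' `DOC = NPP * FL_DOC`; `POC = NPP * FL_POC`. Together with harvested
#' carbon these close the mass balance `NPP = harvested C + DOC + POC`.
#'
#' @param npp NPP vector from [npp_from_harvest()].
#' @param draws draw matrix/vector.
#' @return list with components `doc` and `poc`.
#' @export
detrital_fluxes <- function(npp, draws) {
  if (any(npp < 0)) stop("NPP must be >= 0")
  list(doc = npp * draw_col(draws, "fl_doc"),
       poc = npp * draw_col(draws, "fl_poc"))
}
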