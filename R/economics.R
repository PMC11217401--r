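#' Techno-economic assessment
#'
#' Annual cost of each scenario (production, transport, processing),
#' value of seaweed-based products, net cost, and net cost per teragram
#' of CO2e sequestered or avoided. All monetary amounts are Canadian
#' dollars with no discounting; results are reported in millions of CAD
#' per year. Carbon credits are not valued.
#'
#' @name economics
NULL

CAD_PER_MCAD <- 1e6

#' Scenario costs (million CAD per year)
#'
#' Production costs scale with area (operating, amortized capital,
#' nursery, insurance/licensing, maintenance trips, zone-resolved);
#' harvest, transport and sinking costs scale with the fate-resolved
#' biomass; processing costs are per-product.
#'
#' @param scenario a `kelp_scenario`.
#' @param draws draw matrix/vector.
#' @param b_h per-species harvest matrix (kg ww per year).
#' @param zone_table zone table covering the scenario.
#' @return list with components `production`, `transport`, `processing`,
#'   `total` (vectors, million CAD per year).
#' @export
scenario_costs <- function(scenario, draws, b_h, zone_table) {
  zt <- scenario_zones(zone_table, scenario)
  total <- rowSums(b_h)
  fates <- scenario$fates
  n <- length(total)

  prod_cost <- numeric(n)
  for (k in seq_len(nrow(zt))) {
    z <- zt$zone[k]
    a_m2 <- zt$area_km2[k] * M2_PER_KM2
    if (a_m2 == 0) next
    zc <- function(nm) draw_col(draws, param_id(nm, zone = z))
    prod_cost <- prod_cost +
      a_m2 * (zc("prod_cost_per_m2") +
                zc("capital_cost_per_m2") /
                  draw_col(draws, "capital_cost_amort_years") +
                draw_col(draws, "nursery_cost_per_m2")) +
      zt$area_km2[k] * (draw_col(draws, "insurance_license_per_km2") +
                          zc("maint_trips_per_km2") *
                            draw_col(draws, "maint_cost_per_trip"))
  }

  harvested_ww <- total * (1 - fates[["near_farm_release"]])
  product_ww <- total * sum(fates[PRODUCT_FATES])
  sink_ww <- total * fates[["deep_sink"]]
  port_dist <- if (sum(zt$area_km2) > 0)
    zonal_average(zt, NULL, "port_distance", draws) else 0
  trans_cost <- harvested_ww * draw_col(draws, "harvest_cost_per_kg") +
    product_ww * (draw_col(draws, "trans_cost_per_kg_km") * port_dist +
                    draw_col(draws, "port_fee_per_kg")) +
    sink_ww * draw_col(draws, "sink_cost_per_kg_km") *
      draw_col(draws, "sink_distance")

  proc_cost <- numeric(n)
  for (p in PRODUCT_FATES) {
    if (fates[[p]] == 0) next
    proc_cost <- proc_cost + total * fates[[p]] *
      draw_col(draws, paste0("proc_cost_", product_tag(p)))
  }

  list(production = prod_cost / CAD_PER_MCAD,
       transport = trans_cost / CAD_PER_MCAD,
       processing = proc_cost / CAD_PER_MCAD,
       total = (prod_cost + trans_cost + proc_cost) / CAD_PER_MCAD)
}

#' Product values (million CAD per year)
#'
#' `sum_p fate_p * B_H_total * yield_p * unit_value_p` over food, animal
#' feed and biofuel.
#'
#' @inheritParams scenario_costs
#' @return vector of product value, million CAD per year.
#' @export
product_values <- function(scenario, draws, b_h) {
  total <- rowSums(b_h)
  fates <- scenario$fates
  val <- numeric(length(total))
  for (p in PRODUCT_FATES) {
    if (fates[[p]] == 0) next
    tag <- product_tag(p)
    val <- val + total * fates[[p]] *
      draw_col(draws, paste0("yield_", tag)) *
      draw_col(draws, paste0("price_", tag))
  }
  val / CAD_PER_MCAD
}

#' Net cost per Tg CO2e (per-run distribution)
#'
#' The ratio `net_cost / net_benefit` is computed run by run on paired
#' draws and then summarized, not as a ratio of medians. By default every
#' run with a non-zero net benefit contributes its ratio, including runs
#' where the scenario is a net emitter (these produce negative ratios and
#' keep the summary percentiles consistent with per-run pairing); set
#' `negative_benefit = "na"` to flag such runs as undefined instead.
#' Negative ratios with positive benefit indicate profit per Tg avoided.
#'
#' @param net_cost vector of per-run net cost (million CAD per year).
#' @param net_benefit vector of per-run net benefit (kg CO2e per year),
#'   paired with `net_cost` (same draws, same order).
#' @param negative_benefit `"keep"` (default) or `"na"`: how to treat runs
#'   whose net benefit is negative.
#' @return vector of million CAD per Tg CO2e, `NA` where the ratio is
#'   undefined.
#' @export
net_cost_per_benefit <- function(net_cost, net_benefit,
                                 negative_benefit = c("keep", "na")) {
  negative_benefit <- match.arg(negative_benefit)
  if (length(net_cost) != length(net_benefit))
    stop("net_cost and net_benefit must be paired per-run vectors of equal length")
  benefit_tg <- net_benefit / KG_PER_TG
  keep <- if (negative_benefit == "keep") benefit_tg != 0 else benefit_tg > 0
  ifelse(keep, net_cost / benefit_tg, NA_real_)
}

#' Monte Carlo economic assessment of a scenario
#'
#' Runs the carbon ledger and the cost/value model on the same draws and
#' summarizes total cost, product value, net cost and net cost per Tg
#' CO2e by median and quartiles. The per-Tg summary is reported as `NA`
#' for scenarios whose median net climate benefit is not positive (a net
#' emitter has no meaningful cost per unit of benefit).
#'
#' @param scenario a `kelp_scenario`.
#' @param registry a `kelp_registry`.
#' @param zone_table zone table covering the scenario.
#' @param n_runs Monte Carlo runs (default 10000).
#' @param seed integer seed.
#' @return a `kelp_econ` object: list with `runs` (per-run data frame),
#'   `summary` (quartile table in million CAD), `valid_fraction`
#'   (share of runs with positive net benefit), `scenario`, `n_runs`,
#'   `seed`.
#' @export
run_economics <- function(scenario, registry, zone_table,
                          n_runs = 10000L, seed = 1L) {
  draws <- draw_parameters(registry, mode = "sampled", seed = seed,
                           n = n_runs)
  ledgers <- eval_ledger(scenario, draws, zone_table)
  b_h <- as.matrix(ledgers[paste0("B_H_", SPECIES)])
  colnames(b_h) <- SPECIES
  costs <- scenario_costs(scenario, draws, b_h, zone_table)
  value <- product_values(scenario, draws, b_h)
  net_cost <- costs$total - value
  per_tg <- net_cost_per_benefit(net_cost, ledgers$net_benefit)
  runs <- data.frame(total_cost = costs$total, product_value = value,
                     net_cost = net_cost, cost_per_tg = per_tg,
                     net_benefit = ledgers$net_benefit)
  valid <- mean(ledgers$net_benefit > 0)
  q3 <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), type = 7,
                                    na.rm = TRUE)
  benefit_positive <- stats::median(ledgers$net_benefit) > 0
  summary <- rbind(total_cost = q3(costs$total),
                   product_value = q3(value),
                   net_cost = q3(net_cost),
                   cost_per_tg = if (benefit_positive) q3(per_tg)
                                 else rep(NA_real_, 3))
  summary <- data.frame(field = rownames(summary), p25 = summary[, 1],
                        median = summary[, 2], p75 = summary[, 3],
                        row.names = NULL)
  structure(list(runs = runs, summary = summary, valid_fraction = valid,
                 scenario = scenario$name, n_runs = as.integer(n_runs),
                 seed = seed),
            class = "kelp_econ")
}

#' @export
print.kelp_econ <- function(x, ...) {
  cat(sprintf("<kelp_econ> scenario: %s, %d runs (seed %s)\n", x$scenario,
              x$n_runs, format(x$seed)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    if (is.na(s$median[i])) {
      cat(sprintf("  %-14s NA\n", s$field[i]))
    } else {
      cat(sprintf("  %-14s %9.2f (%.2f-%.2f) M CAD%s\n", s$field[i],
                  s$median[i], s$p25[i], s$p75[i],
                  if (s$field[i] == "cost_per_tg") " per Tg CO2e" else ""))
    }
  }
  invisible(x)
}
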