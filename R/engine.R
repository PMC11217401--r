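#' Scenario evaluation engine
#'
#' Evaluates a scenario end-to-end: production, carbon fates, emissions and
#' the net climate benefit, either once at central parameter estimates
#' (deterministic) or as a Monte Carlo batch over sampled parameters. A
#' single evaluation yields a `carbon_ledger`; a batch yields a `kelp_run`
#' holding per-run ledgers and their percentile summary.
#'
#' Sign convention: `net_benefit = C_Total - E_Total`; positive values are
#' a net reduction in atmospheric CO2, negative values a net emitter.
#'
#' @name engine
NULL

LEDGER_FIELDS <- c("B_H_saccharina", "B_H_alaria", "B_H_nereocystis",
                   "B_H_total", "NPP", "DOC", "POC", "harvested_carbon",
                   "C_SeqP", "C_SeqA", "C_Avoid", "C_Total",
                   EMISSION_TERMS, "E_Total", "net_benefit")

# Vectorized ledger over a draw matrix: one row per draw.
eval_ledger <- function(scenario, draws, zone_table) {
  n <- if (is.matrix(draws)) nrow(draws) else 1L
  b_h <- harvested_biomass(scenario, draws)
  npp <- npp_from_harvest(b_h, draws, scenario)
  det <- detrital_fluxes(npp, draws)
  hc <- npp - det$doc - det$poc

  c_seq_p <- passive_sequestration(det$doc, det$poc, draws)
  c_seq_a <- active_sequestration(b_h, scenario$fates, draws)
  c_avoid <- avoided_emissions(b_h, scenario$fates, draws)
  c_total <- total_climate_pathways(c_seq_p, c_seq_a, c_avoid)

  farm <- farm_phase_emissions(scenario, draws, zone_table)
  post <- postharvest_emissions(scenario, draws, b_h, zone_table)
  eterms <- c(farm, post)
  e_total <- total_emissions(eterms)

  out <- data.frame(matrix(0, nrow = n, ncol = length(LEDGER_FIELDS),
                           dimnames = list(NULL, LEDGER_FIELDS)))
  for (s in colnames(b_h)) out[[paste0("B_H_", s)]] <- b_h[, s]
  out$B_H_total <- rowSums(b_h)
  out$NPP <- npp
  out$DOC <- det$doc
  out$POC <- det$poc
  out$harvested_carbon <- hc
  out$C_SeqP <- c_seq_p
  out$C_SeqA <- c_seq_a
  out$C_Avoid <- c_avoid
  out$C_Total <- c_total
  for (t in EMISSION_TERMS) out[[t]] <- eterms[[t]]
  out$E_Total <- e_total
  out$net_benefit <- c_total - e_total
  out
}

#' Deterministic scenario evaluation
#'
#' Evaluates the full carbon ledger once with every parameter at its
#' central estimate. A pure function of its inputs: repeated calls return
#' bitwise-identical ledgers.
#'
#' @param scenario a `kelp_scenario`.
#' @param registry a `kelp_registry`.
#' @param zone_table zone table covering the scenario.
#' @return a `carbon_ledger`: named numeric vector of ledger fields in kg
#'   (ww, C, or CO2e) per year.
#' @export
run_deterministic <- function(scenario, registry, zone_table) {
  draws <- draw_parameters(registry, mode = "central", n = 1L)
  led <- eval_ledger(scenario, draws, zone_table)
  structure(unlist(led[1, ]), class = "carbon_ledger",
            scenario = scenario$name)
}

#' Monte Carlo scenario evaluation
#'
#' Runs `n_runs` independent parameter draws through the full ledger and
#' summarizes every field by its median and 25th/75th percentiles.
#' Identical seeds reproduce the batch exactly.
#'
#' @param scenario a `kelp_scenario`.
#' @param registry a `kelp_registry`.
#' @param zone_table zone table covering the scenario.
#' @param n_runs number of Monte Carlo runs (default 10000).
#' @param seed integer seed.
#' @param subset optional sub-model tags / parameter ids to sample
#'   (others held at central estimates), as in [draw_parameters()].
#' @return a `kelp_run` with components `ledgers` (data frame, one row per
#'   run), `summary` (a `run_summary`), `scenario`, `n_runs`, `seed`.
#' @export
run_monte_carlo <- function(scenario, registry, zone_table,
                            n_runs = 10000L, seed = 1L, subset = NULL) {
  stopifnot(n_runs >= 1)
  draws <- draw_parameters(registry, mode = "sampled", subset = subset,
                           seed = seed, n = n_runs)
  ledgers <- eval_ledger(scenario, draws, zone_table)
  structure(list(ledgers = ledgers, summary = summarize_runs(ledgers),
                 scenario = scenario$name, n_runs = as.integer(n_runs),
                 seed = seed),
            class = "kelp_run")
}

#' Percentile summary of a ledger batch
#'
#' Median and 25th/75th percentiles of every ledger field, using linear
#' interpolation between order statistics (quantile type 7). Medians of
#' components need not sum to the median of totals.
#'
#' @param ledgers data frame of per-run ledgers (non-empty).
#' @return a `run_summary` data frame with columns `field, p25, median, p75`.
#' @export
summarize_runs <- function(ledgers) {
  if (NROW(ledgers) == 0L) stop("cannot summarize an empty run list")
  qs <- t(vapply(ledgers, stats::quantile,
                 numeric(3), probs = c(0.25, 0.5, 0.75), type = 7,
                 na.rm = FALSE))
  out <- data.frame(field = rownames(qs), p25 = qs[, 1], median = qs[, 2],
                    p75 = qs[, 3], row.names = NULL)
  class(out) <- c("run_summary", "data.frame")
  out
}

#' @export
print.carbon_ledger <- function(x, ...) {
  cat(sprintf("<carbon_ledger> scenario: %s (central estimates)\n",
              attr(x, "scenario")))
  tg <- x / KG_PER_TG
  cat(sprintf("  harvest    %10.4f Tg ww\n", tg[["B_H_total"]]))
  cat(sprintf("  C_Total    %10.4f Tg CO2e (SeqP %.4f, SeqA %.4f, Avoid %.4f)\n",
              tg[["C_Total"]], tg[["C_SeqP"]], tg[["C_SeqA"]], tg[["C_Avoid"]]))
  cat(sprintf("  E_Total    %10.4f Tg CO2e\n", tg[["E_Total"]]))
  cat(sprintf("  net        %10.4f Tg CO2e yr-1\n", tg[["net_benefit"]]))
  invisible(x)
}

#' @export
print.kelp_run <- function(x, ...) {
  cat(sprintf("<kelp_run> scenario: %s, %d Monte Carlo runs (seed %s)\n",
              x$scenario, x$n_runs, format(x$seed)))
  s <- x$summary
  show <- c("B_H_total", "C_Avoid", "C_SeqP", "C_SeqA", "E_Total",
            "net_benefit")
  for (f in show) {
    r <- s[s$field == f, ]
    unit <- if (f == "B_H_total") "Tg ww" else "Tg CO2e"
    cat(sprintf("  %-12s %8.4f (%.4f-%.4f) %s yr-1\n", f,
                r$median / KG_PER_TG, r$p25 / KG_PER_TG, r$p75 / KG_PER_TG,
                unit))
  }
  invisible(x)
}

#' @export
summary.kelp_run <- function(object, in_tg = TRUE, ...) {
  s <- object$summary
  if (in_tg) s[, c("p25", "median", "p75")] <-
      s[, c("p25", "median", "p75")] / KG_PER_TG
  s
}

#' @export
as.data.frame.kelp_run <- function(x, ...) x$ledgers

#' @export
quantile.kelp_run <- function(x, field = "net_benefit",
                              probs = c(0.25, 0.5, 0.75), ...) {
  stats::quantile(x$ledgers[[field]], probs = probs, type = 7, ...)
}

# median of a ledger field in Tg
median_tg <- function(run, field) {
  s <- run$summary
  s$median[s$field == field] / KG_PER_TG
}
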