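#' One-at-a-time sensitivity analysis
#'
#' Uncertainty attribution by sampling only a chosen sub-model's (or a
#' single parameter's) distributions while every other parameter is held
#' at its central estimate. Each run's net benefit is divided by the
#' deterministic baseline (the run with no uncertainty), giving unitless
#' relative values whose spread measures how much that target contributes
#' to overall model uncertainty. Results are scenario-specific.
#'
#' @name sensitivity
NULL

new_sensitivity <- function(target, rel, baseline, n_runs, seed, scenario) {
  structure(list(target = target, relative_net_benefit = rel,
                 baseline = baseline, n_runs = n_runs, seed = seed,
                 scenario = scenario),
            class = "kelp_sensitivity")
}

sensitivity_run <- function(scenario, registry, zone_table, target,
                            n_runs, seed) {
  base <- run_deterministic(scenario, registry, zone_table)[["net_benefit"]]
  if (base == 0) stop("deterministic baseline net benefit is zero; ",
                      "relative sensitivity undefined")
  run <- run_monte_carlo(scenario, registry, zone_table, n_runs = n_runs,
                         seed = seed, subset = target)
  new_sensitivity(target, run$ledgers$net_benefit / base, base,
                  n_runs, seed, scenario$name)
}

#' Sub-model sensitivity
#'
#' Samples only the parameters tagged with one sub-model
#' (`production`, `sequestration` or `emissions`).
#'
#' @param scenario a `kelp_scenario`.
#' @param registry a `kelp_registry`.
#' @param zone_table zone table covering the scenario.
#' @param tag sub-model tag.
#' @param n_runs Monte Carlo runs (default 10000).
#' @param seed integer seed.
#' @return a `kelp_sensitivity` with per-run relative net benefit.
#' @export
submodel_sensitivity <- function(scenario, registry, zone_table, tag,
                                 n_runs = 10000L, seed = 1L) {
  if (!tag %in% c("production", "sequestration", "emissions"))
    stop("unknown sub-model tag: ", tag)
  sensitivity_run(scenario, registry, zone_table, tag, n_runs, seed)
}

#' Single-parameter sensitivity
#'
#' Samples only one named parameter.
#'
#' @inheritParams submodel_sensitivity
#' @param name parameter identifier (or bare name matching all its
#'   species/zone variants).
#' @param n_runs Monte Carlo runs (default 1000).
#' @return a `kelp_sensitivity`.
#' @export
parameter_sensitivity <- function(scenario, registry, zone_table, name,
                                  n_runs = 1000L, seed = 1L) {
  if (!name %in% c(registry$id, registry$name))
    stop("unknown parameter: ", name)
  sensitivity_run(scenario, registry, zone_table, name, n_runs, seed)
}

#' Rank sensitivity results by spread
#'
#' Orders results by decreasing interquartile range of the relative net
#' benefit, with deterministic alphabetical tie-break on the target name.
#' All results must share the same deterministic baseline.
#'
#' @param results list of `kelp_sensitivity` objects.
#' @return data frame with columns `target, iqr, p25, median, p75`, ordered.
#' @export
rank_parameters <- function(results) {
  if (!length(results)) stop("no sensitivity results to rank")
  bases <- vapply(results, function(r) r$baseline, numeric(1))
  if (max(bases) - min(bases) > 1e-9 * max(abs(bases)))
    stop("sensitivity results have mixed baselines; rankings would not be comparable")
  rows <- lapply(results, function(r) {
    q <- stats::quantile(r$relative_net_benefit, c(0.25, 0.5, 0.75), type = 7)
    data.frame(target = r$target, iqr = q[[3]] - q[[1]], p25 = q[[1]],
               median = q[[2]], p75 = q[[3]])
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$iqr, out$target), ]
  rownames(out) <- NULL
  out
}

#' @export
print.kelp_sensitivity <- function(x, ...) {
  q <- stats::quantile(x$relative_net_benefit, c(0.25, 0.5, 0.75), type = 7)
  cat(sprintf(paste0("<kelp_sensitivity> %s on %s: %d runs, baseline %.4f ",
                     "Tg CO2e yr-1\n  relative net benefit %.3f (%.3f-%.3f),",
                     " IQR %.3f\n"),
              x$target, x$scenario, x$n_runs, x$baseline / KG_PER_TG,
              q[[2]], q[[1]], q[[3]], q[[3]] - q[[1]]))
  invisible(x)
}
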