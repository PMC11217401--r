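#' Scenario configuration
#'
#' A `kelp_scenario` encodes one industry-development scenario: the
#' cultivated area, the species mix, which production-rate set applies
#' (farmer-reported vs literature), the number of harvests per year, and
#' the fate vector of harvested biomass over
#' `near_farm_release, deep_sink, food, animal_feed, biofuel`.
#'
#' @name scenario-config
NULL

FATES <- c("near_farm_release", "deep_sink", "food", "animal_feed", "biofuel")
PRODUCT_FATES <- c("food", "animal_feed", "biofuel")
SPECIES <- c("saccharina", "alaria", "nereocystis")

#' Construct a scenario
#'
#' @param name scenario label.
#' @param area_km2 total cultivated area (km^2), > 0.
#' @param species_mix named proportions over the cultivated species, summing
#'   to 1.
#' @param rate_source `"farmer_reported"` or `"literature"`; selects which
#'   production-rate parameters apply.
#' @param harvests_per_year number of cultivation/harvest cycles per year
#'   (default 1, a single annual cycle).
#' @param fates named proportions over
#'   `near_farm_release, deep_sink, food, animal_feed, biofuel`, summing to
#'   1; omitted fates are 0.
#' @return a `kelp_scenario` object.
#' @export
kelp_scenario <- function(name, area_km2, species_mix,
                          rate_source = c("farmer_reported", "literature"),
                          harvests_per_year = 1, fates) {
  rate_source <- match.arg(rate_source)
  fv <- stats::setNames(numeric(length(FATES)), FATES)
  fv[names(fates)] <- unlist(fates)
  mix <- unlist(species_mix)
  s <- structure(list(name = name, area_km2 = as.numeric(area_km2),
                      species_mix = mix, rate_source = rate_source,
                      harvests_per_year = as.numeric(harvests_per_year),
                      fates = fv),
                 class = "kelp_scenario")
  findings <- validate_scenario(s)
  if (length(findings)) stop("invalid scenario '", name, "': ",
                             paste(findings, collapse = "; "))
  s
}

#' Validate a scenario
#'
#' Returns findings (character vector) rather than raising: an empty vector
#' means all invariants hold and, when a registry is given, that every
#' species in the mix has production parameters.
#'
#' @param s a `kelp_scenario` (or compatible list).
#' @param registry optional `kelp_registry` to cross-check species coverage.
#' @return character vector of findings, empty if valid.
#' @export
validate_scenario <- function(s, registry = NULL) {
  f <- character()
  if (!is.finite(s$area_km2) || s$area_km2 < 0)
    f <- c(f, "area_km2 must be a non-negative number")
  if (abs(sum(s$species_mix) - 1) > 1e-9)
    f <- c(f, sprintf("species_mix sums to %.6f, not 1", sum(s$species_mix)))
  if (any(s$species_mix < 0)) f <- c(f, "species_mix has negative entries")
  if (abs(sum(s$fates) - 1) > 1e-9)
    f <- c(f, sprintf("fate vector sums to %.6f, not 1", sum(s$fates)))
  if (any(s$fates < 0)) f <- c(f, "fate vector has negative entries")
  if (!is.null(names(s$fates)) && !all(names(s$fates) %in% FATES))
    f <- c(f, paste("unknown fate(s):",
                    paste(setdiff(names(s$fates), FATES), collapse = ", ")))
  if (s$harvests_per_year < 1) f <- c(f, "harvests_per_year must be >= 1")
  if (!is.null(registry)) {
    rate_name <- if (s$rate_source == "literature") "rate_literature" else "rate_farmer"
    for (sp in names(s$species_mix)[s$species_mix > 0]) {
      for (nm in c(rate_name, "dw_frac", "c_frac")) {
        if (!param_id(nm, sp) %in% registry$id)
          f <- c(f, sprintf("no %s parameter for species '%s'", nm, sp))
      }
    }
  }
  f
}

#' @export
print.kelp_scenario <- function(x, ...) {
  cat(sprintf("<kelp_scenario> %s: %g km2, rates %s, %g harvest(s)/yr\n",
              x$name, x$area_km2, x$rate_source, x$harvests_per_year))
  mix <- paste(sprintf("%s %.0f%%", names(x$species_mix), 100 * x$species_mix),
               collapse = ", ")
  fat <- x$fates[x$fates > 0]
  cat("  mix: ", mix, "\n  fates: ",
      paste(sprintf("%s %.0f%%", names(fat), 100 * fat), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Load scenarios from a YAML file
#'
#' The scenario file holds one document per scenario with keys `name`,
#' `area_km2`, `species_mix`, `rate_source`, `harvests_per_year`, `fates`.
#'
#' @param path YAML file path.
#' @return named list of `kelp_scenario` objects.
#' @seealso [write_scenarios()], [default_scenarios()]
#' @export
load_scenarios <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  docs <- yaml::read_yaml(path)
  if (!is.null(docs$name)) docs <- list(docs)  # single scenario file
  out <- lapply(docs, function(d) {
    kelp_scenario(d$name, d$area_km2, d$species_mix, d$rate_source,
                  if (is.null(d$harvests_per_year)) 1 else d$harvests_per_year,
                  d$fates)
  })
  stats::setNames(out, vapply(out, function(s) s$name, ""))
}

#' Write scenarios to a YAML file
#'
#' Round-trips with [load_scenarios()]: writing then reading reproduces
#' identical scenario values.
#'
#' @param scenarios list of `kelp_scenario` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scenarios <- function(scenarios, path) {
  docs <- lapply(unname(scenarios), function(s) {
    list(name = s$name, area_km2 = s$area_km2,
         species_mix = as.list(s$species_mix),
         rate_source = s$rate_source,
         harvests_per_year = s$harvests_per_year,
         fates = as.list(s$fates[s$fates > 0]))
  })
  yaml::write_yaml(docs, path, precision = 15)
  invisible(path)
}
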