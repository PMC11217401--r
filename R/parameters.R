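#' Parameter registry: load, validate and sample model parameters
#'
#' A `kelp_registry` is a data frame with one row per model parameter. Each
#' row records the parameter's name, optional species and zone tags, its
#' sub-model (`production`, `sequestration`, `emissions` or `economics`), a
#' central estimate and a sampling distribution. The distribution columns
#' `p1,p2,p3` are interpreted per family: sd for (truncated) normal;
#' min,max for uniform; min,mode,max for triangular.
#'
#' @name parameter-registry
NULL

REGISTRY_COLS <- c("name", "symbol", "submodel", "species", "zone", "units",
                   "dist_kind", "central", "p1", "p2", "p3", "truncated",
                   "source")
SUBMODELS <- c("production", "sequestration", "emissions", "economics")

#' Fully qualified parameter identifier
#'
#' Parameters are identified by `name`, qualified with the species and/or
#' zone tag where present, joined by dots (e.g. `rate_farmer.saccharina`,
#' `capital_steel.deep`).
#'
#' @param name,species,zone character vectors (species/zone may be `NA` or
#'   empty for untagged parameters).
#' @return character vector of identifiers.
#' @export
param_id <- function(name, species = NA, zone = NA) {
  tag <- function(x) ifelse(is.na(x) | x == "", "", paste0(".", x))
  paste0(name, tag(species), tag(zone))
}

new_registry <- function(df) {
  df$species <- as.character(df$species)
  df$zone <- as.character(df$zone)
  df$id <- param_id(df$name, df$species, df$zone)
  rownames(df) <- NULL
  class(df) <- c("kelp_registry", "data.frame")
  df
}

#' Validate a parameter registry
#'
#' Checks the structural invariants: finite central values, known
#' distribution kinds and sub-models, distribution-specific parameter
#' ordering (min <= mode/central <= max), and uniqueness of the qualified
#' identifier.
#'
#' @param reg a `kelp_registry` or plain data frame with the registry columns.
#' @return the validated registry, invisibly classed; errors name the
#'   offending row and column.
#' @export
validate_registry <- function(reg) {
  missing_cols <- setdiff(REGISTRY_COLS, names(reg))
  if (length(missing_cols))
    stop("parameter table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(reg) == 0L) stop("parameter table is empty")
  reg <- new_registry(as.data.frame(reg))

  bad_row <- function(i, msg) stop(sprintf("parameter row %d (%s): %s",
                                           i, reg$id[i], msg))
  dup <- duplicated(reg$id)
  if (any(dup)) bad_row(which(dup)[1], "duplicate (name, species, zone)")
  for (i in seq_len(nrow(reg))) {
    if (!is.finite(reg$central[i])) bad_row(i, "central is not finite")
    if (!reg$dist_kind[i] %in% DIST_KINDS)
      bad_row(i, paste0("unknown dist_kind '", reg$dist_kind[i], "'"))
    if (!reg$submodel[i] %in% SUBMODELS)
      bad_row(i, paste0("unknown submodel '", reg$submodel[i], "'"))
    k <- reg$dist_kind[i]
    if (k %in% c("normal", "truncated_normal")) {
      if (!is.finite(reg$p1[i]) || reg$p1[i] < 0) bad_row(i, "sd (p1) must be >= 0")
    } else if (k == "uniform") {
      if (!is.finite(reg$p1[i]) || !is.finite(reg$p2[i]))
        bad_row(i, "uniform needs finite min (p1) and max (p2)")
      if (reg$p1[i] > reg$p2[i]) bad_row(i, "uniform min > max")
      if (reg$central[i] < reg$p1[i] || reg$central[i] > reg$p2[i])
        bad_row(i, "central outside [min, max]")
    } else if (k == "triangular") {
      if (any(!is.finite(c(reg$p1[i], reg$p2[i], reg$p3[i]))))
        bad_row(i, "triangular needs finite min, mode, max (p1..p3)")
      if (reg$p1[i] > reg$p2[i] || reg$p2[i] > reg$p3[i])
        bad_row(i, "triangular requires min <= mode <= max")
      if (reg$central[i] < reg$p1[i] || reg$central[i] > reg$p3[i])
        bad_row(i, "central outside [min, max]")
    }
  }
  reg
}

#' Load a parameter table from CSV
#'
#' Reads the comma-separated parameter schema
#' `name,symbol,submodel,species,zone,units,dist_kind,central,p1,p2,p3,truncated,source`
#' and returns a validated registry. No partial registry is returned on
#' failure.
#'
#' @param path path to the CSV file.
#' @return a `kelp_registry`.
#' @seealso [write_parameter_table()], [default_registry()]
#' @export
load_parameter_table <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", "")),
    error = function(e) stop("malformed parameter CSV: ", conditionMessage(e))
  )
  if (nrow(df) == 0L) stop("parameter table is empty: ", path)
  df$truncated <- as.logical(df$truncated)
  validate_registry(df)
}

#' Write a parameter table to CSV
#'
#' @param reg a `kelp_registry`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(reg, path) {
  utils::write.csv(reg[, REGISTRY_COLS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.kelp_registry <- function(x, ...) {
  cat(sprintf("<kelp_registry> %d parameters (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(table(x$submodel)),
                            as.integer(table(x$submodel))), collapse = ", ")))
  src <- table(x$source)
  cat("  provenance:", paste(sprintf("%s %d", names(src), as.integer(src)),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Draw realized parameter values
#'
#' Produces `n` realizations of every registered parameter. In `central`
#' mode every value equals its central estimate. In `sampled` mode the
#' parameters selected by `subset` follow their distributions while all
#' others stay at their central estimate; `subset = NULL` samples everything.
#' Each parameter has its own uniform stream keyed on (`seed`, identifier),
#' so a one-at-a-time draw of parameter `p` reproduces exactly the values
#' `p` takes in a full draw with the same seed.
#'
#' @param reg a `kelp_registry`.
#' @param mode `"central"` or `"sampled"`.
#' @param subset optional character vector of sub-model tags and/or
#'   parameter identifiers restricting which parameters are sampled.
#' @param seed integer seed for the draw.
#' @param n number of realizations (rows).
#' @return a `kelp_draws` numeric matrix, `n` rows by one column per
#'   parameter identifier, with attributes `mode` and `seed`.
#' @export
draw_parameters <- function(reg, mode = c("central", "sampled"),
                            subset = NULL, seed = 1L, n = 1L) {
  mode <- match.arg(mode)
  ids <- reg$id
  if (!is.null(subset)) {
    known <- subset %in% c(SUBMODELS, ids, reg$name)
    if (!all(known))
      stop("unknown subset name(s): ", paste(subset[!known], collapse = ", "))
    sampled <- reg$submodel %in% subset | ids %in% subset | reg$name %in% subset
  } else {
    sampled <- rep(TRUE, nrow(reg))
  }
  m <- matrix(rep(reg$central, each = n), nrow = n, dimnames = list(NULL, ids))
  if (mode == "sampled") {
    for (i in which(sampled & reg$dist_kind != "point")) {
      u <- param_uniforms(seed, ids[i], n)
      m[, i] <- quantile_for_spec(u, reg$dist_kind[i], reg$central[i],
                                  reg$p1[i], reg$p2[i], reg$p3[i],
                                  isTRUE(reg$truncated[i]))
    }
  }
  structure(m, mode = mode, seed = seed, class = c("kelp_draws", class(m)))
}

# Column accessor tolerant of single-draw vectors
draw_col <- function(draws, id) {
  if (is.matrix(draws)) {
    if (!id %in% colnames(draws)) stop("parameter not found in draw: ", id)
    draws[, id]
  } else {
    if (!id %in% names(draws)) stop("parameter not found in draw: ", id)
    unname(draws[id])
  }
}

#' Zone tables and zonal averaging
#'
#' A zone table is a data frame with columns `scenario`, `zone`, `area_km2`,
#' plus optionally one column per zoned parameter holding fixed per-zone
#' values. Spatially varying parameters (e.g. transport distance between
#' port and farm) are combined into a single effective value per scenario by
#' area weighting over its zones.
#'
#' @param zone_table data frame as above.
#' @param scenario scenario name to subset on, or `NULL` if `zone_table`
#'   already holds a single scenario.
#' @param parameter bare parameter name; per-zone values are taken from a
#'   matching `zone_table` column if present, otherwise from zone-tagged
#'   entries (`parameter.zone`) of `draws`.
#' @param draws optional draw matrix/vector supplying sampled zone values.
#' @return area-weighted average; a vector of length `n` when `draws` has
#'   `n` rows.
#' @examples
#' zt <- data.frame(scenario = "s", zone = c("a", "b"),
#'                  area_km2 = c(100, 300), depth = c(10, 20))
#' zonal_average(zt, "s", "depth")  # 17.5
#' @export
zonal_average <- function(zone_table, scenario = NULL, parameter, draws = NULL) {
  zt <- zone_table
  if (!is.null(scenario)) zt <- zt[zt$scenario == scenario, , drop = FALSE]
  if (nrow(zt) == 0L) stop("no zones for scenario: ", scenario)
  if (any(zt$area_km2 < 0)) stop("zone areas must be >= 0")
  zt <- zt[zt$area_km2 > 0, , drop = FALSE]
  if (nrow(zt) == 0L) stop("scenario has zero total area across zones")
  w <- zt$area_km2 / sum(zt$area_km2)
  if (parameter %in% names(zt)) {
    vals <- zt[[parameter]]
    if (anyNA(vals))
      stop("missing value for parameter '", parameter, "' in zone(s): ",
           paste(zt$zone[is.na(vals)], collapse = ", "))
    return(drop(sum(w * vals)))
  }
  if (is.null(draws))
    stop("parameter '", parameter, "' not in zone table and no draws supplied")
  acc <- 0
  for (k in seq_len(nrow(zt))) {
    id <- param_id(parameter, zone = zt$zone[k])
    acc <- acc + w[k] * draw_col(draws, id)
  }
  acc
}

#' Load a zone table from CSV
#'
#' @param path CSV with columns `scenario,zone,area_km2` plus optional
#'   per-zone parameter columns.
#' @return a data frame; duplicate zone tags within a scenario are rejected.
#' @export
load_zone_table <- function(path) {
  if (!file.exists(path)) stop("zone table not found: ", path)
  zt <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("scenario", "zone", "area_km2")
  if (!all(need %in% names(zt)))
    stop("zone table must have columns: ", paste(need, collapse = ", "))
  key <- paste(zt$scenario, zt$zone)
  if (anyDuplicated(key))
    stop("duplicate zone tag within a scenario: ", key[duplicated(key)][1])
  zt
}
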