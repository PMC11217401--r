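# shared fixtures for the suite: built once, used read-only
REG <- default_registry()
SCN <- default_scenarios()
ZON <- default_zone_table()

# registry with every distribution collapsed to its central estimate
point_registry <- function(reg = REG) {
  reg$dist_kind <- "point"
  reg$p1 <- reg$p2 <- reg$p3 <- NA_real_
  validate_registry(reg)
}

# single-draw named vector at central values, with optional overrides
central_draw <- function(overrides = NULL, reg = REG) {
  d <- draw_parameters(reg, mode = "central", n = 1L)
  v <- stats::setNames(as.numeric(d[1, ]), colnames(d))
  if (!is.null(overrides)) v[names(overrides)] <- overrides
  v
}

median_of <- function(run, field) {
  run$summary$median[run$summary$field == field]
}

# independent sort-based type-7 quantile (oracle for summarize_runs)
sort_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- pmin(lo + 1, n)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
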