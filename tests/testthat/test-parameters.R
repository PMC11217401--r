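test_that("default registry loads, validates and round-trips through CSV", {
  expect_s3_class(REG, "kelp_registry")
  expect_equal(nrow(REG), 81L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_parameter_table(REG, path)
  reg2 <- load_parameter_table(path)
  expect_equal(reg2$id, REG$id)
  expect_equal(reg2$central, REG$central)
  expect_equal(reg2$p1, REG$p1)
  expect_equal(reg2$source, REG$source)
})

test_that("malformed parameter tables are rejected without partial registries", {
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(c("name", "symbol", "submodel", "species", "zone", "units",
                     "dist_kind", "central", "p1", "p2", "p3", "truncated",
                     "source"), collapse = ","), empty)
  expect_error(load_parameter_table(empty), "empty")
  expect_error(load_parameter_table(tempfile()), "not found")

  bad <- REG
  i <- which(bad$name == "fl_doc")
  bad$p1[i] <- 0.5  # uniform with min > max
  bad$p2[i] <- 0.2
  expect_error(validate_registry(bad), "min > max")
  expect_error(validate_registry(bad), as.character(i))  # names the row

  dup <- rbind(REG, REG[1, ])
  expect_error(validate_registry(dup), "duplicate")

  neg <- REG
  neg$central[2] <- NaN
  expect_error(validate_registry(neg), "not finite")
})

test_that("central mode returns exactly the central estimates", {
  d <- draw_parameters(REG, mode = "central", seed = 99L, n = 3L)
  expect_equal(dim(d), c(3L, 81L))
  for (j in seq_len(ncol(d))) expect_equal(unname(d[, j]), rep(REG$central[j], 3))
})

test_that("sampling is reproducible and seed-sensitive", {
  d1 <- draw_parameters(REG, "sampled", seed = 7L, n = 50L)
  d2 <- draw_parameters(REG, "sampled", seed = 7L, n = 50L)
  d3 <- draw_parameters(REG, "sampled", seed = 8L, n = 50L)
  expect_identical(unclass(d1)[, ], unclass(d2)[, ])
  expect_gt(sum(d1 != d3), 0)
})

test_that("subset sampling holds other parameters at central and reuses streams", {
  full <- draw_parameters(REG, "sampled", seed = 11L, n = 100L)
  sub <- draw_parameters(REG, "sampled", subset = "production",
                         seed = 11L, n = 100L)
  prod_ids <- REG$id[REG$submodel == "production"]
  other_ids <- setdiff(REG$id, prod_ids)
  # identical streams for the sampled subset
  expect_identical(sub[, prod_ids], full[, prod_ids])
  # everything else pinned to centrals
  for (id in other_ids)
    expect_equal(unname(sub[, id]), rep(REG$central[REG$id == id], 100))
  # single-parameter subset by qualified id
  one <- draw_parameters(REG, "sampled", subset = "rate_farmer.saccharina",
                         seed = 11L, n = 100L)
  expect_identical(one[, "rate_farmer.saccharina"],
                   full[, "rate_farmer.saccharina"])
  expect_error(draw_parameters(REG, "sampled", subset = "no_such_param"),
               "unknown subset")
})

test_that("sampled distributions match analytic moments within 3 standard errors", {
  n <- 1e5
  d <- draw_parameters(REG, "sampled", seed = 3L, n = n)
  check_moments <- function(id, mean_true, var_true) {
    x <- d[, id]
    se_mean <- sqrt(var_true / n)
    expect_lt(abs(mean(x) - mean_true), 3 * se_mean)
  }
  # uniform: fl_doc ~ U(0.14, 0.32)
  check_moments("fl_doc", (0.14 + 0.32) / 2, (0.32 - 0.14)^2 / 12)
  # triangular: sink_distance ~ Tri(70, 100, 130)
  check_moments("sink_distance", (70 + 100 + 130) / 3,
                (70^2 + 100^2 + 130^2 - 70 * 100 - 70 * 130 - 100 * 130) / 18)
  # zero-truncated normal: dw_frac saccharina ~ N(0.15, 0.02) | x >= 0
  a <- (0 - 0.15) / 0.02
  lam <- dnorm(a) / (1 - pnorm(a))
  m_tn <- 0.15 + 0.02 * lam
  v_tn <- 0.02^2 * (1 + a * lam - lam^2)
  check_moments("dw_frac.saccharina", m_tn, v_tn)
})

test_that("triangular sampling recovers the analytic mean (toy spec example)", {
  toy <- validate_registry(data.frame(
    name = "t", symbol = "t", submodel = "production", species = NA, zone = NA,
    units = "u", dist_kind = "triangular", central = 1, p1 = 0, p2 = 1, p3 = 2,
    truncated = TRUE, source = "placeholder"))
  x <- draw_parameters(toy, "sampled", seed = 1L, n = 1e5)[, 1]
  expect_lt(abs(mean(x) - 1), 0.01)
})

test_that("truncated parameters never go negative over a million draws", {
  tn_rows <- REG[REG$dist_kind == "truncated_normal" &
                   REG$p1 > 0.5 * REG$central, ]
  tn_rows <- validate_registry(tn_rows)
  d <- draw_parameters(tn_rows, "sampled", seed = 17L, n = 1e6)
  expect_true(all(d >= 0))
  # and the wide parent normals really would have gone negative
  expect_gt(mean(d[, "rate_farmer.saccharina"] < 1e-3), 0)
})

test_that("zonal averaging is an area-weighted mean", {
  zt <- data.frame(scenario = "s", zone = c("a", "b"),
                   area_km2 = c(100, 300), depth = c(10, 20))
  expect_equal(zonal_average(zt, "s", "depth"), 17.5)
  one <- data.frame(scenario = "s", zone = "a", area_km2 = 507, v = 3.21)
  expect_equal(zonal_average(one, "s", "v"), 3.21)
  eq <- data.frame(scenario = "s", zone = c("a", "b"), area_km2 = c(5, 5),
                   v = c(2, 8))
  expect_equal(zonal_average(eq, "s", "v"), 5)
  # zone-tagged parameters resolved from draws
  d <- central_draw()
  pd <- zonal_average(ZON, "Expanded", "port_distance", d)
  expect_equal(pd, (507 * 25 + 703 * 40) / 1210)
  # missing value errors name the zone
  miss <- data.frame(scenario = "s", zone = c("a", "b"), area_km2 = c(1, 1),
                     v = c(1, NA))
  expect_error(zonal_average(miss, "s", "v"), "zone")
})
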