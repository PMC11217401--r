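test_that("targets with no uncertainty give relative net benefit identically 1", {
  preg <- point_registry()
  s <- submodel_sensitivity(SCN$Expanded, preg, ZON, "production",
                            n_runs = 200L, seed = 2L)
  expect_equal(unique(s$relative_net_benefit), 1)
  expect_equal(s$baseline,
               run_deterministic(SCN$Expanded, preg, ZON)[["net_benefit"]])
  # single point-distribution parameter in an otherwise sampled registry
  p <- parameter_sensitivity(SCN$Expanded, REG, ZON, "c_to_co2",
                             n_runs = 200L, seed = 2L)
  expect_equal(unique(p$relative_net_benefit), 1)
  expect_error(submodel_sensitivity(SCN$Expanded, REG, ZON, "economics"),
               "unknown sub-model")
  expect_error(parameter_sensitivity(SCN$Expanded, REG, ZON, "nope"),
               "unknown parameter")
})

test_that("sensitivity runs never mutate the registry", {
  before <- REG
  invisible(submodel_sensitivity(SCN$Expanded, REG, ZON, "sequestration",
                                 n_runs = 100L, seed = 3L))
  invisible(parameter_sensitivity(SCN$Expanded, REG, ZON, "fl_doc",
                                  n_runs = 100L, seed = 3L))
  expect_identical(REG, before)
})

test_that("production uncertainty dominates, then sequestration, then emissions", {
  iqr <- function(tag) {
    s <- submodel_sensitivity(SCN$Expanded, REG, ZON, tag,
                              n_runs = 3000L, seed = 14L)
    diff(stats::quantile(s$relative_net_benefit, c(0.25, 0.75), type = 7))
  }
  spread <- vapply(c("production", "sequestration", "emissions"), iqr, 1)
  expect_true(spread[["production"]] > spread[["sequestration"]])
  expect_true(spread[["sequestration"]] > spread[["emissions"]])
})

test_that("sampling the union of the three sub-models reproduces the full model spread", {
  full <- run_monte_carlo(SCN$Expanded, REG, ZON, n_runs = 2000L, seed = 15L)
  union <- run_monte_carlo(SCN$Expanded, REG, ZON, n_runs = 2000L, seed = 15L,
                           subset = c("production", "sequestration",
                                      "emissions"))
  # economics parameters do not enter the carbon ledger, so the union of the
  # three climate sub-models is the full model
  expect_equal(union$ledgers, full$ledgers, tolerance = 1e-12)
})

test_that("a model linear in one uniform parameter has the analytic relative spread", {
  reg <- point_registry()
  i <- which(reg$name == "repl_factor_food")
  reg$dist_kind[i] <- "uniform"
  c0 <- reg$central[i]
  reg$p1[i] <- 0.5 * c0
  reg$p2[i] <- 1.5 * c0
  reg <- validate_registry(reg)
  base <- run_deterministic(SCN$Expanded, reg, ZON)[["net_benefit"]]
  # elasticity from an independent finite difference
  up <- reg
  up$central[i] <- c0 * 1.01
  slope <- (run_deterministic(SCN$Expanded, validate_registry(up),
                              ZON)[["net_benefit"]] - base) / (0.01 * c0)
  s <- parameter_sensitivity(SCN$Expanded, reg, ZON, "repl_factor_food",
                             n_runs = 20000L, seed = 16L)
  got_iqr <- diff(stats::quantile(s$relative_net_benefit, c(0.25, 0.75),
                                  type = 7))
  want_iqr <- slope * (0.5 * c0) / base  # IQR of U(0.5c, 1.5c) is c/2
  expect_equal(unname(got_iqr), want_iqr, tolerance = 0.02)
})

test_that("key parameters reproduce the reported sensitivity magnitudes", {
  s_rate <- parameter_sensitivity(SCN$Expanded, REG, ZON,
                                  "rate_farmer.saccharina",
                                  n_runs = 1000L, seed = 17L)
  # some draws push net benefit beyond four times the no-uncertainty baseline
  expect_gt(max(s_rate$relative_net_benefit), 4)
  s_food <- parameter_sensitivity(SCN$Expanded, REG, ZON, "repl_factor_food",
                                  n_runs = 1000L, seed = 17L)
  # the food replacement factor alone swings net benefit beyond +/- 50%
  expect_gt(max(s_food$relative_net_benefit), 1.5)
  expect_lt(min(s_food$relative_net_benefit), 0.5)
})

test_that("ranking orders by IQR with deterministic tie-breaks", {
  mk <- function(target, rel) {
    s <- submodel_sensitivity(SCN$Expanded, point_registry(), ZON,
                              "production", n_runs = 4L, seed = 1L)
    s$target <- target
    s$relative_net_benefit <- rel
    s
  }
  r <- rank_parameters(list(mk("narrow", c(0.95, 1, 1, 1.05)),
                            mk("wide", c(0.5, 1, 1, 1.5)),
                            mk("b_flat", rep(1, 4)),
                            mk("a_flat", rep(1, 4))))
  expect_equal(r$target, c("wide", "narrow", "a_flat", "b_flat"))
  # stable under permutation of the input list
  r2 <- rank_parameters(list(mk("a_flat", rep(1, 4)),
                             mk("wide", c(0.5, 1, 1, 1.5)),
                             mk("b_flat", rep(1, 4)),
                             mk("narrow", c(0.95, 1, 1, 1.05))))
  expect_equal(r2, r)
  bad <- mk("other", rep(1, 4))
  bad$baseline <- bad$baseline * 2
  expect_error(rank_parameters(list(mk("x", rep(1, 4)), bad)),
               "mixed baselines")
})
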