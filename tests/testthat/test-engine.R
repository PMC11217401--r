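test_that("deterministic evaluation is pure and internally consistent", {
  l1 <- run_deterministic(SCN$Expanded, REG, ZON)
  l2 <- run_deterministic(SCN$Expanded, REG, ZON)
  expect_identical(l1, l2)
  expect_equal(l1[["net_benefit"]], l1[["C_Total"]] - l1[["E_Total"]])
  expect_equal(l1[["C_Total"]],
               l1[["C_SeqP"]] + l1[["C_SeqA"]] + l1[["C_Avoid"]])
  expect_equal(l1[["B_H_total"]],
               l1[["B_H_saccharina"]] + l1[["B_H_alaria"]] +
                 l1[["B_H_nereocystis"]])
})

test_that("a zero-area scenario yields an all-zero ledger", {
  s <- kelp_scenario("empty", 0,
                     c(saccharina = 0.8, alaria = 0.1, nereocystis = 0.1),
                     "farmer_reported", fates = c(food = 1))
  zt <- data.frame(scenario = "empty", zone = "shallow", area_km2 = 0)
  led <- run_deterministic(s, REG, zt)
  expect_true(all(led == 0))
})

test_that("Monte Carlo runs are reproducible and degenerate correctly", {
  r1 <- run_monte_carlo(SCN$Expanded, REG, ZON, n_runs = 500L, seed = 4L)
  r2 <- run_monte_carlo(SCN$Expanded, REG, ZON, n_runs = 500L, seed = 4L)
  expect_identical(r1$ledgers, r2$ledgers)
  expect_identical(r1$summary, r2$summary)
  r3 <- run_monte_carlo(SCN$Expanded, REG, ZON, n_runs = 500L, seed = 5L)
  expect_false(identical(r1$ledgers, r3$ledgers))
  # all-point registry: a single Monte Carlo run equals the deterministic run
  preg <- point_registry()
  mc1 <- run_monte_carlo(SCN$Expanded, preg, ZON, n_runs = 1L, seed = 9L)
  det <- run_deterministic(SCN$Expanded, preg, ZON)
  expect_equal(unlist(mc1$ledgers[1, ]), unclass(det)[names(det)])
  # and n runs have zero variance
  mc <- run_monte_carlo(SCN$Expanded, preg, ZON, n_runs = 50L, seed = 9L)
  expect_equal(unname(vapply(mc$ledgers, stats::sd, 1)),
               rep(0, ncol(mc$ledgers)))
})

test_that("summaries match an independent sort-based percentile oracle", {
  set.seed(88)
  x <- rlnorm(1000, 1, 0.8)
  df <- data.frame(net_benefit = x)
  s <- summarize_runs(df)
  for (p in c(0.25, 0.5, 0.75)) {
    col <- c("0.25" = "p25", "0.5" = "median", "0.75" = "p75")[[as.character(p)]]
    expect_equal(s[[col]], sort_quantile(x, p), tolerance = 1e-12)
  }
  expect_equal(summarize_runs(data.frame(net_benefit = c(1, 2, 3)))$median, 2)
  cst <- summarize_runs(data.frame(net_benefit = rep(7, 10)))
  expect_equal(cst$p25, cst$p75)
  expect_error(summarize_runs(data.frame()), "empty")
  r <- run_monte_carlo(SCN$Expanded, REG, ZON, n_runs = 1000L, seed = 10L)
  expect_equal(median_cmp <- r$summary$median[r$summary$field == "net_benefit"],
               sort_quantile(r$ledgers$net_benefit, 0.5))
})

test_that("the Monte Carlo median of a linear one-normal-parameter model recovers the central value", {
  # only the harvest transport factor varies, normally and far from zero:
  # net benefit is then an affine function of a single normal parameter, so
  # its Monte Carlo median estimates the deterministic value
  reg <- point_registry()
  i <- which(reg$name == "swtrans_em_per_kg_km")
  reg$dist_kind[i] <- "normal"
  reg$truncated[i] <- FALSE
  reg$p1[i] <- 0.1 * reg$central[i]
  reg <- validate_registry(reg)
  det <- run_deterministic(SCN$Expanded, reg, ZON)[["net_benefit"]]
  n <- 10000L
  r <- run_monte_carlo(SCN$Expanded, reg, ZON, n_runs = n, seed = 12L)
  x <- r$ledgers$net_benefit
  # se of the median of a normal sample: 1.2533 * sd / sqrt(n)
  se_med <- 1.2533 * stats::sd(x) / sqrt(n)
  expect_lt(abs(median_of(r, "net_benefit") - det), 3 * se_med)
})

test_that("median net benefit orders the scenarios as industry develops", {
  meds <- vapply(SCN, function(s)
    median_of(run_monte_carlo(s, REG, ZON, n_runs = 3000L, seed = 6L),
              "net_benefit"), 1)
  expect_true(meds[["Techno Industrial"]] > meds[["Expanded-Optimized"]])
  expect_true(meds[["Expanded-Optimized"]] > meds[["Expanded"]])
  expect_true(meds[["Expanded"]] > meds[["Local-Products"]])
  expect_true(meds[["Local-Products"]] > meds[["Local-No Harvest"]])
  expect_lt(meds[["Local-No Harvest"]], 0)
})
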