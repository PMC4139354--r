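test_that("a fixed-point run is steady from the start", {
  spec <- model_spec("verhulst", P0 = 7e9, K0 = 7e9, r_soc = 1e-13,
                     t_end = 50L)
  tr <- simulate_model(spec)
  expect_true(all(tr$points$dP == 0))
  eq <- summarize_equilibrium(tr)
  expect_true(eq$reached)
  expect_identical(eq$year_of_steady_state, 1L)
  expect_false(eq$oscillating)
})

test_that("the OC benchmark run reaches its steady state by 2500", {
  an <- bundled_cases("oc")[2, ]
  spec <- model_spec("oc", P0 = an$P0, K0 = 2 * an$P0, r_soc = an$r_soc,
                     L = an$L)
  cal <- calibrate_K0(spec, 1800, an$P_1800)
  eq <- summarize_equilibrium(simulate_model(cal$spec), threshold = 1e-2)
  expect_true(eq$reached)
  expect_lt(rel_err(eq$P_infinity, 286e9), 0.02)
})

test_that("equilibrium summary is monotone in the threshold", {
  tr <- simulate_model(tiny_oc())
  loose <- summarize_equilibrium(tr, threshold = 1e-2)
  tight <- summarize_equilibrium(tr, threshold = 1e-6)
  if (loose$reached && tight$reached) {
    expect_lte(loose$year_of_steady_state, tight$year_of_steady_state)
  }
  expect_true(loose$reached)
})

test_that("boom-bust regimes are flagged as oscillating, not steady", {
  # population-dependent cost tuned so K repeatedly crosses P: while the
  # run is still inside the boom-bust window no steady state is declared
  spec <- model_spec("cc_m", P0 = 1e9, K0 = 5e9, r_soc = 1e-11, L = 2e10,
                     a = 5e-12, b = 1.5, t0 = 1L, t_end = 30L)
  eq <- summarize_equilibrium(simulate_model(spec))
  expect_false(eq$reached)
  expect_true(eq$oscillating)
  expect_gt(eq$n_dP_sign_changes, 1)
  # the same system run to 2000 damps into a (weak) steady state
  eq2 <- summarize_equilibrium(simulate_model(update_spec(spec,
                                                          t_end = 2000L)))
  expect_true(eq2$reached)
  expect_true(eq2$oscillating)
})

test_that("elasticity series follows the D7 missing-value convention", {
  tr <- simulate_model(tiny_oc(t_end = 500L))
  s <- elasticity_series(tr)
  expect_identical(names(s), c("year", "c_realized", "pct_growth"))
  expect_identical(s$c_realized, tr$spec$L / tr$points$P)
  # a fixed-point year has dP = 0 and an empty elasticity cell
  fp <- simulate_model(model_spec("verhulst", P0 = 1e9, K0 = 1e9,
                                  r_soc = 1e-13, t_end = 10L))
  expect_true(all(is.na(elasticity_series(fp)$c_realized)))
})

test_that("the identified cost law drives elasticity negative near equilibrium", {
  an <- bundled_cases("cc")[1, ]
  spec <- model_spec("cc_m", P0 = an$P0, K0 = 2 * an$P0, r_soc = an$r_soc,
                     L = an$L, a = an$a, b = an$b)
  cal <- calibrate_K0(spec, 1800, an$P_1800)
  tr <- simulate_model(cal$spec)
  s <- elasticity_series(tr)
  late <- s$c_realized[s$year >= 2200]
  expect_true(all(late < 0, na.rm = TRUE))
  # and carrying capacity peaks then declines
  eq <- summarize_equilibrium(tr)
  expect_lt(eq$peak_K[["year"]], 2500)
  expect_lt(eq$K_infinity, eq$peak_K[["K"]])
})

test_that("pct_error_2012 is the signed deviation from 7.00e9", {
  at_level <- function(p) {
    simulate_model(model_spec("verhulst", P0 = p, K0 = p,
                              r_soc = 1e-13, t_end = 2012L))
  }
  expect_equal(pct_error_2012(at_level(7.00e9)), 0, tolerance = 1e-10)
  expect_equal(pct_error_2012(at_level(7.5609e9)), 8.0129, tolerance = 1e-4)
  expect_equal(pct_error_2012(at_level(6.7968e9)), -2.9029, tolerance = 1e-4)
  expect_error(pct_error_2012(simulate_model(tiny_oc(t_end = 100L))),
               class = "ccpop_state_error")
})

test_that("un_range_check brackets 2100 populations inclusively", {
  at_level <- function(p) {
    simulate_model(model_spec("verhulst", P0 = p, K0 = p,
                              r_soc = 1e-13, t_end = 2100L))
  }
  expect_true(un_range_check(at_level(1.4505e10))$within)
  expect_false(un_range_check(at_level(7.8536e10))$within)
  edge <- un_range_check(at_level(17e9))
  expect_true(edge$within)
  expect_equal(edge$margin, 0, tolerance = 1e-9)
  expect_lt(un_range_check(at_level(5e9))$margin, 0)
})

test_that("write_report emits the bundle without re-simulating", {
  dir <- tempfile()
  on.exit(unlink(dir, recursive = TRUE))
  obs <- table1_observations()
  tr <- simulate_model(tiny_oc())
  write_report(tr, dir, obs = obs)
  expect_true(file.exists(file.path(dir, "trajectory.csv")))
  kv <- readLines(file.path(dir, "summary.txt"))
  expect_true(any(grepl("^d_avg_log10=", kv)))
  expect_true(any(grepl("^pct_error_2012=", kv)))
  # report quantities are pure functions of the trajectory
  expect_identical(pct_error_2012(tr), pct_error_2012(tr))
})

test_that("overlay import accepts year/value CSVs only", {
  p <- tempfile(fileext = ".csv")
  on.exit(unlink(p))
  writeLines(c("year,value", "1000,0.2", "1100,0.3"), p)
  ov <- read_overlay(p)
  expect_identical(names(ov), c("year", "value"))
  writeLines(c("a,b", "1,2"), p)
  expect_error(read_overlay(p), class = "ccpop_data_error")
})
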