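test_that("aerobic uptake reproduces the printed worked example", {
  r <- cycle_records("Run 4", 85, aerobic_influent_p = 50,
                     aerobic_effluent_p = 48.8)
  expect_equal(as.numeric(aerobic_uptake(r)), 3.24 * (9 / 24) * 1.2,
               tolerance = 1e-12)
  expect_equal(as.numeric(aerobic_uptake(r)), 1.458)

  flat <- cycle_records("x", 1, 5, 5)
  expect_equal(as.numeric(aerobic_uptake(flat)), 0)

  neg <- cycle_records("x", 1, 5, 6)
  u <- aerobic_uptake(neg)
  expect_lt(as.numeric(u), 0)
  expect_true(attr(u, "flagged"))
  expect_identical(attr(u, "flag"), "release-during-aerobic")
})

test_that("anaerobic release discounts the carried-over phosphate", {
  r <- cycle_records("Run 3", 85, 5, 5, anaerobic_end_p = 20,
                     retained_liquid_volume = 0.006)
  expect_equal(as.numeric(anaerobic_release(r)), 0.070 * 20 - 0.006 * 5,
               tolerance = 1e-12)
  expect_equal(as.numeric(anaerobic_release(r)), 1.37)

  # equal volumes and equal concentrations: nothing released
  same <- cycle_records("x", 1, 5, 10, anaerobic_end_p = 10,
                        retained_liquid_volume = 0.070)
  expect_equal(as.numeric(anaerobic_release(same)), 0)

  # no retained liquid: release is simply the end-of-phase mass
  none <- cycle_records("x", 1, 5, 5, anaerobic_end_p = 20,
                        retained_liquid_volume = 0)
  expect_equal(as.numeric(anaerobic_release(none)), 0.070 * 20)

  carry <- cycle_records("x", 1, 50, 48.8, anaerobic_end_p = 0,
                         retained_liquid_volume = 0.006)
  rel <- anaerobic_release(carry)
  expect_lt(as.numeric(rel), 0)
  expect_true(attr(rel, "flagged"))
})

test_that("COD consumption and fraction remaining match the printed values", {
  r <- cycle_records(c("Run 1", "Run 2"), 85, c(0.05, 0.5), c(0.03, 0.42),
                     anaerobic_end_cod = c(120, 70))
  cod <- cod_consumed(r)
  expect_equal(cod$fraction_remaining, c(0.60, 0.35))
  expect_equal(cod$cod_consumed_mg, 0.070 * c(80, 130))

  full <- cycle_records("x", 1, 5, 4, anaerobic_end_cod = 0)
  cf <- cod_consumed(full)
  expect_equal(cf$fraction_remaining, 0)
  expect_equal(cf$cod_consumed_mg, 0.070 * 200)  # 14 mg

  zero <- cycle_records("x", 1, 5, 4, anaerobic_influent_cod = 0,
                        anaerobic_end_cod = 0)
  cz <- cod_consumed(zero)
  expect_true(is.na(cz$fraction_remaining))
  expect_identical(cz$flag, "zero-influent-cod")
})

test_that("specific rates normalize to sponge volume and phase duration", {
  expect_equal(as.numeric(specific_rates(1.458, 6, 9)), 0.027)
  expect_equal(as.numeric(specific_rates(0, 6, 9)), 0)
  neg <- specific_rates(-0.5, 6, 3)
  expect_lt(as.numeric(neg), 0)
  expect_true(attr(neg, "flagged"))
  expect_error(specific_rates(1, 6, 0), "phase_hours")
  expect_error(specific_rates(1, 0, 9), "sponge_volume")
})

test_that("mass balances are linear in concentrations", {
  r1 <- cycle_records("x", 1, 50, 48.8, anaerobic_end_p = 20,
                      retained_liquid_volume = 0.006,
                      anaerobic_end_cod = 70)
  r2 <- cycle_records("x", 1, 100, 97.6, anaerobic_end_p = 40,
                      retained_liquid_volume = 0.006,
                      anaerobic_influent_cod = 400,
                      anaerobic_end_cod = 140)
  expect_equal(as.numeric(aerobic_uptake(r2)),
               2 * as.numeric(aerobic_uptake(r1)))
  expect_equal(as.numeric(anaerobic_release(r2)),
               2 * as.numeric(anaerobic_release(r1)))
  expect_equal(cod_consumed(r2)$cod_consumed_mg,
               2 * cod_consumed(r1)$cod_consumed_mg)
})

test_that("uptake balances release at the simulated plateau", {
  sp <- synth_spec(seed = 7)
  for (run in 3:4) {
    rec <- gen_reactor_timeseries(sp, run, n_days = 120)
    bal <- cycle_balance(rec)
    plateau <- bal[rec$day > 70, ]
    rel_gap <- abs(mean(plateau$p_uptake_mg) - mean(plateau$p_release_mg)) /
      mean(plateau$p_uptake_mg)
    expect_lt(rel_gap, 0.10)
  }
})

test_that("cycle record validation catches bad inputs", {
  expect_error(cycle_records("x", 1, -1, 0), "aerobic_influent_p")
  expect_error(cycle_records("x", 1, 5, 4, aerobic_flow = 0), "aerobic_flow")
  expect_error(validate_cycle_records(data.frame(run_id = "x")),
               "missing columns")
})
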