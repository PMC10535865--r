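# Forward model of the fluorescence uptake assay.

test_that("simulated uptake conserves mass and decays monotonically", {
  cond <- default_conditions()
  for (ka in c(0, 3e-12, 12e-12)) {
    tr <- simulate_uptake(transport_params(k_act = ka), cond)
    conc <- attr(tr, "concentrations")
    total <- conc$C_e + conc$C_c + conc$C_n
    expect_lt(max(abs(total - cond$total_drug)),
              1e-6 * cond$total_drug)
    # F non-increasing up to the detergent step
    pre <- tr$intensities[tr$times <= 1600]
    expect_true(all(diff(pre) <= 1e-9))
    expect_true(all(tr$intensities >= 0))
  }
})

test_that("no permeation means nothing enters and F stays flat", {
  cond <- default_conditions()
  tr <- simulate_uptake(transport_params(k_plus = 0, k_act = 0), cond,
                        permeabilization_time = NULL)
  conc <- attr(tr, "concentrations")
  expect_equal(max(abs(conc$C_n)), 0, tolerance = 1e-12)
  expect_equal(diff(range(tr$intensities)), 0, tolerance = 1e-9)
})

test_that("long-run steady state matches the algebraic fixed point", {
  # independent root-finder oracle on the stationarity equations
  cond <- default_conditions()
  p <- transport_params(k_plus = 2e-12, k_act = 4e-12,
                        k_on = 1e-4, k_off = 1e-3, b_max = 600)
  ss <- steady_state_oracle(p, cond)
  tr <- simulate_uptake(p, cond, times = seq(0, 5e4, by = 10),
                        permeabilization_time = NULL)
  conc <- attr(tr, "concentrations")
  final <- unlist(conc[nrow(conc), c("C_e", "C_c", "C_n")])
  expect_equal(unname(final), unname(ss), tolerance = 1e-4)
})

test_that("permeabilization releases the pump and fills the nucleus", {
  cond <- default_conditions()
  tr <- simulate_uptake(transport_params(), cond)
  conc <- attr(tr, "concentrations")
  cn_pre <- conc$C_n[conc$time == 1600]
  cn_post <- conc$C_n[nrow(conc)]
  expect_gt(cn_post, cn_pre)
  # merged free pool: cytosol ceases to exist as a compartment
  expect_equal(conc$C_c[conc$time > 1600], rep(0, sum(conc$time > 1600)))
})

test_that("invalid inputs are rejected", {
  cond <- default_conditions()
  expect_error(transport_params(k_plus = -1), "rates")
  expect_error(transport_params(b_max = 0), "b_max")
  expect_error(assay_conditions(total_drug = 0), "total_drug")
  expect_error(simulate_uptake(transport_params(), cond,
                               times = c(0, 1, 1, 2)),
               "strictly increasing")
  expect_error(simulate_uptake(transport_params(), cond,
                               permeabilization_time = 99999),
               "permeabilization_time")
  expect_error(fluorescence_trace(c(0, 1), c(-1, 1)), ">= 0")
})
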