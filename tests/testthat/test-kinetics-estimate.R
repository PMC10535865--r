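# Inversion of uptake traces: fluorescence levels -> concentrations ->
# transport coefficients.

make_level_trace <- function(f0_gross, fn_gross, fN_gross, bg = 0) {
  # piecewise-constant trace hitting the three characteristic levels
  times <- 0:2000
  ints <- ifelse(times < 100, f0_gross,
                 ifelse(times <= 1600, fn_gross, fN_gross))
  fluorescence_trace(times, ints,
                     events = list(drug_added = 0,
                                   steady_state_window = c(1280, 1600),
                                   permeabilization = 1600))
}

test_that("concentrations follow C = C_T (F0 - F)/F0", {
  cond <- assay_conditions(total_drug = 1000, background = 0)
  tr <- make_level_trace(100, 70, 40)
  est <- concentrations_from_trace(tr, cond, method = "mean")
  expect_equal(est$F0, 100)
  expect_equal(est$C_n, 300)   # (100-70)/100 * 1000
  expect_equal(est$C_N, 600)

  # no quenching: nothing bound
  est0 <- concentrations_from_trace(make_level_trace(100, 100, 100),
                                    cond, method = "mean")
  expect_equal(est0$C_n, 0)

  # full quenching after permeabilization: everything bound
  condbg <- assay_conditions(total_drug = 1000, background = 5)
  trN <- make_level_trace(105, 75, 5)
  estN <- concentrations_from_trace(trN, condbg, method = "mean")
  expect_equal(estN$C_N, 1000)
})

test_that("missing event markers are named in errors", {
  cond <- default_conditions()
  tr <- fluorescence_trace(0:100, rep(50, 101))
  expect_error(concentrations_from_trace(tr, cond), "drug_added")
  tr2 <- fluorescence_trace(0:100, rep(50, 101),
                            events = list(drug_added = 0))
  expect_error(concentrations_from_trace(tr2, cond),
               "steady_state_window")
  expect_error(estimate_initial_influx(tr, cond), "drug_added")
})

test_that("active-efflux closure matches its algebraic form", {
  cond <- assay_conditions(total_drug = 1000, background = 0)
  est <- structure(list(F0 = 100, Fn = 70, FN = 40, C_n = 300,
                        C_N = 600, C_T = 1000),
                   class = "kinetic_estimates")
  out <- estimate_active_efflux(est, cond, k_plus = 1e-12)
  expect_equal(out$C_i, 300 * 400 / 600)  # 200 nM
  expect_equal(out$C_e_ss, 1000 - 300 - 200)
  expect_equal(out$V_a, 1e-12 * cond$cell_density * (500 - 200))
  expect_equal(out$k_a, out$V_a / (200 * cond$cell_density))

  est$C_N <- NA_real_
  expect_error(estimate_active_efflux(est, cond, 1e-12),
               "permeabilization")
})

test_that("flat traces give zero influx with a warning, not an error", {
  cond <- assay_conditions(total_drug = 1000, background = 0)
  tr <- fluorescence_trace(0:2000, rep(100, 2001),
                           events = list(drug_added = 0,
                                         steady_state_window = c(1280, 1600)))
  expect_warning(out <- estimate_initial_influx(tr, cond), "flat")
  expect_equal(out$V_plus, 0)
  expect_equal(out$k_plus, 0)
})

test_that("noise-free pipeline recovers the generator coefficients", {
  cond <- default_conditions()
  kp <- 3e-12
  ka <- 6e-12
  tr <- gen_uptake_trace(transport_params(k_plus = kp, k_act = ka),
                         cond, noise_sd = 0, seed = 1)
  est <- fit_efflux_kinetics(tr, cond)
  expect_lt(abs(est$k_plus / kp - 1), 0.05)
  expect_lt(abs(est$k_a / ka - 1), 0.05)
  # internal consistency of the estimates
  expect_true(est$C_i <= est$C_e_ss)
  expect_true(est$C_n <= est$C_N)
  expect_gt(est$V_plus, 0)
})

test_that("a pump-free assay equilibrates free drug (C_i ~ C_e_ss)", {
  cond <- default_conditions()
  tr <- gen_uptake_trace(transport_params(k_act = 0), cond,
                         noise_sd = 0, seed = 1)
  est <- fit_efflux_kinetics(tr, cond)
  expect_lt(abs(est$C_i - est$C_e_ss), 0.03 * est$C_e_ss)
  expect_lt(abs(est$V_a), 0.02 * est$V_plus)
})

test_that("inhibition ratio anchors and scale invariance hold", {
  expect_equal(inhibition_ratio(0, 2.9e-9)$ratio, 0)
  expect_equal(inhibition_ratio(1.5e-9, 1.5e-9)$ratio, 1)
  expect_error(inhibition_ratio(1e-9, 0), "k_a_control")

  # multiplying all intensities of both traces by c > 0 leaves r
  # unchanged (concentrations are ratios of intensities)
  cond <- assay_conditions(total_drug = 1000, background = 0)
  tr_i <- gen_uptake_trace(transport_params(k_act = 3e-12), cond,
                           noise_sd = 0, seed = 1)
  tr_c <- gen_uptake_trace(transport_params(k_act = 6e-12), cond,
                           noise_sd = 0, seed = 1)
  r1 <- inhibition_ratio(fit_efflux_kinetics(tr_i, cond)$k_a,
                         fit_efflux_kinetics(tr_c, cond)$k_a)$ratio
  scale_trace <- function(tr, c) {
    fluorescence_trace(tr$times, tr$intensities * c, tr$events)
  }
  r2 <- inhibition_ratio(
    fit_efflux_kinetics(scale_trace(tr_i, 3.7), cond)$k_a,
    fit_efflux_kinetics(scale_trace(tr_c, 3.7), cond)$k_a)$ratio
  expect_equal(r1, r2, tolerance = 1e-6)
})
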