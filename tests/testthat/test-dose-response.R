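# Hill fitting, IC-level extraction, resistance/reversal indices,
# ddCt expression and accumulation folds.

test_that("noise-free Hill data are recovered essentially exactly", {
  dd <- gen_dose_response(ic50 = 4.54, hill = 1.2, noise_sd = 0, seed = 1)
  fit <- fit_dose_response(dd)
  expect_true(fit$converged)
  expect_lt(abs(fit$ic50 / 4.54 - 1), 0.01)
  expect_lt(abs(fit$hill / 1.2 - 1), 0.01)
})

test_that("dose-unit rescaling scales the IC50 exactly", {
  dd <- gen_dose_response(noise_sd = 0, seed = 1)
  f1 <- fit_dose_response(dd)
  dd2 <- dd
  dd2$dose <- dd2$dose * 1000   # uM -> nM
  f2 <- fit_dose_response(dd2)
  expect_equal(f2$ic50 / f1$ic50, 1000, tolerance = 1e-6)
})

test_that("degenerate and non-crossing data are flagged honestly", {
  flat <- data.frame(dose = c(0, 1, 2, 4, 8), viability = rep(100, 5))
  expect_error(fit_dose_response(flat), "non-identifiable")
  expect_error(fit_dose_response(data.frame(dose = c(0, 1, 2),
                                            viability = c(100, 90, 70))),
               "4 distinct doses")
  # true IC50 far above the dose range: reported as a bound
  dd <- gen_dose_response(ic50 = 100, noise_sd = 0, seed = 1)
  fit <- fit_dose_response(dd)
  expect_false(fit$converged)
  expect_true(fit$ic50_is_bound)
  expect_equal(fit$ic50, max(dd$dose))
})

test_that("IC levels follow the closed-form inversion", {
  f <- structure(list(ic50 = 1, hill = 1, top = 100, bottom = 0,
                      converged = TRUE), class = "hill_fit")
  expect_equal(ic_level(f, 50), 1)        # definition
  expect_equal(ic_level(f, 20), 0.25)     # 20/80
  f2 <- structure(list(ic50 = 2, hill = 2, top = 100, bottom = 0,
                       converged = TRUE), class = "hill_fit")
  expect_equal(ic_level(f2, 10), 2 * sqrt(1 / 9), tolerance = 1e-12)
  # numeric inversion cross-check: viability at the returned dose
  d10 <- ic_level(f2, 10)
  v <- 100 / (1 + (d10 / 2)^2)
  expect_equal(v, 90, tolerance = 1e-9)
  expect_error(ic_level(f2, 0), "level")
})

test_that("resistance and reversal indices use round-half-up", {
  expect_equal(resistance_index(4.54, 0.64), 7.1)
  expect_equal(resistance_index(0.64, 0.64), 1.0)
  expect_equal(resistance_index(0.22, 0.64), 0.3)
  expect_equal(reversal_index(7.1, 0.3), 23.7)
  expect_equal(reversal_index(7.1, 7.1), 1.0)
  expect_equal(reversal_index(7.1, 5.2), 1.4)
  expect_error(resistance_index(-1, 2), "> 0")
  # unrounded quotients satisfy exact reciprocity
  a <- resistance_index(4.54, 0.64, exact = TRUE)
  b <- resistance_index(0.64, 4.54, exact = TRUE)
  expect_equal(a * b, 1, tolerance = 1e-12)
})

test_that("the full modulator table is assembled from IC50s", {
  tab <- resistance_table(
    ic50_sensitive_no_mod = 0.64,
    ic50_resistant = c(none = 4.54, mod12.5 = 3.30, mod25 = 0.95,
                       mod50 = 0.22))
  expect_equal(tab$resistance_index, c(7.1, 5.2, 1.5, 0.3))
  expect_equal(tab$reversal_index, c(1, 1.4, 4.7, 23.7))
})

test_that("ddCt expression folds are exact and shift-invariant", {
  expect_equal(ddct_expression(20, 20, 20, 20), 1)
  expect_equal(ddct_expression(25, 20, 24, 20), 0.5)   # ddCt = 1
  expect_equal(ddct_expression(22, 20, 24, 20), 4)     # ddCt = -2
  # adding a constant to all four Ct values changes nothing
  expect_equal(ddct_expression(25 + 3, 20 + 3, 24 + 3, 20 + 3), 0.5)
  expect_warning(ddct_expression(50, 20, 20, 20), "cycle range")
})

test_that("accumulation folds are background-subtracted ratios", {
  expect_equal(accumulation_fold(100, 100), 1)
  expect_equal(accumulation_fold(200, 100), 2)
  expect_equal(accumulation_fold(0, 100), 0)
  expect_equal(accumulation_fold(110, 60, background = 10), 2)
  expect_error(accumulation_fold(50, 10, background = 10), "> 0")
})
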