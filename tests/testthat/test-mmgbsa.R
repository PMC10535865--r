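# MM-GBSA aggregation, interaction entropy, replica statistics and
# decomposition filtering.

test_that("free-energy aggregation is the sum of its printed parts", {
  s <- mmgbsa_total(-57.36, -9.45, 31.87, -8.21, 9.28)
  expect_equal(s$dG_bind, -33.87, tolerance = 1e-9)
  expect_equal(s$dH, s$e_vdw + s$e_elect + s$g_polar + s$g_nonpolar,
               tolerance = 1e-9)
  expect_equal(s$dG_bind, s$dH + s$minus_tds, tolerance = 1e-9)
  expect_equal(mmgbsa_total(0, 0, 0, 0, 0)$dG_bind, 0)
  expect_warning(mmgbsa_total(0, 0, 0, 0, -1), "-TdS")
  expect_error(mmgbsa_total(NA, 0, 0, 0, 0), "finite")
})

test_that("interaction entropy matches closed forms and Jensen bound", {
  expect_equal(interaction_entropy(rep(-50, 20), 310), 0)
  # two-point series {m + d, m - d}: (1/beta) log cosh(beta d)
  kB <- 0.0019872041
  beta <- 1 / (kB * 310)
  for (d in c(0.25, 1, 2)) {
    expect_equal(interaction_entropy(c(-50 + d, -50 - d), 310),
                 log(cosh(beta * d)) / beta, tolerance = 1e-9)
  }
  # non-negative on arbitrary seeded series
  set.seed(7)
  for (i in 1:100) {
    x <- rnorm(50, mean = -60, sd = runif(1, 0.1, 3))
    expect_gte(interaction_entropy(x, 310), 0)
  }
  # huge fluctuations warn instead of overflowing
  expect_warning(v <- interaction_entropy(c(-500, 0, -500), 310),
                 "unreliable")
  expect_true(is.finite(v))
  expect_error(interaction_entropy(-5, 310), "2 frames")
})

test_that("interaction entropy approaches the Gaussian limit", {
  kB <- 0.0019872041
  beta <- 1 / (kB * 310)
  set.seed(11)
  x <- rnorm(1e5, mean = -80, sd = 1)
  expect_lt(abs(interaction_entropy(x, 310) / (beta / 2) - 1), 0.1)
})

test_that("replica summaries give mean and SEM", {
  s <- replica_summary(c(-33, -34, -35))
  expect_equal(s$mean, -34)
  expect_equal(s$sem, 1 / sqrt(3), tolerance = 1e-9)
  expect_equal(replica_summary(c(-5, -5, -5))$sem, 0)
  expect_warning(s1 <- replica_summary(-42), "single replica")
  expect_equal(s1$sem, 0)
  # order invariance
  expect_equal(replica_summary(c(-35, -33, -34))$mean, s$mean)
})

test_that("decomposition filtering is strict and sorted", {
  d <- data.frame(residue = c("F343", "X1", "F728", "Y2"),
                  energy = c(-3.66, -0.4, -3.49, -0.5))
  out <- decompose_filter(d)
  expect_equal(out$residue, c("F343", "F728"))  # -0.5 itself excluded
  expect_equal(decompose_filter(d[0, ]), d[0, ])
  expect_error(decompose_filter(data.frame(residue = c("A", "A"),
                                           energy = c(-1, -2))),
               "unique")
})

test_that("frame tables aggregate to the configured truth", {
  # sd = 0: means reproduced exactly, -TdS = 0
  fr <- gen_energy_frames(sds = c(e_vdw = 0, e_elect = 0, g_polar = 0,
                                  g_nonpolar = 0),
                          n_frames = 50, n_replicas = 3, seed = 4)
  truth <- attr(fr, "truth")
  s <- mmgbsa_summarize(fr)
  m <- setNames(s$summary$mean, s$summary$term)
  expect_equal(m[["e_vdw"]], unname(truth$means["e_vdw"]))
  expect_equal(m[["minus_tds"]], 0)
  expect_equal(m[["dG_bind"]], sum(truth$means), tolerance = 1e-9)
  expect_equal(unname(setNames(s$summary$sem, s$summary$term)["dG_bind"]),
               0)

  # stochastic case: per-replica -TdS equals the truth embedded by the
  # generator, and the additivity identity holds per replica
  fr2 <- gen_energy_frames(n_frames = 200, n_replicas = 2, seed = 5)
  t2 <- attr(fr2, "truth")
  s2 <- mmgbsa_summarize(fr2)
  expect_equal(unname(s2$per_replica$minus_tds), unname(t2$minus_tds),
               tolerance = 1e-9)
  expect_equal(s2$per_replica$dG_bind,
               s2$per_replica$dH + s2$per_replica$minus_tds,
               tolerance = 1e-12)
})
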