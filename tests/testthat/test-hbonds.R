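# Geometric hydrogen-bond detection and occupancy bookkeeping.

test_that("the distance and angle criteria gate detection", {
  # well inside both cut-offs
  expect_equal(nrow(detect_hbonds(hbond_frame(2.8, 180))), 1)
  # distance fails
  expect_equal(nrow(detect_hbonds(hbond_frame(3.6, 180))), 0)
  # angle fails
  expect_equal(nrow(detect_hbonds(hbond_frame(2.8, 100))), 0)
  # distance-only criterion ignores the angle
  expect_equal(nrow(detect_hbonds(hbond_frame(2.8, 100),
                                  angle_def = "none")), 1)
  # just outside either cut-off
  expect_equal(nrow(detect_hbonds(hbond_frame(3.5001, 180))), 0)
  expect_equal(nrow(detect_hbonds(hbond_frame(2.8, 119.99))), 0)
})

test_that("donors without hydrogens are an error under the DHA rule", {
  tj <- hbond_frame(2.8, 170)
  tj$atoms$role[2] <- NA
  tj$atoms$parent[2] <- NA
  expect_error(detect_hbonds(tj), "no annotated hydrogen")
  expect_silent(detect_hbonds(tj, angle_def = "none"))
})

test_that("occupancy equals the planted schedule", {
  pairs <- list(list(donor_res = "E875", acceptor_res = "PGG",
                     bonded_frames = 1:65))
  tj <- gen_toy_trajectory(pairs, n_frames = 100, seed = 1)
  occ <- hbond_occupancy(tj, min_occupancy = 0)
  expect_equal(occ$occupancy, 65)
  expect_lt(abs(occ$distance_mean - 1.81), 0.1)

  # never-formed bond: zero and suppressed from the default report
  none <- gen_toy_trajectory(list(list(donor_res = "Q990",
                                       acceptor_res = "PGG",
                                       bonded_frames = integer(0))),
                             n_frames = 50, seed = 2)
  expect_equal(nrow(hbond_occupancy(none)), 0)
  expect_equal(nrow(hbond_occupancy(none, min_occupancy = 0)), 0)
})

test_that("residue grouping sums atom-pair occupancies (can exceed 100%)", {
  pairs <- list(
    list(donor_res = "Q441", acceptor_res = "PGG", bonded_frames = 1:100),
    list(donor_res = "Q441", acceptor_res = "PGG", bonded_frames = 1:100))
  tj <- gen_toy_trajectory(pairs, n_frames = 100, seed = 3)
  occ_atom <- hbond_occupancy(tj, grouping = "atom", min_occupancy = 0)
  occ_res <- hbond_occupancy(tj, grouping = "residue", min_occupancy = 0)
  expect_equal(sort(occ_atom$occupancy), c(100, 100))
  expect_equal(occ_res$occupancy, 200)
  expect_equal(occ_res$occupancy, sum(occ_atom$occupancy))
})

test_that("the default report suppresses occupancy below 30%", {
  pairs <- list(
    list(donor_res = "E875", acceptor_res = "PGG", bonded_frames = 1:65),
    list(donor_res = "Y310", acceptor_res = "PGG", bonded_frames = 1:29))
  tj <- gen_toy_trajectory(pairs, n_frames = 100, seed = 4)
  occ <- hbond_occupancy(tj)
  expect_match(occ$donor, "^E875")
  expect_equal(nrow(hbond_occupancy(tj, min_occupancy = 0)), 2)
})

test_that("bond-count series give the sample mean and SD", {
  # three bonds in every frame
  always <- lapply(c("A1", "B2", "C3"), function(r) {
    list(donor_res = r, acceptor_res = "LIG9", bonded_frames = 1:20)
  })
  tj <- gen_toy_trajectory(always, n_frames = 20, seed = 5)
  cs <- hbond_count_series(tj)
  expect_equal(cs$mean, 3)
  expect_equal(cs$sd, 0)

  # alternating 1 and 3 bonds over 100 frames
  odd <- seq(1, 100, by = 2)
  alt <- list(
    list(donor_res = "A1", acceptor_res = "LIG9", bonded_frames = 1:100),
    list(donor_res = "B2", acceptor_res = "LIG9", bonded_frames = odd),
    list(donor_res = "C3", acceptor_res = "LIG9", bonded_frames = odd))
  tj2 <- gen_toy_trajectory(alt, n_frames = 100, seed = 6)
  cs2 <- hbond_count_series(tj2)
  expect_equal(cs2$mean, 2)
  expect_equal(cs2$sd, sqrt(100 / 99), tolerance = 1e-9)

  # no donors annotated
  tj3 <- trajectory(data.frame(serial = 1:2, name = c("C", "O"),
                               residue = c("A1", "B2"),
                               role = NA_character_, parent = NA_integer_),
                    array(rnorm(2 * 3 * 4), c(2, 3, 4)))
  cs3 <- hbond_count_series(tj3)
  expect_equal(cs3$mean, 0)
  expect_equal(cs3$sd, 0)
})
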