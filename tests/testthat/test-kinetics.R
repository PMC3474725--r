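test_that("relative bioluminescence reproduces hand-computed ratios", {
  ks <- kinetic_series("w1", time = c(0, 10, 20, 30, 40),
                       lum = c(1000, 0, 600, 750, 900),
                       od = c(0.5, 0.4, 0.5, 0.6, 0.45),
                       condition = "induced")
  norm <- relative_bioluminescence(ks)
  expect_equal(norm$rel_lum, c(2000, 0, 1200, 1250, 2000))

  # zero luminescence everywhere stays zero
  ks0 <- kinetic_series("w2", c(0, 10), c(0, 0), c(0.2, 0.3),
                        "vehicle_control")
  expect_equal(relative_bioluminescence(ks0)$rel_lum, c(0, 0))

  # doubling both lum and od leaves the ratio unchanged
  ks2 <- kinetic_series("w3", ks$time, 2 * ks$lum, 2 * ks$od, "induced")
  expect_equal(relative_bioluminescence(ks2)$rel_lum, norm$rel_lum)
})

test_that("series validation rejects unusable wells", {
  expect_error(kinetic_series("w", c(0, 10), c(1, 2), c(0.5, 0), "induced"),
               "OD")
  expect_error(kinetic_series("w", c(10, 0), c(1, 2), c(0.5, 0.5),
                              "induced"), "increasing")
  expect_error(kinetic_series("w", c(0, 10), c(1, -2), c(0.5, 0.5),
                              "induced"), ">= 0")
  expect_error(kinetic_series("w", c(0, 10), c(1, 2, 3), c(0.5, 0.5),
                              "induced"), "equal length")
})

test_that("induction calling needs two consecutive above-threshold points", {
  times <- seq(0, 100, by = 10)
  ctrl <- rep(100, 11)
  # equal series: never induced
  expect_false(call_induction(ctrl, ctrl, times = times)$induced)

  # a 10x jump at t = 10 that persists: onset at 10 min
  ind <- c(100, rep(1000, 10))
  call <- call_induction(ind, ctrl, times = times)
  expect_true(call$induced)
  expect_identical(call$onset_time, 10)

  # a single-point spike is ignored
  spike <- c(100, 1000, rep(100, 9))
  expect_false(call_induction(spike, ctrl, times = times)$induced)

  expect_error(call_induction(ind, ctrl[1:5], times = times), "grids")
})

test_that("lowering the fold threshold never delays the onset", {
  sim <- simulate_kinetic_series(onset_index = 8, seed = 241)
  ind <- relative_bioluminescence(sim$induced)
  ctl <- relative_bioluminescence(sim$control)
  onsets <- vapply(c(8, 4, 2, 1.5), function(fold) {
    call_induction(ind$rel_lum, ctl$rel_lum, times = ind$time,
                   fold_threshold = fold)$onset_time
  }, numeric(1))
  expect_true(all(diff(onsets) <= 0))
})

test_that("planted onsets are recovered exactly across seeds", {
  set.seed(249)
  for (s in 1:20) {
    k <- sample(2:18, 1)
    sim <- simulate_kinetic_series(onset_index = k, seed = 250 + s)
    ind <- relative_bioluminescence(sim$induced)
    ctl <- relative_bioluminescence(sim$control)
    call <- call_induction(ind$rel_lum, ctl$rel_lum, times = ind$time)
    expect_true(call$induced)
    expect_identical(call$onset_time, sim$onset_time)
  }
})

test_that("replicate averaging and plate CSV round-trip work together", {
  sim1 <- simulate_kinetic_series(onset_index = 5, seed = 261)
  sim2 <- simulate_kinetic_series(onset_index = 5, seed = 262)
  avg <- average_replicates(list(sim1$induced, sim2$induced))
  expect_identical(nrow(avg), nrow(sim1$induced))
  expect_true(all(avg$rel_lum_sd >= 0))

  f <- withr::local_tempfile(fileext = ".csv")
  df <- rbind(
    data.frame(well = "A1", time_min = sim1$induced$time,
               lum = sim1$induced$lum, od600 = sim1$induced$od,
               condition = "induced"),
    data.frame(well = "A2", time_min = sim1$control$time,
               lum = sim1$control$lum, od600 = sim1$control$od,
               condition = "vehicle_control"))
  write.csv(df, f, row.names = FALSE)
  wells <- read_plate_csv(f)
  expect_identical(names(wells), c("A1", "A2"))
  expect_equal(wells$A1$lum, sim1$induced$lum)
})
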