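test_that("default epoch template matches the click-rate trial timeline", {
  tpl <- epoch_template()
  expect_equal(tpl$span, c(0, 3.2))
  expect_equal(epoch_interval(tpl, "pre_silence"), c(0, 0.4))
  expect_equal(epoch_interval(tpl, "torc"), c(0.4, 1.65))
  expect_equal(epoch_interval(tpl, "click_train"), c(1.65, 2.4))
  expect_equal(epoch_interval(tpl, "post_silence"), c(2.4, 3.2))
  expect_equal(epoch_window(tpl, "sound_window"), c(1.7, 2.0))
  expect_equal(epoch_window(tpl, "silence_window"), c(2.5, 2.8))
  expect_equal(epoch_window(tpl, "early_sound"), c(1.7, 1.9))
  expect_equal(epoch_window(tpl, "late_sound"), c(2.2, 2.4))
})

test_that("epoch template rejects gaps, overlaps and stray windows", {
  bad <- data.frame(label = c("pre_silence", "torc"),
                    start = c(0, 0.5), end = c(0.4, 1.65))
  expect_error(epoch_template(epochs = bad), "contiguous")
  expect_error(epoch_template(windows = list(sound_window = c(3.0, 3.5))),
               "outside")
  expect_error(epoch_template(windows = list(w = c(1, 1))), "interval")
  bad2 <- data.frame(label = "noise", start = 0, end = 1)
  expect_error(epoch_template(epochs = bad2), "unknown epoch label")
})

test_that("session validation flags bad rows by position", {
  s <- tiny_session()
  expect_s3_class(s, "session_data")
  expect_equal(nrow(s$units), 3)
  expect_equal(nrow(s$trials), 4)
  bad_spikes <- rbind(s$spikes,
                      data.frame(unit_id = 1, trial_id = 1, time_s = -0.1))
  expect_error(tiny_session(bad_spikes), "row 5")
  orphan <- rbind(s$spikes,
                  data.frame(unit_id = 99, trial_id = 1, time_s = 0.2))
  expect_error(tiny_session(orphan), "unregistered unit_id")
})

test_that("write/read round trip preserves a session", {
  s <- tiny_session()
  dir <- withr::local_tempdir()
  write_session(s, dir)
  s2 <- read_session(dir)
  expect_equal(s2$trials$state, s$trials$state)
  expect_equal(s2$spikes$time_s, s$spikes$time_s, tolerance = 1e-9)
  expect_equal(s2$clicks$time_s, s$clicks$time_s, tolerance = 1e-9)
  expect_equal(s2$units$unit_id, s$units$unit_id)
  expect_error(read_session(file.path(dir, "nope")), "missing file")
})

test_that("binning counts single events and respects the half-open rule", {
  s <- tiny_session(data.frame(unit_id = 1, trial_id = 1, time_s = 0.05))
  b <- bin_spikes(s, width = 0.1)
  expect_equal(unclass(b)[1, 1, 1], 10)           # 1 spike / 0.1 s
  expect_equal(sum(unclass(b)[1, 1, -1]), 0)
  expect_equal(sum(unclass(b)[2:3, , ]), 0)
  # boundary spike goes to the later bin
  s2 <- tiny_session(data.frame(unit_id = 1, trial_id = 1, time_s = 0.1))
  b2 <- bin_spikes(s2, width = 0.1)
  expect_equal(unclass(b2)[1, 1, 1], 0)
  expect_equal(unclass(b2)[1, 1, 2], 10)
  expect_error(bin_spikes(s, width = 5), "span")
})

test_that("binning conserves spike counts for non-overlapping bins", {
  set.seed(11)
  tt <- sort(runif(1000, 0, 1))
  s <- tiny_session(data.frame(unit_id = 1, trial_id = 1, time_s = tt))
  b <- bin_spikes(s, width = 0.1)
  expect_equal(sum(unclass(b)[1, 1, ]) * 0.1, 1000)
})

test_that("coarse bins equal block averages of fine bins", {
  set.seed(12)
  tt <- sort(runif(400, 0, 3.2))
  s <- tiny_session(data.frame(unit_id = 1, trial_id = 2, time_s = tt))
  fine <- bin_spikes(s, width = 0.01)
  coarse <- bin_spikes(s, width = 0.1)
  fine_rates <- unclass(fine)[1, 2, ]
  blocks <- colMeans(matrix(fine_rates, nrow = 10))
  expect_equal(unclass(coarse)[1, 2, ], blocks, tolerance = 1e-12)
})

test_that("overlapping bins place each spike in every covering bin", {
  s <- tiny_session(data.frame(unit_id = 1, trial_id = 1, time_s = 0.055))
  b <- bin_spikes(s, width = 0.01, step = 0.001)
  starts <- attr(b, "bin_starts")
  hit <- which(unclass(b)[1, 1, ] > 0)
  # covered bins have start in (t - width, t]
  expect_true(all(starts[hit] > 0.055 - 0.01 - 1e-9 &
                  starts[hit] <= 0.055 + 1e-9))
  expect_equal(length(hit), 10)
})

test_that("epoch mean rate averages windows and baseline-corrects", {
  s <- constant_rate_session(rate = 5)
  b <- bin_spikes(s, width = 0.2)
  m <- epoch_mean_rate(b, c(1.7, 2.0))
  expect_equal(unname(m[1, 1]), 5, tolerance = 1e-9)
  mc <- epoch_mean_rate(b, c(1.7, 2.0), baseline_correct = TRUE)
  expect_equal(unname(mc[1, 1]), 0, tolerance = 1e-9)
  expect_error(epoch_mean_rate(b, c(5, 6)), "no bins")
})
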