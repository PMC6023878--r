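test_that("identical config and seed give identical sessions", {
  cfg <- small_config()
  a <- generate_session(cfg, seed = 5)
  b <- generate_session(cfg, seed = 5)
  expect_identical(a$session$spikes, b$session$spikes)
  expect_identical(a$session$licks, b$session$licks)
  expect_identical(a$truth, b$truth)
  c <- generate_session(cfg, seed = 6)
  expect_false(identical(a$session$spikes, c$session$spikes))
})

test_that("cohorts have disjoint unit ids and deterministic lick units", {
  cfg <- generator_config(n_sessions = 3, n_units = 20, n_trials = 8)
  coh <- generate_cohort(cfg, seed = 2)
  ids <- unlist(lapply(coh$sessions, function(s) s$units$unit_id))
  expect_equal(length(unique(ids)), 60)
  expect_equal(length(coh$truth$lick_units), 6)    # 10% of 60
  coh2 <- generate_cohort(cfg, seed = 2)
  expect_identical(coh$sessions[[2]]$spikes, coh2$sessions[[2]]$spikes)
})

test_that("generated sessions satisfy the data-model invariants", {
  g <- generate_session(small_config(), seed = 9)
  s <- g$session
  expect_s3_class(s, "session_data")      # constructor re-validates
  expect_true(all(s$clicks$time_s >= 1.65 & s$clicks$time_s < 2.4))
  expect_true(all(s$spikes$time_s >= 0 & s$spikes$time_s < 3.2))
  expect_true(all(table(s$trials$state, s$trials$stimulus) == 20))
})

test_that("near-deterministic phase limit yields vector strength near 1", {
  cfg <- small_config(kappa_passive = 300, lick_fraction = 0,
                      baseline_meanlog = log(0.01), baseline_sdlog = 0.01,
                      torc_gain = 0, sound_gain = 25, class_contrast = 0,
                      state_shift = 0, silence_amp_engaged = 0,
                      silence_amp_passive = 0, kernel_norm_block = NULL)
  g <- generate_session(cfg, seed = 4)
  tab <- vs_table(g$session)
  pas <- tab[tab$state == "passive" & tab$included, ]
  expect_true(all(pas$r > 0.9))
})

test_that("the planted engaged baseline shift is recovered in silence", {
  cfg <- generator_config(n_sessions = 1, n_units = 50, n_trials = 40,
                          state_shift = 2, lick_fraction = 0,
                          error_fraction = 0)
  g <- generate_session(cfg, seed = 8)
  b <- bin_spikes(g$session, width = 0.1)
  pre <- epoch_mean_rate(b, c(0, 0.4))
  st <- g$session$trials$state
  diff_rate <- rowMeans(pre[, st == "engaged"]) -
    rowMeans(pre[, st == "passive"])
  planted <- 2 * g$truth$u
  # each unit's shift matches its planted mean within 3 SE of the estimate
  n_tr <- sum(st == "engaged")
  se <- sqrt(rowMeans(pre[, st == "engaged"]) / (0.4 * n_tr) +
             rowMeans(pre[, st == "passive"]) / (0.4 * n_tr)) + 1e-6
  expect_gt(mean(abs(diff_rate - planted) < 3 * se), 0.95)
  # and the population-level regression on u has slope ~ state_shift
  fit <- coef(lm(diff_rate ~ g$truth$u))
  expect_lt(abs(fit[2] - 2), 0.75)
})

test_that("spontaneous modulation index is positive iff a shift is planted", {
  mis <- sapply(c(6, 0), function(delta) {
    cfg <- generator_config(n_sessions = 1, n_units = 40, n_trials = 20,
                            state_shift = delta, lick_fraction = 0)
    g <- generate_session(cfg, seed = 15)
    sp <- spontaneous_rates(g$session)
    median(modulation_index(sp[, "engaged"], sp[, "passive"])$mi,
           na.rm = TRUE)
  })
  expect_gt(mis[1], 0.01)
  expect_lt(abs(mis[2]), 0.05)
})

test_that("lick behavior follows the avoidance contingency", {
  cfg <- small_config()
  g <- generate_session(cfg, seed = 12)
  s <- g$session
  t_stop <- 1.65 + cfg$lick_stop_latency
  for (i in seq_len(nrow(s$trials))) {
    lt <- s$licks$time_s[s$licks$trial_id == s$trials$trial_id[i]]
    if (s$trials$state[i] == "passive") {
      expect_length(lt, 0)
    } else if (s$trials$stimulus[i] == "target" &&
               s$trials$outcome[i] == "correct") {
      expect_true(all(lt < t_stop + 1e-9))
    }
  }
  # error target trials keep licking into the response window
  err <- s$trials$trial_id[s$trials$stimulus == "target" &
                           s$trials$outcome == "error"]
  late <- s$licks$time_s[s$licks$trial_id %in% err] > t_stop
  expect_gt(sum(late), 0)
})

test_that("lick counts follow the rate x duration Poisson scale", {
  cfg <- generator_config(n_sessions = 1, n_units = 2, n_trials = 30,
                          error_fraction = 0)
  g <- generate_session(cfg, seed = 3)
  s <- g$session
  ref <- s$trials$trial_id[s$trials$state == "engaged" &
                           s$trials$stimulus == "reference"]
  counts <- sapply(ref, function(id) sum(s$licks$trial_id == id))
  lambda <- 7 * 3.2                            # ~22.4 licks per trial
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / length(ref)))
})

test_that("appetitive mode reverses the lick contingency", {
  cfg <- small_config(lick_mode = "appetitive")
  g <- generate_session(cfg, seed = 10)
  s <- g$session
  ref <- s$trials$trial_id[s$trials$state == "engaged" &
                           s$trials$stimulus == "reference"]
  expect_equal(sum(s$licks$trial_id %in% ref), 0)
  tgt <- s$trials$trial_id[s$trials$state == "engaged" &
                           s$trials$stimulus == "target" &
                           s$trials$outcome == "correct"]
  lt <- s$licks$time_s[s$licks$trial_id %in% tgt]
  expect_gt(length(lt), 0)
  expect_true(all(lt >= 1.65 + cfg$lick_start_latency - 1e-9))
})

test_that("infeasible configs are rejected", {
  expect_error(generator_config(n_trials = 0), "infeasible")
  expect_error(generator_config(lick_fraction = 1.5), "fractions")
})
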