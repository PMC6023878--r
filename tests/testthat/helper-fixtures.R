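# Small hand-built session fixtures used across test files.

tiny_session <- function(spike_times = NULL) {
  tpl <- epoch_template()
  units <- data.frame(unit_id = 1:3, session_id = "fix")
  trials <- data.frame(trial_id = 1:4,
                       state = c("passive", "passive", "engaged", "engaged"),
                       stimulus = c("reference", "target",
                                    "reference", "target"),
                       outcome = "correct",
                       click_rate_hz = c(8, 30, 8, 30))
  if (is.null(spike_times))
    spike_times <- data.frame(unit_id = c(1, 1, 2, 3),
                              trial_id = c(1, 2, 3, 4),
                              time_s = c(0.05, 1.0, 2.0, 3.0))
  clicks <- do.call(rbind, lapply(1:4, function(k) {
    per <- 1 / trials$click_rate_hz[k]
    data.frame(trial_id = k, time_s = seq(1.65, 2.4 - 1e-9, by = per))
  }))
  licks <- data.frame(trial_id = c(3, 3), time_s = c(0.5, 1.2))
  session_data(units, trials, spike_times, clicks, licks, tpl)
}

# A session with constant-rate spiking (deterministic, evenly spaced spikes)
constant_rate_session <- function(rate = 5, n_units = 2, n_trials = 2) {
  tpl <- epoch_template()
  units <- data.frame(unit_id = seq_len(n_units), session_id = "const")
  trials <- data.frame(trial_id = seq_len(n_trials), state = "passive",
                       stimulus = rep(c("reference", "target"),
                                      length.out = n_trials),
                       outcome = "correct", click_rate_hz = 10)
  tt <- seq(0, 3.2 - 1 / rate, by = 1 / rate)
  spikes <- expand.grid(unit_id = units$unit_id, trial_id = trials$trial_id)
  spikes <- do.call(rbind, lapply(seq_len(nrow(spikes)), function(i)
    data.frame(unit_id = spikes$unit_id[i], trial_id = spikes$trial_id[i],
               time_s = tt)))
  clicks <- data.frame(trial_id = rep(trials$trial_id, each = 2),
                       time_s = rep(c(1.65, 1.75), n_trials))
  licks <- data.frame(trial_id = integer(0), time_s = numeric(0))
  session_data(units, trials, spikes, clicks, licks, tpl)
}

# Generator config scaled down for fast tests.
small_config <- function(...) {
  generator_config(n_sessions = 1, n_units = 10, n_trials = 20, ...)
}
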