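#' Configuration for the synthetic session generator
#'
#' Describes a cohort of simulated recording sessions with the population
#' structure the pipeline is designed to detect, planted in inhomogeneous
#' Poisson spike trains at `dt` resolution:
#'
#' * log-normal per-unit spontaneous rates, shifted in the engaged state by
#'   `state_shift` (spikes/s) along a unit-norm population direction `u`;
#' * click-epoch evoked patterns: a common gain `sound_gain` plus a
#'   class contrast of amplitude `class_contrast` along a unit-norm
#'   direction `v` (reference `-`, target `+`), temporally modulated by a
#'   von Mises kernel at the trial's click rate with state-specific
#'   concentration `kappa_*` (weaker locking when engaged);
#' * a persistent silence-epoch code along a direction `v2` orthogonal to
#'   `v`, present on target trials only, with amplitude
#'   `silence_amp_engaged` on correct engaged trials, `silence_amp_passive`
#'   on passive and on engaged error trials;
#' * a fraction `lick_fraction` of units receiving a Gaussian rate kernel
#'   (`lick_amp`, `lick_sd`) around every lick event.
#'
#' `mechanism` selects how the engaged state differs from passive:
#' `"baseline_shift"` keeps evoked patterns state-invariant and shifts the
#' engaged spontaneous pattern along the reference-evoked direction
#' (`u` is the normalized reference pattern), so the reference response
#' barely leaves the engaged baseline; `"evoked_change"` keeps the
#' spontaneous pattern state-invariant (`state_shift` is typically 0, `u`
#' random) and instead removes the reference class contrast in the engaged
#' state while boosting the target contrast to `engaged_target_boost`.
#'
#' @param n_sessions number of sessions in a cohort
#' @param n_units units per session
#' @param n_trials trials per state per stimulus class
#' @param template an [epoch_template()]
#' @param reference_rates_hz,target_rates_hz candidate click rates; each
#'   session draws one rate per class (rates fixed within a session)
#' @param baseline_meanlog,baseline_sdlog log-normal spontaneous-rate draw
#' @param state_shift engaged spontaneous shift magnitude (spikes/s)
#' @param mechanism `"baseline_shift"` or `"evoked_change"` (see Details)
#' @param torc_gain rate added to every unit during the neutral noise epoch
#' @param sound_gain common click-epoch evoked gain (spikes/s)
#' @param class_contrast class-contrast amplitude along `v` (spikes/s)
#' @param engaged_target_boost engaged target amplitude along `v` under the
#'   `"evoked_change"` mechanism
#' @param silence_amp_engaged,silence_amp_passive silence-code amplitudes
#' @param kappa_passive,kappa_engaged von Mises concentrations of click
#'   phase locking
#' @param lick_fraction fraction of units that are lick-locked
#' @param lick_amp,lick_sd Gaussian lick kernel amplitude (spikes/s) and
#'   width (s)
#' @param lick_rate_hz lick rate while licking
#' @param lick_mode `"avoidance"` (lick on reference, stop after target) or
#'   `"appetitive"` (lick only after target)
#' @param lick_stop_latency s after click-train onset at which licking stops
#'   on correct avoidance target trials
#' @param lick_start_latency s after click-train onset at which licking
#'   starts on correct appetitive target trials
#' @param error_fraction fraction of engaged trials per class with outcome
#'   `"error"`
#' @param dt simulation time step (s)
#' @param kernel_norm_block block length (s) within which the phase-locking
#'   kernel is renormalized to mean 1, so planted class patterns appear
#'   exactly as bin-level rates while the kernel only shapes spike timing;
#'   `NULL` disables (raw periodic kernel)
#' @return object of class `generator_config`
#' @export
generator_config <- function(n_sessions = 3, n_units = 20, n_trials = 40,
                             template = epoch_template(),
                             reference_rates_hz = c(6, 7, 8, 15),
                             target_rates_hz = c(24, 26, 28, 30, 32, 33, 36),
                             baseline_meanlog = log(4), baseline_sdlog = 0.5,
                             state_shift = 6,
                             mechanism = c("baseline_shift", "evoked_change"),
                             torc_gain = 5, sound_gain = 4,
                             class_contrast = 20, engaged_target_boost = 40,
                             silence_amp_engaged = 15, silence_amp_passive = 3,
                             kappa_passive = 5, kappa_engaged = 2,
                             lick_fraction = 0.1, lick_amp = 10,
                             lick_sd = 0.02, lick_rate_hz = 7,
                             lick_mode = c("avoidance", "appetitive"),
                             lick_stop_latency = 0.4, lick_start_latency = 0.4,
                             error_fraction = 0.2, dt = 0.001,
                             kernel_norm_block = 0.1) {
  mechanism <- match.arg(mechanism)
  lick_mode <- match.arg(lick_mode)
  cfg <- list(n_sessions = n_sessions, n_units = n_units, n_trials = n_trials,
              template = template, reference_rates_hz = reference_rates_hz,
              target_rates_hz = target_rates_hz,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog, state_shift = state_shift,
              mechanism = mechanism, torc_gain = torc_gain,
              sound_gain = sound_gain, class_contrast = class_contrast,
              engaged_target_boost = engaged_target_boost,
              silence_amp_engaged = silence_amp_engaged,
              silence_amp_passive = silence_amp_passive,
              kappa_passive = kappa_passive, kappa_engaged = kappa_engaged,
              lick_fraction = lick_fraction, lick_amp = lick_amp,
              lick_sd = lick_sd, lick_rate_hz = lick_rate_hz,
              lick_mode = lick_mode, lick_stop_latency = lick_stop_latency,
              lick_start_latency = lick_start_latency,
              error_fraction = error_fraction, dt = dt,
              kernel_norm_block = kernel_norm_block)
  if (cfg$n_sessions < 1 || cfg$n_units < 1 || cfg$n_trials < 1)
    stop("infeasible config: counts must be >= 1")
  if (cfg$lick_fraction < 0 || cfg$lick_fraction > 1 ||
      cfg$error_fraction < 0 || cfg$error_fraction > 1)
    stop("fractions must lie in [0, 1]")
  structure(cfg, class = "generator_config")
}

# Deterministic named substream seed below 2^31, derived from a master seed.
substream_seed <- function(master, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 2654435761) %% 2147480009
  as.integer((as.numeric(master) * 69069 + h) %% 2147480009)
}

# Random unit vectors: v and v2 orthonormal; u per mechanism.
plant_directions <- function(cfg, n_total, seed) {
  set.seed(substream_seed(seed, "directions"))
  rnd <- function() {
    x <- stats::rnorm(n_total)
    x / sqrt(sum(x^2))
  }
  v <- rnd()
  v2 <- stats::rnorm(n_total)
  v2 <- v2 - sum(v2 * v) * v
  v2 <- v2 / sqrt(sum(v2^2))
  if (cfg$mechanism == "baseline_shift") {
    u <- cfg$sound_gain - cfg$class_contrast * v   # reference-evoked pattern
    u <- u / sqrt(sum(u^2))
  } else {
    u <- stats::rnorm(n_total)
    u <- u - sum(u * v) * v - sum(u * v2) * v2
    u <- u / sqrt(sum(u^2))
  }
  list(u = u, v = v, v2 = v2)
}

# von Mises rate kernel with circular mean 1: exp(kappa*cos(theta))/I0(kappa)
vm_kernel <- function(theta, kappa) {
  if (kappa <= 0) return(rep(1, length(theta)))
  exp(kappa * cos(theta)) / besselI(kappa, 0, expon.scaled = FALSE)
}

# Expected resultant length of a von Mises phase distribution
vm_resultant <- function(kappa) {
  if (kappa <= 0) return(0)
  besselI(kappa, 1) / besselI(kappa, 0)
}

#' Generate lick event times for a set of trials
#'
#' Homogeneous Poisson licking at the configured rate, gated by the behavior
#' model. In `"avoidance"` mode the animal licks throughout reference
#' trials, stops `lick_stop_latency` s after click-train onset on correct
#' target trials, and keeps licking on error target trials. In
#' `"appetitive"` mode licking is confined to correct target trials from
#' `lick_start_latency` s after click-train onset. Passive trials never
#' have licks.
#'
#' @param trials trial registry data.frame (`trial_id`, `state`, `stimulus`,
#'   `outcome`)
#' @param cfg a [generator_config()]
#' @param seed integer seed
#' @return data.frame with columns `trial_id`, `time_s`
#' @export
make_lick_times <- function(trials, cfg, seed) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(substream_seed(seed, "licks"))
  span <- cfg$template$span
  t_click <- epoch_interval(cfg$template, "click_train")[1]
  out <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    if (trials$state[i] != "engaged") next
    iv <- NULL
    if (cfg$lick_mode == "avoidance") {
      iv <- if (trials$stimulus[i] == "reference" ||
                trials$outcome[i] == "error") span
            else c(span[1], min(span[2], t_click + cfg$lick_stop_latency))
    } else {
      if (trials$stimulus[i] == "target" && trials$outcome[i] == "correct")
        iv <- c(min(span[2], t_click + cfg$lick_start_latency), span[2])
    }
    if (is.null(iv) || diff(iv) <= 0) next
    n <- stats::rpois(1, cfg$lick_rate_hz * diff(iv))
    if (n == 0) next
    out[[i]] <- data.frame(trial_id = trials$trial_id[i],
                           time_s = sort(stats::runif(n, iv[1], iv[2])))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(trial_id = integer(0), time_s = numeric(0)))
  do.call(rbind, out)
}

#' Generate one synthetic recording session
#'
#' Draws a full `session_data` from the planted-structure model described in
#' [generator_config()], together with the ground truth needed to verify
#' recovery by the downstream analyses. Identical `(config, seed)` give
#' identical output.
#'
#' @param cfg a [generator_config()]
#' @param seed integer master seed; named substreams (directions, baselines,
#'   trials, licks, spikes) are derived from it so components can be varied
#'   independently
#' @param session_id session label
#' @param unit_offset added to unit ids (used by [generate_cohort()] to keep
#'   ids disjoint)
#' @param directions optional pre-computed list(u, v, v2) restricted to this
#'   session's units (cohort use)
#' @return list with elements `session` (a [session_data()]) and `truth`
#'   (list: `u`, `v`, `v2`, `state_shift`, `kappa`, `lick_units`,
#'   `baseline`, `expected_vs`, `planted_distance`, `mechanism`)
#' @export
generate_session <- function(cfg, seed, session_id = "s1", unit_offset = 0,
                             directions = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  n <- cfg$n_units
  tpl <- cfg$template
  span <- tpl$span
  dt <- cfg$dt
  n_t <- round(diff(span) / dt)
  tgrid <- span[1] + (seq_len(n_t) - 0.5) * dt

  if (is.null(directions)) directions <- plant_directions(cfg, n, seed)
  u <- directions$u; v <- directions$v; v2 <- directions$v2

  set.seed(substream_seed(seed, paste0("baselines_", session_id)))
  b <- stats::rlnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog)
  n_lick <- round(cfg$lick_fraction * n)
  lick_units <- seq_len(n_lick)                      # deterministic assignment

  # trial registry -----------------------------------------------------------
  set.seed(substream_seed(seed, paste0("trials_", session_id)))
  rate_ref <- sample(cfg$reference_rates_hz, 1)
  rate_tgt <- sample(cfg$target_rates_hz, 1)
  reg <- expand.grid(idx = seq_len(cfg$n_trials),
                     stimulus = c("reference", "target"),
                     state = c("passive", "engaged"),
                     stringsAsFactors = FALSE)
  reg$outcome <- "correct"
  n_err <- round(cfg$error_fraction * cfg$n_trials)
  for (cl in c("reference", "target")) {
    rows <- which(reg$state == "engaged" & reg$stimulus == cl)
    if (n_err > 0) reg$outcome[sample(rows, n_err)] <- "error"
  }
  reg <- reg[sample(nrow(reg)), , drop = FALSE]      # shuffle trial order
  reg$trial_id <- seq_len(nrow(reg))
  reg$click_rate_hz <- ifelse(reg$stimulus == "reference", rate_ref, rate_tgt)
  trials <- reg[, c("trial_id", "state", "stimulus", "outcome",
                    "click_rate_hz")]
  rownames(trials) <- NULL

  licks <- make_lick_times(trials, cfg, substream_seed(seed, session_id))

  # click event times -------------------------------------------------------
  click_iv <- epoch_interval(tpl, "click_train")
  clicks <- do.call(rbind, lapply(seq_len(nrow(trials)), function(i) {
    per <- 1 / trials$click_rate_hz[i]
    tt <- seq(click_iv[1], click_iv[2] - 1e-9, by = per)
    data.frame(trial_id = trials$trial_id[i], time_s = tt)
  }))

  # epoch masks on the simulation grid --------------------------------------
  in_iv <- function(iv) tgrid >= iv[1] & tgrid < iv[2]
  mask_torc <- in_iv(epoch_interval(tpl, "torc"))
  mask_click <- in_iv(click_iv)
  mask_post <- in_iv(epoch_interval(tpl, "post_silence"))
  mask_silent <- !(mask_torc | mask_click)   # pre- and post-stimulus silence

  evoked_pattern <- function(state, stimulus) {
    sgn <- if (stimulus == "target") 1 else -1
    if (state == "passive" || cfg$mechanism == "baseline_shift")
      return(cfg$sound_gain + sgn * cfg$class_contrast * v)
    if (stimulus == "reference") rep(cfg$sound_gain, n)
    else cfg$sound_gain + cfg$engaged_target_boost * v
  }

  set.seed(substream_seed(seed, paste0("spikes_", session_id)))
  spikes <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    st <- trials$state[i]
    lam <- matrix(b, n, n_t)
    if (st == "engaged") {
      # the engaged baseline shift lives in the silent epochs; during sound
      # the absolute evoked pattern is clamped by the stimulus drive, so the
      # passive and engaged evoked activity can be compared directly
      lam[, mask_silent] <- lam[, mask_silent] + cfg$state_shift * u
    }
    lam[, mask_torc] <- lam[, mask_torc] + cfg$torc_gain
    kap <- if (st == "engaged") cfg$kappa_engaged else cfg$kappa_passive
    theta <- 2 * pi * (tgrid[mask_click] - click_iv[1]) *
      trials$click_rate_hz[i]
    ker <- vm_kernel(theta, kap)
    if (!is.null(cfg$kernel_norm_block) && cfg$kernel_norm_block > 0) {
      # keep bin-level evoked rates equal to the planted pattern: the kernel
      # shapes spike timing within each block but averages to 1 over it
      blk <- floor(tgrid[mask_click] / cfg$kernel_norm_block + 1e-9)
      ker <- ker / stats::ave(ker, blk, FUN = mean)
    }
    lam[, mask_click] <- lam[, mask_click] +
      outer(evoked_pattern(st, trials$stimulus[i]), ker)
    if (trials$stimulus[i] == "target") {
      amp <- if (st == "engaged" && trials$outcome[i] == "correct")
        cfg$silence_amp_engaged else cfg$silence_amp_passive
      lam[, mask_post] <- lam[, mask_post] + amp * v2
    }
    if (n_lick > 0) {
      lt <- licks$time_s[licks$trial_id == trials$trial_id[i]]
      if (length(lt)) {
        ker <- rowSums(exp(-outer(tgrid, lt, "-")^2 / (2 * cfg$lick_sd^2)))
        lam[lick_units, ] <- lam[lick_units, , drop = FALSE] +
          cfg$lick_amp * matrix(ker, n_lick, n_t, byrow = TRUE)
      }
    }
    lam[lam < 0] <- 0
    cnt <- stats::rpois(length(lam), lam * dt)
    hit <- which(cnt > 0)
    if (!length(hit)) next
    reps <- cnt[hit]
    uu <- rep((hit - 1) %% n + 1, reps)
    bb <- rep((hit - 1) %/% n + 1, reps)
    tt <- span[1] + (rep(bb, 1) - 1) * dt + stats::runif(length(uu)) * dt
    o <- order(uu, tt)
    spikes[[i]] <- data.frame(unit_id = uu[o] + unit_offset,
                              trial_id = trials$trial_id[i], time_s = tt[o])
  }
  spikes <- spikes[!vapply(spikes, is.null, logical(1))]
  spikes <- if (length(spikes)) do.call(rbind, spikes)
            else data.frame(unit_id = integer(0), trial_id = integer(0),
                            time_s = numeric(0))

  units <- data.frame(unit_id = seq_len(n) + unit_offset,
                      session_id = session_id, stringsAsFactors = FALSE)
  sess <- session_data(units, trials, spikes, clicks, licks, tpl)

  # ground truth -------------------------------------------------------------
  rvs <- c(passive = vm_resultant(cfg$kappa_passive),
           engaged = vm_resultant(cfg$kappa_engaged))
  exp_vs <- lapply(c(passive = "passive", engaged = "engaged"), function(st) {
    sapply(c(reference = "reference", target = "target"), function(cl) {
      e <- pmax(evoked_pattern(st, cl), 0)
      e / (e + b) * rvs[[st]]     # click-epoch baseline is state-invariant
    })
  })
  planted_d <- lapply(c(passive = "passive", engaged = "engaged"),
    function(st) {
      # distance of each class's evoked pattern from that state's baseline,
      # along the ideal decoding axis (normalized target - reference pattern)
      er <- evoked_pattern(st, "reference"); et <- evoked_pattern(st, "target")
      w <- et - er; w <- w / sqrt(sum(w^2))
      c(reference = abs(sum(er * w)), target = abs(sum(et * w)))
    })
  truth <- list(u = u, v = v, v2 = v2, state_shift = cfg$state_shift,
                kappa = c(passive = cfg$kappa_passive,
                          engaged = cfg$kappa_engaged),
                lick_units = if (n_lick) lick_units + unit_offset else integer(0),
                baseline = b, expected_vs = exp_vs,
                planted_distance = planted_d, mechanism = cfg$mechanism)
  list(session = sess, truth = truth)
}

#' Generate a cohort of synthetic sessions
#'
#' Generates `cfg$n_sessions` sessions with disjoint unit ids. The planted
#' population directions are drawn once over the pooled cohort units and
#' sliced per session, so pseudo-population analyses across sessions see a
#' single coherent geometry.
#'
#' @inheritParams generate_session
#' @return list with `sessions` (list of `session_data`) and `truth`
#'   (pooled ground truth over all cohort units)
#' @export
generate_cohort <- function(cfg, seed) {
  stopifnot(inherits(cfg, "generator_config"))
  n_total <- cfg$n_sessions * cfg$n_units
  dirs <- plant_directions(cfg, n_total, seed)
  sessions <- vector("list", cfg$n_sessions)
  truths <- vector("list", cfg$n_sessions)
  for (j in seq_len(cfg$n_sessions)) {
    idx <- (j - 1) * cfg$n_units + seq_len(cfg$n_units)
    slice <- list(u = dirs$u[idx], v = dirs$v[idx], v2 = dirs$v2[idx])
    g <- generate_session(cfg, seed, session_id = paste0("s", j),
                          unit_offset = (j - 1) * cfg$n_units,
                          directions = slice)
    sessions[[j]] <- g$session
    truths[[j]] <- g$truth
  }
  truth <- list(u = dirs$u, v = dirs$v, v2 = dirs$v2,
                state_shift = cfg$state_shift,
                kappa = truths[[1]]$kappa,
                lick_units = unlist(lapply(truths, `[[`, "lick_units")),
                baseline = unlist(lapply(truths, `[[`, "baseline")),
                mechanism = cfg$mechanism,
                per_session = truths)
  list(sessions = sessions, truth = truth)
}
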