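#' Sampled event signal for reconstruction
#'
#' Converts point events (clicks or licks) into the target signal of the
#' linear reconstruction: `S(t) = amplitude` for `kernel_width` seconds
#' after each event, else 0, sampled every `sample_step` seconds over
#' `window`. The default 10 ms boxcar matches the response binning
#' resolution.
#'
#' @param event_times event times (s) for one trial
#' @param window length-2 interval (s) covered by the signal
#' @param sample_step sampling step (s)
#' @param kernel_width boxcar duration (s)
#' @param amplitude boxcar height
#' @return numeric vector of samples; sample `j` covers time
#'   `window[1] + (j-1)*sample_step`
#' @export
event_signal <- function(event_times, window, sample_step = 0.001,
                         kernel_width = 0.01, amplitude = 1) {
  n <- round(diff(window) / sample_step)
  tt <- window[1] + (seq_len(n) - 1) * sample_step
  s <- numeric(n)
  for (e in event_times) {
    s[tt >= e - 1e-9 & tt < e + kernel_width - 1e-9] <- amplitude
  }
  s
}

#' Lagged design matrix for one trial
#'
#' Stacks the lagged responses of all units: row `(i, delta)` and column `t`
#' hold unit `i`'s rate at sample `t + delta`, for lags `delta = 0..tau`
#' (in samples). With a response of `T + tau` samples the design has
#' `(tau + 1) * n_units` rows and `T` columns; the reconstruction at sample
#' `t` therefore uses activity from `t` up to `tau` samples later.
#'
#' @param rates matrix units x samples of binned rates for one trial
#' @param tau_samples number of positive lags (response must have more than
#'   `tau_samples` samples)
#' @return matrix `(tau_samples + 1) * n_units` x `(n_samples - tau_samples)`
#' @export
build_lagged_design <- function(rates, tau_samples) {
  stopifnot(is.matrix(rates), tau_samples >= 0)
  n_u <- nrow(rates)
  n_s <- ncol(rates)
  T_out <- n_s - tau_samples
  if (T_out < 1) stop("trial too short for the requested lag span")
  out <- matrix(0, (tau_samples + 1) * n_u, T_out)
  for (i in seq_len(n_u)) {
    for (d in 0:tau_samples) {
      out[(i - 1) * (tau_samples + 1) + d + 1, ] <-
        rates[i, (1 + d):(T_out + d)]
    }
  }
  out
}

# Truncated pseudo-inverse solve: x = c %*% pinv(A) for symmetric PSD A,
# keeping at most rank_cap eigencomponents and none below floor * max.
pinv_solve <- function(c_vec, A, rank_cap, floor_rel = 1e-10) {
  e <- eigen(A, symmetric = TRUE)
  pos <- e$values > max(e$values[1], 0) * floor_rel & e$values > 0
  keep <- which(pos)[seq_len(min(sum(pos), rank_cap))]
  if (!length(keep))
    return(list(g = numeric(length(c_vec)), rank = 0L))
  V <- e$vectors[, keep, drop = FALSE]
  g <- as.numeric((c_vec %*% V) %*% (t(V) / e$values[keep]))
  list(g = g, rank = length(keep))
}

#' Fit a lagged reconstruction filter by least squares
#'
#' Optimal-prior linear reconstruction: finds filter coefficients `G`
#' minimizing the summed squared error of `S_k = G R_k` over training
#' trials, via the normal equations
#' `G = (sum_k S_k R_k') (sum_k R_k R_k')^-1`. Before inversion the
#' autocorrelation matrix is eigendecomposed and only the leading
#' `rank_cap` components (default 70) are retained, dropping in addition
#' any component below `1e-10` of the largest — this removes the noisy
#' directions of the autocorrelation.
#'
#' @param designs list of design matrices from [build_lagged_design()]
#' @param signals list of matching signal vectors (length = design columns)
#' @param rank_cap maximum retained eigencomponents
#' @param tau_samples lag span (stored for reconstruction bookkeeping)
#' @return object of class `lagged_filter`: list with `g` (coefficient
#'   vector over (unit, lag) rows), `tau_samples`, `rank_cap`,
#'   `retained_rank`, `train_mse`
#' @export
fit_filter <- function(designs, signals, rank_cap = 70, tau_samples = NULL) {
  stopifnot(length(designs) >= 1, length(designs) == length(signals),
            rank_cap >= 1)
  M <- nrow(designs[[1]])
  A <- matrix(0, M, M)
  cv <- numeric(M)
  for (k in seq_along(designs)) {
    R <- designs[[k]]
    if (length(signals[[k]]) != ncol(R)) stop("signal/design length mismatch")
    A <- A + tcrossprod(R)
    cv <- cv + as.numeric(R %*% signals[[k]])
  }
  if (all(A == 0)) {
    warning("all-zero responses; returning zero filter")
    sol <- list(g = numeric(M), rank = 0L)
  } else {
    sol <- pinv_solve(cv, A, rank_cap)
  }
  mse <- mean(vapply(seq_along(designs), function(k) {
    mean((signals[[k]] - as.numeric(sol$g %*% designs[[k]]))^2)
  }, numeric(1)))
  structure(list(g = sol$g, tau_samples = tau_samples, rank_cap = rank_cap,
                 retained_rank = sol$rank, train_mse = mse),
            class = "lagged_filter")
}

#' Reconstruct a signal from a design matrix
#'
#' @param filter a `lagged_filter` from [fit_filter()]
#' @param design a design matrix with the same row layout
#' @return numeric vector `G R`, the reconstructed signal
#' @export
reconstruct <- function(filter, design) {
  stopifnot(inherits(filter, "lagged_filter"))
  if (length(filter$g) != nrow(design))
    stop("design has ", nrow(design), " rows but filter has ",
         length(filter$g), " coefficients")
  as.numeric(filter$g %*% design)
}

# Per-state spontaneous rate (pre-stimulus silence) per unit, spikes/s.
spontaneous_rates <- function(session) {
  pre <- epoch_interval(session$template, "pre_silence")
  dur <- diff(pre)
  sp <- session$spikes
  sp <- sp[sp$time_s >= pre[1] & sp$time_s < pre[2], , drop = FALSE]
  st <- session$trials$state[match(sp$trial_id, session$trials$trial_id)]
  out <- sapply(c(passive = "passive", engaged = "engaged"), function(s) {
    n_tr <- sum(session$trials$state == s)
    if (n_tr == 0) return(rep(NA_real_, nrow(session$units)))
    cnt <- table(factor(sp$unit_id[st == s], levels = session$units$unit_id))
    as.numeric(cnt) / (n_tr * dur)
  })
  rownames(out) <- session$units$unit_id
  out
}

#' Leave-one-trial-out reconstruction error
#'
#' Fits one reconstruction filter per (state, stimulus) cell of a session
#' — responses binned at `sample_width` with `sample_step` spacing, lags up
#' to `tau` — leaving each trial out in turn, reconstructing the held-out
#' trial's event signal, and scoring the mean squared error. Units whose
#' spontaneous rate is below `rate_floor` (spikes/s) in every state are
#' excluded. The engaged-versus-passive change in error is summarized per
#' stimulus class with the modulation index MI(engaged, passive), so
#' positive values mean degraded reconstruction when engaged.
#'
#' @param session a [session_data()]
#' @param target `"clicks"` or `"licks"`
#' @param window reconstruction window (default: the click-train epoch)
#' @param sample_width,sample_step response binning (s)
#' @param tau lag span in seconds
#' @param rank_cap eigencomponent cap for [fit_filter()]
#' @param rate_floor spontaneous-rate inclusion threshold (spikes/s)
#' @param kernel_width event boxcar duration (s)
#' @return list of class `reconstruction_result`: `per_trial` data.frame
#'   (trial_id, state, stimulus, mse), `mean_mse` (state x stimulus),
#'   `mi` (per-class MI of engaged vs passive mean error), `units_used`
#' @export
loo_reconstruction_mse <- function(session, target = c("clicks", "licks"),
                                   window = NULL, sample_width = 0.01,
                                   sample_step = 0.001, tau = 0.1,
                                   rank_cap = 70, rate_floor = 2,
                                   kernel_width = 0.01) {
  target <- match.arg(target)
  stopifnot(inherits(session, "session_data"))
  if (is.null(window))
    window <- if (target == "clicks")
      epoch_interval(session$template, "click_train") else
      session$template$span
  spont <- spontaneous_rates(session)
  keep_units <- session$units$unit_id[
    apply(spont, 1, function(r) any(r >= rate_floor, na.rm = TRUE))]
  if (!length(keep_units)) stop("no unit passes the spontaneous-rate floor")
  events <- if (target == "clicks") session$clicks else session$licks
  if (!nrow(events)) stop("no ", target, " events in this session")

  tau_samples <- round(tau / sample_step)
  # rates sampled on the step lattice over [window[1], window[2] + tau]
  rspan <- c(window[1], min(window[2] + tau, session$template$span[2]))
  n_s <- round(diff(rspan) / sample_step)
  T_out <- n_s - tau_samples

  sub <- session
  sub$units <- session$units[session$units$unit_id %in% keep_units, ,
                             drop = FALSE]
  sub$spikes <- session$spikes[session$spikes$unit_id %in% keep_units, ,
                               drop = FALSE]
  binned <- bin_spikes(sub, width = sample_width, step = sample_step)
  starts <- attr(binned, "bin_starts")
  sel <- which(starts >= rspan[1] - 1e-9)[seq_len(n_s)]
  if (any(is.na(sel))) stop("trial too short for the requested window + tau")

  trials <- session$trials
  per_trial <- trials[, c("trial_id", "state", "stimulus")]
  per_trial$mse <- NA_real_
  for (st in unique(trials$state)) {
    for (cl in unique(trials$stimulus)) {
      rows <- which(trials$state == st & trials$stimulus == cl)
      if (length(rows) < 2)
        stop("need >= 2 trials per (state, stimulus) cell, got ",
             length(rows), " for ", st, "/", cl)
      designs <- lapply(rows, function(i) {
        m <- matrix(unclass(binned)[, i, sel, drop = FALSE],
                    nrow = dim(binned)[1])
        build_lagged_design(m, tau_samples)
      })
      sigs <- lapply(rows, function(i) {
        ev <- events$time_s[events$trial_id == trials$trial_id[i]]
        event_signal(ev, c(window[1], window[1] + T_out * sample_step),
                     sample_step, kernel_width)
      })
      M <- nrow(designs[[1]])
      A <- matrix(0, M, M); cv <- numeric(M)
      for (k in seq_along(designs)) {
        A <- A + tcrossprod(designs[[k]])
        cv <- cv + as.numeric(designs[[k]] %*% sigs[[k]])
      }
      for (k in seq_along(rows)) {
        Ak <- A - tcrossprod(designs[[k]])
        ck <- cv - as.numeric(designs[[k]] %*% sigs[[k]])
        sol <- pinv_solve(ck, Ak, rank_cap)
        shat <- as.numeric(sol$g %*% designs[[k]])
        per_trial$mse[rows[k]] <- mean((sigs[[k]] - shat)^2)
      }
    }
  }
  mean_mse <- tapply(per_trial$mse,
                     list(state = per_trial$state,
                          stimulus = per_trial$stimulus), mean)
  mi <- NULL
  if (all(c("passive", "engaged") %in% rownames(mean_mse))) {
    mi <- sapply(colnames(mean_mse), function(cl)
      modulation_index(mean_mse["engaged", cl], mean_mse["passive", cl])$mi)
  }
  structure(list(per_trial = per_trial, mean_mse = mean_mse, mi = mi,
                 units_used = keep_units, tau_samples = tau_samples,
                 rank_cap = rank_cap),
            class = "reconstruction_result")
}
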