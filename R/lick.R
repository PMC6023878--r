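#' Per-unit lick reconstruction features
#'
#' For every unit of `session`, fits single-unit lagged reconstruction
#' filters mapping the unit's binned activity on engaged trials to the
#' lick event signal, reconstructs each engaged trial leave-one-trial-out
#' (a filter fit on the other trials, so in-sample overfitting cannot
#' mimic lick locking), and samples the reconstruction at lick times and
#' at an equal number of randomly chosen non-lick times (at least
#' `exclusion_margin` away from any lick on the same trial). The sampled
#' values form population vectors of lick and non-lick activity.
#'
#' Passing a different session as `lick_source` reconstructs that
#' session's licking from this session's neural activity (trials paired by
#' engaged-trial order) — the randomized control used to calibrate
#' lick decodability.
#'
#' @param session a [session_data()] providing the neural activity
#' @param lick_source session providing lick times (default: `session`
#'   itself, the matched case)
#' @param sample_width,sample_step response binning (s)
#' @param tau lag span (s)
#' @param rank_cap eigencomponent cap per single-unit filter
#' @param kernel_width lick-signal boxcar (s)
#' @param exclusion_margin minimum distance of non-lick samples from any
#'   lick (s)
#' @param max_events cap on sampled lick events (subsampled with `seed`)
#' @param seed integer seed for event subsampling and non-lick times
#' @return object of class `lick_feature_set`: `lick` and `nonlick`
#'   (events x units matrices), `unit_ids`, `session_id`
#' @export
lick_feature_extraction <- function(session, lick_source = session,
                                    sample_width = 0.02, sample_step = 0.01,
                                    tau = 0.1, rank_cap = 11,
                                    kernel_width = 0.02,
                                    exclusion_margin = 0.1,
                                    max_events = 150, seed = 1) {
  stopifnot(inherits(session, "session_data"),
            inherits(lick_source, "session_data"))
  if (!nrow(lick_source$licks)) stop("no lick events in the lick source")
  span <- session$template$span
  eng_act <- session$trials$trial_id[session$trials$state == "engaged"]
  eng_src <- lick_source$trials$trial_id[lick_source$trials$state == "engaged"]
  n_pair <- min(length(eng_act), length(eng_src))
  if (n_pair < 2) stop("need at least 2 engaged trials")
  eng_act <- eng_act[seq_len(n_pair)]
  eng_src <- eng_src[seq_len(n_pair)]

  tau_samples <- round(tau / sample_step)
  binned <- bin_spikes(session, width = sample_width, step = sample_step)
  starts <- attr(binned, "bin_starts")
  n_s <- length(starts)
  T_out <- n_s - tau_samples
  act_idx <- match(eng_act, attr(binned, "trial_ids"))

  sigs <- lapply(eng_src, function(tid) {
    lt <- lick_source$licks$time_s[lick_source$licks$trial_id == tid]
    event_signal(lt, c(span[1], span[1] + T_out * sample_step),
                 sample_step, kernel_width)
  })

  # leave-one-trial-out reconstruction per unit, as in the click
  # reconstruction protocol: each trial's values come from a filter fit on
  # the other trials, so in-sample overfitting cannot mimic lick locking
  U <- nrow(session$units)
  recon <- array(NA_real_, c(U, n_pair, T_out))
  for (u in seq_len(U)) {
    designs <- lapply(act_idx, function(i)
      build_lagged_design(matrix(unclass(binned)[u, i, ], nrow = 1),
                          tau_samples))
    M <- tau_samples + 1
    A <- matrix(0, M, M); cv <- numeric(M)
    for (k in seq_len(n_pair)) {
      A <- A + tcrossprod(designs[[k]])
      cv <- cv + as.numeric(designs[[k]] %*% sigs[[k]])
    }
    for (k in seq_len(n_pair)) {
      Ak <- A - tcrossprod(designs[[k]])
      ck <- cv - as.numeric(designs[[k]] %*% sigs[[k]])
      sol <- pinv_solve(ck, Ak, rank_cap)
      recon[u, k, ] <- as.numeric(sol$g %*% designs[[k]])
    }
  }

  # sample events: lick times of the source, mapped to sample indices
  set.seed(seed)
  ev <- lick_source$licks[lick_source$licks$trial_id %in% eng_src, ,
                          drop = FALSE]
  ev$pair <- match(ev$trial_id, eng_src)
  keep <- ev$time_s < span[1] + T_out * sample_step
  ev <- ev[keep, , drop = FALSE]
  if (!nrow(ev)) stop("no lick events fall inside the reconstruction span")
  if (nrow(ev) > max_events)
    ev <- ev[sort(sample.int(nrow(ev), max_events)), , drop = FALSE]
  t2idx <- function(t) pmin(pmax(floor((t - span[1]) / sample_step) + 1, 1),
                            T_out)
  lick_feat <- t(vapply(seq_len(nrow(ev)), function(j)
    recon[, ev$pair[j], t2idx(ev$time_s[j])], numeric(U)))

  # matched non-lick times: uniform, >= margin from any lick on that trial
  non <- matrix(NA_real_, nrow(ev), U)
  for (j in seq_len(nrow(ev))) {
    pair <- sample.int(n_pair, 1)
    lt <- lick_source$licks$time_s[
      lick_source$licks$trial_id == eng_src[pair]]
    for (try in 1:200) {
      tt <- stats::runif(1, span[1], span[1] + T_out * sample_step)
      if (!length(lt) || min(abs(tt - lt)) >= exclusion_margin) break
      tt <- NA_real_
    }
    if (is.na(tt)) tt <- stats::runif(1, span[1], span[1] + T_out * sample_step)
    non[j, ] <- recon[, pair, t2idx(tt)]
  }
  structure(list(lick = lick_feat, nonlick = non,
                 unit_ids = session$units$unit_id,
                 session_id = session$units$session_id[1]),
            class = "lick_feature_set")
}

# Drop units (by id) from a feature set.
drop_units <- function(features, ids) {
  keep <- !features$unit_ids %in% ids
  features$lick <- features$lick[, keep, drop = FALSE]
  features$nonlick <- features$nonlick[, keep, drop = FALSE]
  features$unit_ids <- features$unit_ids[keep]
  features
}

# Split-half CV accuracy of lick vs non-lick classification for one
# feature set; also returns the mean normalized |weight| per unit.
lick_cv_accuracy <- function(features, n_cv = 100, seed = 1) {
  n <- nrow(features$lick)
  n_train <- floor(n / 2)
  if (n_train < 1 || n - n_train < 1) stop("too few lick events to split")
  acc <- numeric(n_cv)
  wsum <- numeric(ncol(features$lick))
  set.seed(seed)
  for (r in seq_len(n_cv)) {
    tr_l <- sample.int(n, n_train)
    tr_n <- sample.int(n, n_train)
    dec <- fit_prototype_decoder(features$nonlick[tr_n, , drop = FALSE],
                                 features$lick[tr_l, , drop = FALSE])
    y_l <- classify(dec, features$lick[-tr_l, , drop = FALSE])
    y_n <- classify(dec, features$nonlick[-tr_n, , drop = FALSE])
    acc[r] <- (sum(y_l == "target") + sum(y_n == "reference")) /
      (length(y_l) + length(y_n))
    nw <- sqrt(sum(dec$w^2))
    if (nw > 0) wsum <- wsum + abs(dec$w) / nw
  }
  list(accuracy = mean(acc), weights = wsum / n_cv)
}

#' Population decodability of lick events
#'
#' Cross-validated accuracy of classifying lick from non-lick feature
#' vectors (prototype decoder, split-half resampling), compared with a
#' null distribution from randomized session pairings — each control
#' replicate reconstructs every session's licking from a *different*
#' session's neural activity. The p-value is the add-one-corrected
#' fraction of control replicates at least as accurate as the observed
#' data (the raw exceedance count is also returned). With a single session
#' the control falls back to pairing the session's licks with a circular
#' shift of its own engaged trials.
#'
#' @param matched list of [lick_feature_extraction()] results, one per
#'   session (matched activity/licks)
#' @param controls list of control replicates, each a list of feature sets
#'   (from randomized pairings); see [iterative_unit_removal()] for
#'   construction
#' @param n_cv split-half resamples per feature set
#' @param seed integer seed
#' @return list with `accuracy` (observed, averaged over sessions),
#'   `null` (per-replicate accuracies), `p`, `exceed_count`, `weights`
#'   (named per-unit mean |decoder weight|, normalized within session)
#' @export
lick_decodability <- function(matched, controls, n_cv = 100, seed = 1) {
  obs <- lapply(seq_along(matched), function(i)
    lick_cv_accuracy(matched[[i]], n_cv = n_cv, seed = seed + i))
  accuracy <- mean(vapply(obs, `[[`, numeric(1), "accuracy"))
  weights <- unlist(lapply(obs, `[[`, "weights"))
  names(weights) <- unlist(lapply(matched, `[[`, "unit_ids"))
  null <- vapply(seq_along(controls), function(c) {
    mean(vapply(seq_along(controls[[c]]), function(i)
      lick_cv_accuracy(controls[[c]][[i]], n_cv = n_cv,
                       seed = seed + 101 * c + i)$accuracy, numeric(1)))
  }, numeric(1))
  cnt <- sum(null >= accuracy)
  list(accuracy = accuracy, null = null,
       p = (1 + cnt) / (1 + length(null)), exceed_count = cnt,
       weights = weights)
}

# Build control feature sets from randomized session pairings. With one
# session, pair its licks with a circular shift of its own engaged trials.
lick_control_features <- function(sessions, n_control, seed, ...) {
  S <- length(sessions)
  lapply(seq_len(n_control), function(c) {
    set.seed(substream_seed(seed, paste0("pairing_", c)))
    if (S == 1) {
      src <- sessions[[1]]
      shift <- sample(nrow(src$trials) - 1, 1)
      shifted <- src
      eng <- which(shifted$trials$state == "engaged")
      # circular shift of lick-to-trial assignment across engaged trials
      ids <- shifted$trials$trial_id[eng]
      map <- stats::setNames(ids[(seq_along(ids) + shift - 1) %%
                                   length(ids) + 1], ids)
      li <- shifted$licks
      keep <- li$trial_id %in% ids
      li$trial_id[keep] <- map[as.character(li$trial_id[keep])]
      shifted$licks <- li[order(li$trial_id, li$time_s), , drop = FALSE]
      return(list(lick_feature_extraction(
        sessions[[1]], lick_source = shifted,
        seed = substream_seed(seed, paste0("ctrlfeat_", c)), ...)))
    }
    repeat {                                     # derangement of sessions
      perm <- sample.int(S)
      if (all(perm != seq_len(S))) break
    }
    lapply(seq_len(S), function(i)
      lick_feature_extraction(
        sessions[[i]], lick_source = sessions[[perm[i]]],
        seed = substream_seed(seed, paste0("ctrlfeat_", c, "_", i)), ...))
  })
}

#' Iterative removal of lick-responsive units
#'
#' Implements the motor-confound control: compute lick decodability; while
#' its p-value against the randomized-pairing null is at most
#' `p_threshold` (0.4), remove the unit with the highest mean absolute
#' classifier weight and re-evaluate. Removal only drops feature columns
#' (the per-unit reconstruction filters are independent), so features are
#' extracted once. The retained units are the ones carrying no more lick
#' information than randomized data; downstream analyses can be re-run on
#' them via the `exclude` argument of [run_full_analysis()] or by
#' subsetting sessions.
#'
#' @param sessions list of [session_data()]
#' @param p_threshold stop once the decodability p-value exceeds this
#'   (default 0.4)
#' @param n_control randomized-pairing control replicates
#' @param n_cv split-half resamples per decodability evaluation (a reduced
#'   count keeps the per-step cost bounded; a final full evaluation is
#'   reported in `final`)
#' @param n_cv_final resamples for the final evaluation of the retained set
#' @param max_steps safety cap on removals (default: half the units)
#' @param seed integer seed
#' @param ... passed to [lick_feature_extraction()]
#' @return object of class `lick_removal_result`: `removed` (ordered unit
#'   ids), `p_trajectory` (one p per evaluation, starting before any
#'   removal), `retained`, `final` (full-resample decodability of the
#'   retained set), `terminated` (TRUE if the threshold was reached)
#' @export
iterative_unit_removal <- function(sessions, p_threshold = 0.4,
                                   n_control = 20, n_cv = 20,
                                   n_cv_final = 100, max_steps = NULL,
                                   seed = 1, ...) {
  if (inherits(sessions, "session_data")) sessions <- list(sessions)
  matched <- lapply(seq_along(sessions), function(i)
    lick_feature_extraction(sessions[[i]],
                            seed = substream_seed(seed, paste0("feat_", i)),
                            ...))
  controls <- lick_control_features(sessions, n_control, seed, ...)
  n_units_total <- sum(vapply(matched, function(f) length(f$unit_ids),
                              numeric(1)))
  if (is.null(max_steps)) max_steps <- floor(n_units_total / 2)
  removed <- c()
  p_traj <- c()
  terminated <- FALSE
  for (step in 0:max_steps) {
    d <- lick_decodability(matched, controls, n_cv = n_cv,
                           seed = substream_seed(seed, paste0("cv_", step)))
    p_traj <- c(p_traj, d$p)
    if (d$p > p_threshold) { terminated <- TRUE; break }
    if (step == max_steps) break
    if (n_units_total - length(removed) <= 1)
      stop("removal would empty the population before decodability ",
           "reached chance (p = ", d$p, ")")
    worst <- names(d$weights)[which.max(d$weights)]
    removed <- c(removed, worst)
    matched <- lapply(matched, drop_units, ids = worst)
    controls <- lapply(controls, function(cc)
      lapply(cc, drop_units, ids = worst))
  }
  retained <- setdiff(unlist(lapply(matched, `[[`, "unit_ids")), removed)
  final <- lick_decodability(matched, controls, n_cv = n_cv_final,
                             seed = substream_seed(seed, "final"))
  structure(list(removed = removed, p_trajectory = p_traj,
                 retained = retained, final = final,
                 terminated = terminated, p_threshold = p_threshold),
            class = "lick_removal_result")
}

#' @export
print.lick_removal_result <- function(x, ...) {
  cat("lick_removal_result:", length(x$removed), "unit(s) removed,",
      length(x$retained), "retained; final p =",
      signif(x$final$p, 3), "\n")
  invisible(x)
}
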