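#' Trial-averaged class means of a pseudo-population
#'
#' @param pop a [pseudo_population()]
#' @return list with `reference` and `target` (units x bins matrices of
#'   trial-averaged rates)
#' @export
class_mean_rates <- function(pop) {
  stopifnot(inherits(pop, "pseudo_population"))
  lapply(c(reference = "reference", target = "target"), function(cl) {
    t(vapply(pop$by_unit, function(u) colMeans(u[[cl]]),
             numeric(length(pop$bin_starts))))
  })
}

#' Per-unit spontaneous baseline of a pseudo-population
#'
#' Mean rate over the pre-stimulus silence bins, averaged over all trials
#' of both classes — the state's spontaneous activity pattern.
#'
#' @param pop a [pseudo_population()]
#' @return numeric vector, one baseline rate per unit
#' @export
spontaneous_baseline <- function(pop) {
  stopifnot(inherits(pop, "pseudo_population"))
  pre <- epoch_interval(pop$template, "pre_silence")
  bns <- which(pop$bin_starts >= pre[1] - 1e-9 & pop$bin_starts < pre[2] - 1e-9)
  if (!length(bns)) stop("no bins fall in the pre_silence epoch")
  vapply(pop$by_unit, function(u)
    mean(rbind(u$reference, u$target)[, bns]), numeric(1))
}

# Unit-normalize decoder rows; degenerate all-zero rows stay zero.
normalize_axes <- function(decoders) {
  decoders <- rbind(decoders)
  nrm <- sqrt(rowSums(decoders^2))
  nrm[nrm == 0] <- 1
  decoders / nrm
}

#' Project class-mean population activity onto decoding axes
#'
#' Projects the trial-averaged population vector of each class, at each
#' time bin, onto every stored cross-validation decoding axis (unit-
#' normalized so projections are in comparable rate units). In
#' `"subtract_spontaneous"` mode, each unit's spontaneous baseline is
#' subtracted from its rates before projection, so the projected
#' spontaneous point is 0 by construction and deviations from 0 are
#' excursions from spontaneous activity along the decoding axis. In
#' `"raw_with_baselines"` mode rates are projected as-is and the projected
#' baseline(s) are reported alongside.
#'
#' @param pop a [pseudo_population()] supplying the evoked activity
#' @param decoders matrix (resamples x units) of decoding vectors, e.g.
#'   `result$decoders` from a window-mode [cross_validated_accuracy()]
#' @param baseline_mode `"subtract_spontaneous"` or `"raw_with_baselines"`
#' @param baseline per-unit baseline vector; defaults to
#'   [spontaneous_baseline()] of `pop`. In raw mode this (and any entries
#'   of `extra_baselines`) is projected, not subtracted.
#' @param extra_baselines named list of additional per-unit baseline
#'   vectors to project in raw mode (e.g. the other state's spontaneous
#'   pattern)
#' @return object of class `projection_trace`: `mean` and `sd` (class x
#'   bins matrices over decoders), `per_decoder` (decoders x class x bins
#'   array), `baseline_proj` (list of per-decoder projected baselines),
#'   `bin_starts`
#' @export
project_on_axis <- function(pop, decoders,
                            baseline_mode = c("subtract_spontaneous",
                                              "raw_with_baselines"),
                            baseline = NULL, extra_baselines = list()) {
  baseline_mode <- match.arg(baseline_mode)
  means <- class_mean_rates(pop)
  U <- length(pop$by_unit)
  W <- normalize_axes(decoders)
  if (ncol(W) != U) stop("decoders and population have different unit sets")
  if (is.null(baseline)) baseline <- spontaneous_baseline(pop)
  B <- length(pop$bin_starts)
  per <- array(NA_real_, c(nrow(W), 2, B),
               dimnames = list(NULL, c("reference", "target"), NULL))
  base_proj <- list()
  for (cl in c("reference", "target")) {
    m <- means[[cl]]
    if (baseline_mode == "subtract_spontaneous") m <- m - baseline
    per[, cl, ] <- W %*% m
  }
  if (baseline_mode == "subtract_spontaneous") {
    base_proj$spontaneous <- rep(0, nrow(W))
  } else {
    base_proj$spontaneous <- as.numeric(W %*% baseline)
    for (nm in names(extra_baselines))
      base_proj[[nm]] <- as.numeric(W %*% extra_baselines[[nm]])
  }
  structure(list(mean = apply(per, c(2, 3), mean),
                 sd = if (nrow(W) > 1) apply(per, c(2, 3), stats::sd),
                 per_decoder = per, baseline_proj = base_proj,
                 baseline_mode = baseline_mode,
                 bin_starts = pop$bin_starts),
            class = "projection_trace")
}

#' Distance of a class projection from baseline
#'
#' Absolute difference between the window-mean projection of a class and
#' the projected baseline, per stored decoder; summarized as mean and sd
#' over decoders.
#'
#' @param trace a [project_on_axis()] result
#' @param window length-2 interval in seconds
#' @param class `"reference"` or `"target"`
#' @param baseline name of the baseline in the trace (default
#'   `"spontaneous"`)
#' @return list with `d` (mean distance), `sd`, `per_decoder`
#' @export
distance_from_baseline <- function(trace, window, class,
                                   baseline = "spontaneous") {
  stopifnot(inherits(trace, "projection_trace"))
  bns <- which(trace$bin_starts >= window[1] - 1e-9 &
               trace$bin_starts < window[2] - 1e-9)
  if (!length(bns)) stop("window contains no bins")
  b <- trace$baseline_proj[[baseline]]
  if (is.null(b)) stop("no baseline named '", baseline, "' in the trace")
  per <- abs(apply(trace$per_decoder[, class, bns, drop = FALSE], 1, mean) - b)
  list(d = mean(per), sd = if (length(per) > 1) stats::sd(per) else NA_real_,
       per_decoder = per)
}

#' Reference/target asymmetry of projection distances
#'
#' `index = d(target) - d(reference)`: positive when the target class sits
#' farther from baseline along the decoding axis than the reference class.
#'
#' @param d_target,d_reference non-negative distances from baseline
#' @return numeric `d_target - d_reference`
#' @export
asymmetry_index <- function(d_target, d_reference) {
  if (any(d_target < 0) || any(d_reference < 0))
    stop("distances must be >= 0")
  d_target - d_reference
}

#' Target enhancement index across states
#'
#' Engaged-minus-passive change in the reference/target asymmetry:
#' `(d(Targ_eng) - d(Targ_pass)) - (d(Ref_eng) - d(Ref_pass))`.
#'
#' @param d_t_eng,d_t_pass,d_r_eng,d_r_pass distances from baseline (>= 0)
#' @return numeric index
#' @export
target_enhancement_index <- function(d_t_eng, d_t_pass, d_r_eng, d_r_pass) {
  if (any(c(d_t_eng, d_t_pass, d_r_eng, d_r_pass) < 0))
    stop("distances must be >= 0")
  (d_t_eng - d_t_pass) - (d_r_eng - d_r_pass)
}

#' Cross-state attribution of the engaged asymmetry
#'
#' Separates baseline-shift from evoked-pattern change: using one fixed
#' set of decoding axes (by convention the engaged ones), the asymmetry
#' index is evaluated for three combinations of evoked activity and
#' spontaneous baseline: passive evoked activity against the engaged
#' baseline, engaged evoked activity against the passive baseline, and
#' engaged evoked activity against the engaged baseline. If the engaged
#' asymmetry is driven purely by a shift of the spontaneous pattern (with
#' state-invariant evoked responses), case 1 matches case 3; if it is
#' driven by changed evoked patterns over a fixed baseline, case 1 stays
#' near the passive value and differs from case 3.
#'
#' @param pop_passive,pop_engaged [pseudo_population()]s of the two states
#'   over the same units
#' @param decoders decoding-axis matrix (resamples x units), normally the
#'   engaged sound- or silence-window decoders
#' @param window evaluation window (s)
#' @return data.frame with one row per case: evoked state, baseline state,
#'   `d_target`, `d_reference`, `asymmetry`, `sd` (over decoders)
#' @export
cross_state_projection <- function(pop_passive, pop_engaged, decoders,
                                   window) {
  if (length(pop_passive$by_unit) != length(pop_engaged$by_unit))
    stop("the two states must share the unit set")
  sp_pass <- spontaneous_baseline(pop_passive)
  sp_eng <- spontaneous_baseline(pop_engaged)
  cases <- list(
    list(evoked = pop_passive, base = sp_eng,
         evoked_state = "passive", baseline_state = "engaged"),
    list(evoked = pop_engaged, base = sp_pass,
         evoked_state = "engaged", baseline_state = "passive"),
    list(evoked = pop_engaged, base = sp_eng,
         evoked_state = "engaged", baseline_state = "engaged"))
  out <- lapply(cases, function(cs) {
    tr <- project_on_axis(cs$evoked, decoders,
                          baseline_mode = "raw_with_baselines",
                          baseline = cs$base)
    dt <- distance_from_baseline(tr, window, "target")
    dr <- distance_from_baseline(tr, window, "reference")
    per <- asymmetry_index(dt$per_decoder, dr$per_decoder)
    data.frame(evoked_state = cs$evoked_state,
               baseline_state = cs$baseline_state,
               d_target = dt$d, d_reference = dr$d,
               asymmetry = mean(per),
               sd = if (length(per) > 1) stats::sd(per) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Projection with uniform weights (control)
#'
#' Repeats the projection analysis with the decoding axis replaced by the
#' normalized all-ones vector — every unit weighted equally. An asymmetry
#' that survives this control reflects a global rate change; one that
#' vanishes is carried by a specific population direction that the decoder
#' found.
#'
#' @inheritParams project_on_axis
#' @return a `projection_trace` (single "decoder" row)
#' @export
uniform_weight_projection <- function(pop,
                                      baseline_mode = "subtract_spontaneous",
                                      baseline = NULL,
                                      extra_baselines = list()) {
  U <- length(pop$by_unit)
  project_on_axis(pop, matrix(1, 1, U), baseline_mode = baseline_mode,
                  baseline = baseline, extra_baselines = extra_baselines)
}

#' Latency to half-maximum response
#'
#' First time, after light smoothing (boxcar over `smooth_bins` bins), at
#' which a trace crosses baseline + 0.5 * (peak - baseline) within the
#' response window; the crossing is located by linear interpolation between
#' bins and reported relative to `onset` (by convention the click-train
#' onset). A flat trace (peak not above baseline) yields an undefined
#' result rather than a number.
#'
#' @param values per-bin trace values
#' @param bin_starts bin start times (s)
#' @param response_window interval searched for the peak and crossing (s)
#' @param baseline_window interval defining the baseline level (s)
#' @param onset reference time subtracted from the crossing (s)
#' @param smooth_bins boxcar width in bins (default 3)
#' @return list with `latency` (s, NA when undefined), `undefined`,
#'   `half_level`, `peak`, `baseline`
#' @export
latency_half_max <- function(values, bin_starts, response_window,
                             baseline_window, onset = 0, smooth_bins = 3) {
  stopifnot(length(values) == length(bin_starts))
  if (smooth_bins > 1) {
    raw <- values
    k <- rep(1 / smooth_bins, smooth_bins)
    values <- as.numeric(stats::filter(values, k, sides = 2))
    # ends where the boxcar runs off the trace keep their raw values
    values[is.na(values)] <- raw[is.na(values)]
  }
  base_idx <- which(bin_starts >= baseline_window[1] - 1e-9 &
                    bin_starts < baseline_window[2] - 1e-9)
  resp_idx <- which(bin_starts >= response_window[1] - 1e-9 &
                    bin_starts < response_window[2] - 1e-9)
  if (!length(base_idx) || !length(resp_idx))
    stop("empty baseline or response window")
  base <- mean(values[base_idx])
  peak <- max(values[resp_idx])
  if (peak <= base + 1e-12)
    return(list(latency = NA_real_, undefined = TRUE, half_level = NA_real_,
                peak = peak, baseline = base))
  half <- base + 0.5 * (peak - base)
  lat <- NA_real_
  prev_t <- response_window[1]
  prev_v <- base
  for (j in resp_idx) {
    if (values[j] >= half) {
      if (values[j] > prev_v) {
        lat <- prev_t + (half - prev_v) / (values[j] - prev_v) *
          (bin_starts[j] - prev_t)
      } else {
        lat <- bin_starts[j]
      }
      break
    }
    prev_t <- bin_starts[j]
    prev_v <- values[j]
  }
  list(latency = lat - onset, undefined = FALSE, half_level = half,
       peak = peak, baseline = base)
}
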