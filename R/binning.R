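#' Bin spikes into a units x trials x bins rate tensor
#'
#' Counts spikes in half-open bins `[start, start + width)` laid out every
#' `step` seconds from trial onset, and converts counts to rates
#' (spikes/s) by dividing by the bin width. Overlapping bins
#' (`step < width`) are allowed and used by the reconstruction stage
#' (10 ms bins on a 1 ms lattice); decoding uses non-overlapping 100 ms bins.
#' A spike exactly on a bin boundary belongs to the later bin.
#'
#' @param session a [session_data()]
#' @param width bin width in seconds (> 0, at most the trial span)
#' @param step bin step in seconds (> 0; `step <= width` gives overlap)
#' @return a `binned_tensor`: 3-D array `units x trials x bins` of rates with
#'   attributes `bin_width`, `bin_step`, `bin_starts`, `unit_ids`,
#'   `trial_ids`, `template`
#' @export
bin_spikes <- function(session, width, step = width) {
  stopifnot(inherits(session, "session_data"), width > 0, step > 0)
  span <- session$template$span
  if (width > diff(span) + 1e-12)
    stop("bin width exceeds the trial span")
  n_bins <- floor((diff(span) - width) / step + 1e-9) + 1
  starts <- span[1] + step * (seq_len(n_bins) - 1)
  unit_ids <- session$units$unit_id
  trial_ids <- session$trials$trial_id
  x <- array(0, dim = c(length(unit_ids), length(trial_ids), n_bins))

  sp <- session$spikes
  if (nrow(sp)) {
    ui <- match(sp$unit_id, unit_ids)
    ti <- match(sp$trial_id, trial_ids)
    # a spike at relative time t lies in every bin with start in (t-width, t]
    rel <- sp$time_s - span[1]
    lo <- pmax(1L, as.integer(floor((rel - width) / step + 1e-9)) + 2L)
    hi <- pmin(n_bins, as.integer(floor(rel / step + 1e-9)) + 1L)
    keep <- which(hi >= lo)
    reps <- hi[keep] - lo[keep] + 1L
    rows <- rep(ui[keep], reps)
    cols <- rep(ti[keep], reps)
    bins <- sequence(reps) - 1L + rep(lo[keep], reps)
    flat <- (as.numeric(bins) - 1) * (length(unit_ids) * length(trial_ids)) +
      (as.numeric(cols) - 1) * length(unit_ids) + rows
    cnt <- tabulate(flat, nbins = length(x))
    x <- array(as.numeric(cnt), dim = dim(x))
  }
  x <- x / width
  structure(x, class = "binned_tensor",
            bin_width = width, bin_step = step, bin_starts = starts,
            unit_ids = unit_ids, trial_ids = trial_ids,
            template = session$template)
}

#' @export
print.binned_tensor <- function(x, ...) {
  d <- dim(x)
  cat("binned_tensor:", d[1], "units x", d[2], "trials x", d[3], "bins",
      sprintf("(width %g s, step %g s)\n",
              attr(x, "bin_width"), attr(x, "bin_step")))
  invisible(x)
}

#' Bins whose start time lies inside a window
#' @param binned a `binned_tensor`
#' @param window length-2 interval in seconds
#' @return integer vector of bin indices
#' @export
bins_in_window <- function(binned, window) {
  stopifnot(inherits(binned, "binned_tensor"), length(window) == 2)
  s <- attr(binned, "bin_starts")
  which(s >= window[1] - 1e-9 & s < window[2] - 1e-9)
}

#' Mean rate per unit and trial over an analysis window
#'
#' Averages rates over the bins whose start lies in `window`. With
#' `baseline_correct = TRUE`, each unit's mean rate over the pre-stimulus
#' silence (`pre_silence` epoch), averaged over the same trials, is
#' subtracted — the "spontaneous-corrected" evoked rate.
#'
#' @param binned a `binned_tensor` from [bin_spikes()]
#' @param window length-2 interval in seconds within the trial span
#' @param baseline_correct subtract per-unit pre-stimulus mean?
#' @return matrix units x trials of mean rates (spikes/s)
#' @export
epoch_mean_rate <- function(binned, window, baseline_correct = FALSE) {
  idx <- bins_in_window(binned, window)
  if (!length(idx)) stop("window contains no bins")
  m <- apply(unclass(binned)[, , idx, drop = FALSE], c(1, 2), mean)
  if (baseline_correct) {
    pre <- epoch_interval(attr(binned, "template"), "pre_silence")
    jdx <- bins_in_window(binned, pre)
    if (!length(jdx)) stop("pre_silence epoch contains no bins")
    base <- rowMeans(apply(unclass(binned)[, , jdx, drop = FALSE],
                           c(1, 2), mean))
    m <- m - base
  }
  dimnames(m) <- list(attr(binned, "unit_ids"), attr(binned, "trial_ids"))
  m
}
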