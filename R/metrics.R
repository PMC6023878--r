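#' Vector strength of phase locking to a periodic stimulus
#'
#' Measures how tightly spikes lock to one phase of a periodic click train.
#' Each spike time is converted to a phase of the click period,
#' `theta_j = 2*pi*((t_j - onset) mod P)/P`, and the vector strength is the
#' length of the mean resultant vector, `|sum(exp(i*theta_j))| / n`:
#' 1 when all spikes fall at exactly the same phase, near 0 for firing
#' uniformly distributed over phase. Significance uses the Rayleigh
#' approximation `p = exp(-n r^2)` with the conventional p < 0.001 criterion.
#'
#' @param spike_times spike times (s) within the click-train epoch
#' @param period click period in seconds (1 / click rate)
#' @param onset epoch onset (s); phase zero is anchored here
#' @return list of class `vector_strength_result` with fields `r`, `n`,
#'   `rayleigh_p`, `significant`, `undefined` (TRUE when `n = 0`, in which
#'   case `r` and `rayleigh_p` are `NA` rather than 0)
#' @examples
#' vector_strength(c(0, 0.1, 0.2), period = 0.1, onset = 0)$r  # fully locked
#' @export
vector_strength <- function(spike_times, period, onset = 0) {
  stopifnot(period > 0)
  n <- length(spike_times)
  if (n == 0) {
    return(structure(list(r = NA_real_, n = 0L, rayleigh_p = NA_real_,
                          significant = NA, undefined = TRUE),
                     class = "vector_strength_result"))
  }
  theta <- 2 * pi * (((spike_times - onset) %% period) / period)
  r <- Mod(sum(exp(1i * theta))) / n
  r <- min(max(r, 0), 1)
  p <- rayleigh_p(r, n)
  structure(list(r = r, n = as.integer(n), rayleigh_p = p,
                 significant = p < 0.001, undefined = FALSE),
            class = "vector_strength_result")
}

#' Rayleigh significance of a vector strength
#'
#' Large-sample Rayleigh approximation `p = exp(-n r^2)` for the null
#' hypothesis of uniform phases, clipped to (0, 1].
#'
#' @param r vector strength in \[0, 1\]
#' @param n number of spikes (>= 1)
#' @return p-value in (0, 1]
#' @export
rayleigh_p <- function(r, n) {
  stopifnot(all(r >= 0 & r <= 1), all(n >= 1))
  p <- exp(-n * r^2)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Modulation index between two conditions
#'
#' Normalized difference `MI = (x1 - x2) / (x1 + x2)` comparing a
#' non-negative quantity (firing rate, vector strength, error) between two
#' situations; lies in \[-1, 1\] whenever `x1 + x2 > 0`. Throughout this
#' package the argument order is (engaged, passive), so positive MI means
#' larger in the engaged state.
#'
#' @param x1,x2 non-negative scalars or equal-length vectors
#' @return list of class `modulation_index_result` with `mi` (NA where
#'   `x1 + x2 = 0`, flagged in `undefined`), `x1`, `x2`
#' @export
modulation_index <- function(x1, x2) {
  if (any(x1 < 0) || any(x2 < 0)) stop("modulation index inputs must be >= 0")
  stopifnot(length(x1) == length(x2))
  s <- x1 + x2
  mi <- ifelse(s > 0, (x1 - x2) / s, NA_real_)
  structure(list(mi = mi, x1 = x1, x2 = x2, undefined = s == 0),
            class = "modulation_index_result")
}

#' Behavioral discrimination ratio
#'
#' Go/No-Go performance measure `DR = HR * (1 - FA)` combining the hit rate
#' on targets with the false-alarm rate on references; the training
#' criterion for the click-rate task is DR >= 0.64 (HR = 0.8, FA = 0.2).
#'
#' @param hit_rate,false_alarm rates in \[0, 1\]
#' @return list with `dr`, `hit_rate`, `false_alarm`
#' @examples
#' discrimination_ratio(0.8, 0.2)$dr  # 0.64
#' @export
discrimination_ratio <- function(hit_rate, false_alarm) {
  if (any(hit_rate < 0 | hit_rate > 1) || any(false_alarm < 0 | false_alarm > 1))
    stop("hit_rate and false_alarm must lie in [0, 1]")
  list(dr = hit_rate * (1 - false_alarm), hit_rate = hit_rate,
       false_alarm = false_alarm)
}

#' Per-unit vector-strength table for a session
#'
#' Computes vector strength per (unit, state, stimulus) over the click-train
#' epoch, pooling spikes across that cell's trials against each trial's own
#' click period. Units firing below `rate_floor` (spikes/s within the
#' epoch, per cell) are reported with `included = FALSE`.
#'
#' @param session a [session_data()]
#' @param rate_floor minimum within-epoch firing rate (default 1 spikes/s)
#' @return data.frame with one row per (unit, state, stimulus)
#' @export
vs_table <- function(session, rate_floor = 1) {
  stopifnot(inherits(session, "session_data"))
  epoch <- epoch_interval(session$template, "click_train")
  dur <- diff(epoch)
  tr <- session$trials
  sp <- session$spikes
  sp <- sp[sp$time_s >= epoch[1] & sp$time_s < epoch[2], , drop = FALSE]
  sp$state <- tr$state[match(sp$trial_id, tr$trial_id)]
  sp$stimulus <- tr$stimulus[match(sp$trial_id, tr$trial_id)]
  sp$period <- 1 / tr$click_rate_hz[match(sp$trial_id, tr$trial_id)]
  cells <- expand.grid(unit_id = session$units$unit_id,
                       state = c("passive", "engaged"),
                       stimulus = c("reference", "target"),
                       stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- sp$unit_id == cells$unit_id[i] & sp$state == cells$state[i] &
      sp$stimulus == cells$stimulus[i]
    n_tr <- sum(tr$state == cells$state[i] & tr$stimulus == cells$stimulus[i])
    s <- sp[sel, , drop = FALSE]
    # trials within a session share one click rate per stimulus class
    period <- if (nrow(s)) s$period[1] else NA_real_
    v <- if (nrow(s)) vector_strength(s$time_s, period, onset = epoch[1])
         else vector_strength(numeric(0), period = 1)
    rate <- if (n_tr > 0) nrow(s) / (n_tr * dur) else NA_real_
    data.frame(unit_id = cells$unit_id[i], state = cells$state[i],
               stimulus = cells$stimulus[i], n_spikes = v$n, r = v$r,
               rayleigh_p = v$rayleigh_p, significant = v$significant,
               rate = rate, included = !is.na(rate) && rate >= rate_floor,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
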