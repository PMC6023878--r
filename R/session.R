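#' Construct a validated recording session
#'
#' Bundles the event tables of one recording session (spikes, stimulus clicks,
#' licks) with the per-trial labels and the epoch template. All event times
#' are seconds relative to trial onset and must lie within the trial span;
#' click times must fall inside the `click_train` epoch.
#'
#' @param units data.frame with columns `unit_id`, `session_id`
#' @param trials data.frame with columns `trial_id`, `state`
#'   (`"passive"`/`"engaged"`), `stimulus` (`"reference"`/`"target"`),
#'   `outcome` (`"correct"`/`"error"`), `click_rate_hz`
#' @param spikes data.frame with columns `unit_id`, `trial_id`, `time_s`
#' @param clicks,licks data.frames with columns `trial_id`, `time_s`
#' @param template an [epoch_template()]
#' @return object of class `session_data`
#' @export
session_data <- function(units, trials, spikes, clicks, licks,
                         template = epoch_template()) {
  stopifnot(inherits(template, "epoch_template"))
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(what, ": missing column(s) ", paste(miss, collapse = ", "))
  }
  need(units, c("unit_id", "session_id"), "units")
  need(trials, c("trial_id", "state", "stimulus", "outcome", "click_rate_hz"),
       "trials")
  need(spikes, c("unit_id", "trial_id", "time_s"), "spikes")
  need(clicks, c("trial_id", "time_s"), "clicks")
  need(licks, c("trial_id", "time_s"), "licks")
  if (anyDuplicated(units$unit_id)) stop("duplicate unit_id in unit registry")
  if (anyDuplicated(trials$trial_id)) stop("duplicate trial_id in trials")

  check_labels <- function(x, allowed, what) {
    bad <- which(!x %in% allowed)
    if (length(bad))
      stop("trials: unknown ", what, " '", x[bad[1]], "' at row ", bad[1])
  }
  check_labels(trials$state, c("passive", "engaged"), "state")
  check_labels(trials$stimulus, c("reference", "target"), "stimulus")
  check_labels(trials$outcome, c("correct", "error"), "outcome")

  span <- template$span
  check_events <- function(ev, what, interval = span, unit_check = FALSE) {
    if (!nrow(ev)) return(invisible())
    bad <- which(ev$time_s < interval[1] - 1e-9 |
                 ev$time_s >= interval[2] + 1e-9)
    if (length(bad))
      stop(what, ": time ", ev$time_s[bad[1]], " out of range at row ", bad[1])
    bad <- which(!ev$trial_id %in% trials$trial_id)
    if (length(bad))
      stop(what, ": unregistered trial_id at row ", bad[1])
    if (unit_check) {
      bad <- which(!ev$unit_id %in% units$unit_id)
      if (length(bad))
        stop(what, ": unregistered unit_id at row ", bad[1])
    }
    invisible()
  }
  check_events(spikes, "spikes", unit_check = TRUE)
  check_events(clicks, "clicks", interval = epoch_interval(template, "click_train"))
  check_events(licks, "licks")

  structure(list(units = units, trials = trials, spikes = spikes,
                 clicks = clicks, licks = licks, template = template),
            class = "session_data")
}

#' @export
print.session_data <- function(x, ...) {
  cat("session_data:", nrow(x$units), "units,", nrow(x$trials), "trials,",
      nrow(x$spikes), "spikes,", nrow(x$clicks), "clicks,",
      nrow(x$licks), "licks\n")
  cat("  states: ", paste(names(table(x$trials$state)), table(x$trials$state),
                          sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a session from delimited text files
#'
#' Reads the four event/label tables (UTF-8, comma-separated, header row,
#' times as decimal seconds) and validates them into a [session_data()].
#'
#' @param dir directory containing `spikes.csv`, `trials.csv`, `clicks.csv`,
#'   `licks.csv` (and optionally `units.csv`; if absent, units are inferred
#'   from the spike table)
#' @param template an [epoch_template()]
#' @param session_id session identifier used when `units.csv` is absent
#' @return a `session_data`
#' @export
read_session <- function(dir, template = epoch_template(),
                         session_id = basename(dir)) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing file: ", p)
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  spikes <- rd("spikes.csv")
  trials <- rd("trials.csv")
  clicks <- rd("clicks.csv")
  licks <- rd("licks.csv")
  up <- file.path(dir, "units.csv")
  units <- if (file.exists(up)) utils::read.csv(up, stringsAsFactors = FALSE)
           else data.frame(unit_id = sort(unique(spikes$unit_id)),
                           session_id = session_id, stringsAsFactors = FALSE)
  session_data(units, trials, spikes, clicks, licks, template)
}

#' Write a session to delimited text files
#'
#' Inverse of [read_session()]; the round trip is lossless to the printed
#' precision (15 significant digits, well below 1e-9 s).
#'
#' @param session a `session_data`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "session_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f)
    utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                     file.path(dir, f), row.names = FALSE, quote = FALSE)
  wr(session$spikes, "spikes.csv")
  wr(session$trials, "trials.csv")
  wr(session$clicks, "clicks.csv")
  wr(session$licks, "licks.csv")
  wr(session$units, "units.csv")
  invisible(dir)
}
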