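#' Trial epoch template
#'
#' Defines the within-trial timeline shared by all analyses: an ordered set of
#' contiguous, non-overlapping epochs (seconds from trial onset) plus named
#' analysis windows. The default corresponds to the click-rate discrimination
#' trial: 0.4 s pre-stimulus silence, a 1.25 s neutral broadband noise (TORC),
#' a 0.75 s click train, and a 0.8 s post-stimulus silence whose final part
#' contains the behavioral response window.
#'
#' @param epochs data.frame with columns `label`, `start`, `end` (seconds).
#'   Labels must come from `pre_silence`, `torc`, `click_train`,
#'   `post_silence`, `response_window`.
#' @param windows named list of length-2 numeric intervals (seconds) used by
#'   decoding and projection analyses. Must lie within the trial span.
#' @return An object of class `epoch_template`.
#' @examples
#' tpl <- epoch_template()
#' tpl$span
#' epoch_window(tpl, "sound_window")
#' @export
epoch_template <- function(epochs = NULL, windows = NULL) {
  if (is.null(epochs)) {
    epochs <- data.frame(
      label = c("pre_silence", "torc", "click_train", "post_silence"),
      start = c(0, 0.4, 1.65, 2.4),
      end   = c(0.4, 1.65, 2.4, 3.2),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(windows)) {
    windows <- list(
      sound_window   = c(1.7, 2.0),
      silence_window = c(2.5, 2.8),
      early_sound    = c(1.7, 1.9),
      late_sound     = c(2.2, 2.4)
    )
  }
  stopifnot(is.data.frame(epochs),
            all(c("label", "start", "end") %in% names(epochs)))
  allowed <- c("pre_silence", "torc", "click_train", "post_silence",
               "response_window")
  bad <- setdiff(epochs$label, allowed)
  if (length(bad))
    stop("unknown epoch label(s): ", paste(bad, collapse = ", "))
  o <- order(epochs$start)
  epochs <- epochs[o, , drop = FALSE]
  if (any(epochs$end <= epochs$start))
    stop("epochs must have end > start")
  if (nrow(epochs) > 1 &&
      any(abs(epochs$start[-1] - epochs$end[-nrow(epochs)]) > 1e-9))
    stop("epochs must be contiguous and non-overlapping")
  span <- c(min(epochs$start), max(epochs$end))
  for (w in names(windows)) {
    iv <- windows[[w]]
    if (length(iv) != 2 || iv[1] >= iv[2])
      stop("window '", w, "' is not a valid interval")
    if (iv[1] < span[1] - 1e-9 || iv[2] > span[2] + 1e-9)
      stop("window '", w, "' lies outside the trial span")
  }
  structure(list(epochs = epochs, windows = windows, span = span),
            class = "epoch_template")
}

#' Look up an epoch interval by label
#' @param template an `epoch_template`
#' @param label epoch label
#' @return numeric length-2 interval `c(start, end)` in seconds
#' @export
epoch_interval <- function(template, label) {
  stopifnot(inherits(template, "epoch_template"))
  i <- match(label, template$epochs$label)
  if (is.na(i)) stop("no epoch labelled '", label, "'")
  c(template$epochs$start[i], template$epochs$end[i])
}

#' Look up a named analysis window
#' @inheritParams epoch_interval
#' @param name window name (e.g. `"sound_window"`)
#' @return numeric length-2 interval in seconds
#' @export
epoch_window <- function(template, name) {
  stopifnot(inherits(template, "epoch_template"))
  w <- template$windows[[name]]
  if (is.null(w)) stop("no analysis window named '", name, "'")
  w
}

#' @export
print.epoch_template <- function(x, ...) {
  cat("Trial epoch template, span [", x$span[1], ", ", x$span[2], ") s\n",
      sep = "")
  print(x$epochs, row.names = FALSE)
  cat("Windows:\n")
  for (w in names(x$windows))
    cat("  ", w, ": [", x$windows[[w]][1], ", ", x$windows[[w]][2], ")\n",
        sep = "")
  invisible(x)
}
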