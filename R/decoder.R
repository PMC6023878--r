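#' Prototype linear decoder from class means
#'
#' The per-bin linear classifier: with class-mean pseudo-population vectors
#' `c_R` (reference) and `c_T` (target), the decoding vector is
#' `w = c_T - c_R` and the bias `b = -((c_R + c_T) . w) / 2`, so the
#' decision surface passes through the midpoint of the prototypes. A vector
#' `x` scores `y(x) = w . x + b`: positive scores are classified target,
#' negative reference, and the measure-zero tie `y = 0` deterministically
#' as reference.
#'
#' @param train_ref,train_tgt matrices pseudo-trials x units of training
#'   vectors for the reference and target classes (>= 1 row each)
#' @return object of class `linear_decoder`: list with `w`, `b`, `c_R`,
#'   `c_T`, `degenerate` (TRUE when the prototypes coincide and `w = 0`)
#' @export
fit_prototype_decoder <- function(train_ref, train_tgt) {
  train_ref <- rbind(train_ref); train_tgt <- rbind(train_tgt)
  if (!nrow(train_ref) || !nrow(train_tgt))
    stop("both classes need at least one training pseudo-trial")
  if (ncol(train_ref) != ncol(train_tgt)) stop("unit dimension mismatch")
  c_R <- colMeans(train_ref)
  c_T <- colMeans(train_tgt)
  w <- c_T - c_R
  b <- -sum((c_R + c_T) * w) / 2
  structure(list(w = w, b = b, c_R = c_R, c_T = c_T,
                 degenerate = all(w == 0)),
            class = "linear_decoder")
}

#' Classify population vectors with a prototype decoder
#'
#' @param decoder a `linear_decoder`
#' @param x numeric vector (one population vector) or matrix with one
#'   vector per row
#' @return character vector of labels (`"reference"`/`"target"`); the
#'   scores are attached as attribute `"score"`
#' @export
classify <- function(decoder, x) {
  stopifnot(inherits(decoder, "linear_decoder"))
  x <- rbind(x)
  if (ncol(x) != length(decoder$w))
    stop("vector has ", ncol(x), " units, decoder expects ",
         length(decoder$w))
  y <- as.numeric(x %*% decoder$w + decoder$b)
  structure(ifelse(y > 0, "target", "reference"), score = y)
}

#' Pool sessions into a pseudo-population
#'
#' Bins every session and collects, for each unit, its per-trial rate rows
#' for the requested state/outcome, keyed by stimulus class. Trials of
#' different units are later paired at random, so noise correlations are
#' destroyed by construction. Units with fewer than `min_trials` trials in
#' either class are dropped with a warning rather than failing the pool.
#'
#' @param sessions list of [session_data()] (or a single session)
#' @param state `"passive"` or `"engaged"`
#' @param outcome trial outcomes to include (default `"correct"`)
#' @param width,step decoding bin geometry in seconds (default 100 ms,
#'   non-overlapping)
#' @param min_trials minimum trials per class for a unit to be kept
#' @return object of class `pseudo_population`: list with `unit_ids`,
#'   `bin_starts`, `width`, `template` and `by_unit` (per unit, matrices
#'   `reference` and `target` of trials x bins rates)
#' @export
pseudo_population <- function(sessions, state, outcome = "correct",
                              width = 0.1, step = width, min_trials = 1) {
  if (inherits(sessions, "session_data")) sessions <- list(sessions)
  by_unit <- list()
  unit_ids <- c()
  bin_starts <- NULL
  template <- NULL
  for (s in sessions) {
    binned <- bin_spikes(s, width = width, step = step)
    bin_starts <- attr(binned, "bin_starts")
    template <- attr(binned, "template")
    for (cl in c("reference", "target")) {
      idx <- which(s$trials$state == state & s$trials$stimulus == cl &
                   s$trials$outcome %in% outcome)
      for (ui in seq_len(nrow(s$units))) {
        id <- as.character(s$units$unit_id[ui])
        m <- matrix(unclass(binned)[ui, idx, , drop = FALSE],
                    nrow = length(idx))
        by_unit[[id]][[cl]] <- m
      }
    }
    unit_ids <- c(unit_ids, s$units$unit_id)
  }
  n_tr <- vapply(by_unit, function(u)
    min(nrow(u$reference), nrow(u$target)), numeric(1))
  drop <- names(by_unit)[n_tr < min_trials]
  if (length(drop)) {
    warning("dropping ", length(drop), " unit(s) with fewer than ",
            min_trials, " trials per class")
    by_unit <- by_unit[!names(by_unit) %in% drop]
    unit_ids <- unit_ids[!as.character(unit_ids) %in% drop]
  }
  if (!length(by_unit)) stop("no units left in the pseudo-population")
  structure(list(unit_ids = unit_ids, bin_starts = bin_starts, width = width,
                 template = template, by_unit = by_unit, state = state),
            class = "pseudo_population")
}

#' @export
print.pseudo_population <- function(x, ...) {
  cat("pseudo_population:", length(x$by_unit), "units,",
      length(x$bin_starts), "bins, state:", x$state, "\n")
  invisible(x)
}

#' Draw one balanced train/test split of pseudo-trials
#'
#' For every unit independently, samples `n_train` reference and `n_train`
#' target trials for training; the test set is drawn from each unit's
#' remaining trials, subsampled to the largest balanced size available to
#' all units. Pseudo-trial `j` of a class pairs the `j`-th sampled trial of
#' every unit.
#'
#' @param pop a [pseudo_population()]
#' @param n_train training trials per class per unit (default 15)
#' @param seed integer seed
#' @return list with per-unit index matrices `train_ref`, `train_tgt`,
#'   `test_ref`, `test_tgt` (pseudo-trials x units) and `n_test`
#' @export
assemble_pseudo_population <- function(pop, n_train = 15, seed = 1) {
  stopifnot(inherits(pop, "pseudo_population"), n_train >= 1)
  avail <- vapply(pop$by_unit, function(u)
    c(nrow(u$reference), nrow(u$target)), numeric(2))
  if (any(avail < n_train + 1))
    stop("every unit needs >= n_train + 1 = ", n_train + 1,
         " trials per class; minimum available is ", min(avail))
  n_test <- min(avail) - n_train
  set.seed(seed)
  U <- length(pop$by_unit)
  idx <- function(n_avail) {
    o <- sample.int(n_avail)
    list(train = o[seq_len(n_train)],
         test = o[n_train + seq_len(n_test)])
  }
  train_ref <- matrix(0L, n_train, U); train_tgt <- matrix(0L, n_train, U)
  test_ref <- matrix(0L, n_test, U); test_tgt <- matrix(0L, n_test, U)
  for (u in seq_len(U)) {
    a <- idx(avail[1, u]); b <- idx(avail[2, u])
    train_ref[, u] <- a$train; test_ref[, u] <- a$test
    train_tgt[, u] <- b$train; test_tgt[, u] <- b$test
  }
  list(train_ref = train_ref, train_tgt = train_tgt,
       test_ref = test_ref, test_tgt = test_tgt, n_test = n_test)
}

# Extract pseudo-trial x bins x units array for one class from index matrix.
pp_array <- function(pop, index_mat, class, bins) {
  U <- length(pop$by_unit)
  n <- nrow(index_mat)
  out <- array(0, c(n, length(bins), U))
  for (u in seq_len(U)) {
    out[, , u] <- pop$by_unit[[u]][[class]][index_mat[, u], bins,
                                            drop = FALSE]
  }
  out
}

# Mean over the bin dimension -> pseudo-trials x units matrix.
pp_window_matrix <- function(arr) {
  apply(arr, c(1, 3), mean)
}

#' Cross-validated decoding accuracy
#'
#' Repeats the balanced pseudo-population split `n_resamples` times
#' (default 400, redrawing train and test sets each time), fits the
#' prototype decoder, and scores held-out pseudo-trials. Two modes:
#'
#' * `bins` (default: all bins): the decoder is trained and tested
#'   separately at each time bin, giving a per-bin accuracy time course;
#' * `window`: rates are averaged over the window's bins first, giving one
#'   accuracy per resample and one stored decoding vector per resample
#'   (reused by the projection analyses).
#'
#' The resample spread is reported both as 1 standard deviation and as a
#' 95% percentile interval. With `n_resamples` resamples, p-values derived
#' from the cross-validation cannot fall below `1 / n_resamples` (0.0025 at
#' the default 400); this floor is reported as `min_p`.
#'
#' @param pop a [pseudo_population()]
#' @param bins integer bin indices to decode (ignored when `window` given)
#' @param window length-2 interval in seconds; see Details
#' @param n_train training trials per class per unit
#' @param n_resamples number of cross-validation resamples
#' @param seed integer seed
#' @return object of class `decoding_result`: `accuracy` (resamples x bins
#'   matrix, or x 1 in window mode), `mean`, `sd`, `ci` (2 x bins 95%
#'   percentile bounds), `decoders` (window mode: resamples x units matrix
#'   of decoding vectors, plus `biases`), `bin_starts`, `min_p`
#' @export
cross_validated_accuracy <- function(pop, bins = NULL, window = NULL,
                                     n_train = 15, n_resamples = 400,
                                     seed = 1) {
  stopifnot(inherits(pop, "pseudo_population"), n_resamples >= 1)
  if (n_resamples == 1)
    warning("a single resample gives a mean only; no spread or CI")
  window_mode <- !is.null(window)
  if (window_mode) {
    bins <- which(pop$bin_starts >= window[1] - 1e-9 &
                  pop$bin_starts < window[2] - 1e-9)
    if (!length(bins)) stop("window contains no bins")
  } else if (is.null(bins)) {
    bins <- seq_along(pop$bin_starts)
  }
  U <- length(pop$by_unit)
  B <- if (window_mode) 1L else length(bins)
  acc <- matrix(NA_real_, n_resamples, B)
  decoders <- if (window_mode) matrix(NA_real_, n_resamples, U) else NULL
  biases <- if (window_mode) numeric(n_resamples) else NULL
  for (r in seq_len(n_resamples)) {
    split <- assemble_pseudo_population(pop, n_train, seed = seed + r - 1)
    tr_r <- pp_array(pop, split$train_ref, "reference", bins)
    tr_t <- pp_array(pop, split$train_tgt, "target", bins)
    te_r <- pp_array(pop, split$test_ref, "reference", bins)
    te_t <- pp_array(pop, split$test_tgt, "target", bins)
    if (window_mode) {
      dec <- fit_prototype_decoder(pp_window_matrix(tr_r),
                                   pp_window_matrix(tr_t))
      y_r <- classify(dec, pp_window_matrix(te_r))
      y_t <- classify(dec, pp_window_matrix(te_t))
      acc[r, 1] <- (sum(y_r == "reference") + sum(y_t == "target")) /
        (2 * split$n_test)
      decoders[r, ] <- dec$w
      biases[r] <- dec$b
    } else {
      for (j in seq_len(B)) {
        dec <- fit_prototype_decoder(tr_r[, j, ], tr_t[, j, ])
        y_r <- classify(dec, te_r[, j, , drop = TRUE])
        y_t <- classify(dec, te_t[, j, , drop = TRUE])
        acc[r, j] <- (sum(y_r == "reference") + sum(y_t == "target")) /
          (2 * split$n_test)
      }
    }
  }
  structure(list(
    accuracy = acc,
    mean = colMeans(acc),
    sd = if (n_resamples > 1) apply(acc, 2, stats::sd) else rep(NA_real_, B),
    ci = if (n_resamples > 1)
      apply(acc, 2, stats::quantile, c(0.025, 0.975)) else NULL,
    decoders = decoders, biases = biases,
    bins = bins,
    bin_starts = if (window_mode) mean(pop$bin_starts[bins])
                 else pop$bin_starts[bins],
    window = window, n_resamples = n_resamples, n_train = n_train,
    min_p = 1 / n_resamples, seed = seed),
    class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("decoding_result:", x$n_resamples, "resamples,",
      length(x$mean), "bin(s); mean accuracy",
      paste(sprintf("%.3f", x$mean), collapse = " "), "\n")
  invisible(x)
}

# Label-shuffled copy of a pseudo-population: within each unit, trials are
# pooled and reassigned to classes at random (class counts preserved).
shuffle_labels <- function(pop) {
  pop$by_unit <- lapply(pop$by_unit, function(u) {
    all <- rbind(u$reference, u$target)
    n_r <- nrow(u$reference)
    o <- sample.int(nrow(all))
    list(reference = all[o[seq_len(n_r)], , drop = FALSE],
         target = all[o[(n_r + 1):nrow(all)], , drop = FALSE])
  })
  pop
}

#' Label-shuffle null distribution of decoding accuracy
#'
#' Repeats the full cross-validated decoding on surrogate data in which
#' each unit's trial labels are permuted: `n_perm` label permutations, each
#' evaluated with `n_cv` cross-validation resamples. The empirical p-value
#' of an observed accuracy uses the add-one form
#' `p = (1 + #\{null >= obs\}) / (1 + n_perm)` (the raw exceedance count is
#' also returned), so p can never fall below `1 / (n_perm + 1)`.
#'
#' @inheritParams cross_validated_accuracy
#' @param n_perm number of label permutations (default 100)
#' @param n_cv cross-validation resamples per permutation (default 100)
#' @param observed optional observed per-bin accuracies to score against
#'   the null
#' @return list of class `decoding_null`: `null` (n_perm x bins matrix of
#'   null mean accuracies), `mean`, `ci` (2 x bins), and when `observed`
#'   given, `p` and `exceed_count`
#' @export
shuffled_null <- function(pop, bins = NULL, window = NULL, n_perm = 100,
                          n_cv = 100, n_train = 15, seed = 1,
                          observed = NULL) {
  stopifnot(n_perm >= 1)
  B <- if (!is.null(window)) 1L else length(if (is.null(bins))
    seq_along(pop$bin_starts) else bins)
  null <- matrix(NA_real_, n_perm, B)
  for (p in seq_len(n_perm)) {
    set.seed(seed + 7919 * p)
    sh <- shuffle_labels(pop)
    res <- cross_validated_accuracy(sh, bins = bins, window = window,
                                    n_train = n_train, n_resamples = n_cv,
                                    seed = seed + 7919 * p)
    null[p, ] <- res$mean
  }
  out <- list(null = null, mean = colMeans(null),
              ci = apply(null, 2, stats::quantile, c(0.025, 0.975)),
              n_perm = n_perm, n_cv = n_cv)
  if (!is.null(observed)) {
    stopifnot(length(observed) == B)
    cnt <- vapply(seq_len(B), function(j) sum(null[, j] >= observed[j]),
                  numeric(1))
    out$exceed_count <- cnt
    out$p <- (1 + cnt) / (1 + n_perm)
  }
  structure(out, class = "decoding_null")
}

#' Temporal generalization of window-trained decoders
#'
#' Trains the prototype decoder on the window-averaged rates of each
#' training window and tests it at every requested time bin, producing a
#' train-window x test-bin accuracy matrix. The same resamples also score
#' each window on its own held-out window-averaged trials (`within`), which
#' is identical to [cross_validated_accuracy()] in window mode.
#'
#' @inheritParams cross_validated_accuracy
#' @param train_windows named list of length-2 second intervals
#' @param test_bins bin indices to test at (default all)
#' @return list of class `generalization_result`: `matrix` (windows x test
#'   bins, mean over resamples), `sd`, `within` (per-window mean within-
#'   window accuracy), `bin_starts`
#' @export
temporal_generalization <- function(pop, train_windows, test_bins = NULL,
                                    n_train = 15, n_resamples = 400,
                                    seed = 1) {
  stopifnot(inherits(pop, "pseudo_population"))
  if (is.null(test_bins)) test_bins <- seq_along(pop$bin_starts)
  W <- length(train_windows)
  acc <- array(NA_real_, c(n_resamples, W, length(test_bins)))
  within <- matrix(NA_real_, n_resamples, W)
  win_bins <- lapply(train_windows, function(w) {
    b <- which(pop$bin_starts >= w[1] - 1e-9 & pop$bin_starts < w[2] - 1e-9)
    if (!length(b)) stop("a training window contains no bins")
    b
  })
  for (r in seq_len(n_resamples)) {
    split <- assemble_pseudo_population(pop, n_train, seed = seed + r - 1)
    te_r_all <- pp_array(pop, split$test_ref, "reference", test_bins)
    te_t_all <- pp_array(pop, split$test_tgt, "target", test_bins)
    for (wi in seq_len(W)) {
      bns <- win_bins[[wi]]
      dec <- fit_prototype_decoder(
        pp_window_matrix(pp_array(pop, split$train_ref, "reference", bns)),
        pp_window_matrix(pp_array(pop, split$train_tgt, "target", bns)))
      for (j in seq_along(test_bins)) {
        y_r <- classify(dec, te_r_all[, j, , drop = TRUE])
        y_t <- classify(dec, te_t_all[, j, , drop = TRUE])
        acc[r, wi, j] <- (sum(y_r == "reference") + sum(y_t == "target")) /
          (2 * split$n_test)
      }
      y_r <- classify(dec, pp_window_matrix(
        pp_array(pop, split$test_ref, "reference", bns)))
      y_t <- classify(dec, pp_window_matrix(
        pp_array(pop, split$test_tgt, "target", bns)))
      within[r, wi] <- (sum(y_r == "reference") + sum(y_t == "target")) /
        (2 * split$n_test)
    }
  }
  m <- apply(acc, c(2, 3), mean)
  s <- apply(acc, c(2, 3), stats::sd)
  rownames(m) <- rownames(s) <- names(train_windows)
  w_mean <- colMeans(within)
  names(w_mean) <- names(train_windows)
  structure(list(matrix = m,
                 sd = s,
                 within = w_mean,
                 windows = train_windows,
                 bin_starts = pop$bin_starts[test_bins],
                 n_resamples = n_resamples),
            class = "generalization_result")
}

#' Transfer of correct-trial decoders to error trials
#'
#' Applies decoders trained on correct trials (the stored per-resample
#' decoding vectors of a window-mode [cross_validated_accuracy()]) to
#' pseudo-population vectors assembled from error trials, per test bin.
#'
#' @param result a window-mode `decoding_result` with stored decoders
#' @param error_pop a [pseudo_population()] built with `outcome = "error"`
#'   over the same units
#' @param test_bins bin indices of `error_pop` to score (default all)
#' @param seed integer seed for the error pseudo-trial pairing
#' @return list of class `transfer_result`: `mean`, `sd` per bin over the
#'   stored decoders, `bin_starts`
#' @export
decode_transfer <- function(result, error_pop, test_bins = NULL, seed = 1) {
  stopifnot(inherits(result, "decoding_result"),
            inherits(error_pop, "pseudo_population"))
  if (is.null(result$decoders))
    stop("transfer needs a window-mode decoding_result with stored decoders")
  if (ncol(result$decoders) != length(error_pop$by_unit))
    stop("unit sets of decoders and error population differ")
  if (is.null(test_bins)) test_bins <- seq_along(error_pop$bin_starts)
  n_err <- min(vapply(error_pop$by_unit, function(u)
    c(nrow(u$reference), nrow(u$target)), numeric(2)))
  if (n_err < 1) stop("no error trials available in both classes")
  set.seed(seed)
  U <- length(error_pop$by_unit)
  idx_r <- sapply(error_pop$by_unit, function(u)
    sample.int(nrow(u$reference))[seq_len(n_err)])
  idx_t <- sapply(error_pop$by_unit, function(u)
    sample.int(nrow(u$target))[seq_len(n_err)])
  idx_r <- matrix(idx_r, n_err, U); idx_t <- matrix(idx_t, n_err, U)
  te_r <- pp_array(error_pop, idx_r, "reference", test_bins)
  te_t <- pp_array(error_pop, idx_t, "target", test_bins)
  R <- nrow(result$decoders)
  acc <- matrix(NA_real_, R, length(test_bins))
  for (r in seq_len(R)) {
    w <- result$decoders[r, ]; b <- result$biases[r]
    for (j in seq_along(test_bins)) {
      y_r <- as.numeric(matrix(te_r[, j, ], ncol = U) %*% w + b)
      y_t <- as.numeric(matrix(te_t[, j, ], ncol = U) %*% w + b)
      acc[r, j] <- (sum(y_r <= 0) + sum(y_t > 0)) / (2 * n_err)
    }
  }
  structure(list(mean = colMeans(acc), sd = apply(acc, 2, stats::sd),
                 accuracy = acc, bin_starts = error_pop$bin_starts[test_bins],
                 n_err = n_err),
            class = "transfer_result")
}
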