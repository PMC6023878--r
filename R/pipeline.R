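#' One-sample Wilcoxon signed-rank test
#'
#' Thin wrapper around [stats::wilcox.test()] (two-sided, exact where
#' possible) used for testing whether modulation or asymmetry indices are
#' centered on a null median — the package's standard non-parametric
#' one-sample test.
#'
#' @param values numeric sample
#' @param mu null median (default 0)
#' @return list with `statistic` (V), `p`, `n` (non-null values used)
#' @export
wilcoxon_signed_rank_one_sample <- function(values, mu = 0) {
  values <- values[!is.na(values)]
  if (!length(values) || all(values == mu))
    stop("no non-null values for the signed-rank test")
  ht <- stats::wilcox.test(values, mu = mu, alternative = "two.sided",
                           exact = NULL, correct = TRUE)
  list(statistic = unname(ht$statistic), p = ht$p.value,
       n = sum(values != mu))
}

# Small stable FNV-1a hash of a serialized R object (hex string); used to
# fingerprint configurations in reports.
config_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Read a run configuration from YAML or JSON
#'
#' The file may contain a `generator` block (fields of
#' [generator_config()]) and an `analysis` block (decoding, reconstruction
#' and lick-control parameters plus `seed`).
#'
#' @param path file path (`.yaml`/`.yml` or `.json`)
#' @return list with `generator` (a `generator_config`) and `analysis`
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  gen <- do.call(generator_config, if (is.null(raw$generator)) list()
                 else raw$generator)
  analysis <- if (is.null(raw$analysis)) list() else raw$analysis
  list(generator = gen, analysis = analysis)
}

#' Run the full analysis sequence on a synthetic cohort
#'
#' Executes the pipeline in the order the analyses build on one another:
#' generate (or accept) a cohort, single-unit metrics (vector strength,
#' spontaneous-rate modulation), optional lick-unit removal, per-window
#' decoding with shuffle null, and projection geometry (asymmetry per
#' state, target enhancement, cross-state attribution). Identical
#' configuration and seed give an identical report payload.
#'
#' @param cfg a [generator_config()] (or a cohort list from
#'   [generate_cohort()] passed as `cohort`)
#' @param seed master seed
#' @param cohort optional pre-generated cohort (overrides `cfg` generation)
#' @param windows named list of decoding windows (default: the template's
#'   sound and silence windows)
#' @param n_resamples,n_perm,n_cv cross-validation and null sizes
#' @param lick_control run iterative lick-unit removal and exclude the
#'   removed units from decoding/geometry?
#' @param reconstruction run leave-one-out stimulus reconstruction per
#'   session? (the slowest stage; off by default)
#' @param recon_args list of arguments passed to
#'   [loo_reconstruction_mse()]
#' @param lick_args list of arguments passed to
#'   [iterative_unit_removal()]
#' @return object of class `analysis_report`; a nested list of stage
#'   results with provenance (`config_hash`, `seed`)
#' @export
run_full_analysis <- function(cfg = generator_config(), seed = 1,
                              cohort = NULL, windows = NULL,
                              n_resamples = 400, n_perm = 100, n_cv = 100,
                              lick_control = FALSE, reconstruction = FALSE,
                              recon_args = list(), lick_args = list()) {
  stopifnot(inherits(cfg, "generator_config"))
  t0 <- proc.time()[["elapsed"]]
  if (is.null(cohort)) cohort <- generate_cohort(cfg, seed)
  sessions <- cohort$sessions
  tpl <- sessions[[1]]$template
  if (is.null(windows))
    windows <- list(sound = epoch_window(tpl, "sound_window"),
                    silence = epoch_window(tpl, "silence_window"))
  report <- list(provenance = list(config_hash = config_hash(cfg),
                                   seed = seed,
                                   n_sessions = length(sessions)))

  # ---- single-unit metrics --------------------------------------------------
  vs <- do.call(rbind, lapply(sessions, vs_table))
  vs_mi <- local({
    eng <- vs[vs$state == "engaged" & vs$included, ]
    pas <- vs[vs$state == "passive" & vs$included, ]
    key <- paste(eng$unit_id, eng$stimulus)
    m <- match(key, paste(pas$unit_id, pas$stimulus))
    ok <- !is.na(m) & !is.na(eng$r) & !is.na(pas$r[m])
    modulation_index(eng$r[ok], pas$r[m][ok])$mi
  })
  spont_mi <- local({
    per_sess <- lapply(sessions, function(s) {
      sp <- spontaneous_rates(s)
      modulation_index(pmax(sp[, "engaged"], 0), pmax(sp[, "passive"], 0))$mi
    })
    unlist(per_sess)
  })
  report$metrics <- list(
    vs_table = vs, vs_mi = vs_mi,
    vs_mi_test = if (sum(!is.na(vs_mi) & vs_mi != 0) >= 5)
      wilcoxon_signed_rank_one_sample(vs_mi),
    spont_mi = spont_mi,
    spont_mi_test = if (sum(!is.na(spont_mi) & spont_mi != 0) >= 5)
      wilcoxon_signed_rank_one_sample(spont_mi))

  # ---- reconstruction -------------------------------------------------------
  if (reconstruction) {
    report$reconstruction <- lapply(sessions, function(s)
      do.call(loo_reconstruction_mse, c(list(s), recon_args)))
  }

  # ---- lick control ---------------------------------------------------------
  exclude <- c()
  if (lick_control) {
    lr <- do.call(iterative_unit_removal,
                  c(list(sessions, seed = substream_seed(seed, "lick")),
                    lick_args))
    report$lick_control <- lr
    exclude <- as.integer(lr$removed)
  }
  use_sessions <- lapply(sessions, function(s) {
    if (!length(exclude)) return(s)
    s$units <- s$units[!s$units$unit_id %in% exclude, , drop = FALSE]
    s$spikes <- s$spikes[!s$spikes$unit_id %in% exclude, , drop = FALSE]
    s
  })

  # ---- decoding -------------------------------------------------------------
  pops <- list(passive = pseudo_population(use_sessions, "passive"),
               engaged = pseudo_population(use_sessions, "engaged"))
  decoding <- list()
  for (st in names(pops)) {
    for (wn in names(windows)) {
      res <- cross_validated_accuracy(pops[[st]], window = windows[[wn]],
                                      n_resamples = n_resamples,
                                      seed = substream_seed(seed,
                                        paste0("cv_", st, "_", wn)))
      nul <- shuffled_null(pops[[st]], window = windows[[wn]],
                           n_perm = n_perm, n_cv = n_cv,
                           seed = substream_seed(seed,
                             paste0("null_", st, "_", wn)),
                           observed = res$mean)
      decoding[[st]][[wn]] <- list(cv = res, null = nul)
    }
  }
  # Bonferroni over the tested windows within each state
  for (st in names(decoding)) {
    ps <- vapply(decoding[[st]], function(x) x$null$p, numeric(1))
    adj <- stats::p.adjust(ps, method = "bonferroni")
    for (i in seq_along(decoding[[st]]))
      decoding[[st]][[i]]$p_bonferroni <- adj[i]
  }
  report$decoding <- decoding

  # ---- geometry -------------------------------------------------------------
  geometry <- list()
  for (st in names(pops)) {
    axes <- decoding[[st]][["sound"]]$cv$decoders
    tr <- project_on_axis(pops[[st]], axes)
    dists <- lapply(windows, function(w)
      list(target = distance_from_baseline(tr, w, "target"),
           reference = distance_from_baseline(tr, w, "reference")))
    geometry[[st]] <- list(
      trace = tr,
      distances = dists,
      asymmetry = lapply(dists, function(d)
        asymmetry_index(d$target$d, d$reference$d)))
  }
  geometry$target_enhancement <- lapply(names(windows), function(wn) {
    target_enhancement_index(
      geometry$engaged$distances[[wn]]$target$d,
      geometry$passive$distances[[wn]]$target$d,
      geometry$engaged$distances[[wn]]$reference$d,
      geometry$passive$distances[[wn]]$reference$d)
  })
  names(geometry$target_enhancement) <- names(windows)
  geometry$cross_state <- cross_state_projection(
    pops$passive, pops$engaged,
    decoding$engaged[["sound"]]$cv$decoders, windows$sound)
  report$geometry <- geometry
  report$elapsed_s <- proc.time()[["elapsed"]] - t0
  structure(report, class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report (config ", x$provenance$config_hash, ", seed ",
      x$provenance$seed, ")\n", sep = "")
  for (st in names(x$decoding)) {
    for (wn in names(x$decoding[[st]])) {
      d <- x$decoding[[st]][[wn]]
      cat(sprintf("  decoding %-8s %-8s acc %.3f (null p = %.4g)\n",
                  st, wn, d$cv$mean, d$null$p))
    }
  }
  for (st in intersect(c("passive", "engaged"), names(x$geometry))) {
    cat(sprintf("  asymmetry %-8s sound %.2f silence %.2f\n", st,
                x$geometry[[st]]$asymmetry$sound,
                x$geometry[[st]]$asymmetry$silence))
  }
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed_s))
  invisible(x)
}
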