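test_that("prototype decoder reproduces the defining formulas", {
  d <- fit_prototype_decoder(matrix(c(1, 0), 1), matrix(c(0, 1), 1))
  expect_equal(d$w, c(-1, 1))
  expect_equal(d$b, 0)
  expect_equal(as.character(classify(d, c(0.2, 0.9))), "target")
  expect_equal(attr(classify(d, c(0.2, 0.9)), "score"), 0.7,
               tolerance = 1e-12)
  # prototypes classify to their own side; the midpoint ties to reference
  expect_equal(as.character(classify(d, c(1, 0))), "reference")
  expect_equal(as.character(classify(d, c(0.5, 0.5))), "reference")
  # degenerate prototypes
  dd <- fit_prototype_decoder(matrix(c(1, 1), 1), matrix(c(1, 1), 1))
  expect_true(dd$degenerate)
})

test_that("decoder is invariant to common translations and scalings", {
  set.seed(9)
  tr_r <- matrix(rnorm(40), 8); tr_t <- matrix(rnorm(40, 1), 8)
  x <- matrix(rnorm(30), 6)
  d1 <- fit_prototype_decoder(tr_r, tr_t)
  shift <- matrix(rnorm(5), nrow(tr_r), 5, byrow = TRUE)
  d2 <- fit_prototype_decoder(tr_r + shift, tr_t + shift)
  expect_equal(d2$w, d1$w, tolerance = 1e-12)
  expect_equal(as.character(classify(d2, x + shift[1, ][col(x)])),
               as.character(classify(d1, x)))
  d3 <- fit_prototype_decoder(3 * tr_r, 3 * tr_t)
  expect_equal(as.character(classify(d3, 3 * x)),
               as.character(classify(d1, x)))
})

test_that("pseudo-population assembly balances classes and enforces
           trial minima", {
  cfg <- generator_config(n_sessions = 2, n_units = 5, n_trials = 20,
                          error_fraction = 0)
  coh <- generate_cohort(cfg, seed = 30)
  pop <- pseudo_population(coh$sessions, "engaged")
  split <- assemble_pseudo_population(pop, n_train = 15, seed = 1)
  expect_equal(dim(split$train_ref), c(15, 10))
  expect_equal(split$n_test, 5)
  s2 <- assemble_pseudo_population(pop, n_train = 15, seed = 2)
  expect_false(identical(split$train_ref, s2$train_ref))
  expect_error(assemble_pseudo_population(pop, n_train = 20), "n_train")
})

test_that("accuracy equals exhaustive evaluation of the decision rule", {
  # <= 8 pseudo-trials: brute force every test item by hand
  cfg <- generator_config(n_sessions = 1, n_units = 4, n_trials = 19,
                          error_fraction = 0)
  coh <- generate_cohort(cfg, seed = 31)
  pop <- pseudo_population(coh$sessions, "engaged")
  res <- cross_validated_accuracy(pop, window = c(1.7, 2.0),
                                  n_resamples = 3, seed = 77)
  for (r in 1:3) {
    split <- assemble_pseudo_population(pop, n_train = 15, seed = 77 + r - 1)
    bins <- which(pop$bin_starts >= 1.7 - 1e-9 & pop$bin_starts < 2.0 - 1e-9)
    getmat <- function(idx, cl) t(sapply(seq_len(nrow(idx)), function(j)
      sapply(seq_along(pop$by_unit), function(u)
        mean(pop$by_unit[[u]][[cl]][idx[j, u], bins]))))
    cR <- colMeans(getmat(split$train_ref, "reference"))
    cT <- colMeans(getmat(split$train_tgt, "target"))
    w <- cT - cR; b <- -sum((cR + cT) * w) / 2
    te_r <- getmat(split$test_ref, "reference")
    te_t <- getmat(split$test_tgt, "target")
    correct <- sum(te_r %*% w + b <= 0) + sum(te_t %*% w + b > 0)
    expect_equal(res$accuracy[r, 1], correct / (2 * split$n_test))
  }
})

test_that("prototype accuracy approaches the Gaussian closed form", {
  set.seed(55)
  dim_u <- 12
  for (delta in c(0.5, 1.5)) {
    acc <- replicate(8, {
      mu <- rep(0, dim_u); mu[1] <- delta
      tr_r <- matrix(rnorm(200 * dim_u), 200)
      tr_t <- matrix(rnorm(200 * dim_u), 200) + rep(mu, each = 200)
      d <- fit_prototype_decoder(tr_r, tr_t)
      te_r <- matrix(rnorm(400 * dim_u), 400)
      te_t <- matrix(rnorm(400 * dim_u), 400) + rep(mu, each = 400)
      (sum(classify(d, te_r) == "reference") +
         sum(classify(d, te_t) == "target")) / 800
    })
    expect_lt(abs(mean(acc) - pnorm(delta / 2)), 0.03)
  }
})

test_that("indistinguishable classes decode at chance and separable ones
           beat the shuffle null", {
  cfg <- generator_config(n_sessions = 1, n_units = 20, n_trials = 20,
                          error_fraction = 0)
  coh <- generate_cohort(cfg, seed = 40)
  pop <- pseudo_population(coh$sessions, "passive")
  # pre-stimulus silence carries no class information
  pre <- cross_validated_accuracy(pop, window = c(0, 0.4),
                                  n_resamples = 50, seed = 3)
  nul <- shuffled_null(pop, window = c(0, 0.4), n_perm = 15, n_cv = 15,
                       seed = 4, observed = pre$mean)
  expect_lt(abs(nul$mean - 0.5), 3 * sd(nul$null) / sqrt(nul$n_perm) + 0.02)
  expect_gt(nul$p, 0.05)
  # the sound window is separable
  snd <- cross_validated_accuracy(pop, window = c(1.7, 2.0),
                                  n_resamples = 50, seed = 5)
  nul2 <- shuffled_null(pop, window = c(1.7, 2.0), n_perm = 15, n_cv = 15,
                        seed = 6, observed = snd$mean)
  expect_gt(snd$mean, nul2$ci[2, 1])
  expect_equal(nul2$p, 1 / 16)            # the add-one lower bound
})

test_that("a single resample warns and reports a mean only", {
  cfg <- generator_config(n_sessions = 1, n_units = 5, n_trials = 17,
                          error_fraction = 0)
  coh <- generate_cohort(cfg, seed = 41)
  pop <- pseudo_population(coh$sessions, "passive")
  expect_warning(res <- cross_validated_accuracy(pop, window = c(1.7, 2.0),
                                                 n_resamples = 1, seed = 1),
                 "single resample")
  expect_length(res$mean, 1)
  expect_null(res$ci)
  expect_equal(res$min_p, 1)
})

test_that("temporal generalization separates sound and silence codes", {
  cfg <- generator_config(n_sessions = 1, n_units = 30, n_trials = 25,
                          error_fraction = 0)
  coh <- generate_cohort(cfg, seed = 50)
  pop <- pseudo_population(coh$sessions, "engaged")
  bs <- pop$bin_starts
  test_bins <- which((bs >= 1.7 & bs < 2.0) | (bs >= 2.5 & bs < 2.8))
  gen <- temporal_generalization(pop,
                                 list(sound = c(1.7, 2.0),
                                      silence = c(2.5, 2.8)),
                                 test_bins = test_bins,
                                 n_resamples = 40, seed = 8)
  snd_cols <- which(gen$bin_starts < 2.0)
  sil_cols <- which(gen$bin_starts >= 2.5)
  # within-epoch decoding is high; the codes are planted along orthogonal
  # directions, so cross-epoch generalization collapses towards chance
  expect_gt(mean(gen$matrix["sound", snd_cols]), 0.9)
  expect_gt(mean(gen$matrix["silence", sil_cols]), 0.7)
  expect_lt(mean(gen$matrix["sound", sil_cols]), 0.65)
  expect_lt(mean(gen$matrix["silence", snd_cols]), 0.65)
  # training and testing on the same window reproduces window-mode CV
  cv <- cross_validated_accuracy(pop, window = c(1.7, 2.0),
                                 n_resamples = 40, seed = 8)
  expect_equal(gen$within[["sound"]], cv$mean, tolerance = 1e-12)
})

test_that("correct-trained decoders transfer per the planted error model", {
  cfg <- generator_config(n_sessions = 2, n_units = 25, n_trials = 40)
  coh <- generate_cohort(cfg, seed = 60)
  pop_e <- pseudo_population(coh$sessions, "engaged")
  pop_err <- pseudo_population(coh$sessions, "engaged", outcome = "error")
  bs <- pop_err$bin_starts
  sil_bins <- which(bs >= 2.5 - 1e-9 & bs < 2.8 - 1e-9)
  snd_bins <- which(bs >= 1.7 - 1e-9 & bs < 2.0 - 1e-9)
  r_sil <- cross_validated_accuracy(pop_e, window = c(2.5, 2.8),
                                    n_resamples = 40, seed = 2)
  r_snd <- cross_validated_accuracy(pop_e, window = c(1.7, 2.0),
                                    n_resamples = 40, seed = 2)
  tr_sil <- decode_transfer(r_sil, pop_err, test_bins = sil_bins, seed = 3)
  tr_snd <- decode_transfer(r_snd, pop_err, test_bins = snd_bins, seed = 3)
  # the silence code is planted at the weak passive amplitude on error
  # trials: transfer collapses, while the sound code is intact
  expect_lt(mean(tr_sil$mean), r_sil$mean - 0.2)
  expect_gt(mean(tr_snd$mean), 0.9)
  # no error trials at all -> precondition error
  cfg0 <- generator_config(n_sessions = 1, n_units = 5, n_trials = 17,
                           error_fraction = 0)
  coh0 <- generate_cohort(cfg0, seed = 61)
  expect_error(suppressWarnings(
    pseudo_population(coh0$sessions, "engaged", outcome = "error")))
})
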