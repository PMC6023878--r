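# Build a minimal pseudo_population by hand with known class means.
fake_pop <- function(mean_ref, mean_tgt, spont, n_trials = 6, noise = 0,
                     n_bins = 32, seed = 1) {
  set.seed(seed)
  tpl <- epoch_template()
  bs <- seq(0, 3.1, by = 0.1)
  U <- length(spont)
  pre_bins <- which(bs < 0.4)
  by_unit <- lapply(seq_len(U), function(u) {
    mk <- function(mu_evoked) {
      m <- matrix(spont[u], n_trials, length(bs))
      sound <- which(bs >= 1.65 & bs < 2.4)
      m[, sound] <- mu_evoked
      m + noise * matrix(rnorm(length(m)), n_trials)
    }
    list(reference = mk(mean_ref[u]), target = mk(mean_tgt[u]))
  })
  names(by_unit) <- seq_len(U)
  structure(list(unit_ids = seq_len(U), bin_starts = bs, width = 0.1,
                 template = tpl, by_unit = by_unit, state = "passive"),
            class = "pseudo_population")
}

test_that("projection of spontaneous activity is zero after subtraction and
           planted excursions project at their planted distance", {
  U <- 30
  set.seed(3)
  w <- rnorm(U); w <- w / sqrt(sum(w^2))
  spont <- runif(U, 2, 6)
  d_t <- 4
  pop <- fake_pop(mean_ref = spont, mean_tgt = spont + d_t * w, spont = spont)
  tr <- project_on_axis(pop, matrix(w, 1))
  pre <- which(tr$bin_starts < 0.4)
  sound <- which(tr$bin_starts >= 1.7 & tr$bin_starts < 2.0)
  # spontaneous epochs project to 0; the planted pattern to its distance
  expect_equal(max(abs(tr$mean[, pre])), 0, tolerance = 1e-10)
  expect_equal(mean(tr$mean["target", sound]), d_t, tolerance = 1e-10)
  # reference evoked equals spontaneous -> projects with the baseline
  expect_equal(mean(tr$mean["reference", sound]), 0, tolerance = 1e-10)
  # a pattern orthogonal to the axis projects at the baseline too
  v_orth <- rnorm(U); v_orth <- v_orth - sum(v_orth * w) * w
  pop2 <- fake_pop(mean_ref = spont + v_orth, mean_tgt = spont + d_t * w,
                   spont = spont)
  tr2 <- project_on_axis(pop2, matrix(w, 1))
  expect_equal(mean(tr2$mean["reference", sound]), 0, tolerance = 1e-10)
})

test_that("projecting averaged activity equals averaging projections", {
  U <- 10
  set.seed(4)
  w <- matrix(rnorm(3 * U), 3)
  spont <- runif(U, 1, 5)
  mA_r <- spont + rnorm(U); mA_t <- spont + rnorm(U)
  mB_r <- spont + rnorm(U); mB_t <- spont + rnorm(U)
  popA <- fake_pop(mA_r, mA_t, spont)
  popB <- fake_pop(mB_r, mB_t, spont)
  popM <- fake_pop((mA_r + mB_r) / 2, (mA_t + mB_t) / 2, spont)
  trA <- project_on_axis(popA, w)
  trB <- project_on_axis(popB, w)
  trM <- project_on_axis(popM, w)
  expect_equal(trM$per_decoder, (trA$per_decoder + trB$per_decoder) / 2,
               tolerance = 1e-12)
})

test_that("distance from baseline is the window mean offset", {
  U <- 8
  w <- rep(1, U) / sqrt(U)
  spont <- rep(3, U)
  pop <- fake_pop(spont, spont + 2 * w, spont)
  tr <- project_on_axis(pop, matrix(w, 1))
  d <- distance_from_baseline(tr, c(1.7, 2.0), "target")
  expect_equal(d$d, 2, tolerance = 1e-10)
  expect_equal(distance_from_baseline(tr, c(1.7, 2.0), "reference")$d, 0,
               tolerance = 1e-10)
  # hand arithmetic on the stored trace
  sound <- which(tr$bin_starts >= 1.7 & tr$bin_starts < 2.0)
  expect_equal(d$d, abs(mean(tr$per_decoder[1, "target", sound])),
               tolerance = 1e-12)
  expect_error(distance_from_baseline(tr, c(5, 6), "target"), "no bins")
})

test_that("asymmetry and target-enhancement indices follow their formulas", {
  expect_equal(asymmetry_index(2, 0.5), 1.5)
  expect_equal(asymmetry_index(1, 1), 0)
  expect_equal(asymmetry_index(0.5, 2), -asymmetry_index(2, 0.5))
  expect_error(asymmetry_index(-1, 0), ">= 0")
  expect_equal(target_enhancement_index(3, 1, 0.5, 1), 2.5)
  expect_equal(target_enhancement_index(2, 2, 1, 1), 0)
  # symmetric gain g on both classes: index = (g - 1) * (d_T - d_P)
  g <- 1.7; d_t <- 2.3; d_r <- 0.9
  expect_equal(target_enhancement_index(g * d_t, d_t, g * d_r, d_r),
               (g - 1) * (d_t - d_r), tolerance = 1e-12)
})

test_that("cross-state cases coincide for identical states", {
  U <- 12
  set.seed(6)
  w <- matrix(rnorm(2 * U), 2)
  spont <- runif(U, 2, 4)
  pop <- fake_pop(spont + rnorm(U), spont + rnorm(U), spont, seed = 7)
  cs <- cross_state_projection(pop, pop, w, c(1.7, 2.0))
  expect_equal(cs$asymmetry[1], cs$asymmetry[2], tolerance = 1e-10)
  expect_equal(cs$asymmetry[2], cs$asymmetry[3], tolerance = 1e-10)
})

test_that("uniform weights expose only global-rate asymmetries", {
  U <- 20
  set.seed(8)
  ones <- rep(1, U) / sqrt(U)
  v <- rnorm(U); v <- v - sum(v * ones) * ones; v <- v / sqrt(sum(v^2))
  spont <- rep(4, U)
  # asymmetry confined to a direction orthogonal to the all-ones vector
  pop <- fake_pop(spont, spont + 5 * v, spont)
  tru <- uniform_weight_projection(pop)
  trv <- project_on_axis(pop, matrix(v, 1))
  sound_w <- c(1.7, 2.0)
  expect_lt(abs(distance_from_baseline(tru, sound_w, "target")$d), 1e-10)
  expect_equal(distance_from_baseline(trv, sound_w, "target")$d, 5,
               tolerance = 1e-10)
  # a global rate increase for the target appears in both
  pop2 <- fake_pop(spont, spont + 2, spont)
  tru2 <- uniform_weight_projection(pop2)
  expect_equal(distance_from_baseline(tru2, sound_w, "target")$d,
               2 * sqrt(U), tolerance = 1e-10)
})

test_that("latency to half max interpolates ramps and flags flat traces", {
  bs <- seq(0, 1, by = 0.1)
  ramp <- 2 * bs
  lat <- latency_half_max(ramp, bs, c(0.05, 1.05), c(0, 0.05),
                          smooth_bins = 1)
  expect_equal(lat$latency, 0.5, tolerance = 1e-9)
  # a step trace crosses within one bin of the step time
  step <- ifelse(bs >= 0.5, 2, 0)
  lat2 <- latency_half_max(step, bs, c(0.05, 1.05), c(0, 0.05),
                           smooth_bins = 1)
  expect_gte(lat2$latency, 0.4)
  expect_lte(lat2$latency, 0.5)
  flat <- rep(1, length(bs))
  lat3 <- latency_half_max(flat, bs, c(0.05, 1.0), c(0, 0.05))
  expect_true(lat3$undefined)
  # onset referencing
  lat4 <- latency_half_max(ramp, bs, c(0.05, 1.05), c(0, 0.05),
                           onset = 0.2, smooth_bins = 1)
  expect_equal(lat4$latency, 0.3, tolerance = 1e-9)
})

test_that("end-to-end: engaged asymmetry exceeds passive under the planted
           baseline shift", {
  coh <- generate_cohort(generator_config(), seed = 101)
  pop_p <- pseudo_population(coh$sessions, "passive")
  pop_e <- pseudo_population(coh$sessions, "engaged")
  sw <- c(1.7, 2.0)
  re <- cross_validated_accuracy(pop_e, window = sw, n_resamples = 30,
                                 seed = 7)
  rp <- cross_validated_accuracy(pop_p, window = sw, n_resamples = 30,
                                 seed = 7)
  asym <- function(pop, dec) {
    tr <- project_on_axis(pop, dec)
    asymmetry_index(distance_from_baseline(tr, sw, "target")$d,
                    distance_from_baseline(tr, sw, "reference")$d)
  }
  expect_gt(asym(pop_e, re$decoders), asym(pop_p, rp$decoders))
})
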