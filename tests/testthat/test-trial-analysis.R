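# Small deterministic trial set: 2 ROIs, step response of height `amp` (in
# normalised units) on ROI 1 only. The lead-in holds a clean resting
# baseline (samples 1-2 s, F = 100) and a full-range plateau (2-7 s,
# F = 150) long enough (> 5% of samples) that the 95% quantile sits on it,
# so dFF = 0 at rest and `amp` during stimulation.
step_trial_set <- function(n_trials = 4, amp = 0.5, noise = 0, seed = 1,
                           sr = 10) {
  set.seed(seed)
  stim_n <- 5 * sr
  isi_n <- 10 * sr
  pre_n <- 10 * sr
  n_t <- pre_n + n_trials * (stim_n + isi_n)
  onsets <- pre_n + (seq_len(n_trials) - 1) * (stim_n + isi_n) + 1
  stim <- numeric(n_t)
  for (o in onsets) stim[o:(o + stim_n - 1)] <- 1
  plateau <- numeric(n_t)
  plateau[(2 * sr + 1):(7 * sr)] <- 1
  F <- rbind(100 + 50 * pmax(amp * stim, plateau) + rnorm(n_t, 0, noise),
             100 + 50 * plateau + rnorm(n_t, 0, noise))
  behaviour <- rep("rest", n_t)
  behaviour[plateau > 0] <- "undefined"
  for (o in onsets) behaviour[(o - sr):(o - 1)] <- "forward"
  roi_trial_set(F, sample_rate = sr,
                stim_epochs = tibble::tibble(onset = onsets,
                                             offset = onsets + stim_n - 1),
                behaviour = behaviour)
}

test_that("smoothing preserves constants, removes impulses, reduces noise", {
  const <- matrix(5, 1, 200)
  expect_equal(smooth_traces(const), const, tolerance = 1e-12)

  impulse <- matrix(0, 1, 100)
  impulse[1, 50] <- 10
  sm <- median_smooth(impulse[1, ], 3)
  expect_equal(sm, rep(0, 100))

  set.seed(4)
  noisy <- matrix(rnorm(5000), 5, 1000)
  smn <- smooth_traces(noisy)
  expect_true(all(apply(smn, 1, var) < apply(noisy, 1, var)))

  expect_error(smooth_traces(matrix(1, 1, 3), gaussian_sd = 3), "shorter")
})

test_that("rest-onset detection enforces all three criteria", {
  sr <- 10
  epochs <- tibble::tibble(onset = 61L, offset = 80L)
  # continuous rest block outside stimulation: one onset at block start
  beh <- rep("undefined", 120)
  beh[21:40] <- "rest"
  expect_equal(detect_rest_onsets(beh, epochs, sr), 21L)

  # rest block inside stimulation is excluded
  beh2 <- rep("undefined", 120)
  beh2[65:80] <- "rest"
  expect_length(detect_rest_onsets(beh2, epochs, sr), 0)

  # randomized label sequences match an independent rule-by-rule scan
  set.seed(7)
  for (rep in 1:20) {
    beh3 <- sample(c("rest", "forward", "undefined"), 200, TRUE,
                   prob = c(0.5, 0.3, 0.2))
    got <- detect_rest_onsets(beh3, epochs, sr)
    # oracle: direct scan over rest transitions
    is_rest <- beh3 == "rest"
    trans <- which(is_rest & !c(FALSE, is_rest[-200]))
    expected <- integer()
    last <- -Inf
    for (t in trans) {
      if (t + 9 > 200) next
      if (t - last < 10) next
      if (any(seq(t, t + 9) %in% 61:80)) next
      if (mean(is_rest[t:(t + 9)]) < 0.75) next
      expected <- c(expected, t)
      last <- t
    }
    expect_equal(got, expected)
  }
})

test_that("deltaF/F maps rest to 0 and the 95% quantile to 1", {
  rts <- step_trial_set(amp = 0.5)
  rts <- compute_dff(rts)
  # a flat-baseline ROI has dFF ~ 0 outside plateau/stimulation
  late_rest <- which(rts$behaviour == "rest")
  late_rest <- late_rest[late_rest > 100]
  expect_equal(mean(rts$dff[2, late_rest]), 0, tolerance = 1e-6)
  # plateau samples of the responding ROI sit near 1 (95% quantile)
  expect_equal(max(rts$dff[1, ]), 1, tolerance = 0.05)

  # constant trace is degenerate, flagged and NA
  Fc <- matrix(100, 2, 400)
  Fc[2, ] <- 100 + sin(seq_len(400) / 10)
  rts2 <- roi_trial_set(Fc, sample_rate = 10,
                        stim_epochs = tibble::tibble(onset = 50L, offset = 99L))
  rts2 <- quietly(compute_dff(rts2))
  expect_equal(rts2$degenerate_rois, "roi1")
  expect_true(all(is.na(rts2$dff[1, ])))

  # without rest onsets the 5% quantile fallback is used
  rts3 <- roi_trial_set(Fc[2, , drop = FALSE], sample_rate = 10,
                        stim_epochs = tibble::tibble(onset = 50L, offset = 99L))
  rts3 <- quietly(compute_dff(rts3))
  f <- Fc[2, ]
  f0 <- quantile(f, 0.05, names = FALSE)
  fmax <- quantile(f, 0.95, names = FALSE)
  expect_equal(unname(rts3$dff[1, 1]), (f[1] - f0) / (fmax - f0))
})

test_that("trial selection applies the pre-stimulus walking rule", {
  rts <- step_trial_set(n_trials = 12)
  sel <- select_trials(rts, min_trials = 10)
  expect_true(all(sel$kept))
  expect_true(attr(sel, "fly_ok"))

  # flip the pre-stimulus second of 4 trials to rest: 8 < 10 remain
  rts2 <- rts
  for (k in 1:4) {
    o <- rts2$stim_epochs$onset[k]
    rts2$behaviour[(o - 10):(o - 1)] <- "rest"
  }
  sel2 <- select_trials(rts2, min_trials = 10)
  expect_equal(sum(sel2$kept), 8)
  expect_false(attr(sel2, "fly_ok"))
})

test_that("stimulus-triggered averages mask unreliable samples", {
  # identical trials with a +0.5 step: mean 0.5 in-stimulus, nothing masked
  rts <- step_trial_set(amp = 0.5, noise = 0)
  rts <- compute_dff(rts)
  sta <- stimulus_triggered_average(rts)
  in_stim <- sta$time > 0.5 & sta$time < 4.5
  expect_equal(mean(sta$masked[1, in_stim]), 0.5, tolerance = 0.01)
  expect_true(all(abs(sta$ci[1, in_stim]) < 1e-9))

  # masking never increases |mean|: masked values are 0 or >= CI
  rtsn <- step_trial_set(amp = 0.3, noise = 1, seed = 5)
  rtsn <- compute_dff(rtsn)
  stan <- stimulus_triggered_average(rtsn)
  off <- abs(stan$masked) > 0
  expect_true(all(abs(stan$masked[off]) >= stan$ci[off] - 1e-12))

  # trials alternating +/-0.5 average to zero and are fully masked
  sr <- 10
  n_trials <- 6
  stim_n <- 5 * sr; isi_n <- 10 * sr; pre_n <- 6 * sr
  n_t <- pre_n + n_trials * (stim_n + isi_n)
  onsets <- pre_n + (seq_len(n_trials) - 1) * (stim_n + isi_n) + 1
  x <- numeric(n_t)
  for (k in seq_len(n_trials)) {
    x[onsets[k]:(onsets[k] + stim_n - 1)] <- 0.5 * (-1)^k
  }
  rts_alt <- roi_trial_set(matrix(x, 1), sample_rate = sr,
                           stim_epochs = tibble::tibble(
                             onset = onsets, offset = onsets + stim_n - 1))
  rts_alt$dff <- matrix(x, 1)  # already on the dFF scale
  sta_alt <- stimulus_triggered_average(rts_alt)
  expect_true(all(sta_alt$masked[1, ] == 0))
})

test_that("ROI responses and activation metrics follow their definitions", {
  rts <- step_trial_set(amp = 0.5, noise = 0)
  rts <- compute_dff(rts)
  sta <- stimulus_triggered_average(rts)
  resp <- roi_response(sta)
  expect_equal(resp$response[1], 0.5, tolerance = 0.03)
  expect_true(resp$activated[1])
  expect_false(resp$activated[2])

  # an all-masked trace yields response 0, not activated
  expect_equal(resp$response[2], 0)

  met <- activation_metrics(tibble::tibble(
    roi = paste0("r", 1:4),
    response = c(0.5, 0.2, 0, -0.3),
    responsive = c(TRUE, TRUE, FALSE, TRUE),
    activated = c(TRUE, TRUE, FALSE, FALSE)
  ), n_visible_rois = 4)
  expect_equal(met$n_activated, 2)
  expect_equal(met$fraction_activated, 0.5)
  expect_equal(met$summed_positive, 0.7)

  all_masked <- activation_metrics(tibble::tibble(
    roi = "r1", response = 0, responsive = FALSE, activated = FALSE
  ), 1)
  expect_equal(unlist(all_masked), c(n_activated = 0, fraction_activated = 0,
                                     summed_positive = 0))
  expect_error(activation_metrics(tibble::tibble(response = numeric(),
                                                 activated = logical()), 0),
               "no visible")
})

test_that("Mann-Whitney comparisons match exact enumeration", {
  # extreme ordering of 3 vs 3: two-sided p = 0.1
  res <- compare_flies_mwu(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, mwu_exact_enumeration(c(1, 2, 3), c(4, 5, 6)))

  # identical groups give the maximal p of 1
  expect_equal(compare_flies_mwu(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  # agreement with enumeration for random untied samples up to n = 8
  set.seed(12)
  for (rep in 1:15) {
    na <- sample(2:8, 1)
    nb <- sample(2:8, 1)
    x <- sample(seq(1, 100), na)
    y <- sample(seq(101, 200), nb) - runif(nb) * 150
    expect_equal(compare_flies_mwu(x, y)$p_value,
                 mwu_exact_enumeration(x, y))
  }

  # rank invariance: a monotone shift of ranks preserves p
  x <- c(3, 9, 27)
  y <- c(5, 11, 40)
  expect_equal(compare_flies_mwu(x, y)$p_value,
               compare_flies_mwu(rank(c(x, y))[1:3],
                                 rank(c(x, y))[4:6])$p_value)
})

test_that("density maps register flies and preserve response units", {
  # single fly, single nonzero ROI: peak value equals the response
  fly1 <- tibble::tibble(fly = 1, y = c(10, 40, 25), x = c(30, 32, 20),
                         response = c(0, 0, 1))
  m <- density_map(fly1, sigma = 3, canvas = c(60, 60))
  expect_equal(max(m), 1, tolerance = 1e-6)

  # two flies with identical maps average to the same map
  fly2 <- fly1
  fly2$fly <- 2
  m2 <- density_map(dplyr::bind_rows(fly1, fly2), sigma = 3,
                    canvas = c(60, 60))
  expect_equal(unclass(m2), unclass(m), tolerance = 1e-12)

  # a translated copy registers onto the same map
  fly3 <- fly1
  fly3$y <- fly3$y + 7
  fly3$x <- fly3$x - 4
  m3 <- density_map(fly3, sigma = 3, canvas = c(60, 60))
  expect_equal(unclass(m3), unclass(m), tolerance = 1e-12)

  flat <- tibble::tibble(fly = 1, y = c(5, 5), x = c(1, 2), response = 1)
  expect_error(density_map(flat), "distinct y")
})
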