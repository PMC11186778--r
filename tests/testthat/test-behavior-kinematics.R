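test_that("velocity filters preserve constants and suppress noise", {
  const <- rep(3, 300)
  expect_equal(filter_velocity(const, "ball"), const, tolerance = 1e-9)
  expect_equal(filter_velocity(const, "wheel"), const, tolerance = 1e-9)

  spike <- rep(0, 300)
  spike[150] <- 50
  expect_equal(filter_velocity(spike, "ball"), rep(0, 300), tolerance = 1e-9)

  set.seed(3)
  noisy <- rnorm(2000)
  expect_lt(var(filter_velocity(noisy, "ball")), var(noisy))
  expect_lt(var(filter_velocity(noisy, "wheel")), var(noisy))
})

test_that("motion energy is frame-to-frame displacement with moving average", {
  # stationary keypoint -> zero everywhere
  expect_equal(motion_energy(rep(2, 100), rep(5, 100)), rep(0, 100))

  # one-frame jump of (3, 4) px: instantaneous ME = 5 before averaging
  x <- rep(0, 100); y <- rep(0, 100)
  x[51:100] <- 3; y[51:100] <- 4
  me_raw <- c(0, sqrt(diff(x)^2 + diff(y)^2))
  expect_equal(max(me_raw), 5)
  expect_equal(sum(motion_energy(x, y, window = 50) > 0), 50)

  # sinusoidal trajectory matches the direct two-line oracle
  t <- seq(0, 4 * pi, length.out = 300)
  xs <- 10 * sin(t); ys <- 3 * cos(t)
  oracle <- c(0, sqrt(diff(xs)^2 + diff(ys)^2))
  cs <- cumsum(c(0, oracle))
  lo <- pmax(seq_len(300) - 24, 1); hi <- pmin(seq_len(300) + 25, 300)
  oracle_avg <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  expect_equal(motion_energy(xs, ys), oracle_avg)
})

test_that("front-leg height follows the pixel-down sign convention", {
  coxa_y <- rep(50, 10)
  expect_equal(front_leg_height(rep(60, 10), coxa_y), rep(10, 10)) # leg low
  expect_equal(front_leg_height(rep(50, 10), coxa_y), rep(0, 10))
  expect_equal(front_leg_height(rep(30, 10), coxa_y), rep(-20, 10)) # lifted
})

test_that("behaviour classification applies thresholds and precedence", {
  n <- 5
  zero <- rep(0, n)
  expect_equal(classify_behaviour(rep(2, n), zero, rep(10, n)),
               rep("forward", n))
  expect_equal(classify_behaviour(rep(-1.5, n), zero, rep(10, n)),
               rep("backward", n))
  # boundary: exactly -1 is backward, exactly +1 is not forward (and, being
  # neither slow enough for rest nor a grooming pose, it is undefined)
  expect_equal(classify_behaviour(c(-1, 1), c(0, 0), c(10, 10)),
               c("backward", "undefined"))
  # grooming OR-rule: lifted leg or high motion energy
  expect_equal(classify_behaviour(zero, zero, rep(-10, n)),
               rep("anterior_grooming", n))
  expect_equal(classify_behaviour(zero, rep(8, n), rep(10, n)),
               rep("anterior_grooming", n))
  expect_equal(classify_behaviour(zero, zero, rep(10, n)), rep("rest", n))
  # moderate velocity with low ME fits nothing
  expect_equal(classify_behaviour(rep(0.6, n), rep(2, n), rep(10, n)),
               rep("undefined", n))
  # precedence: backward beats grooming cues
  expect_equal(classify_behaviour(rep(-3, n), rep(9, n), rep(-10, n)),
               rep("backward", n))
  # determinism
  expect_identical(classify_behaviour(rep(2, n), zero, rep(10, n)),
                   classify_behaviour(rep(2, n), zero, rep(10, n)))
})

test_that("behaviour probabilities are per-time fractions that sum to 1", {
  # single trial: indicator functions
  single <- matrix(c("forward", "forward", "rest"), nrow = 1)
  bp <- behaviour_probability(single)
  expect_true(all(bp$probability == 1))

  # two trials disagreeing everywhere: all fractions 0.5
  two <- rbind(rep("forward", 4), rep("rest", 4))
  bp2 <- behaviour_probability(two)
  expect_true(all(bp2$probability == 0.5))

  # random stacks: equals a direct per-column tally, sums to 1
  set.seed(8)
  m <- matrix(sample(c("forward", "rest", "undefined"), 60, TRUE), nrow = 6)
  bp3 <- behaviour_probability(m)
  sums <- tapply(bp3$probability, bp3$time, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_equal(
    bp3$probability[bp3$time == 3 & bp3$label == "rest"],
    mean(m[, 3] == "rest")
  )
})

test_that("kinematic metrics compute the named distances", {
  kp <- tibble::tibble(
    frame = rep(1:2, each = 4),
    landmark = rep(c("anal_plate", "posterior_stripe", "front_tibia_tarsus",
                     "neck"), 2),
    x = c(0, 0, 0, 3, 0, 3, 1, 1),
    y = c(0, 0, 0, 4, 0, 4, 1, 1)
  )
  m <- kinematic_metric(kp, "abdomen_contraction")
  expect_equal(m$value, c(0, 5))   # coincident then 3-4-5
  m2 <- kinematic_metric(kp, "front_leg_approach")
  expect_equal(m2$value, c(5, 0))
  m3 <- kinematic_metric(kp, "abdomen_dip")
  expect_equal(m3$value, c(0, 0))
  m4 <- kinematic_metric(metric = "turn_magnitude",
                         turn_velocity = c(-30, 20))
  expect_equal(m4$value, c(30, 20))
  expect_error(kinematic_metric(kp[kp$landmark != "neck", ],
                                "front_leg_approach"), "neck")

  # metrics are invariant to uniform pixel translation
  kp_shift <- kp
  kp_shift$x <- kp_shift$x + 11
  kp_shift$y <- kp_shift$y - 7
  expect_equal(kinematic_metric(kp_shift, "abdomen_contraction")$value,
               m$value)
})

test_that("stimulus-window comparison averages trials within flies", {
  # two conditions with a planted step difference
  mk <- function(fly, condition, delta) {
    tidyr::expand_grid(trial = 1:3, time = seq(-1, 3, by = 0.1)) |>
      dplyr::mutate(fly = fly, condition = condition,
                    value = ifelse(time >= 0, delta, 0))
  }
  dat <- dplyr::bind_rows(
    mk("f1", "intact", 2), mk("f2", "intact", 2.2), mk("f3", "intact", 1.9),
    mk("f4", "headless", 0.1), mk("f5", "headless", 0), mk("f6", "headless", -0.1)
  )
  res <- stim_window_compare(dat, window_s = 2.5)
  expect_equal(nrow(res$per_fly), 6)
  expect_equal(res$test$p_value, 0.1)  # extreme 3-vs-3 ordering
  expect_equal(res$per_fly$mean_value[res$per_fly$fly == "f1"], 2)

  # identical conditions: maximal p
  dat2 <- dplyr::bind_rows(mk("f1", "a", 1), mk("f2", "b", 1))
  expect_equal(stim_window_compare(dat2)$test$p_value, 1)

  # small synthetic groups match the exact enumeration oracle
  set.seed(10)
  vals <- list(a = runif(4), b = runif(5))
  dat3 <- dplyr::bind_rows(lapply(seq_along(vals$a), function(i) {
    mk(paste0("a", i), "a", vals$a[i])
  }), lapply(seq_along(vals$b), function(i) {
    mk(paste0("b", i), "b", vals$b[i])
  }))
  res3 <- stim_window_compare(dat3)
  expect_equal(res3$test$p_value, mwu_exact_enumeration(vals$a, vals$b))
})
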