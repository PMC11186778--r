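# Heuristic behaviour classification from treadmill velocities and 2D pose
# keypoints, motion energy, behaviour probabilities and stimulus-window
# kinematic statistics.

KEYPOINT_NAMES <- c("anal_plate", "ovipositor", "posterior_stripe", "neck",
                    "front_coxa", "front_femur_tibia", "front_tibia_tarsus",
                    "mid_tibia_tarsus", "hind_tibia_tarsus")

#' Low-pass filter a treadmill velocity trace
#'
#' Spherical-treadmill (`"ball"`) velocities are median filtered (width 5 =
#' 0.05 s at 100 Hz) and then Gaussian filtered (sigma 10 = 0.1 s);
#' cylindrical-treadmill (`"wheel"`) velocities, whose noise is
#' high-frequency only, get a single Gaussian filter (sigma 20 = 0.2 s).
#'
#' @param v numeric velocity series (mm/s).
#' @param mode `"ball"` or `"wheel"`.
#' @return filtered series, same length.
#' @export
filter_velocity <- function(v, mode = c("ball", "wheel")) {
  mode <- match.arg(mode)
  if (mode == "ball") {
    gaussian_smooth(median_smooth(v, 5), 10)
  } else {
    gaussian_smooth(v, 20)
  }
}

#' Motion energy of a keypoint trajectory
#'
#' The instantaneous Euclidean displacement between consecutive frames,
#' `sqrt(dx^2 + dy^2)`, followed by a moving average over `window` samples
#' (0.5 s at 100 Hz) to focus on longer-timescale movement.
#'
#' @param x,y keypoint pixel coordinates per frame.
#' @param window moving-average window in samples (default 50).
#' @return numeric motion-energy series, same length (first sample 0).
#' @export
motion_energy <- function(x, y, window = 50) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  me <- c(0, sqrt(diff(x)^2 + diff(y)^2))
  moving_average(me, window)
}

#' Front-leg height relative to the coxa
#'
#' Vertical distance between the front-leg tibia-tarsus joint and the median
#' coxa position. Pixel y grows downward, so the value is positive when the
#' leg is low (resting) and negative when it is lifted high (grooming).
#'
#' @param tibia_tarsus_y,coxa_y pixel y series of the two landmarks.
#' @return numeric height series.
#' @export
front_leg_height <- function(tibia_tarsus_y, coxa_y) {
  tibia_tarsus_y - median(coxa_y)
}

#' Behaviour classifier thresholds
#'
#' Walking thresholds are +1 / -1 mm/s of forward velocity. The grooming and
#' rest cutoffs are laboratory calibration constants; the defaults assume
#' pose coordinates in pixels at 100 Hz: a front leg is "lifted high" when
#' its height is below `groom_height` and "moving" when its windowed motion
#' energy exceeds `groom_me`; rest requires near-zero speed and motion
#' energy.
#'
#' @param forward forward-walking velocity threshold, exclusive (1 mm/s).
#' @param backward backward threshold, inclusive (-1 mm/s).
#' @param groom_height front-leg height below which the leg counts as lifted
#'   (default -5 px).
#' @param groom_me front-leg motion energy above which the leg counts as
#'   moving (default 3 px/frame).
#' @param rest_velocity absolute velocity below which rest is possible
#'   (default 0.3 mm/s).
#' @param rest_me motion energy below which rest is possible (default 3).
#' @return named list of class `behaviour_thresholds`.
#' @export
behaviour_thresholds <- function(forward = 1, backward = -1,
                                 groom_height = -5, groom_me = 3,
                                 rest_velocity = 0.3, rest_me = 3) {
  structure(list(forward = forward, backward = backward,
                 groom_height = groom_height, groom_me = groom_me,
                 rest_velocity = rest_velocity, rest_me = rest_me),
            class = "behaviour_thresholds")
}

#' Classify behaviour per frame
#'
#' Heuristic, deterministic classifier. Backwards walking is velocity <=
#' backward threshold; forwards walking is velocity > forward threshold;
#' anterior grooming is a logical OR of the front leg being lifted high or
#' moving with high motion energy; rest requires low speed and low motion
#' energy; anything else is undefined. When several conditions hold the
#' precedence is backward > forward > grooming > rest.
#'
#' @param velocity forward velocity (mm/s), filtered as appropriate.
#' @param me_front front-leg motion energy series.
#' @param height front-leg height series (see [front_leg_height()]).
#' @param thresholds a [behaviour_thresholds()].
#' @return character vector of labels: `forward`, `backward`,
#'   `anterior_grooming`, `rest`, `undefined`.
#' @export
classify_behaviour <- function(velocity, me_front, height,
                               thresholds = behaviour_thresholds()) {
  stopifnot(length(velocity) == length(me_front),
            length(velocity) == length(height))
  th <- thresholds
  case_when(
    velocity <= th$backward ~ "backward",
    velocity > th$forward ~ "forward",
    height < th$groom_height | me_front > th$groom_me ~ "anterior_grooming",
    abs(velocity) < th$rest_velocity & me_front < th$rest_me ~ "rest",
    TRUE ~ "undefined"
  )
}

#' Behaviour probability curves across trials
#'
#' For trial-aligned label series, the fraction of trials in which each
#' behaviour occurs at each time point after stimulus onset. Fractions sum
#' to 1 across labels at every time point.
#'
#' @param labels character matrix (trials x time) or tibble with `trial`,
#'   `time`, `label`.
#' @return tibble `time`, `label`, `probability`.
#' @export
behaviour_probability <- function(labels) {
  if (is.matrix(labels)) {
    labels <- tibble(
      trial = rep(seq_len(nrow(labels)), ncol(labels)),
      time = rep(seq_len(ncol(labels)), each = nrow(labels)),
      label = as.vector(labels)
    )
  }
  labels |>
    count(.data$time, .data$label) |>
    group_by(.data$time) |>
    mutate(probability = .data$n / sum(.data$n)) |>
    ungroup() |>
    select("time", "label", "probability")
}

#' Kinematic metrics from pose keypoints
#'
#' Named per-frame scalars used to quantify headless-fly movements:
#' `abdomen_contraction` (Euclidean distance between the anal plate and the
#' most posterior stripe), `front_leg_approach` (distance between the
#' front-leg tibia-tarsus joint and the neck), `abdomen_dip` (anal-plate
#' vertical position) and `turn_magnitude` (absolute, undirected turn
#' velocity; requires `turn_velocity`). The "change" framing of these
#' metrics -- relative to the 1-s pre-stimulus mean -- is applied by
#' [stim_window_compare()] at trial alignment.
#'
#' @param keypoints tibble `frame`, `landmark`, `x`, `y` (long format).
#' @param metric one of `"abdomen_contraction"`, `"front_leg_approach"`,
#'   `"abdomen_dip"`, `"turn_magnitude"`.
#' @param turn_velocity numeric series (deg/s), only for `turn_magnitude`.
#' @return tibble `frame`, `value`.
#' @export
kinematic_metric <- function(keypoints = NULL,
                             metric = c("abdomen_contraction",
                                        "front_leg_approach", "abdomen_dip",
                                        "turn_magnitude"),
                             turn_velocity = NULL) {
  metric <- match.arg(metric)
  if (metric == "turn_magnitude") {
    if (is.null(turn_velocity)) abort("turn_magnitude needs turn_velocity")
    return(tibble(frame = seq_along(turn_velocity), value = abs(turn_velocity)))
  }
  need <- switch(metric,
    abdomen_contraction = c("anal_plate", "posterior_stripe"),
    front_leg_approach = c("front_tibia_tarsus", "neck"),
    abdomen_dip = "anal_plate"
  )
  miss <- setdiff(need, unique(keypoints$landmark))
  if (length(miss)) abort(paste0("missing landmark(s): ", toString(miss)))
  wide <- keypoints |>
    filter(.data$landmark %in% need) |>
    pivot_wider(id_cols = "frame", names_from = "landmark",
                values_from = c("x", "y"))
  value <- switch(metric,
    abdomen_contraction = sqrt((wide$x_anal_plate - wide$x_posterior_stripe)^2 +
                                 (wide$y_anal_plate - wide$y_posterior_stripe)^2),
    front_leg_approach = sqrt((wide$x_front_tibia_tarsus - wide$x_neck)^2 +
                                (wide$y_front_tibia_tarsus - wide$y_neck)^2),
    abdomen_dip = wide$y_anal_plate
  )
  tibble(frame = wide$frame, value = value)
}

#' Stimulus-window kinematic comparison across flies
#'
#' For each trial, subtracts the mean of the `baseline_s` seconds before
#' stimulus onset (the "change in" convention), averages the series over the
#' first `window_s` seconds of stimulation, then averages trials within each
#' fly and compares the two conditions across flies with a two-sided
#' Mann-Whitney U test (technical replicates are averaged; only biological
#' replicates are compared).
#'
#' @param data tibble with `fly`, `condition`, `trial`, `time` (seconds,
#'   0 = stimulus onset) and `value`.
#' @param window_s averaging window after onset (default 2.5 s).
#' @param baseline_s pre-onset baseline window (default 1 s); set to 0 to
#'   skip baseline subtraction (absolute metrics such as turn magnitude).
#' @return list with `per_fly` (tibble `fly`, `condition`, `mean_value`) and
#'   `test` (tibble from [compare_flies_mwu()]).
#' @export
stim_window_compare <- function(data, window_s = 2.5, baseline_s = 1) {
  conds <- unique(data$condition)
  if (length(conds) != 2) abort("need exactly two conditions")
  per_trial <- data |>
    group_by(.data$fly, .data$condition, .data$trial) |>
    summarise(
      baseline = if (baseline_s > 0) {
        mean(.data$value[.data$time >= -baseline_s & .data$time < 0])
      } else 0,
      trial_mean = mean(.data$value[.data$time >= 0 & .data$time < window_s]) -
        baseline,
      .groups = "drop"
    )
  per_fly <- per_trial |>
    group_by(.data$fly, .data$condition) |>
    summarise(mean_value = mean(.data$trial_mean), .groups = "drop")
  a <- per_fly$mean_value[per_fly$condition == conds[1]]
  b <- per_fly$mean_value[per_fly$condition == conds[2]]
  list(per_fly = per_fly, test = compare_flies_mwu(a, b))
}
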