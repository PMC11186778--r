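# Trial-based calcium-imaging analysis: resting-baseline deltaF/F, trial
# selection, stimulus-triggered averages with CI masking, per-ROI response
# statistics, cross-fly tests and multi-fly density maps.

#' Construct a trial recording (ROI x time fluorescence set)
#'
#' Container for one fly's recording: an ROI-by-time fluorescence matrix,
#' stimulus epochs, optional per-sample behaviour labels on the neural clock
#' and optional ROI pixel coordinates.
#'
#' @param F numeric ROI x time matrix of raw fluorescence.
#' @param sample_rate imaging frame rate in Hz (default 16.23).
#' @param stim_epochs tibble/data frame with integer `onset`, `offset`
#'   sample indices (1-based, inclusive).
#' @param behaviour optional character vector, one label per sample.
#' @param roi_coords optional tibble `roi`, `y`, `x` (pixels, y increases
#'   downward).
#' @param fly optional fly identifier.
#' @return object of class `roi_trial_set`.
#' @export
roi_trial_set <- function(F, sample_rate = 16.23, stim_epochs,
                          behaviour = NULL, roi_coords = NULL, fly = NULL) {
  stopifnot(is.matrix(F), is.numeric(F))
  n_t <- ncol(F)
  stim_epochs <- as_tibble(stim_epochs)
  stopifnot(all(c("onset", "offset") %in% names(stim_epochs)))
  if (any(stim_epochs$onset < 1 | stim_epochs$offset > n_t |
            stim_epochs$onset > stim_epochs$offset)) {
    abort("stimulus epochs must lie within the recording")
  }
  if (!is.null(behaviour) && length(behaviour) != n_t) {
    abort("behaviour labels must match the neural time axis length")
  }
  if (is.null(rownames(F))) rownames(F) <- paste0("roi", seq_len(nrow(F)))
  structure(
    list(F = F, sample_rate = sample_rate, stim_epochs = stim_epochs,
         behaviour = behaviour, roi_coords = roi_coords, fly = fly,
         dff = NULL, degenerate_rois = character()),
    class = "roi_trial_set"
  )
}

#' @export
print.roi_trial_set <- function(x, ...) {
  cat(sprintf("<roi_trial_set> %d ROIs x %d samples @ %.2f Hz, %d stimulus epochs%s\n",
              nrow(x$F), ncol(x$F), x$sample_rate, nrow(x$stim_epochs),
              if (is.null(x$dff)) "" else " (dFF computed)"))
  invisible(x)
}

stim_mask <- function(n_t, stim_epochs) {
  m <- logical(n_t)
  for (k in seq_len(nrow(stim_epochs))) {
    m[stim_epochs$onset[k]:stim_epochs$offset[k]] <- TRUE
  }
  m
}

#' Low-pass filter fluorescence traces
#'
#' Median filter then Gaussian filter, applied per ROI; edges handled by
#' reflection. Widths are in samples (the defaults, 3 samples each, are
#' about 0.185 s at 16.23 Hz).
#'
#' @param x an `roi_trial_set` or numeric matrix (rows are traces).
#' @param median_width odd median window (default 3).
#' @param gaussian_sd Gaussian sigma in samples (default 3).
#' @return same type as input, smoothed.
#' @export
smooth_traces <- function(x, median_width = 3, gaussian_sd = 3) {
  smooth_one <- function(v) gaussian_smooth(median_smooth(v, median_width), gaussian_sd)
  if (inherits(x, "roi_trial_set")) {
    x$F <- t(apply(x$F, 1, smooth_one))
    return(x)
  }
  t(apply(x, 1, smooth_one))
}

#' Detect prolonged-rest onsets
#'
#' An onset of prolonged resting is a transition into the rest label such
#' that (1) at least `min_rest_fraction` of the following `window_s` seconds
#' is labelled rest, (2) it falls at least `refractory_s` seconds after the
#' previously accepted rest onset, and (3) the window lies outside all
#' stimulation epochs.
#'
#' @param behaviour character label vector on the neural clock.
#' @param stim_epochs tibble with `onset`, `offset` sample indices.
#' @param sample_rate Hz.
#' @param rest_label label counting as rest (default `"rest"`).
#' @param window_s onset evaluation window (default 1 s).
#' @param min_rest_fraction required rest fraction in the window (0.75).
#' @param refractory_s minimum spacing between onsets (default 1 s).
#' @return integer vector of onset sample indices (possibly empty).
#' @export
detect_rest_onsets <- function(behaviour, stim_epochs, sample_rate,
                               rest_label = "rest", window_s = 1,
                               min_rest_fraction = 0.75, refractory_s = 1) {
  n_t <- length(behaviour)
  win <- seconds_to_samples(window_s, sample_rate)
  refr <- seconds_to_samples(refractory_s, sample_rate)
  in_stim <- stim_mask(n_t, stim_epochs)
  is_rest <- behaviour == rest_label
  candidates <- which(is_rest & !c(FALSE, is_rest[-n_t]))
  onsets <- integer()
  last <- -Inf
  for (t in candidates) {
    hi <- t + win - 1L
    if (hi > n_t) next
    if (t - last < refr) next
    if (any(in_stim[t:hi])) next
    if (mean(is_rest[t:hi]) < min_rest_fraction) next
    onsets <- c(onsets, t)
    last <- t
  }
  onsets
}

#' Compute delta F / F with a resting baseline
#'
#' Normalises each ROI as `(F - F0) / (Fmax - F0)`. `Fmax` is the 95%
#' quantile of the trace over the whole recording. `F0` is the resting
#' baseline: the median trace across rest-onset-aligned repetitions,
#' minimised over the `baseline_window_s` seconds following rest onset. If
#' no rest onsets are available the 5% quantile of the trace is used
#' instead. A value of 0 thus means resting-level activity and 1 the 95%
#' quantile of activity. ROIs with `Fmax == F0` are flagged degenerate and
#' their rows set to `NA`.
#'
#' @param x an `roi_trial_set` (smooth first with [smooth_traces()]).
#' @param rest_onsets integer onsets from [detect_rest_onsets()]; computed
#'   from the behaviour labels when `NULL`.
#' @param f_max_quantile upper normalisation quantile (default 0.95).
#' @param fallback_f0_quantile baseline quantile when no rest onsets exist
#'   (default 0.05).
#' @param baseline_window_s search window after rest onset (default 2 s).
#' @return the `roi_trial_set` with `dff` (matrix) and `degenerate_rois`
#'   filled in.
#' @export
compute_dff <- function(x, rest_onsets = NULL, f_max_quantile = 0.95,
                        fallback_f0_quantile = 0.05, baseline_window_s = 2) {
  stopifnot(inherits(x, "roi_trial_set"))
  n_t <- ncol(x$F)
  if (is.null(rest_onsets) && !is.null(x$behaviour)) {
    rest_onsets <- detect_rest_onsets(x$behaviour, x$stim_epochs, x$sample_rate)
  }
  rest_onsets <- rest_onsets %||% integer()
  win <- seconds_to_samples(baseline_window_s, x$sample_rate)
  rest_onsets <- rest_onsets[rest_onsets + win - 1L <= n_t]
  f0 <- if (length(rest_onsets) > 0) {
    segs <- vapply(rest_onsets,
                   function(t) seq.int(t, t + win - 1L),
                   integer(win))
    apply(x$F, 1, function(v) {
      seg <- matrix(v[segs], nrow = win)
      min(apply(seg, 1, median))
    })
  } else {
    inform("no usable rest onsets; falling back to the low-quantile baseline")
    apply(x$F, 1, quantile, probs = fallback_f0_quantile, names = FALSE)
  }
  f_max <- apply(x$F, 1, quantile, probs = f_max_quantile, names = FALSE)
  range_ok <- (f_max - f0) > .Machine$double.eps^0.5
  if (any(!range_ok)) {
    inform(sprintf("%d degenerate ROI(s) (Fmax == F0) excluded", sum(!range_ok)))
  }
  dff <- (x$F - f0) / (f_max - f0)
  dff[!range_ok, ] <- NA_real_
  x$dff <- dff
  x$degenerate_rois <- rownames(x$F)[!range_ok]
  x
}

#' Select trials by pre-stimulus behaviour
#'
#' A trial is kept iff the majority behaviour label in the `pre_window_s`
#' seconds before stimulation matches `required`. The fly qualifies only if
#' at least `min_trials` trials remain.
#'
#' @param x an `roi_trial_set` with behaviour labels.
#' @param required required pre-stimulus behaviour (default `"forward"`).
#' @param pre_window_s pre-stimulus window (default 1 s).
#' @param min_trials fly-level threshold (default 10).
#' @return tibble `trial`, `onset`, `offset`, `kept`, with attribute
#'   `fly_ok` (logical: enough qualifying trials).
#' @export
select_trials <- function(x, required = "forward", pre_window_s = 1,
                          min_trials = 10) {
  stopifnot(inherits(x, "roi_trial_set"))
  if (is.null(x$behaviour)) abort("trial selection needs behaviour labels")
  pre <- seconds_to_samples(pre_window_s, x$sample_rate)
  kept <- vapply(seq_len(nrow(x$stim_epochs)), function(k) {
    t0 <- x$stim_epochs$onset[k]
    if (t0 - pre < 1) return(FALSE)
    lab <- x$behaviour[(t0 - pre):(t0 - 1L)]
    tab <- sort(table(lab), decreasing = TRUE)
    names(tab)[1] == required
  }, logical(1))
  out <- tibble(trial = seq_len(nrow(x$stim_epochs)),
                onset = x$stim_epochs$onset,
                offset = x$stim_epochs$offset,
                kept = kept)
  attr(out, "fly_ok") <- sum(kept) >= min_trials
  out
}

#' Stimulus-triggered average with confidence-interval masking
#'
#' Aligns the deltaF/F traces of the selected trials to stimulus onset over
#' the window from `pre_s` seconds before onset to `post_s` seconds after
#' offset, subtracts each trial's mean activity in the second before
#' stimulation, and averages across trials. The 95% confidence interval of
#' the mean is `1.96 x SD / sqrt(n)` across trials; samples whose |mean| is
#' below their CI are masked to 0.
#'
#' @param x an `roi_trial_set` with `dff` computed.
#' @param trials integer trial indices or a [select_trials()] table; all
#'   trials by default.
#' @param pre_s,post_s window padding around the epoch (default 5 s each).
#' @param baseline_s pre-stimulus baseline window (default 1 s).
#' @return object of class `roi_sta`: `time` (seconds, 0 = onset), `mean`,
#'   `ci`, `masked` (ROI x time matrices), `n_trials`, `stim_off_s`,
#'   `sample_rate`.
#' @export
stimulus_triggered_average <- function(x, trials = NULL, pre_s = 5,
                                       post_s = 5, baseline_s = 1) {
  stopifnot(inherits(x, "roi_trial_set"))
  if (is.null(x$dff)) abort("run compute_dff() first")
  if (is.data.frame(trials)) trials <- trials$trial[trials$kept]
  trials <- trials %||% seq_len(nrow(x$stim_epochs))
  ep <- x$stim_epochs[trials, ]
  dur <- min(ep$offset - ep$onset + 1L)
  pre <- seconds_to_samples(pre_s, x$sample_rate)
  post <- seconds_to_samples(post_s, x$sample_rate)
  base <- seconds_to_samples(baseline_s, x$sample_rate)
  n_t <- ncol(x$dff)
  fits <- ep$onset - pre >= 1 & ep$onset + dur - 1L + post <= n_t
  ep <- ep[fits, ]
  if (nrow(ep) < 2) abort("need at least 2 trials fully inside the recording")
  len <- pre + dur + post
  n_roi <- nrow(x$dff)
  acc_mean <- matrix(0, n_roi, len)
  acc_sq <- matrix(0, n_roi, len)
  for (k in seq_len(nrow(ep))) {
    idx <- (ep$onset[k] - pre):(ep$onset[k] + dur - 1L + post)
    seg <- x$dff[, idx, drop = FALSE]
    b <- rowMeans(x$dff[, (ep$onset[k] - base):(ep$onset[k] - 1L), drop = FALSE])
    seg <- seg - b
    acc_mean <- acc_mean + seg
    acc_sq <- acc_sq + seg^2
  }
  n <- nrow(ep)
  m <- acc_mean / n
  v <- pmax(acc_sq / n - m^2, 0) * n / (n - 1)
  ci <- qnorm(0.975) * sqrt(v / n)
  masked <- ifelse(abs(m) < ci, 0, m)
  rownames(masked) <- rownames(m) <- rownames(ci) <- rownames(x$dff)
  structure(
    list(time = (seq_len(len) - pre - 1L) / x$sample_rate,
         mean = m, ci = ci, masked = masked, n_trials = n,
         stim_off_s = dur / x$sample_rate, sample_rate = x$sample_rate),
    class = "roi_sta"
  )
}

#' @export
print.roi_sta <- function(x, ...) {
  cat(sprintf("<roi_sta> %d ROIs, %d trials, window %.1f..%.1f s (stim 0..%.1f s)\n",
              nrow(x$mean), x$n_trials, min(x$time), max(x$time), x$stim_off_s))
  invisible(x)
}

#' Per-ROI response value and activation flag
#'
#' For each ROI, locates the peak |masked response| during the first
#' `first_half_s` seconds of stimulation, then takes the mean response over
#' `window_s` seconds centred on that peak. The ROI is responsive iff the
#' mean is confidently different from zero (|mean| > CI) during at least
#' half of that window; otherwise its response is masked to 0. An ROI is
#' "activated" iff it is responsive with a positive response.
#'
#' @param sta an [stimulus_triggered_average()] result.
#' @param first_half_s search window from stimulus onset (default 2.5 s).
#' @param window_s averaging window around the peak (default 1 s).
#' @return tibble `roi`, `response`, `responsive`, `activated`, `t_peak_s`.
#' @export
roi_response <- function(sta, first_half_s = 2.5, window_s = 1) {
  sr <- sta$sample_rate
  idx_on <- which(sta$time >= 0)[1]
  idx_hi <- idx_on + seconds_to_samples(first_half_s, sr) - 1L
  half <- seconds_to_samples(window_s, sr) %/% 2L
  n_t <- ncol(sta$mean)
  res <- map(seq_len(nrow(sta$mean)), function(i) {
    if (anyNA(sta$mean[i, ])) {
      return(tibble(response = 0, responsive = FALSE, t_peak_s = NA_real_))
    }
    seg <- sta$masked[i, idx_on:idx_hi]
    # latest tied maximum: plateaus tie from their first sample, and the
    # averaging window should sit on the plateau, not the onset
    t_pk <- idx_on + max(which(abs(seg) == max(abs(seg)))) - 1L
    w <- max(1L, t_pk - half):min(n_t, t_pk + half)
    confident <- abs(sta$mean[i, w]) >= sta$ci[i, w] & sta$masked[i, w] != 0
    responsive <- mean(confident) >= 0.5
    tibble(response = if (responsive) mean(sta$mean[i, w]) else 0,
           responsive = responsive,
           t_peak_s = sta$time[t_pk])
  }) |> list_rbind()
  tibble(roi = rownames(sta$mean),
         response = res$response,
         responsive = res$responsive,
         activated = res$responsive & res$response > 0,
         t_peak_s = res$t_peak_s)
}

#' Per-fly activation metrics
#'
#' Number of activated ROIs, the fraction of activated ROIs among the
#' visible ones, and the summed response of positively activated ROIs
#' (negative responses are excluded from the sum, since reduced indicator
#' fluorescence cannot be read as inhibition).
#'
#' @param responses tibble from [roi_response()].
#' @param n_visible_rois number of visible ROIs (defaults to
#'   `nrow(responses)`).
#' @return one-row tibble `n_activated`, `fraction_activated`,
#'   `summed_positive`.
#' @export
activation_metrics <- function(responses, n_visible_rois = nrow(responses)) {
  if (!isTRUE(n_visible_rois > 0)) abort("no visible ROIs")
  act <- responses$activated & responses$response > 0
  tibble(
    n_activated = sum(act),
    fraction_activated = sum(act) / n_visible_rois,
    summed_positive = sum(responses$response[act])
  )
}

#' Two-sided Mann-Whitney U test between fly groups
#'
#' Wrapper around [stats::wilcox.test()] comparing per-fly metrics between
#' two groups of biological replicates (exact enumeration for small
#' untied samples, normal approximation otherwise). Being a rank test, small
#' equal-sized groups in an extreme ordering always attain the same minimal
#' p regardless of the metric's absolute values.
#'
#' @param a,b numeric per-fly values for the two groups.
#' @return tibble `statistic` (U for group `a`), `p_value`, `n_a`, `n_b`,
#'   `method`.
#' @export
compare_flies_mwu <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  if (length(unique(c(a, b))) == 1) {
    # fully tied pooled sample: the rank test is maximally non-significant
    return(tibble(statistic = length(a) * length(b) / 2, p_value = 1,
                  n_a = length(a), n_b = length(b),
                  method = "Wilcoxon rank sum test (all values tied)"))
  }
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         n_a = length(a), n_b = length(b), method = wt$method)
}

#' Multi-fly response density map
#'
#' Registers each fly's ROI coordinates onto a common canvas (the y axis is
#' scaled and shifted so the most dorsal and most ventral ROIs align; the x
#' axis is shifted so the most lateral ROI aligns), renders responses as
#' impulses, blurs with a Gaussian kernel normalised to 1 at its centre
#' (preserving response units), and averages across flies.
#'
#' @param flies tibble with `fly`, `y`, `x`, `response` (one row per ROI),
#'   or a list of per-fly tibbles with `y`, `x`, `response`.
#' @param sigma blur standard deviation in pixels (default 25).
#' @param canvas `c(height, width)` of the output (default `c(160, 368)`).
#' @param margin fractional margin of the canvas kept free (default 0.1).
#' @return numeric matrix of class `response_density` (height x width).
#' @export
density_map <- function(flies, sigma = 25, canvas = c(160, 368), margin = 0.1) {
  if (is.data.frame(flies)) flies <- split(as_tibble(flies), flies$fly)
  if (!length(flies)) abort("need at least one fly")
  h <- canvas[1]; w <- canvas[2]
  y_lo <- margin * h; y_hi <- (1 - margin) * h
  x_hi <- (1 - margin) * w
  acc <- matrix(0, h, w)
  for (f in flies) {
    if (length(unique(f$y)) < 2) abort("a fly needs at least 2 distinct y positions to register")
    y <- (f$y - min(f$y)) / (max(f$y) - min(f$y)) * (y_hi - y_lo) + y_lo
    x <- f$x + (x_hi - max(f$x))
    img <- matrix(0, h, w)
    iy <- pmin(pmax(round(y), 1), h)
    ix <- pmin(pmax(round(x), 1), w)
    for (k in seq_along(iy)) img[iy[k], ix[k]] <- img[iy[k], ix[k]] + f$response[k]
    acc <- acc + gaussian_blur_centre1(img, sigma)
  }
  structure(acc / length(flies), class = c("response_density", "matrix"))
}

# Separable 2-d Gaussian blur with the kernel scaled to 1 at its centre
# (so a unit impulse keeps peak value 1); zero padding outside the canvas.
gaussian_blur_centre1 <- function(img, sigma) {
  radius <- ceiling(3 * sigma)
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  conv_rows <- function(m) {
    t(apply(m, 1, function(v) {
      pad <- c(rep(0, radius), v, rep(0, radius))
      out <- stats::filter(pad, k, sides = 2)
      as.numeric(out[(radius + 1L):(radius + length(v))])
    }))
  }
  conv_rows(t(conv_rows(t(img))))
}
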