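# Synthetic-data generators with known ground truth: planted-partition
# signed connectomes in the Codex table dialect, trial-structured ROI
# fluorescence recordings, and kinematic series with planted behaviour
# episodes. These exist so every pipeline stage can be exercised and
# verified without external downloads; they validate machinery, not biology.

#' Specification for a synthetic planted-partition connectome
#'
#' The generator plants `n_clusters` groups of DNs with predominantly
#' cholinergic (excitatory) within-cluster connections and predominantly
#' GABAergic (inhibitory) between-cluster connections, mirroring the
#' excitatory-within / inhibitory-between organisation of DN networks. A
#' minority of "broadcaster" hubs gets heavy-tailed extra out-degree.
#' Synapse counts follow a shifted negative binomial; each connection is
#' split across a small set of neuropils with a controlled GNG share.
#'
#' @param n_dns number of descending neurons (default 120).
#' @param n_clusters planted clusters (default 4).
#' @param p_within_exc within-cluster connection probability (default 0.25).
#' @param p_between_inh between-cluster connection probability (default
#'   0.04).
#' @param syn_mean mean synapse count per connection (default 12).
#' @param syn_size negative-binomial size parameter (default 4).
#' @param broadcaster_fraction fraction of DNs that are hubs (default 0.05).
#' @param tail_exponent Pareto exponent of hub extra out-degree (default
#'   2.5).
#' @param hub_scale scale of hub extra out-degree (default 10).
#' @param gng_synapse_share probability a synapse lands in a GNG neuropil
#'   (default 0.7).
#' @param gng_node_fraction share of DNs given GNG-type consensus names
#'   (default 0.5).
#' @param nt_within,nt_between named transmitter mixes per edge class.
#' @param n_nondn non-descending neurons added to exercise filtering
#'   (default 12).
#' @param seed mandatory integer seed.
#' @return list of class `connectome_sim_spec`.
#' @export
connectome_sim_spec <- function(n_dns = 120, n_clusters = 4,
                                p_within_exc = 0.25, p_between_inh = 0.04,
                                syn_mean = 12, syn_size = 4,
                                broadcaster_fraction = 0.05,
                                tail_exponent = 2.5, hub_scale = 10,
                                gng_synapse_share = 0.7,
                                gng_node_fraction = 0.5,
                                nt_within = c(ACH = 0.88, GLUT = 0.07, GABA = 0.05),
                                nt_between = c(GABA = 0.8, GLUT = 0.1, ACH = 0.1),
                                n_nondn = 12, seed = 1) {
  stopifnot(
    n_dns >= n_clusters, n_clusters >= 1,
    p_within_exc >= 0, p_within_exc <= 1,
    p_between_inh >= 0, p_between_inh <= 1,
    broadcaster_fraction >= 0, broadcaster_fraction <= 1,
    gng_synapse_share >= 0, gng_synapse_share <= 1,
    is.numeric(seed), length(seed) == 1
  )
  structure(as.list(environment()), class = "connectome_sim_spec")
}

NEUROPIL_POOL <- c("GNG_L", "GNG_R", "T1_L", "T1_R", "T2_L", "T2_R",
                   "T3_L", "T3_R", "WTct_L", "WTct_R")

draw_syn_counts <- function(n, mean, size) {
  1L + rnbinom(n, size = size, mu = mean - 1)
}

# split `syn` synapses of each connection across 1-3 neuropil rows
split_neuropils <- function(pre, post, syn, nt, gng_share) {
  n_parts <- sample(1:3, length(syn), replace = TRUE)
  n_parts <- pmin(n_parts, syn)
  rows <- map(seq_along(syn), function(k) {
    parts <- n_parts[k]
    cuts <- sort(sample(syn[k] - 1, parts - 1))
    counts <- diff(c(0, cuts, syn[k]))
    gng <- runif(parts) < gng_share
    np <- ifelse(gng, sample(c("GNG_L", "GNG_R"), parts, replace = TRUE),
                 sample(setdiff(NEUROPIL_POOL, c("GNG_L", "GNG_R")), parts,
                        replace = TRUE))
    tibble(pre_root_id = pre[k], post_root_id = post[k],
           neuropil = np, syn_count = as.integer(counts), nt_type = nt[k])
  })
  list_rbind(rows)
}

#' Generate a synthetic connectome in the Codex table dialect
#'
#' @param spec a [connectome_sim_spec()].
#' @return list with `neurons` and `connections` tibbles (ready for
#'   [read_codex_tables()] semantics or [write_codex_tables()]), and `truth`
#'   holding the planted `membership` (named by root ID), `broadcasters`,
#'   `dn_ids` and the pre-threshold edge table.
#' @export
generate_connectome <- function(spec) {
  stopifnot(inherits(spec, "connectome_sim_spec"))
  set.seed(as.integer(spec$seed))
  n <- spec$n_dns
  dn_ids <- sprintf("7205759406%08d", seq_len(n))
  membership <- sort(rep_len(seq_len(spec$n_clusters), n))
  names(membership) <- dn_ids

  same <- outer(membership, membership, "==")
  diag(same) <- NA # no self-loops
  p <- ifelse(same, spec$p_within_exc, spec$p_between_inh)
  p[is.na(p)] <- 0
  connected <- matrix(runif(n * n) < p, n, n)
  idx <- which(connected, arr.ind = TRUE)
  within <- membership[idx[, 1]] == membership[idx[, 2]]

  draw_nt <- function(k, mix) sample(names(mix), k, replace = TRUE, prob = mix)
  nt <- character(nrow(idx))
  nt[within] <- draw_nt(sum(within), spec$nt_within)
  nt[!within] <- draw_nt(sum(!within), spec$nt_between)

  pre <- dn_ids[idx[, 1]]
  post <- dn_ids[idx[, 2]]

  # broadcaster hubs: heavy-tailed extra cholinergic out-degree
  n_hubs <- round(spec$broadcaster_fraction * n)
  hubs <- if (n_hubs > 0) sample(dn_ids, n_hubs) else character()
  for (h in hubs) {
    extra <- min(n - 1,
                 round(spec$hub_scale * runif(1)^(-1 / (spec$tail_exponent - 1))))
    tgt <- sample(setdiff(dn_ids, h), extra)
    new <- !(paste(h, tgt) %in% paste(pre, post))
    pre <- c(pre, rep(h, sum(new)))
    post <- c(post, tgt[new])
    nt <- c(nt, rep("ACH", sum(new)))
  }
  syn <- draw_syn_counts(length(pre), spec$syn_mean, spec$syn_size)
  connections <- split_neuropils(pre, post, syn, nt, spec$gng_synapse_share)

  # non-DN neurons with connections to/from DNs, to exercise filtering
  nondn_ids <- sprintf("7205759409%08d", seq_len(spec$n_nondn))
  if (spec$n_nondn > 0) {
    m <- spec$n_nondn
    extra <- tibble(
      pre_root_id = c(sample(nondn_ids, m, TRUE), sample(dn_ids, m, TRUE)),
      post_root_id = c(sample(dn_ids, m, TRUE), sample(nondn_ids, m, TRUE)),
      neuropil = sample(NEUROPIL_POOL, 2 * m, TRUE),
      syn_count = draw_syn_counts(2 * m, spec$syn_mean, spec$syn_size),
      nt_type = sample(c("ACH", "GABA", "DA"), 2 * m, TRUE)
    )
    connections <- bind_rows(connections, extra)
  }

  # naming attributes exercising every branch of the assignment rules
  style <- sample(c("both", "hemi_only", "consensus", "conflict", "none"),
                  n, replace = TRUE, prob = c(0.4, 0.1, 0.4, 0.05, 0.05))
  namiki <- sprintf("DN%s%02d", sample(letters, n, TRUE), seq_len(n) %% 100)
  consensus_idx <- which(style == "consensus")
  n_gng <- min(length(consensus_idx), round(spec$gng_node_fraction * n))
  gng_pick <- head(consensus_idx, n_gng)
  consensus <- sprintf("DN%se%03d",
                       ifelse(seq_len(n) %in% gng_pick, "g", "p"),
                       seq_len(n))
  cell_type <- case_when(
    style == "both" ~ namiki,
    style == "hemi_only" ~ consensus,
    style == "consensus" ~ consensus,
    style == "conflict" ~ sprintf("DN%s%02d", sample(letters, n, TRUE),
                                  (seq_len(n) + 7) %% 100),
    TRUE ~ NA_character_
  )
  hemibrain_type <- case_when(
    style %in% c("both", "hemi_only", "conflict") ~ namiki,
    TRUE ~ NA_character_
  )
  neurons <- tibble(
    root_id = c(dn_ids, nondn_ids),
    super_class = c(rep("descending", n), rep("central", spec$n_nondn)),
    cell_type = c(cell_type, rep(NA_character_, spec$n_nondn)),
    hemibrain_type = c(hemibrain_type, rep(NA_character_, spec$n_nondn)),
    community_labels = NA_character_,
    side = sample(c("left", "right"), n + spec$n_nondn, TRUE)
  )
  truth <- list(
    membership = membership,
    broadcasters = hubs,
    dn_ids = dn_ids,
    edges = tibble(pre = pre, post = post, syn_count = syn, nt = nt)
  )
  list(neurons = neurons, connections = connections, truth = truth)
}

#' Write synthetic connectome tables as Codex-dialect CSVs
#'
#' @param sim result of [generate_connectome()].
#' @param dir output directory (created if needed).
#' @return invisible character vector of the two file paths.
#' @export
write_codex_tables <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(neurons = file.path(dir, "neurons.csv"),
             connections = file.path(dir, "connections.csv"))
  write_csv(sim$neurons, paths["neurons"])
  write_csv(sim$connections, paths["connections"])
  invisible(paths)
}

#' Specification for a synthetic trial-structured ROI recording
#'
#' Emulates an open-loop optogenetic session: `n_trials` stimulation epochs
#' of `stim_s` seconds separated by `isi_s` seconds of spontaneous
#' behaviour. A recruited subset of ROIs responds to the stimulus with
#' planted amplitudes (in normalised deltaF/F units) through a
#' slow-indicator calcium kernel (exponential rise and decay). Every ROI
#' also shows full-range spontaneous activity bouts mid-ISI; these calibrate
#' the 95%-quantile F_max of each ROI to its own dynamic range, which is
#' what makes the planted amplitudes recoverable on the deltaF/F scale.
#' Behaviour labels come from a simple episode machine that rests mid-ISI
#' and walks before a configurable fraction of stimuli.
#'
#' @param n_rois number of ROIs (default 60).
#' @param n_trials number of stimulation trials (default 40).
#' @param sample_rate imaging rate, Hz (default 16.23).
#' @param stim_s stimulation duration (default 5 s).
#' @param isi_s inter-stimulus interval (default 10 s).
#' @param pre_s lead-in before the first stimulus (default 12 s).
#' @param recruited_fraction fraction of ROIs recruited (default 0.3).
#' @param amplitude_range planted response amplitudes, deltaF/F units
#'   (default 0.3 to 1).
#' @param tau_rise,tau_decay calcium kernel time constants, seconds
#'   (defaults 0.3 and 1.5; rise much faster than decay, decay of order
#'   seconds, as for slow indicators).
#' @param noise_sd Gaussian noise SD in deltaF/F units (default 0.03).
#' @param spont_bout_prob probability an ISI contains a spontaneous bout
#'   (default 0.5).
#' @param walk_before_fraction fraction of trials with guaranteed walking in
#'   the pre-stimulus second (default 0.9).
#' @param baseline_range raw-fluorescence baseline range (default 80-120).
#' @param gain_range raw-fluorescence dynamic-range gain (default 40-80).
#' @param seed mandatory integer seed.
#' @return list of class `trial_sim_spec`.
#' @export
trial_sim_spec <- function(n_rois = 60, n_trials = 40, sample_rate = 16.23,
                           stim_s = 5, isi_s = 10, pre_s = 12,
                           recruited_fraction = 0.3,
                           amplitude_range = c(0.3, 1),
                           tau_rise = 0.3, tau_decay = 1.5,
                           noise_sd = 0.03, spont_bout_prob = 0.5,
                           walk_before_fraction = 0.9,
                           baseline_range = c(80, 120),
                           gain_range = c(40, 80), seed = 1) {
  stopifnot(stim_s > 0, isi_s > 0, n_trials >= 1,
            recruited_fraction >= 0, recruited_fraction <= 1,
            is.numeric(seed), length(seed) == 1)
  structure(as.list(environment()), class = "trial_sim_spec")
}

# normalised stimulus response template for one trial window:
# saturating exponential rise during the stimulus, exponential decay after.
calcium_template <- function(stim_n, tail_n, sample_rate, tau_rise, tau_decay) {
  t_on <- seq_len(stim_n) / sample_rate
  rise <- 1 - exp(-t_on / tau_rise)
  t_off <- seq_len(tail_n) / sample_rate
  decay <- rise[stim_n] * exp(-t_off / tau_decay)
  c(rise, decay)
}

#' Generate a synthetic trial-structured ROI recording
#'
#' @param spec a [trial_sim_spec()].
#' @return list with `recording` (an [roi_trial_set()]) and `truth`
#'   (`recruited` ROI names, `amplitudes` named by ROI, `behaviour` labels).
#' @export
generate_trial_recording <- function(spec) {
  stopifnot(inherits(spec, "trial_sim_spec"))
  set.seed(as.integer(spec$seed))
  sr <- spec$sample_rate
  stim_n <- seconds_to_samples(spec$stim_s, sr)
  isi_n <- seconds_to_samples(spec$isi_s, sr)
  pre_n <- seconds_to_samples(spec$pre_s, sr)
  trial_n <- stim_n + isi_n
  n_t <- pre_n + spec$n_trials * trial_n
  onsets <- pre_n + (seq_len(spec$n_trials) - 1L) * trial_n + 1L
  stim_epochs <- tibble(onset = onsets, offset = onsets + stim_n - 1L)

  # stimulus-locked response signal, unit plateau
  tmpl <- calcium_template(stim_n, isi_n, sr, spec$tau_rise, spec$tau_decay)
  resp <- numeric(n_t)
  for (o in onsets) {
    idx <- o:min(o + length(tmpl) - 1L, n_t)
    resp[idx] <- resp[idx] + tmpl[seq_along(idx)]
  }

  # behaviour labels: walk in the pre-stimulus second for most trials,
  # rest mid-ISI (plenty of prolonged-rest onsets), undefined elsewhere
  behaviour <- rep("undefined", n_t)
  one_s <- seconds_to_samples(1, sr)
  walk_trials <- runif(spec$n_trials) < spec$walk_before_fraction
  rest_lo <- seconds_to_samples(7, sr) # ISI seconds 7..9 after stimulus offset
  rest_hi <- seconds_to_samples(9, sr)
  for (k in seq_len(spec$n_trials)) {
    off <- stim_epochs$offset[k]
    behaviour[(off + rest_lo):min(off + rest_hi, n_t)] <- "rest"
    if (walk_trials[k]) {
      behaviour[(onsets[k] - one_s):(onsets[k] - 1L)] <- "forward"
    }
  }
  behaviour[seq_len(min(one_s * 3, pre_n))] <- "rest"

  # spontaneous full-range bouts, mid-ISI (seconds 4..7 after offset), kept
  # clear of the pre-stimulus baseline window; a long lead-in bout tops up
  # the >5% duty cycle needed for the 95% quantile to sit on the plateau
  bout_lo <- seconds_to_samples(4, sr)
  bout_n <- seconds_to_samples(3, sr)
  lead_idx <- seq_len(max(1L, pre_n - 2L * one_s))
  n_roi <- spec$n_rois
  rois <- paste0("roi", seq_len(n_roi))
  n_recruited <- round(spec$recruited_fraction * n_roi)
  recruited <- sort(sample(rois, n_recruited))
  amplitudes <- setNames(numeric(n_roi), rois)
  amplitudes[recruited] <- runif(n_recruited, spec$amplitude_range[1],
                                 spec$amplitude_range[2])

  F <- matrix(0, n_roi, n_t, dimnames = list(rois, NULL))
  baselines <- runif(n_roi, spec$baseline_range[1], spec$baseline_range[2])
  gains <- runif(n_roi, spec$gain_range[1], spec$gain_range[2])
  for (i in seq_len(n_roi)) {
    spont <- numeric(n_t)
    spont[lead_idx] <- 1
    for (k in seq_len(spec$n_trials)) {
      if (runif(1) < spec$spont_bout_prob) {
        s <- stim_epochs$offset[k] + bout_lo
        spont[s:min(s + bout_n - 1L, n_t)] <- 1
      }
    }
    x <- pmin(spont + amplitudes[i] * resp, max(1, amplitudes[i]))
    noise <- if (spec$noise_sd > 0) rnorm(n_t, 0, spec$noise_sd) else 0
    F[i, ] <- baselines[i] + gains[i] * (x + noise)
  }
  recording <- roi_trial_set(F, sample_rate = sr, stim_epochs = stim_epochs,
                             behaviour = behaviour)
  list(recording = recording,
       truth = list(recruited = recruited, amplitudes = amplitudes,
                    behaviour = behaviour))
}

#' Specification for synthetic kinematics
#'
#' Piecewise behaviour episodes (forward, backward, anterior grooming, rest)
#' with velocities and keypoint trajectories consistent with the behaviour
#' classifier's definitions, plus optional planted kinematic events
#' (abdominal contraction, front-leg approach, abdomen dip).
#'
#' @param duration_s total duration (default 40 s).
#' @param sample_rate camera rate, Hz (default 100).
#' @param episode_s episode length (default 2 s).
#' @param forward_v,backward_v planted walking velocities (5, -3 mm/s).
#' @param noise_sd velocity/keypoint noise SD (default 0; set > 0 for noisy
#'   realisations).
#' @param events optional tibble `metric`, `time_s`, `duration_s`,
#'   `amplitude` of planted kinematic events.
#' @param seed mandatory integer seed.
#' @return list of class `kinematic_sim_spec`.
#' @export
kinematic_sim_spec <- function(duration_s = 40, sample_rate = 100,
                               episode_s = 2, forward_v = 5, backward_v = -3,
                               noise_sd = 0, events = NULL, seed = 1) {
  stopifnot(duration_s > 0, is.numeric(seed), length(seed) == 1)
  structure(as.list(environment()), class = "kinematic_sim_spec")
}

#' Generate synthetic kinematics with known behaviour labels
#'
#' Keypoint geometry (pixels, y grows downward): the front coxa sits at
#' (60, 50); the front tibia-tarsus rests low at (60, 62) and lifts to
#' (45, 30) during grooming; planted events displace the abdominal
#' landmarks. Episode velocities sit far from the classifier thresholds, so
#' noise-free realisations are labelled perfectly by construction.
#'
#' @param spec a [kinematic_sim_spec()].
#' @return list with `velocity` (tibble `frame`, `forward`, `turn`),
#'   `keypoints` (tibble `frame`, `landmark`, `x`, `y`), `sample_rate` and
#'   `truth` (`labels` per frame, `events`).
#' @export
generate_kinematics <- function(spec) {
  stopifnot(inherits(spec, "kinematic_sim_spec"))
  set.seed(as.integer(spec$seed))
  sr <- spec$sample_rate
  n <- seconds_to_samples(spec$duration_s, sr)
  ep_n <- seconds_to_samples(spec$episode_s, sr)
  states <- c("forward", "backward", "anterior_grooming", "rest")
  n_ep <- ceiling(n / ep_n)
  labels <- rep(sample(states, n_ep, replace = TRUE), each = ep_n)[seq_len(n)]

  v <- dplyr::case_match(labels,
    "forward" ~ spec$forward_v,
    "backward" ~ spec$backward_v,
    .default = 0
  ) + rnorm(n, 0, spec$noise_sd)
  turn <- rnorm(n, 0, max(spec$noise_sd, 1e-6)) +
    ifelse(labels == "forward", 20, 0)

  # landmark layout (x, y): pairs used by the change metrics share a y
  # coordinate, so a planted displacement along x changes the Euclidean
  # distance by exactly its amplitude
  base <- list(
    anal_plate = c(150, 30), ovipositor = c(155, 35),
    posterior_stripe = c(140, 30), neck = c(30, 62),
    front_coxa = c(60, 50), front_femur_tibia = c(60, 56),
    front_tibia_tarsus = c(60, 62), mid_tibia_tarsus = c(90, 64),
    hind_tibia_tarsus = c(120, 64)
  )
  kp <- map(names(base), function(lm) {
    x <- rep(base[[lm]][1], n)
    y <- rep(base[[lm]][2], n)
    if (lm == "front_tibia_tarsus") {
      groom <- labels == "anterior_grooming"
      x[groom] <- 45
      y[groom] <- 30
    }
    if (lm %in% c("mid_tibia_tarsus", "hind_tibia_tarsus")) {
      walking <- labels %in% c("forward", "backward")
      x <- x + ifelse(walking, 4 * sin(2 * pi * 8 * seq_len(n) / sr), 0)
    }
    tibble(frame = seq_len(n), landmark = lm,
           x = x + rnorm(n, 0, spec$noise_sd),
           y = y + rnorm(n, 0, spec$noise_sd))
  }) |> list_rbind()

  if (!is.null(spec$events)) {
    for (k in seq_len(nrow(spec$events))) {
      ev <- spec$events[k, ]
      idx <- seq(seconds_to_samples(ev$time_s, sr),
                 length.out = seconds_to_samples(ev$duration_s, sr))
      idx <- idx[idx <= n]
      move <- function(lm, dx = 0, dy = 0) {
        sel <- kp$landmark == lm & kp$frame %in% idx
        kp$x[sel] <<- kp$x[sel] + dx
        kp$y[sel] <<- kp$y[sel] + dy
      }
      switch(ev$metric,
        abdomen_contraction = move("posterior_stripe", dx = ev$amplitude),
        front_leg_approach = move("front_tibia_tarsus",
                                  dx = -ev$amplitude),
        abdomen_dip = move("anal_plate", dy = ev$amplitude),
        abort(paste0("unknown event metric: ", ev$metric))
      )
    }
  }
  list(velocity = tibble(frame = seq_len(n), forward = v, turn = turn),
       keypoints = kp, sample_rate = sr,
       truth = list(labels = labels, events = spec$events))
}
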