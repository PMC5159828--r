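# Synthetic multi-day corpus generator.
#
# Emulates the statistical structure of multielectrode motor-cortical
# recordings during planar center-out reaching: cosine-tuned Poisson
# threshold-crossing counts, minimum-jerk reach kinematics that stay stable
# across days, and recording conditions (gains, baselines, tuning rotation,
# electrode loss) that drift day to day with occasional recurrence of past
# conditions.

#' Cosine tuning model for a synthetic array
#'
#' Each electrode fires at a rectified-linear rate
#' `max(0, baseline + depth * (v . pd) + position_gain * (p . pd))` (Hz),
#' where `pd` is its preferred direction in the velocity plane.
#'
#' @param baseline_rate per-electrode baseline, Hz (>= 0).
#' @param modulation_depth per-electrode depth, Hz per cm/s.
#' @param preferred_direction 2 x E matrix of unit vectors.
#' @param position_gain per-electrode positional gain, Hz/cm (may be 0).
#' @return A `tuning_model`.
#' @export
tuning_model <- function(baseline_rate, modulation_depth,
                         preferred_direction, position_gain = 0) {
  E <- length(baseline_rate)
  preferred_direction <- as.matrix(preferred_direction)
  if (any(baseline_rate < 0)) stop("baseline_rate must be >= 0")
  if (ncol(preferred_direction) != E || nrow(preferred_direction) != 2L)
    stop("preferred_direction must be 2 x E")
  nrm <- sqrt(colSums(preferred_direction^2))
  if (any(abs(nrm - 1) > 1e-8)) stop("preferred directions must be unit norm")
  if (length(position_gain) == 1L) position_gain <- rep(position_gain, E)
  structure(list(baseline_rate = as.numeric(baseline_rate),
                 modulation_depth = as.numeric(modulation_depth),
                 preferred_direction = preferred_direction,
                 position_gain = as.numeric(position_gain), E = E),
            class = "tuning_model")
}

#' Sample a random tuning model
#'
#' Baselines 15-35 Hz, uniform preferred directions, position gains
#' 0-0.4 Hz/cm. Modulation depths are Gamma-distributed (shape 1.3, mean
#' 0.5 Hz per cm/s): chronically implanted arrays have a long-tailed
#' distribution of electrode quality, with a few strongly tuned channels
#' carrying a disproportionate share of the kinematic information — the
#' premise of ranked electrode-dropping experiments. Uses the current RNG
#' stream.
#'
#' @param E number of electrodes.
#' @param position_gain_range range for positional gains; `c(0, 0)` for
#'   velocity-only tuning.
#' @return A [tuning_model].
#' @export
sample_tuning <- function(E, position_gain_range = c(0, 0.4)) {
  ang <- stats::runif(E, 0, 2 * pi)
  tuning_model(
    baseline_rate = stats::runif(E, 15, 35),
    modulation_depth = pmin(stats::rgamma(E, shape = 1.3, scale = 0.385), 2.5),
    preferred_direction = rbind(cos(ang), sin(ang)),
    position_gain = stats::runif(E, position_gain_range[1L],
                                 position_gain_range[2L]))
}

#' A recording condition
#'
#' The multiplicative/additive state of the array on one day: a global day
#' gain, per-electrode gains (0 = lost electrode), per-electrode baseline
#' offsets, and a common rotation of preferred directions.
#'
#' @param day_gain scalar > 0.
#' @param electrode_gain per-electrode gains >= 0.
#' @param baseline_offset per-electrode baseline offsets, Hz.
#' @param pd_rotation rotation of all preferred directions, radians.
#' @return A `recording_condition`.
#' @export
recording_condition <- function(day_gain = 1, electrode_gain,
                                baseline_offset = NULL, pd_rotation = 0) {
  if (day_gain <= 0) stop("day_gain must be > 0")
  if (is.null(baseline_offset)) baseline_offset <- rep(0, length(electrode_gain))
  if (any(electrode_gain < 0)) stop("electrode_gain must be >= 0")
  if (length(baseline_offset) != length(electrode_gain))
    stop("baseline_offset and electrode_gain must have equal length")
  structure(list(day_gain = day_gain,
                 electrode_gain = as.numeric(electrode_gain),
                 baseline_offset = as.numeric(baseline_offset),
                 pd_rotation = pd_rotation),
            class = "recording_condition")
}

#' Identity recording condition for E electrodes
#' @param E number of electrodes.
#' @return A [recording_condition] with unit gains and no offsets.
#' @export
identity_condition <- function(E)
  recording_condition(1, rep(1, E), rep(0, E), 0)

#' Day-to-day drift process
#'
#' Random-walk scales per day-step plus an electrode-dropout probability and
#' a probability that a day revisits (a perturbed copy of) a past condition,
#' so chronologically distant days can be the most similar ones.
#'
#' @param gain_sd per-electrode gain random-walk sd per day.
#' @param baseline_sd baseline-offset random-walk sd per day, Hz.
#' @param rotation_sd preferred-direction rotation random-walk sd, rad/day.
#' @param day_gain_sd log-normal sd of the global day gain walk.
#' @param dropout_prob per-electrode probability per day of losing the
#'   electrode (gain set to 0).
#' @param recurrence_prob probability that a day resamples a past condition.
#' @return A `drift_process`.
#' @export
drift_process <- function(gain_sd = 0.15, baseline_sd = 2,
                          rotation_sd = 0.1, day_gain_sd = 0.05,
                          dropout_prob = 0.05, recurrence_prob = 0.2) {
  stopifnot(gain_sd >= 0, baseline_sd >= 0, rotation_sd >= 0,
            day_gain_sd >= 0,
            dropout_prob >= 0, dropout_prob <= 1,
            recurrence_prob >= 0, recurrence_prob <= 1)
  structure(list(gain_sd = gain_sd, baseline_sd = baseline_sd,
                 rotation_sd = rotation_sd, day_gain_sd = day_gain_sd,
                 dropout_prob = dropout_prob,
                 recurrence_prob = recurrence_prob),
            class = "drift_process")
}

#' Zero-drift process (conditions never change)
#' @return A [drift_process] with all scales and probabilities 0.
#' @export
no_drift <- function()
  drift_process(0, 0, 0, 0, 0, 0)

random_walk_step <- function(cond, drift) {
  E <- length(cond$electrode_gain)
  eg <- pmax(0, cond$electrode_gain + stats::rnorm(E, 0, drift$gain_sd))
  drop <- stats::runif(E) < drift$dropout_prob
  eg[drop] <- 0
  recording_condition(
    day_gain = max(0.05, cond$day_gain *
                     exp(stats::rnorm(1, 0, drift$day_gain_sd))),
    electrode_gain = eg,
    baseline_offset = cond$baseline_offset +
      stats::rnorm(E, 0, drift$baseline_sd),
    pd_rotation = cond$pd_rotation + stats::rnorm(1, 0, drift$rotation_sd))
}

#' Evolve a recording condition to the next day
#'
#' With probability `recurrence_prob` a uniformly drawn past condition is
#' revisited (a perturbed copy: one random-walk step applied to it);
#' otherwise the previous condition takes one random-walk step. Uses the
#' current RNG stream. The returned condition carries a logical attribute
#' `"recurrence"`.
#'
#' @param prev the previous day's [recording_condition].
#' @param drift a [drift_process].
#' @param history list of all past conditions (may be empty).
#' @return The next day's [recording_condition].
#' @export
evolve_condition <- function(prev, drift, history = list()) {
  recur <- length(history) > 0 && stats::runif(1) < drift$recurrence_prob
  base <- if (recur) history[[sample.int(length(history), 1L)]] else prev
  out <- random_walk_step(base, drift)
  attr(out, "recurrence") <- recur
  out
}

#' Minimum-jerk point-to-point reach
#'
#' Position follows the minimum-jerk polynomial from `start` to `target`
#' (zero velocity and acceleration at both ends); velocity is the analytic
#' derivative, both sampled at bin centers.
#'
#' @param start,target length-2 positions, cm.
#' @param duration reach duration, ms.
#' @param bin_width bin width, ms.
#' @return A [kinematics] object with `round(duration / bin_width)` bins.
#' @export
generate_reach <- function(start, target, duration, bin_width = 20) {
  if (duration <= 0) stop("duration must be positive")
  nb <- round(duration / bin_width)
  if (nb < 3L) stop("reach must span at least 3 bins")
  tc <- (seq_len(nb) - 0.5) * bin_width   # bin centers, ms
  s <- tc / duration
  shape <- 10 * s^3 - 15 * s^4 + 6 * s^5
  dshape <- (30 * s^2 - 60 * s^3 + 30 * s^4) / duration * 1000  # per second
  delta <- as.numeric(target) - as.numeric(start)
  pos <- as.numeric(start) + outer(delta, shape)
  vel <- outer(delta, dshape)
  kinematics(pos, vel, bin_width)
}

#' Emit Poisson spike counts for a kinematic trace
#'
#' Per electrode e and bin t the rate is
#' `lambda = max(0, day_gain * gain_e * (baseline_e + offset_e +
#'  depth_e * (v(t) . R(rot) pd_e) + posgain_e * (p(t) . pd_e)))` in Hz and
#' counts are drawn `Poisson(lambda * dt)` with `dt` the bin width in
#' seconds. Uses the current RNG stream.
#'
#' @param kin a [kinematics] object.
#' @param tuning a [tuning_model].
#' @param cond a [recording_condition].
#' @return A [binned_counts] object (E x T).
#' @export
emit_counts <- function(kin, tuning, cond) {
  lam <- rate_matrix(kin, tuning, cond)
  dt_s <- kin$bin_width / 1000
  cts <- matrix(stats::rpois(length(lam), lam * dt_s),
                nrow(lam), ncol(lam))
  binned_counts(cts, kin$bin_width)
}

# Deterministic rate matrix (Hz), E x T.
rate_matrix <- function(kin, tuning, cond) {
  th <- cond$pd_rotation
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pd_rot <- Rm %*% tuning$preferred_direction         # 2 x E
  vdrive <- t(pd_rot) %*% kin$velocity                # E x T
  pdrive <- t(tuning$preferred_direction) %*% kin$position
  lam <- (tuning$baseline_rate + cond$baseline_offset) +
    tuning$modulation_depth * vdrive +
    tuning$position_gain * pdrive
  lam <- cond$day_gain * cond$electrode_gain * lam
  pmax(lam, 0)
}

#' Generate a multi-day synthetic corpus
#'
#' Radial-8 center-out task: trials alternate between an outward reach from
#' the workspace center to one of 8 equidistant peripheral targets and the
#' corresponding inward return reach. Within every cycle of 8 outward
#' reaches the targets appear in a fresh random order, and the stationary
#' hold appended to each reach has a random duration, so trial timing and
#' upcoming target direction are not predictable from the past -- as in a
#' real session. Outward reaches last 700 ms and inward 600 ms. Reach
#' endpoints get small Gaussian scatter (sd `endpoint_sd` cm) so behavior
#' is statistically stable, not bitwise identical, across days, while the
#' recording condition drifts according to `drift`. Day 1 starts from the
#' identity condition.
#'
#' @param n_days number of days (>= 1).
#' @param trials_per_day trials per day.
#' @param E number of electrodes.
#' @param radius peripheral-target radius, cm.
#' @param n_targets number of peripheral targets.
#' @param drift a [drift_process].
#' @param seed integer seed; the corpus is a deterministic function of it.
#' @param bin_width bin width, ms.
#' @param tuning optional [tuning_model]; sampled if `NULL`.
#' @param out_duration,in_duration outward/inward reach durations, ms.
#' @param hold_range range of the stationary target hold appended to each
#'   reach, ms (drawn uniformly per trial in bin multiples; the task
#'   requires a hold, and its exact duration varies trial to trial).
#' @param endpoint_sd endpoint scatter sd, cm.
#' @return A [session_corpus] with `condition_truth` and `tuning_truth`.
#' @export
generate_corpus <- function(n_days, trials_per_day, E = 32,
                            radius = 8, n_targets = 8,
                            drift = drift_process(), seed = 1,
                            bin_width = 20, tuning = NULL,
                            out_duration = 700, in_duration = 600,
                            hold_range = c(400, 800), endpoint_sd = 0.3) {
  stopifnot(n_days >= 1, trials_per_day >= 1, E >= 1)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  if (is.null(tuning)) tuning <- sample_tuning(E)
  ang <- 2 * pi * (seq_len(n_targets) - 1L) / n_targets
  targets <- rbind(radius * cos(ang), radius * sin(ang))

  conds <- vector("list", n_days)
  conds[[1L]] <- identity_condition(E)
  if (n_days > 1) for (d in 2:n_days)
    conds[[d]] <- evolve_condition(conds[[d - 1L]], drift,
                                   history = conds[seq_len(d - 2L)])

  hold_bins <- round(hold_range / bin_width)
  days <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    trials <- vector("list", trials_per_day)
    n_pairs <- ceiling(trials_per_day / 2)
    order_k <- unlist(lapply(seq_len(ceiling(n_pairs / n_targets)),
                             function(i) sample.int(n_targets)))
    for (i in seq_len(trials_per_day)) {
      k <- order_k[ceiling(i / 2)]
      outward <- i %% 2L == 1L
      from <- if (outward) c(0, 0) else targets[, k]
      to <- if (outward) targets[, k] else c(0, 0)
      to_actual <- to + stats::rnorm(2, 0, endpoint_sd)
      kin <- generate_reach(from, to_actual,
                            if (outward) out_duration else in_duration,
                            bin_width)
      nh <- if (hold_bins[2L] > 0)
        sample(hold_bins[1L]:hold_bins[2L], 1L) else 0L
      if (nh > 0) {
        kin <- kinematics(
          cbind(kin$position, matrix(to_actual, 2, nh)),
          cbind(kin$velocity, matrix(0, 2, nh)), bin_width)
      }
      spikes <- emit_counts(kin, tuning, conds[[d]])
      trials[[i]] <- bmi_trial(spikes, kin, target_position = to,
                               start_position = from,
                               day_index = d, trial_index = i)
    }
    days[[d]] <- trials
  }
  session_corpus(days, condition_truth = conds, tuning_truth = tuning)
}
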