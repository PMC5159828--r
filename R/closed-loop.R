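# Closed-loop cursor-control simulation.
#
# A feedback user model forms an intended velocity toward the current target
# from the (delayed) visible cursor; the synthetic tuning model and the
# day's recording condition emit spike counts from that intention; the
# decoder under test maps counts to a new cursor position; task state
# machines implement the radial-8 and random-target protocols with the
# standard acceptance-window/hold/timeout rules and the 50%-after-10-trials
# block-failure rule.

#' Cursor blending specification
#'
#' The drawn cursor follows
#' `d <- beta * (d_prev + gamma_v * v_norm * dt) + (1 - beta) * gamma_p * p_norm`,
#' so at `beta = 1` the cursor purely integrates decoded velocity and at
#' `beta = 0` it equals the decoded position. The default `beta = 0.99`
#' gives a velocity-dominated decode with a slight position contribution
#' that offsets accumulated drift.
#'
#' @param beta position-vs-velocity blending, in `[0, 1]`.
#' @param norm `norm_spec` supplying `gamma_v` (cm/s) and `gamma_p` (cm).
#' @param dt bin width, ms.
#' @return A `blend_spec`.
#' @export
blend_spec <- function(beta = 0.99, norm, dt = 20) {
  stopifnot(beta >= 0, beta <= 1)
  structure(list(beta = beta, gamma_v = norm$gamma_v,
                 gamma_p = norm$gamma_p, dt = dt),
            class = "blend_spec")
}

#' One cursor blending update
#'
#' @param prev previous drawn cursor position, cm.
#' @param v_norm,p_norm normalized decoded velocity and position
#'   (length 2).
#' @param spec a [blend_spec].
#' @param workspace workspace width/height for clamping, cm.
#' @return New cursor position, cm.
#' @export
blend_cursor <- function(prev, v_norm, p_norm, spec,
                         workspace = c(40, 30)) {
  dt_s <- spec$dt / 1000
  d <- spec$beta * (prev + spec$gamma_v * v_norm * dt_s) +
    (1 - spec$beta) * spec$gamma_p * p_norm
  pmin(pmax(d, -workspace / 2), workspace / 2)
}

#' Task configuration
#'
#' @param task `"radial8"` (alternating centre/peripheral targets) or
#'   `"random_target"` (uniform targets in a central region, successive
#'   acceptance areas non-overlapping).
#' @param radius peripheral-target radius, cm.
#' @param n_targets peripheral target count.
#' @param window acceptance window edge lengths, cm.
#' @param hold required continuous in-window time, ms.
#' @param timeout trial time limit, ms.
#' @param region random-target sampling region (width, height), cm.
#' @param workspace full workspace (width, height), cm.
#' @return A `task_config`.
#' @export
task_config <- function(task = c("radial8", "random_target"),
                        radius = 8, n_targets = 8, window = c(4, 4),
                        hold = 500, timeout = 5000,
                        region = c(20, 20), workspace = c(40, 30)) {
  task <- match.arg(task)
  stopifnot(hold < timeout, all(window > 0))
  structure(list(task = task, radius = radius, n_targets = n_targets,
                 window = window, hold = hold, timeout = timeout,
                 region = region, workspace = workspace),
            class = "task_config")
}

#' Feedback user model
#'
#' Supplies intended kinematics during closed-loop simulation. The user
#' issues a sequence of corrective submovements: each is aimed from the
#' visible (reaction-delayed) cursor at the target and follows a
#' minimum-jerk speed profile scaled to the remaining distance, re-planned
#' whenever the previous submovement completes without acquiring the
#' target. Inside the acceptance window the intended velocity is zero
#' (hold). Gaussian intention noise is added throughout. This intermittent
#' structure keeps the intended kinematics statistically similar to natural
#' point-to-point reaches.
#'
#' @param duration_8cm submovement duration for an 8 cm error, ms (scales
#'   linearly with distance).
#' @param min_duration,max_duration submovement duration clamp, ms.
#' @param noise_sd intention noise sd, cm/s.
#' @param delay_bins visual reaction delay, bins.
#' @return A `feedback_user`.
#' @export
feedback_user <- function(duration_8cm = 700, min_duration = 250,
                          max_duration = 900, noise_sd = 2,
                          delay_bins = 5) {
  stopifnot(duration_8cm > 0, min_duration > 0,
            max_duration >= min_duration, noise_sd >= 0, delay_bins >= 0)
  structure(list(duration_8cm = duration_8cm, min_duration = min_duration,
                 max_duration = max_duration,
                 noise_sd = noise_sd, delay_bins = delay_bins),
            class = "feedback_user")
}

# ---- decoder stepping interface ---------------------------------------

#' Closed-loop decoder stepping
#'
#' S3 interface used by [run_block]: `decoder_init` returns the decoder's
#' per-block state; `decoder_step` consumes one bin of spike counts and the
#' current drawn cursor and returns `list(state, cursor)`. Methods exist
#' for `mrnn_pair` (blending law), `fitkf` (velocity integration with
#' known-position feedback), and the diagnostic `oracle_decoder` /
#' `zero_decoder`.
#'
#' @param decoder decoder object.
#' @param ctx simulation context (list with `dt`, `beta`, `workspace`,
#'   `v_intent` for the oracle).
#' @param state decoder state from `decoder_init`.
#' @param y length-E spike counts for the bin.
#' @param cursor current drawn cursor position, cm.
#' @return `decoder_init`: a state. `decoder_step`: `list(state, cursor)`.
#' @export
decoder_init <- function(decoder, ctx) UseMethod("decoder_init")

#' @rdname decoder_init
#' @export
decoder_step <- function(decoder, state, y, cursor, ctx)
  UseMethod("decoder_step")

#' @export
decoder_init.mrnn_pair <- function(decoder, ctx) {
  list(xv = mrnn_state(decoder$velocity$params, decoder$velocity$x0),
       xp = mrnn_state(decoder$position$params, decoder$position$x0),
       blend = blend_spec(ctx$beta, decoder$norm, dt = ctx$dt))
}

#' @export
decoder_step.mrnn_pair <- function(decoder, state, y, cursor, ctx) {
  state$xv <- mrnn_step(decoder$velocity$params, state$xv, y)
  state$xp <- mrnn_step(decoder$position$params, state$xp, y)
  v_norm <- mrnn_readout(decoder$velocity$params, state$xv)
  p_norm <- mrnn_readout(decoder$position$params, state$xp)
  list(state = state,
       cursor = blend_cursor(cursor, v_norm, p_norm, state$blend,
                             ctx$workspace))
}

#' @export
decoder_init.fitkf <- function(decoder, ctx) kf_state(decoder)

#' @export
decoder_step.fitkf <- function(decoder, state, y, cursor, ctx) {
  state <- kf_decode_step(decoder, state, y, cursor)
  d <- cursor + state$mean[KF_VEL] * ctx$dt / 1000
  list(state = state,
       cursor = pmin(pmax(d, -ctx$workspace / 2), ctx$workspace / 2))
}

#' Diagnostic decoders for the closed-loop machinery
#'
#' `oracle_decoder()` outputs the user's intended velocity directly (the
#' task machinery should then succeed on every trial); `zero_decoder()`
#' outputs zero velocity (every block should fail by the 50%-after-10
#' rule).
#'
#' @return Classed marker objects usable as `decoder` in [run_block].
#' @export
oracle_decoder <- function() structure(list(), class = "oracle_decoder")

#' @rdname oracle_decoder
#' @export
zero_decoder <- function() structure(list(), class = "zero_decoder")

#' @export
decoder_init.oracle_decoder <- function(decoder, ctx) list()

#' @export
decoder_step.oracle_decoder <- function(decoder, state, y, cursor, ctx)
  list(state = state, cursor = cursor + ctx$v_intent * ctx$dt / 1000)

#' @export
decoder_init.zero_decoder <- function(decoder, ctx) list()

#' @export
decoder_step.zero_decoder <- function(decoder, state, y, cursor, ctx)
  list(state = state, cursor = cursor)

# ---- block simulation --------------------------------------------------

new_target <- function(task, trial_i, prev_target, prev_peripheral_idx) {
  if (task$task == "radial8") {
    if (trial_i %% 2L == 1L) {
      k <- (prev_peripheral_idx %% task$n_targets) + 1L
      ang <- 2 * pi * (k - 1L) / task$n_targets
      list(target = task$radius * c(cos(ang), sin(ang)),
           peripheral = TRUE, k = k)
    } else list(target = c(0, 0), peripheral = FALSE, k = prev_peripheral_idx)
  } else {
    repeat {
      tg <- stats::runif(2, -task$region / 2, task$region / 2)
      if (is.null(prev_target) ||
          any(abs(tg - prev_target) >= task$window)) break
    }
    list(target = tg, peripheral = TRUE, k = prev_peripheral_idx)
  }
}

#' Run one closed-loop evaluation block
#'
#' Simulates `n_trials` trials of the configured task with the given
#' decoder, user model and recording condition. The block halts early and
#' is marked failed if the success rate drops below 50% after at least 10
#' trials; a failed block scores 0 targets per minute.
#'
#' @param decoder decoder object with [decoder_init]/[decoder_step]
#'   methods.
#' @param user a [feedback_user].
#' @param tuning a [tuning_model].
#' @param condition a [recording_condition].
#' @param task a [task_config].
#' @param n_trials trials to attempt.
#' @param dt simulation bin width, ms.
#' @param beta blending parameter for MRNN decoders.
#' @param drop integer vector of electrodes whose counts are zeroed before
#'   reaching the decoder (simulated electrode loss).
#' @param seed optional RNG seed for the block.
#' @param warmup_trials leading trials excluded from metrics (decoder
#'   transition period).
#' @return A `block_metrics` object: `outcomes` data.frame, `failed`,
#'   `wall_time_ms`, `targets_per_min`.
#' @export
run_block <- function(decoder, user, tuning, condition,
                      task = task_config(), n_trials = 40, dt = 20,
                      beta = 0.99, drop = integer(0), seed = NULL,
                      warmup_trials = 0) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  ctx <- list(dt = dt, beta = beta, workspace = task$workspace)
  dstate <- decoder_init(decoder, ctx)
  cursor <- c(0, 0)
  seen <- matrix(0, 2, max(1L, user$delay_bins))  # delayed cursor buffer
  th <- condition$pd_rotation
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pd_rot <- Rm %*% tuning$preferred_direction
  gains <- condition$day_gain * condition$electrode_gain
  base <- tuning$baseline_rate + condition$baseline_offset
  dt_s <- dt / 1000

  outcomes <- vector("list", n_trials)
  prev_target <- NULL; k_idx <- 0L
  failed <- FALSE; wall <- 0
  done <- 0L
  for (i in seq_len(n_trials)) {
    tg <- new_target(task, i, prev_target, k_idx)
    k_idx <- tg$k
    target <- tg$target
    t_ms <- 0; in_since <- NA_real_; first_entry <- NA_real_
    final_entry <- NA_real_; success <- FALSE
    sub_t <- Inf; sub_D <- 0; sub_d0 <- 0    # submovement clock
    max_bins <- ceiling(task$timeout / dt)
    for (b in seq_len(max_bins)) {
      vis <- seen[, 1L]                       # delayed visible cursor
      err <- target - vis
      inside_vis <- all(abs(err) <= task$window / 2)
      if (inside_vis) {
        v_int <- c(0, 0)
        sub_t <- Inf                          # next exit replans
      } else {
        d <- sqrt(sum(err^2))
        if (sub_t >= sub_D) {                 # (re)plan a submovement
          sub_d0 <- d
          sub_D <- min(max(user$duration_8cm * d / 8, user$min_duration),
                       user$max_duration)
          sub_t <- 0
        }
        s <- sub_t / sub_D
        speed <- sub_d0 * (30 * s^2 - 60 * s^3 + 30 * s^4) / sub_D * 1000
        v_int <- err / d * speed
        sub_t <- sub_t + dt
      }
      v_int <- v_int + stats::rnorm(2, 0, user$noise_sd)
      ctx$v_intent <- v_int
      lam <- pmax(0, gains * (base + tuning$modulation_depth *
                                drop(t(pd_rot) %*% v_int) +
                              tuning$position_gain *
                                drop(t(tuning$preferred_direction) %*% cursor)))
      y <- stats::rpois(length(lam), lam * dt_s)
      if (length(drop)) y[drop] <- 0L
      st <- decoder_step(decoder, dstate, y, cursor, ctx)
      dstate <- st$state; cursor <- st$cursor
      if (user$delay_bins > 0)
        seen <- cbind(seen[, -1L, drop = FALSE], cursor)
      else seen[, 1L] <- cursor
      t_ms <- b * dt
      inside <- all(abs(target - cursor) <= task$window / 2)
      if (inside) {
        if (is.na(in_since)) {
          in_since <- t_ms
          if (is.na(first_entry)) first_entry <- t_ms
          final_entry <- t_ms
        }
        if (t_ms - in_since >= task$hold - dt / 2) { success <- TRUE; break }
      } else in_since <- NA_real_
    }
    wall <- wall + t_ms
    outcomes[[i]] <- data.frame(
      trial = i, success = success, peripheral = tg$peripheral,
      time_to_target = if (success) final_entry else NA_real_,
      first_entry = first_entry, final_entry = final_entry,
      target_x = target[1L], target_y = target[2L], duration = t_ms,
      warmup = i <= warmup_trials)
    prev_target <- target
    done <- i
    counted <- done - min(done, warmup_trials)
    if (counted >= 10L) {
      oc <- do.call(rbind, outcomes[seq_len(done)])
      oc <- oc[!oc$warmup, ]
      if (mean(oc$success) < 0.5) { failed <- TRUE; break }
    }
  }
  oc <- do.call(rbind, outcomes[seq_len(done)])
  oc_m <- oc[!oc$warmup, , drop = FALSE]
  tpm <- if (failed || !nrow(oc_m)) 0
         else sum(oc_m$success & oc_m$peripheral) / (sum(oc_m$duration) / 60000)
  structure(list(outcomes = oc, failed = failed, wall_time_ms = wall,
                 targets_per_min = tpm),
            class = "block_metrics")
}

#' @export
print.block_metrics <- function(x, ...) {
  cat(sprintf("<block_metrics> %d trials, success %.0f%%, %.1f targets/min%s\n",
              nrow(x$outcomes), 100 * mean(x$outcomes$success),
              x$targets_per_min, if (x$failed) " [FAILED]" else ""))
  invisible(x)
}

# ---- performance metrics ----------------------------------------------

#' Closed-loop performance metrics
#'
#' `targets_per_minute`: peripheral successes over block wall time (0 for a
#' failed block). `success_rate`: fraction of counted trials acquired.
#' `time_to_target`: per successful peripheral trial, target presentation
#' to final window entry, excluding the hold. `dial_in_time`: mean time
#' between first and final window entry on successful trials.
#' `normalized_time_to_target`: time to target divided by straight-line
#' distance from the previously acquired target, for successes that follow
#' a success (s/cm).
#'
#' @param block a `block_metrics` object (or its `outcomes` data.frame for
#'   the trial-level metrics).
#' @return See each function.
#' @export
targets_per_minute <- function(block) {
  stopifnot(inherits(block, "block_metrics"))
  block$targets_per_min
}

metric_outcomes <- function(block) {
  oc <- if (inherits(block, "block_metrics")) block$outcomes else block
  if (is.null(oc) || !nrow(oc)) stop("no trial outcomes")
  oc[!oc$warmup, , drop = FALSE]
}

#' @rdname targets_per_minute
#' @export
success_rate <- function(block) mean(metric_outcomes(block)$success)

#' @rdname targets_per_minute
#' @export
time_to_target <- function(block) {
  oc <- metric_outcomes(block)
  oc$time_to_target[oc$success & oc$peripheral]
}

#' @rdname targets_per_minute
#' @export
dial_in_time <- function(block) {
  oc <- metric_outcomes(block)
  oc <- oc[oc$success, ]
  if (!nrow(oc)) stop("no successful trials")
  mean(oc$final_entry - oc$first_entry)
}

#' @rdname targets_per_minute
#' @export
normalized_time_to_target <- function(block) {
  oc <- metric_outcomes(block)
  out <- numeric(0)
  for (i in seq_len(nrow(oc))[-1]) {
    if (oc$success[i] && oc$success[i - 1L]) {
      d <- sqrt((oc$target_x[i] - oc$target_x[i - 1L])^2 +
                (oc$target_y[i] - oc$target_y[i - 1L])^2)
      if (d > 0) out <- c(out, oc$time_to_target[i] / 1000 / d)
    }
  }
  out
}

#' Offline decode accuracy
#'
#' Squared Pearson correlation between true and decoded endpoint velocity,
#' computed per dimension on the concatenated bins and averaged over the
#' two dimensions.
#'
#' @param true_v,decoded_v 2 x T velocity matrices.
#' @return Scalar mean r-squared.
#' @export
decode_accuracy_r2 <- function(true_v, decoded_v) {
  if (ncol(true_v) < 3L) stop("need at least 3 bins")
  r2 <- vapply(1:2, function(d) {
    if (stats::sd(true_v[d, ]) == 0 || stats::sd(decoded_v[d, ]) == 0)
      stop("zero-variance velocity input")
    stats::cor(true_v[d, ], decoded_v[d, ])^2
  }, numeric(1))
  mean(r2)
}
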