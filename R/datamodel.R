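#' Binned multiunit spike counts
#'
#' Container for threshold-crossing counts on a multielectrode array, binned
#' at a fixed width. Rows are electrodes, columns are time bins (half-open
#' `[t, t + bin_width)` intervals). Counts are non-negative integers; no rate
#' conversion happens inside the data model.
#'
#' @param counts integer matrix, electrodes x time bins, all entries >= 0.
#' @param bin_width bin width in milliseconds (> 0).
#' @param electrode_ids optional character vector of electrode labels;
#'   defaults to `"e1" ... "eE"`.
#' @return An object of class `binned_counts`.
#' @export
binned_counts <- function(counts, bin_width, electrode_ids = NULL) {
  counts <- as.matrix(counts)
  if (length(counts) && (any(!is.finite(counts)) || any(counts < 0)))
    stop("spike counts must be finite and non-negative")
  if (length(counts) && any(counts != round(counts)))
    stop("spike counts must be integers")
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("bin_width must be a single positive number (ms)")
  storage.mode(counts) <- "integer"
  if (is.null(electrode_ids))
    electrode_ids <- paste0("e", seq_len(nrow(counts)))
  if (length(electrode_ids) != nrow(counts))
    stop("electrode_ids length must equal number of electrode rows")
  structure(
    list(counts = counts, bin_width = bin_width,
         electrode_ids = as.character(electrode_ids)),
    class = "binned_counts")
}

#' @export
print.binned_counts <- function(x, ...) {
  cat(sprintf("<binned_counts> %d electrodes x %d bins @ %g ms (total %d spikes)\n",
              nrow(x$counts), ncol(x$counts), x$bin_width, sum(x$counts)))
  invisible(x)
}

#' @export
dim.binned_counts <- function(x) dim(x$counts)

#' 2D reach kinematics
#'
#' Position (cm) and velocity (cm/s) of the hand or cursor in the
#' fronto-parallel workspace plane, sampled on the same timebase as the
#' spike-count bins. Origin is the workspace center.
#'
#' @param position 2 x T matrix, cm (rows x, y).
#' @param velocity 2 x T matrix, cm/s.
#' @param bin_width bin width in ms.
#' @return An object of class `kinematics`.
#' @export
kinematics <- function(position, velocity, bin_width) {
  position <- as.matrix(position); velocity <- as.matrix(velocity)
  if (nrow(position) != 2L || nrow(velocity) != 2L)
    stop("position and velocity must have 2 rows (x, y)")
  if (ncol(position) != ncol(velocity))
    stop("position and velocity must share the same timebase")
  if (any(!is.finite(position)) || any(!is.finite(velocity)))
    stop("kinematics must be finite")
  if (bin_width <= 0) stop("bin_width must be positive")
  structure(list(position = position, velocity = velocity,
                 bin_width = bin_width),
            class = "kinematics")
}

#' @export
print.kinematics <- function(x, ...) {
  cat(sprintf("<kinematics> %d bins @ %g ms, peak speed %.1f cm/s\n",
              ncol(x$position), x$bin_width,
              max(sqrt(colSums(x$velocity^2)), 0)))
  invisible(x)
}

#' A single reach trial
#'
#' One point-to-point reach: spike counts, aligned kinematics, the target and
#' start positions, and bookkeeping indices.
#'
#' @param spikes a [binned_counts] object.
#' @param kin a [kinematics] object with the same number of bins.
#' @param target_position,start_position length-2 numeric, cm.
#' @param day_index,trial_index integer bookkeeping indices.
#' @return An object of class `bmi_trial`.
#' @export
bmi_trial <- function(spikes, kin, target_position, start_position,
                      day_index = 1L, trial_index = 1L) {
  stopifnot(inherits(spikes, "binned_counts"), inherits(kin, "kinematics"))
  if (ncol(spikes$counts) != ncol(kin$position))
    stop("spikes and kinematics must have equal timebin counts")
  if (spikes$bin_width != kin$bin_width)
    stop("spikes and kinematics must share bin width")
  structure(list(spikes = spikes, kin = kin,
                 target_position = as.numeric(target_position),
                 start_position = as.numeric(start_position),
                 day_index = as.integer(day_index),
                 trial_index = as.integer(trial_index)),
            class = "bmi_trial")
}

#' Multi-day session corpus
#'
#' An ordered collection of recording days, each a list of [bmi_trial]s.
#' All trials must share an electrode count. For synthetic corpora the
#' per-day ground-truth recording conditions can be attached.
#'
#' @param days named or unnamed list; element `i` is the list of trials for
#'   the i-th day. Day indices are taken from the trials and must be strictly
#'   increasing across the list.
#' @param condition_truth optional list of `recording_condition` objects,
#'   one per day (synthetic corpora only).
#' @param tuning_truth optional `tuning_model` (synthetic corpora only).
#' @return An object of class `session_corpus`.
#' @export
session_corpus <- function(days, condition_truth = NULL, tuning_truth = NULL) {
  if (!length(days)) stop("corpus must contain at least one day")
  day_idx <- vapply(days, function(tr) tr[[1L]]$day_index, integer(1))
  if (any(diff(day_idx) <= 0))
    stop("day_index must be strictly increasing across days")
  E <- nrow(days[[1L]][[1L]]$spikes$counts)
  for (d in seq_along(days)) for (tr in days[[d]]) {
    if (nrow(tr$spikes$counts) != E)
      stop(sprintf("inconsistent electrode count on day %d trial %d",
                   tr$day_index, tr$trial_index))
  }
  structure(list(days = days, day_indices = day_idx,
                 condition_truth = condition_truth,
                 tuning_truth = tuning_truth),
            class = "session_corpus")
}

#' @export
print.session_corpus <- function(x, ...) {
  nt <- vapply(x$days, length, integer(1))
  cat(sprintf("<session_corpus> %d days, %d trials, %d electrodes @ %g ms bins\n",
              length(x$days), sum(nt),
              nrow(x$days[[1]][[1]]$spikes$counts),
              x$days[[1]][[1]]$spikes$bin_width))
  invisible(x)
}

#' @export
summary.session_corpus <- function(object, ...) {
  nt <- vapply(object$days, length, integer(1))
  rates <- vapply(object$days, function(trials) {
    s <- vapply(trials, function(tr) sum(tr$spikes$counts), numeric(1))
    b <- vapply(trials, function(tr)
      ncol(tr$spikes$counts) * nrow(tr$spikes$counts) *
        tr$spikes$bin_width / 1000, numeric(1))
    sum(s) / sum(b)
  }, numeric(1))
  out <- data.frame(day_index = object$day_indices, n_trials = nt,
                    mean_rate_hz = rates)
  class(out) <- c("summary.session_corpus", "data.frame")
  out
}

corpus_trials <- function(corpus) unlist(corpus$days, recursive = FALSE)

corpus_n_electrodes <- function(corpus)
  nrow(corpus$days[[1L]][[1L]]$spikes$counts)

corpus_bin_width <- function(corpus)
  corpus$days[[1L]][[1L]]$spikes$bin_width

#' Differentiate a position trace
#'
#' Velocity from position by central differences: interior bins use the
#' symmetric two-sided difference, the two endpoints one-sided first
#' differences (so the trial keeps its full length).
#'
#' @param position 2 x T matrix, cm.
#' @param bin_width bin width, ms.
#' @return 2 x T velocity matrix, cm/s.
#' @export
compute_velocity <- function(position, bin_width) {
  position <- as.matrix(position)
  T <- ncol(position)
  if (T < 3L) stop("need at least 3 bins to differentiate")
  dt_s <- bin_width / 1000
  v <- matrix(0, nrow(position), T)
  v[, 1L] <- (position[, 2L] - position[, 1L]) / dt_s
  v[, T] <- (position[, T] - position[, T - 1L]) / dt_s
  idx <- 2:(T - 1L)
  v[, idx] <- (position[, idx + 1L] - position[, idx - 1L]) / (2 * dt_s)
  v
}

#' Fit kinematic normalization for decoder targets
#'
#' The MRNN readout passes through bounded rates, so training targets are
#' normalized to `[-1, 1]` by per-dimension maximum-absolute scaling over the
#' whole training corpus. The scales double as the gains (`gamma_v`,
#' `gamma_p`) that convert normalized decoder output back to workspace
#' coordinates.
#'
#' @param corpus a [session_corpus].
#' @return A `norm_spec` with `position_scale` and `velocity_scale`
#'   (length-2, cm and cm/s) and aliases `gamma_p`, `gamma_v`.
#' @export
fit_normalization <- function(corpus) {
  trials <- corpus_trials(corpus)
  if (!length(trials)) stop("corpus is empty")
  pmax_ <- c(0, 0); vmax_ <- c(0, 0)
  for (tr in trials) {
    pmax_ <- pmax(pmax_, apply(abs(tr$kin$position), 1, max))
    vmax_ <- pmax(vmax_, apply(abs(tr$kin$velocity), 1, max))
  }
  if (any(pmax_ == 0) || any(vmax_ == 0))
    stop("degenerate normalization: a kinematic dimension is identically zero")
  structure(list(position_scale = pmax_, velocity_scale = vmax_,
                 gamma_p = pmax_, gamma_v = vmax_),
            class = "norm_spec")
}

#' Normalize / denormalize kinematics
#'
#' @param k 2 x T matrix.
#' @param spec a `norm_spec` from [fit_normalization].
#' @param what `"position"` or `"velocity"`.
#' @return 2 x T matrix.
#' @export
normalize_kin <- function(k, spec, what = c("velocity", "position")) {
  what <- match.arg(what)
  s <- if (what == "velocity") spec$velocity_scale else spec$position_scale
  k / s
}

#' @rdname normalize_kin
#' @export
denormalize_kin <- function(k, spec, what = c("velocity", "position")) {
  what <- match.arg(what)
  s <- if (what == "velocity") spec$velocity_scale else spec$position_scale
  k * s
}
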