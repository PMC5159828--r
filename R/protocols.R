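# The three decoder-robustness experiment protocols, run end to end on a
# synthetic corpus: training-set-size sweep (offline), unexpected loss of
# the most informative electrodes (closed loop), and stale training data
# across a withheld gap (closed loop). Closed-loop protocols need the
# corpus's ground-truth tuning/conditions, so they apply to synthetic
# corpora from generate_corpus().

#' Offline velocity-decode accuracy on a set of trials
#'
#' Concatenates the trials into one stream, runs the velocity decoder with
#' persistent state, discards the first two trials as state seeding, and
#' returns the mean per-dimension r-squared against the true velocities.
#'
#' @param decoder an `mrnn_decoder` (velocity target), `mrnn_pair`, or
#'   `fitkf`.
#' @param trials list of [bmi_trial]s.
#' @return Scalar r-squared.
#' @export
offline_decode_r2 <- function(decoder, trials) {
  if (inherits(decoder, "mrnn_pair")) decoder <- decoder$velocity
  counts <- do.call(cbind, lapply(trials, function(tr) tr$spikes$counts))
  true_v <- do.call(cbind, lapply(trials, function(tr) tr$kin$velocity))
  dec_v <- if (inherits(decoder, "fitkf")) {
    true_p <- do.call(cbind, lapply(trials, function(tr) tr$kin$position))
    predict(decoder, counts, cursor_pos = true_p)$velocity
  } else predict(decoder, counts)
  seed_bins <- sum(vapply(trials[1:2], function(tr)
    ncol(tr$spikes$counts), integer(1)))
  keep <- (seed_bins + 1L):ncol(true_v)
  decode_accuracy_r2(true_v[, keep, drop = FALSE],
                     dec_v[, keep, drop = FALSE])
}

check_synthetic <- function(corpus) {
  if (is.null(corpus$condition_truth) || is.null(corpus$tuning_truth))
    stop("closed-loop protocols need a synthetic corpus with ground-truth ",
         "tuning and conditions (see generate_corpus)")
}

day_condition <- function(corpus, day_index)
  corpus$condition_truth[[match(day_index, corpus$day_indices)]]

#' Training-set-size sweep (offline)
#'
#' Trains velocity MRNNs on increasing numbers of days immediately
#' preceding the held-out test day -- data are added by looking further
#' back in time, so corpus size is not conflated with recency -- and
#' reports offline decode accuracy on the test day.
#'
#' @param corpus a [session_corpus].
#' @param day_counts integer vector of training-day counts.
#' @param config an [hf_config].
#' @param perturb a [perturbation_spec].
#' @param test_day day index to test on (default: the last day, never in
#'   training).
#' @param ... passed to [train_mrnn] (`N`, `tau`, ...).
#' @return data.frame with `n_days`, `r2`.
#' @export
protocol_training_size_sweep <- function(corpus, day_counts,
                                         config = hf_config(),
                                         perturb = perturbation_spec(),
                                         test_day = NULL, ...) {
  idx <- corpus$day_indices
  if (is.null(test_day)) test_day <- idx[length(idx)]
  pre <- idx[idx < test_day]
  if (max(day_counts) > length(pre))
    stop("not enough pre-test days for the requested sweep")
  test_trials <- corpus$days[[match(test_day, idx)]]
  rows <- lapply(day_counts, function(n) {
    train_days <- utils::tail(pre, n)
    dec <- train_mrnn(corpus, target = "velocity", config = config,
                      perturb = perturb, days = train_days, ...)
    data.frame(n_days = n, r2 = offline_decode_r2(dec, test_trials))
  })
  do.call(rbind, rows)
}

#' Electrode-dropping robustness protocol (closed loop)
#'
#' Trains an augmented multi-day MRNN pair (all days before the test day)
#' and a same-day FIT-KF, ranks the test day's electrodes by mutual
#' information with reach direction, then for each requested k zeroes the
#' top-k electrodes at the decoder input (no retraining) and runs
#' interleaved closed-loop blocks under the test day's recording
#' condition.
#'
#' @param corpus synthetic [session_corpus] with ground truth.
#' @param ks integer vector of drop counts.
#' @param config,perturb MRNN training settings.
#' @param user a [feedback_user].
#' @param task a [task_config].
#' @param n_trials trials per block.
#' @param seed base RNG seed for the evaluation blocks.
#' @param mrnn optional pre-trained `mrnn_pair` (trained on the pre-test
#'   days); trained here if missing.
#' @param ... passed to [train_decoder_pair].
#' @return data.frame with one row per decoder x k: `decoder`, `k`,
#'   `targets_per_min`, `success_rate`, `failed`.
#' @export
protocol_electrode_drop <- function(corpus, ks = c(0, 3),
                                    config = hf_config(),
                                    perturb = perturbation_spec(),
                                    user = feedback_user(),
                                    task = task_config(), n_trials = 30,
                                    seed = 1, mrnn = NULL, ...) {
  check_synthetic(corpus)
  idx <- corpus$day_indices
  test_day <- idx[length(idx)]
  dt <- corpus_bin_width(corpus)
  if (is.null(mrnn))
    mrnn <- train_decoder_pair(corpus, config = config, perturb = perturb,
                               days = idx[idx < test_day], ...)
  kf <- train_fitkf(corpus, days = test_day)
  ranking <- rank_electrodes(corpus$days[[match(test_day, idx)]])
  cond <- day_condition(corpus, test_day)
  tun <- corpus$tuning_truth
  decs <- list(mrnn = mrnn, fit_sameday = kf)
  rows <- list()
  for (ki in seq_along(ks)) for (dn in names(decs)) {
    k <- ks[ki]
    bl <- run_block(decs[[dn]], user, tun, cond, task, n_trials, dt = dt,
                    drop = if (k > 0) ranking$electrode[seq_len(k)]
                           else integer(0),
                    seed = seed + 97L * ki + match(dn, names(decs)))
    rows[[length(rows) + 1L]] <- data.frame(
      decoder = dn, k = k, targets_per_min = targets_per_minute(bl),
      success_rate = success_rate(bl), failed = bl$failed)
  }
  do.call(rbind, rows)
}

#' Stale-training-data robustness protocol (closed loop)
#'
#' Withholds the most recent `gap_days` of recordings: the MRNN pair and a
#' pooled "FIT Long" train on all pre-gap days, "FIT Old" on the last
#' pre-gap day only, and "FIT Sameday" on the test day itself. All four
#' are evaluated in closed loop under the test day's recording condition.
#'
#' @param corpus synthetic [session_corpus] with ground truth.
#' @param gap_days number of withheld days between training data and the
#'   test day.
#' @param mrnn optional pre-trained `mrnn_pair` (trained on the pre-gap
#'   days); trained here if missing.
#' @inheritParams protocol_electrode_drop
#' @return data.frame with one row per decoder.
#' @export
protocol_stale_training <- function(corpus, gap_days,
                                    config = hf_config(),
                                    perturb = perturbation_spec(),
                                    user = feedback_user(),
                                    task = task_config(), n_trials = 30,
                                    seed = 1, mrnn = NULL, ...) {
  check_synthetic(corpus)
  idx <- corpus$day_indices
  test_day <- idx[length(idx)]
  pre <- idx[idx <= test_day - gap_days - 1L]
  if (!length(pre)) stop("corpus is not longer than the gap")
  dt <- corpus_bin_width(corpus)
  decs <- list(
    mrnn = if (!is.null(mrnn)) mrnn
           else train_decoder_pair(corpus, config = config,
                                   perturb = perturb, days = pre, ...),
    fit_long = train_fitkf(corpus, days = pre),
    fit_old = train_fitkf(corpus, days = pre[length(pre)]),
    fit_sameday = train_fitkf(corpus, days = test_day))
  cond <- day_condition(corpus, test_day)
  tun <- corpus$tuning_truth
  rows <- lapply(seq_along(decs), function(i) {
    bl <- run_block(decs[[i]], user, tun, cond, task, n_trials, dt = dt,
                    seed = seed + 31L * i)
    data.frame(decoder = names(decs)[i],
               targets_per_min = targets_per_minute(bl),
               success_rate = success_rate(bl), failed = bl$failed)
  })
  do.call(rbind, rows)
}
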