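# Corpus and parameter-bundle serialization.
#
# The on-disk container is a hierarchical JSON document mirroring the layout
#   days/<i>/trials/<j>/{counts, position, velocity, target, start}
# with corpus-level bin width and electrode labels. JSON keeps integer spike
# counts exact and the whole artifact greppable/diffable.

CORPUS_FORMAT <- "robustbmi-corpus"
PARAMS_FORMAT <- "robustbmi-params"

#' Write a corpus to disk
#'
#' @param corpus a [session_corpus].
#' @param path output file path (`.json`).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  if (!inherits(corpus, "session_corpus")) stop("not a session_corpus")
  if (!length(corpus$days) || !length(corpus$days[[1L]]))
    stop("refusing to write an empty corpus")
  doc <- list(
    format = CORPUS_FORMAT, version = 1L,
    bin_width = corpus_bin_width(corpus),
    electrode_ids = corpus$days[[1L]][[1L]]$spikes$electrode_ids,
    days = lapply(corpus$days, function(trials) {
      list(
        day_index = trials[[1L]]$day_index,
        trials = lapply(trials, function(tr) list(
          trial_index = tr$trial_index,
          counts = tr$spikes$counts,
          position = tr$kin$position,
          velocity = tr$kin$velocity,
          target = tr$target_position,
          start = tr$start_position)))
    }),
    condition_truth = if (!is.null(corpus$condition_truth))
      lapply(corpus$condition_truth, function(cc)
        list(day_gain = cc$day_gain, electrode_gain = cc$electrode_gain,
             baseline_offset = cc$baseline_offset,
             pd_rotation = cc$pd_rotation)),
    tuning_truth = if (!is.null(corpus$tuning_truth)) {
      tt <- corpus$tuning_truth
      list(baseline_rate = tt$baseline_rate,
           modulation_depth = tt$modulation_depth,
           preferred_direction = tt$preferred_direction,
           position_gain = tt$position_gain)
    })
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a corpus from disk
#'
#' @param path file written by [write_corpus].
#' @return A [session_corpus].
#' @export
read_corpus <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = TRUE)
  if (!identical(doc$format, CORPUS_FORMAT))
    stop("not a ", CORPUS_FORMAT, " file: ", path)
  bw <- doc$bin_width
  eids <- doc$electrode_ids
  E <- length(eids)
  days <- lapply(doc$days, function(day) {
    lapply(day$trials, function(tr) {
      cm <- as.matrix(tr$counts)
      if (nrow(cm) != E)
        stop(sprintf("format error: day %d trial %d has %d electrode rows, expected %d",
                     day$day_index, tr$trial_index, nrow(cm), E))
      bmi_trial(
        binned_counts(cm, bw, eids),
        kinematics(as.matrix(tr$position), as.matrix(tr$velocity), bw),
        target_position = tr$target, start_position = tr$start,
        day_index = day$day_index, trial_index = tr$trial_index)
    })
  })
  cond <- doc$condition_truth
  if (!is.null(cond))
    cond <- lapply(cond, function(cc)
      recording_condition(day_gain = cc$day_gain,
                          electrode_gain = cc$electrode_gain,
                          baseline_offset = cc$baseline_offset,
                          pd_rotation = cc$pd_rotation))
  tun <- doc$tuning_truth
  if (!is.null(tun))
    tun <- tuning_model(baseline_rate = tun$baseline_rate,
                        modulation_depth = tun$modulation_depth,
                        preferred_direction = as.matrix(tun$preferred_direction),
                        position_gain = tun$position_gain)
  session_corpus(days, condition_truth = cond, tuning_truth = tun)
}

#' Export one trial as CSV
#'
#' Flat per-bin table: time, position, velocity and one column per electrode.
#'
#' @param trial a [bmi_trial].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  T <- ncol(trial$spikes$counts)
  df <- data.frame(
    time_ms = (seq_len(T) - 1L) * trial$spikes$bin_width,
    pos_x = trial$kin$position[1L, ], pos_y = trial$kin$position[2L, ],
    vel_x = trial$kin$velocity[1L, ], vel_y = trial$kin$velocity[2L, ])
  cts <- t(trial$spikes$counts)
  colnames(cts) <- trial$spikes$electrode_ids
  utils::write.csv(cbind(df, cts), path, row.names = FALSE)
  invisible(path)
}

# Save/load a fitted decoder (MRNN pair, single MRNN, or FIT-KF) in the same
# JSON container family, with a manifest describing how it was produced.

#' Save a fitted decoder bundle
#'
#' @param object an `mrnn_decoder`, `mrnn_pair` or `fitkf` object.
#' @param path output file path (`.json`).
#' @return `path`, invisibly.
#' @export
write_decoder <- function(object, path) {
  doc <- list(format = PARAMS_FORMAT, version = 1L,
              kind = class(object)[1L],
              payload = decoder_payload(object))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Load a decoder bundle saved with [write_decoder]
#' @param path file path.
#' @return The decoder object.
#' @export
read_decoder <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = TRUE)
  if (!identical(doc$format, PARAMS_FORMAT))
    stop("not a ", PARAMS_FORMAT, " file: ", path)
  decoder_unpayload(doc$kind, doc$payload)
}

decoder_payload <- function(object) UseMethod("decoder_payload")

decoder_unpayload <- function(kind, payload) {
  switch(kind,
    mrnn_decoder = unpayload_mrnn_decoder(payload),
    mrnn_pair = unpayload_mrnn_pair(payload),
    fitkf = unpayload_fitkf(payload),
    stop("unknown decoder kind: ", kind))
}
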