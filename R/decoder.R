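# Fitted-decoder interface: train_mrnn() / train_decoder_pair() are the
# model-fitting entry points; the returned objects carry everything needed
# to decode new spike counts (weights + kinematic normalization).

#' Fit an MRNN decoder to a corpus
#'
#' Trains a multiplicative RNN to read out one normalized 2D kinematic
#' signal (velocity or position) from binned spike counts, using
#' Hessian-free optimization with spike-count augmentation (see
#' [hf_train]).
#'
#' @inheritParams hf_train
#' @param ... passed to [hf_train] (`N`, `F`, `tau`, `days`,
#'   `init_params`, `norm`).
#' @return An object of class `mrnn_decoder` with methods `print`,
#'   `summary`, `coef`, `predict`.
#' @export
train_mrnn <- function(corpus, target = c("velocity", "position"),
                       config = hf_config(), perturb = perturbation_spec(),
                       ...) {
  target <- match.arg(target)
  fit <- hf_train(corpus, config = config, perturb = perturb,
                  target = target, ...)
  structure(list(params = fit$params, norm = fit$norm, x0 = fit$x0,
                 target = target,
                 snapshots = fit$snapshots, history = fit$history,
                 heldout_loss = fit$heldout_loss, best_step = fit$best_step,
                 config = config, perturb = perturb,
                 call = match.call()),
            class = "mrnn_decoder")
}

#' @export
print.mrnn_decoder <- function(x, ...) {
  d <- x$params$dims
  cat(sprintf("MRNN %s decoder: N=%d F=%d E=%d M=%d (%d parameters)\n",
              x$target, d["N"], d["F"], d["E"], d["M"],
              count_mrnn_params(d["N"], d["F"], d["E"], d["M"])))
  cat(sprintf("  best snapshot: step %d, held-out MSE %.4g\n",
              x$best_step, x$heldout_loss))
  invisible(x)
}

#' @export
summary.mrnn_decoder <- function(object, ...) {
  print(object)
  cat("snapshots:\n")
  print(object$snapshots, row.names = FALSE)
  invisible(object)
}

#' @export
coef.mrnn_decoder <- function(object, ...) flatten_params(object$params)

#' Decode kinematics from spike counts with a fitted MRNN
#'
#' Runs the network over the counts and denormalizes the readout, returning
#' the decoded kinematic signal in workspace units.
#'
#' @param object an `mrnn_decoder`.
#' @param counts a [binned_counts] or E x T matrix.
#' @param x0 initial hidden activation; defaults to the state the decoder
#'   was trained to start sequences from.
#' @param ... unused.
#' @return 2 x T matrix (cm/s for a velocity decoder, cm for position).
#' @export
predict.mrnn_decoder <- function(object, counts, x0 = object$x0, ...) {
  run <- mrnn_run(object$params, counts, x0 = x0)
  denormalize_kin(run$Z, object$norm, object$target)
}

#' @export
residuals.mrnn_decoder <- function(object, counts, kin, ...) {
  pred <- predict(object, counts)
  truth <- if (object$target == "velocity") kin$velocity else kin$position
  truth - pred
}

#' Train the position/velocity MRNN decoder pair
#'
#' Two independently trained networks (both `M = 2`) sharing one kinematic
#' normalization: one reads out normalized position, the other normalized
#' velocity. The pair is what drives closed-loop cursor control through the
#' blending law (see [blend_cursor]).
#'
#' @inheritParams train_mrnn
#' @param config_position optional separate [hf_config] for the position
#'   net (defaults to `config` with a different seed so the nets are not
#'   aliased).
#' @return An object of class `mrnn_pair`.
#' @export
train_decoder_pair <- function(corpus, config = hf_config(),
                               perturb = perturbation_spec(),
                               config_position = NULL, ...) {
  norm <- NULL
  vel <- train_mrnn(corpus, target = "velocity", config = config,
                    perturb = perturb, ...)
  if (is.null(config_position)) {
    config_position <- config
    config_position$seed <- config$seed + 1000L
  }
  pos <- train_mrnn(corpus, target = "position", config = config_position,
                    perturb = perturb, norm = vel$norm, ...)
  structure(list(velocity = vel, position = pos, norm = vel$norm),
            class = "mrnn_pair")
}

#' @export
print.mrnn_pair <- function(x, ...) {
  cat("MRNN decoder pair (velocity + position nets)\n")
  print(x$velocity); print(x$position)
  invisible(x)
}

#' Offline decode with an MRNN pair
#'
#' @param object an `mrnn_pair`.
#' @param counts a [binned_counts] or E x T matrix.
#' @param ... unused.
#' @return List with `velocity` (2 x T, cm/s) and `position` (2 x T, cm).
#' @export
predict.mrnn_pair <- function(object, counts, ...) {
  list(velocity = predict(object$velocity, counts),
       position = predict(object$position, counts))
}

# ---- serialization payloads -------------------------------------------

params_payload <- function(p)
  list(J_xf = p$J_xf, J_fu = p$J_fu, J_fx = p$J_fx, b_x = p$b_x,
       W_o = p$W_o, b_z = p$b_z, tau = p$tau, dt = p$dt)

params_unpayload <- function(pl)
  mrnn_params(as.matrix(pl$J_xf), as.matrix(pl$J_fu), as.matrix(pl$J_fx),
              pl$b_x, as.matrix(pl$W_o), pl$b_z, pl$tau, pl$dt)

norm_payload <- function(n)
  list(position_scale = n$position_scale, velocity_scale = n$velocity_scale)

norm_unpayload <- function(pl)
  structure(list(position_scale = pl$position_scale,
                 velocity_scale = pl$velocity_scale,
                 gamma_p = pl$position_scale, gamma_v = pl$velocity_scale),
            class = "norm_spec")

#' @export
decoder_payload.mrnn_decoder <- function(object)
  list(params = params_payload(object$params),
       norm = norm_payload(object$norm), x0 = object$x0,
       target = object$target, best_step = object$best_step,
       heldout_loss = object$heldout_loss)

unpayload_mrnn_decoder <- function(pl)
  structure(list(params = params_unpayload(pl$params),
                 norm = norm_unpayload(pl$norm), x0 = pl$x0,
                 target = pl$target,
                 snapshots = NULL, history = NULL,
                 heldout_loss = pl$heldout_loss, best_step = pl$best_step,
                 config = NULL, perturb = NULL, call = NULL),
            class = "mrnn_decoder")

#' @export
decoder_payload.mrnn_pair <- function(object)
  list(velocity = decoder_payload(object$velocity),
       position = decoder_payload(object$position))

unpayload_mrnn_pair <- function(pl)
  structure(list(velocity = unpayload_mrnn_decoder(pl$velocity),
                 position = unpayload_mrnn_decoder(pl$position),
                 norm = norm_unpayload(pl$velocity$norm)),
            class = "mrnn_pair")
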