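# Hessian-free training of the MRNN on multi-day corpora.
#
# Training sequences are sliding windows of 5 consecutive reaching trials;
# the first 2 seed the hidden state (no error), the last 3 carry the squared
# error. Spike-count augmentation multiplies each electrode's per-sequence
# total by trial-level and electrode-level Gaussian gains (mean 1) and
# adds/removes spikes at random bins; it is re-drawn on every optimizer
# iteration. The optimizer is Hessian-free: damped Gauss-Newton systems
# solved by conjugate gradient on a per-day-sampled minibatch, with
# Levenberg-Marquardt lambda adaptation and held-out snapshot selection.

#' Spike-count perturbation specification
#'
#' @param sigma_trial sd of the trial-level gain (shared across electrodes
#'   within one training sequence).
#' @param sigma_electrode sd of the electrode-level gain.
#' @return A `perturbation_spec`. Both gains are Gaussian with mean 1.
#' @export
perturbation_spec <- function(sigma_trial = 0.045, sigma_electrode = 0.3) {
  stopifnot(sigma_trial >= 0, sigma_electrode >= 0)
  structure(list(sigma_trial = sigma_trial, sigma_electrode = sigma_electrode),
            class = "perturbation_spec")
}

#' Hessian-free optimizer configuration
#'
#' Defaults follow the standard recipe for this decoder family: minibatch
#' one-fifth of the training sequences, initial damping 0.1, at most 50 CG
#' iterations, 200 optimization steps with a snapshot every 10.
#'
#' @param total_steps optimization steps.
#' @param minibatch_fraction fraction of training sequences per minibatch.
#' @param initial_lambda initial Levenberg-Marquardt damping.
#' @param max_cg_iters conjugate-gradient iteration cap.
#' @param snapshot_interval steps between held-out snapshots.
#' @param heldout_fraction per-day fraction of sequences held out for
#'   snapshot selection (taken from the end of each day).
#' @param curvature_fraction fraction of the minibatch used for
#'   Gauss-Newton (curvature) products inside CG; the gradient always uses
#'   the whole minibatch. 1 = same batch for both; smaller values are the
#'   classic Hessian-free economy.
#' @param cg_tol relative residual tolerance for CG.
#' @param seed RNG seed for minibatch sampling and augmentation.
#' @return An `hf_config`.
#' @export
hf_config <- function(total_steps = 200, minibatch_fraction = 1 / 5,
                      initial_lambda = 0.1, max_cg_iters = 50,
                      snapshot_interval = 10, heldout_fraction = 0.1,
                      curvature_fraction = 0.5,
                      cg_tol = 5e-4, seed = 1) {
  stopifnot(minibatch_fraction > 0, minibatch_fraction <= 1,
            max_cg_iters >= 1, total_steps >= 1, snapshot_interval >= 1,
            heldout_fraction >= 0, heldout_fraction < 1,
            curvature_fraction > 0, curvature_fraction <= 1)
  structure(list(total_steps = total_steps,
                 minibatch_fraction = minibatch_fraction,
                 initial_lambda = initial_lambda,
                 max_cg_iters = max_cg_iters,
                 snapshot_interval = snapshot_interval,
                 heldout_fraction = heldout_fraction,
                 curvature_fraction = curvature_fraction,
                 cg_tol = cg_tol, seed = seed),
            class = "hf_config")
}

#' Build MRNN training sequences for one day
#'
#' Sliding windows of 5 consecutive trials with stride 1 (`n - 4` sequences
#' from `n` trials), so with the exception of a day's first two trials every
#' trial appears in some learn span.
#'
#' @param day_trials list of [bmi_trial]s from one day, in order.
#' @param norm a `norm_spec` from [fit_normalization].
#' @param target `"velocity"` or `"position"`: which normalized kinematic
#'   signal becomes the readout target.
#' @return List of training sequences: each has `counts` (E x T), `targets`
#'   (2 x T, normalized), `seed_end` (last seed bin), `day_index`.
#' @export
build_training_sequences <- function(day_trials, norm,
                                     target = c("velocity", "position")) {
  target <- match.arg(target)
  n <- length(day_trials)
  if (n < 5L) {
    warning("day has fewer than 5 trials; no training sequences built")
    return(list())
  }
  lapply(seq_len(n - 4L), function(i) {
    w <- day_trials[i:(i + 4L)]
    counts <- do.call(cbind, lapply(w, function(tr) tr$spikes$counts))
    kin <- do.call(cbind, lapply(w, function(tr)
      if (target == "velocity") tr$kin$velocity else tr$kin$position))
    tgt <- normalize_kin(kin, norm, target)
    seed_end <- ncol(w[[1L]]$spikes$counts) + ncol(w[[2L]]$spikes$counts)
    list(counts = counts, targets = tgt, seed_end = seed_end,
         day_index = w[[1L]]$day_index)
  })
}

#' Perturb a sequence's spike counts (data augmentation)
#'
#' For electrode `c` with per-sequence total `n`, the perturbed total is
#' `n_hat = round(eta_trial * eta_c * n)` with both gains Gaussian(mean 1,
#' sd `sigma_trial` / `sigma_electrode`). If `n_hat` falls outside
#' `[0, 2n]` the pair of gains is resampled for that electrode, which keeps
#' the expected perturbed total roughly equal to `n`. Surplus spikes are
#' added to uniformly random bins (increments allowed); deficits are removed
#' uniformly from existing spike events. Electrodes with `n = 0` are left
#' unchanged. Uses the current RNG stream.
#'
#' @param counts E x T non-negative integer matrix.
#' @param spec a [perturbation_spec].
#' @return E x T perturbed integer matrix.
#' @export
perturb_counts <- function(counts, spec) {
  counts <- as.matrix(counts)
  E <- nrow(counts); Tn <- ncol(counts)
  eta_trial <- stats::rnorm(1, 1, spec$sigma_trial)
  out <- counts
  for (e in seq_len(E)) {
    n <- sum(counts[e, ])
    if (n == 0L) next
    etaj <- eta_trial
    etac <- stats::rnorm(1, 1, spec$sigma_electrode)
    nhat <- round(etaj * etac * n)
    tries <- 0L
    while (nhat < 0 || nhat > 2 * n) {
      etaj <- stats::rnorm(1, 1, spec$sigma_trial)
      etac <- stats::rnorm(1, 1, spec$sigma_electrode)
      nhat <- round(etaj * etac * n)
      tries <- tries + 1L
      if (tries > 10000L) { nhat <- n; break }
    }
    if (nhat > n) {
      add <- tabulate(sample.int(Tn, nhat - n, replace = TRUE), nbins = Tn)
      out[e, ] <- out[e, ] + add
    } else if (nhat < n) {
      ev <- rep.int(seq_len(Tn), counts[e, ])
      rem <- ev[sample.int(length(ev), n - nhat)]
      out[e, ] <- out[e, ] - tabulate(rem, nbins = Tn)
    }
  }
  storage.mode(out) <- "integer"
  out
}

# ---- batched sequence packing -----------------------------------------

# Pack sequences into one zero-padded batch of cubes with an explicit
# learn mask: mask[m, b, t] is 1 on sequence b's learn-span bins and 0 on
# its seed span and padding.
pack_sequences <- function(seqs) {
  Ts <- vapply(seqs, function(s) ncol(s$counts), integer(1))
  Tmax <- max(Ts); B <- length(seqs)
  E <- nrow(seqs[[1L]]$counts); M <- nrow(seqs[[1L]]$targets)
  U <- array(0, c(E, B, Tmax)); Y <- array(0, c(M, B, Tmax))
  mask <- matrix(0, B, Tmax)
  for (b in seq_len(B)) {
    Tb <- Ts[b]
    U[, b, seq_len(Tb)] <- seqs[[b]]$counts
    Y[, b, seq_len(Tb)] <- seqs[[b]]$targets
    se <- seqs[[b]]$seed_end
    if (se < Tb) mask[b, (se + 1L):Tb] <- 1
  }
  maskc <- aperm(array(mask, c(B, Tmax, M)), c(3L, 1L, 2L))
  list(list(U = U, Y = Y, mask = maskc, T = Tmax, B = B,
            learn_bins = sum(mask)))
}

# Forward pass over packed groups; caches activations for bptt/rop. x0 is
# the shared initial activation for every sequence (zeros if NULL).
forward_groups <- function(params, groups, x0 = NULL) {
  a <- params$dt / params$tau
  N <- params$dims[["N"]]
  if (is.null(x0)) x0 <- rep(0, N)
  lapply(groups, function(g) {
    X0 <- matrix(x0, N, g$B)
    fw <- mrnn_forward_cpp(params$J_xf, params$J_fu, params$J_fx, params$b_x,
                           params$W_o, params$b_z, a, g$U, X0)
    c(g, list(X = fw$X, Z = fw$Z, X0 = X0))
  })
}

total_learn <- function(groups)
  sum(vapply(groups, function(g) g$learn_bins, numeric(1)))

# Masked output-gradient cube: 2 (Z - Y) / (M * total learn bins) on learn
# bins, 0 on seed-span and padding bins.
output_grad <- function(g, denom)
  2 * (g$Z - g$Y) * g$mask / denom

#' Mean squared training error of an MRNN on sequences
#'
#' Error is averaged over learn-span bins, output dimensions and sequences;
#' seed-span bins drive the state but contribute no error.
#'
#' @param params an [mrnn_params].
#' @param seqs list of sequences from [build_training_sequences].
#' @param x0 optional shared initial activation (default zeros).
#' @return Scalar mean squared error.
#' @export
mrnn_loss <- function(params, seqs, x0 = NULL) {
  if (!length(seqs)) stop("empty batch")
  fg <- forward_groups(params, pack_sequences(seqs), x0)
  M <- params$dims[["M"]]
  sse <- sum(vapply(fg, function(g) sum(((g$Z - g$Y) * g$mask)^2),
                    numeric(1)))
  sse / (M * total_learn(fg))
}

#' Exact loss gradient by backpropagation through time
#'
#' @inheritParams mrnn_loss
#' @return Flat gradient vector over `{J_xf, J_fu, J_fx, b_x, W_o, b_z}` (in
#'   that order, column-major), with the loss as attribute `"loss"`.
#' @export
mrnn_gradient <- function(params, seqs, x0 = NULL) {
  if (!length(seqs)) stop("empty batch")
  fg <- forward_groups(params, pack_sequences(seqs), x0)
  grad_from_cache(params, fg)
}

grad_from_cache <- function(params, fg) {
  a <- params$dt / params$tau
  M <- params$dims[["M"]]
  denom <- M * total_learn(fg)
  acc <- NULL; sse <- 0
  for (g in fg) {
    sse <- sse + sum(((g$Z - g$Y) * g$mask)^2)
    gr <- mrnn_bptt_cpp(params$J_xf, params$J_fu, params$J_fx, params$b_x,
                        params$W_o, params$b_z, a, g$U, g$X0,
                        g$X, output_grad(g, denom))
    v <- c(as.numeric(gr$J_xf), as.numeric(gr$J_fu), as.numeric(gr$J_fx),
           gr$b_x, as.numeric(gr$W_o), gr$b_z)
    acc <- if (is.null(acc)) v else acc + v
  }
  structure(acc, loss = sse / denom)
}

#' Damped Gauss-Newton matrix-vector product
#'
#' Computes `(G + lambda I) v` where `G` is the Gauss-Newton curvature of
#' the squared-error loss, via a forward directional pass through the
#' network followed by backpropagation -- no explicit Hessian is formed.
#'
#' @param params an [mrnn_params].
#' @param seqs sequences (or a cached forward from the internal API).
#' @param v flat parameter vector (length [count_mrnn_params]).
#' @param lambda damping (>= 0).
#' @return Flat vector `(G + lambda I) v`.
#' @export
mrnn_gn_product <- function(params, seqs, v, lambda = 0, x0 = NULL) {
  fg <- if (!is.null(attr(seqs, "is_cache"))) seqs
        else forward_groups(params, pack_sequences(seqs), x0)
  gn_product_cached(params, fg, v, lambda)
}

forward_cache <- function(params, seqs, x0 = NULL) {
  fg <- forward_groups(params, pack_sequences(seqs), x0)
  attr(fg, "is_cache") <- TRUE
  fg
}

gn_product_cached <- function(params, fg, v, lambda) {
  a <- params$dt / params$tau
  dp <- unflatten_params(v, params)
  M <- params$dims[["M"]]
  denom <- M * total_learn(fg)
  acc <- NULL
  for (g in fg) {
    dZ <- mrnn_rop_cpp(params$J_xf, params$J_fu, params$J_fx, params$b_x,
                       params$W_o, params$b_z, a, g$U, g$X0, g$X,
                       dp$J_xf, dp$J_fu, dp$J_fx, dp$b_x, dp$W_o, dp$b_z)
    dZ <- dZ * g$mask * (2 / denom)
    gr <- mrnn_bptt_cpp(params$J_xf, params$J_fu, params$J_fx, params$b_x,
                        params$W_o, params$b_z, a, g$U, g$X0, g$X, dZ)
    w <- c(as.numeric(gr$J_xf), as.numeric(gr$J_fu), as.numeric(gr$J_fx),
           gr$b_x, as.numeric(gr$W_o), gr$b_z)
    acc <- if (is.null(acc)) w else acc + w
  }
  acc + lambda * v
}

# Conjugate gradient on (G + lambda I) delta = -grad, starting from 0.
cg_solve <- function(Aprod, b, max_iters, tol) {
  x <- numeric(length(b))
  r <- b                      # residual b - A x with x = 0
  p <- r
  rs <- sum(r^2)
  b_norm <- sqrt(rs)
  iters <- 0L
  for (i in seq_len(max_iters)) {
    Ap <- Aprod(p)
    alpha <- rs / sum(p * Ap)
    if (!is.finite(alpha) || alpha <= 0) break  # lost positive definiteness
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r^2)
    iters <- i
    if (sqrt(rs_new) <= tol * b_norm) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  list(x = x, iters = iters)
}

# ---- the HF loop -------------------------------------------------------

split_heldout <- function(day_seqs, frac) {
  train <- list(); held <- list()
  for (d in seq_along(day_seqs)) {
    ss <- day_seqs[[d]]
    nh <- floor(frac * length(ss))
    if (nh > 0) {
      keep <- seq_len(length(ss) - nh)
      train[[d]] <- ss[keep]
      held <- c(held, ss[-keep])
    } else train[[d]] <- ss
  }
  list(train = train, held = held)
}

#' Train an MRNN with Hessian-free optimization
#'
#' Per step: the spike counts of a freshly sampled minibatch (containing
#' sequences from every training day) are re-perturbed, the gradient is
#' computed by backpropagation through time, a damped Gauss-Newton system is
#' solved by conjugate gradient, and the damping is adapted by the
#' Levenberg-Marquardt reduction ratio. Snapshots are scored on held-out
#' sequences with unperturbed counts; the best snapshot is returned.
#'
#' @param corpus a [session_corpus].
#' @param config an [hf_config].
#' @param perturb a [perturbation_spec]; use sigmas 0 to disable
#'   augmentation.
#' @param target `"velocity"` or `"position"`.
#' @param N,F network and factor dimensions (`F = N` by default).
#' @param tau time constant, ms.
#' @param b_x_sd sd of the random state-bias initialization (see
#'   [init_mrnn]; 0 would leave training stuck at the zero-state saddle).
#' @param days optional integer vector of day indices to train on (default
#'   all days in the corpus).
#' @param init_params optional [mrnn_params] to warm-start from (e.g. an
#'   existing decoder's weights when retraining with added data).
#' @param norm optional `norm_spec`; fitted on the training days if `NULL`.
#' @return List with `params` (best snapshot), `norm`, `snapshots`
#'   (data.frame step/heldout loss), `history` (per-step data.frame), and
#'   `heldout_loss` of the returned snapshot.
#' @export
hf_train <- function(corpus, config = hf_config(),
                     perturb = perturbation_spec(),
                     target = c("velocity", "position"),
                     N = 50, F = N, tau = 100, b_x_sd = 0.1,
                     days = NULL, init_params = NULL, norm = NULL) {
  target <- match.arg(target)
  sel <- if (is.null(days)) seq_along(corpus$days)
         else match(days, corpus$day_indices)
  if (anyNA(sel)) stop("requested training days not present in corpus")
  day_trials <- corpus$days[sel]
  sub <- session_corpus(day_trials)
  if (is.null(norm)) norm <- fit_normalization(sub)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  day_seqs <- lapply(day_trials, build_training_sequences, norm = norm,
                     target = target)
  day_seqs <- day_seqs[vapply(day_seqs, length, integer(1)) > 0]
  if (!length(day_seqs)) stop("corpus yields no training sequences")
  sp <- split_heldout(day_seqs, config$heldout_fraction)
  train_days <- sp$train
  held <- sp$held

  E <- corpus_n_electrodes(corpus)
  dt <- corpus_bin_width(corpus)
  # b_x_sd > 0 breaks the zero-state saddle of the fresh network (see
  # init_mrnn); sequences themselves start from a zero hidden state, which
  # the two seeding trials wash out.
  params <- if (is.null(init_params))
    init_mrnn(N, F, E, M = 2L, tau = tau, dt = dt, b_x_sd = b_x_sd,
              seed = config$seed)
  else init_params
  x0 <- NULL

  heldout_loss <- function(p)
    if (length(held)) mrnn_loss(p, held, x0)
    else mrnn_loss(p, unlist(train_days, recursive = FALSE), x0)

  lambda <- config$initial_lambda
  snapshots <- data.frame(step = 0L, heldout = heldout_loss(params))
  best <- list(step = 0L, loss = snapshots$heldout[1L],
               theta = flatten_params(params))
  hist <- vector("list", config$total_steps)

  for (step in seq_len(config$total_steps)) {
    mb <- unlist(lapply(train_days, function(ss) {
      m <- max(1L, round(config$minibatch_fraction * length(ss)))
      ss[sample.int(length(ss), m)]
    }), recursive = FALSE)
    if (perturb$sigma_trial > 0 || perturb$sigma_electrode > 0)
      mb <- lapply(mb, function(s) {
        s$counts <- perturb_counts(s$counts, perturb)
        s
      })

    fg <- forward_cache(params, mb, x0)
    g <- grad_from_cache(params, fg)
    f0 <- attr(g, "loss")
    if (!is.finite(f0))
      stop("HF training diverged at step ", step, " (non-finite loss)")
    fg_curv <- if (config$curvature_fraction < 1) {
      nc <- max(1L, ceiling(config$curvature_fraction * length(mb)))
      forward_cache(params, mb[sample.int(length(mb), nc)], x0)
    } else fg
    cg <- cg_solve(function(p) gn_product_cached(params, fg_curv, p, lambda),
                   -as.numeric(g), config$max_cg_iters, config$cg_tol)
    delta <- cg$x
    cand <- unflatten_params(flatten_params(params) + delta, params)
    f1 <- mrnn_loss(cand, mb, x0)
    pred <- sum(g * delta) +
      0.5 * sum(delta * gn_product_cached(params, fg_curv, delta, lambda))
    rho <- if (is.finite(f1) && pred < 0) (f1 - f0) / pred else -Inf
    accepted <- is.finite(f1) && f1 < f0
    if (accepted) params <- cand
    if (rho > 0.75) lambda <- lambda / 1.5
    else if (rho < 0.25) lambda <- lambda * 1.5
    hist[[step]] <- data.frame(step = step, loss = f0, new_loss = f1,
                               lambda = lambda, cg_iters = cg$iters,
                               accepted = accepted)

    if (step %% config$snapshot_interval == 0L ||
        step == config$total_steps) {
      hl <- heldout_loss(params)
      snapshots <- rbind(snapshots, data.frame(step = step, heldout = hl))
      if (hl < best$loss)
        best <- list(step = step, loss = hl, theta = flatten_params(params))
    }
  }

  list(params = unflatten_params(best$theta, params), norm = norm, x0 = x0,
       snapshots = snapshots, history = do.call(rbind, hist),
       heldout_loss = best$loss, best_step = best$step, target = target)
}
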