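# Feedback-intention-trained Kalman filter (FIT-KF) baseline.
#
# Linear dynamical system over the kinematic state z = [px, py, vx, vy, 1]
# (cm, cm/s, constant bias):
#   z(t+dt) = A z(t) + w,  y(t) = C z(t) + q,  w ~ N(0, W), q ~ N(0, Q).
# Fitting rotates training velocities toward the target (the user is assumed
# to always intend to move straight at it) and decoding applies the
# position-feedback assumptions: decoded position is treated as known
# (pinned, zero covariance) and its neural contribution is subtracted from
# the observed counts before the velocity update.

KF_POS <- 1:2; KF_VEL <- 3:4; KF_BIAS <- 5L

#' Rotate training kinematics toward the target
#'
#' Each velocity vector keeps its magnitude but is re-aimed from the current
#' cursor position straight at the target; inside the target acceptance
#' window the intended velocity is zero. Positions are unchanged.
#'
#' @param kin a [kinematics] object.
#' @param cursor_pos 2 x T cursor (or hand) positions, cm.
#' @param target_pos 2 x T (or length-2) target positions, cm.
#' @param window acceptance window edge lengths, cm (default 4 x 4).
#' @return A [kinematics] object with rotated velocities.
#' @export
rotate_intention <- function(kin, cursor_pos, target_pos,
                             window = c(4, 4)) {
  Tn <- ncol(kin$velocity)
  if (length(target_pos) == 2L) target_pos <- matrix(target_pos, 2, Tn)
  if (ncol(cursor_pos) != Tn || ncol(target_pos) != Tn)
    stop("cursor/target trajectories must match the kinematic timebase")
  err <- target_pos - cursor_pos
  inside <- abs(err[1L, ]) <= window[1L] / 2 & abs(err[2L, ]) <= window[2L] / 2
  speed <- sqrt(colSums(kin$velocity^2))
  dist <- sqrt(colSums(err^2))
  v <- matrix(0, 2, Tn)
  ok <- !inside & dist > 0
  v[, ok] <- err[, ok] * rep(speed[ok] / dist[ok], each = 2L)
  kinematics(kin$position, v, kin$bin_width)
}

#' Fit the FIT-KF from reach training data
#'
#' Maximum-likelihood fitting of the linear dynamical system on
#' intention-rotated kinematics. Position rows of `A` are fixed to kinematic
#' integration (`p <- p + v dt`); the velocity block and its noise are least
#' squares on consecutive state pairs; `C` and `Q` come from regressing
#' counts on states (`Q` symmetrized with a small diagonal load for
#' invertibility).
#'
#' @param corpus a [session_corpus] of hand-control reaches.
#' @param days optional day indices to pool (default: all).
#' @param window target acceptance window for intention rotation, cm.
#' @return An object of class `fitkf` with methods `print`, `coef`,
#'   `predict`.
#' @export
train_fitkf <- function(corpus, days = NULL, window = c(4, 4)) {
  sel <- if (is.null(days)) seq_along(corpus$days)
         else match(days, corpus$day_indices)
  if (anyNA(sel)) stop("requested days not present in corpus")
  trials <- unlist(corpus$days[sel], recursive = FALSE)
  dt <- trials[[1L]]$spikes$bin_width
  dt_s <- dt / 1000

  Zs <- list(); Ys <- list(); Z0 <- list(); Z1 <- list()
  for (tr in trials) {
    rot <- rotate_intention(tr$kin, tr$kin$position, tr$target_position,
                            window)
    Tn <- ncol(rot$velocity)
    z <- rbind(rot$position, rot$velocity, rep(1, Tn))
    Zs[[length(Zs) + 1L]] <- z
    Ys[[length(Ys) + 1L]] <- tr$spikes$counts
    if (Tn >= 2L) {
      Z0[[length(Z0) + 1L]] <- z[, -Tn, drop = FALSE]
      Z1[[length(Z1) + 1L]] <- z[, -1L, drop = FALSE]
    }
  }
  Z <- do.call(cbind, Zs); Y <- do.call(cbind, Ys)
  if (ncol(Z) < 2L) stop("need at least 2 bins of training data")
  Zp <- do.call(cbind, Z0); Zn <- do.call(cbind, Z1)

  # velocity dynamics: v(t+1) ~ [v(t), 1]
  Xv <- rbind(Zp[KF_VEL, , drop = FALSE], 1)
  G <- Xv %*% t(Xv)
  if (rcond(G) < 1e-12)
    stop("rank-deficient velocity regressors; cannot fit A")
  Av <- (Zn[KF_VEL, , drop = FALSE] %*% t(Xv)) %*% solve(G)
  A <- diag(5)
  A[KF_POS, KF_VEL] <- diag(2) * dt_s
  A[KF_VEL, KF_VEL] <- Av[, 1:2]
  A[KF_VEL, KF_BIAS] <- Av[, 3L]
  vres <- Zn[KF_VEL, , drop = FALSE] - Av %*% Xv
  W <- matrix(0, 5, 5)
  W[KF_VEL, KF_VEL] <- (vres %*% t(vres)) / ncol(vres)

  # observation model: y ~ z
  Gz <- Z %*% t(Z)
  if (rcond(Gz) < 1e-12)
    stop("rank-deficient state regressors; cannot fit C")
  C <- (Y %*% t(Z)) %*% solve(Gz)
  yres <- Y - C %*% Z
  Q <- (yres %*% t(yres)) / ncol(yres)
  Q <- (Q + t(Q)) / 2 + diag(1e-6, nrow(Q))

  structure(list(A = A, C = C, W = W, Q = Q, dt = dt,
                 state = c("px", "py", "vx", "vy", "bias"),
                 E = nrow(C), window = window,
                 days = corpus$day_indices[sel]),
            class = "fitkf")
}

#' @export
print.fitkf <- function(x, ...) {
  cat(sprintf("FIT-KF decoder: %d electrodes, dt = %g ms, trained on day(s) %s\n",
              x$E, x$dt, paste(x$days, collapse = ", ")))
  cat("velocity dynamics block:\n")
  print(round(x$A[KF_VEL, KF_VEL], 3))
  invisible(x)
}

#' @export
coef.fitkf <- function(object, ...)
  object[c("A", "C", "W", "Q")]

#' Fresh FIT-KF decoding state
#' @param params a `fitkf` object.
#' @param cursor_pos initial cursor position (default origin).
#' @return List with `mean` (5-vector) and `cov` (5 x 5).
#' @export
kf_state <- function(params, cursor_pos = c(0, 0)) {
  m <- c(cursor_pos, 0, 0, 1)
  list(mean = m, cov = matrix(0, 5, 5))
}

#' One FIT-KF predict/update step
#'
#' Standard Kalman recursion with the two position-feedback modifications
#' applied every step: the position (and bias) entries are pinned to the
#' known cursor position with exactly zero covariance, and the observation
#' residual `y - C z_pred` subtracts the neural activity explained by that
#' known position before the velocity update.
#'
#' @param params a `fitkf` object.
#' @param state a state from [kf_state] or a previous step.
#' @param y length-E spike-count observation for the bin.
#' @param cursor_pos known (drawn) cursor position, cm.
#' @return Updated state.
#' @export
kf_decode_step <- function(params, state, y, cursor_pos) {
  fixed <- c(KF_POS, KF_BIAS)
  m <- params$A %*% state$mean
  P <- params$A %*% state$cov %*% t(params$A) + params$W
  m[KF_POS] <- cursor_pos; m[KF_BIAS] <- 1
  P[fixed, ] <- 0; P[, fixed] <- 0

  resid <- as.numeric(y) - drop(params$C %*% m)
  S <- params$C %*% P %*% t(params$C) + params$Q
  K <- t(solve(S, params$C %*% P))       # 5 x E
  m <- drop(m + K %*% resid)
  P <- (diag(5) - K %*% params$C) %*% P
  P <- (P + t(P)) / 2
  m[KF_POS] <- cursor_pos; m[KF_BIAS] <- 1
  P[fixed, ] <- 0; P[, fixed] <- 0
  if (any(diag(P) < -1e-8))
    stop("FIT-KF covariance lost positive semidefiniteness")
  diag(P) <- pmax(diag(P), 0)
  list(mean = m, cov = P)
}

#' Decode a spike-count sequence with the FIT-KF
#'
#' In offline mode (`cursor_pos` a 2 x T matrix, e.g. true hand positions)
#' the known-position feedback comes from that trajectory. If `cursor_pos`
#' is `NULL` the decoder integrates its own decoded velocity, as in closed
#' loop.
#'
#' @param object a `fitkf`.
#' @param counts a [binned_counts] or E x T matrix.
#' @param cursor_pos optional 2 x T matrix of known cursor positions.
#' @param ... unused.
#' @return A [kinematics] object: decoded velocity and the position
#'   trajectory used/produced.
#' @export
predict.fitkf <- function(object, counts, cursor_pos = NULL, ...) {
  U <- if (inherits(counts, "binned_counts")) {
    if (counts$bin_width != object$dt)
      stop("counts bin width does not match FIT-KF dt")
    counts$counts
  } else as.matrix(counts)
  Tn <- ncol(U)
  vel <- matrix(0, 2, Tn); pos <- matrix(0, 2, Tn)
  if (Tn == 0L) return(kinematics(pos, vel, object$dt))
  closed <- is.null(cursor_pos)
  cur <- if (closed) c(0, 0) else cursor_pos[, 1L]
  st <- kf_state(object, cur)
  dt_s <- object$dt / 1000
  for (t in seq_len(Tn)) {
    if (!closed) cur <- cursor_pos[, t]
    st <- kf_decode_step(object, st, U[, t], cur)
    vel[, t] <- st$mean[KF_VEL]
    if (closed) cur <- cur + vel[, t] * dt_s
    pos[, t] <- cur
  }
  kinematics(pos, vel, object$dt)
}

#' @export
decoder_payload.fitkf <- function(object)
  list(A = object$A, C = object$C, W = object$W, Q = object$Q,
       dt = object$dt, window = object$window, days = object$days)

unpayload_fitkf <- function(pl)
  structure(list(A = as.matrix(pl$A), C = as.matrix(pl$C),
                 W = as.matrix(pl$W), Q = as.matrix(pl$Q), dt = pl$dt,
                 state = c("px", "py", "vx", "vy", "bias"),
                 E = nrow(as.matrix(pl$C)), window = pl$window,
                 days = pl$days),
            class = "fitkf")
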