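# Multiplicative RNN core.
#
# State x (N), rates r = tanh(x). The effective recurrent weight matrix is
# re-parameterized every bin by the spike-count input u through a factorized
# tensor: J^u r = J_xf ((J_fu u) * (J_fx r)), elementwise product over the F
# factors, so the N x N x |u| tensor is never materialized. Discretized with
# a first-order Euler leak alpha = dt / tau:
#   x <- (1 - alpha) x + alpha (J^u r + b_x),   r <- tanh x,
#   z  = W_o r + b_z.

#' MRNN parameter container
#'
#' @param J_xf N x F factor-to-state matrix.
#' @param J_fu F x E input-to-factor matrix.
#' @param J_fx F x N state-to-factor matrix.
#' @param b_x length-N state bias.
#' @param W_o M x N readout matrix.
#' @param b_z length-M readout bias.
#' @param tau network time constant, ms.
#' @param dt input bin width, ms (0 < dt <= tau).
#' @return An `mrnn_params` object.
#' @export
mrnn_params <- function(J_xf, J_fu, J_fx, b_x, W_o, b_z, tau, dt) {
  N <- nrow(J_xf); F <- ncol(J_xf); E <- ncol(J_fu); M <- nrow(W_o)
  if (nrow(J_fu) != F || nrow(J_fx) != F || ncol(J_fx) != N ||
      length(b_x) != N || ncol(W_o) != N || length(b_z) != M)
    stop("inconsistent MRNN parameter shapes")
  if (!all(is.finite(J_xf)) || !all(is.finite(J_fu)) ||
      !all(is.finite(J_fx)) || !all(is.finite(b_x)) ||
      !all(is.finite(W_o)) || !all(is.finite(b_z)))
    stop("MRNN parameters must be finite")
  if (dt <= 0 || dt > tau)
    stop("need 0 < dt <= tau (dt = ", dt, ", tau = ", tau, ")")
  structure(list(J_xf = J_xf, J_fu = J_fu, J_fx = J_fx,
                 b_x = as.numeric(b_x), W_o = W_o, b_z = as.numeric(b_z),
                 tau = tau, dt = dt,
                 dims = c(N = N, F = F, E = E, M = M)),
            class = "mrnn_params")
}

#' @export
print.mrnn_params <- function(x, ...) {
  d <- x$dims
  cat(sprintf("<mrnn_params> N=%d F=%d E=%d M=%d, tau=%g ms, dt=%g ms, %d parameters\n",
              d["N"], d["F"], d["E"], d["M"], x$tau, x$dt,
              count_mrnn_params(d["N"], d["F"], d["E"], d["M"])))
  invisible(x)
}

#' Number of trainable MRNN parameters
#'
#' Sum of the element counts of the trained set
#' `{J_xf, J_fu, J_fx, b_x, W_o, b_z}`:
#' `N*F + F*E + F*N + N + M*N + M`.
#'
#' @param N,F,E,M network, factor, input and output dimensions.
#' @return Integer parameter count.
#' @export
count_mrnn_params <- function(N, F, E, M) {
  stopifnot(N >= 1, F >= 1, E >= 1, M >= 1)
  as.integer(N * F + F * E + F * N + N + M * N + M)
}

#' Initialize an MRNN
#'
#' Factor matrices are drawn iid Gaussian with zero mean and variances
#' `g_xf/F`, `g_fu/E`, `g_fx/N`; the readout `W_o` and both biases start at
#' zero, so a fresh network outputs exactly zero.
#'
#' With every bias at zero the all-zero state is an exact fixed point of the
#' multiplicative recurrence (the input only enters through `diag(J_fu u)`
#' acting on the rates) and an exact saddle of the training loss, so
#' training started there cannot move any parameter except the readout
#' bias. Setting `b_x_sd > 0` draws a small random state bias that breaks
#' this degeneracy; [hf_train] does so by default.
#'
#' @param N,F,E,M dimensions (all >= 1). `F = N` is the conventional choice.
#' @param tau time constant, ms.
#' @param dt bin width, ms.
#' @param g_xf,g_fu,g_fx variance scale factors (default 1.0).
#' @param b_x_sd sd of the state-bias initialization (default 0: exact
#'   zero bias).
#' @param seed integer seed; initialization is deterministic given it.
#' @return An [mrnn_params] object.
#' @export
init_mrnn <- function(N, F = N, E, M = 2, tau = 100, dt = 20,
                      g_xf = 1, g_fu = 1, g_fx = 1, b_x_sd = 0, seed = 1) {
  stopifnot(N >= 1, F >= 1, E >= 1, M >= 1, g_xf >= 0, g_fu >= 0, g_fx >= 0)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  mrnn_params(
    J_xf = matrix(stats::rnorm(N * F, 0, sqrt(g_xf / F)), N, F),
    J_fu = matrix(stats::rnorm(F * E, 0, sqrt(g_fu / E)), F, E),
    J_fx = matrix(stats::rnorm(F * N, 0, sqrt(g_fx / N)), F, N),
    b_x = if (b_x_sd > 0) stats::rnorm(N, 0, b_x_sd) else rep(0, N),
    W_o = matrix(0, M, N),
    b_z = rep(0, M),
    tau = tau, dt = dt)
}

#' Input-dependent recurrence
#'
#' Applies the input-parameterized recurrent weights to a rate vector:
#' `J^u r = J_xf ((J_fu u) * (J_fx r))`, equivalent to
#' `J_xf diag(J_fu u) J_fx r` without forming the tensor.
#'
#' @param params an [mrnn_params].
#' @param u length-E input (spike counts for the bin).
#' @param r length-N rate vector.
#' @return Length-N vector.
#' @export
mrnn_recurrence <- function(params, u, r) {
  if (length(u) != params$dims["E"] || length(r) != params$dims["N"])
    stop("shape mismatch in mrnn_recurrence")
  drop(params$J_xf %*% (drop(params$J_fu %*% u) * drop(params$J_fx %*% r)))
}

#' One Euler step of the MRNN
#'
#' @param params an [mrnn_params].
#' @param state list with elements `x` (length N) and the rates `tanh(x)`; see
#'   [mrnn_state()].
#' @param u length-E spike-count input for this bin.
#' @return The updated state.
#' @export
mrnn_step <- function(params, state, u) {
  a <- params$dt / params$tau
  x <- (1 - a) * state$x +
    a * (mrnn_recurrence(params, u, state$r) + params$b_x)
  list(x = x, r = tanh(x))
}

#' Fresh MRNN state
#' @param params an [mrnn_params].
#' @param x optional initial activation (default all zero).
#' @return A state list with `x` and rates `r` (`tanh` of `x`).
#' @export
mrnn_state <- function(params, x = NULL) {
  if (is.null(x)) x <- rep(0, params$dims["N"])
  list(x = x, r = tanh(x))
}

#' Linear readout
#' @param params an [mrnn_params].
#' @param state an MRNN state.
#' @return Length-M output `z = W_o r + b_z`.
#' @export
mrnn_readout <- function(params, state)
  drop(params$W_o %*% state$r) + params$b_z

#' Run the MRNN over a spike-count sequence
#'
#' Applies [mrnn_step] then [mrnn_readout] per bin. Deterministic; state
#' persists only within the call (pass `x0` to chain runs).
#'
#' @param params an [mrnn_params].
#' @param counts a [binned_counts] object or plain E x T count matrix.
#' @param x0 optional initial activation vector.
#' @return List with `Z` (M x T outputs), `X` (N x T activations) and
#'   `x_final` (length-N final activation).
#' @export
mrnn_run <- function(params, counts, x0 = NULL) {
  U <- if (inherits(counts, "binned_counts")) counts$counts else as.matrix(counts)
  if (inherits(counts, "binned_counts") && counts$bin_width != params$dt)
    stop("counts bin width (", counts$bin_width,
         " ms) does not match network dt (", params$dt, " ms)")
  if (nrow(U) != params$dims["E"]) stop("input has wrong electrode count")
  Tn <- ncol(U)
  M <- params$dims["M"]; N <- params$dims["N"]
  if (Tn == 0L)
    return(list(Z = matrix(0, M, 0), X = matrix(0, N, 0),
                x_final = if (is.null(x0)) rep(0, N) else x0))
  fw <- mrnn_forward_cpp(params$J_xf, params$J_fu, params$J_fx, params$b_x,
                         params$W_o, params$b_z, params$dt / params$tau,
                         array(U, c(nrow(U), 1L, Tn)),
                         matrix(if (is.null(x0)) rep(0, N) else x0, N, 1L))
  list(Z = matrix(fw$Z, M, Tn), X = matrix(fw$X, N, Tn),
       x_final = fw$X[, 1L, Tn])
}

# Flatten / unflatten the trained parameter set in a fixed order.
flatten_params <- function(p)
  c(as.numeric(p$J_xf), as.numeric(p$J_fu), as.numeric(p$J_fx),
    p$b_x, as.numeric(p$W_o), p$b_z)

unflatten_params <- function(theta, template) {
  d <- template$dims
  N <- d[["N"]]; F <- d[["F"]]; E <- d[["E"]]; M <- d[["M"]]
  sizes <- c(N * F, F * E, F * N, N, M * N, M)
  stopifnot(length(theta) == sum(sizes))
  off <- cumsum(c(0, sizes))
  take <- function(i) theta[(off[i] + 1):off[i + 1]]
  mrnn_params(
    J_xf = matrix(take(1), N, F), J_fu = matrix(take(2), F, E),
    J_fx = matrix(take(3), F, N), b_x = take(4),
    W_o = matrix(take(5), M, N), b_z = take(6),
    tau = template$tau, dt = template$dt)
}
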