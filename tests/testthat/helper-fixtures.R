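# Shared fixtures and independent reference implementations used as oracles.

# Small deterministic corpus for structural tests.
tiny_corpus <- function(n_days = 2, trials_per_day = 12, E = 8, seed = 42,
                        drift = drift_process()) {
  generate_corpus(n_days = n_days, trials_per_day = trials_per_day, E = E,
                  drift = drift, seed = seed)
}

# Hand-built trial with prescribed kinematics and counts.
manual_trial <- function(counts, position, bin_width = 20,
                         target = c(8, 0), start = c(0, 0),
                         day_index = 1L, trial_index = 1L) {
  kin <- kinematics(position, compute_velocity(position, bin_width),
                    bin_width)
  bmi_trial(binned_counts(counts, bin_width), kin, target, start,
            day_index, trial_index)
}

# Reference MRNN forward pass written independently in plain R (scalar
# loops), used to cross-check the compiled batched pass.
ref_mrnn_run <- function(params, U, x0 = NULL) {
  N <- params$dims[["N"]]; M <- params$dims[["M"]]
  a <- params$dt / params$tau
  x <- if (is.null(x0)) rep(0, N) else x0
  Tn <- ncol(U)
  Z <- matrix(0, M, Tn); X <- matrix(0, N, Tn)
  for (t in seq_len(Tn)) {
    r <- tanh(x)
    f <- as.numeric(params$J_fu %*% U[, t]) * as.numeric(params$J_fx %*% r)
    x <- (1 - a) * x + a * (as.numeric(params$J_xf %*% f) + params$b_x)
    X[, t] <- x
    Z[, t] <- as.numeric(params$W_o %*% tanh(x)) + params$b_z
  }
  list(Z = Z, X = X)
}

# Central-finite-difference gradient of mrnn_loss over the flat parameter
# vector; the independent oracle for backpropagation through time.
fd_gradient <- function(params, seqs, h = 1e-6) {
  th <- robustbmi:::flatten_params(params)
  vapply(seq_along(th), function(i) {
    tp <- th; tp[i] <- th[i] + h
    tm <- th; tm[i] <- th[i] - h
    (mrnn_loss(robustbmi:::unflatten_params(tp, params), seqs) -
       mrnn_loss(robustbmi:::unflatten_params(tm, params), seqs)) / (2 * h)
  }, numeric(1))
}

# Tiny random training sequences (well away from the zero-state saddle).
random_seqs <- function(n_seq, E, Tn, seed_end, params_seed = 1) {
  lapply(seq_len(n_seq), function(i) {
    list(counts = matrix(rpois(E * Tn, 2), E, Tn),
         targets = matrix(rnorm(2 * Tn, 0, 0.5), 2, Tn),
         seed_end = seed_end, day_index = 1L)
  })
}

# Random small MRNN with non-degenerate readout and biases.
random_mrnn <- function(N = 4, F = 4, E = 3, seed = 3) {
  p <- init_mrnn(N, F, E, M = 2, tau = 100, dt = 20, seed = seed)
  set.seed(seed + 100)
  p$W_o <- matrix(rnorm(2 * N, 0, 0.3), 2, N)
  p$b_z <- rnorm(2, 0, 0.1)
  p$b_x <- rnorm(N, 0, 0.2)
  p
}

# Brute-force linear-Gaussian posterior: condition z ~ N(m, P) on
# y = C z + q, q ~ N(0, Q). The oracle for the Kalman update.
gaussian_posterior <- function(m, P, C, Q, y) {
  S <- C %*% P %*% t(C) + Q
  K <- P %*% t(C) %*% solve(S)
  list(mean = as.numeric(m + K %*% (y - C %*% m)),
       cov = P - K %*% C %*% P)
}

# Brute-force mutual information by direct double sum over the joint table.
ref_mutual_information <- function(tab) {
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  s
}
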