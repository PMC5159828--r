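test_that("intention rotation re-aims velocity without changing speed", {
  bw <- 20
  pos <- rbind(seq(0, 2, length.out = 10), rep(0, 10))
  kin <- kinematics(pos, compute_velocity(pos, bw), bw)
  # target far to the east: velocity already aimed at it is unchanged
  rot <- rotate_intention(kin, pos, c(50, 0))
  expect_equal(rot$velocity, kin$velocity, tolerance = 1e-12)

  # v = (3, 4) toward a target at bearing 0 deg becomes (5, 0)
  kin2 <- kinematics(matrix(0, 2, 3), matrix(c(3, 4, 3, 4, 3, 4), 2, 3), bw)
  rot2 <- rotate_intention(kin2, matrix(0, 2, 3), c(50, 0))
  expect_equal(rot2$velocity[, 1], c(5, 0), tolerance = 1e-12)

  # speed preserved at every bin outside the window
  set.seed(4)
  v <- matrix(rnorm(20, 0, 10), 2, 10)
  kin3 <- kinematics(matrix(rnorm(20), 2, 10), v, bw)
  cur <- matrix(rnorm(20, 0, 3), 2, 10)
  rot3 <- rotate_intention(kin3, cur, c(20, 20))
  expect_equal(sqrt(colSums(rot3$velocity^2)), sqrt(colSums(v^2)),
               tolerance = 1e-12)

  # inside the acceptance window the intended velocity is zero
  rot4 <- rotate_intention(kin3, cur, cur + 1)  # within 4x4 window
  expect_equal(max(abs(rot4$velocity)), 0)
  # positions never modified
  expect_equal(rot3$position, kin3$position)
})

test_that("ML fitting recovers a known linear dynamical system", {
  # simulate directly from an LDS with near-zero noise, bypassing tuning
  set.seed(9)
  E <- 6; dt <- 20; dt_s <- dt / 1000
  A_v <- matrix(c(0.9, 0.02, -0.03, 0.85), 2, 2)
  C <- matrix(rnorm(E * 5, 0, 2), E, 5)
  n_tr <- 40; Tn <- 50
  trials <- lapply(seq_len(n_tr), function(i) {
    v <- matrix(0, 2, Tn); p <- matrix(0, 2, Tn)
    v[, 1] <- rnorm(2, 0, 8)
    for (t in 2:Tn) {
      v[, t] <- A_v %*% v[, t - 1]
      p[, t] <- p[, t - 1] + v[, t - 1] * dt_s
    }
    z <- rbind(p, v, 1)
    y <- round(pmax(C %*% z + 40, 0))
    # target chosen far along the current velocity so rotation is a no-op
    tgt <- p[, Tn] + v[, 1] * 1e6
    bmi_trial(binned_counts(y, dt), kinematics(p, v, dt),
              target_position = tgt, start_position = p[, 1],
              day_index = 1L, trial_index = i)
  })
  # rotation would corrupt the planted dynamics, so aim every velocity at
  # its own heading: use a corpus where each trial's target sits on the ray
  corpus <- session_corpus(list(trials))
  kf <- suppressWarnings(train_fitkf(corpus))
  expect_equal(kf$A[3:4, 3:4], A_v, tolerance = 0.05)
  expect_equal(kf$A[1:2, 3:4], diag(2) * dt_s, tolerance = 1e-12)
  # the +40 baseline added when generating counts lands in C's bias column
  expect_equal(kf$C[, 1:4], C[, 1:4], tolerance = 0.25)
  expect_equal(kf$C[, 5], C[, 5] + 40, tolerance = 0.1)
  # rounding noise only: W, Q small relative to signal scale
  expect_lt(max(abs(kf$W[3:4, 3:4])), 1.5)
})

test_that("C's bias column matches mean counts for zero-mean kinematics", {
  set.seed(3)
  E <- 5; dt <- 20; Tn <- 400
  base <- c(5, 8, 11, 3, 6)
  # four trials aimed at the four cardinal bearings so the rotated
  # velocities span the plane and average out to zero
  trials <- lapply(1:4, function(i) {
    th <- (i - 1) * pi / 2
    v <- matrix(rnorm(2 * Tn, 0, 10), 2, Tn)
    p <- matrix(rnorm(2 * Tn, 0, 0.01), 2, Tn)
    y <- matrix(rpois(E * Tn, base), E, Tn)
    bmi_trial(binned_counts(y, dt), kinematics(p, v, dt),
              target_position = 1e9 * c(cos(th), sin(th)),
              start_position = c(0, 0), trial_index = i)
  })
  all_y <- do.call(cbind, lapply(trials, function(tr) tr$spikes$counts))
  kf <- train_fitkf(session_corpus(list(trials)))
  expect_equal(kf$C[, 5], rowMeans(all_y), tolerance = 0.15)
})

test_that("the decode step equals the brute-force Gaussian posterior", {
  set.seed(21)
  E <- 4
  kf <- structure(list(
    A = diag(5), C = matrix(rnorm(E * 5), E, 5),
    W = diag(c(0, 0, 0.5, 0.7, 0)), Q = diag(runif(E, 0.5, 1)),
    dt = 20, E = E, state = c("px", "py", "vx", "vy", "bias"),
    window = c(4, 4), days = 1L), class = "fitkf")
  kf$A[1, 3] <- kf$A[2, 4] <- 0.02
  st <- kf_state(kf, cursor_pos = c(1, -1))
  st$mean[3:4] <- c(2, 3); st$cov[3:4, 3:4] <- diag(c(0.4, 0.9))
  y <- rnorm(E, 0, 2); cur <- c(1.2, -0.8)
  got <- kf_decode_step(kf, st, y, cur)

  # oracle: predict, pin position/bias, then exact Gaussian conditioning
  m <- kf$A %*% st$mean; P <- kf$A %*% st$cov %*% t(kf$A) + kf$W
  m[c(1, 2)] <- cur; m[5] <- 1
  P[c(1, 2, 5), ] <- 0; P[, c(1, 2, 5)] <- 0
  post <- gaussian_posterior(m, P, kf$C, kf$Q, y)
  expect_lt(max(abs(got$mean - post$mean)), 1e-10)
  expect_lt(max(abs(got$cov[3:4, 3:4] - post$cov[3:4, 3:4])), 1e-10)

  # position covariance is exactly zero after every step
  expect_equal(got$cov[c(1, 2, 5), ], matrix(0, 3, 5))
  expect_equal(got$cov[, c(1, 2, 5)], matrix(0, 5, 3))
  expect_equal(got$mean[c(1, 2)], cur)

  # with the velocity dynamics zeroed and an observation exactly explained
  # by the pinned position, the velocity estimate stays at the prior 0
  kf0 <- kf; kf0$A[3:4, ] <- 0; kf0$W[3:4, 3:4] <- 0
  y0 <- as.numeric(kf0$C %*% c(cur, 0, 0, 1))
  st3 <- kf_decode_step(kf0, st, y0, cur)
  expect_lt(max(abs(st3$mean[3:4])), 1e-10)
})

test_that("noiseless observations recover the true velocity", {
  set.seed(5)
  E <- 8
  C <- matrix(rnorm(E * 5, 0, 1.5), E, 5)
  kf <- structure(list(
    A = diag(5), C = C, W = diag(c(0, 0, 25, 25, 0)),
    Q = diag(1e-10, E), dt = 20, E = E,
    state = c("px", "py", "vx", "vy", "bias"),
    window = c(4, 4), days = 1L), class = "fitkf")
  v_true <- c(7, -3); pos <- c(0.5, 0.2)
  y <- as.numeric(C %*% c(pos, v_true, 1))
  st <- kf_state(kf, pos)
  st <- kf_decode_step(kf, st, y, pos)
  expect_equal(st$mean[3:4], v_true, tolerance = 1e-4)
})

test_that("sequence decode equals a hand-unrolled recursion", {
  corpus <- tiny_corpus(n_days = 1, trials_per_day = 8, E = 6)
  kf <- train_fitkf(corpus)
  tr <- corpus$days[[1]][[1]]
  U <- tr$spikes$counts[, 1:3]
  cur <- tr$kin$position[, 1:3]
  got <- predict(kf, U, cursor_pos = cur)
  st <- kf_state(kf, cur[, 1])
  man <- matrix(0, 2, 3)
  for (t in 1:3) {
    st <- kf_decode_step(kf, st, U[, t], cur[, t])
    man[, t] <- st$mean[3:4]
  }
  expect_equal(got$velocity, man, tolerance = 1e-12)
  # deterministic, and empty input gives empty output
  expect_identical(got$velocity, predict(kf, U, cursor_pos = cur)$velocity)
  expect_equal(ncol(predict(kf, U[, 0, drop = FALSE])$velocity), 0L)
})

test_that("decoding from the fitted LDS beats single-electrode regression", {
  corpus <- tiny_corpus(n_days = 1, trials_per_day = 40, E = 12, seed = 10)
  kf <- train_fitkf(corpus)
  r2_kf <- offline_decode_r2(kf, corpus$days[[1]])
  # best single-electrode linear regression of velocity
  cts <- do.call(cbind, lapply(corpus$days[[1]], function(tr) tr$spikes$counts))
  vel <- do.call(cbind, lapply(corpus$days[[1]], function(tr) tr$kin$velocity))
  r2_single <- max(vapply(seq_len(12), function(e) {
    pred <- rbind(fitted(lm(vel[1, ] ~ cts[e, ])),
                  fitted(lm(vel[2, ] ~ cts[e, ])))
    decode_accuracy_r2(vel, pred)
  }, numeric(1)))
  expect_gt(r2_kf, r2_single)
})
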