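test_that("training sequences are sliding 5-trial windows with stride 1", {
  corpus <- tiny_corpus(n_days = 1, trials_per_day = 9, E = 4)
  norm <- fit_normalization(corpus)
  seqs <- build_training_sequences(corpus$days[[1]], norm, "velocity")
  expect_length(seqs, 5L)  # n - 4
  bins <- vapply(corpus$days[[1]], function(tr) ncol(tr$spikes$counts),
                 integer(1))
  for (i in seq_along(seqs)) {
    expect_equal(ncol(seqs[[i]]$counts), sum(bins[i:(i + 4)]))
    expect_equal(seqs[[i]]$seed_end, sum(bins[i:(i + 1)]))
  }
  # every trial except the day's first two appears in some learn span
  covered <- logical(9)
  for (i in seq_along(seqs)) covered[(i + 2):(i + 4)] <- TRUE
  expect_equal(covered, c(FALSE, FALSE, rep(TRUE, 7)))

  expect_length(build_training_sequences(corpus$days[[1]][1:5], norm), 1L)
  expect_warning(out <- build_training_sequences(corpus$days[[1]][1:4], norm),
                 "fewer than 5")
  expect_length(out, 0L)
})

test_that("spike-count augmentation preserves the contract totals", {
  set.seed(31)
  cts <- matrix(rpois(8 * 60, 1.2), 8, 60)

  # sigma = 0 is the identity
  expect_identical(perturb_counts(cts, perturbation_spec(0, 0)), cts)

  # totals always in [0, 2n]; counts never negative
  sp <- perturbation_spec(0.045, 0.3)
  n <- rowSums(cts)
  for (rep in 1:50) {
    out <- perturb_counts(cts, sp)
    expect_true(all(out >= 0))
    expect_true(all(rowSums(out) >= 0 & rowSums(out) <= 2 * n))
  }
  # zero electrodes stay zero
  cts0 <- cts; cts0[3, ] <- 0L
  out <- perturb_counts(cts0, sp)
  expect_equal(sum(out[3, ]), 0L)
})

test_that("augmentation keeps the mean perturbed total near the true total", {
  set.seed(77)
  cts <- matrix(rpois(4 * 50, 2), 4, 50)
  sp <- perturbation_spec(0.045, 0.3)
  draws <- 1e4
  tot <- matrix(0, draws, 4)
  for (i in seq_len(draws)) tot[i, ] <- rowSums(perturb_counts(cts, sp))
  n <- rowSums(cts)
  for (e in 1:4) {
    se <- sd(tot[, e]) / sqrt(draws)
    expect_lt(abs(mean(tot[, e]) - n[e]), 2 * se + 0.5)
  }
})

test_that("loss is masked mean squared error over the learn span", {
  p <- random_mrnn(4, 4, 3, seed = 3)
  set.seed(12)
  seqs <- random_seqs(2, 3, 12, seed_end = 4L)
  # invariance to seed-span target values
  seqs2 <- lapply(seqs, function(s) {
    s$targets[, 1:4] <- 99; s
  })
  expect_equal(mrnn_loss(p, seqs), mrnn_loss(p, seqs2))

  # zero-initialized net: loss equals the mean square of the learn targets
  p0 <- init_mrnn(4, 4, 3, M = 2, seed = 1)
  msq <- mean(vapply(seqs, function(s)
    mean(s$targets[, 5:12]^2), numeric(1)))
  expect_equal(mrnn_loss(p0, seqs), msq, tolerance = 1e-12)

  # outputs equal to targets give zero loss
  seqs3 <- lapply(seqs, function(s) {
    run <- mrnn_run(p, s$counts)
    s$targets <- run$Z
    s
  })
  expect_equal(mrnn_loss(p, seqs3), 0, tolerance = 1e-20)
  expect_error(mrnn_loss(p, list()), "empty")
})

test_that("BPTT gradient matches central finite differences", {
  p <- random_mrnn(4, 4, 3, seed = 5)
  set.seed(17)
  seqs <- random_seqs(2, 3, 12, seed_end = 4L)
  g <- mrnn_gradient(p, seqs)
  fd <- fd_gradient(p, seqs)
  expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-5)

  # readout-layer gradient in closed form: dW_o = 2/(M Tl) sum e r'
  fg <- robustbmi:::forward_groups(p, robustbmi:::pack_sequences(seqs))
  M <- 2; Tl <- sum(vapply(fg, function(g_) g_$learn_bins, numeric(1)))
  dWo <- matrix(0, 2, 4)
  for (g_ in fg) {
    for (b in seq_len(g_$B)) {
      R <- tanh(g_$X[, b, ])
      Err <- g_$Z[, b, ] - g_$Y[, b, ]
      mask <- g_$mask[1, b, ] == 1
      dWo <- dWo + (2 / (M * Tl)) * Err[, mask] %*% t(R[, mask])
    }
  }
  d <- p$dims
  w_ix <- d["N"] * d["F"] + d["F"] * d["E"] + d["F"] * d["N"] + d["N"]
  got_Wo <- matrix(g[(w_ix + 1):(w_ix + 8)], 2, 4)
  expect_equal(got_Wo, dWo, tolerance = 1e-10)

  # zero output error implies zero gradient
  seqs0 <- lapply(seqs, function(s) {
    s$targets <- mrnn_run(p, s$counts)$Z; s
  })
  expect_lt(max(abs(mrnn_gradient(p, seqs0))), 1e-14)
})

test_that("Gauss-Newton products are symmetric, PSD and damp correctly", {
  p <- random_mrnn(4, 4, 3, seed = 7)
  set.seed(23)
  seqs <- random_seqs(2, 3, 10, seed_end = 3L)
  np <- count_mrnn_params(4, 4, 3, 2)
  expect_equal(mrnn_gn_product(p, seqs, rep(0, np), 0), rep(0, np))
  for (rep in 1:5) {
    v1 <- rnorm(np); v2 <- rnorm(np)
    g1 <- mrnn_gn_product(p, seqs, v1, 0)
    g2 <- mrnn_gn_product(p, seqs, v2, 0)
    expect_lt(abs(sum(v2 * g1) - sum(v1 * g2)) /
                max(abs(sum(v2 * g1)), 1e-12), 1e-8)
    expect_gte(sum(v1 * g1), -1e-12)  # PSD
  }
  v <- rnorm(np)
  big <- mrnn_gn_product(p, seqs, v, 1e9)
  expect_lt(max(abs(big - 1e9 * v)) / max(abs(1e9 * v)), 1e-6)
})

test_that("CG reduces the residual monotonically on the damped system", {
  p <- random_mrnn(4, 4, 3, seed = 2)
  set.seed(3)
  seqs <- random_seqs(3, 3, 10, seed_end = 3L)
  g <- as.numeric(mrnn_gradient(p, seqs))
  fg <- robustbmi:::forward_cache(p, seqs)
  Ap <- function(v) robustbmi:::gn_product_cached(p, fg, v, 0.1)
  # run CG manually, tracking residual norms
  b <- -g; x <- numeric(length(b)); r <- b; pp <- r; rs <- sum(r^2)
  res <- sqrt(rs)
  for (i in 1:10) {
    Av <- Ap(pp); al <- rs / sum(pp * Av)
    x <- x + al * pp; r <- r - al * Av
    rsn <- sum(r^2); res <- c(res, sqrt(rsn))
    pp <- r + (rsn / rs) * pp; rs <- rsn
  }
  expect_lt(res[11], res[1] * 0.5)
  # solution satisfies the system approximately
  sol <- robustbmi:::cg_solve(Ap, b, 50, 1e-8)
  expect_lt(sqrt(sum((Ap(sol$x) - b)^2)) / sqrt(sum(b^2)), 1e-6)
})

test_that("hf_train learns a one-day corpus and selects the best snapshot", {
  corpus <- generate_corpus(1, 100, E = 32, seed = 5, drift = no_drift())
  cfg <- hf_config(total_steps = 45, max_cg_iters = 10,
                   snapshot_interval = 5, seed = 2)
  fit <- hf_train(corpus, config = cfg, perturb = perturbation_spec(),
                  target = "velocity", N = 30)
  # returned snapshot never worse than the initial parameters
  expect_lte(fit$heldout_loss, fit$snapshots$heldout[1])
  expect_equal(fit$heldout_loss, min(fit$snapshots$heldout))
  # end-to-end decode quality on the training day
  dec <- structure(list(params = fit$params, norm = fit$norm, x0 = fit$x0,
                        target = "velocity"), class = "mrnn_decoder")
  expect_gt(offline_decode_r2(dec, corpus$days[[1]]), 0.6)
})

test_that("minibatches sample every training day", {
  corpus <- tiny_corpus(n_days = 3, trials_per_day = 10, E = 6)
  cfg <- hf_config(total_steps = 3, max_cg_iters = 2, snapshot_interval = 3,
                   minibatch_fraction = 1 / 5, seed = 1)
  # instrument by capturing day indices through the perturbation path:
  # with sigma = 0 the minibatch is used as-is, so check via internals
  norm <- fit_normalization(corpus)
  day_seqs <- lapply(corpus$days, build_training_sequences, norm = norm,
                     target = "velocity")
  sp <- robustbmi:::split_heldout(day_seqs, 0.1)
  set.seed(1)
  mb <- unlist(lapply(sp$train, function(ss) {
    m <- max(1L, round(1 / 5 * length(ss)))
    ss[sample.int(length(ss), m)]
  }), recursive = FALSE)
  days_in_mb <- sort(unique(vapply(mb, function(s) s$day_index, integer(1))))
  expect_equal(days_in_mb, 1:3)
})

test_that("the decoder pair trains two distinct M=2 networks sharing a norm", {
  corpus <- generate_corpus(1, 40, E = 16, seed = 6, drift = no_drift())
  cfg <- hf_config(total_steps = 6, max_cg_iters = 5, snapshot_interval = 3,
                   seed = 3)
  pair <- train_decoder_pair(corpus, config = cfg, N = 10)
  expect_s3_class(pair, "mrnn_pair")
  expect_equal(unname(pair$velocity$params$dims["M"]), 2L)
  expect_equal(unname(pair$position$params$dims["M"]), 2L)
  expect_false(isTRUE(all.equal(coef(pair$velocity), coef(pair$position))))
  expect_identical(pair$velocity$norm$velocity_scale,
                   pair$position$norm$velocity_scale)

  # warm start: training resumes from supplied weights
  cfg1 <- hf_config(total_steps = 2, max_cg_iters = 2,
                    snapshot_interval = 2, seed = 9)
  warm <- hf_train(corpus, config = cfg1, target = "velocity", N = 10,
                   init_params = pair$velocity$params)
  expect_lt(warm$snapshots$heldout[1],
            mrnn_loss(init_mrnn(10, 10, 16, seed = 9),
                      build_training_sequences(
                        corpus$days[[1]],
                        fit_normalization(corpus), "velocity")))
})
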