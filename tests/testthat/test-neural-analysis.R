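test_that("count discretization caps at the 5+ category", {
  expect_equal(discretize_counts(c(0, 1, 4, 5, 7, 100)),
               c(0, 1, 4, 5, 5, 5))
  # 5 spikes in a 20 ms bin is a 250 Hz instantaneous rate
  expect_equal(5 / 0.020, 250)
})

test_that("mutual information matches the brute-force double sum", {
  set.seed(14)
  for (rep in 1:20) {
    D <- sample(2:4, 1)
    tab <- matrix(rpois(D * 6, 3), D, 6)
    tab[1, 1] <- tab[1, 1] + 1  # keep non-empty
    got <- mutual_information(tab)
    expect_lt(abs(got - ref_mutual_information(tab)), 1e-12)
    expect_gte(got, 0)
    p_y <- colSums(tab) / sum(tab)
    h_y <- -sum(p_y[p_y > 0] * log2(p_y[p_y > 0]))
    expect_lte(got, min(h_y, log2(D)) + 1e-12)
  }
  # independence: identical rows carry no information
  tab <- matrix(rep(c(4, 3, 2, 1, 0, 0), 3), 3, 6, byrow = TRUE)
  expect_equal(mutual_information(tab), 0)
  # 4 directions deterministically emitting distinct categories: 2 bits
  tab <- matrix(0, 4, 6); tab[cbind(1:4, 1:4)] <- 10
  expect_equal(mutual_information(tab), 2)
  expect_error(mutual_information(matrix(0, 2, 6)), "empty")
})

test_that("electrode ranking orders by information and is deterministic", {
  set.seed(6)
  E <- 10
  ang <- runif(E, 0, 2 * pi)
  depth <- rep(0.05, E); depth[4] <- 1.2   # one strongly tuned electrode
  tun <- tuning_model(baseline_rate = rep(20, E),
                      modulation_depth = depth,
                      preferred_direction = rbind(cos(ang), sin(ang)),
                      position_gain = 0)
  wins <- 0
  for (s in 1:20) {
    corpus <- generate_corpus(1, 48, E = E, seed = 100 + s, tuning = tun,
                              drift = no_drift())
    rk <- rank_electrodes(corpus)
    wins <- wins + (rk$electrode[1] == 4)
  }
  expect_gte(wins, 19)  # strongly tuned electrode ranks first

  corpus <- generate_corpus(1, 48, E = E, seed = 1, tuning = tun,
                            drift = no_drift())
  expect_identical(rank_electrodes(corpus), rank_electrodes(corpus))

  # a dead electrode ranks last with zero information
  cond0 <- recording_condition(1, c(0, rep(1, E - 1)))
  dead <- lapply(corpus$days[[1]], function(tr) {
    tr$spikes$counts[1, ] <- 0L
    tr
  })
  rk <- rank_electrodes(dead)
  expect_equal(rk$electrode[E], 1)
  expect_equal(rk$mi_bits[E], 0)
})

test_that("electrode dropping zeroes exactly the top-k rows, idempotently", {
  set.seed(2)
  cts <- matrix(rpois(6 * 20, 3), 6, 20)
  ranking <- c(5, 2, 6, 1, 3, 4)
  expect_identical(drop_electrodes(cts, ranking, 0), cts)
  out <- drop_electrodes(cts, ranking, 2)
  expect_equal(sum(out[c(5, 2), ]), 0)
  expect_identical(out[c(1, 3, 4, 6), ], cts[c(1, 3, 4, 6), ])
  expect_identical(drop_electrodes(out, ranking, 2), out)  # idempotent
  expect_equal(sum(drop_electrodes(cts, ranking, 6)), 0)
  expect_error(drop_electrodes(cts, ranking, 7), "0..E")
})

test_that("subspace basis recovers planted low-rank structure", {
  set.seed(8)
  E <- 12
  # activity confined to a known 2-plane
  B2 <- qr.Q(qr(matrix(rnorm(E * 2), E, 2)))
  Y <- B2 %*% matrix(rnorm(2 * 300, 0, 3), 2, 300)
  sb <- subspace_basis(Y, across_day_means = rep(0, E), K = 2)
  proj_got <- sb$V %*% t(sb$V)
  proj_true <- B2 %*% t(B2)
  expect_lt(max(abs(proj_got - proj_true)), 1e-8)
  expect_true(all(diff(sb$eigenvalues) <= 1e-10))
  expect_lt(max(abs(t(sb$V) %*% sb$V - diag(2))), 1e-10)
  expect_error(subspace_basis(Y, rep(0, E), K = 12), "smaller")
  expect_error(subspace_basis(Y[, 1:5], rep(0, E), K = 10), "more time bins")
})

test_that("minimum principal angles hit the closed-form cases", {
  e <- diag(4)
  expect_equal(min_principal_angle(e[, 1:2], e[, 1:2]), 0)
  expect_equal(min_principal_angle(e[, 1, drop = FALSE],
                                   e[, 2, drop = FALSE]), pi / 2)
  # shared basis vector: minimum angle 0
  expect_equal(min_principal_angle(e[, 1:2], e[, 2:3]), 0)
  # symmetry and range on random subspaces
  set.seed(4)
  for (rep in 1:10) {
    Vi <- qr.Q(qr(matrix(rnorm(8 * 3), 8, 3)))
    Vj <- qr.Q(qr(matrix(rnorm(8 * 3), 8, 3)))
    a <- min_principal_angle(Vi, Vj)
    expect_gte(a, 0); expect_lte(a, pi / 2 + 1e-12)
    expect_equal(a, min_principal_angle(Vj, Vi), tolerance = 1e-10)
  }
  expect_error(min_principal_angle(e[, 1:2], diag(5)[, 1:2]), "ambient")
})

test_that("zero drift leaves day-to-day subspace angles at within-day level", {
  corpus <- generate_corpus(4, 60, E = 16, seed = 13, drift = no_drift())
  ang <- principal_angle_matrix(corpus, K = 4)
  across <- ang[upper.tri(ang)]
  # within-day split-half angles for comparison
  day_mats <- lapply(corpus$days, function(trials)
    do.call(cbind, lapply(trials, function(tr) tr$spikes$counts)))
  mu <- rowMeans(do.call(cbind, day_mats))
  within <- vapply(day_mats, function(Y) {
    h <- ncol(Y) %/% 2
    min_principal_angle(subspace_basis(Y[, 1:h], mu, 4),
                        subspace_basis(Y[, (h + 1):(2 * h)], mu, 4))
  }, numeric(1))
  expect_lt(mean(across), mean(within) + 2 * sd(within) + 0.05)
})

test_that("drifting conditions separate subspaces more than stable ones", {
  stable <- generate_corpus(3, 40, E = 16, seed = 5, drift = no_drift())
  drifty <- generate_corpus(3, 40, E = 16, seed = 5,
                            drift = drift_process(gain_sd = 0.5,
                                                  rotation_sd = 0.4,
                                                  dropout_prob = 0.2,
                                                  recurrence_prob = 0))
  a_s <- principal_angle_matrix(stable, K = 4)
  a_d <- principal_angle_matrix(drifty, K = 4)
  expect_gt(mean(a_d[upper.tri(a_d)]), mean(a_s[upper.tri(a_s)]))
})

test_that("behavioral similarity is 1 on identical days and near 1 across drift", {
  corpus <- generate_corpus(2, 32, E = 8, seed = 19)
  expect_equal(behavioral_similarity(corpus$days[[1]], corpus$days[[1]]), 1)
  # same kinematic statistics under different neural conditions
  expect_gt(behavioral_similarity(corpus$days[[1]], corpus$days[[2]]), 0.9)
  # concatenated vector spans 8 x (700 + 600) ms = 10,400 ms
  bw <- corpus_bin_width <- corpus$days[[1]][[1]]$kin$bin_width
  nb <- 8 * (round(700 / bw) + round(600 / bw))
  expect_equal(nb * bw, 10400)
})
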