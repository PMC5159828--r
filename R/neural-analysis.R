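# Electrode-importance ranking by mutual information with reach direction,
# electrode-dropping transforms, principal-angle subspace similarity across
# days, and the behavioral-similarity metric.

#' Discretize spike counts into the standard category set
#'
#' Categories {0, 1, 2, 3, 4, 5+}: counts of 5 or more share the top
#' category (5 spikes in a 20 ms bin is an instantaneous rate of 250 Hz).
#'
#' @param counts non-negative integer vector/matrix.
#' @return Same shape, values in 0..5 where 5 means "5+".
#' @export
discretize_counts <- function(counts) pmin(counts, 5L)

#' Mutual information between reach direction and binned counts
#'
#' `I(X; Y) = H(Y) - H(Y | X)` in bits, computed from a joint count table
#' over directions (rows) and count categories (columns), with the
#' convention `0 log 0 = 0`. Clipped at 0 against rounding.
#'
#' @param table D x |Y| matrix of joint occurrence counts (D >= 2
#'   directions).
#' @return Mutual information, bits.
#' @export
mutual_information <- function(table) {
  table <- as.matrix(table)
  tot <- sum(table)
  if (tot <= 0) stop("empty direction/count table")
  if (nrow(table) < 2L) stop("need at least 2 directions")
  p_y <- colSums(table) / tot
  p_x <- rowSums(table) / tot
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  h_y <- ent(p_y)
  h_y_x <- sum(vapply(seq_len(nrow(table)), function(j) {
    if (p_x[j] == 0) return(0)
    p_x[j] * ent(table[j, ] / sum(table[j, ]))
  }, numeric(1)))
  max(h_y - h_y_x, 0)
}

trial_direction_labels <- function(trials) {
  ang <- vapply(trials, function(tr) {
    d <- tr$target_position - tr$start_position
    atan2(d[2L], d[1L])
  }, numeric(1))
  match(round(ang, 6), sort(unique(round(ang, 6))))
}

#' Joint direction x count-category table for one electrode
#'
#' Pools all bins of each trial (target onset through acquisition) under the
#' trial's reach-direction label.
#'
#' @param trials list of [bmi_trial]s.
#' @param electrode electrode row index.
#' @return D x 6 count table (rows directions, columns categories 0..5+).
#' @export
direction_count_table <- function(trials, electrode) {
  labs <- trial_direction_labels(trials)
  D <- max(labs)
  tab <- matrix(0, D, 6L)
  for (i in seq_along(trials)) {
    cats <- discretize_counts(trials[[i]]$spikes$counts[electrode, ])
    tab[labs[i], ] <- tab[labs[i], ] + tabulate(cats + 1L, nbins = 6L)
  }
  tab
}

#' Rank electrodes by mutual information with reach direction
#'
#' Most-informative first; ties broken by ascending electrode index. The
#' ranking is decoder-independent.
#'
#' @param x a [session_corpus] or a list of [bmi_trial]s (e.g. one day).
#' @return data.frame with `electrode` (row index), `mi_bits`, ordered by
#'   decreasing mutual information.
#' @export
rank_electrodes <- function(x) {
  trials <- if (inherits(x, "session_corpus")) corpus_trials(x) else x
  labs <- trial_direction_labels(trials)
  if (max(labs) < 2L) stop("need at least 2 reach directions to rank")
  E <- nrow(trials[[1L]]$spikes$counts)
  mi <- vapply(seq_len(E), function(e)
    mutual_information(direction_count_table(trials, e)), numeric(1))
  ord <- order(-mi, seq_len(E))
  data.frame(electrode = ord, mi_bits = mi[ord])
}

#' Zero out the top-ranked electrodes
#'
#' Simulates sudden loss of the k most informative electrodes: their rows
#' are set to zero; the decoder is not retrained.
#'
#' @param counts a [binned_counts] or E x T matrix.
#' @param ranking data.frame from [rank_electrodes] (or an integer vector
#'   of electrode indices in drop order).
#' @param k number of electrodes to drop (0..E).
#' @return Same type as `counts` with k rows zeroed.
#' @export
drop_electrodes <- function(counts, ranking, k) {
  is_bc <- inherits(counts, "binned_counts")
  m <- if (is_bc) counts$counts else as.matrix(counts)
  if (k < 0 || k > nrow(m)) stop("k must be in 0..E")
  idx <- if (is.data.frame(ranking)) ranking$electrode else ranking
  if (k > 0) m[idx[seq_len(k)], ] <- 0L
  if (is_bc) binned_counts(m, counts$bin_width, counts$electrode_ids) else m
}

#' Top-K principal subspace of a day's neural activity
#'
#' Rows are centered by the supplied across-days electrode means, the
#' covariance `(1/T) Y Y'` is eigendecomposed, and the K leading
#' eigenvectors form the day's subspace basis.
#'
#' @param day_activity E x T activity matrix (e.g. binned counts or rates).
#' @param across_day_means length-E vector of across-days electrode means.
#' @param K subspace dimension (default 10; must satisfy K < E, T > K).
#' @return List with `V` (E x K orthonormal), `eigenvalues`
#'   (non-increasing), `day_index` if present on the input.
#' @export
subspace_basis <- function(day_activity, across_day_means, K = 10) {
  Y <- as.matrix(day_activity)
  E <- nrow(Y); Tn <- ncol(Y)
  if (K >= E) stop("K must be smaller than the electrode count")
  if (Tn <= K) stop("need more time bins than subspace dimensions")
  Yc <- Y - across_day_means
  cov <- (Yc %*% t(Yc)) / Tn
  eg <- eigen(cov, symmetric = TRUE)
  list(V = eg$vectors[, seq_len(K), drop = FALSE],
       eigenvalues = eg$values[seq_len(K)])
}

#' Minimum principal angle between two subspaces
#'
#' Angles are `acos` of the singular values of `V_i' V_j` (clipped to
#' unit interval); the minimum angle measures the best-aligned pair of directions.
#'
#' @param Vi,Vj E x K orthonormal basis matrices (or lists from
#'   [subspace_basis]).
#' @return Minimum principal angle, radians (in `[0, pi/2]`).
#' @export
min_principal_angle <- function(Vi, Vj) {
  if (is.list(Vi)) Vi <- Vi$V
  if (is.list(Vj)) Vj <- Vj$V
  if (nrow(Vi) != nrow(Vj)) stop("subspace bases must share the ambient dimension")
  sv <- svd(t(Vi) %*% Vj, nu = 0, nv = 0)$d
  min(acos(pmin(pmax(sv, 0), 1)))
}

#' Day-by-day minimum principal angle matrix for a corpus
#'
#' Concatenates each day's spike counts, centers by across-days electrode
#' means, and computes the pairwise minimum principal angles between the
#' days' top-K subspaces.
#'
#' @param corpus a [session_corpus].
#' @param K subspace dimension.
#' @return Symmetric n_days x n_days matrix of angles (radians).
#' @export
principal_angle_matrix <- function(corpus, K = 10) {
  day_mats <- lapply(corpus$days, function(trials)
    do.call(cbind, lapply(trials, function(tr) tr$spikes$counts)))
  all_mat <- do.call(cbind, day_mats)
  mu <- rowMeans(all_mat)
  bases <- lapply(day_mats, subspace_basis, across_day_means = mu, K = K)
  n <- length(bases)
  ang <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    ang[i, j] <- ang[j, i] <- min_principal_angle(bases[[i]], bases[[j]])
  }
  dimnames(ang) <- list(corpus$day_indices, corpus$day_indices)
  ang
}

target_key <- function(p) paste(round(p[1L], 3), round(p[2L], 3))

#' Behavioral similarity between two days of radial-task reaches
#'
#' Per day, trial-averaged x and y velocity traces are built per peripheral
#' target (a fixed window after target onset: outward reaches use
#' `out_window` ms, inward `in_window` ms), concatenated across the 8
#' targets, Pearson-correlated across days per dimension, and the two
#' dimensions' correlations averaged.
#'
#' @param day_i,day_j lists of [bmi_trial]s (radial task: all 8 peripheral
#'   targets present as both reach destinations and origins).
#' @param out_window,in_window averaging windows, ms.
#' @return Scalar correlation in `[-1, 1]`.
#' @export
behavioral_similarity <- function(day_i, day_j,
                                  out_window = 700, in_window = 600) {
  build <- function(trials) {
    bw <- trials[[1L]]$kin$bin_width
    nb_out <- round(out_window / bw); nb_in <- round(in_window / bw)
    is_out <- vapply(trials, function(tr)
      sum(tr$start_position^2) < sum(tr$target_position^2), logical(1))
    keys_out <- vapply(trials, function(tr) target_key(tr$target_position),
                       character(1))
    keys_in <- vapply(trials, function(tr) target_key(tr$start_position),
                      character(1))
    targets <- sort(unique(keys_out[is_out]))
    if (length(targets) != 8L)
      stop("expected 8 peripheral targets, found ",
           length(targets), " (", paste(targets, collapse = "; "), ")")
    avg <- function(idx, nb) {
      if (!length(idx)) return(NULL)
      acc <- matrix(0, 2, nb)
      for (i in idx) {
        v <- trials[[i]]$kin$velocity
        if (ncol(v) < nb)
          stop("trial shorter than the averaging window")
        acc <- acc + v[, seq_len(nb)]
      }
      acc / length(idx)
    }
    vx <- c(); vy <- c()
    for (tg in targets) {
      o <- avg(which(is_out & keys_out == tg), nb_out)
      i_ <- avg(which(!is_out & keys_in == tg), nb_in)
      if (is.null(o) || is.null(i_))
        stop("missing outward or inward reaches for target ", tg)
      vx <- c(vx, o[1L, ], i_[1L, ]); vy <- c(vy, o[2L, ], i_[2L, ])
    }
    list(vx = vx, vy = vy)
  }
  a <- build(day_i); b <- build(day_j)
  (stats::cor(a$vx, b$vx) + stats::cor(a$vy, b$vy)) / 2
}
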