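# Independent oracles used by the test suite. These deliberately take
# different computational routes from the package implementation.

# Exhaustive (amplitude, phase) grid search for y = a*sin(b*x - c) at fixed b.
oracle_grid_search_sine <- function(x, y, b, a_max = 120, a_step = 0.5,
                                    phase_step = 0.01) {
  a_grid <- seq(0, a_max, by = a_step)
  phase_grid <- seq(0, 2 * pi, by = phase_step)
  S <- sin(outer(x, phase_grid, function(xx, ph) b * xx - ph)) # n x n_phase
  ys <- drop(crossprod(y, S))        # sum(y * s) per phase
  ss <- colSums(S * S)               # sum(s^2) per phase
  yy <- sum(y * y)
  # SSE(phase, a) = yy - 2 a ys + a^2 ss
  sse <- outer(ys, a_grid, function(v, a) -2 * a * v) +
    outer(ss, a_grid, function(v, a) a^2 * v) + yy
  idx <- arrayInd(which.min(sse), dim(sse))
  list(a = a_grid[idx[2]], phase = phase_grid[idx[1]], sse = min(sse))
}

# Brute-force Spearman: mid-ranks by pairwise counting, Pearson by raw sums.
oracle_spearman_r <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- midrank(x)
  ry <- midrank(y)
  n <- length(x)
  num <- n * sum(rx * ry) - sum(rx) * sum(ry)
  den <- sqrt(n * sum(rx^2) - sum(rx)^2) * sqrt(n * sum(ry^2) - sum(ry)^2)
  num / den
}

# Exact Mann-Whitney by enumeration, with U computed by pair counting
# (not rank sums): U = #{a_i > b_j} + 0.5 * #{a_i = b_j}.
oracle_mw_exact <- function(a, b) {
  m <- length(a); n <- length(b); N <- m + n
  pooled <- c(a, b)
  u_pairs <- function(av, bv) {
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  u_obs <- u_pairs(a, b)
  sets <- utils::combn(N, m)
  u_all <- apply(sets, 2, function(sel) {
    u_pairs(pooled[sel], pooled[-sel])
  })
  center <- m * n / 2
  mean(abs(u_all - center) >= abs(u_obs - center) - 1e-9)
}

# Tie-corrected rank-sum z for one pair (definition, shared with the
# permutation oracle below).
oracle_pair_z <- function(a, b) {
  m <- length(a); n <- length(b); N <- m + n
  r <- rank(c(a, b))
  Tsum <- sum(r[seq_len(m)])
  ties <- table(c(a, b))
  v <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (v <= 0) return(0)
  (Tsum - m * (N + 1) / 2) / sqrt(v)
}

# Permutation oracle for the Steel-Dwass family-wise adjusted p of each pair:
# p_adj(i,j) = P( max over pairs |z*| >= |z_obs(i,j)| ) under label shuffles.
oracle_sd_permutation <- function(groups, n_perm = 1e4, seed = 1) {
  set.seed(seed)
  k <- length(groups)
  sizes <- lengths(groups)
  pooled <- unlist(groups)
  pairs <- utils::combn(k, 2)
  zs_of <- function(gs) {
    apply(pairs, 2, function(ij) abs(oracle_pair_z(gs[[ij[1]]], gs[[ij[2]]])))
  }
  z_obs <- zs_of(groups)
  max_null <- replicate(n_perm, {
    perm <- sample(pooled)
    gs <- split(perm, rep(seq_len(k), sizes))
    max(zs_of(gs))
  })
  vapply(z_obs, function(z) mean(max_null >= z - 1e-12), numeric(1))
}

# Cohort config with all programmed effects switched off.
null_cohort_config <- function(n_eyes = 500, ...) {
  zero <- stats::setNames(rep(0, 8), sector_names())
  cohort_config(n_eyes = n_eyes, target_r_al = zero, target_r_pmp = zero,
                target_r_tilt = zero, ...)
}
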