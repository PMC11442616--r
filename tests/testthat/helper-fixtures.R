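# shared fixture builders; everything is generated in code at test time

# minimal fit-capable scheme: one b0 + six well-spread directions
tiny_scheme <- function(b = 1000) {
  dirs <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0) / sqrt(2), c(1, 0, 1) / sqrt(2), c(0, 1, 1) / sqrt(2)
  )
  gradient_table(c(0, rep(b, 6)), rbind(c(0, 0, 0), dirs))
}

# random symmetric positive-definite tensor with eigenvalues in [lo, hi]
random_spd_tensor <- function(lo = 0.2e-3, hi = 2.5e-3) {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  lam <- runif(3, lo, hi)
  m <- q %*% diag(lam) %*% t(q)
  c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
}

# independent scalar-loop evaluation of S = s0 exp(-b g' D g)
signal_loop_oracle <- function(tensors6, gt, s0) {
  nvox <- nrow(tensors6)
  out <- matrix(NA_real_, nvox, nrow(gt))
  for (v in seq_len(nvox)) {
    D <- matrix(c(tensors6[v, 1], tensors6[v, 4], tensors6[v, 5],
                  tensors6[v, 4], tensors6[v, 2], tensors6[v, 6],
                  tensors6[v, 5], tensors6[v, 6], tensors6[v, 3]), 3, 3)
    for (i in seq_len(nrow(gt))) {
      g <- c(gt$gx[i], gt$gy[i], gt$gz[i])
      out[v, i] <- s0 * exp(-gt$bval[i] * drop(t(g) %*% D %*% g))
    }
  }
  out
}

# a uniform single-tensor dwi volume on a small grid
uniform_dwi <- function(tensor6, gt, grid = c(4, 4, 2), s0 = 1000) {
  S <- signal_loop_oracle(matrix(tensor6, 1), gt, s0)
  arr <- array(rep(S, each = prod(grid)), c(grid, nrow(gt)))
  dwi_volume(arr, c(2, 2, 2), gt)
}

# brute-force two-sided signed-rank p over all 2^n sign assignments
signed_rank_enum_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  tot <- sum(r)
  w_low <- min(w_obs, tot - w_obs)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- drop(signs %*% r)
  min(1, mean(w_all <= w_low + 1e-9) + mean(w_all >= tot - w_low - 1e-9))
}

# brute-force two-sided rank-sum p over all C(n, na) labelings (no ties)
rank_sum_enum_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  u_low <- min(u_obs, na * nb - u_obs)
  sets <- combn(na + nb, na)
  u_all <- apply(sets, 2, function(s) sum(seq_len(na + nb)[s])) -
    na * (na + 1) / 2
  min(1, mean(u_all <= u_low + 1e-9) + mean(u_all >= na * nb - u_low - 1e-9))
}

# per-voxel relative tensor error against ground truth, scaled by the
# voxel's largest element magnitude (off-diagonals can be exactly zero)
tensor_rel_error <- function(fit, truth) {
  gs <- dim(fit$s0)
  F <- matrix(fit$tensors, prod(gs), 6)
  V <- matrix(truth$tensors, prod(gs), 6)
  scale <- apply(abs(V), 1, max)
  max(abs(F - V) / scale)
}
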