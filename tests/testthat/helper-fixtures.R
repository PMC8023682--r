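# Shared small fixtures and dense oracles, built in code at test time.

# A complete small dataset plus dense-operator oracle pieces.
make_fixture <- function(N = 40, M = 50, L = 2, seed = 7, h2_g = 0.3,
                         h2_gxe = 0.15, covar_frac = 0.01, M_G = 10,
                         M_GxE = 5, L_active = min(2, L)) {
  cfg <- sim_config(N = N, M = M, L = L, L_active = L_active, M_G = M_G,
                    M_GxE = M_GxE, h2_g = h2_g, h2_gxe = h2_gxe,
                    covar_frac = covar_frac, seed = seed)
  sim <- simulate_dataset(cfg)
  des <- assemble_design(sim$E, sim$C)
  Xs <- as.matrix(sim$geno)
  K <- tcrossprod(Xs) / sim$geno$M
  Wm <- diag(N) - tcrossprod(des$Q)
  yp <- drop(Wm %*% (sim$y - mean(sim$y)))
  list(cfg = cfg, sim = sim, des = des, Xs = Xs, K = K, Wm = Wm, yp = yp)
}

# Dense operator for one Gram dictionary entry: 1 = WKW, 2 = W,
# 2 + (l-1)L + m = W F_l F_m^T W / M.
dense_op <- function(fx, i) {
  L <- fx$des$L
  if (i == 1) fx$Wm %*% fx$K %*% fx$Wm
  else if (i == 2) fx$Wm
  else {
    p <- i - 2L
    l <- (p - 1L) %/% L + 1L
    m <- (p - 1L) %% L + 1L
    fx$Wm %*% (outer(fx$des$E[, l], fx$des$E[, m]) * fx$K) %*% fx$Wm
  }
}

# Per-probe contributions <Op_i z_b, Op_j z_b> for empirical Monte-Carlo
# standard errors of randomized Gram entries.
probe_contributions <- function(fx, probes, i, j) {
  Oi <- dense_op(fx, i)
  Oj <- dense_op(fx, j)
  colSums((Oi %*% probes$Z) * (Oj %*% probes$Z))
}

# Dense GPLEMMA model vector f(theta) = vec(W (sb K + K2(w) + se I) W).
dense_f <- function(fx, theta) {
  L <- fx$des$L
  w <- theta[2:(L + 1)]
  eta <- drop(fx$des$E %*% w)
  as.vector(fx$Wm %*% (theta[1] * fx$K +
    diag(eta) %*% fx$K %*% diag(eta) +
    theta[L + 2] * diag(fx$des$N)) %*% fx$Wm)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(abs(y)), tol)
}
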