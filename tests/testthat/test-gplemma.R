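test_that("squared error matches the dense Frobenius objective and its symmetries", {
  fx <- make_fixture(N = 30, M = 40, L = 2, seed = 67)
  pcd <- rhe_precompute(fx$sim$geno, fx$des, fx$sim$y, exact = TRUE)
  parts <- gxeherit:::gp_parts(pcd)

  # all-zero parameters leave only the data term (y_p' y_p)^2
  expect_equal(gxeherit:::gp_S(rep(0, 4), parts), parts$yWy^2)

  th <- c(0.3, 0.2, -0.4, 0.5)
  S_dense <- sum((fx$yp %o% fx$yp - matrix(dense_f(fx, th), 30))^2)
  expect_equal(gxeherit:::gp_S(th, parts), S_dense, tolerance = 1e-10)

  # sign of the weight vector is unidentifiable
  th_flip <- th
  th_flip[2:3] <- -th_flip[2:3]
  expect_equal(gxeherit:::gp_S(th_flip, parts), gxeherit:::gp_S(th, parts))
})

test_that("J'J and J'eps match central finite differences of the dense model", {
  fx <- make_fixture(N = 30, M = 40, L = 2, seed = 71)
  pcd <- rhe_precompute(fx$sim$geno, fx$des, fx$sim$y, exact = TRUE)
  parts <- gxeherit:::gp_parts(pcd)
  th <- c(0.25, 0.3, -0.15, 0.6)
  jp <- gxeherit:::gp_jacobian(th, parts)

  h <- 1e-5
  Jnum <- vapply(1:4, function(i) {
    tp <- th; tm <- th
    tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
    (dense_f(fx, tp) - dense_f(fx, tm)) / (2 * h)
  }, numeric(30 * 30))
  JJnum <- crossprod(Jnum)
  Y <- as.vector(fx$yp %o% fx$yp)
  Jte_num <- drop(crossprod(Jnum, Y - dense_f(fx, th)))
  expect_lt(max(abs(jp$JJ - JJnum)) / max(abs(JJnum)), 1e-4)
  expect_lt(max(abs(jp$Jte - Jte_num)) / max(abs(Jte_num)), 1e-4)
  expect_equal(jp$JJ, t(jp$JJ))
  expect_equal(jp$JJ[4, 4], 30 - fx$des$D)

  # gradient identity: dS/dtheta = -2 J'eps
  gnum <- vapply(1:4, function(i) {
    tp <- th; tm <- th
    tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
    (gxeherit:::gp_S(tp, parts) - gxeherit:::gp_S(tm, parts)) / (2 * h)
  }, numeric(1))
  expect_equal(gnum, -2 * jp$Jte, tolerance = 1e-5)
})

test_that("damped least-squares driver: one-step convergence on a linear model, monotone descent, steepest-descent limit", {
  set.seed(5)
  A <- matrix(rnorm(60), 20, 3)
  b <- rnorm(20)
  ls <- qr.solve(A, b)
  S_fun <- function(th) sum((b - A %*% th)^2)
  jac_fun <- function(th) list(JJ = crossprod(A), Jte = drop(crossprod(A, b - A %*% th)))

  # Gauss-Newton is exact for a linear model: one accepted step from zero
  fit <- gxeherit:::lm_nls(rep(0, 3), S_fun, jac_fun, mu0 = 1e-12,
                           tol = 1e-12, trace_S = TRUE)
  expect_equal(fit$theta, ls, tolerance = 1e-6, ignore_attr = TRUE)
  expect_lt(fit$accepted, 4)

  # accepted squared errors decrease strictly
  expect_true(all(diff(fit$S_path) < 0))

  # huge damping: step direction approaches J'eps (steepest descent)
  jp0 <- jac_fun(rep(0, 3))
  big <- 1e8
  delta <- solve(jp0$JJ + big * diag(3), jp0$Jte)
  cosang <- sum(delta * jp0$Jte) / sqrt(sum(delta^2) * sum(jp0$Jte^2))
  expect_gt(cosang, 0.999999)
})

test_that("monotone descent holds on the GxE objective for every restart", {
  fx <- make_fixture(N = 50, M = 60, L = 3, seed = 73)
  pc <- rhe_precompute(fx$sim$geno, fx$des, fx$sim$y, B = 30, seed = 74)
  parts <- gxeherit:::gp_parts(pc)
  for (r in 1:4) {
    th0 <- gxeherit:::gp_init(parts, r, 75)
    run <- gxeherit:::lm_nls(th0, function(t) gxeherit:::gp_S(t, parts),
                             function(t) gxeherit:::gp_jacobian(t, parts),
                             trace_S = TRUE)
    expect_true(all(diff(run$S_path) < 0))
  }
})

test_that("initialization has the documented distribution and respects restart seeding", {
  fx <- make_fixture(N = 50, M = 60, L = 4, seed = 79)
  pc <- rhe_precompute(fx$sim$geno, fx$des, fx$sim$y, B = 30, seed = 80)
  parts <- gxeherit:::gp_parts(pc)
  th_a <- gxeherit:::gp_init(parts, 1, 99)
  th_b <- gxeherit:::gp_init(parts, 1, 99)
  th_c <- gxeherit:::gp_init(parts, 2, 99)
  expect_identical(th_a, th_b)
  expect_false(identical(th_a, th_c))
  # raw init weights: mean 1/L, sd sqrt(2)/L entrywise
  L <- 4
  draws <- vapply(1:400, function(r) {
    set.seed(gxeherit:::derive_seed(99, r))
    1 / L + rnorm(L, 0, sqrt(2) / L)
  }, numeric(L))
  expect_lt(abs(mean(draws) - 1 / L), 4 * sqrt(2) / L / sqrt(400 * L))
  expect_equal(sd(as.vector(draws)), sqrt(2) / L, tolerance = 0.1)
})

test_that("with dense traces the LM fixed point matches an independent non-linear least-squares solver", {
  fx <- make_fixture(N = 40, M = 50, L = 2, seed = 83)
  pcd <- rhe_precompute(fx$sim$geno, fx$des, fx$sim$y, exact = TRUE)
  fit <- gplemma(fx$sim$y, precompute = pcd, design = fx$des, restarts = 5,
                 seed = 85, tol = 1e-12, max_iter = 500)
  resfun <- function(th) as.vector(fx$yp %o% fx$yp) - dense_f(fx, th)
  set.seed(86)
  nl_best <- NULL
  for (s in 1:5) {
    start <- gxeherit:::gp_init(gxeherit:::gp_parts(pcd), s, 86) *
      (1 + 0.1 * rnorm(4))
    nl <- minpack.lm::nls.lm(par = start, fn = resfun,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 1000, ftol = 1e-15, ptol = 1e-15))
    if (is.null(nl_best) || nl$deviance < nl_best$deviance) nl_best <- nl
  }
  thn <- nl_best$par
  if (sum(thn[2:3] * fit$theta[2:3]) < 0) thn[2:3] <- -thn[2:3]
  expect_lt(max(abs(thn - fit$theta)) / max(abs(fit$theta)), 1e-4)
  expect_equal(nl_best$deviance, fit$S, tolerance = 1e-6)
})

test_that("gplemma fit object is coherent, deterministic, and sign-canonical", {
  fx <- make_fixture(N = 60, M = 80, L = 3, seed = 87)
  fit <- gplemma(fx$sim$y, fx$sim$geno, fx$sim$E, fx$sim$C, probes = 30,
                 restarts = 3, seed = 88)
  expect_s3_class(fit, "gplemma")
  expect_equal(sum(fit$pve), 1)
  expect_true(all(fit$pve >= 0))
  expect_equal(sqrt(sum(fit$es_weights^2)), 1)
  expect_gt(fit$es_weights[which.max(abs(fit$es_weights))], 0)
  expect_equal(fit$eta_hat, drop(fx$des$E %*% fit$es_weights))
  expect_equal(fit$S, min(fit$restarts$S))
  expect_equal(length(coef(fit)), 5)

  fit2 <- gplemma(fx$sim$y, fx$sim$geno, fx$sim$E, fx$sim$C, probes = 30,
                  restarts = 3, seed = 88)
  expect_identical(fit$theta, fit2$theta)

  # single restart equals a bare LM run from the first initialization
  pc <- rhe_precompute(fx$sim$geno, assemble_design(fx$sim$E, fx$sim$C),
                       fx$sim$y, B = 30, seed = 88)
  parts <- gxeherit:::gp_parts(pc)
  run <- gxeherit:::lm_nls(gxeherit:::gp_init(parts, 1, 88),
                           function(t) gxeherit:::gp_S(t, parts),
                           function(t) gxeherit:::gp_jacobian(t, parts))
  fit1 <- gplemma(fx$sim$y, precompute = pc, design = fx$des, restarts = 1,
                  seed = 88)
  expect_equal(fit1$theta, run$theta, ignore_attr = TRUE)
})

test_that("flipping the sign of every environment leaves the variance partition unchanged", {
  fx <- make_fixture(N = 50, M = 60, L = 3, seed = 91)
  f1 <- gplemma(fx$sim$y, fx$sim$geno, fx$sim$E, fx$sim$C, probes = 25,
                restarts = 2, seed = 92)
  f2 <- gplemma(fx$sim$y, fx$sim$geno, -fx$sim$E, fx$sim$C, probes = 25,
                restarts = 2, seed = 92)
  expect_equal(f1$pve, f2$pve, tolerance = 1e-8)
  expect_equal(abs(cor(f1$eta_hat, -f2$eta_hat)), 1, tolerance = 1e-8)
})

test_that("gplemma recovers a strong planted environmental score", {
  cfg <- sim_config(N = 1500, M = 2500, L = 5, L_active = 3, M_G = 60,
                    M_GxE = 30, h2_g = 0.2, h2_gxe = 0.1, covar_frac = 0.01,
                    seed = 95)
  sim <- simulate_dataset(cfg)
  fit <- gplemma(sim$y, sim$geno, sim$E, sim$C, probes = 40, restarts = 10,
                 seed = 96)
  expect_gt(abs(cor(fit$eta_hat, sim$truth$eta_true)), 0.75)
  expect_gt(fit$h2_GxE, 0.03)
  expect_lt(fit$h2_GxE, 0.25)
  expect_gt(fit$h2_G, 0.10)
  expect_lt(fit$h2_G, 0.32)
})

test_that("with three orthogonal scores the fitted ES tracks the dominant one", {
  cfg <- sim_config(N = 2000, M = 2000, L = 6, L_active = 4, M_G = 80,
                    M_GxE = 40, h2_g = 0.15, h2_gxe = 0.2, covar_frac = 0.01,
                    seed = 97)
  sim <- simulate_dataset(cfg, phenotype = "multi_es",
                          singular_values = c(80, 60, 40))
  fit <- gplemma(sim$y, sim$geno, sim$E, sim$C, probes = 40, restarts = 10,
                 seed = 98)
  cors <- abs(cor(fit$eta_hat, sim$truth$eta_true))
  expect_equal(which.max(drop(cors)), 1L)
  expect_gt(max(cors), 0.6)
})
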