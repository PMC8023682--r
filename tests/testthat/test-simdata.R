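test_that("simulated genotypes are valid, reproducible dosages with the requested allele frequency", {
  g1 <- simulate_genotypes(100, 50, 0.05, 0.5, seed = 1)
  expect_true(all(g1$G %in% 0:2))
  expect_true(all(g1$maf >= 0.05 & g1$maf <= 0.5))
  g2 <- simulate_genotypes(100, 50, 0.05, 0.5, seed = 1)
  expect_identical(g1$G, g2$G)
  expect_false(identical(g1$G, simulate_genotypes(100, 50, 0.05, 0.5, seed = 2)$G))
  expect_error(simulate_genotypes(10, 5, 0.6, 0.7), "maf")

  # binomial sampling oracle: 2N draws at p = 0.3
  g3 <- simulate_genotypes(10000, 1, 0.3, 0.3, seed = 2)
  se <- sqrt(0.3 * 0.7 / (2 * 10000))
  expect_lt(abs(mean(g3$G) / 2 - 0.3), 3 * se)

  # monomorphic columns are resampled away even at low MAF and small N
  g4 <- simulate_genotypes(25, 300, 0.05, 0.06, seed = 3)
  expect_true(all(apply(g4$G, 2, stats::var) > 0))
})

test_that("simulated environments are standardized; ordinal columns have 2-5 levels", {
  E <- simulate_environments(1000, 5, "continuous", seed = 3)
  expect_lt(max(abs(colMeans(E))), 1e-12)
  expect_lt(max(abs(colSums(E^2) / 1000 - 1)), 1e-12)
  expect_false(identical(E, simulate_environments(1000, 5, "continuous", seed = 4)))

  Eo <- simulate_environments(1000, 5, "ordinal", seed = 3)
  n_distinct <- apply(Eo, 2, function(x) length(unique(x)))
  expect_true(all(n_distinct >= 2 & n_distinct <= 5))
  expect_lt(max(abs(colMeans(Eo))), 1e-12)
  expect_true(all(attr(Eo, "n_levels") %in% 3:5))
})

test_that("interaction weight sequence matches the alternating decreasing formula", {
  w <- make_interaction_weights(30, 6)
  expect_equal(w[1:6], c(-11/12, 5/6, -3/4, 2/3, -7/12, 1/2))
  expect_true(all(w[7:30] == 0))
  expect_true(all(diff(abs(w[1:6])) < 0))
  expect_equal(make_interaction_weights(1, 1), -1/2)
  expect_equal(sum(make_interaction_weights(9, 4) != 0), 4)
  ws <- make_interaction_weights(6, 6, form = "sqrt")
  expect_equal(abs(ws), sqrt(1 - (1:6) / 12))
  expect_error(make_interaction_weights(3, 5))
})

test_that("baseline phenotype hits target variance fractions exactly and records truth", {
  cfg <- sim_config(N = 400, M = 300, L = 4, L_active = 2, M_G = 30,
                    M_GxE = 10, h2_g = 0.2, h2_gxe = 0.05,
                    covar_frac = 0.01, seed = 5)
  sim <- simulate_dataset(cfg)
  y <- sim$y
  tr <- sim$truth
  vy <- sum((y - mean(y))^2) / cfg$N
  vf <- vapply(tr$components, function(cm) sum(cm^2) / cfg$N, numeric(1)) / vy
  expect_equal(unname(vf["covar"]), 0.01, tolerance = 1e-10)
  expect_equal(unname(vf["main"]), 0.20, tolerance = 1e-10)
  expect_equal(unname(vf["gxe"]), 0.05, tolerance = 1e-10)
  expect_equal(unname(sum(vf)), 1, tolerance = 1e-10)
  expect_equal(sum(tr$beta != 0), 30)
  expect_equal(sum(tr$gamma != 0), 10)
  expect_equal(tr$eta_true, drop(sim$E %*% tr$w_true))

  # zero GxE heritability yields an exactly zero interaction coefficient vector
  cfg0 <- sim_config(N = 200, M = 100, L = 3, L_active = 2, M_G = 20,
                     M_GxE = 10, h2_g = 0.2, h2_gxe = 0, covar_frac = 0.01,
                     seed = 6)
  sim0 <- simulate_dataset(cfg0)
  expect_true(all(sim0$truth$gamma == 0))
  expect_equal(sum(sim0$truth$components$gxe^2), 0)

  # invalid fraction budget
  expect_error(sim_config(h2_g = 0.6, h2_gxe = 0.3, covar_frac = 0.2), "< 1")
})

test_that("environment columns outside the active weight set are uncorrelated with the true ES", {
  cors <- vapply(1:30, function(r) {
    E <- simulate_environments(400, 4, seed = 100 + r)
    w <- make_interaction_weights(4, 2)
    cor(drop(E %*% w), E[, 4])
  }, numeric(1))
  expect_lt(abs(mean(cors)), 3 / sqrt(400 * 30))
})

test_that("three-score phenotype has orthonormal weight columns, disjoint supports, decreasing scales", {
  cfg <- sim_config(N = 500, M = 600, L = 8, L_active = 4, M_G = 40,
                    M_GxE = 30, h2_g = 0.15, h2_gxe = 0.1,
                    covar_frac = 0.01, seed = 9)
  sim <- simulate_dataset(cfg, phenotype = "multi_es",
                          singular_values = c(80, 60, 40))
  tr <- sim$truth
  expect_equal(crossprod(tr$W_true), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  supp <- apply(tr$gamma, 2, function(g) which(g != 0))
  expect_equal(length(Reduce(intersect, asplit(supp, 2))), 0)
  expect_equal(ncol(supp), 3)
  expect_true(all(diff(tr$per_es_scale) < 0))
  expect_equal(tr$per_es_scale / tr$per_es_scale[1], c(1, 60/80, 40/80))
  vy <- sum((sim$y - mean(sim$y))^2) / cfg$N
  expect_equal(sum(tr$components$gxe^2) / cfg$N / vy, 0.1, tolerance = 1e-10)

  cfg_bad <- sim_config(N = 100, M = 50, L = 6, L_active = 3, M_G = 10,
                        M_GxE = 20, h2_g = 0.1, h2_gxe = 0.1, seed = 2)
  sim_g <- simulate_genotypes(100, 50, seed = 1)$G
  E <- simulate_environments(100, 6, seed = 1)
  expect_error(simulate_multi_es(cfg_bad, standardize_block(sim_g), E),
               "disjoint")
})

test_that("misspecified phenotype adds a squared heritable environment with exact 30% heritability", {
  cfg <- sim_config(N = 300, M = 400, L = 4, L_active = 2, M_G = 20,
                    M_GxE = 10, h2_g = 0.15, h2_gxe = 0.05,
                    covar_frac = 0.01, seed = 11)
  sim1 <- simulate_dataset(cfg, phenotype = "misspecified", alpha_s = 1)
  sim0 <- simulate_dataset(cfg, phenotype = "misspecified", alpha_s = 0)
  expect_equal(sim1$y - sim0$y, sim1$S^2, ignore_attr = TRUE)
  expect_equal(sim1$truth$S_h2, 0.30, tolerance = 1e-10)
  expect_equal(length(sim1$truth$S_causal), round(2500 * 400 / 1e5))
  # S is standardized and inserted as the first environment column
  expect_equal(unname(sim1$E[, 1]), unname(sim1$S))
  expect_lt(abs(mean(sim1$S)), 1e-12)
  expect_equal(sum(sim1$S^2) / cfg$N, 1, tolerance = 1e-12)
})

test_that("dataset simulation is bit-reproducible under a fixed seed", {
  cfg <- sim_config(N = 120, M = 80, L = 3, L_active = 2, M_G = 10,
                    M_GxE = 5, h2_g = 0.2, h2_gxe = 0.05, covar_frac = 0.01,
                    seed = 42)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$geno$data, s2$geno$data)
  expect_identical(s1$E, s2$E)
  expect_identical(s1$y, s2$y)
  expect_identical(s1$truth$beta, s2$truth$beta)
})
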