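test_that("heritability scaling follows the outcome-anchored closed form", {
  inp <- gsens_input(0.1, 0.2, 0.3, 6000)

  # no-op when the score already explains h2 of the outcome
  s0 <- scale_to_heritability(inp, 0.2^2)
  expect_equal(s0$r_gy, 0.2, tolerance = 1e-12)
  expect_equal(s0$r_gx, 0.1, tolerance = 1e-12)

  # closed-form scaling to h2 = 0.5
  s <- scale_to_heritability(inp, 0.5)
  expect_equal(s$r_gy, sqrt(0.5), tolerance = 1e-10)
  expect_equal(s$r_gx, 0.1 * sqrt(0.5) / 0.2, tolerance = 1e-10)
  expect_equal(s$r_xy, 0.3)

  # a score unrelated to the exposure stays unrelated
  s2 <- scale_to_heritability(gsens_input(0, 0.2, 0.3, 6000), 0.5)
  expect_identical(s2$r_gx, 0)

  # degenerate and inadmissible requests
  expect_error(scale_to_heritability(gsens_input(0.1, 0.001, 0.3, 6000), 1e-7),
               "exceeds")
  expect_error(scale_to_heritability(inp, 0.02), "exceeds")
  expect_error(scale_to_heritability(inp, 1.2), "\\(0, 1\\]")
  # scaling that would demand more confounding than the associations allow
  expect_error(scale_to_heritability(gsens_input(0.5, 0.3, 0.05, 6000), 0.9),
               "positive definite|cannot exceed")
})

test_that("adjusted effect matches an independent least-squares oracle", {
  # no genetic path to the exposure: adjustment changes nothing
  r0 <- adjusted_effect(gsens_input(0, 0.3, 0.3, 6000))
  expect_equal(r0$b_adjusted, r0$b_unadjusted, tolerance = 1e-12)
  expect_equal(r0$attenuation_pct, 0, tolerance = 1e-12)

  # fully confounded configuration r_xy = r_gx r_gy: adjusted effect 0
  r1 <- adjusted_effect(gsens_input(0.2, 0.3, 0.06, 6000))
  expect_equal(r1$b_adjusted, 0, tolerance = 1e-12)
  expect_equal(r1$attenuation_pct, 100, tolerance = 1e-12)

  # worked twin-heritability case against an OLS fit on exact-moment data
  M <- matrix(c(1, 0.35355339, 0.70710678,
                0.35355339, 1, 0.3,
                0.70710678, 0.3, 1), 3, 3,
              dimnames = rep(list(c("G", "X", "Y")), 2))
  X <- make_exact_cor_data(500, M, seed = 191)
  ols <- coef(lm(X[, "Y"] ~ X[, "X"] + X[, "G"]))[2]
  r2 <- adjusted_effect(gsens_input(0.35355339, 0.70710678, 0.3, 6000))
  expect_lt(abs(r2$b_adjusted - unname(ols)), 1e-10)
  expect_lt(abs(r2$b_adjusted - 0.0571), 5e-5)
  expect_lt(abs(r2$attenuation_pct - 81.0), 0.05)

  # brute-force agreement holds across arbitrary admissible inputs
  set.seed(192)
  for (i in 1:20) {
    r <- c(runif(2, -0.5, 0.5), runif(1, -0.5, 0.5))
    Mi <- matrix(c(1, r[1], r[2], r[1], 1, r[3], r[2], r[3], 1), 3, 3)
    if (min(eigen(Mi, only.values = TRUE)$values) < 0.05) next
    Xi <- make_exact_cor_data(200, Mi, seed = i)
    oi <- coef(lm(Xi[, 3] ~ Xi[, 2] + Xi[, 1]))[2]
    ri <- adjusted_effect(gsens_input(r[1], r[2], r[3], 1000))
    expect_equal(ri$b_adjusted, unname(oi), tolerance = 1e-10)
  }

  expect_error(adjusted_effect(gsens_input(0.9999999, 1e-4, 1e-4, 6000)),
               "near-singular|positive definite")
})

test_that("attenuation grows with the scenario heritability", {
  inp <- gsens_input(0.1, 0.2, 0.3, 6000)
  h2_grid <- seq(0.05, 0.95, by = 0.1)
  att <- sapply(h2_grid, function(h2)
    adjusted_effect(scale_to_heritability(inp, h2))$attenuation_pct)
  expect_true(all(diff(att) >= -1e-10))
})

test_that("scenario analysis separates confounded from causal cohorts", {
  # identical SNP and twin heritabilities give identical results
  inp <- gsens_input(0.1, 0.2, 0.3, 6000, h2_snp = 0.4, h2_twin = 0.4)
  sc <- scenario_analysis(inp)
  expect_identical(sc$snp_h2$b_adjusted, sc$twin_h2$b_adjusted)
  expect_warning(
    scenario_analysis(gsens_input(0.1, 0.2, 0.3, 6000,
                                  h2_snp = 0.6, h2_twin = 0.4)),
    "h2_snp")

  # purely confounded cohort: twin-heritability scenario removes the
  # association (averaged over replicate cohorts to tame the scaling noise)
  att <- sapply(1:10, function(i) {
    d <- simulate_gps_cohort(gps_sim_config(50000, h2_y = 0.5, r2_gps = 0.01,
                                            b_gx = 0.5, b_xy = 0,
                                            seed = 200 + i))
    tr <- attr(d, "truth")
    inp_i <- gsens_input(cor(d$GPS, d$X), cor(d$GPS, d$Y), cor(d$X, d$Y),
                         nrow(d), h2_snp = 0.15, h2_twin = tr$h2_total)
    sc_i <- scenario_analysis(inp_i)
    c(obs = sc_i$observed$attenuation_pct, twin = sc_i$twin_h2$attenuation_pct)
  })
  expect_lt(mean(att["obs", ]), 10)
  expect_lt(abs(mean(att["twin", ]) - 100), 5)

  # purely causal cohort: attenuation near zero in every scenario
  d2 <- simulate_gps_cohort(gps_sim_config(200000, h2_y = 0.5, r2_gps = 0.05,
                                           b_gx = 0, b_xy = 0.3, seed = 211))
  inp2 <- gsens_input(cor(d2$GPS, d2$X), cor(d2$GPS, d2$Y), cor(d2$X, d2$Y),
                      nrow(d2), h2_snp = 0.15, h2_twin = 0.5)
  sc2 <- scenario_analysis(inp2)
  expect_true(all(abs(sc2$table$attenuation_pct) < 3))
})

test_that("the twin scenario recovers a mixed causal effect", {
  d <- simulate_gps_cohort(gps_sim_config(100000, h2_y = 0.4, r2_gps = 0.02,
                                          b_gx = 0.4, b_xy = 0.2, seed = 221))
  tr <- attr(d, "truth")
  inp <- gsens_input(cor(d$GPS, d$X), cor(d$GPS, d$Y), cor(d$X, d$Y),
                     nrow(d), h2_snp = 0.15, h2_twin = tr$h2_total)
  sc <- scenario_analysis(inp)
  expect_lt(abs(sc$twin_h2$b_adjusted - 0.2), 0.02)
})

test_that("parametric bootstrap intervals are calibrated", {
  # population structure with known adjusted effect
  r_gx <- 0.2; r_gy <- 0.3; r_xy <- 0.25
  b_true <- (r_xy - r_gx * r_gy) / (1 - r_gx^2)
  M <- matrix(c(1, r_gx, r_gy, r_gx, 1, r_xy, r_gy, r_xy, 1), 3, 3)
  L <- chol(M)
  n <- 6000
  set.seed(231)
  cover <- 0L
  n_rep <- 300
  for (i in seq_len(n_rep)) {
    Z <- matrix(rnorm(n * 3), n, 3) %*% L
    C <- cor(Z)
    res <- adjusted_effect(gsens_input(C[1, 2], C[1, 3], C[2, 3], n),
                           bootstrap = TRUE, n_boot = 1000, seed = i)
    ci <- res$ci["b_adjusted", ]
    if (ci[1] <= b_true && b_true <= ci[2]) cover <- cover + 1L
  }
  expect_gte(cover / n_rep, 0.93)
  expect_lte(cover / n_rep, 0.97)
})
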