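test_that("cross-twin cross-trait correlations match the generative algebra", {
  # unrelated pseudo-pairs: all off-diagonals near zero
  set.seed(131)
  n <- 5000
  fake <- data.frame(family_id = seq_len(n),
                     zygosity = rep(c("MZ", "DZss"), length.out = n),
                     x_1 = rnorm(n), y_1 = rnorm(n),
                     x_2 = rnorm(n), y_2 = rnorm(n))
  ct0 <- cross_twin_cross_trait(fake)
  expect_lt(max(abs(ct0$MZ[upper.tri(ct0$MZ)])), 0.04)

  # duplicated trait: cross-twin cross-trait equals cross-twin same-trait
  dup <- fake
  dup$y_1 <- dup$x_1
  dup$y_2 <- dup$x_2
  ctd <- cross_twin_cross_trait(dup)
  expect_equal(ctd$MZ["x_1", "y_2"], ctd$MZ["x_1", "x_2"], tolerance = 1e-12)

  # genetic covariance only: MZ cross-twin cross-trait sqrt(a2x a2y) rA,
  # halved in DZ pairs
  d <- simulate_bivariate_twins(
    twin_sim_config(20000, 20000, a2 = c(0.5, 0.5), c2 = c(0, 0),
                    e2 = c(0.5, 0.5), rA = 0.8, rC = 0, rE = 0, seed = 132))
  ct <- cross_twin_cross_trait(d)
  expect_lt(abs(ct$MZ["x_1", "y_2"] - 0.40), 0.02)
  expect_lt(abs(ct$DZ["x_1", "y_2"] - 0.20), 0.02)
  expect_equal(diag(ct$MZ), rep(1, 4), ignore_attr = TRUE)
  expect_equal(ct$MZ, t(ct$MZ), tolerance = 1e-12)
})

test_that("bivariate Cholesky fit recovers the covariance decomposition", {
  # truth: cov_a / r_ph = 0.88, cov_c = 0, cov_e / r_ph = 0.12
  # (a2 = 0.5 both traits, rA = 0.55, rE = 0.075 -> r_ph = 0.3125)
  d <- simulate_bivariate_twins(
    twin_sim_config(20000, 20000, a2 = c(0.5, 0.5), c2 = c(0, 0),
                    e2 = c(0.5, 0.5), rA = 0.55, rC = 0, rE = 0.075,
                    seed = 141))
  f <- fit_bivariate_cholesky(d)
  expect_lt(abs(f$prop_a - 0.88), 0.05)
  expect_lt(abs(f$r_ph - 0.3125), 0.02)

  # decomposition identities
  expect_equal(f$cov_a + f$cov_c + f$cov_e, f$r_ph, tolerance = 1e-6)
  expect_equal(f$prop_a + f$prop_c + f$prop_e, 1, tolerance = 1e-6)

  # implied covariance matrices are positive semi-definite at the optimum
  for (kin in c(1, 0.5)) {
    Sg <- twinconfound:::biv_sigma(
      list(a2 = f$a2, c2 = f$c2, e2 = f$e2,
           cov_a = f$cov_a, cov_c = f$cov_c, cov_e = f$cov_e), kin)
    expect_gte(min(eigen(Sg, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }

  # nonshared-environment-only covariance
  d2 <- simulate_bivariate_twins(
    twin_sim_config(20000, 20000, a2 = c(0.4, 0.4), c2 = c(0, 0),
                    e2 = c(0.6, 0.6), rA = 0, rC = 0, rE = 0.5, seed = 142))
  f2 <- fit_bivariate_cholesky(d2)
  expect_lt(abs(f2$prop_e - 1), 0.05)
  expect_lt(abs(f2$prop_a - 0), 0.05)
})

test_that("duplicate trait reduces the decomposition to the univariate split", {
  d <- simulate_univariate_twins(
    twin_sim_config(5000, 5000, a2 = 0.5, c2 = 0.2, e2 = 0.3, seed = 143))
  d$y_1 <- d$trait_1
  d$y_2 <- d$trait_2
  d$x_1 <- d$trait_1
  d$x_2 <- d$trait_2
  expect_warning(f <- fit_bivariate_cholesky(d), "duplicates")
  uni <- fit_ace_ml_raw(d)
  expect_equal(f$r_ph, 1, tolerance = 1e-3)
  expect_lt(abs(f$prop_a - uni$a2), 0.02)
  expect_lt(abs(f$prop_c - uni$c2), 0.02)
  expect_lt(abs(f$prop_e - uni$e2), 0.02)
})

test_that("bivariate marginals agree with the univariate fits", {
  d <- simulate_bivariate_twins(
    twin_sim_config(20000, 20000, a2 = c(0.5, 0.3), c2 = c(0.1, 0.2),
                    e2 = c(0.4, 0.5), rA = 0.5, rC = 0.3, rE = 0.2,
                    seed = 144))
  f <- fit_bivariate_cholesky(d)
  fx <- fit_ace_ml_raw(d, "x")
  fy <- fit_ace_ml_raw(d, "y")
  expect_lt(abs(f$a2[1] - fx$a2), 0.01)
  expect_lt(abs(f$c2[1] - fx$c2), 0.01)
  expect_lt(abs(f$a2[2] - fy$a2), 0.01)
  expect_lt(abs(f$e2[2] - fy$e2), 0.01)
})

test_that("component correlations follow the Cholesky path algebra", {
  # no cross path: zero genetic correlation
  paths0 <- c(a11 = 0.7, a21 = 0, a22 = 0.5, c11 = 0.3, c21 = 0.1, c22 = 0.2,
              e11 = 0.6, e21 = 0.2, e22 = 0.5)
  expect_equal(unname(genetic_correlation(paths0)["rA"]), 0)

  # collinear genetic factors: rA = 1
  paths1 <- paths0
  paths1["a21"] <- 0.4
  paths1["a22"] <- 0
  expect_equal(unname(genetic_correlation(paths1)["rA"]), 1)

  # zero genetic variance: undefined with warning
  paths2 <- paths0
  paths2[c("a11")] <- 0
  expect_warning(rc <- genetic_correlation(paths2), "undefined")
  expect_true(is.na(rc[["rA"]]))

  # recovery of a simulated genetic correlation
  d <- simulate_bivariate_twins(
    twin_sim_config(20000, 20000, a2 = c(0.5, 0.5), c2 = c(0, 0),
                    e2 = c(0.5, 0.5), rA = 0.8, rC = 0, rE = 0, seed = 145))
  f <- fit_bivariate_cholesky(d)
  expect_lt(abs(genetic_correlation(f$paths)[["rA"]] - 0.8), 0.05)
})

test_that("near-zero phenotypic correlations trigger the precision guard", {
  d <- simulate_bivariate_twins(
    twin_sim_config(2000, 3000, a2 = c(0.5, 0.5), c2 = c(0, 0),
                    e2 = c(0.5, 0.5), rA = 0, rC = 0, rE = 0, seed = 146))
  expect_warning(fit_bivariate_cholesky(d), "low-precision")
})

test_that("bootstrap intervals on the proportions cover the point estimate", {
  d <- simulate_bivariate_twins(
    twin_sim_config(1500, 2500, a2 = c(0.5, 0.5), c2 = c(0, 0),
                    e2 = c(0.5, 0.5), rA = 0.55, rC = 0, rE = 0.075,
                    seed = 147))
  f <- fit_bivariate_cholesky(d, ci = "bootstrap", n_boot = 50, seed = 7)
  expect_true(f$ci["prop_a", "lower"] <= f$prop_a &&
                f$prop_a <= f$ci["prop_a", "upper"])
})
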