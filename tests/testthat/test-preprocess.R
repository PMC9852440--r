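test_that("residualize removes age/sex signal and flags degenerate input", {
  set.seed(61)
  n <- 10000
  age <- rnorm(n, 22, 1)
  sex <- rbinom(n, 1, 0.5)

  # no-op limit: phenotype unrelated to covariates survives (up to scaling)
  y0 <- rnorm(n)
  expect_gt(cor(residualize(y0, age, sex), y0), 0.999)

  # OLS orthogonality: engineered cor(y, age) = 0.6 is removed
  y1 <- scale(age)[, 1] * 0.6 + sqrt(1 - 0.36) * rnorm(n)
  expect_gt(abs(cor(y1, age)), 0.55)
  expect_lt(abs(cor(residualize(y1, age, sex), age)), 0.02)

  # exact linear function of age: degenerate, flagged
  expect_warning(r <- residualize(2 * age, age, sex), "zero")
  expect_true(isTRUE(attr(r, "degenerate")))

  # constant covariate skipped with warning
  expect_warning(residualize(y0, age, rep(1, n)), "constant")

  # missingness propagates
  y0[c(3, 7)] <- NA
  expect_true(all(is.na(residualize(y0, age, sex)[c(3, 7)])))
})

test_that("van der Waerden transform maps ranks onto normal quantiles", {
  # quartile oracle: ranks 1..3 over n+1 = 4 -> Phi^-1(0.25, 0.5, 0.75)
  expect_equal(vdw_transform(c(1, 2, 3)),
               qnorm(c(0.25, 0.5, 0.75)), tolerance = 1e-12)

  # median of an odd-length tie-free vector maps to exactly 0
  x <- c(10, 3, 8, 1, 5)
  expect_identical(vdw_transform(x)[x == 5], 0)

  # heavy skew is corrected by construction of the rank map
  set.seed(62)
  skewed <- warp_skew(rnorm(5000), 1.5)
  expect_gt(abs(sample_skewness(skewed)), 1)
  expect_lt(abs(sample_skewness(vdw_transform(skewed))), 0.1)

  # monotone on the tie-free subset; ties get average ranks
  set.seed(63)
  z <- rnorm(100)
  expect_equal(cor(vdw_transform(z), z, method = "spearman"), 1)
  expect_equal(vdw_transform(c(1, 1, 2))[1], vdw_transform(c(1, 1, 2))[2])

  # degenerate input
  expect_error(vdw_transform(rep(1, 10)), "identical")
  expect_error(vdw_transform(c(1, 2)), "at least 3")
})

test_that("double-entry intraclass correlation behaves as a twin ICC", {
  cfg <- twin_sim_config(200, 300, a2 = 0.5, c2 = 0.2, e2 = 0.3, seed = 71)
  d <- simulate_univariate_twins(cfg)

  # identical co-twins: exactly 1
  d1 <- d
  d1$trait_2 <- d1$trait_1
  expect_equal(intraclass_correlation(d1, "MZ")$r, 1, tolerance = 1e-12)

  # independent co-twins: near 0
  set.seed(72)
  d2 <- simulate_univariate_twins(
    twin_sim_config(5000, 5000, a2 = 0, c2 = 0, e2 = 1, seed = 72))
  expect_lt(abs(intraclass_correlation(d2, "MZ")$r), 0.03)

  # converges to a2 + c2 under the generative model
  d3 <- simulate_univariate_twins(
    twin_sim_config(20000, 100, a2 = 0.43, c2 = 0, e2 = 0.57, seed = 73))
  expect_lt(abs(intraclass_correlation(d3, "MZ")$r - 0.43), 0.02)

  # exact invariance to within-pair ordering
  d4 <- d
  flip <- seq(1, nrow(d4), by = 2)
  tmp <- d4$trait_1[flip]
  d4$trait_1[flip] <- d4$trait_2[flip]
  d4$trait_2[flip] <- tmp
  expect_equal(intraclass_correlation(d4, "DZ")$r,
               intraclass_correlation(d, "DZ")$r, tolerance = 1e-12)

  # report structure
  rep <- intraclass_correlation(d, "MZ")
  expect_true(rep$ci_low <= rep$r && rep$r <= rep$ci_high)
  expect_identical(rep$n, 200L)
  expect_error(intraclass_correlation(d[d$zygosity != "MZ", ], "MZ"),
               "at least 3")
})

test_that("FDR adjustment matches the brute-force step-up rule", {
  # the worked adjustment of (0.002, 0.01, 0.03, 0.04)
  expect_equal(bh_bruteforce(c(0.002, 0.01, 0.03, 0.04)),
               c(0.008, 0.020, 0.040, 0.040), tolerance = 1e-12)

  # p.adjust (used internally) agrees with the definition on random vectors
  set.seed(81)
  for (i in 1:1000) {
    p <- runif(sample(1:12, 1))
    expect_equal(p.adjust(p, "BH"), bh_bruteforce(p), tolerance = 1e-12)
  }
})

test_that("correlation matrix reports are FDR-controlled and well-formed", {
  set.seed(82)
  n <- 2000
  left <- data.frame(m1 = rnorm(n), m2 = rnorm(n))
  right <- data.frame(h1 = rnorm(n), h2 = rnorm(n))
  right$h1 <- 0.3 * left$m1 + sqrt(1 - 0.09) * right$h1
  out <- correlation_matrix_fdr(left, right)
  expect_identical(nrow(out), 4L)
  expect_true(all(out$p_fdr >= out$p_raw - 1e-15))
  expect_true(all(out$ci_low <= out$r & out$r <= out$ci_high))
  expect_equal(out$p_fdr, bh_bruteforce(out$p_raw), tolerance = 1e-12)

  # single test: adjustment is a no-op
  one <- correlation_matrix_fdr(left["m1"], right["h1"])
  expect_equal(one$p_fdr, one$p_raw)

  # zero-variance variable gives a missing cell
  left$m2 <- 1
  expect_true(is.na(suppressWarnings(
    correlation_matrix_fdr(left, right))$r[2]))
})

test_that("FDR keeps the null false-discovery fraction at its nominal level", {
  set.seed(83)
  n <- 5000
  hits <- 0L
  cells <- 0L
  for (rep in 1:200) {
    left <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("m", 1:3)))
    right <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("h", 1:3)))
    out <- correlation_matrix_fdr(left, right)
    hits <- hits + sum(out$p_fdr < 0.05)
    cells <- cells + nrow(out)
  }
  tol <- 2 * sqrt(0.05 * 0.95 / cells)
  expect_lte(hits / cells, 0.05 + tol)
})

test_that("sex and zygosity ANOVA returns calibrated variance shares", {
  cfg <- twin_sim_config(2000, 3000, a2 = 0.4, c2 = 0.1, e2 = 0.5, seed = 91)
  d <- select_one_per_pair(simulate_univariate_twins(cfg), seed = 91)

  # phenotype equal to sex: all variance to sex
  d_sex <- d
  d_sex$phenotype <- d_sex$sex
  out <- variance_by_sex_zygosity(d_sex)
  expect_equal(out$eta2_sex, 1, tolerance = 1e-9)

  # engineered 20% variance share for the zygosity contrast
  set.seed(92)
  z <- as.numeric(d$zygosity == "MZ")
  eff <- sqrt(0.2 / var(z))
  d_eng <- d
  d_eng$phenotype <- eff * z + sqrt(0.8) * rnorm(nrow(d))
  out2 <- variance_by_sex_zygosity(d_eng)
  expect_lt(abs(out2$eta2_joint - 0.2), 0.03)

  # null phenotype: joint share < 1% in at least 95% of seeded replicates
  ok <- 0L
  set.seed(93)
  for (rep in 1:100) {
    d$phenotype <- rnorm(nrow(d))
    if (variance_by_sex_zygosity(d)$eta2_joint < 0.01) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("Cronbach's alpha follows the variance-ratio definition", {
  # two standardized items with r = 0.5: alpha = 2 (1 - 2/3) = 2/3
  M <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  items <- make_exact_cor_data(500, M, seed = 101)
  expect_equal(cronbach_alpha(items), 2 / 3, tolerance = 1e-10)

  # identical items: exactly 1
  x <- rnorm(100)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1, tolerance = 1e-12)

  # independent items: near 0
  set.seed(102)
  expect_lt(abs(cronbach_alpha(matrix(rnorm(10000 * 6), ncol = 6))), 0.05)

  expect_error(cronbach_alpha(matrix(1, 5, 2)), "zero variance")
})
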