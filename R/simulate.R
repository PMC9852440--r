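#' @keywords internal
#' @details
#' Derive a per-operation RNG seed from the global seed so that different
#' generators called with the same cohort seed draw from distinct but
#' reproducible streams. The result always fits in a 32-bit integer.
#' @noRd
stream_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

#' Draw n pairs of standard normals with a given correlation
#' @noRd
corr_pair <- function(n, r) {
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  cbind(z1, r * z1 + sqrt(1 - r^2) * z2)
}

#' Configuration for a synthetic twin cohort
#'
#' Defines the generative ACE model for one trait (univariate) or two traits
#' (bivariate). Variance components are proportions of a unit-variance latent
#' phenotype; additive genetic factors correlate 1 between monozygotic (MZ)
#' co-twins and 0.5 between dizygotic (DZ) co-twins, the shared environment C
#' is identical within a pair, and the nonshared environment E is drawn
#' independently per twin.
#'
#' @param n_mz,n_dz Number of MZ and DZ pairs (each at least 1).
#' @param a2,c2,e2 Variance proportions of the additive genetic, shared
#'   environmental and nonshared environmental components; length 1
#'   (univariate) or 2 (bivariate), each row summing to 1.
#' @param rA,rC,rE Cross-trait correlations of the A, C and E factors
#'   (bivariate cohorts only), each in `[-1, 1]`.
#' @param beta_age,beta_sex Fixed-effect slopes of age (years) and sex (0/1)
#'   added to the raw phenotype before any standardization; defaults 0.
#' @param traits Trait names used for the phenotype columns; defaults to
#'   `"trait"` (univariate) or `c("x", "y")` (bivariate).
#' @param seed Integer seed; every generator derives its stream from it, so
#'   identical configurations yield bit-identical cohorts.
#' @return An object of class `twin_sim_config`.
#' @export
twin_sim_config <- function(n_mz, n_dz, a2, c2, e2,
                            rA = 0, rC = 0, rE = 0,
                            beta_age = 0, beta_sex = 0,
                            traits = NULL, seed = 1L) {
  k <- length(a2)
  if (!(k %in% c(1L, 2L)) || length(c2) != k || length(e2) != k)
    stop("a2, c2, e2 must share length 1 (univariate) or 2 (bivariate)",
         call. = FALSE)
  if (length(n_mz) != 1 || length(n_dz) != 1 || n_mz < 1 || n_dz < 1)
    stop("n_mz and n_dz must each be at least 1", call. = FALSE)
  comp <- cbind(a2, c2, e2)
  if (any(!is.finite(comp)) || any(comp < 0) || any(comp > 1))
    stop("each variance component must lie in [0, 1]", call. = FALSE)
  if (any(abs(rowSums(comp) - 1) > 1e-12))
    stop("a2 + c2 + e2 must equal 1 for each trait (tolerance 1e-12)",
         call. = FALSE)
  if (any(abs(c(rA, rC, rE)) > 1))
    stop("rA, rC, rE must lie in [-1, 1]", call. = FALSE)
  if (is.null(traits)) traits <- if (k == 1L) "trait" else c("x", "y")
  if (length(traits) != k) stop("need one trait name per trait", call. = FALSE)
  structure(
    list(n_mz = as.integer(n_mz), n_dz = as.integer(n_dz),
         a2 = a2, c2 = c2, e2 = e2, rA = rA, rC = rC, rE = rE,
         beta_age = beta_age, beta_sex = beta_sex,
         traits = traits, seed = as.integer(seed)),
    class = "twin_sim_config")
}

## Shared scaffolding for a cohort: family ids, zygosity, sexes, ages.
## DZ pairs get independently drawn sexes and are labelled DZss/DZos by
## outcome; no sex-limitation model is simulated.
sim_pair_frame <- function(n_mz, n_dz) {
  n <- n_mz + n_dz
  is_mz <- rep(c(TRUE, FALSE), c(n_mz, n_dz))
  sex1 <- stats::rbinom(n, 1L, 0.5)
  sex2 <- ifelse(is_mz, sex1, stats::rbinom(n, 1L, 0.5))
  zyg <- ifelse(is_mz, "MZ", ifelse(sex1 == sex2, "DZss", "DZos"))
  data.frame(family_id = sprintf("fam%06d", seq_len(n)),
             zygosity = zyg, sex1 = sex1, sex2 = sex2,
             age = stats::rnorm(n, 22.14, 0.85),
             stringsAsFactors = FALSE)
}

#' Simulate a univariate twin cohort under a known ACE model
#'
#' Each co-twin phenotype is `sqrt(a2) * A + sqrt(c2) * C + sqrt(e2) * E`
#' (plus any fixed age/sex effects), where the A factors of co-twins
#' correlate 1 (MZ) or 0.5 (DZ), C is pair-shared and E is independent per
#' twin, so population intraclass correlations are `a2 + c2` (MZ) and
#' `a2/2 + c2` (DZ).
#'
#' @param config A univariate [twin_sim_config()].
#' @return A data frame with one row per pair (`family_id`, `zygosity`,
#'   `sex1`, `sex2`, `age`, `<trait>_1`, `<trait>_2`) carrying the generating
#'   parameters in `attr(, "truth")`.
#' @export
simulate_univariate_twins <- function(config) {
  stopifnot(inherits(config, "twin_sim_config"))
  if (length(config$a2) != 1L)
    stop("univariate simulation needs scalar a2/c2/e2; see simulate_bivariate_twins",
         call. = FALSE)
  set.seed(stream_seed(config$seed, 101L))
  d <- sim_pair_frame(config$n_mz, config$n_dz)
  n <- nrow(d)
  k_a <- ifelse(d$zygosity == "MZ", 1, 0.5)
  A_sh <- stats::rnorm(n)
  A1 <- sqrt(k_a) * A_sh + sqrt(1 - k_a) * stats::rnorm(n)
  A2 <- sqrt(k_a) * A_sh + sqrt(1 - k_a) * stats::rnorm(n)
  C <- stats::rnorm(n)
  with_fixed <- function(latent, sex) {
    latent + config$beta_age * d$age + config$beta_sex * sex
  }
  p1 <- with_fixed(sqrt(config$a2) * A1 + sqrt(config$c2) * C +
                     sqrt(config$e2) * stats::rnorm(n), d$sex1)
  p2 <- with_fixed(sqrt(config$a2) * A2 + sqrt(config$c2) * C +
                     sqrt(config$e2) * stats::rnorm(n), d$sex2)
  d[[paste0(config$traits[1], "_1")]] <- p1
  d[[paste0(config$traits[1], "_2")]] <- p2
  attr(d, "truth") <- unclass(config)
  d
}

#' Simulate a bivariate twin cohort with cross-trait factor correlations
#'
#' Generates two traits whose A/C/E factors correlate `rA`/`rC`/`rE` across
#' traits, so that the within-twin cross-trait covariance is
#' `sqrt(a2x a2y) rA + sqrt(c2x c2y) rC + sqrt(e2x e2y) rE`, the MZ
#' cross-twin cross-trait covariance drops the E term and the DZ one halves
#' the A term — the structure bivariate Cholesky twin models identify.
#'
#' @param config A bivariate [twin_sim_config()] (length-2 components).
#' @return A data frame with per-pair columns `<x>_1, <x>_2, <y>_1, <y>_2`
#'   and the generating parameters in `attr(, "truth")`.
#' @export
simulate_bivariate_twins <- function(config) {
  stopifnot(inherits(config, "twin_sim_config"))
  if (length(config$a2) != 2L)
    stop("bivariate simulation needs length-2 a2/c2/e2", call. = FALSE)
  set.seed(stream_seed(config$seed, 202L))
  d <- sim_pair_frame(config$n_mz, config$n_dz)
  n <- nrow(d)
  k_a <- ifelse(d$zygosity == "MZ", 1, 0.5)
  A_sh <- corr_pair(n, config$rA)
  A1 <- sqrt(k_a) * A_sh + sqrt(1 - k_a) * corr_pair(n, config$rA)
  A2 <- sqrt(k_a) * A_sh + sqrt(1 - k_a) * corr_pair(n, config$rA)
  C <- corr_pair(n, config$rC)
  E1 <- corr_pair(n, config$rE)
  E2 <- corr_pair(n, config$rE)
  sa <- sqrt(config$a2); sc <- sqrt(config$c2); se <- sqrt(config$e2)
  for (t in 1:2) {
    p1 <- sa[t] * A1[, t] + sc[t] * C[, t] + se[t] * E1[, t] +
      config$beta_age * d$age + config$beta_sex * d$sex1
    p2 <- sa[t] * A2[, t] + sc[t] * C[, t] + se[t] * E2[, t] +
      config$beta_age * d$age + config$beta_sex * d$sex2
    d[[paste0(config$traits[t], "_1")]] <- p1
    d[[paste0(config$traits[t], "_2")]] <- p2
  }
  attr(d, "truth") <- unclass(config)
  d
}

#' Configuration for a synthetic polygenic-score cohort
#'
#' Ground-truth model for testing the genetic-confounding sensitivity
#' analysis: a latent genetic factor G influences an exposure X (path
#' `b_gx`) and an outcome Y (heritability `h2_y` at `b_xy = 0`), X may have
#' a direct causal effect on Y (`b_xy`), and the observed polygenic score is
#' a noisy proxy of G calibrated to explain `r2_gps` of the outcome
#' variance.
#'
#' @param n Number of unrelated individuals.
#' @param h2_y Outcome heritability (variance explained by G at `b_xy = 0`).
#' @param r2_gps Outcome variance explained by the observed score; must not
#'   exceed `h2_y`.
#' @param b_gx Standardized path from G to the exposure, in `[-1, 1]`.
#' @param b_xy Standardized causal exposure-to-outcome path.
#' @param seed Integer seed.
#' @return An object of class `gps_sim_config`.
#' @export
gps_sim_config <- function(n, h2_y, r2_gps, b_gx, b_xy, seed = 1L) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (r2_gps < 0 || h2_y > 1 || r2_gps > h2_y)
    stop("need 0 <= r2_gps <= h2_y <= 1", call. = FALSE)
  if (abs(b_gx) > 1) stop("|b_gx| must not exceed 1", call. = FALSE)
  b_gy <- sqrt(h2_y)
  v_res <- 1 - b_xy^2 - b_gy^2 - 2 * b_xy * b_gx * b_gy
  if (v_res < -1e-12)
    stop("implied outcome variance exceeds 1; reduce b_xy or h2_y",
         call. = FALSE)
  structure(list(n = as.integer(n), h2_y = h2_y, r2_gps = r2_gps,
                 b_gx = b_gx, b_xy = b_xy, b_gy = b_gy,
                 v_res = max(v_res, 0), seed = as.integer(seed)),
            class = "gps_sim_config")
}

#' Simulate a polygenic-score cohort with known confounding structure
#'
#' Draws `G ~ N(0, 1)`, `X = b_gx G + e_x` and
#' `Y = b_xy X + sqrt(h2_y) G + e_y`, each standardized to unit variance,
#' and an observed score `GPS = lambda G + e_g` with
#' `lambda = sqrt(r2_gps / h2_y)`, so that at `b_xy = 0` the squared
#' score-outcome correlation equals `r2_gps`.
#'
#' @param config A [gps_sim_config()].
#' @return A data frame with columns `G_latent`, `GPS`, `X`, `Y`; the
#'   population correlations and total genetic variance of Y implied by the
#'   configuration are attached as `attr(, "truth")`.
#' @export
simulate_gps_cohort <- function(config) {
  stopifnot(inherits(config, "gps_sim_config"))
  set.seed(stream_seed(config$seed, 303L))
  n <- config$n
  G <- stats::rnorm(n)
  X <- config$b_gx * G + sqrt(1 - config$b_gx^2) * stats::rnorm(n)
  Y <- config$b_xy * X + config$b_gy * G + sqrt(config$v_res) * stats::rnorm(n)
  lambda <- if (config$h2_y > 0) sqrt(config$r2_gps / config$h2_y) else 0
  GPS <- lambda * G + sqrt(1 - lambda^2) * stats::rnorm(n)
  out <- data.frame(G_latent = G, GPS = GPS, X = X, Y = Y)
  g_total <- config$b_xy * config$b_gx + config$b_gy
  attr(out, "truth") <- c(unclass(config), list(
    lambda = lambda,
    r_gx = lambda * config$b_gx,
    r_gy = lambda * g_total,
    r_xy = config$b_xy + config$b_gx * config$b_gy,
    h2_total = g_total^2))
  out
}

#' Simulate a battery of mutually independent polygenic scores
#'
#' Produces `length(r)` independent standardized scores and a phenotype whose
#' population correlation with score i is `r[i]`; `sum(r^2)` must stay below
#' 1. Used to exercise the per-score and joint regression analyses against
#' known effect sizes in the sub-0.1 regime typical of polygenic prediction.
#'
#' @param n Individuals.
#' @param r Vector of true score-phenotype correlations (one per score).
#' @param score_names Optional column names; defaults to `gps1..gpsk`.
#' @param seed Integer seed.
#' @return A list with `scores` (n x k matrix) and `phenotype` (length-n
#'   vector).
#' @export
simulate_score_battery <- function(n, r, score_names = NULL, seed = 1L) {
  k <- length(r)
  if (sum(r^2) >= 1) stop("sum(r^2) must be < 1", call. = FALSE)
  set.seed(stream_seed(seed, 404L))
  S <- matrix(stats::rnorm(n * k), n, k)
  colnames(S) <- if (is.null(score_names)) paste0("gps", seq_len(k)) else score_names
  phen <- drop(S %*% r) + sqrt(1 - sum(r^2)) * stats::rnorm(n)
  list(scores = S, phenotype = phen)
}

#' Monotone exponential warp to induce skewness
#'
#' Applies `(exp(lambda * x) - 1) / lambda`, a strictly increasing map that
#' skews a Gaussian variable while preserving ranks, so the latent ACE truth
#' is exactly recoverable after a rank-based inverse-normal transform.
#'
#' @param x Numeric vector.
#' @param lambda Warp strength; `lambda -> 0` recovers the identity.
#' @return Warped numeric vector.
#' @export
warp_skew <- function(x, lambda = 1) {
  if (abs(lambda) < 1e-12) return(x)
  (exp(lambda * x) - 1) / lambda
}
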