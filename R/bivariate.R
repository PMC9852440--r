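## Bivariate ACE (Cholesky) decomposition of the covariance between two
## traits. Identification comes from cross-twin cross-trait correlations:
## within-twin cross-trait cov = covA + covC + covE, MZ cross-twin
## cross-trait cov = covA + covC, DZ cross-twin cross-trait cov =
## covA/2 + covC, where covK = sqrt(k2_x k2_y) * rK.

RPH_GUARD <- 0.05

#' Per-zygosity cross-twin cross-trait correlation matrices
#'
#' Double-entered 4x4 Pearson correlation matrices over
#' (trait X twin 1, trait Y twin 1, trait X twin 2, trait Y twin 2), the
#' summary statistics that identify the bivariate twin model.
#'
#' @param pairs Twin-pair data frame carrying both traits.
#' @param traits Length-2 character vector of trait names.
#' @return A list with symmetric unit-diagonal matrices `MZ` and `DZ` and
#'   the complete-pair counts `n`.
#' @export
cross_twin_cross_trait <- function(pairs, traits = c("x", "y")) {
  stopifnot(length(traits) == 2)
  tx <- pair_trait(pairs, traits[1])
  ty <- pair_trait(pairs, traits[2])
  grp <- zyg_group(pairs$zygosity)
  ok <- !is.na(tx$t1) & !is.na(tx$t2) & !is.na(ty$t1) & !is.na(ty$t2) & !is.na(grp)
  nm <- c(paste0(traits, "_1"), paste0(traits, "_2"))
  out <- lapply(c(MZ = "MZ", DZ = "DZ"), function(g) {
    sel <- ok & grp == g
    if (sum(sel) < 20)
      stop("need at least 20 complete ", g, " pairs", call. = FALSE)
    X <- cbind(tx$t1[sel], ty$t1[sel], tx$t2[sel], ty$t2[sel])
    de <- rbind(X, X[, c(3, 4, 1, 2)])  # double entry: both pair orderings
    m <- stats::cor(de)
    dimnames(m) <- list(nm, nm)
    m
  })
  out$n <- c(MZ = sum(ok & grp == "MZ"), DZ = sum(ok & grp == "DZ"))
  out
}

## Map the 7 free parameters (per-trait simplex coordinates + component
## correlations) to variance components and cross-trait covariances.
biv_par_expand <- function(par) {
  ax <- uv_to_ace(par[1:2]); ay <- uv_to_ace(par[3:4])
  a2 <- c(ax[1], ay[1]); c2 <- c(ax[2], ay[2])
  e2 <- pmax(1 - a2 - c2, 0)  # guard roundoff at the u = 1 boundary
  list(a2 = unname(a2), c2 = unname(c2), e2 = unname(e2),
       cov_a = sqrt(prod(a2)) * par[5],
       cov_c = sqrt(prod(c2)) * par[6],
       cov_e = sqrt(prod(e2)) * par[7])
}

## Model-implied 4x4 covariance of (x1, y1, x2, y2) for one zygosity group.
biv_sigma <- function(p, kin) {
  rph <- p$cov_a + p$cov_c + p$cov_e
  W <- matrix(c(1, rph, rph, 1), 2, 2)
  cross_diag <- kin * p$a2 + p$c2
  cross_off <- kin * p$cov_a + p$cov_c
  B <- matrix(c(cross_diag[1], cross_off, cross_off, cross_diag[2]), 2, 2)
  rbind(cbind(W, B), cbind(B, W))
}

mvn_negll <- function(S, n, Sigma) {
  # a fixed small ridge keeps the objective smooth through the singular
  # boundary reached by (near-)duplicate traits; negligible elsewhere
  ch <- tryCatch(chol(Sigma + diag(1e-8, nrow(Sigma))),
                 error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  logdet <- 2 * sum(log(diag(ch)))
  inv <- chol2inv(ch)
  0.5 * (n * (4 * log(2 * pi) + logdet) + sum(inv * S))
}

#' Fit the bivariate ACE Cholesky model to raw twin pairs
#'
#' Maximizes the 4-variate normal likelihood of (x1, y1, x2, y2) per
#' zygosity group (means 0, unit variances fixed; phenotypes assumed
#' standardized), returning the Cholesky path coefficients and the
#' decomposition of the phenotypic correlation into genetic, shared- and
#' nonshared-environmental covariance, with the proportions rphA, rphC,
#' rphE of the correlation each component mediates.
#'
#' @param pairs Twin-pair data frame with both traits and both zygosity
#'   groups.
#' @param traits Length-2 trait names.
#' @param ci `"none"` (default) or `"bootstrap"` for nonparametric
#'   pair-resampling percentile intervals on the proportions.
#' @param n_boot Bootstrap replicates (default 200).
#' @param level CI level.
#' @param seed Seed for the bootstrap resampling.
#' @return A list of class `biv_fit`: `paths` (a11 ... e22), `a2`, `c2`,
#'   `e2` per trait, `r_ph`, `cov_a`/`cov_c`/`cov_e`, `prop_a`/`prop_c`/
#'   `prop_e`, component correlations `rA`/`rC`/`rE`, `loglik`, and `ci`
#'   when requested. When `|r_ph| < 0.05` the proportions are unstable and
#'   a low-precision warning is raised.
#' @export
fit_bivariate_cholesky <- function(pairs, traits = c("x", "y"),
                                   ci = c("none", "bootstrap"),
                                   n_boot = 200, level = 0.95, seed = 1L) {
  ci <- match.arg(ci)
  fit <- biv_fit_core(pairs, traits)
  if (abs(fit$r_ph) < RPH_GUARD)
    warning("phenotypic correlation |r_ph| < ", RPH_GUARD,
            "; proportions of a near-zero correlation are low-precision")
  if (ci == "bootstrap") {
    set.seed(stream_seed(seed, 606L))
    grp <- zyg_group(pairs$zygosity)
    idx_mz <- which(grp == "MZ"); idx_dz <- which(grp == "DZ")
    props <- matrix(NA_real_, n_boot, 3,
                    dimnames = list(NULL, c("prop_a", "prop_c", "prop_e")))
    for (b in seq_len(n_boot)) {
      bi <- c(sample(idx_mz, replace = TRUE), sample(idx_dz, replace = TRUE))
      bf <- try(biv_fit_core(pairs[bi, ], traits), silent = TRUE)
      if (!inherits(bf, "try-error"))
        props[b, ] <- c(bf$prop_a, bf$prop_c, bf$prop_e)
    }
    alpha <- (1 - level) / 2
    fit$ci <- t(apply(props, 2, stats::quantile,
                      probs = c(alpha, 1 - alpha), na.rm = TRUE))
    colnames(fit$ci) <- c("lower", "upper")
    fit$ci_level <- level
  }
  fit
}

## Falconer-style moment start from the double-entered per-group
## correlation structure: per-trait components from same-trait cross-twin
## correlations, cross-trait covariances from the cross-twin cross-trait
## contrast covA = 2 (c_mz - c_dz), covC = 2 c_dz - c_mz, covE = r_w - c_mz.
biv_moment_start <- function(stats_g) {
  clip01 <- function(x) min(max(x, 0), 1)
  # same-trait cross-twin correlations (double-entered)
  r_cross <- function(st, i) (st$S[i, i + 2]) / sqrt(st$S[i, i] * st$S[i + 2, i + 2])
  par <- numeric(7)
  a2 <- c2 <- numeric(2)
  for (t in 1:2) {
    rmz <- r_cross(stats_g$MZ, t)
    rdz <- r_cross(stats_g$DZ, t)
    a2[t] <- clip01(2 * (rmz - rdz))
    c2[t] <- clip01(rmz - a2[t])
    tot <- a2[t] + c2[t]
    if (tot > 0.98) { a2[t] <- a2[t] / tot * 0.98; c2[t] <- c2[t] / tot * 0.98 }
    u <- a2[t] + c2[t]
    par[2 * t - 1] <- u
    par[2 * t] <- if (u > 0) c2[t] / u else 0
  }
  # cross-trait correlations: within-twin and cross-twin per group
  xt <- function(st) {
    de <- (st$S[1, 4] + st$S[2, 3]) / 2
    de / sqrt((st$S[1, 1] + st$S[3, 3]) / 2 * (st$S[2, 2] + st$S[4, 4]) / 2)
  }
  r_w <- (stats_g$MZ$S[1, 2] / sqrt(stats_g$MZ$S[1, 1] * stats_g$MZ$S[2, 2]) +
            stats_g$DZ$S[1, 2] / sqrt(stats_g$DZ$S[1, 1] * stats_g$DZ$S[2, 2])) / 2
  c_mz <- xt(stats_g$MZ)
  c_dz <- xt(stats_g$DZ)
  cov_a <- 2 * (c_mz - c_dz)
  cov_c <- 2 * c_dz - c_mz
  cov_e <- r_w - c_mz
  clip1 <- function(x) min(max(x, -1), 1)
  e2 <- 1 - a2 - c2
  rden <- function(v2) if (prod(v2) > 1e-6) sqrt(prod(v2)) else 1
  par[5] <- clip1(cov_a / rden(a2))
  par[6] <- clip1(cov_c / rden(c2))
  par[7] <- clip1(cov_e / rden(e2))
  par
}

## Exact singular limit for duplicated traits: the covariance decomposition
## equals the univariate variance decomposition of the (shared) trait, with
## component correlations +-1.
biv_duplicate_reduction <- function(pairs, traits, sgn) {
  uni <- fit_ace_ml_raw(pairs, traits[1])
  v2 <- c(uni$a2, uni$c2, uni$e2)
  paths <- c(a11 = sqrt(uni$a2), a21 = sgn * sqrt(uni$a2), a22 = 0,
             c11 = sqrt(uni$c2), c21 = sgn * sqrt(uni$c2), c22 = 0,
             e11 = sqrt(uni$e2), e21 = sgn * sqrt(uni$e2), e22 = 0)
  structure(list(
    traits = traits, paths = paths,
    a2 = rep(uni$a2, 2), c2 = rep(uni$c2, 2), e2 = rep(uni$e2, 2),
    r_ph = sgn, cov_a = sgn * uni$a2, cov_c = sgn * uni$c2,
    cov_e = sgn * uni$e2,
    prop_a = uni$a2, prop_c = uni$c2, prop_e = uni$e2,
    rA = if (uni$a2 > 1e-8) sgn else NA_real_,
    rC = if (uni$c2 > 1e-8) sgn else NA_real_,
    rE = if (uni$e2 > 1e-8) sgn else NA_real_,
    loglik = NA_real_, n = uni$n), class = "biv_fit")
}

biv_fit_core <- function(pairs, traits) {
  tx <- pair_trait(pairs, traits[1])
  ty <- pair_trait(pairs, traits[2])
  grp <- zyg_group(pairs$zygosity)
  ok <- !is.na(tx$t1) & !is.na(tx$t2) & !is.na(ty$t1) & !is.na(ty$t2) & !is.na(grp)
  stats_g <- lapply(c(MZ = "MZ", DZ = "DZ"), function(g) {
    sel <- ok & grp == g
    X <- cbind(tx$t1[sel], ty$t1[sel], tx$t2[sel], ty$t2[sel])
    list(n = nrow(X), S = crossprod(X))
  })
  if (stats_g$MZ$n < 20 || stats_g$DZ$n < 20)
    stop("need at least 20 complete pairs per zygosity group", call. = FALSE)
  # (near-)duplicate traits make the 4-variate model singular; the
  # decomposition then reduces exactly to the univariate ACE split
  r_w <- (stats_g$MZ$S[1, 2] + stats_g$DZ$S[1, 2]) /
    sqrt((stats_g$MZ$S[1, 1] + stats_g$DZ$S[1, 1]) *
           (stats_g$MZ$S[2, 2] + stats_g$DZ$S[2, 2]))
  if (abs(r_w) > 0.999) {
    warning("traits are (near) duplicates (|r| > 0.999); returning the ",
            "univariate ACE reduction of the decomposition")
    return(biv_duplicate_reduction(pairs, traits, sign(r_w)))
  }
  lo <- c(0, 0, 0, 0, -1, -1, -1)
  hi <- rep(1, 7)
  obj <- function(par) {
    # numeric gradients probe just outside the box: clamp first
    p <- biv_par_expand(pmin(pmax(par, lo), hi))
    v <- mvn_negll(stats_g$MZ$S, stats_g$MZ$n, biv_sigma(p, 1)) +
      mvn_negll(stats_g$DZ$S, stats_g$DZ$n, biv_sigma(p, 0.5))
    if (!is.finite(v)) 1e10 else v
  }
  starts <- rbind(biv_moment_start(stats_g),
                  c(0.5, 0.3, 0.5, 0.3, 0.3, 0.3, 0.3),
                  c(0.4, 0.1, 0.4, 0.1, 0.7, 0.0, 0.1),
                  c(0.6, 0.5, 0.6, 0.5, -0.3, 0.3, 0.0),
                  c(0.3, 0.2, 0.7, 0.4, 0.0, 0.0, 0.5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- try(stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                          lower = lo, upper = hi,
                          control = list(factr = 1e4, maxit = 1000)),
             silent = TRUE)
    if (inherits(f, "try-error")) next
    if (is.null(best) || f$value < best$value) best <- f
  }
  if (is.null(best))
    stop("bivariate Cholesky optimizer failed to converge", call. = FALSE)
  # Nelder-Mead polish; L-BFGS-B can stall on the boundary ridges that
  # arise for (near-)degenerate trait pairs
  pol <- stats::optim(best$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  if (pol$value <= best$value)
    best <- list(par = pmin(pmax(pol$par, lo), hi), value = pol$value)
  p <- biv_par_expand(best$par)
  r_ph <- p$cov_a + p$cov_c + p$cov_e
  path_tri <- function(v2, cov) {
    # lower-triangular paths for one component: trait1 loading, cross path,
    # trait2 specific
    l11 <- sqrt(v2[1])
    l21 <- if (l11 > 1e-8) cov / l11 else 0
    l22 <- sqrt(max(v2[2] - l21^2, 0))
    c(l11, l21, l22)
  }
  pa <- path_tri(p$a2, p$cov_a)
  pc <- path_tri(p$c2, p$cov_c)
  pe <- path_tri(p$e2, p$cov_e)
  paths <- c(a11 = pa[1], a21 = pa[2], a22 = pa[3],
             c11 = pc[1], c21 = pc[2], c22 = pc[3],
             e11 = pe[1], e21 = pe[2], e22 = pe[3])
  comp_cor <- function(v2, cov) {
    den <- sqrt(prod(v2))
    if (den < 1e-8) NA_real_ else cov / den
  }
  structure(list(
    traits = traits, paths = paths,
    a2 = p$a2, c2 = p$c2, e2 = p$e2,
    r_ph = r_ph, cov_a = p$cov_a, cov_c = p$cov_c, cov_e = p$cov_e,
    prop_a = p$cov_a / r_ph, prop_c = p$cov_c / r_ph, prop_e = p$cov_e / r_ph,
    rA = comp_cor(p$a2, p$cov_a), rC = comp_cor(p$c2, p$cov_c),
    rE = comp_cor(p$e2, p$cov_e),
    loglik = -best$value,
    n = c(n_mz = stats_g$MZ$n, n_dz = stats_g$DZ$n)),
    class = "biv_fit")
}

#' @export
print.biv_fit <- function(x, ...) {
  cat(sprintf("Bivariate ACE fit (%s, %s): r_ph = %.4f\n",
              x$traits[1], x$traits[2], x$r_ph))
  cat(sprintf("  proportions of r_ph: A = %.4f, C = %.4f, E = %.4f\n",
              x$prop_a, x$prop_c, x$prop_e))
  cat(sprintf("  component correlations: rA = %.4f, rC = %.4f, rE = %.4f\n",
              x$rA, x$rC, x$rE))
  invisible(x)
}

#' Component correlations from Cholesky paths
#'
#' The genetic correlation implied by lower-triangular paths is
#' `rA = a11 a21 / (|a11| sqrt(a21^2 + a22^2))`, and analogously for the
#' shared- and nonshared-environment components. Components with (near)
#' zero variance in either trait are undefined and returned as `NA` with a
#' warning.
#'
#' @param paths Named numeric vector with elements `a11, a21, a22, c11,
#'   c21, c22, e11, e21, e22` (e.g. `fit$paths` from
#'   [fit_bivariate_cholesky()]).
#' @return Named vector `c(rA, rC, rE)`.
#' @export
genetic_correlation <- function(paths) {
  one <- function(l11, l21, l22, label) {
    l11 <- unname(l11); l21 <- unname(l21); l22 <- unname(l22)
    den <- abs(l11) * sqrt(l21^2 + l22^2)
    if (den < 1e-8) {
      warning("zero ", label, " variance in one trait; correlation undefined")
      return(NA_real_)
    }
    l11 * l21 / den
  }
  c(rA = one(paths["a11"], paths["a21"], paths["a22"], "genetic"),
    rC = one(paths["c11"], paths["c21"], paths["c22"], "shared-environment"),
    rE = one(paths["e11"], paths["e21"], paths["e22"], "nonshared-environment"))
}
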