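## Genetic-confounding sensitivity analysis over a 3x3 correlation matrix
## of (polygenic score G, exposure X, outcome Y). The observed score is a
## weak proxy of genetic liability; scaling the score-outcome correlation
## up to the SNP- or twin-heritability of the outcome emulates a fully
## predictive latent score and bounds the genetic confounding of the
## exposure-outcome association.

gsens_cor_matrix <- function(r_gx, r_gy, r_xy) {
  matrix(c(1, r_gx, r_gy,
           r_gx, 1, r_xy,
           r_gy, r_xy, 1), 3, 3,
         dimnames = rep(list(c("G", "X", "Y")), 2))
}

#' Input bundle for the genetic-confounding sensitivity analysis
#'
#' @param r_gx Correlation between the polygenic score and the exposure.
#' @param r_gy Correlation between the polygenic score and the outcome.
#' @param r_xy Observed exposure-outcome correlation.
#' @param n Sample size behind the correlations.
#' @param h2_snp,h2_twin Scenario heritabilities of the outcome (SNP-based
#'   and twin-based), each in `[0, 1]`; optional until
#'   [scenario_analysis()] is called.
#' @return An object of class `gsens_input`. The implied 3x3 correlation
#'   matrix must be positive definite, otherwise an error is raised.
#' @export
gsens_input <- function(r_gx, r_gy, r_xy, n,
                        h2_snp = NA_real_, h2_twin = NA_real_) {
  r <- c(r_gx = r_gx, r_gy = r_gy, r_xy = r_xy)
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("correlations must lie strictly inside (-1, 1)", call. = FALSE)
  if (n < 4) stop("n must be at least 4", call. = FALSE)
  M <- gsens_cor_matrix(r_gx, r_gy, r_xy)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("correlation matrix is not positive definite (min eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  structure(list(r_gx = r_gx, r_gy = r_gy, r_xy = r_xy, n = n,
                 h2_snp = h2_snp, h2_twin = h2_twin),
            class = "gsens_input")
}

#' Rescale the score correlations to a heritability scenario
#'
#' Anchors on the outcome: the score-outcome correlation is inflated to
#' `sign(r_gy) * sqrt(h2)`, as if the score explained the full heritability
#' `h2` of the outcome, and the score-exposure correlation is scaled by the
#' same factor `sqrt(h2) / |r_gy|`, preserving the score's
#' exposure/outcome association ratio. The exposure-outcome correlation is
#' untouched. The scaled matrix must remain positive definite — if not,
#' genetic confounding at that heritability would exceed the observed
#' association structure and an error identifies the bound.
#'
#' @param input A [gsens_input()].
#' @param h2 Target heritability of the outcome, in `(0, 1]`, with
#'   `r_gy^2 <= h2`.
#' @return A new `gsens_input` with scaled `r_gx`, `r_gy`.
#' @export
scale_to_heritability <- function(input, h2) {
  stopifnot(inherits(input, "gsens_input"))
  if (!is.finite(h2) || h2 <= 0 || h2 > 1)
    stop("h2 must lie in (0, 1]", call. = FALSE)
  if (abs(input$r_gy) < 1e-12)
    stop("r_gy = 0: heritability scaling is undefined", call. = FALSE)
  if (input$r_gy^2 > h2 + 1e-12)
    stop("r_gy^2 exceeds the target heritability h2", call. = FALSE)
  fac <- sqrt(h2) / abs(input$r_gy)
  r_gy2 <- sign(input$r_gy) * sqrt(h2)
  r_gx2 <- input$r_gx * fac
  if (abs(r_gx2) >= 1)
    stop("scaled score-exposure correlation |r_gx'| = ",
         format(abs(r_gx2)),
         " >= 1: genetic confounding cannot exceed the observed ",
         "association structure at h2 = ", h2, call. = FALSE)
  out <- tryCatch(
    gsens_input(r_gx2, r_gy2, input$r_xy, input$n,
                input$h2_snp, input$h2_twin),
    error = function(e)
      stop("scaled correlation matrix is not positive definite at h2 = ",
           h2, ": genetic confounding alone cannot reproduce the observed ",
           "associations (", conditionMessage(e), ")", call. = FALSE))
  out
}

#' Genetically adjusted exposure-outcome effect
#'
#' The unadjusted standardized effect is the exposure-outcome correlation
#' itself; the adjusted effect is the standardized partial regression
#' coefficient of the outcome on the exposure given the (possibly scaled)
#' genetic variable, `(r_xy - r_gx r_gy) / (1 - r_gx^2)`. The confounding
#' proportion is `1 - b_adjusted / b_unadjusted` and the attenuation is
#' that proportion in percent (100 exactly when the adjusted effect is 0;
#' negative under suppression).
#'
#' @param input A [gsens_input()].
#' @param scenario Label carried into the result (default `"observed"`).
#' @param bootstrap If `TRUE`, percentile CIs from a seeded parametric
#'   bootstrap: the sample correlation matrix of `n` trivariate-normal
#'   observations with the input correlation structure is redrawn `n_boot`
#'   times (through its exact Wishart distribution) and the quantities
#'   recomputed from each draw.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param level CI level.
#' @param seed Bootstrap seed.
#' @return A list of class `gsens_result`: `b_unadjusted`, `b_adjusted`,
#'   `confounding_prop`, `attenuation_pct`, analytic `se_unadjusted` /
#'   `se_adjusted` (regression standard errors), and bootstrap `ci` when
#'   requested.
#' @export
adjusted_effect <- function(input, scenario = "observed", bootstrap = FALSE,
                            n_boot = 1000, level = 0.95, seed = 1L) {
  stopifnot(inherits(input, "gsens_input"))
  if (1 - input$r_gx^2 < 1e-6)
    stop("score-exposure correlation too close to 1; model near-singular",
         call. = FALSE)
  b_un <- input$r_xy
  b_adj <- (input$r_xy - input$r_gx * input$r_gy) / (1 - input$r_gx^2)
  conf <- if (abs(b_un) < 1e-12) NA_real_ else 1 - b_adj / b_un
  R2 <- {
    # outcome variance explained by exposure + genetic variable jointly
    M <- gsens_cor_matrix(input$r_gx, input$r_gy, input$r_xy)
    rvec <- c(input$r_gy, input$r_xy)
    Sxx <- M[c("G", "X"), c("G", "X")]
    drop(rvec %*% solve(Sxx, rvec))
  }
  n <- input$n
  res <- structure(list(
    scenario = scenario,
    b_unadjusted = b_un,
    b_adjusted = b_adj,
    confounding_prop = conf,
    attenuation_pct = 100 * conf,
    se_unadjusted = sqrt((1 - b_un^2)^2 / (n - 3)),
    se_adjusted = sqrt(max(1 - R2, 0) / ((n - 3) * (1 - input$r_gx^2))),
    n = n), class = "gsens_result")
  if (bootstrap) {
    set.seed(stream_seed(seed, 707L))
    M <- gsens_cor_matrix(input$r_gx, input$r_gy, input$r_xy)
    # sample covariance of n centred trivariate-normal draws is Wishart with
    # n - 1 degrees of freedom: sample its correlation matrix directly
    W <- stats::rWishart(n_boot, n - 1, M / (n - 1))
    draws <- matrix(NA_real_, n_boot, 2,
                    dimnames = list(NULL, c("b_unadjusted", "b_adjusted")))
    for (b in seq_len(n_boot)) {
      Cb <- stats::cov2cor(W[, , b])
      draws[b, ] <- c(Cb[2, 3],
                      (Cb[2, 3] - Cb[1, 2] * Cb[1, 3]) / (1 - Cb[1, 2]^2))
    }
    alpha <- (1 - level) / 2
    res$ci <- t(apply(draws, 2, stats::quantile, probs = c(alpha, 1 - alpha)))
    colnames(res$ci) <- c("lower", "upper")
    res$ci_level <- level
  }
  res
}

#' @export
print.gsens_result <- function(x, ...) {
  cat(sprintf("Gsens (%s): b_unadjusted = %.4f, b_adjusted = %.4f, attenuation = %.1f%%\n",
              x$scenario, x$b_unadjusted, x$b_adjusted, x$attenuation_pct))
  invisible(x)
}

#' Three-scenario genetic-confounding sensitivity analysis
#'
#' Runs [adjusted_effect()] on the observed correlations and on the inputs
#' rescaled to the SNP- and twin-heritability scenarios, mirroring the
#' standard observed / SNP-h2 / twin-h2 comparison.
#'
#' @param input A [gsens_input()] with `h2_snp` and `h2_twin` set. A
#'   warning is raised (and the analysis proceeds) if `h2_snp > h2_twin`.
#' @param bootstrap,n_boot,level,seed Passed to [adjusted_effect()].
#' @return A list with the three `gsens_result`s (`observed`, `snp_h2`,
#'   `twin_h2`) and `table`, a tidy per-scenario data frame.
#' @export
scenario_analysis <- function(input, bootstrap = FALSE, n_boot = 1000,
                              level = 0.95, seed = 1L) {
  stopifnot(inherits(input, "gsens_input"))
  if (!is.finite(input$h2_snp) || !is.finite(input$h2_twin))
    stop("scenario_analysis needs h2_snp and h2_twin", call. = FALSE)
  if (input$h2_snp > input$h2_twin)
    warning("h2_snp exceeds h2_twin; proceeding, but SNP heritability is ",
            "normally the lower bound")
  runs <- list(
    observed = adjusted_effect(input, "observed", bootstrap, n_boot, level, seed),
    snp_h2 = adjusted_effect(scale_to_heritability(input, input$h2_snp),
                             "snp_h2", bootstrap, n_boot, level, seed),
    twin_h2 = adjusted_effect(scale_to_heritability(input, input$h2_twin),
                              "twin_h2", bootstrap, n_boot, level, seed))
  tab <- do.call(rbind, lapply(runs, function(r)
    data.frame(scenario = r$scenario,
               b_unadjusted = r$b_unadjusted,
               b_adjusted = r$b_adjusted,
               se_adjusted = r$se_adjusted,
               confounding_prop = r$confounding_prop,
               attenuation_pct = r$attenuation_pct)))
  rownames(tab) <- NULL
  c(runs, list(table = tab))
}
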