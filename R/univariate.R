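## ACE variance-component estimation from twin data.
##
## The ACE model implies co-twin correlations rho_MZ = a2 + c2 and
## rho_DZ = a2/2 + c2. Components are parameterized directly as (a2, c2)
## on the constrained simplex a2 >= 0, c2 >= 0, a2 + c2 <= 1 (e2 is the
## remainder), which keeps boundary solutions explicit; internally the
## optimizer works on the box u = a2 + c2 in [0,1], v = c2 / u in [0,1].

BOUNDARY_TOL <- 1e-5

uv_to_ace <- function(par) {
  u <- par[1]; v <- par[2]
  c(a2 = u * (1 - v), c2 = u * v)
}

## Deterministic spread of optimizer starting points over the box.
ACE_STARTS <- rbind(c(0.5, 0.5), c(0.2, 0.1), c(0.8, 0.2),
                    c(0.3, 0.8), c(0.6, 0.05))

## Minimize negll(a2, c2) over the constrained simplex; returns estimates,
## the maximized log-likelihood and boundary flags.
optimize_ace <- function(negll) {
  obj <- function(par) {
    par <- pmin(pmax(par, 0), 1)
    ac <- uv_to_ace(par)
    val <- negll(ac[1], ac[2])
    if (!is.finite(val)) 1e10 else val
  }
  best <- NULL
  for (i in seq_len(nrow(ACE_STARTS))) {
    fit <- try(stats::optim(ACE_STARTS[i, ], obj, method = "L-BFGS-B",
                            lower = c(0, 0), upper = c(1, 1),
                            control = list(factr = 1e3, maxit = 500)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("ACE optimizer failed to converge after restarts", call. = FALSE)
  # Nelder-Mead polish for high absolute accuracy at interior optima
  pol <- stats::optim(best$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 2000))
  if (pol$value <= best$value)
    best <- list(par = pmin(pmax(pol$par, 0), 1), value = pol$value)
  ac <- uv_to_ace(best$par)
  a2 <- unname(ac[1]); c2 <- unname(ac[2]); e2 <- 1 - a2 - c2
  list(a2 = a2, c2 = c2, e2 = e2,
       loglik = -best$value,
       boundary = c(a2 = a2 < BOUNDARY_TOL,
                    c2 = c2 < BOUNDARY_TOL,
                    e2 = e2 < BOUNDARY_TOL))
}

new_ace_fit <- function(opt, method, negll, n_info, flags = NULL) {
  structure(list(a2 = opt$a2, c2 = opt$c2, e2 = opt$e2,
                 loglik = opt$loglik, boundary = opt$boundary,
                 flags = flags, method = method, n = n_info,
                 ci = NULL, .negll = negll),
            class = "ace_fit")
}

#' @export
print.ace_fit <- function(x, ...) {
  cat(sprintf("ACE fit (%s): a2 = %.4f, c2 = %.4f, e2 = %.4f\n",
              x$method, x$a2, x$c2, x$e2))
  if (any(x$boundary)) cat("  at boundary:",
                           paste(names(x$boundary)[x$boundary], collapse = ", "), "\n")
  if (!is.null(x$flags) && any(x$flags))
    cat("  out of range:", paste(names(x$flags)[x$flags], collapse = ", "), "\n")
  if (is.finite(x$loglik)) cat(sprintf("  log-likelihood: %.4f\n", x$loglik))
  if (!is.null(x$ci)) {
    for (k in rownames(x$ci))
      cat(sprintf("  %s 95%% CI: (%.4f, %.4f)\n", k, x$ci[k, 1], x$ci[k, 2]))
  }
  invisible(x)
}

#' Falconer (moment) estimates of ACE components
#'
#' The rough textbook decomposition: doubling the MZ-DZ correlation gap
#' estimates the additive genetic share, `a2 = 2 (r_mz - r_dz)`; the shared
#' environment is what remains of the MZ correlation, `c2 = r_mz - a2`; and
#' `e2 = 1 - a2 - c2`. No constraints are applied — components outside
#' `[0, 1]` are returned as-is and flagged.
#'
#' @param r_mz,r_dz MZ and DZ intraclass correlations, each in `[-1, 1]`.
#' @return An `ace_fit` with `method = "falconer"` and out-of-range flags.
#' @export
falconer_estimates <- function(r_mz, r_dz) {
  if (abs(r_mz) > 1 || abs(r_dz) > 1)
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  a2 <- 2 * (r_mz - r_dz)
  c2 <- r_mz - a2
  e2 <- 1 - a2 - c2
  est <- c(a2 = a2, c2 = c2, e2 = e2)
  new_ace_fit(list(a2 = a2, c2 = c2, e2 = e2, loglik = NA_real_,
                   boundary = c(a2 = FALSE, c2 = FALSE, e2 = FALSE)),
              method = "falconer", negll = NULL,
              n_info = NULL, flags = est < 0 | est > 1)
}

#' Constrained ML fit of the ACE model to summary correlations
#'
#' When only the group intraclass correlations and pair counts are available
#' (as printed in a results table), the model is fitted by maximizing the
#' Fisher-z likelihood `z(r_g) ~ N(z(rho_g(a2, c2)), 1/(n_g - 3))` over the
#' MZ and DZ groups, subject to `a2 >= 0`, `c2 >= 0`, `a2 + c2 <= 1`. This
#' is the standard asymptotically equivalent summary-level counterpart of
#' the raw-data structural-equation fit, and reproduces boundary-constrained
#' solutions (e.g. `c2` pinned at 0 when `r_dz < r_mz / 2`).
#'
#' @param r_mz,r_dz Observed intraclass correlations.
#' @param n_mz,n_dz Number of pairs per group (at least 4 each).
#' @return An `ace_fit` with `method = "ml_summary"`, boundary flags and the
#'   maximized (relative) log-likelihood; pass to [profile_ci()] for
#'   likelihood-ratio intervals.
#' @export
fit_ace_ml_summary <- function(r_mz, r_dz, n_mz, n_dz) {
  if (abs(r_mz) > 1 || abs(r_dz) > 1)
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  if (n_mz < 4 || n_dz < 4) stop("need at least 4 pairs per group", call. = FALSE)
  z_mz <- atanh(r_mz); z_dz <- atanh(r_dz)
  w_mz <- n_mz - 3; w_dz <- n_dz - 3
  negll <- function(a2, c2) {
    rho_mz <- min(a2 + c2, 1 - 1e-12)
    rho_dz <- min(a2 / 2 + c2, 1 - 1e-12)
    0.5 * (w_mz * (z_mz - atanh(rho_mz))^2 + w_dz * (z_dz - atanh(rho_dz))^2)
  }
  opt <- optimize_ace(negll)
  new_ace_fit(opt, "ml_summary", negll,
              n_info = c(n_mz = n_mz, n_dz = n_dz))
}

## Per-group sufficient statistics of the co-twin bivariate-normal
## likelihood for standardized phenotypes (means 0, variances 1 fixed).
pair_suffstats <- function(pairs, trait) {
  tr <- pair_trait(pairs, trait)
  grp <- zyg_group(pairs$zygosity)
  ok <- !is.na(tr$t1) & !is.na(tr$t2) & !is.na(grp)
  lapply(c(MZ = "MZ", DZ = "DZ"), function(g) {
    sel <- ok & grp == g
    x1 <- tr$t1[sel]; x2 <- tr$t2[sel]
    list(n = sum(sel), s11 = sum(x1^2), s22 = sum(x2^2), s12 = sum(x1 * x2))
  })
}

group_negll <- function(st, rho) {
  rho <- min(max(rho, -1 + 1e-10), 1 - 1e-10)
  st$n * log(2 * pi) + st$n / 2 * log(1 - rho^2) +
    (st$s11 + st$s22 - 2 * rho * st$s12) / (2 * (1 - rho^2))
}

#' Constrained ML fit of the ACE model to raw twin pairs
#'
#' Maximizes the bivariate-normal log-likelihood of the co-twin pairs with
#' model-implied correlation `a2 + c2` (MZ) or `a2/2 + c2` (DZ), means 0 and
#' unit variances fixed (phenotypes are assumed residualized and
#' standardized), under `a2, c2 >= 0`, `a2 + c2 <= 1`. Complete pairs only;
#' DZss and DZos are pooled into one DZ group.
#'
#' @param pairs Twin-pair data frame with both zygosity groups.
#' @param trait Trait name.
#' @return An `ace_fit` with `method = "ml_raw"` and the full log-likelihood
#'   (usable for nested submodel comparison).
#' @export
fit_ace_ml_raw <- function(pairs, trait = "trait") {
  st <- pair_suffstats(pairs, trait)
  if (st$MZ$n < 20 || st$DZ$n < 20)
    stop("need at least 20 complete pairs in each zygosity group ",
         "(MZ: ", st$MZ$n, ", DZ: ", st$DZ$n, "); both groups are required ",
         "for identification", call. = FALSE)
  negll <- function(a2, c2) {
    group_negll(st$MZ, a2 + c2) + group_negll(st$DZ, a2 / 2 + c2)
  }
  opt <- optimize_ace(negll)
  new_ace_fit(opt, "ml_raw", negll,
              n_info = c(n_mz = st$MZ$n, n_dz = st$DZ$n))
}

## Profile log-likelihood slice: minimized negll with one component fixed.
profile_negll <- function(negll, component, t) {
  width <- 1 - t
  inner <- switch(component,
    a2 = function(z) negll(t, z),
    c2 = function(z) negll(z, t),
    e2 = function(z) negll(z, width - z))
  if (width < 1e-9) return(inner(0))
  stats::optimize(inner, c(0, width), tol = 1e-8)$objective
}

#' Profile-likelihood confidence intervals for ACE components
#'
#' For each component, the bound is the value where twice the drop from the
#' maximized log-likelihood equals the chi-squared quantile (3.84 at 95%),
#' profiling out the remaining free parameter; intervals are truncated at
#' `[0, 1]`, so a component estimated on the boundary gets a limit of
#' exactly 0 (or 1).
#'
#' @param fit An `ace_fit` from [fit_ace_ml_summary()] or
#'   [fit_ace_ml_raw()].
#' @param level Coverage level (default 0.95).
#' @return The fit with a `ci` matrix (rows `a2`, `c2`, `e2`) attached. If a
#'   root fails to bracket the bound is returned as `NA` with a warning.
#' @export
profile_ci <- function(fit, level = 0.95) {
  if (!inherits(fit, "ace_fit") || is.null(fit$.negll))
    stop("profile_ci needs a converged ML ace_fit", call. = FALSE)
  crit <- stats::qchisq(level, 1) / 2
  nll_min <- -fit$loglik
  ci <- matrix(NA_real_, 3, 2,
               dimnames = list(c("a2", "c2", "e2"), c("lower", "upper")))
  for (comp in rownames(ci)) {
    est <- fit[[comp]]
    g <- function(t) profile_negll(fit$.negll, comp, t) - nll_min - crit
    lo <- tryCatch({
      if (est < 1e-9 || g(0) <= 0) 0
      else stats::uniroot(g, c(0, est), tol = 1e-7)$root
    }, error = function(e) { warning("lower profile bound for ", comp,
                                     " failed to bracket"); NA_real_ })
    hi <- tryCatch({
      if (est > 1 - 1e-9 || g(1) <= 0) 1
      else stats::uniroot(g, c(est, 1), tol = 1e-7)$root
    }, error = function(e) { warning("upper profile bound for ", comp,
                                     " failed to bracket"); NA_real_ })
    ci[comp, ] <- c(lo, hi)
  }
  fit$ci <- ci
  fit$ci_level <- level
  fit
}

#' Compare nested ACE submodels on raw twin pairs
#'
#' Fits the full ACE model and its nested reductions (AE: no shared
#' environment; CE: no additive genetics; E: no familial resemblance) to the
#' same pairs and reports -2 log-likelihood, AIC and the likelihood-ratio
#' test of each reduction against ACE.
#'
#' @param pairs Twin-pair data frame.
#' @param trait Trait name.
#' @return A data frame with one row per model: `model`, `npar`, `loglik`,
#'   `minus2ll`, `aic`, `lrt_df`, `lrt_p`.
#' @export
compare_submodels <- function(pairs, trait = "trait") {
  st <- pair_suffstats(pairs, trait)
  if (st$MZ$n < 20 || st$DZ$n < 20)
    stop("need at least 20 complete pairs per zygosity group", call. = FALSE)
  negll <- function(a2, c2) {
    group_negll(st$MZ, a2 + c2) + group_negll(st$DZ, a2 / 2 + c2)
  }
  ll_1d <- function(f) {
    opt <- stats::optimize(f, c(0, 1), tol = 1e-9)
    -opt$objective
  }
  ll <- c(ACE = optimize_ace(negll)$loglik,
          AE = ll_1d(function(a2) negll(a2, 0)),
          CE = ll_1d(function(c2) negll(0, c2)),
          E = -negll(0, 0))
  npar <- c(ACE = 2L, AE = 1L, CE = 1L, E = 0L)
  out <- data.frame(model = names(ll), npar = npar, loglik = ll,
                    minus2ll = -2 * ll, aic = -2 * ll + 2 * npar,
                    row.names = NULL)
  out$lrt_df <- 2L - out$npar
  out$lrt_p <- ifelse(out$lrt_df > 0,
                      stats::pchisq(2 * (ll[["ACE"]] - out$loglik),
                                    out$lrt_df, lower.tail = FALSE),
                      NA_real_)
  out
}
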