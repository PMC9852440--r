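#' Residualize a phenotype on age and sex
#'
#' Twin analyses require age/sex adjustment because co-twins share age and MZ
#' co-twins share sex, which would otherwise inflate the shared-environment
#' estimate. Returns the least-squares residuals of `values` on an intercept,
#' age and sex, re-standardized to mean 0 and unit variance; missing rows
#' propagate as missing.
#'
#' @param values Numeric phenotype vector.
#' @param age,sex Numeric covariates of the same length (sex coded 0/1).
#' @return A numeric vector of standardized residuals. If the phenotype is an
#'   exact linear function of the covariates the result is flagged via
#'   `attr(, "degenerate") = TRUE` and left unscaled (zero residual
#'   variance). Constant covariates are skipped with a warning.
#' @export
residualize <- function(values, age = NULL, sex = NULL) {
  n <- length(values)
  covs <- list(age = age, sex = sex)
  covs <- covs[!vapply(covs, is.null, logical(1))]
  keep <- !is.na(values)
  for (v in covs) keep <- keep & !is.na(v)
  if (!any(keep)) stop("no complete observations to residualize", call. = FALSE)
  X <- matrix(1, sum(keep), 1)
  for (nm in names(covs)) {
    v <- covs[[nm]][keep]
    if (stats::var(v) < 1e-12) {
      warning("covariate '", nm, "' is constant; skipped")
      next
    }
    X <- cbind(X, v)
  }
  fit <- stats::lm.fit(X, values[keep])
  res <- rep(NA_real_, n)
  res[keep] <- fit$residuals
  s <- stats::sd(res, na.rm = TRUE)
  if (!is.finite(s) || s < 1e-10) {
    attr(res, "degenerate") <- TRUE
    warning("residual variance is (near) zero; phenotype is a linear function of the covariates")
    return(res)
  }
  res[keep] <- (res[keep] - mean(res[keep])) / s
  res
}

#' Van der Waerden rank-based inverse-normal transformation
#'
#' Maps each value to `qnorm(rank / (n + 1))` where `n` is the number of
#' non-missing values and ties receive their average rank, correcting
#' skewness by projecting the empirical distribution onto standard-normal
#' quantiles while preserving ranks exactly.
#'
#' @param values Numeric vector with at least 3 non-missing values.
#' @return Numeric vector of normal scores; missing values are preserved.
#' @export
vdw_transform <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 non-missing values", call. = FALSE)
  x <- values[ok]
  if (max(x) - min(x) < 1e-300)
    stop("all values identical; transform undefined", call. = FALSE)
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm(rank(x, ties.method = "average") / (n + 1))
  out
}

#' Double-enter a pair table for one trait
#'
#' Stacks both within-pair orderings so that pair-level statistics are
#' symmetric in twin order.
#' @noRd
double_enter <- function(t1, t2) {
  cbind(c(t1, t2), c(t2, t1))
}

#' Twin intraclass correlation by double entry
#'
#' Pearson correlation over the double-entered pair table (each complete pair
#' contributes both orderings), which makes the estimate exactly invariant to
#' within-pair ordering. The confidence interval and p-value use the Fisher-z
#' approximation with the number of complete *pairs* as effective sample
#' size.
#'
#' @param pairs Twin-pair data frame.
#' @param group Zygosity group: `"MZ"` or `"DZ"` (pools `DZss` and `DZos`).
#' @param trait Trait name (matching `<trait>_1` / `<trait>_2` columns).
#' @param level Confidence level (default 0.95).
#' @return A list of class `icc_report`: `r`, `n` (complete pairs), `p_raw`,
#'   `ci_low`, `ci_high`.
#' @export
intraclass_correlation <- function(pairs, group = c("MZ", "DZ"),
                                   trait = "trait", level = 0.95) {
  group <- match.arg(group)
  tr <- pair_trait(pairs, trait)
  sel <- zyg_group(pairs$zygosity) == group & !is.na(tr$t1) & !is.na(tr$t2)
  sel[is.na(sel)] <- FALSE
  n <- sum(sel)
  if (n < 3) stop("need at least 3 complete ", group, " pairs", call. = FALSE)
  de <- double_enter(tr$t1[sel], tr$t2[sel])
  r <- stats::cor(de[, 1], de[, 2])
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(r = r, n = n,
                 p_raw = 2 * stats::pnorm(-abs(z) / se),
                 ci_low = tanh(z - q * se), ci_high = tanh(z + q * se)),
            class = "icc_report")
}

#' Pairwise correlations with Benjamini-Hochberg FDR control
#'
#' Computes all left-by-right Pearson correlations (pairwise-complete), raw
#' p-values from the t approximation, Fisher-z confidence intervals, and
#' FDR-adjusted p-values over the full family of left-by-right tests.
#'
#' @param left,right Data frames or matrices of variables (e.g. media-use
#'   measures vs mental-health measures).
#' @param level Confidence level for the intervals.
#' @return A data frame with one row per cell: `var_left`, `var_right`, `r`,
#'   `n`, `p_raw`, `p_fdr`, `ci_low`, `ci_high`. Zero-variance variables
#'   yield missing cells.
#' @export
correlation_matrix_fdr <- function(left, right, level = 0.95) {
  left <- as.data.frame(left)
  right <- as.data.frame(right)
  if (ncol(left) + ncol(right) < 2) stop("need at least 2 variables", call. = FALSE)
  grid <- expand.grid(var_left = names(left), var_right = names(right),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  q <- stats::qnorm(1 - (1 - level) / 2)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- left[[grid$var_left[i]]]
    y <- right[[grid$var_right[i]]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 10)
      stop("pairwise-complete n < 10 for ", grid$var_left[i], " x ",
           grid$var_right[i], call. = FALSE)
    if (stats::var(x[ok]) < 1e-12 || stats::var(y[ok]) < 1e-12)
      return(data.frame(r = NA_real_, n = n, p_raw = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_))
    r <- stats::cor(x[ok], y[ok])
    tval <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
    p <- 2 * stats::pt(-abs(tval), n - 2)
    z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
    se <- 1 / sqrt(n - 3)
    data.frame(r = r, n = n, p_raw = p,
               ci_low = tanh(z - q * se), ci_high = tanh(z + q * se))
  })
  out <- cbind(grid, do.call(rbind, rows))
  out$p_fdr <- stats::p.adjust(out$p_raw, method = "BH")
  out[, c("var_left", "var_right", "r", "n", "p_raw", "p_fdr",
          "ci_low", "ci_high")]
}

#' Select one twin per pair at random
#'
#' Returns an individual-level table with one randomly chosen member per
#' pair, preserving independence for ANOVA-type analyses.
#'
#' @param pairs Twin-pair data frame.
#' @param trait Trait name.
#' @param seed Integer seed for the per-pair selection.
#' @return Data frame with `family_id`, `zygosity`, `sex`, `age`,
#'   `phenotype`.
#' @export
select_one_per_pair <- function(pairs, trait = "trait", seed = 1L) {
  set.seed(stream_seed(seed, 505L))
  tr <- pair_trait(pairs, trait)
  pick2 <- stats::rbinom(nrow(pairs), 1L, 0.5) == 1L
  data.frame(family_id = pairs$family_id,
             zygosity = pairs$zygosity,
             sex = ifelse(pick2, pairs$sex2, pairs$sex1),
             age = pairs$age,
             phenotype = ifelse(pick2, tr$t2, tr$t1),
             stringsAsFactors = FALSE)
}

#' Variance shares explained by sex and zygosity
#'
#' Two-way ANOVA of a phenotype (one individual per pair) on sex and
#' zygosity, returning eta-squared (sum-of-squares share) for each factor
#' and for the joint model — the check behind pooling sexes and zygosity
#' groups when these shares are negligible.
#'
#' @param data Data frame with columns `phenotype`, `sex`, `zygosity` (one
#'   row per independent individual, e.g. from [select_one_per_pair()]).
#' @param interaction Include the sex-by-zygosity interaction (dropped with a
#'   warning if any cell is empty).
#' @return A list: `eta2_sex`, `eta2_zygosity`, `eta2_joint`, and the
#'   underlying `anova` table.
#' @export
variance_by_sex_zygosity <- function(data, interaction = TRUE) {
  d <- data.frame(phenotype = data$phenotype,
                  sex = factor(data$sex),
                  zygosity = factor(data$zygosity))
  d <- d[stats::complete.cases(d), ]
  if (interaction && any(table(d$sex, d$zygosity) == 0)) {
    warning("empty sex x zygosity cells; interaction term dropped")
    interaction <- FALSE
  }
  form <- if (interaction) phenotype ~ sex * zygosity else phenotype ~ sex + zygosity
  fit <- stats::aov(form, data = d)
  tab <- summary(fit)[[1]]
  ss <- tab[["Sum Sq"]]
  terms <- trimws(rownames(tab))
  ss_total <- sum(ss)
  share <- function(term) {
    i <- match(term, terms)
    if (is.na(i)) 0 else ss[i] / ss_total
  }
  list(eta2_sex = share("sex"),
       eta2_zygosity = share("zygosity"),
       eta2_joint = sum(ss[terms != "Residuals"]) / ss_total,
       anova = tab)
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' `alpha = k/(k - 1) * (1 - sum(item variances) / var(total score))` for a
#' matrix of k items.
#'
#' @param items Numeric matrix or data frame, individuals x items (k >= 2,
#'   at least 3 complete rows).
#' @return Alpha in `(-Inf, 1]`.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  items <- items[stats::complete.cases(items), , drop = FALSE]
  k <- ncol(items)
  if (k < 2) stop("need at least 2 items", call. = FALSE)
  if (nrow(items) < 3) stop("need at least 3 complete individuals", call. = FALSE)
  v_total <- stats::var(rowSums(items))
  if (v_total < 1e-12) stop("total score has zero variance", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / v_total)
}
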