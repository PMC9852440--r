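#' Standardize a polygenic-score matrix
#'
#' Centers and scales each score column to mean 0, unit variance, erroring
#' on zero-variance columns.
#'
#' @param scores Numeric matrix or data frame, individuals x scores.
#' @return Standardized numeric matrix.
#' @export
standardize_scores <- function(scores) {
  S <- as.matrix(scores)
  sds <- apply(S, 2, stats::sd)
  if (any(sds < 1e-12))
    stop("zero-variance score column(s): ",
         paste(colnames(S)[sds < 1e-12], collapse = ", "), call. = FALSE)
  scale(S)[, , drop = FALSE]
}

#' Per-score correlations with a phenotype, FDR-controlled
#'
#' Pearson correlation of each polygenic score with the (residualized)
#' phenotype, with raw p-values from the t approximation and
#' Benjamini-Hochberg adjustment across the battery.
#'
#' @param scores Individuals x scores matrix (rows aligned to `phenotype`).
#' @param phenotype Numeric vector.
#' @param level Confidence level for Fisher-z intervals.
#' @return Data frame with one row per score: `score`, `r`, `n`, `p_raw`,
#'   `p_fdr`, `ci_low`, `ci_high`.
#' @export
gps_correlations <- function(scores, phenotype, level = 0.95) {
  S <- as.matrix(scores)
  if (nrow(S) != length(phenotype))
    stop("scores and phenotype are misaligned: ", nrow(S), " rows vs ",
         length(phenotype), " values", call. = FALSE)
  if (nrow(S) < 50) stop("need at least 50 individuals", call. = FALSE)
  if (is.null(colnames(S))) colnames(S) <- paste0("gps", seq_len(ncol(S)))
  out <- correlation_matrix_fdr(as.data.frame(S),
                                data.frame(phenotype = phenotype),
                                level = level)
  names(out)[names(out) == "var_left"] <- "score"
  out$var_right <- NULL
  out
}

#' Joint multiple regression of a phenotype on a score battery
#'
#' Least-squares fit of the standardized phenotype on all standardized
#' scores jointly, reporting signed standardized betas, the multiple
#' correlation `R = sqrt(R2)`, adjusted R-squared and the overall F-test.
#' Exactly collinear columns are dropped with a warning.
#'
#' @param scores Individuals x scores matrix.
#' @param phenotype Numeric vector aligned to the rows of `scores`.
#' @return A list of class `gps_fit`: `beta` (named, standardized), `R2`,
#'   `multiple_R`, `adj_R2`, `f_p`, `n`, `k`, `dropped`.
#' @export
multiple_gps_regression <- function(scores, phenotype) {
  S <- as.matrix(scores)
  if (nrow(S) != length(phenotype))
    stop("scores and phenotype are misaligned", call. = FALSE)
  ok <- stats::complete.cases(S) & !is.na(phenotype)
  S <- S[ok, , drop = FALSE]
  y <- phenotype[ok]
  n <- nrow(S)
  if (is.null(colnames(S))) colnames(S) <- paste0("gps", seq_len(ncol(S)))
  if (ncol(S) >= n / 10)
    stop("too many scores for the sample (need k < n/10)", call. = FALSE)
  S <- standardize_scores(S)
  y <- (y - mean(y)) / stats::sd(y)
  qrS <- qr(S)
  dropped <- character(0)
  if (qrS$rank < ncol(S)) {
    keep <- qrS$pivot[seq_len(qrS$rank)]
    dropped <- colnames(S)[-keep]
    warning("rank-deficient score matrix; dropped: ",
            paste(dropped, collapse = ", "))
    S <- S[, keep, drop = FALSE]
  }
  fit <- stats::lm(y ~ S)
  sm <- summary(fit)
  beta <- stats::coef(fit)[-1]
  names(beta) <- colnames(S)
  fstat <- sm$fstatistic
  structure(list(beta = beta,
                 R2 = sm$r.squared,
                 multiple_R = sqrt(sm$r.squared),
                 adj_R2 = sm$adj.r.squared,
                 f_p = stats::pf(fstat[1], fstat[2], fstat[3],
                                 lower.tail = FALSE),
                 n = n, k = ncol(S), dropped = dropped),
            class = "gps_fit")
}

#' @export
print.gps_fit <- function(x, ...) {
  cat(sprintf("Polygenic-score regression: k = %d scores, n = %d\n", x$k, x$n))
  cat(sprintf("  multiple R = %.4f (R2 = %.4f, adjusted R2 = %.4f), F-test p = %.3g\n",
              x$multiple_R, x$R2, x$adj_R2, x$f_p))
  invisible(x)
}
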