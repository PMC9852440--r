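## End-to-end orchestration: simulate (or read) twin cohorts, preprocess,
## fit univariate and bivariate twin models, run polygenic-score and
## genetic-confounding analyses, and write machine-readable outputs.

fmt4 <- function(x) {
  if (is.numeric(x)) sprintf("%.4f", x) else x
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
}

stage_error <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage ", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full genetically informed analysis pipeline
#'
#' Executes the enabled stages in order — cohort simulation (or reading),
#' preprocessing (age/sex residualization + van der Waerden transform),
#' univariate ACE fits with profile intervals, bivariate Cholesky
#' decompositions, polygenic-score regression, and the genetic-confounding
#' sensitivity analysis — and writes per-stage JSON, a combined
#' results-table-shaped CSV (rows = traits; columns = A/C/E and intraclass
#' correlations with intervals) and a plain-text run log.
#'
#' @param config A configuration list or path to a YAML file. Recognized
#'   fields: `seed` (integer), `outdir`, `fdr_level`, `traits` (list of
#'   univariate specs, each either a simulation spec with `name`, `n_mz`,
#'   `n_dz`, `a2`, `c2`, `e2` or `input` = path to a pair CSV plus `name`),
#'   `bivariate` (list of bivariate specs with `rA`, `rC`, `rE` and
#'   length-2 components), `gps` (`n`, `r`, optional `names`), `gsens`
#'   (`r_gx`, `r_gy`, `r_xy`, `n`, `h2_snp`, `h2_twin`).
#' @param outdir Output directory (overrides `config$outdir`).
#' @return Invisibly, a list with the per-stage results and the summary
#'   table.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  seed <- as.integer(config$seed %||% 1L)
  outdir <- outdir %||% config$outdir %||% "twinconfound_results"
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logline <- function(...) {
    msg <- paste0(...)
    writeLines(msg, log_con)
    message(msg)
  }
  t0 <- Sys.time()
  logline("twinconfound ", as.character(utils::packageVersion("twinconfound")),
          " | R ", getRversion(), " | seed ", seed)

  # referenced input files must exist before any work starts
  for (spec in config$traits %||% list()) {
    if (!is.null(spec$input) && !file.exists(spec$input))
      stop("[stage startup] input file not found: ", spec$input, call. = FALSE)
  }

  results <- list()

  ## ---- univariate traits -------------------------------------------------
  summary_rows <- list()
  for (spec in config$traits %||% list()) {
    trait <- spec$name %||% "trait"
    res <- stage_error(paste0("univariate:", trait), {
      pairs <- if (!is.null(spec$input)) {
        read_twin_pairs(spec$input)
      } else {
        cfg <- twin_sim_config(spec$n_mz, spec$n_dz, spec$a2, spec$c2, spec$e2,
                               beta_age = spec$beta_age %||% 0,
                               beta_sex = spec$beta_sex %||% 0,
                               traits = trait, seed = seed)
        simulate_univariate_twins(cfg)
      }
      for (side in c("_1", "_2")) {
        col <- paste0(trait, side)
        sexcol <- if (side == "_1") pairs$sex1 else pairs$sex2
        pairs[[col]] <- vdw_transform(
          residualize(pairs[[col]], age = pairs$age, sex = sexcol))
      }
      icc_mz <- intraclass_correlation(pairs, "MZ", trait)
      icc_dz <- intraclass_correlation(pairs, "DZ", trait)
      fit <- profile_ci(fit_ace_ml_raw(pairs, trait))
      list(trait = trait, icc_mz = icc_mz, icc_dz = icc_dz, fit = fit)
    })
    results$univariate[[trait]] <- res
    summary_rows[[trait]] <- data.frame(
      trait = trait,
      A = res$fit$a2, A_low = res$fit$ci["a2", 1], A_high = res$fit$ci["a2", 2],
      C = res$fit$c2, C_low = res$fit$ci["c2", 1], C_high = res$fit$ci["c2", 2],
      E = res$fit$e2, E_low = res$fit$ci["e2", 1], E_high = res$fit$ci["e2", 2],
      rMZ = res$icc_mz$r, rMZ_low = res$icc_mz$ci_low, rMZ_high = res$icc_mz$ci_high,
      rDZ = res$icc_dz$r, rDZ_low = res$icc_dz$ci_low, rDZ_high = res$icc_dz$ci_high,
      n_mz = res$icc_mz$n, n_dz = res$icc_dz$n)
    write_json_out(list(trait = trait,
                        estimates = res$fit[c("a2", "c2", "e2", "loglik")],
                        ci = as.data.frame(res$fit$ci),
                        boundary = as.list(res$fit$boundary),
                        icc = list(MZ = unclass(res$icc_mz),
                                   DZ = unclass(res$icc_dz))),
                   file.path(outdir, paste0("univariate_", trait, ".json")))
    logline("univariate ", trait, ": A=", fmt4(res$fit$a2),
            " C=", fmt4(res$fit$c2), " E=", fmt4(res$fit$e2))
  }
  if (length(summary_rows)) {
    tab <- do.call(rbind, summary_rows)
    tab_fmt <- as.data.frame(lapply(tab, function(col)
      if (is.numeric(col) && !is.integer(col)) sprintf("%.4f", col) else col))
    utils::write.csv(tab_fmt, file.path(outdir, "ace_summary.csv"),
                     row.names = FALSE, quote = FALSE)
    results$summary_table <- tab
  }

  ## ---- bivariate decompositions ------------------------------------------
  for (spec in config$bivariate %||% list()) {
    traits <- unlist(spec$traits %||% c("x", "y"))
    label <- paste(traits, collapse = "_")
    res <- stage_error(paste0("bivariate:", label), {
      cfg <- twin_sim_config(spec$n_mz, spec$n_dz,
                             unlist(spec$a2), unlist(spec$c2), unlist(spec$e2),
                             rA = spec$rA %||% 0, rC = spec$rC %||% 0,
                             rE = spec$rE %||% 0, traits = traits, seed = seed)
      pairs <- simulate_bivariate_twins(cfg)
      fit_bivariate_cholesky(pairs, traits)
    })
    results$bivariate[[label]] <- res
    write_json_out(res[c("traits", "r_ph", "prop_a", "prop_c", "prop_e",
                         "rA", "rC", "rE", "paths")],
                   file.path(outdir, paste0("bivariate_", label, ".json")))
    logline("bivariate ", label, ": r_ph=", fmt4(res$r_ph),
            " propA=", fmt4(res$prop_a), " propE=", fmt4(res$prop_e))
  }

  ## ---- polygenic scores ---------------------------------------------------
  if (!is.null(config$gps)) {
    res <- stage_error("gps", {
      g <- config$gps
      batt <- simulate_score_battery(g$n, unlist(g$r),
                                     score_names = unlist(g$names),
                                     seed = seed)
      list(per_score = gps_correlations(batt$scores, batt$phenotype),
           joint = multiple_gps_regression(batt$scores, batt$phenotype))
    })
    results$gps <- res
    utils::write.csv(
      as.data.frame(lapply(res$per_score, function(col)
        if (is.numeric(col) && !is.integer(col)) sprintf("%.4f", col) else col)),
      file.path(outdir, "gps_correlations.csv"), row.names = FALSE, quote = FALSE)
    write_json_out(list(beta = as.list(res$joint$beta),
                        multiple_R = res$joint$multiple_R,
                        R2 = res$joint$R2, adj_R2 = res$joint$adj_R2,
                        f_p = res$joint$f_p, n = res$joint$n),
                   file.path(outdir, "gps_regression.json"))
    logline("gps: multiple R=", fmt4(res$joint$multiple_R))
  }

  ## ---- genetic-confounding sensitivity ------------------------------------
  if (!is.null(config$gsens)) {
    res <- stage_error("gsens", {
      g <- config$gsens
      inp <- gsens_input(g$r_gx, g$r_gy, g$r_xy, g$n,
                         h2_snp = g$h2_snp, h2_twin = g$h2_twin)
      scenario_analysis(inp, bootstrap = isTRUE(g$bootstrap),
                        n_boot = g$n_boot %||% 1000, seed = seed)
    })
    results$gsens <- res
    write_json_out(res$table, file.path(outdir, "gsens_scenarios.json"))
    logline("gsens: attenuation observed=", fmt4(res$table$attenuation_pct[1]),
            "% twin=", fmt4(res$table$attenuation_pct[3]), "%")
  }

  logline("completed in ",
          fmt4(as.numeric(difftime(Sys.time(), t0, units = "secs"))), " s")
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
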