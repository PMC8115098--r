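## Orchestration of the full bidirectional exposure x outcome analysis grid.

#' Read an analysis configuration file
#'
#' YAML configuration declaring the studies (summary-statistics path,
#' metadata, roles) and analysis parameters. Unspecified parameters take
#' the defaults documented in [runGrid()].
#'
#' @param path Path to a YAML file with a \code{studies} list (each entry:
#'   \code{path}, \code{trait_type}, \code{unit}, \code{n}, \code{n_cases},
#'   \code{prevalence}, \code{roles}, optional \code{ld_path},
#'   \code{prevalence_bounds}) and optional top-level analysis parameters
#'   (\code{iv_p_threshold}, \code{clump_r2}, \code{clump_window_kb},
#'   \code{eaf_ambiguity}, \code{correction}, \code{alpha}, \code{min_ivs},
#'   \code{seed}, ...).
#' @return A config list suitable for [runGrid()].
#' @export
readAnalysisConfig <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$studies) || !length(cfg$studies))
    stop("config declares no studies")
  cfg$studies <- lapply(cfg$studies, function(s) {
    ## YAML 1.1 parses a bare `n:` key as the boolean "no"; restore it
    if ("FALSE" %in% names(s) && !"n" %in% names(s))
      names(s)[names(s) == "FALSE"] <- "n"
    pick <- function(key) if (key %in% names(s)) s[[key]] else NULL
    s$meta <- studyMeta(
      trait_name = pick("trait_name") %||% pick("name") %||% "trait",
      trait_type = pick("trait_type") %||% "continuous",
      unit = pick("unit") %||% "",
      n = pick("n") %||% NA_real_,
      n_cases = pick("n_cases") %||% NA_real_,
      prevalence = pick("prevalence") %||% NA_real_)
    s
  })
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.load_study <- function(s) {
  if (!is.null(s$sumstats)) {
    ss <- s$sumstats
    if (!is(ss, "GwasSumstats"))
      ss <- new("GwasSumstats", variants = as.data.frame(ss),
                meta = s$meta %||% studyMeta("trait"),
                dropCounts = setNames(integer(0), character(0)))
    return(ss)
  }
  readSumstats(s$path, meta = s$meta %||% studyMeta("trait"))
}

## Deterministic per-pair seed independent of study listing order.
.pair_seed <- function(seed, exposure, outcome) {
  h <- sum(utf8ToInt(paste(exposure, outcome, sep = "->")) *
             seq_along(utf8ToInt(paste(exposure, outcome, sep = "->"))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

.result_row <- function(pair, method, fit = NULL, status = "ok",
                        reason = "", flags = "", beta_liab = NA_real_) {
  if (is.null(fit))
    return(data.frame(exposure = pair[1], outcome = pair[2], method = method,
                      beta = NA_real_, se = NA_real_, or = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                      k = NA_integer_, beta_liability = NA_real_,
                      status = status, reason = reason, flags = flags,
                      stringsAsFactors = FALSE))
  data.frame(exposure = pair[1], outcome = pair[2], method = fit@method,
             beta = fit@beta, se = fit@se, or = exp(fit@beta),
             ci_low = fit@ci_low, ci_high = fit@ci_high, p = fit@pvalue,
             k = fit@k_used, beta_liability = beta_liab,
             status = status, reason = reason, flags = flags,
             stringsAsFactors = FALSE)
}

#' Run the full exposure-by-outcome MR grid
#'
#' For every ordered exposure-outcome study pair: select genome-wide
#' significant instruments, LD-clump them, harmonize against the outcome,
#' and fit the primary multiplicative random-effects IVW. Pairs with fewer
#' usable instruments than \code{min_ivs} are reported as not-assessable.
#' Pairs significant after multiple-testing correction over the whole grid
#' receive the full estimator suite (MR-Egger — flagged when the
#' no-measurement-error I-squared is at most 0.9 — weighted median, weighted
#' mode, MR-PRESSO, correlated-instrument IVW) and a full
#' [SensitivityReport-class]; pairs at uncorrected p < 0.05 receive the
#' lighter Egger/median/mode follow-up. Binary-exposure estimates are
#' additionally reported on the liability scale at the exposure's
#' prevalence.
#'
#' @param config List (see [readAnalysisConfig()]) with elements:
#'   \code{studies} (each \code{path} or \code{sumstats}, \code{meta},
#'   \code{roles}, optional \code{ld} matrix / \code{ld_path},
#'   \code{prevalence_bounds}); optional \code{iv_p_threshold} (5e-8),
#'   \code{clump_r2} (0.001), \code{clump_window_kb} (10000),
#'   \code{eaf_ambiguity} (0.08), \code{correction} ("bonferroni"),
#'   \code{alpha} (0.05), \code{min_ivs} (3), \code{force_full_suite}
#'   (FALSE), \code{n_boot} (1000), \code{presso_n_sim} (1000), \code{seed}
#'   (1).
#' @return List with \code{results} (long-format data.frame, one row per
#'   pair x method), \code{sensitivity} (named list of
#'   [SensitivityReport-class]), \code{harmonized} (named list of
#'   [HarmonizedSet-class]), and \code{config}.
#' @export
runGrid <- function(config) {
  st <- config$studies
  if (is.null(names(st)) || any(!nzchar(names(st))))
    names(st) <- vapply(st, function(s)
      if (!is.null(s$meta)) s$meta@trait_name else s$name, character(1))
  p_iv <- config$iv_p_threshold %||% 5e-8
  clump_r2 <- config$clump_r2 %||% 0.001
  clump_win <- config$clump_window_kb %||% 10000
  eaf_amb <- config$eaf_ambiguity %||% 0.08
  correction <- config$correction %||% "bonferroni"
  alpha <- config$alpha %||% 0.05
  min_ivs <- max(3L, as.integer(config$min_ivs %||% 3L))
  seed <- config$seed %||% 1
  n_boot <- config$n_boot %||% 1000
  presso_n_sim <- config$presso_n_sim %||% 1000
  force_full <- isTRUE(config$force_full_suite)

  loaded <- lapply(st, .load_study)
  roles <- lapply(st, function(s) s$roles %||% c("exposure", "outcome"))
  lds <- lapply(st, function(s) {
    if (!is.null(s$ld)) s$ld
    else if (!is.null(s$ld_path)) readLDMatrix(s$ld_path) else NULL
  })

  pairs <- list()
  for (e in names(st)) for (o in names(st)) {
    if (e == o) next
    if ("exposure" %in% roles[[e]] && "outcome" %in% roles[[o]])
      pairs[[paste(e, o, sep = " -> ")]] <- c(e, o)
  }
  if (!length(pairs)) stop("zero eligible exposure-outcome pairs")
  pairs <- pairs[order(names(pairs))]

  harmonized <- list()
  primary <- list()
  rows <- list()
  for (pid in names(pairs)) {
    pr <- pairs[[pid]]
    res <- tryCatch({
      sel <- selectInstruments(loaded[[pr[1]]], p_iv)
      if (nrow(sel) >= 2)
        sel <- suppressWarnings(
          clumpInstruments(sel, ld = lds[[pr[1]]], r2_threshold = clump_r2,
                           window_kb = clump_win))
      h <- harmonizeInstruments(sel, loaded[[pr[2]]],
                                eaf_ambiguity = eaf_amb,
                                exposure_name = pr[1], outcome_name = pr[2])
      harmonized[[pid]] <- h
      if (nrow(usable(h)) < min_ivs) {
        rows[[pid]] <- .result_row(pr, "ivw_multiplicative", status = "not_assessable",
          reason = sprintf("only %d usable IVs (minimum %d)",
                           nrow(usable(h)), min_ivs))
      } else {
        fit <- mrIVW(h)
        primary[[pid]] <- fit
        bl <- NA_real_
        mexp <- loaded[[pr[1]]]@meta
        if (mexp@trait_type == "binary" && !is.na(mexp@prevalence))
          bl <- liabilityBeta(fit@beta, mexp@prevalence)
        rows[[pid]] <- .result_row(pr, fit@method, fit, beta_liab = bl)
      }
      TRUE
    }, error = function(e) e)
    if (inherits(res, "error"))
      rows[[pid]] <- .result_row(pr, "ivw_multiplicative", status = "failed",
                                 reason = conditionMessage(res))
  }

  ## multiple-testing correction over the whole grid (N/A cells included in m)
  m_grid <- length(pairs)
  p_primary <- vapply(primary, function(f) f@pvalue, numeric(1))
  bonf_thr <- alpha / m_grid
  sig_corr <- if (correction == "bonferroni") {
    names(p_primary)[p_primary < bonf_thr]
  } else {
    padded <- c(p_primary, rep(1, m_grid - length(p_primary)))
    adj <- p.adjust(padded, "BH")[seq_along(p_primary)]
    names(p_primary)[adj < alpha]
  }
  sig_nom <- setdiff(names(p_primary)[p_primary < 0.05], sig_corr)
  full_set <- if (force_full) names(p_primary) else sig_corr
  light_set <- if (force_full) character(0) else sig_nom

  sens <- list()
  for (pid in names(primary)) {
    pr <- pairs[[pid]]
    h <- harmonized[[pid]]
    k_use <- nrow(usable(h))
    ps <- .pair_seed(seed, pr[1], pr[2])
    tier <- if (pid %in% full_set) "full" else if (pid %in% light_set) "light" else "none"
    if (tier == "none") next
    mexp <- loaded[[pr[1]]]@meta
    liab <- function(f) if (mexp@trait_type == "binary" &&
                            !is.na(mexp@prevalence))
      liabilityBeta(f@beta, mexp@prevalence) else NA_real_
    add <- function(fit, flags = "") {
      rows[[paste(pid, fit@method)]] <<-
        .result_row(pr, fit@method, fit, flags = flags, beta_liab = liab(fit))
    }
    gate <- i2GX(h)
    if (gate <= 0.9)
      warning(pid, ": I2_GX = ", signif(gate, 3),
              " <= 0.9; MR-Egger estimate flagged (NOME assumption weak)")
    if (k_use >= 3) {
      add(mrEgger(h), flags = if (gate <= 0.9) "i2_gx_below_0.9" else "")
      add(mrMedian(h, n_boot = n_boot, seed = ps))
      add(mrMode(h, n_boot = n_boot, seed = ps))
    }
    if (tier == "full") {
      if (k_use >= 4)
        add(mrPresso(h, n_sim = presso_n_sim, seed = ps))
      ld_e <- lds[[pr[1]]]
      hu <- usable(h)
      ld_corr <- if (!is.null(ld_e) && all(hu$SNP %in% rownames(ld_e))) {
        r <- sqrt(pmax(ld_e[hu$SNP, hu$SNP, drop = FALSE], 0))
        diag(r) <- 1
        r
      } else diag(nrow(hu))
      dimnames(ld_corr) <- list(hu$SNP, hu$SNP)
      add(mrIVWCorrelated(h, ld_corr))
      pb <- st[[pr[2]]]$prevalence_bounds %||% loaded[[pr[2]]]@meta@prevalence
      sens[[pid]] <- sensitivityReport(h, outcome_meta = loaded[[pr[2]]]@meta,
                                       prevalence_bounds = pb,
                                       n_sim = presso_n_sim, seed = ps)
    }
  }

  results <- do.call(rbind, rows)
  results <- results[order(results$exposure, results$outcome, results$method), ]
  rownames(results) <- NULL
  results$bonferroni_threshold <- bonf_thr
  results$significant_corrected <-
    paste(results$exposure, "->", results$outcome) %in% sig_corr &
    results$method == "ivw_multiplicative" & results$status == "ok" &
    results$p < bonf_thr
  list(results = results, sensitivity = sens, harmonized = harmonized,
       config = list(iv_p_threshold = p_iv, clump_r2 = clump_r2,
                     clump_window_kb = clump_win, eaf_ambiguity = eaf_amb,
                     correction = correction, alpha = alpha,
                     min_ivs = min_ivs, seed = seed,
                     m_grid = m_grid))
}

#' Write the analysis grid report
#'
#' Serializes (1) the long-format results table (one row per pair and
#' method, with OR columns equal to the exponentiated beta columns and
#' explicit reason codes for not-assessable pairs), (2) the sensitivity
#' diagnostics table, (3) a run log with package version, configuration and
#' seed, and (4) the per-pair harmonized instrument sets from which every
#' reported number is reproducible.
#'
#' @param run Result of [runGrid()].
#' @param path Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
renderReport <- function(run, path) {
  if (!nrow(run$results)) stop("empty results; nothing to render")
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", path)
  f_res <- file.path(path, "results.tsv")
  data.table::fwrite(run$results, f_res, sep = "\t")

  sens_rows <- lapply(names(run$sensitivity), function(pid) {
    s <- run$sensitivity[[pid]]
    data.frame(pair = pid, q_stat = s@q_stat, q_df = s@q_df, q_p = s@q_p,
               egger_intercept = s@egger_intercept,
               egger_intercept_p = s@egger_intercept_p,
               presso_global_p = s@presso_global_p,
               loo_flagged = sum(s@loo_estimates$flagged),
               steiger_correct = if (length(s@steiger))
                 paste(vapply(s@steiger, function(x)
                   x@correct_direction, logical(1)), collapse = ",") else NA,
               steiger_p = if (length(s@steiger))
                 paste(signif(vapply(s@steiger, function(x)
                   x@p_direction, numeric(1)), 4), collapse = ",") else NA,
               stringsAsFactors = FALSE)
  })
  f_sens <- file.path(path, "sensitivity.tsv")
  data.table::fwrite(
    if (length(sens_rows)) do.call(rbind, sens_rows)
    else data.frame(pair = character(0)), f_sens, sep = "\t")

  f_log <- file.path(path, "run_log.txt")
  writeLines(c(
    paste("ivmr version:", as.character(utils::packageVersion("ivmr"))),
    paste("R version:", R.version.string),
    paste("timestamp:", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    "config:",
    paste0("  ", names(run$config), " = ",
           vapply(run$config, function(x) paste(format(x), collapse = ","),
                  character(1)))
  ), f_log)

  hdir <- file.path(path, "harmonized")
  dir.create(hdir, showWarnings = FALSE)
  f_h <- character(0)
  for (pid in names(run$harmonized)) {
    fn <- file.path(hdir, paste0(gsub("[^A-Za-z0-9_]+", "_", pid), ".tsv"))
    data.table::fwrite(instruments(run$harmonized[[pid]]), fn, sep = "\t")
    f_h <- c(f_h, fn)
  }
  invisible(c(f_res, f_sens, f_log, f_h))
}
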