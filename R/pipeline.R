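# Orchestration of the full bidirectional analysis: per exposure-outcome
# pair, instrument selection (two significance tiers), clumping, proxy
# substitution, harmonization, confounder screening, instrument-strength
# check, Steiger filtering, all estimators; then per-exposure meta-analysis
# across outcome sources, evidence classification, and result tables.

#' Analysis configuration
#'
#' @param p_primary primary instrument-selection threshold (default 5e-8,
#'   genome-wide significance).
#' @param p_fallback relaxed threshold used when too few independent SNPs
#'   reach the primary one (default 5e-6).
#' @param min_snps_for_fallback fewer than this many post-clumping
#'   instruments at the primary tier triggers the fallback tier (default 3).
#' @param tier_mode `"fallback"` (two-tier rule, default), `"force_primary"`
#'   or `"force_fallback"`.
#' @param r2_clump,window_bp LD clumping parameters (defaults 0.001, 10 Mb).
#' @param proxy_r2 minimum r2 for proxy substitution, strict (default 0.80).
#' @param confounder_alpha family-wise level of the confounder screen
#'   (default 0.05; Bonferroni-divided by the instrument count).
#' @param screen_reverse apply the confounder screen in the reverse
#'   direction too (default TRUE).
#' @param n_sim MR-PRESSO simulations (default 1000).
#' @param n_boot weighted-median bootstrap replicates (default 1000).
#' @param seed run seed (mandatory; per-analysis seeds are derived from it
#'   and the trait ids).
#' @param bonferroni_n denominator for the strong-evidence threshold
#'   (default: number of exposures in the batch).
#' @param strong_alpha,suggestive_alpha evidence cut points (defaults
#'   0.0012 and 0.05).
#' @param second_order_wald,f_method,egger_t_dist estimator flags passed
#'   through.
#' @return A list of class `mr_config`.
#' @export
mr_config <- function(p_primary = 5e-8, p_fallback = 5e-6,
                      min_snps_for_fallback = 3,
                      tier_mode = c("fallback", "force_primary", "force_fallback"),
                      r2_clump = 0.001, window_bp = 1e7,
                      proxy_r2 = 0.80,
                      confounder_alpha = 0.05, screen_reverse = TRUE,
                      n_sim = 1000, n_boot = 1000, seed = 1,
                      bonferroni_n = NULL,
                      strong_alpha = NULL, suggestive_alpha = 0.05,
                      second_order_wald = FALSE,
                      f_method = "per_snp", egger_t_dist = FALSE) {
  tier_mode <- match.arg(tier_mode)
  for (p in c(p_primary, p_fallback, suggestive_alpha)) {
    if (p <= 0 || p >= 1) config_error("thresholds must be in (0, 1)")
  }
  structure(as.list(environment()), class = "mr_config")
}

#' Read an analysis configuration from YAML
#'
#' Recognized keys mirror the arguments of [mr_config()]; additionally
#' `exposures`, `outcomes` and `confounders` (named maps trait -> file
#' path), `ld_pairs` and `ld_snps` (LD panel paths) are carried through in
#' the `paths` attribute for [run_bidirectional()] drivers.
#'
#' @param path YAML file path.
#' @return An `mr_config` with attribute `"paths"`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(mr_config))
  cfg <- do.call(mr_config, y[intersect(names(y), known)])
  attr(cfg, "paths") <- y[setdiff(names(y), known)]
  cfg
}

#' Classify evidence strength from a meta-analysis p-value
#'
#' Strict-less comparisons at both cut points: below `strong_alpha` (0.05
#' Bonferroni-divided by the number of exposures, 0.0012 for 41) is strong
#' evidence; between `strong_alpha` and `suggestive_alpha` is suggestive;
#' otherwise none.
#'
#' @param meta_pval p-value in (0, 1\].
#' @param strong_alpha,suggestive_alpha cut points (defaults 0.0012, 0.05).
#' @return `"strong"`, `"suggestive"` or `"none"` (vectorized).
#' @export
classify <- function(meta_pval, strong_alpha = 0.0012, suggestive_alpha = 0.05) {
  ifelse(meta_pval < strong_alpha, "strong",
         ifelse(meta_pval < suggestive_alpha, "suggestive", "none"))
}

not_estimable <- function(stage, reason, log) {
  list(status = "not estimable", stage = stage, reason = reason,
       estimates = NULL, hset = NULL, steiger = NULL, presso = NULL,
       tier = NA_character_, mean_f = NA_real_, log = log)
}

#' Run one exposure-outcome MR analysis
#'
#' Stages, in order: select instruments at the primary threshold and clump;
#' if fewer than `min_snps_for_fallback` independent SNPs remain, reselect at
#' the fallback threshold and clump again; substitute LD proxies for
#' instruments missing from the outcome; harmonize (palindromic SNPs
#' dropped); screen against confounder traits; compute the mean F-statistic
#' (warning when <= 10); Steiger-filter; then estimate with IVW (auto
#' fixed/multiplicative-random), MR-Egger, weighted median, MR-PRESSO and
#' Cochran Q. Every stage is logged with its SNP count. Degenerate inputs
#' yield `status = "not estimable"`, never an error.
#'
#' @param exposure,outcome canonical summary-statistics data.frames.
#' @param config an [mr_config()].
#' @param ld optional [ld_panel()] (no clumping/proxies without it).
#' @param confounders named list of confounder summary-statistics
#'   data.frames.
#' @param analysis_seed seed for the stochastic estimators (default derived
#'   from the config seed and trait ids).
#' @return List with `status`, `tier`, `estimates` (one row per method),
#'   `hset`, `steiger`, `presso`, `mean_f`, `log` (stage, n_snps).
#' @export
run_single <- function(exposure, outcome, config = mr_config(),
                       ld = NULL, confounders = list(),
                       analysis_seed = NULL) {
  exposure_id <- exposure$trait_id[1] %||% "exposure"
  outcome_id <- outcome$trait_id[1] %||% "outcome"
  if (is.null(analysis_seed)) {
    analysis_seed <- seed_for(config$seed, exposure_id, outcome_id)
  }
  log <- data.frame(stage = character(), n_snps = integer(),
                    stringsAsFactors = FALSE)
  note <- function(stage, n) {
    log <<- rbind(log, data.frame(stage = stage, n_snps = n,
                                  stringsAsFactors = FALSE))
  }

  select_and_clump <- function(p) {
    sel <- select_instruments(exposure, p)
    note(sprintf("selected p<%g", p), nrow(sel))
    if (!is.null(ld) && nrow(sel) > 0L) {
      sel <- clump(sel, ld, r2_max = config$r2_clump, window_bp = config$window_bp)
      note(sprintf("clumped p<%g", p), nrow(sel))
    }
    sel
  }

  tier <- "primary"
  if (config$tier_mode == "force_fallback") {
    inst <- select_and_clump(config$p_fallback)
    tier <- "fallback"
  } else {
    inst <- select_and_clump(config$p_primary)
    if (config$tier_mode == "fallback" && nrow(inst) < config$min_snps_for_fallback) {
      inst <- select_and_clump(config$p_fallback)
      tier <- "fallback"
    }
  }
  if (nrow(inst) == 0L) return(not_estimable("selection", "no instruments", log))

  if (!is.null(ld)) {
    prox <- substitute_proxies(inst, outcome, ld, r2_min = config$proxy_r2)
    outcome <- prox$outcome
    note("after proxy substitution", nrow(inst) - sum(!prox$log$found))
  }

  hset <- tryCatch(harmonize(inst, outcome),
                   bidirmr_analysis_error = function(e) NULL)
  if (is.null(hset) || nrow(hset$records) == 0L) {
    return(not_estimable("harmonization", "no harmonizable instruments", log))
  }
  note("harmonized", nrow(hset$records))

  if (length(confounders) > 0L) {
    keep_ids <- confounder_filter(
      hset$records, confounders, alpha = config$confounder_alpha
    )
    drop_ids <- setdiff(hset$records$snp_id, keep_ids$kept$snp_id)
    if (length(drop_ids) > 0L) {
      hset$dropped <- rbind(hset$dropped, data.frame(
        snp_id = drop_ids, reason = "confounder-associated",
        stringsAsFactors = FALSE))
      hset$records <- hset$records[!(hset$records$snp_id %in% drop_ids), , drop = FALSE]
    }
    note("confounder screen", nrow(hset$records))
  }
  if (nrow(hset$records) == 0L) {
    return(not_estimable("confounder screen", "all instruments removed", log))
  }

  fstat <- mean_f_statistic(
    data.frame(beta = hset$records$beta_exp, se = hset$records$se_exp,
               n = hset$records$n_exp),
    method = config$f_method
  )
  if (fstat <= 10) {
    warning(sprintf("%s -> %s: mean F-statistic %.2f <= 10 (weak instruments)",
                    exposure_id, outcome_id, fstat), call. = FALSE)
  }

  st <- steiger_filter(hset)
  hset <- st$hset
  note("steiger filter", nrow(hset$records))
  k <- nrow(hset$records)
  if (k == 0L) return(not_estimable("steiger", "all instruments removed", log))

  ests <- if (k == 1L) {
    list(wald_ratio(hset$records[1, ], second_order = config$second_order_wald))
  } else {
    list(mr_ivw(hset, model = "auto"))
  }
  if (k >= 3L) {
    ests <- c(ests, list(
      mr_egger(hset, t_dist = config$egger_t_dist),
      mr_weighted_median(hset, n_boot = config$n_boot, seed = analysis_seed)
    ))
  }
  presso <- NULL
  if (k >= 4L) {
    presso <- mr_presso(hset, n_sim = config$n_sim, seed = analysis_seed + 1L)
    ests <- c(ests, list(presso$raw),
              if (!is.null(presso$corrected)) list(presso$corrected))
  }
  estimates <- do.call(rbind, ests)
  estimates <- cbind(
    data.frame(exposure_id = exposure_id, outcome_id = outcome_id,
               tier = tier, stringsAsFactors = FALSE),
    estimates
  )
  list(status = "ok", tier = tier, estimates = estimates, hset = hset,
       steiger = st$results, presso = presso, mean_f = fstat, log = log)
}

primary_row <- function(res) {
  # the headline per-source estimate: IVW (auto), or the single-SNP Wald
  est <- res$estimates
  est[est$method %in% c("ivw_fe", "ivw_mre", "wald"), , drop = FALSE][1, , drop = FALSE]
}

#' Run the full bidirectional analysis
#'
#' Forward: every exposure against every outcome source, per-source results
#' meta-combined across sources. Reverse: every outcome source in turn used
#' as the exposure against every forward-exposure trait, combined per trait.
#' Evidence classification uses the meta-analysis p-value (the sole source's
#' p-value when only one source is given, with a notice). Per-pair failures
#' are flagged rows; the batch never aborts on one degenerate trait.
#'
#' @param exposures named list of canonical summary-statistics data.frames
#'   (one per exposure trait).
#' @param outcomes named list of outcome-source data.frames (>= 1; >= 2 for
#'   meta-analysis).
#' @param config an [mr_config()].
#' @param ld optional [ld_panel()].
#' @param confounders named list of confounder data.frames.
#' @param reverse run the reverse direction (default TRUE).
#' @return An object of class `mr_batch`: list with `per_source` (stacked
#'   estimate rows, column `direction`), `meta` (one row per trait and
#'   direction with pooled estimate, OR conversion, classification),
#'   `instrument_log`, `config`.
#' @export
run_bidirectional <- function(exposures, outcomes, config = mr_config(),
                              ld = NULL, confounders = list(),
                              reverse = TRUE) {
  if (length(outcomes) < 1L) config_error("at least one outcome source required")
  if (length(outcomes) < 2L) {
    message("run_bidirectional: single outcome source; meta-analysis skipped")
  }
  strong_alpha <- config$strong_alpha %||%
    bonferroni_threshold(config$bonferroni_n %||% length(exposures))

  per_source <- list()
  meta_rows <- list()
  logs <- list()

  run_pair <- function(exp_tab, out_tab, direction, conf) {
    tryCatch(
      run_single(exp_tab, out_tab, config, ld = ld, confounders = conf),
      error = function(e) not_estimable("error", conditionMessage(e),
                                        data.frame(stage = character(),
                                                   n_snps = integer()))
    )
  }

  collect <- function(results, exposure_id, outcome_label, direction) {
    # results: one run_single result per source
    ok <- !vapply(results, function(r) is.null(r$estimates), logical(1))
    for (s in names(results)) {
      r <- results[[s]]
      lg <- r$log
      if (nrow(lg) > 0L) {
        lg$exposure_id <- exposure_id; lg$source <- s; lg$direction <- direction
        logs[[length(logs) + 1L]] <<- lg
      }
      if (!is.null(r$estimates)) {
        est <- r$estimates
        est$source <- s; est$direction <- direction
        per_source[[length(per_source) + 1L]] <<- est
      }
    }
    prim <- lapply(results[ok], primary_row)
    status <- if (!any(ok)) "not estimable" else "ok"
    if (any(ok)) {
      if (length(prim) >= 2L) {
        mm <- meta_combine(
          data.frame(beta = vapply(prim, `[[`, numeric(1), "beta"),
                     se = vapply(prim, `[[`, numeric(1), "se")),
          model = "auto")
      } else {
        p1 <- prim[[1L]]
        mm <- data.frame(pooled_beta = p1$beta, pooled_se = p1$se,
                         ci_low = p1$ci_low, ci_high = p1$ci_high,
                         pval = p1$pval, model = "single_source",
                         Q = NA_real_, Q_df = NA_integer_, Q_pval = NA_real_,
                         I2 = NA_real_, tau2 = NA_real_, k_sources = 1L,
                         note = "meta skipped: one source",
                         stringsAsFactors = FALSE)
      }
      orci <- or_with_ci(mm$pooled_beta, mm$pooled_se)
      meta_rows[[length(meta_rows) + 1L]] <<- cbind(
        data.frame(trait = exposure_id, against = outcome_label,
                   direction = direction, status = status,
                   stringsAsFactors = FALSE),
        mm,
        data.frame(or = unname(orci["or"]), or_ci_low = unname(orci["ci_low"]),
                   or_ci_high = unname(orci["ci_high"]),
                   classification = classify(mm$pval, strong_alpha,
                                             config$suggestive_alpha),
                   stringsAsFactors = FALSE)
      )
    } else {
      meta_rows[[length(meta_rows) + 1L]] <<- data.frame(
        trait = exposure_id, against = outcome_label, direction = direction,
        status = "not estimable", pooled_beta = NA_real_, pooled_se = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, pval = NA_real_,
        model = NA_character_, Q = NA_real_, Q_df = NA_integer_,
        Q_pval = NA_real_, I2 = NA_real_, tau2 = NA_real_, k_sources = 0L,
        note = paste(unique(vapply(results, `[[`, character(1), "reason")),
                     collapse = "; "),
        or = NA_real_, or_ci_low = NA_real_, or_ci_high = NA_real_,
        classification = "none", stringsAsFactors = FALSE)
    }
  }

  for (e in names(exposures)) {
    res <- lapply(outcomes, function(out_tab) {
      run_pair(exposures[[e]], out_tab, "forward", confounders)
    })
    collect(res, e, outcome_label = paste(names(outcomes), collapse = "+"),
            direction = "forward")
  }

  if (reverse) {
    rev_conf <- if (config$screen_reverse) confounders else list()
    for (e in names(exposures)) {
      res <- lapply(outcomes, function(out_tab) {
        run_pair(out_tab, exposures[[e]], "reverse", rev_conf)
      })
      collect(res, e, outcome_label = paste(names(outcomes), collapse = "+"),
              direction = "reverse")
    }
  }

  structure(
    list(
      per_source = if (length(per_source)) do.call(rbind, per_source) else NULL,
      meta = do.call(rbind, meta_rows),
      instrument_log = if (length(logs)) do.call(rbind, logs) else NULL,
      config = config
    ),
    class = "mr_batch"
  )
}

#' @export
print.mr_batch <- function(x, ...) {
  m <- x$meta
  cat(sprintf("Bidirectional MR batch: %d trait-direction analyses\n", nrow(m)))
  sig <- m[m$classification != "none" & m$status == "ok", , drop = FALSE]
  if (nrow(sig) > 0L) {
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("  [%s] %s (%s): beta=%.3f (p=%.3g) %s\n",
                  sig$classification[i], sig$trait[i], sig$direction[i],
                  sig$pooled_beta[i], sig$pval[i], sig$model[i]))
    }
  } else cat("  no suggestive or strong associations\n")
  invisible(x)
}

#' Write batch result tables as TSVs
#'
#' Writes `results_forward.tsv`, `results_reverse.tsv` (per-source estimate
#' rows), `meta.tsv` and `instrument_log.tsv`. Stored values are never
#' display-rounded, so two runs with the same config and seed produce
#' byte-identical files.
#'
#' @param batch an `mr_batch`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(batch, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  ps <- batch$per_source
  if (!is.null(ps)) {
    wt(ps[ps$direction == "forward", , drop = FALSE], "results_forward.tsv")
    wt(ps[ps$direction == "reverse", , drop = FALSE], "results_reverse.tsv")
  }
  wt(batch$meta, "meta.tsv")
  if (!is.null(batch$instrument_log)) wt(batch$instrument_log, "instrument_log.tsv")
  invisible(dir)
}
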