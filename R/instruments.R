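# Instrument selection and quality control: significance-threshold selection,
# greedy LD clumping, proxy substitution, instrument-strength F statistics,
# confounder screening, and Steiger directionality filtering.

#' Select candidate instruments by association p-value
#'
#' Keeps records with `pval < p_threshold` (strict), sorted by ascending
#' p-value. Genome-wide significance is 5e-8; the relaxed secondary tier used
#' when too few SNPs reach it is 5e-6.
#'
#' @param sumstats canonical summary-statistics data.frame.
#' @param p_threshold selection threshold in (0, 1\].
#' @return The selected rows, sorted by `pval` (ties by `snp_id`).
#' @export
select_instruments <- function(sumstats, p_threshold = 5e-8) {
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
    config_error("p_threshold must be in (0, 1]")
  }
  sel <- sumstats[sumstats$pval < p_threshold, , drop = FALSE]
  sel <- sel[order(sel$pval, sel$snp_id), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Greedy LD clumping
#'
#' Repeatedly takes the remaining SNP with the lowest p-value as an index SNP
#' and removes every remaining SNP on the same chromosome within `window_bp`
#' of it whose r2 with it exceeds `r2_max`. Equal p-values are broken by the
#' lexicographically smaller `snp_id`, so the result does not depend on input
#' order. SNPs absent from the LD panel are treated as unlinked, with a
#' warning.
#'
#' @param candidates canonical summary-statistics data.frame.
#' @param ld an [ld_panel()].
#' @param r2_max LD pruning threshold (default 0.001).
#' @param window_bp physical window in base pairs (default 10 Mb).
#' @return The index SNPs, sorted by p-value.
#' @export
clump <- function(candidates, ld, r2_max = 0.001, window_bp = 1e7) {
  if (nrow(candidates) == 0L) return(candidates)
  ord <- order(candidates$pval, candidates$snp_id)
  cand <- candidates[ord, , drop = FALSE]
  absent <- setdiff(cand$snp_id, ld$meta$snp_id)
  if (length(absent) > 0L) {
    warning(sprintf("clump: %d SNP(s) absent from LD panel treated as unlinked: %s",
                    length(absent), paste(utils::head(absent, 5L), collapse = ", ")),
            call. = FALSE)
  }
  keep <- logical(nrow(cand))
  alive <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i == nrow(cand)) break
    js <- which(alive & seq_len(nrow(cand)) > i)
    for (j in js) {
      if (cand$chrom[j] != cand$chrom[i]) next
      if (abs(cand$pos[j] - cand$pos[i]) > window_bp) next
      if (ld_r2(ld, cand$snp_id[i], cand$snp_id[j])[["r2"]] > r2_max) alive[j] <- FALSE
    }
  }
  res <- cand[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Find an LD proxy for an instrument missing from the outcome study
#'
#' Among outcome SNPs with r2 strictly above `r2_min` to the missing SNP,
#' returns the one with maximal r2 (ties broken by smaller `snp_id`), with
#' the phase sign needed to align its alleles to the missing SNP.
#'
#' @param missing_snp SNP id present in the LD panel.
#' @param outcome_snps character vector of SNP ids available in the outcome.
#' @param ld an [ld_panel()].
#' @param r2_min proxy threshold, strict (default 0.80).
#' @return `list(proxy=, r2=, phase_sign=)` or `NULL` when no SNP qualifies.
#' @export
find_proxy <- function(missing_snp, outcome_snps, ld, r2_min = 0.80) {
  if (!panel_has_snp(ld, missing_snp)) {
    analysis_error(sprintf("SNP %s not in LD panel", missing_snp))
  }
  cands <- setdiff(unique(outcome_snps), missing_snp)
  if (length(cands) == 0L) return(NULL)
  r2s <- vapply(cands, function(s) ld_r2(ld, missing_snp, s)[["r2"]], numeric(1))
  ok <- r2s > r2_min
  if (!any(ok)) return(NULL)
  cands <- cands[ok]; r2s <- r2s[ok]
  best <- cands[order(-r2s, cands)][1L]
  list(proxy = best, r2 = r2s[match(best, cands)],
       phase_sign = ld_r2(ld, missing_snp, best)[["phase_sign"]])
}

#' Substitute proxies into an outcome table for missing instruments
#'
#' For each exposure instrument absent from the outcome summary statistics,
#' searches the LD panel for a proxy ([find_proxy()]); when one is found, the
#' proxy's outcome association is re-expressed on the missing SNP's alleles
#' (sign via the panel's phase information) and inserted under the missing
#' SNP's id, flagged `is_proxy`. Runs before harmonization, so a palindromic
#' proxy is still subject to the palindromic filter.
#'
#' @param instruments exposure instrument data.frame.
#' @param outcome outcome summary-statistics data.frame.
#' @param ld an [ld_panel()].
#' @param r2_min proxy threshold, strict (default 0.80).
#' @return `list(outcome=, log=)`: the augmented outcome table and a
#'   data.frame log (`snp_id`, `proxy`, `r2`, `found`).
#' @export
substitute_proxies <- function(instruments, outcome, ld, r2_min = 0.80) {
  missing <- setdiff(instruments$snp_id, outcome$snp_id)
  log <- data.frame(snp_id = character(), proxy = character(),
                    r2 = numeric(), found = logical(), stringsAsFactors = FALSE)
  if (!("is_proxy" %in% names(outcome)) && nrow(outcome) > 0L) outcome$is_proxy <- FALSE
  for (ms in missing) {
    if (!panel_has_snp(ld, ms)) {
      log <- rbind(log, data.frame(snp_id = ms, proxy = NA_character_,
                                   r2 = NA_real_, found = FALSE))
      next
    }
    hit <- find_proxy(ms, outcome$snp_id, ld, r2_min = r2_min)
    if (is.null(hit)) {
      log <- rbind(log, data.frame(snp_id = ms, proxy = NA_character_,
                                   r2 = NA_real_, found = FALSE))
      next
    }
    prow <- outcome[match(hit$proxy, outcome$snp_id), , drop = FALSE]
    pmeta <- ld$meta[match(hit$proxy, ld$meta$snp_id), ]
    mmeta <- ld$meta[match(ms, ld$meta$snp_id), ]
    # express the proxy's effect relative to its panel allele1 ...
    beta1 <- if (prow$effect_allele == pmeta$allele1) prow$beta else -prow$beta
    eaf1 <- if (prow$effect_allele == pmeta$allele1) prow$eaf else 1 - prow$eaf
    # ... then carry it to the missing SNP's allele1 through the phase sign
    beta_m <- hit$phase_sign * beta1
    eaf_m <- if (hit$phase_sign > 0) eaf1 else 1 - eaf1
    sub <- prow
    sub$snp_id <- ms
    sub$chrom <- mmeta$chrom; sub$pos <- mmeta$pos
    sub$effect_allele <- mmeta$allele1; sub$other_allele <- mmeta$allele2
    sub$beta <- beta_m; sub$eaf <- eaf_m
    sub$is_proxy <- TRUE
    outcome <- rbind(outcome, sub)
    log <- rbind(log, data.frame(snp_id = ms, proxy = hit$proxy,
                                 r2 = hit$r2, found = TRUE))
  }
  rownames(outcome) <- NULL
  list(outcome = outcome, log = log)
}

#' Mean F-statistic of an instrument set
#'
#' Instrument strength. The default is the mean over SNPs of the per-SNP
#' squared z-score, F_j = (beta_j/se_j)^2, which needs no allele frequencies
#' and is the common two-sample summary-data form. The variance-explained
#' alternative F = (n-k-1)/k * R2/(1-R2), with R2 summed over the k SNPs via
#' r2_j = F_j/(F_j + n - 2), is available behind `method`. A mean F above 10
#' is the conventional weak-instrument bar.
#'
#' @param instruments canonical summary-statistics data.frame (nonempty).
#' @param method `"per_snp"` (default) or `"r2_based"`.
#' @return The mean F-statistic (a single number).
#' @export
mean_f_statistic <- function(instruments, method = c("per_snp", "r2_based")) {
  method <- match.arg(method)
  if (is.null(instruments) || nrow(instruments) == 0L) {
    analysis_error("mean_f_statistic: empty instrument set")
  }
  f <- (instruments$beta / instruments$se)^2
  if (method == "per_snp") return(mean(f))
  k <- nrow(instruments)
  n <- mean(instruments$n)
  r2 <- sum(f / (f + instruments$n - 2))
  (n - k - 1) / k * r2 / (1 - r2)
}

#' Screen instruments for association with measured confounders
#'
#' Removes any instrument associated with any confounder trait at a
#' Bonferroni-corrected level: threshold = alpha / (number of candidate
#' instruments), evaluated against the pre-filter instrument count. A SNP
#' absent from a confounder file provides no evidence and is kept (with a
#' warning).
#'
#' @param instruments canonical summary-statistics data.frame (or any
#'   data.frame with `snp_id`).
#' @param confounder_sumstats named list of confounder summary-statistics
#'   data.frames (names = trait ids; a `trait_id` column also works).
#' @param alpha family-wise level (default 0.05).
#' @return `list(kept=, removed=)`, `removed` a data.frame with `snp_id`,
#'   `trait_id`, `pval`.
#' @export
confounder_filter <- function(instruments, confounder_sumstats = list(), alpha = 0.05) {
  removed <- data.frame(snp_id = character(), trait_id = character(),
                        pval = numeric(), stringsAsFactors = FALSE)
  if (length(confounder_sumstats) == 0L || nrow(instruments) == 0L) {
    return(list(kept = instruments, removed = removed))
  }
  threshold <- alpha / nrow(instruments)
  labels <- names(confounder_sumstats) %||% rep(NA_character_, length(confounder_sumstats))
  missing_any <- character()
  for (ci in seq_along(confounder_sumstats)) {
    conf <- confounder_sumstats[[ci]]
    lab <- if (!is.null(labels[ci]) && nzchar(labels[ci] %||% "")) labels[ci] else conf$trait_id[1]
    idx <- match(instruments$snp_id, conf$snp_id)
    missing_any <- union(missing_any, instruments$snp_id[is.na(idx)])
    hit <- which(!is.na(idx) & conf$pval[idx] < threshold)
    if (length(hit) > 0L) {
      removed <- rbind(removed, data.frame(
        snp_id = instruments$snp_id[hit], trait_id = lab,
        pval = conf$pval[idx[hit]], stringsAsFactors = FALSE
      ))
    }
  }
  if (length(missing_any) > 0L) {
    warning(sprintf("confounder_filter: %d SNP(s) absent from at least one confounder file kept without evidence",
                    length(missing_any)), call. = FALSE)
  }
  kept <- instruments[!(instruments$snp_id %in% removed$snp_id), , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, removed = removed)
}

#' Steiger directionality test and filter
#'
#' A valid instrument should explain more variance in the exposure than in
#' the outcome. Per SNP, variance explained is approximated from summary data
#' as r2 = F/(F + n - 2) with F = (beta/se)^2 (for a binary outcome this is
#' applied on the log-odds scale with the effective sample size). The
#' directionality z-statistic compares Fisher-transformed correlations,
#' z = (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
#'     sqrt(1/(n_exp-3) + 1/(n_out-3)),
#' with a two-sided normal p-value. A SNP is removed iff r2_out > r2_exp
#' (strict, so ties are kept).
#'
#' @param hset a [harmonized_set()] whose records carry `n_exp`, `n_out`.
#' @return `list(hset=, results=)`: the filtered set (removed SNPs appended
#'   to `dropped` with reason `"steiger"`) and a data.frame of per-SNP
#'   results (`snp_id`, `r2_exp`, `r2_out`, `z`, `pval`, `correct_direction`).
#' @export
steiger_filter <- function(hset) {
  r <- hset$records
  if (nrow(r) == 0L) return(list(hset = hset, results = data.frame()))
  if (any(r$n_exp <= 3 | r$n_out <= 3)) analysis_error("steiger_filter: sample size must exceed 3")
  f_exp <- (r$beta_exp / r$se_exp)^2
  f_out <- (r$beta_out / r$se_out)^2
  r2_exp <- f_exp / (f_exp + r$n_exp - 2)
  r2_out <- f_out / (f_out + r$n_out - 2)
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (r$n_exp - 3) + 1 / (r$n_out - 3))
  res <- data.frame(
    snp_id = r$snp_id, r2_exp = r2_exp, r2_out = r2_out, z = z,
    pval = z_pval(z, 1), correct_direction = r2_exp >= r2_out,
    stringsAsFactors = FALSE
  )
  bad <- r2_out > r2_exp
  out <- hset
  out$records <- r[!bad, , drop = FALSE]
  rownames(out$records) <- NULL
  if (any(bad)) {
    out$dropped <- rbind(out$dropped, data.frame(
      snp_id = r$snp_id[bad], reason = "steiger", stringsAsFactors = FALSE
    ))
  }
  list(hset = out, results = res)
}
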