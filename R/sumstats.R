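# GWAS summary statistics: canonical representation, readers/writers, and
# allele harmonization between an exposure and an outcome study.
#
# A summary-statistics table is a plain data.frame with canonical columns
#   snp_id, chrom, pos, effect_allele, other_allele, eaf, beta, se, pval, n,
#   trait_id
# one row per biallelic SNP. `beta` is the per-allele effect of
# `effect_allele` on the trait (SD units for inverse-normalized continuous
# traits, log-odds for binary traits); `se` its standard error; `eaf` the
# effect-allele frequency (may be NA); `n` the sample size (for case-control
# traits the effective sample size 4/(1/ncase + 1/ncontrol)).

SUMSTATS_COLS <- c(
  "snp_id", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pval", "n", "trait_id"
)

#' Default header-name mapping for summary-statistics files
#'
#' GWAS summary files have no single standard header; readers accept a column
#' map from canonical field names to the names used in a particular file.
#' These are the defaults.
#'
#' @return Named character vector mapping canonical names to file headers.
#' @export
default_column_map <- function() {
  c(
    snp_id = "snp", chrom = "chr", pos = "pos",
    effect_allele = "ea", other_allele = "oa", eaf = "eaf",
    beta = "beta", se = "se", pval = "pval", n = "n", trait_id = "trait"
  )
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Is an allele pair palindromic (A/T or C/G)?
#'
#' Palindromic SNPs have the same allele pair on both strands, so strand
#' cannot be resolved from alleles alone.
#'
#' @param a1,a2 allele characters.
#' @return Logical vector.
#' @export
is_palindromic <- function(a1, a2) {
  unname(COMPLEMENT[a1] == a2)
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Accepts tab- or comma-delimited files with a header row (delimiter is
#' sniffed from the header); gzip-compressed files are read transparently.
#' Alleles are upper-cased. Rows that cannot form a valid biallelic SNP
#' record are rejected with a reason and reported: non-ACGT alleles (this
#' excludes indels and multi-allelic sites), identical alleles, nonpositive
#' SE, or a p-value outside (0, 1]. Rejected rows are returned in the
#' `"rejected"` attribute (columns `row`, `snp_id`, `reason`).
#'
#' @param path file path.
#' @param column_map named character vector overriding [default_column_map()]
#'   entries; only the canonical names present are overridden.
#' @param trait_id optional trait label stored in `trait_id` when the file has
#'   no trait column.
#' @return A data.frame with the canonical summary-statistics columns.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_id = NULL) {
  if (!file.exists(path)) input_error(sprintf("file not found: %s", path))
  con <- file(path, "r")  # file() decompresses gzip transparently
  header <- readLines(con, n = 1L)
  close(con)
  if (length(header) == 0L || !nzchar(header)) input_error(sprintf("empty file: %s", path))
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (nrow(raw) == 0L) input_error(sprintf("empty file (header only): %s", path))

  cmap <- default_column_map()
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  mandatory <- setdiff(SUMSTATS_COLS, c("eaf", "trait_id"))
  for (canon in mandatory) {
    if (!(cmap[[canon]] %in% names(raw))) {
      config_error(sprintf("missing mandatory column '%s' (expected header '%s') in %s",
                           canon, cmap[[canon]], path))
    }
  }

  out <- data.frame(
    snp_id = as.character(raw[[cmap[["snp_id"]]]]),
    chrom = as.character(raw[[cmap[["chrom"]]]]),
    pos = as.integer(raw[[cmap[["pos"]]]]),
    effect_allele = toupper(as.character(raw[[cmap[["effect_allele"]]]])),
    other_allele = toupper(as.character(raw[[cmap[["other_allele"]]]])),
    eaf = if (cmap[["eaf"]] %in% names(raw)) as.numeric(raw[[cmap[["eaf"]]]]) else NA_real_,
    beta = as.numeric(raw[[cmap[["beta"]]]]),
    se = as.numeric(raw[[cmap[["se"]]]]),
    pval = as.numeric(raw[[cmap[["pval"]]]]),
    n = as.integer(round(as.numeric(raw[[cmap[["n"]]]]))),
    trait_id = if (cmap[["trait_id"]] %in% names(raw)) {
      as.character(raw[[cmap[["trait_id"]]]])
    } else {
      trait_id %||% NA_character_
    },
    stringsAsFactors = FALSE
  )

  acgt <- c("A", "C", "G", "T")
  reason <- rep(NA_character_, nrow(out))
  bad_allele <- !(out$effect_allele %in% acgt) | !(out$other_allele %in% acgt)
  reason[bad_allele] <- "non-ACGT allele"
  same <- !bad_allele & out$effect_allele == out$other_allele
  reason[same] <- "identical alleles"
  bad_se <- is.na(reason) & (!is.finite(out$se) | out$se <= 0)
  reason[bad_se] <- "nonpositive SE"
  bad_p <- is.na(reason) & (!is.finite(out$pval) | out$pval <= 0 | out$pval > 1)
  reason[bad_p] <- "p-value outside (0,1]"
  bad_beta <- is.na(reason) & !is.finite(out$beta)
  reason[bad_beta] <- "non-numeric beta"

  rejected <- data.frame(
    row = which(!is.na(reason)),
    snp_id = out$snp_id[!is.na(reason)],
    reason = reason[!is.na(reason)],
    stringsAsFactors = FALSE
  )
  if (nrow(rejected) > 0L) {
    message(sprintf("read_sumstats: rejected %d of %d rows (%s)",
                    nrow(rejected), nrow(out),
                    paste(unique(rejected$reason), collapse = "; ")))
  }
  out <- out[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write summary statistics as a headered TSV
#'
#' @param x canonical summary-statistics data.frame.
#' @param path output path (ending in `.gz` for gzip).
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  y <- x[, intersect(SUMSTATS_COLS, names(x)), drop = FALSE]
  names(y) <- unname(default_column_map()[names(y)])
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  utils::write.table(y, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Align the alleles of one outcome record to one exposure record
#'
#' Ensures both effects refer to the same effect allele. Direct allele match
#' is kept as is; a swapped pair (exposure effect allele equals outcome other
#' allele and vice versa) flips the sign of the outcome beta; a pair that
#' matches only after complementing the outcome alleles is a strand flip
#' (combined with a sign flip when also swapped). Palindromic SNPs (A/T or
#' C/G) cannot be strand-resolved from alleles: the default policy drops
#' them; `keep_if_eaf_informative` keeps them when both allele frequencies
#' are far enough from 0.5 to infer orientation, flipping the sign when the
#' frequencies sit on opposite sides.
#'
#' @param exp,out one-row data.frames (or lists) with canonical summary-stat
#'   fields, for the same `snp_id`.
#' @param palindromic_policy `"drop"` (default) or `"keep_if_eaf_informative"`.
#' @param eaf_margin minimum |eaf - 0.5| on both sides for a palindromic SNP
#'   to count as frequency-informative (default 0.08).
#' @return A one-row data.frame with columns `snp_id`, `beta_exp`, `se_exp`,
#'   `pval_exp`, `beta_out`, `se_out`, `pval_out`, `n_exp`, `n_out`,
#'   `action_taken`, `is_proxy` — or, when the pair must be dropped, `NULL`
#'   with the drop reason in attribute `"reason"`.
#' @export
align_alleles <- function(exp, out,
                          palindromic_policy = c("drop", "keep_if_eaf_informative"),
                          eaf_margin = 0.08) {
  palindromic_policy <- match.arg(palindromic_policy)
  stopifnot(exp$snp_id == out$snp_id)

  drop <- function(reason) structure(list(NULL), class = "dropped_snp", reason = reason)

  e_ea <- exp$effect_allele; e_oa <- exp$other_allele
  o_ea <- out$effect_allele; o_oa <- out$other_allele
  beta_out <- out$beta
  action <- NULL

  if (is_palindromic(e_ea, e_oa)) {
    if (palindromic_policy == "drop") return(drop("palindromic"))
    # Orientation from allele frequency: only trustworthy away from 0.5.
    if (!identical(sort(c(e_ea, e_oa)), sort(c(o_ea, o_oa)))) return(drop("allele mismatch"))
    f_e <- exp$eaf; f_o <- if (e_ea == o_ea) out$eaf else 1 - out$eaf
    if (is.na(f_e) || is.na(f_o) ||
        abs(f_e - 0.5) < eaf_margin || abs(f_o - 0.5) < eaf_margin) {
      return(drop("palindromic (eaf uninformative)"))
    }
    same_side <- (f_e - 0.5) * (f_o - 0.5) > 0
    if (e_ea == o_ea) {
      if (same_side) action <- "kept" else { action <- "sign_flipped"; beta_out <- -beta_out }
    } else {
      if (same_side) { action <- "sign_flipped"; beta_out <- -beta_out } else action <- "kept"
    }
  } else if (e_ea == o_ea && e_oa == o_oa) {
    action <- "kept"
  } else if (e_ea == o_oa && e_oa == o_ea) {
    action <- "sign_flipped"; beta_out <- -beta_out
  } else {
    c_ea <- unname(COMPLEMENT[o_ea]); c_oa <- unname(COMPLEMENT[o_oa])
    if (e_ea == c_ea && e_oa == c_oa) {
      action <- "strand_flipped"
    } else if (e_ea == c_oa && e_oa == c_ea) {
      action <- "strand_flipped_and_sign_flipped"; beta_out <- -beta_out
    } else {
      return(drop("allele mismatch"))
    }
  }

  data.frame(
    snp_id = exp$snp_id,
    beta_exp = exp$beta, se_exp = exp$se, pval_exp = exp$pval,
    beta_out = beta_out, se_out = out$se, pval_out = out$pval,
    n_exp = exp$n, n_out = out$n,
    action_taken = action,
    is_proxy = isTRUE(out$is_proxy),
    stringsAsFactors = FALSE
  )
}

#' Construct a harmonized instrument set
#'
#' Container for the per-SNP aligned exposure/outcome effect pairs of one
#' exposure-outcome analysis, plus the SNPs dropped on the way with reasons.
#'
#' @param exposure_id,outcome_id trait labels.
#' @param records data.frame of harmonized records (see [align_alleles()]).
#' @param dropped data.frame with columns `snp_id`, `reason`.
#' @return An object of class `harmonized_set`.
#' @export
harmonized_set <- function(exposure_id, outcome_id, records, dropped = NULL) {
  if (is.null(dropped)) {
    dropped <- data.frame(snp_id = character(), reason = character(),
                          stringsAsFactors = FALSE)
  }
  if (anyDuplicated(records$snp_id)) analysis_error("duplicate snp_id in harmonized records")
  structure(
    list(exposure_id = exposure_id, outcome_id = outcome_id,
         records = records, dropped = dropped),
    class = "harmonized_set"
  )
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized instrument set: %s -> %s\n  %d SNPs kept, %d dropped\n",
              x$exposure_id, x$outcome_id, nrow(x$records), nrow(x$dropped)))
  if (nrow(x$dropped) > 0L) {
    tab <- table(x$dropped$reason)
    cat(paste(sprintf("    %s: %d", names(tab), as.integer(tab)), collapse = "\n"), "\n")
  }
  invisible(x)
}

empty_harmonized_records <- function() {
  data.frame(
    snp_id = character(), beta_exp = numeric(), se_exp = numeric(),
    pval_exp = numeric(), beta_out = numeric(), se_out = numeric(),
    pval_out = numeric(), n_exp = integer(), n_out = integer(),
    action_taken = character(), is_proxy = logical(),
    stringsAsFactors = FALSE
  )
}

#' Harmonize exposure and outcome summary statistics
#'
#' Intersects the two tables by `snp_id` and aligns each shared SNP with
#' [align_alleles()]. Exposure SNPs absent from the outcome are dropped with
#' reason `"missing in outcome"` (proxy substitution, when wanted, must be
#' applied to the outcome table beforehand — see [substitute_proxies()]).
#' Every exposure SNP appears exactly once, in `records` or `dropped`.
#'
#' @param exposure,outcome canonical summary-statistics data.frames.
#' @param palindromic_policy,eaf_margin passed to [align_alleles()].
#' @return A [harmonized_set()].
#' @export
harmonize <- function(exposure, outcome,
                      palindromic_policy = c("drop", "keep_if_eaf_informative"),
                      eaf_margin = 0.08) {
  palindromic_policy <- match.arg(palindromic_policy)
  out_idx <- match(exposure$snp_id, outcome$snp_id)
  if (all(is.na(out_idx))) analysis_error("no shared instruments")

  recs <- vector("list", nrow(exposure))
  drop_id <- character(); drop_reason <- character()
  for (i in seq_len(nrow(exposure))) {
    j <- out_idx[i]
    if (is.na(j)) {
      drop_id <- c(drop_id, exposure$snp_id[i])
      drop_reason <- c(drop_reason, "missing in outcome")
      next
    }
    r <- align_alleles(exposure[i, ], outcome[j, ],
                       palindromic_policy = palindromic_policy,
                       eaf_margin = eaf_margin)
    if (inherits(r, "dropped_snp")) {
      drop_id <- c(drop_id, exposure$snp_id[i])
      drop_reason <- c(drop_reason, attr(r, "reason"))
    } else {
      recs[[i]] <- r
    }
  }
  records <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(records)) records <- empty_harmonized_records()
  harmonized_set(
    exposure_id = exposure$trait_id[1] %||% NA_character_,
    outcome_id = outcome$trait_id[1] %||% NA_character_,
    records = records,
    dropped = data.frame(snp_id = drop_id, reason = drop_reason,
                         stringsAsFactors = FALSE)
  )
}

#' Write a harmonized set as TSV with a dropped-SNP sidecar
#'
#' @param hset a [harmonized_set()].
#' @param path output TSV path; the sidecar is written next to it as
#'   `<path without extension>.dropped.tsv`.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(hset, path) {
  utils::write.table(hset$records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- sub("\\.tsv$", "", path)
  utils::write.table(hset$dropped, paste0(side, ".dropped.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
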