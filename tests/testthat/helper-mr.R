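# Shared fixture builders and independent oracles for the test suite.
# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# one canonical summary-statistics row
rec <- function(snp_id = "rs1", chrom = "1", pos = 1000L,
                ea = "A", oa = "G", eaf = 0.3,
                beta = 0.1, se = 0.02, pval = NULL,
                n = 8000L, trait_id = "trait") {
  data.frame(
    snp_id = snp_id, chrom = chrom, pos = pos,
    effect_allele = ea, other_allele = oa, eaf = eaf,
    beta = beta, se = se,
    pval = if (is.null(pval)) 2 * pnorm(-abs(beta / se)) else pval,
    n = n, trait_id = trait_id, stringsAsFactors = FALSE
  )
}

sumstats_frame <- function(...) do.call(rbind, list(...))

# harmonized-record frame straight from effect vectors (fast estimator input)
hrecs <- function(bx, bxse, by, byse, n_exp = 8000L, n_out = 8000L,
                  ids = sprintf("rs%03d", seq_along(bx))) {
  data.frame(
    snp_id = ids, beta_exp = bx, se_exp = bxse, pval_exp = 2 * pnorm(-abs(bx / bxse)),
    beta_out = by, se_out = byse, pval_out = 2 * pnorm(-abs(by / byse)),
    n_exp = n_exp, n_out = n_out,
    action_taken = "kept", is_proxy = FALSE, stringsAsFactors = FALSE
  )
}

hset_of <- function(records) harmonized_set("X", "Y", records)

# independent weighted-least-squares oracle via lm(): slope of by on bx
wls_oracle <- function(bx, by, w, intercept = TRUE) {
  fit <- if (intercept) lm(by ~ bx, weights = w) else lm(by ~ 0 + bx, weights = w)
  coef(fit)
}

# brute-force weighted median oracle: dense grid over the interpolated cdf
wm_oracle <- function(r, w) {
  ord <- order(r)
  r <- r[ord]; w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  approx(p, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

# a tiny LD panel around three loci for clump/proxy tests
toy_panel <- function() {
  meta <- data.frame(
    snp_id = c("rs1", "rs2", "rs3", "rs4"),
    chrom = c("1", "1", "1", "2"),
    pos = c(1000L, 5000L, 20000000L, 1000L),
    allele1 = c("A", "A", "A", "A"),
    allele2 = c("G", "G", "G", "G"),
    stringsAsFactors = FALSE
  )
  pairs <- data.frame(
    snp_a = c("rs1", "rs1"), snp_b = c("rs2", "rs3"),
    r2 = c(0.5, 0.0), phase_sign = c(1L, 1L),
    stringsAsFactors = FALSE
  )
  ld_panel(meta, pairs)
}
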