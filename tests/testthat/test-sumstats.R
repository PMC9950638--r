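test_that("read_sumstats parses well-formed files, normalizes case, rejects bad rows", {
  tab <- data.frame(
    snp = c("rs1", "rs2", "rs3"), chr = c("1", "1", "2"),
    pos = c(100, 200, 300), ea = c("a", "C", "T"), oa = c("g", "T", "G"),
    eaf = c(0.2, 0.3, 0.4), beta = c(0.1, -0.2, 0.05),
    se = c(0.02, 0.04, 0.01), pval = c(1e-6, 1e-6, 1e-6), n = c(100, 100, 100)
  )
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_sumstats(path, trait_id = "t")
  expect_equal(nrow(got), 3L)
  expect_equal(got$effect_allele, c("A", "C", "T"))   # case normalization
  expect_equal(got$other_allele[1], "G")
  expect_equal(got$beta, tab$beta)
  expect_equal(got$trait_id, rep("t", 3))

  # CSV dialect with a custom column map
  tab2 <- tab
  names(tab2)[names(tab2) == "snp"] <- "rsid"
  path2 <- tempfile(fileext = ".csv")
  write.table(tab2, path2, sep = ",", quote = FALSE, row.names = FALSE)
  got2 <- read_sumstats(path2, column_map = c(snp_id = "rsid"))
  expect_equal(got2$snp_id, got$snp_id)

  # gzip transparently
  pathgz <- tempfile(fileext = ".tsv.gz")
  con <- gzfile(pathgz, "w")
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  expect_equal(read_sumstats(pathgz)$beta, got$beta)

  # rejection rules: nonpositive SE, indel alleles, identical alleles
  bad <- tab
  bad$se[1] <- 0
  bad$ea[2] <- "AT"
  bad$oa[3] <- "T"; bad$ea[3] <- "T"
  path3 <- tempfile(fileext = ".tsv")
  write.table(bad, path3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(got3 <- read_sumstats(path3), "rejected 3")
  expect_equal(nrow(got3), 0L)
  rej <- attr(got3, "rejected")
  expect_setequal(rej$reason, c("nonpositive SE", "non-ACGT allele", "identical alleles"))
})

test_that("read_sumstats errors name the missing column and flag empty files", {
  path <- tempfile(fileext = ".tsv")
  tab <- data.frame(snp = "rs1", chr = "1", pos = 1, ea = "A", oa = "G",
                    beta = 0.1, se = 0.02, pval = 0.5, n = 10)
  write.table(tab[, setdiff(names(tab), "se")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(path), "se", class = "bidirmr_config_error")

  empty <- tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  expect_error(read_sumstats(empty), "empty", class = "bidirmr_input_error")
  header_only <- tempfile(fileext = ".tsv")
  writeLines("snp\tchr\tpos\tea\toa\tbeta\tse\tpval\tn", header_only)
  expect_error(read_sumstats(header_only), "empty", class = "bidirmr_input_error")
})

test_that("align_alleles handles identity, swap, strand flip and palindromes", {
  e <- rec(ea = "A", oa = "G", beta = 0.10)

  same <- align_alleles(e, rec(ea = "A", oa = "G", beta = 0.05))
  expect_equal(same$action_taken, "kept")
  expect_equal(same$beta_out, 0.05)

  swapped <- align_alleles(e, rec(ea = "G", oa = "A", beta = 0.05))
  expect_equal(swapped$action_taken, "sign_flipped")
  expect_equal(swapped$beta_out, -0.05)

  flipped <- align_alleles(e, rec(ea = "T", oa = "C", beta = 0.05))
  expect_equal(flipped$action_taken, "strand_flipped")
  expect_equal(flipped$beta_out, 0.05)

  both <- align_alleles(e, rec(ea = "C", oa = "T", beta = 0.05))
  expect_equal(both$action_taken, "strand_flipped_and_sign_flipped")
  expect_equal(both$beta_out, -0.05)

  pal <- align_alleles(rec(ea = "A", oa = "T"), rec(ea = "A", oa = "T"))
  expect_s3_class(pal, "dropped_snp")
  expect_equal(attr(pal, "reason"), "palindromic")

  mismatch <- align_alleles(e, rec(ea = "A", oa = "C"))
  expect_equal(attr(mismatch, "reason"), "allele mismatch")
})

test_that("palindromic keep_if_eaf_informative uses frequency concordance", {
  e <- rec(ea = "A", oa = "T", eaf = 0.2, beta = 0.1)
  same_side <- align_alleles(e, rec(ea = "A", oa = "T", eaf = 0.25, beta = 0.05),
                             palindromic_policy = "keep_if_eaf_informative")
  expect_equal(same_side$action_taken, "kept")
  expect_equal(same_side$beta_out, 0.05)
  # frequencies on opposite sides: the outcome file reports the other strand
  opp <- align_alleles(e, rec(ea = "A", oa = "T", eaf = 0.75, beta = 0.05),
                       palindromic_policy = "keep_if_eaf_informative")
  expect_equal(opp$action_taken, "sign_flipped")
  # near 0.5: ambiguous, dropped
  amb <- align_alleles(e, rec(ea = "A", oa = "T", eaf = 0.48, beta = 0.05),
                       palindromic_policy = "keep_if_eaf_informative")
  expect_s3_class(amb, "dropped_snp")
})

test_that("alignment is involution-safe and sign-flip round-trips", {
  set.seed(42)
  for (i in 1:50) {
    pair <- rbind(c("A", "G"), c("T", "C"), c("C", "A"), c("G", "T"))[sample(4, 1), ]
    e <- rec(ea = pair[1], oa = pair[2], beta = rnorm(1))
    o <- rec(ea = pair[1], oa = pair[2], beta = rnorm(1), se = 0.03)
    h1 <- align_alleles(e, o)
    expect_equal(h1$action_taken, "kept")
    # already-harmonized pair: applying alignment again is a no-op
    o2 <- o; o2$beta <- h1$beta_out
    expect_equal(align_alleles(e, o2)$beta_out, h1$beta_out)
    # flipping outcome alleles AND beta sign gives an identical record
    oflip <- o
    oflip$effect_allele <- pair[2]; oflip$other_allele <- pair[1]
    oflip$beta <- -o$beta; oflip$eaf <- 1 - o$eaf
    h2 <- align_alleles(e, oflip)
    expect_equal(h2$beta_out, h1$beta_out)
    expect_equal(h2$se_out, h1$se_out)
  }
})

test_that("harmonize intersects, drops with reasons, and conserves counts", {
  exp5 <- do.call(rbind, lapply(1:5, function(i) {
    rec(snp_id = paste0("rs", i), pos = i * 1000L, trait_id = "cytokine")
  }))
  out5 <- exp5
  out5$beta <- rnorm(5, 0, 0.02)
  out5$trait_id <- "pdr"
  h <- harmonize(exp5, out5)
  expect_equal(nrow(h$records), 5L)
  expect_equal(nrow(h$dropped), 0L)
  expect_equal(h$exposure_id, "cytokine")
  expect_equal(h$outcome_id, "pdr")

  h2 <- harmonize(exp5, out5[1:3, ])
  expect_equal(nrow(h2$records), 3L)
  expect_equal(h2$dropped$reason, rep("missing in outcome", 2))

  exp_pal <- exp5[1:4, ]
  exp_pal$effect_allele[2] <- "C"; exp_pal$other_allele[2] <- "G"
  out_pal <- exp_pal
  h3 <- harmonize(exp_pal, out_pal)
  expect_equal(nrow(h3$records), 3L)
  expect_equal(h3$dropped$reason, "palindromic")

  # count conservation across randomized inputs
  set.seed(7)
  for (i in 1:20) {
    n_e <- sample(3:10, 1)
    e <- do.call(rbind, lapply(seq_len(n_e), function(j) {
      pal <- runif(1) < 0.3
      rec(snp_id = paste0("rs", j), ea = if (pal) "A" else "A",
          oa = if (pal) "T" else "G", pos = j * 1000L)
    }))
    o <- e[sample(n_e, sample(n_e, 1)), ]
    o$beta <- rnorm(nrow(o))
    h <- tryCatch(harmonize(e, o), bidirmr_analysis_error = function(err) NULL)
    if (is.null(h)) next
    expect_equal(nrow(h$records) + nrow(h$dropped), n_e)
    expect_false(anyDuplicated(c(h$records$snp_id, h$dropped$snp_id)) > 0)
  }
})

test_that("harmonize with no shared SNPs is an analysis error", {
  e <- rec(snp_id = "rs1")
  o <- rec(snp_id = "rs2")
  expect_error(harmonize(e, o), "no shared instruments",
               class = "bidirmr_analysis_error")
})

test_that("harmonized sets round-trip through TSV with a dropped sidecar", {
  h <- hset_of(hrecs(c(0.1, 0.2), 0.01, c(0.02, 0.03), 0.01))
  h$dropped <- data.frame(snp_id = "rsX", reason = "palindromic")
  path <- file.path(tempdir(), "hset.tsv")
  write_harmonized(h, path)
  back <- read.delim(path)
  expect_equal(back$beta_exp, h$records$beta_exp)
  side <- read.delim(sub("\\.tsv$", ".dropped.tsv", path))
  expect_equal(side$reason, "palindromic")
})
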