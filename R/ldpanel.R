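# Summary-level linkage-disequilibrium panel: pairwise r2 with signed allele
# phase, plus per-SNP metadata. Replaces online LD services with a local
# table; sufficient for clumping and proxy lookup (no genotype-level LD).

#' Construct an LD panel
#'
#' @param meta data.frame with columns `snp_id`, `chrom`, `pos`, `allele1`,
#'   `allele2` (one row per SNP known to the panel).
#' @param pairs data.frame with columns `snp_a`, `snp_b`, `r2` in \[0,1\] and
#'   `phase_sign` in \{+1, -1\}: +1 when `snp_b`'s allele1 co-occurs with
#'   `snp_a`'s allele1 on a haplotype. Pairs are stored symmetrically; the
#'   diagonal (r2 = 1) is implicit.
#' @return An object of class `ld_panel`.
#' @export
ld_panel <- function(meta, pairs = NULL) {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    pairs <- data.frame(snp_a = character(), snp_b = character(),
                        r2 = numeric(), phase_sign = integer(),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("snp_id", "chrom", "pos", "allele1", "allele2") %in% names(meta)),
            all(c("snp_a", "snp_b", "r2", "phase_sign") %in% names(pairs)))
  if (any(pairs$r2 < 0 | pairs$r2 > 1)) config_error("LD r2 outside [0,1]")
  if (any(!(pairs$phase_sign %in% c(-1L, 1L)))) config_error("phase_sign must be +1 or -1")
  # symmetric closure so lookups need one direction only
  swapped <- pairs[, c("snp_b", "snp_a", "r2", "phase_sign")]
  names(swapped) <- c("snp_a", "snp_b", "r2", "phase_sign")
  allp <- unique(rbind(pairs, swapped))
  lookup <- new.env(parent = emptyenv(), size = max(64L, 2L * nrow(allp)))
  for (i in seq_len(nrow(allp))) {
    assign(paste(allp$snp_a[i], allp$snp_b[i], sep = "\r"),
           c(allp$r2[i], allp$phase_sign[i]), envir = lookup)
  }
  structure(list(meta = meta, pairs = pairs, .lookup = lookup), class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("LD panel: %d SNPs, %d stored pairs\n", nrow(x$meta), nrow(x$pairs)))
  invisible(x)
}

#' Pairwise r2 (and phase) lookup
#'
#' @param panel an [ld_panel()].
#' @param a,b SNP ids.
#' @return Named numeric vector `c(r2=, phase_sign=)`; r2 = 1 on the
#'   diagonal, r2 = 0 for pairs the panel does not store.
#' @export
ld_r2 <- function(panel, a, b) {
  if (a == b) return(c(r2 = 1, phase_sign = 1))
  v <- get0(paste(a, b, sep = "\r"), envir = panel$.lookup, ifnotfound = NULL)
  if (is.null(v)) c(r2 = 0, phase_sign = 1) else c(r2 = v[1], phase_sign = v[2])
}

panel_has_snp <- function(panel, id) id %in% panel$meta$snp_id

#' Read an LD panel from its two TSV tables
#'
#' @param pairs_path long-format TSV with columns `snp_a`, `snp_b`, `r2`,
#'   `phase_sign`.
#' @param meta_path SNP metadata TSV with columns `snp_id`, `chrom`, `pos`,
#'   `allele1`, `allele2`.
#' @return An [ld_panel()].
#' @export
read_ld_panel <- function(pairs_path, meta_path) {
  pairs <- utils::read.table(pairs_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                            colClasses = c(chrom = "character"),
                            stringsAsFactors = FALSE)
  ld_panel(meta, pairs)
}

#' Write an LD panel to TSV tables
#'
#' @param panel an [ld_panel()].
#' @param pairs_path,meta_path output paths.
#' @return `pairs_path`, invisibly.
#' @export
write_ld_panel <- function(panel, pairs_path, meta_path) {
  utils::write.table(panel$pairs, pairs_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(panel$meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(pairs_path)
}
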