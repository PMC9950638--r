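# Seeded synthetic GWAS summary statistics with known ground truth.
#
# Emulates the structure of a two-sample MR study of circulating cytokines
# (inverse-normalized continuous exposures, n in the thousands) against a
# binary outcome measured in two independent case-control sources: per-SNP
# effects and SEs consistent with the stated sample sizes, null filler SNPs
# so significance thresholding is nontrivial, summary-level LD blocks for
# clumping/proxy logic, configurable horizontal pleiotropy and reverse
# causation, and a scrambled allele representation in the outcome so
# harmonization has real work to do. All randomness flows from one seed.

#' Ground truth of a synthetic two-sample MR dataset
#'
#' @param theta true causal effect of the exposure on the outcome (log-odds
#'   per SD exposure).
#' @param k_snps number of instrument SNPs (exposure-driven; for reverse
#'   scenarios, outcome-driven).
#' @param gamma_dist `c(mean, sd)` of true per-allele exposure effects (SD
#'   units).
#' @param rho fraction of instruments with a horizontal-pleiotropy direct
#'   effect on the outcome.
#' @param alpha_mean,alpha_sd mean and SD of the pleiotropic direct effects
#'   (log-odds); a nonzero mean makes the pleiotropy directional.
#' @param inside_violation if TRUE, pleiotropic effects additionally gain
#'   `inside_slope * gamma`, correlating instrument strength with direct
#'   effects (violating InSiDE).
#' @param inside_slope see `inside_violation` (default 0.5).
#' @param reverse_theta effect of the outcome on the exposure; when nonzero
#'   the k SNPs act on the outcome (effects from `delta_dist`) and reach the
#'   exposure only through it, so their exposure effects are
#'   `reverse_theta * delta`.
#' @param delta_dist `c(mean, sd)` of outcome-driven SNP effects (log-odds),
#'   used when `reverse_theta != 0`.
#' @param n_exp exposure GWAS sample size.
#' @param n_out_case,n_out_control outcome case-control sizes; outcome SEs
#'   use the effective size n_eff = 4/(1/ncase + 1/ncontrol), and outcome
#'   records store n_eff in their `n` column.
#' @param maf_range uniform range of minor-allele frequencies.
#' @param ld_blocks list of `c(size, r2)` pairs: block i attaches `size - 1`
#'   correlated satellite SNPs at the declared r2 to instrument i.
#' @param n_null count of null filler SNPs (true effect 0 on both traits).
#' @param n_planted number of instruments given a planted pleiotropic effect
#'   of `planted_sigma_mult * alpha_sd` (outlier scenarios).
#' @param planted_sigma_mult planted-outlier magnitude in units of
#'   `alpha_sd` (default 10).
#' @param missing_out_fraction fraction of instruments omitted from the
#'   outcome table (exercises proxy substitution).
#' @param palindromic_fraction fraction of SNPs given A/T or C/G allele
#'   pairs.
#' @param swap_prob,flip_prob probabilities that an outcome record is
#'   written with swapped alleles (sign-consistently) or on the complementary
#'   strand.
#' @param exposure_id,outcome_id trait labels.
#' @param seed integer seed.
#' @return An object of class `simulation_truth` (a list of the above).
#' @export
simulation_truth <- function(theta = 0, k_snps = 30,
                             gamma_dist = c(0.15, 0.05),
                             rho = 0, alpha_mean = 0, alpha_sd = 0,
                             inside_violation = FALSE, inside_slope = 0.5,
                             reverse_theta = 0, delta_dist = c(0.35, 0.05),
                             n_exp = 8293,
                             n_out_case = 2025, n_out_control = 284826,
                             maf_range = c(0.1, 0.4),
                             ld_blocks = list(),
                             n_null = 300,
                             n_planted = 0, planted_sigma_mult = 10,
                             missing_out_fraction = 0,
                             palindromic_fraction = 0.15,
                             swap_prob = 0.3, flip_prob = 0.3,
                             exposure_id = "exposure", outcome_id = "outcome",
                             seed = 1) {
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    config_error("maf_range must lie within (0, 0.5] with low <= high")
  }
  if (rho < 0 || rho > 1) config_error("rho must be in [0, 1]")
  structure(as.list(environment()), class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf(
    "Simulation truth: theta=%g, k=%d, rho=%g, reverse_theta=%g, seed=%d\n",
    x$theta, x$k_snps, x$rho, x$reverse_theta, x$seed))
  invisible(x)
}

NONPAL_PAIRS <- matrix(c("A","G", "A","C", "T","G", "T","C",
                         "G","A", "C","A", "G","T", "C","T"),
                       ncol = 2, byrow = TRUE)
PAL_PAIRS <- matrix(c("A","T", "T","A", "C","G", "G","C"), ncol = 2, byrow = TRUE)

effective_n <- function(n_case, n_control) 4 / (1 / n_case + 1 / n_control)

# Draw the SNP map and true effects. Called with the RNG already seeded.
.draw_snp_map <- function(truth) {
  k <- truth$k_snps
  nn <- truth$n_null
  n_loci <- k + nn
  chrom <- as.character(((seq_len(n_loci) - 1L) %% 22L) + 1L)
  pos <- as.integer(1e6 + ((seq_len(n_loci) - 1L) %/% 22L) * 1e6)
  id <- sprintf("rs%06d", seq_len(n_loci))
  role <- c(rep("instrument", k), rep("null", nn))

  if (truth$reverse_theta != 0) {
    delta <- stats::rnorm(k, truth$delta_dist[1], truth$delta_dist[2])
    gamma <- truth$reverse_theta * delta
    Gamma <- delta
  } else {
    gamma <- stats::rnorm(k, truth$gamma_dist[1], truth$gamma_dist[2])
    alpha <- numeric(k)
    if (truth$rho > 0) {
      invalid <- stats::runif(k) < truth$rho
      alpha[invalid] <- stats::rnorm(sum(invalid), truth$alpha_mean, truth$alpha_sd)
      if (truth$inside_violation) {
        alpha[invalid] <- alpha[invalid] + truth$inside_slope * gamma[invalid]
      }
    }
    if (truth$n_planted > 0) {
      idx <- seq_len(min(truth$n_planted, k))
      alpha[idx] <- truth$planted_sigma_mult * truth$alpha_sd
    }
    Gamma <- truth$theta * gamma + alpha
  }
  gamma <- c(gamma, numeric(nn))
  Gamma <- c(Gamma, numeric(nn))

  n_pal <- round(truth$palindromic_fraction * n_loci)
  is_pal <- seq_len(n_loci) %in% sample.int(n_loci, n_pal)
  al <- matrix("", n_loci, 2)
  pick_np <- sample.int(nrow(NONPAL_PAIRS), n_loci, replace = TRUE)
  pick_p <- sample.int(nrow(PAL_PAIRS), n_loci, replace = TRUE)
  al[!is_pal, ] <- NONPAL_PAIRS[pick_np[!is_pal], , drop = FALSE]
  al[is_pal, ] <- PAL_PAIRS[pick_p[is_pal], , drop = FALSE]

  map <- data.frame(
    snp_id = id, chrom = chrom, pos = pos,
    allele1 = al[, 1], allele2 = al[, 2],
    maf = stats::runif(n_loci, truth$maf_range[1], truth$maf_range[2]),
    gamma = gamma, Gamma = Gamma, role = role,
    stringsAsFactors = FALSE
  )

  pairs <- data.frame(snp_a = character(), snp_b = character(),
                      r2 = numeric(), phase_sign = integer(),
                      stringsAsFactors = FALSE)
  if (length(truth$ld_blocks) > 0L) {
    for (b in seq_along(truth$ld_blocks)) {
      if (b > k) break
      size <- truth$ld_blocks[[b]][1]
      r2 <- truth$ld_blocks[[b]][2]
      if (size < 2) next
      idx <- b  # block b hangs off instrument b
      sat_n <- size - 1
      phase <- sample(c(-1L, 1L), sat_n, replace = TRUE)
      sat <- data.frame(
        snp_id = sprintf("%s_s%d", map$snp_id[idx], seq_len(sat_n)),
        chrom = map$chrom[idx],
        pos = map$pos[idx] + 5000L * seq_len(sat_n),
        allele1 = NONPAL_PAIRS[sample.int(8, sat_n, replace = TRUE), 1],
        allele2 = "", maf = map$maf[idx],
        gamma = phase * sqrt(r2) * map$gamma[idx],
        Gamma = phase * sqrt(r2) * map$Gamma[idx],
        role = "satellite", stringsAsFactors = FALSE
      )
      # fix allele2 consistent with allele1 (non-palindromic partner)
      partner <- c(A = "G", G = "A", C = "T", T = "C")
      sat$allele2 <- unname(partner[sat$allele1])
      map <- rbind(map, sat)
      pairs <- rbind(pairs, data.frame(
        snp_a = map$snp_id[idx], snp_b = sat$snp_id,
        r2 = r2, phase_sign = phase, stringsAsFactors = FALSE
      ))
      if (sat_n > 1) {
        cmb <- utils::combn(seq_len(sat_n), 2)
        pairs <- rbind(pairs, data.frame(
          snp_a = sat$snp_id[cmb[1, ]], snp_b = sat$snp_id[cmb[2, ]],
          r2 = r2, phase_sign = phase[cmb[1, ]] * phase[cmb[2, ]],
          stringsAsFactors = FALSE
        ))
      }
    }
  }
  list(map = map, pairs = pairs)
}

.observe_trait <- function(map, true_effect, n, trait_id) {
  se <- 1 / sqrt(2 * map$maf * (1 - map$maf) * n)
  beta <- stats::rnorm(nrow(map), true_effect, se)
  data.frame(
    snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
    effect_allele = map$allele1, other_allele = map$allele2,
    eaf = map$maf, beta = beta, se = se,
    pval = z_pval(beta, se), n = as.integer(round(n)),
    trait_id = trait_id, stringsAsFactors = FALSE
  )
}

# Scramble outcome representation: random allele swaps (sign-consistent) and
# strand complements (non-palindromic SNPs only), so harmonization is
# exercised but the underlying effect is unchanged.
.scramble_representation <- function(tab, swap_prob, flip_prob) {
  n <- nrow(tab)
  swap <- stats::runif(n) < swap_prob
  if (any(swap)) {
    ea <- tab$effect_allele[swap]
    tab$effect_allele[swap] <- tab$other_allele[swap]
    tab$other_allele[swap] <- ea
    tab$beta[swap] <- -tab$beta[swap]
    tab$eaf[swap] <- 1 - tab$eaf[swap]
  }
  pal <- is_palindromic(tab$effect_allele, tab$other_allele)
  flip <- stats::runif(n) < flip_prob & !pal
  if (any(flip)) {
    tab$effect_allele[flip] <- unname(COMPLEMENT[tab$effect_allele[flip]])
    tab$other_allele[flip] <- unname(COMPLEMENT[tab$other_allele[flip]])
  }
  tab
}

.simulate_core <- function(truth, sources) {
  set.seed(truth$seed)
  drawn <- .draw_snp_map(truth)
  map <- drawn$map
  exposure <- .observe_trait(map, map$gamma, truth$n_exp, truth$exposure_id)
  outcomes <- vector("list", length(sources))
  for (s in seq_along(sources)) {
    n_eff <- effective_n(sources[[s]][1], sources[[s]][2])
    out <- .observe_trait(map, map$Gamma, n_eff,
                          paste0(truth$outcome_id,
                                 if (length(sources) > 1) paste0("_", names(sources)[s]) else ""))
    if (truth$missing_out_fraction > 0) {
      inst <- which(map$role == "instrument")
      n_drop <- floor(truth$missing_out_fraction * length(inst))
      if (n_drop > 0) out <- out[-inst[seq_len(n_drop)], , drop = FALSE]
    }
    out <- .scramble_representation(out, truth$swap_prob, truth$flip_prob)
    rownames(out) <- NULL
    outcomes[[s]] <- out
  }
  names(outcomes) <- names(sources)
  panel <- ld_panel(map[, c("snp_id", "chrom", "pos", "allele1", "allele2")],
                    drawn$pairs)
  list(exposure = exposure, outcomes = outcomes, ld = panel,
       truth = truth, map = map)
}

#' Simulate one exposure-outcome pair of summary-statistics tables
#'
#' Per instrument j the generating model is: exposure effect gamma_j ~
#' N(gamma_dist); direct (pleiotropic) outcome effect alpha_j = 0 with
#' probability 1 - rho, else N(alpha_mean, alpha_sd); true outcome effect
#' Gamma_j = theta gamma_j + alpha_j. Observed effects are drawn around the
#' truth at the analytic SEs se = 1/sqrt(2 maf (1-maf) n) (effective n for
#' the case-control outcome); p-values are two-sided normal, so generated
#' records satisfy the summary-record p-value invariant by construction.
#' Null filler SNPs, LD satellites, palindromic alleles and representation
#' scrambling are controlled by the truth object.
#'
#' @param truth a [simulation_truth()].
#' @return An object of class `mr_simulation`: list with `exposure`,
#'   `outcome` (canonical summary-statistics data.frames), `ld` (an
#'   [ld_panel()]), `truth`, and the internal `map` of true effects.
#' @export
simulate_pair <- function(truth) {
  core <- .simulate_core(truth, list(a = c(truth$n_out_case, truth$n_out_control)))
  structure(list(exposure = core$exposure, outcome = core$outcomes[[1]],
                 ld = core$ld, truth = core$truth, map = core$map),
            class = "mr_simulation")
}

#' Simulate a two-source study (one exposure, several outcome sources)
#'
#' Shares one set of true SNP effects across sources; each source observes
#' the outcome with its own sampling noise at its own case-control size, so
#' source estimates are compatible and meta-analysis is exercised honestly.
#'
#' @param truth a [simulation_truth()].
#' @param sources named list of `c(n_case, n_control)`; the default mirrors
#'   a large biobank source and a small multi-cohort source.
#' @return List with `exposure`, `outcomes` (named list), `ld`, `truth`,
#'   `map`.
#' @export
simulate_study <- function(truth,
                           sources = list(biobank = c(2025, 284826),
                                          cohorts = c(398, 2848))) {
  .simulate_core(truth, sources)
}

#' Named scenario presets for the synthetic generator
#'
#' Fully specified truth objects for the failure modes the sensitivity
#' analyses target:
#' \describe{
#'   \item{null}{no causal effect, no pleiotropy (theta = 0, k = 30).}
#'   \item{causal}{theta = 0.1, k = 50, valid instruments.}
#'   \item{balanced_pleiotropy}{30% invalid instruments, zero-mean direct
#'     effects (k = 100).}
#'   \item{directional_pleiotropy}{30% invalid instruments with positive-mean
#'     direct effects, InSiDE holding (k = 100).}
#'   \item{outliers}{two instruments planted with direct effects of
#'     10 alpha_sd.}
#'   \item{reverse_causation}{theta = 0, reverse_theta = 0.3: SNPs act on the
#'     outcome and reach the exposure only through it, giving Steiger
#'     filtering signal.}
#'   \item{weak_instruments}{exposure effects scaled so the mean F-statistic
#'     of the instrument set falls around 5-15, exercising the F > 10
#'     warning.}
#' }
#'
#' @param name scenario name.
#' @param seed integer seed.
#' @param ... overrides passed to [simulation_truth()].
#' @return A [simulation_truth()].
#' @export
scenario <- function(name = c("null", "causal", "balanced_pleiotropy",
                              "directional_pleiotropy", "outliers",
                              "reverse_causation", "weak_instruments"),
                     seed = 1, ...) {
  if (!is.character(name) || !(name[1] %in% c(
    "null", "causal", "balanced_pleiotropy", "directional_pleiotropy",
    "outliers", "reverse_causation", "weak_instruments"))) {
    config_error(sprintf("unknown scenario '%s'", as.character(name)[1]))
  }
  name <- name[1]
  preset <- switch(
    name,
    null = list(theta = 0, k_snps = 30, gamma_dist = c(0.15, 0.05)),
    causal = list(theta = 0.1, k_snps = 50, gamma_dist = c(0.15, 0.05)),
    balanced_pleiotropy = list(theta = 0.1, k_snps = 200,
                               gamma_dist = c(0.15, 0.07),
                               rho = 0.3, alpha_mean = 0, alpha_sd = 0.1),
    directional_pleiotropy = list(theta = 0.1, k_snps = 300,
                                  gamma_dist = c(0.15, 0.07),
                                  rho = 0.3, alpha_mean = 0.25, alpha_sd = 0.05),
    outliers = list(theta = 0.1, k_snps = 30, gamma_dist = c(0.15, 0.05),
                    alpha_sd = 0.02, n_planted = 2),
    reverse_causation = list(theta = 0, reverse_theta = 0.3, k_snps = 20,
                             delta_dist = c(0.35, 0.05)),
    weak_instruments = list(theta = 0.1, k_snps = 30,
                            gamma_dist = c(0.055, 0.015))
  )
  args <- utils::modifyList(c(preset, list(seed = seed)), list(...))
  do.call(simulation_truth, args)
}

#' Write a simulated study to disk
#'
#' Writes `exposure.tsv`, one `outcome_<source>.tsv` per source,
#' `ld_panel.tsv`, `ld_snps.tsv` and `truth.yaml` into a directory.
#'
#' @param study result of [simulate_study()] (or [simulate_pair()]).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sumstats(study$exposure, file.path(dir, "exposure.tsv"))
  outs <- if (!is.null(study$outcomes)) study$outcomes else list(a = study$outcome)
  for (s in names(outs)) {
    write_sumstats(outs[[s]], file.path(dir, sprintf("outcome_%s.tsv", s)))
  }
  write_ld_panel(study$ld, file.path(dir, "ld_panel.tsv"),
                 file.path(dir, "ld_snps.tsv"))
  tr <- study$truth
  yaml::write_yaml(tr[setdiff(names(tr), character())], file.path(dir, "truth.yaml"))
  invisible(dir)
}
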