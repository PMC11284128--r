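#' Configuration for the synthetic causal-chain generator
#'
#' Parameters of the generative model behind [simulate_chain()]. The chain is
#' exposure -> mediator -> outcome with per-SNP exposure effects `b_j`,
#' exposure->mediator effect `theta_xz` (gamma), mediator->outcome effect
#' `theta_zy` (delta, log-odds per mediator SD) and a direct exposure->outcome
#' effect `theta_direct` (tau), so the true total effect is
#' `theta_direct + theta_xz * theta_zy`.
#'
#' Besides the `n_snps` exposure instruments, `n_snps_mediator` SNPs act on
#' the mediator only (zero exposure effect). These are the mediator's own
#' instruments; without them the mediator's direct effect is not identifiable
#' in a multivariable model, because every SNP would influence the mediator
#' solely through the exposure.
#'
#' @param n_snps Number of exposure-instrument SNPs (>= 3).
#' @param n_snps_mediator Number of mediator-specific SNPs.
#' @param n_snps_outcome Number of outcome-specific SNPs (signal in the
#'   outcome GWAS unrelated to the chain; they make reverse-MR analyses
#'   meaningful, since a disease GWAS has instruments of its own).
#' @param outcome_effect_sd SD of the outcome-specific SNP effects
#'   (log-odds per allele).
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes. Defaults mirror a
#'   microbiome-scale exposure GWAS, a plasma-protein mediator GWAS and a
#'   biobank-scale binary outcome.
#' @param maf_range Minor-allele-frequency interval, within (0, 0.5].
#' @param exposure_effect_sd SD of the per-SNP true exposure effects
#'   (trait-SD units per allele).
#' @param mediator_effect_sd SD of the mediator-specific SNP effects.
#' @param theta_xz,theta_zy,theta_direct Chain coefficients (see above).
#' @param pleiotropy_mean,pleiotropy_sd Direct SNP->outcome effects for the
#'   invalid fraction, defined relative to the exposure-increasing allele so
#'   that a nonzero mean is directional in the MR-Egger sense.
#' @param prop_invalid Fraction of exposure SNPs given a pleiotropic effect.
#' @param n_outliers Number of exposure SNPs whose observed outcome beta is
#'   shifted by +/- 10 standard errors (gross outliers for MR-PRESSO).
#' @param palindrome_frac Fraction of SNPs assigned A/T or G/C allele pairs.
#' @param ld_block_size SNPs per LD block (1 = all independent).
#' @param ld_r2 Pairwise r-squared within a block.
#' @param seed Integer seed; identical configs give bit-identical output.
#' @return A `chain_sim_config` list.
#' @export
chain_sim_config <- function(n_snps = 100, n_snps_mediator = 30,
                             n_snps_outcome = 0,
                             outcome_effect_sd = 0.05,
                             n_exposure = 18340, n_mediator = 21759,
                             n_outcome = 300000,
                             maf_range = c(0.05, 0.5),
                             exposure_effect_sd = 0.05,
                             mediator_effect_sd = 0.05,
                             theta_xz = 0.3, theta_zy = -0.5,
                             theta_direct = -0.2,
                             pleiotropy_mean = 0, pleiotropy_sd = 0,
                             prop_invalid = 0, n_outliers = 0,
                             palindrome_frac = 0.1,
                             ld_block_size = 1, ld_r2 = 0,
                             seed = 1) {
  cfg <- list(
    n_snps = n_snps, n_snps_mediator = n_snps_mediator,
    n_snps_outcome = n_snps_outcome, outcome_effect_sd = outcome_effect_sd,
    n_exposure = n_exposure, n_mediator = n_mediator, n_outcome = n_outcome,
    maf_range = maf_range, exposure_effect_sd = exposure_effect_sd,
    mediator_effect_sd = mediator_effect_sd,
    theta_xz = theta_xz, theta_zy = theta_zy, theta_direct = theta_direct,
    pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
    prop_invalid = prop_invalid, n_outliers = n_outliers,
    palindrome_frac = palindrome_frac,
    ld_block_size = ld_block_size, ld_r2 = ld_r2, seed = seed
  )
  if (cfg$n_snps < 3) stop("config error: n_snps must be >= 3", call. = FALSE)
  if (cfg$prop_invalid < 0 || cfg$prop_invalid > 1) {
    stop("config error: prop_invalid must lie in [0, 1]", call. = FALSE)
  }
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0 ||
    cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("config error: maf_range must lie within (0, 0.5]", call. = FALSE)
  }
  if (cfg$ld_block_size < 1) {
    stop("config error: ld_block_size must be >= 1", call. = FALSE)
  }
  class(cfg) <- "chain_sim_config"
  cfg
}

# Non-palindromic ordered allele pairs (complement pairs excluded).
NONPAL_PAIRS <- matrix(
  c(
    "A", "C", "A", "G", "C", "A", "C", "T",
    "G", "A", "G", "T", "T", "C", "T", "G"
  ),
  ncol = 2, byrow = TRUE
)
PAL_PAIRS <- matrix(c("A", "T", "T", "A", "G", "C", "C", "G"),
  ncol = 2, byrow = TRUE
)

# Draws the structural layer (variants, MAFs, alleles, true effects).
# Assumes the RNG state has already been seeded by the caller.
.chain_truth <- function(cfg) {
  m <- cfg$n_snps + cfg$n_snps_mediator + cfg$n_snps_outcome
  ids <- sprintf("rs%06d", seq_len(m))
  is_mediator_snp <- c(
    rep(FALSE, cfg$n_snps), rep(TRUE, cfg$n_snps_mediator),
    rep(FALSE, cfg$n_snps_outcome)
  )
  is_outcome_snp <- c(
    rep(FALSE, cfg$n_snps + cfg$n_snps_mediator),
    rep(TRUE, cfg$n_snps_outcome)
  )

  # genomic layout: each LD block gets its own slot, slots spaced 25 Mb so
  # independent SNPs never fall in one clumping window (+/- 10 Mb)
  block <- ceiling(seq_len(m) / cfg$ld_block_size)
  chrom <- as.character(((block - 1) %% 22) + 1)
  pos <- 1e6 + ((block - 1) %/% 22) * 25e6 +
    ((seq_len(m) - 1) %% cfg$ld_block_size) * 1e4

  maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])

  n_pal <- round(cfg$palindrome_frac * m)
  pal_idx <- if (n_pal > 0) sample.int(m, n_pal) else integer()
  pair_row <- sample.int(nrow(NONPAL_PAIRS), m, replace = TRUE)
  ea <- NONPAL_PAIRS[pair_row, 1]
  oa <- NONPAL_PAIRS[pair_row, 2]
  if (n_pal > 0) {
    pr <- sample.int(nrow(PAL_PAIRS), n_pal, replace = TRUE)
    ea[pal_idx] <- PAL_PAIRS[pr, 1]
    oa[pal_idx] <- PAL_PAIRS[pr, 2]
  }

  b <- ifelse(is_mediator_snp | is_outcome_snp, 0,
    stats::rnorm(m, 0, cfg$exposure_effect_sd)
  )
  cc <- ifelse(is_mediator_snp,
    stats::rnorm(m, 0, cfg$mediator_effect_sd), 0
  )
  dd <- ifelse(is_outcome_snp,
    stats::rnorm(m, 0, cfg$outcome_effect_sd), 0
  )

  n_invalid <- round(cfg$prop_invalid * cfg$n_snps)
  pleio_idx <- if (n_invalid > 0) sample.int(cfg$n_snps, n_invalid) else integer()
  alpha <- numeric(m)
  if (n_invalid > 0) {
    alpha[pleio_idx] <- stats::rnorm(
      n_invalid, cfg$pleiotropy_mean, cfg$pleiotropy_sd
    )
  }

  n_out <- min(cfg$n_outliers, cfg$n_snps)
  outlier_idx <- if (n_out > 0) sample.int(cfg$n_snps, n_out) else integer()
  outlier_sign <- if (n_out > 0) sample(c(-1, 1), n_out, replace = TRUE) else numeric()

  beta_total_true <- cfg$theta_direct + cfg$theta_xz * cfg$theta_zy
  list(
    ids = ids, chrom = chrom, pos = pos, ea = ea, oa = oa, maf = maf,
    is_mediator_snp = is_mediator_snp, is_outcome_snp = is_outcome_snp,
    exposure_true = b,
    mediator_true = cfg$theta_xz * b + cc,
    # pleiotropy acts on the exposure-increasing allele, hence sign(b)
    outcome_true = beta_total_true * b + sign(b) * alpha +
      cfg$theta_zy * cc + dd,
    pleio_idx = pleio_idx, outlier_idx = outlier_idx,
    outlier_sign = outlier_sign, pal_idx = pal_idx,
    beta_total_true = beta_total_true
  )
}

# Samples one GWAS's observed summary statistics from the truth layer under
# the standardized-trait SE formula se = 1 / sqrt(2 p (1-p) N).
.sample_gwas <- function(tr, true_beta, n_sample, trait_name, trait_type,
                         outlier_idx = integer(), outlier_sign = numeric()) {
  se <- 1 / sqrt(2 * tr$maf * (1 - tr$maf) * n_sample)
  beta <- true_beta + stats::rnorm(length(se)) * se
  if (length(outlier_idx) > 0) {
    beta[outlier_idx] <- beta[outlier_idx] + outlier_sign * 10 * se[outlier_idx]
  }
  records <- data.frame(
    variant_id = tr$ids, chrom = tr$chrom, pos = tr$pos,
    effect_allele = tr$ea, other_allele = tr$oa,
    eaf = tr$maf, beta = beta, se = se,
    # floored where the normal tail underflows double precision, as in
    # published GWAS summary files
    pvalue = pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300),
    n = n_sample, stringsAsFactors = FALSE
  )
  summary_stats(trait_name, trait_type, records)
}

.block_ld <- function(tr, cfg) {
  if (cfg$ld_block_size < 2 || cfg$ld_r2 <= 0) {
    return(ld_table())
  }
  block <- ceiling(seq_along(tr$ids) / cfg$ld_block_size)
  id1 <- character()
  id2 <- character()
  for (bk in unique(block)) {
    members <- tr$ids[block == bk]
    if (length(members) < 2) next
    cmb <- utils::combn(members, 2)
    id1 <- c(id1, cmb[1, ])
    id2 <- c(id2, cmb[2, ])
  }
  ld_table(id1, id2, rep(cfg$ld_r2, length(id1)))
}

#' Simulate an exposure/mediator/outcome summary-statistics triplet
#'
#' Generates three GWAS summary-statistics sets under a known causal chain,
#' together with the ground truth needed for recovery tests. Observed betas
#' are drawn around their true values with the standardized-trait sampling SE
#' `1 / sqrt(2 p (1-p) N)`; the binary outcome is simulated directly on the
#' log-odds summary-statistic scale. P-values are the exact two-sided normal
#' tails of `beta/se`. Identical configs (including seed) give bit-identical
#' output.
#'
#' @param cfg A [chain_sim_config()].
#' @return A list of class `chain_sim` with elements `exposure`, `mediator`,
#'   `outcome` ([summary_stats()] objects), `truth` (a `sim_truth` list) and
#'   `ld` (an [ld_table()], empty unless LD blocks were requested).
#' @export
simulate_chain <- function(cfg) {
  stopifnot(inherits(cfg, "chain_sim_config"))
  set.seed(cfg$seed)
  tr <- .chain_truth(cfg)
  exposure <- .sample_gwas(tr, tr$exposure_true, cfg$n_exposure,
    "exposure", "continuous"
  )
  mediator <- .sample_gwas(tr, tr$mediator_true, cfg$n_mediator,
    "mediator", "continuous"
  )
  outcome <- .sample_gwas(tr, tr$outcome_true, cfg$n_outcome,
    "outcome", "binary",
    outlier_idx = tr$outlier_idx, outlier_sign = tr$outlier_sign
  )
  truth <- structure(
    list(
      theta_xz = cfg$theta_xz, theta_zy = cfg$theta_zy,
      theta_direct = cfg$theta_direct,
      beta_total_true = tr$beta_total_true,
      pleiotropic_ids = tr$ids[tr$pleio_idx],
      outlier_ids = tr$ids[tr$outlier_idx],
      mediator_specific_ids = tr$ids[tr$is_mediator_snp],
      outcome_specific_ids = tr$ids[tr$is_outcome_snp],
      palindromic_ids = tr$ids[tr$pal_idx],
      n_palindromes = length(tr$pal_idx),
      per_snp_exposure_effects = stats::setNames(tr$exposure_true, tr$ids)
    ),
    class = "sim_truth"
  )
  structure(
    list(
      exposure = exposure, mediator = mediator, outcome = outcome,
      truth = truth, ld = .block_ld(tr, cfg)
    ),
    class = "chain_sim"
  )
}

#' Simulate two outcome cohorts sharing the same underlying truth
#'
#' Produces a pair of outcome summary-statistics sets over the same variants
#' and true effects, differing only in sampling noise and sample size — the
#' replication-cohort setting that feeds the meta-analysis stage. Cohort A is
#' exactly the outcome [simulate_chain()] would produce for `cfg`.
#'
#' @param cfg A [chain_sim_config()] (cohort A uses `cfg$n_outcome` and
#'   `cfg$seed`).
#' @param n_outcome_2 Cohort B sample size.
#' @param seed_2 Seed for cohort B's sampling noise.
#' @param offset Added to cohort B's true total causal effect (log-odds per
#'   exposure SD): 0 gives genuinely homogeneous cohorts, a nonzero value
#'   injects between-cohort heterogeneity in the causal slope.
#' @return List with `outcome_a`, `outcome_b` and `truth`.
#' @export
simulate_cohort_pair <- function(cfg, n_outcome_2, seed_2, offset = 0) {
  stopifnot(inherits(cfg, "chain_sim_config"))
  sim <- simulate_chain(cfg)
  set.seed(seed_2)
  tr <- local({
    set.seed(cfg$seed)
    .chain_truth(cfg)
  })
  set.seed(seed_2)
  outcome_b <- .sample_gwas(tr, tr$outcome_true + offset * tr$exposure_true,
    n_outcome_2,
    "outcome_replication", "binary",
    outlier_idx = tr$outlier_idx, outlier_sign = tr$outlier_sign
  )
  list(outcome_a = sim$outcome, outcome_b = outcome_b, truth = sim$truth)
}

#' Serialize simulation ground truth to JSON
#' @param truth A `sim_truth` object from [simulate_chain()].
#' @param path Output path.
#' @export
write_sim_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  jsonlite::write_json(unclass(truth), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
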