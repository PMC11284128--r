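# Shared configuration for the synthetic MR mediation study.
# Every script sources this file; all randomness flows from STUDY_SEED.

library(chainMR)

STUDY_SEED <- 20260929L
DATA_DIR <- "results/data"
OUT_DIR <- "results"

# Analysis parameters mirroring the study design: locus-wide instrument
# threshold 1e-5 (strict rerun at genome-wide 5e-8), clumping r2 < 0.001 in
# a 10 Mb window, per-SNP F >= 10, outcome-association and palindrome
# filters. MR-PRESSO and bootstrap counts kept at 1000.
STUDY_CFG <- study_config(
  p_threshold = 1e-5, p_threshold_strict = 5e-8,
  r2_max = 0.001, window_kb = 10000, min_f = 10,
  n_sim = 1000, n_boot = 1000, seed = STUDY_SEED
)

# Ten microbial taxa screened against one binary outcome; taxa 3 and 7 carry
# a real effect, taxon 3 partially mediated through an inflammatory factor.
N_TAXA <- 10
EFFECT_TAXA <- c(3, 7)
MEDIATED_TAXON <- 3

taxon_config <- function(t) {
  has_effect <- t %in% EFFECT_TAXA
  chain_sim_config(
    n_snps = 60,
    n_snps_mediator = if (t == MEDIATED_TAXON) 30 else 0,
    n_snps_outcome = 40,
    n_exposure = 18340, # microbiome-consortium scale
    n_mediator = 21759, # plasma-protein GWAS scale
    # rare binary outcome: the precision of log-odds effects is governed by
    # the effective sample size 4 / (1/cases + 1/controls), roughly 8000
    # for a biobank-scale cohort with ~2000 cases
    n_outcome = 8000,
    theta_xz = if (t == MEDIATED_TAXON) 0.3 else 0,
    theta_zy = if (t == MEDIATED_TAXON) -0.5 else 0,
    theta_direct = if (t == MEDIATED_TAXON) {
      -0.2
    } else if (has_effect) {
      -0.35
    } else {
      0
    },
    palindrome_frac = 0.15,
    seed = STUDY_SEED + t
  )
}

taxon_names <- sprintf("taxon%02d", seq_len(N_TAXA))
taxon_ranks <- rep(c("phylum", "class", "order", "family", "genus"),
  length.out = N_TAXA
)

relabel_variants <- function(stats, t) {
  stats$records$variant_id <- paste0("t", t, "_", stats$records$variant_id)
  stats
}
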