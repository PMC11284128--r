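# Stage 4 — replication in an independent cohort and meta-analysis.
#
# Taxa surviving the forward screen are re-estimated against the
# replication outcome cohort; per-cohort IVW estimates are pooled by
# fixed-effect inverse-variance meta-analysis (DerSimonian-Laird alongside
# when heterogeneity is suggestive) with I-squared reported. An association
# is retained iff the pooled p-value stays below 0.05.

source("analysis/00_config.R")

exposures <- lapply(seq_len(N_TAXA), function(t) {
  read_sumstats(
    file.path(DATA_DIR, sprintf("%s.tsv", taxon_names[t])),
    taxon_names[t], "continuous"
  )
})
names(exposures) <- taxon_names
discovery <- read_sumstats(
  file.path(DATA_DIR, "outcome_discovery.tsv"),
  "hydrocephalus_discovery", "binary"
)
replication <- read_sumstats(
  file.path(DATA_DIR, "outcome_replication.tsv"),
  "hydrocephalus_replication", "binary"
)

meta <- run_replication_meta(
  exposures,
  list(discovery = discovery, replication = replication),
  cfg = STUDY_CFG
)

render_report(list(meta_replication = meta), OUT_DIR, STUDY_CFG)

retained <- meta[which(meta$retained), ]
cat(sprintf(
  "meta-analysis: %d/%d taxa retained (%s)\n",
  nrow(retained), nrow(meta),
  paste(
    sprintf(
      "%s: pooled OR %.2f, I2 %.0f%%",
      retained$exposure, exp(retained$pooled_beta), retained$i_squared
    ),
    collapse = "; "
  )
))
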