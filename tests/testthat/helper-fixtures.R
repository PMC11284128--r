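# Fixture builders and independent oracles shared across the suite.

# Small canonical summary-statistics data frame.
make_records <- function(n = 5, seed = 1, chrom = "1",
                         pos = NULL, pvalue = NULL) {
  set.seed(seed)
  if (is.null(pos)) pos <- seq(1e6, by = 5e7, length.out = n)
  beta <- rnorm(n, 0, 0.1)
  se <- runif(n, 0.01, 0.05)
  if (is.null(pvalue)) pvalue <- 2 * pnorm(-abs(beta / se))
  data.frame(
    variant_id = sprintf("rs%d", seq_len(n)),
    chrom = rep(chrom, n), pos = pos,
    effect_allele = rep(c("A", "C", "G", "T", "A"), length.out = n),
    other_allele = rep(c("G", "T", "A", "C", "C"), length.out = n),
    eaf = runif(n, 0.1, 0.9), beta = beta, se = se,
    pvalue = pvalue, n = rep(10000, n), stringsAsFactors = FALSE
  )
}

make_sumstats <- function(n = 5, seed = 1, trait = "trait", ...) {
  summary_stats(trait, "continuous", make_records(n, seed, ...))
}

# Harmonized set drawn around a known causal slope.
make_h <- function(k = 20, seed = 1, theta = 0.5, se_y = 0.02,
                   se_x = 0.005) {
  set.seed(seed)
  bx <- runif(k, 0.05, 0.2) * sample(c(-1, 1), k, replace = TRUE)
  sx <- rep(se_x, k)
  sy <- rep(se_y, k)
  by <- theta * bx + rnorm(k) * sy
  harmonized_set(bx, sx, by, sy)
}

# Independent weighted-least-squares oracle via the normal equations.
oracle_wls <- function(y, X, w, intercept = FALSE) {
  if (intercept) X <- cbind(1, X)
  XtW <- t(X * w)
  coef <- solve(XtW %*% X, XtW %*% y)
  resid <- y - X %*% coef
  k <- length(y)
  p <- ncol(X)
  sigma2 <- sum(w * resid^2) / (k - p)
  vc_unscaled <- solve(XtW %*% X)
  list(
    coef = as.numeric(coef),
    se = unname(sqrt(diag(vc_unscaled))) * max(1, sqrt(sigma2)),
    sigma = sqrt(sigma2)
  )
}

# Multi-taxon screen fixture: several independent exposure chains sharing
# one combined outcome GWAS (variant ids prefixed per taxon so the union is
# well defined). Taxa listed in effect_idx carry a real total effect.
make_screen_inputs <- function(n_taxa = 5, effect_idx = integer(),
                               seed = 1, n_snps = 40,
                               n_exposure = 2e5, n_outcome = 2e5,
                               beta_total = -0.35) {
  relabel <- function(stats, t) {
    stats$records$variant_id <- paste0("t", t, "_", stats$records$variant_id)
    stats
  }
  exposures <- list()
  outcome_parts <- list()
  for (t in seq_len(n_taxa)) {
    has_effect <- t %in% effect_idx
    cfg <- chain_sim_config(
      n_snps = n_snps, n_snps_mediator = 0,
      n_exposure = n_exposure, n_outcome = n_outcome,
      theta_xz = 0, theta_zy = 0,
      theta_direct = if (has_effect) beta_total else 0,
      palindrome_frac = 0.1, seed = seed * 100 + t
    )
    sim <- simulate_chain(cfg)
    exposures[[sprintf("taxon%02d", t)]] <- relabel(sim$exposure, t)
    outcome_parts[[t]] <- relabel(sim$outcome, t)$records
  }
  outcome <- summary_stats(
    "hydrocephalus", "binary", do.call(rbind, outcome_parts)
  )
  list(exposures = exposures, outcome = outcome)
}

# Point estimate of the weighted-median estimator (no bootstrap).
.weighted_median_point <- function(h) {
  th <- h$snps$beta_y / h$snps$beta_x
  w <- h$snps$beta_x^2 / h$snps$se_y^2
  chainMR:::.weighted_median(th, w)
}

# Brute-force greedy clumping oracle over plain data frames.
oracle_clump <- function(df, ld_df = NULL, r2_max = 0.001,
                         window_kb = 10000) {
  lookup <- function(a, b) {
    if (is.null(ld_df) || nrow(ld_df) == 0) {
      return(0)
    }
    hit <- (ld_df$id1 == a & ld_df$id2 == b) |
      (ld_df$id1 == b & ld_df$id2 == a)
    if (any(hit)) ld_df$r2[which(hit)[1]] else 0
  }
  df <- df[order(df$pvalue, df$chrom, df$pos, df$variant_id), , drop = FALSE]
  kept <- character()
  while (nrow(df) > 0) {
    idx <- df[1, ]
    kept <- c(kept, idx$variant_id)
    df <- df[-1, , drop = FALSE]
    if (nrow(df) == 0) break
    near <- df$chrom == idx$chrom &
      abs(df$pos - idx$pos) <= window_kb * 1000
    if (any(near)) {
      r2 <- vapply(
        df$variant_id[near],
        function(v) lookup(idx$variant_id, v), numeric(1)
      )
      drop <- which(near)[r2 > r2_max]
      if (length(drop) > 0) df <- df[-drop, , drop = FALSE]
    }
  }
  sort(kept)
}
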