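# Heterogeneity, pleiotropy, outlier and influence diagnostics gating which
# causal claims stand.

#' Cochran's Q heterogeneity test
#'
#' `Q = sum(w_j (theta_j - theta_ivw)^2)` over the per-SNP Wald ratios with
#' inverse-variance weights `w_j = 1/se(theta_j)^2` and the fixed-effect IVW
#' estimate as centre; chi-square with `k - 1` df under homogeneity.
#'
#' @param h A `harmonized_set` with `k >= 2`.
#' @return List with `q_value`, `q_df`, `q_pvalue` (all `NA` with an
#'   `applicable = FALSE` flag when `k < 2`).
#' @export
cochran_q <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  if (h$k < 2) {
    return(list(
      q_value = NA_real_, q_df = NA_integer_, q_pvalue = NA_real_,
      applicable = FALSE
    ))
  }
  r <- .ratio_estimates(h)
  w <- 1 / r$se^2
  theta_ivw <- sum(w * r$theta) / sum(w)
  q <- sum(w * (r$theta - theta_ivw)^2)
  df <- h$k - 1L
  list(
    q_value = q, q_df = df,
    q_pvalue = stats::pchisq(q, df, lower.tail = FALSE),
    applicable = TRUE
  )
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept of the Egger regression and its two-sided p-value; shares
#' the [egger()] code path exactly.
#'
#' @param h A `harmonized_set` with `k >= 3`.
#' @return List with `intercept`, `se`, `pvalue` (`applicable = FALSE` when
#'   `k < 3`).
#' @export
egger_intercept_test <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  if (h$k < 3) {
    return(list(
      intercept = NA_real_, se = NA_real_, pvalue = NA_real_,
      applicable = FALSE
    ))
  }
  e <- egger(h)
  list(
    intercept = e$extra$intercept, se = e$extra$intercept_se,
    pvalue = e$extra$intercept_p, applicable = TRUE
  )
}

# Leave-one-out IVW slopes for all SNPs at once, from weighted totals.
.loo_slopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO global test, outlier search and distortion test
#'
#' The observed global statistic is the weighted residual sum of squares
#' `RSS = sum_j w_j (beta_yj - theta_(-j) beta_xj)^2` with `theta_(-j)` the
#' leave-one-out IVW slope and `w_j = 1/se_yj^2`. Its null distribution is
#' built by parametric simulation: `beta_yj* ~ N(theta_(-j) beta_xj,
#' se_yj^2)` and `beta_xj* ~ N(beta_xj, se_xj^2)`, recomputing the statistic
#' on each draw. The global p uses the add-one Monte-Carlo correction
#' `(1 + #{sim >= obs}) / (n_sim + 1)`, so it is always in (0, 1\].
#'
#' Per-SNP outlier p-values compare each observed weighted residual to its
#' own simulated distribution, with Bonferroni correction over the k SNPs at
#' `outlier_alpha`. When outliers are found, the distortion test compares the
#' change in IVW estimate after their removal against the distribution of
#' changes from removing random subsets of the same size.
#'
#' @param h A `harmonized_set` with `k >= 4`.
#' @param n_sim Number of simulated datasets (default 1000).
#' @param outlier_alpha Family-wise outlier significance level.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `global_p`, `outliers` (variant ids),
#'   `outlier_pvalues`, `distortion_p` (`NA` when no outliers) and
#'   `applicable`.
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed = 1) {
  stopifnot(inherits(h, "harmonized_set"))
  if (h$k < 4) {
    return(list(
      global_p = NA_real_, outliers = character(),
      outlier_pvalues = numeric(), distortion_p = NA_real_,
      applicable = FALSE
    ))
  }
  s <- h$snps
  k <- h$k
  w <- 1 / s$se_y^2
  th_loo <- .loo_slopes(s$beta_x, s$beta_y, w)
  obs_res <- w * (s$beta_y - th_loo * s$beta_x)^2
  rss_obs <- sum(obs_res)

  set.seed(seed)
  bx_s <- matrix(stats::rnorm(k * n_sim, s$beta_x, s$se_x), nrow = k)
  by_s <- matrix(stats::rnorm(k * n_sim, th_loo * s$beta_x, s$se_y), nrow = k)
  # per-simulation leave-one-out slopes, vectorized over simulations
  wb <- w * bx_s * by_s
  wb2 <- w * bx_s^2
  sxy <- colSums(wb)
  sxx <- colSums(wb2)
  th_s <- (rep(sxy, each = k) - wb) / (rep(sxx, each = k) - wb2)
  res_s <- w * (by_s - th_s * bx_s)^2
  rss_s <- colSums(res_s)

  global_p <- (1 + sum(rss_s >= rss_obs)) / (n_sim + 1)
  p_snp <- (1 + rowSums(res_s >= obs_res)) / (n_sim + 1)
  flagged <- which(p_snp * k < outlier_alpha)
  outliers <- s$variant_id[flagged]

  distortion_p <- NA_real_
  if (length(flagged) > 0 && length(flagged) < k - 1) {
    ivw_slope <- function(idx) {
      sum(w[idx] * s$beta_x[idx] * s$beta_y[idx]) /
        sum(w[idx] * s$beta_x[idx]^2)
    }
    d_obs <- ivw_slope(seq_len(k)) - ivw_slope(setdiff(seq_len(k), flagged))
    d_rand <- vapply(seq_len(n_sim), function(i) {
      drop <- sample.int(k, length(flagged))
      ivw_slope(seq_len(k)) - ivw_slope(setdiff(seq_len(k), drop))
    }, numeric(1))
    distortion_p <- (1 + sum(abs(d_rand) >= abs(d_obs))) / (n_sim + 1)
  }
  list(
    global_p = global_p, outliers = outliers,
    outlier_pvalues = stats::setNames(pmin(1, p_snp * k), s$variant_id),
    distortion_p = distortion_p, applicable = TRUE
  )
}

#' Remove MR-PRESSO outliers and re-run
#'
#' Applies the remove-and-rerun rule: if the outlier search flags SNPs, they
#' are dropped and MR-PRESSO is re-run on the reduced set. A single round is
#' the default; `max_rounds > 1` iterates to a fixed point (each round's
#' flagged set is empty or strictly smaller, so the loop terminates).
#'
#' @param h A `harmonized_set`.
#' @param n_sim,outlier_alpha,seed Passed to [mr_presso()].
#' @param max_rounds Removal rounds (default 1).
#' @return List with the final `harmonized` set, final `presso` result,
#'   `removed` ids and `rounds` used.
#' @export
presso_rerun <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed = 1,
                         max_rounds = 1) {
  removed <- character()
  res <- mr_presso(h, n_sim = n_sim, outlier_alpha = outlier_alpha, seed = seed)
  rounds <- 0L
  while (isTRUE(res$applicable) && length(res$outliers) > 0 &&
    rounds < max_rounds) {
    rounds <- rounds + 1L
    removed <- c(removed, res$outliers)
    h <- subset_harmonized(h, !(h$snps$variant_id %in% res$outliers))
    res <- mr_presso(h,
      n_sim = n_sim, outlier_alpha = outlier_alpha,
      seed = seed + rounds
    )
  }
  list(harmonized = h, presso = res, removed = removed, rounds = rounds)
}

#' Leave-one-out influence analysis
#'
#' Re-estimates the IVW effect k times, omitting each instrument in turn.
#' A SNP is flagged influential when its omission flips the sign of the
#' estimate or its significance at 0.05.
#'
#' @param h A `harmonized_set` with `k >= 3`.
#' @return Data frame with one row per left-out SNP (`left_out`, `beta`,
#'   `se`, `pvalue`, `flagged`); `NULL`-like empty frame when `k < 3`.
#' @export
leave_one_out <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  if (h$k < 3) {
    return(data.frame(
      left_out = character(), beta = numeric(), se = numeric(),
      pvalue = numeric(), flagged = logical(), stringsAsFactors = FALSE
    ))
  }
  full <- ivw(h, model = "fixed")
  rows <- lapply(seq_len(h$k), function(j) {
    hj <- subset_harmonized(h, setdiff(seq_len(h$k), j))
    e <- ivw(hj, model = "fixed")
    data.frame(
      left_out = h$snps$variant_id[j], beta = e$beta, se = e$se,
      pvalue = e$pvalue,
      flagged = sign(e$beta) != sign(full$beta) ||
        (e$pvalue < 0.05) != (full$pvalue < 0.05),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Full sensitivity report for one harmonized set
#'
#' Bundles Cochran's Q, the Egger intercept test, MR-PRESSO (with
#' remove-and-rerun) and leave-one-out into one object.
#'
#' @param h A `harmonized_set`.
#' @param n_sim MR-PRESSO simulation count.
#' @param seed Integer seed.
#' @param presso_rounds Outlier-removal rounds (default 1).
#' @return A `sensitivity_report` list.
#' @export
sensitivity_report <- function(h, n_sim = 1000, seed = 1, presso_rounds = 1) {
  q <- cochran_q(h)
  eg <- egger_intercept_test(h)
  pr <- presso_rerun(h, n_sim = n_sim, seed = seed, max_rounds = presso_rounds)
  structure(
    list(
      q_value = q$q_value, q_df = q$q_df, q_pvalue = q$q_pvalue,
      egger_intercept = eg$intercept, egger_intercept_se = eg$se,
      egger_intercept_p = eg$pvalue,
      presso_global_p = pr$presso$global_p,
      presso_outliers = pr$removed,
      presso_distortion_p = pr$presso$distortion_p,
      presso_harmonized = pr$harmonized,
      loo_estimates = leave_one_out(h)
    ),
    class = "sensitivity_report"
  )
}

#' Decision gate for a causal claim
#'
#' A pair is called positive iff the IVW p-value is below 0.05, all method
#' estimates share the same sign, the Egger intercept test shows no
#' directional pleiotropy (p >= 0.05) and the MR-PRESSO global test — after
#' any outlier removal and re-run — shows none either (p >= 0.05).
#' Heterogeneity (Q p < 0.05) does not invalidate a claim; it switches the
#' IVW model to multiplicative random effects. Diagnostics that could not be
#' run (too few instruments) do not veto.
#'
#' @param estimates Named list from [run_all_methods()] (must contain `ivw`
#'   or a single `wald_ratio`).
#' @param report A `sensitivity_report`.
#' @return List with `robust` (logical), `verdict` (`"positive"` or
#'   `"not_established"`), `reasons` (failing conditions) and `model_note`.
#' @export
sensitivity_gate <- function(estimates, report) {
  est <- estimates[["ivw"]]
  if (is.null(est)) est <- estimates[["wald_ratio"]]
  if (is.null(est)) stop("IVW (or Wald ratio) estimate required", call. = FALSE)
  reasons <- character()
  if (!(est$pvalue < 0.05)) reasons <- c(reasons, "ivw_not_significant")
  consistent <- attr(estimates, "direction_consistent")
  if (is.null(consistent)) {
    betas <- vapply(estimates, function(e) e$beta, numeric(1))
    consistent <- all(betas > 0) || all(betas < 0)
  }
  if (!consistent) reasons <- c(reasons, "direction_inconsistent")
  if (!is.na(report$egger_intercept_p) && report$egger_intercept_p < 0.05) {
    reasons <- c(reasons, "pleiotropy_egger_intercept")
  }
  if (!is.na(report$presso_global_p) && report$presso_global_p < 0.05) {
    reasons <- c(reasons, "pleiotropy_presso_global")
  }
  model_note <- if (!is.na(report$q_pvalue) && report$q_pvalue < 0.05) {
    "multiplicative_random_effects"
  } else {
    est$model_note
  }
  list(
    robust = length(reasons) == 0,
    verdict = if (length(reasons) == 0) "positive" else "not_established",
    reasons = reasons, model_note = model_note
  )
}
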