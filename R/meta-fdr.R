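# Cross-cohort meta-analysis and grouped FDR classification.

#' Inverse-variance meta-analysis
#'
#' Fixed-effect pooling uses weights `1/se^2`; the DerSimonian-Laird
#' random-effects model adds the moment estimate
#' `tau2 = max(0, (Q - (n-1)) / (sum(w) - sum(w^2)/sum(w)))` to each
#' variance. Heterogeneity is summarised by Cochran's Q (chi-square, n-1 df)
#' and `I2 = max(0, (Q - df)/Q) * 100`. A single estimate passes through
#' unchanged with `model = "not_applicable"`.
#'
#' @param beta,se Per-cohort estimates and standard errors (se > 0).
#' @param model `"fixed"` or `"dersimonian_laird"`.
#' @return A `meta_result` with `pooled_beta`, `pooled_se`, `pooled_p`,
#'   `or_value`/`ci_low`/`ci_high`, `q_value`, `q_pvalue`, `i_squared`,
#'   `tau2`, `model`.
#' @export
meta_combine <- function(beta, se, model = c("fixed", "dersimonian_laird")) {
  model <- match.arg(model)
  stopifnot(length(beta) == length(se), all(se > 0))
  n <- length(beta)
  if (n == 0) stop("no estimates to combine", call. = FALSE)
  if (n == 1) {
    or <- beta_to_or(beta, se)
    return(structure(
      list(
        pooled_beta = beta, pooled_se = se, pooled_p = p_from_z(beta, se),
        or_value = or$or_value, ci_low = or$ci_low, ci_high = or$ci_high,
        q_value = NA_real_, q_df = NA_integer_, q_pvalue = NA_real_,
        i_squared = NA_real_, tau2 = NA_real_, model = "not_applicable",
        n_studies = 1L
      ),
      class = "meta_result"
    ))
  }
  w <- 1 / se^2
  fixed <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - fixed)^2)
  df <- n - 1L
  q_p <- stats::pchisq(q, df, lower.tail = FALSE)
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  if (model == "fixed") {
    pooled <- fixed
    pooled_se <- sqrt(1 / sum(w))
    tau2 <- 0
  } else {
    tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
    w_dl <- 1 / (se^2 + tau2)
    pooled <- sum(w_dl * beta) / sum(w_dl)
    pooled_se <- sqrt(1 / sum(w_dl))
  }
  or <- beta_to_or(pooled, pooled_se)
  structure(
    list(
      pooled_beta = pooled, pooled_se = pooled_se,
      pooled_p = p_from_z(pooled, pooled_se),
      or_value = or$or_value, ci_low = or$ci_low, ci_high = or$ci_high,
      q_value = q, q_df = df, q_pvalue = q_p, i_squared = i2, tau2 = tau2,
      model = model, n_studies = n
    ),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "Meta-analysis (%s, %d studies): beta=%.4f se=%.4f p=%.3g I2=%.1f%%\n",
    x$model, x$n_studies, x$pooled_beta, x$pooled_se, x$pooled_p,
    if (is.na(x$i_squared)) 0 else x$i_squared
  ))
  invisible(x)
}

#' Grouped Benjamini-Hochberg adjustment
#'
#' Applies the BH step-up procedure independently within each group (the
#' test families: one taxonomic rank per outcome for microbial exposures,
#' the factor-by-outcome family for inflammatory mediators). Results are
#' returned in input order.
#'
#' @param pvalues Numeric vector of raw p-values in (0, 1].
#' @param groups Parallel vector of group labels (a single family when
#'   omitted).
#' @return Vector of adjusted p-values, input order preserved.
#' @export
bh_adjust <- function(pvalues, groups = NULL) {
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  if (is.null(groups)) {
    return(stats::p.adjust(pvalues, method = "BH"))
  }
  stopifnot(length(groups) == length(pvalues))
  out <- numeric(length(pvalues))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    out[idx] <- stats::p.adjust(pvalues[idx], method = "BH")
  }
  out
}

#' Classify an association by raw and FDR-adjusted p-values
#'
#' `significant` requires p < 0.05 and p_fdr < 0.1; `potential` p < 0.05
#' with p_fdr >= 0.1; anything else is `none`. Vectorized.
#'
#' @param p Raw p-values.
#' @param p_fdr FDR-adjusted p-values.
#' @return Character vector in `{"significant", "potential", "none"}`.
#' @export
classify_association <- function(p, p_fdr) {
  ifelse(p < 0.05 & p_fdr < 0.1, "significant",
    ifelse(p < 0.05, "potential", "none")
  )
}
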