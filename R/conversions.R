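#' Two-sided normal p-value from an effect and its standard error
#'
#' @param beta Effect estimate.
#' @param se Standard error, strictly positive.
#' @return Two-sided p-value `2 * pnorm(-|beta/se|)`.
#' @examples
#' p_from_z(-1.046, 0.338)
#' @export
p_from_z <- function(beta, se) {
  stopifnot(all(se > 0))
  2 * stats::pnorm(-abs(beta / se))
}

#' Convert a log-odds effect to an odds ratio with 95% CI
#'
#' Uses the conventional 1.96 normal quantile so that printed confidence
#' intervals are bit-stable across platforms.
#'
#' @param beta Effect on the log-odds scale.
#' @param se Standard error (>= 0).
#' @param digits Display rounding used by [format_or()]; the returned values
#'   are unrounded.
#' @return A list with `or_value`, `ci_low`, `ci_high`.
#' @examples
#' beta_to_or(-1.046, 0.338)
#' @export
beta_to_or <- function(beta, se, digits = 2) {
  stopifnot(all(se >= 0))
  list(
    or_value = exp(beta),
    ci_low   = exp(beta - 1.96 * se),
    ci_high  = exp(beta + 1.96 * se)
  )
}

#' Display-format an odds ratio and CI as "OR (low-high)"
#' @param or A list as returned by [beta_to_or()].
#' @param digits Decimal places (default 2, as in published tables).
#' @export
format_or <- function(or, digits = 2) {
  sprintf(
    "%.*f (%.*f-%.*f)",
    digits, or$or_value, digits, or$ci_low, digits, or$ci_high
  )
}

#' Recover a standard error from a 95% confidence interval
#'
#' Inverts a symmetric Wald interval: `(high - low) / (2 * 1.96)`. For odds
#' ratios, pass the bounds on the log scale.
#'
#' @param low,high Interval bounds with `high > low`.
#' @export
se_from_ci <- function(low, high) {
  stopifnot(all(high > low))
  (high - low) / (2 * 1.96)
}

#' Construct an MR estimate record
#'
#' Container for one method's causal estimate. The odds ratio and its CI are
#' derived from `beta`/`se` so the object is internally consistent by
#' construction.
#'
#' @param method One of `"wald_ratio"`, `"ivw"`, `"egger"`,
#'   `"weighted_median"`, `"weighted_mode"`, `"simple_mode"`.
#' @param beta,se Causal effect (log-odds per exposure unit for binary
#'   outcomes) and standard error.
#' @param k Number of instruments used.
#' @param model_note `"fixed"`, `"multiplicative_random_effects"` or
#'   `"not_applicable"`.
#' @param extra Method-specific extras (for Egger: `intercept`,
#'   `intercept_se`, `intercept_p`).
#' @return An object of class `mr_estimate`.
#' @export
mr_estimate <- function(method, beta, se, k,
                        model_note = "not_applicable", extra = list()) {
  method <- match.arg(method, c(
    "wald_ratio", "ivw", "egger",
    "weighted_median", "weighted_mode", "simple_mode"
  ))
  or <- beta_to_or(beta, se)
  structure(
    list(
      method = method, beta = beta, se = se,
      pvalue = p_from_z(beta, se),
      or_value = or$or_value, ci_low = or$ci_low, ci_high = or$ci_high,
      k = k, model_note = model_note, extra = extra
    ),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "MR estimate [%s] k=%d: beta=%.4f se=%.4f p=%.3g OR=%s model=%s\n",
    x$method, x$k, x$beta, x$se, x$pvalue,
    format_or(list(or_value = x$or_value, ci_low = x$ci_low, ci_high = x$ci_high)),
    x$model_note
  ))
  invisible(x)
}

#' Collect a list of MR estimates into a data frame
#' @param estimates List of `mr_estimate` objects.
#' @export
estimates_to_df <- function(estimates) {
  if (length(estimates) == 0) {
    return(data.frame(
      method = character(), k = integer(), beta = numeric(), se = numeric(),
      pvalue = numeric(), or = numeric(), ci_low = numeric(),
      ci_high = numeric(), model_note = character(),
      egger_intercept = numeric(), egger_intercept_p = numeric(),
      stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(
      method = e$method, k = e$k, beta = e$beta, se = e$se,
      pvalue = e$pvalue, or = e$or_value, ci_low = e$ci_low,
      ci_high = e$ci_high, model_note = e$model_note,
      egger_intercept = if (!is.null(e$extra$intercept)) e$extra$intercept else NA_real_,
      egger_intercept_p = if (!is.null(e$extra$intercept_p)) e$extra$intercept_p else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
}
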