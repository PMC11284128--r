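# Univariable two-sample MR estimators. All consume a harmonized_set whose
# per-SNP (beta_x, beta_y) pairs are aligned to a common effect allele.

.ratio_estimates <- function(h) {
  s <- h$snps
  if (any(s$beta_x == 0)) {
    stop("zero exposure effect among instruments; Wald ratios undefined",
      call. = FALSE
    )
  }
  list(theta = s$beta_y / s$beta_x, se = s$se_y / abs(s$beta_x))
}

#' Wald ratio (single-instrument causal estimate)
#'
#' `beta_y / beta_x` with the first-order standard error `se_y / |beta_x|`,
#' the standard default under strong instruments (F >= 10 is enforced
#' upstream in the selection pipeline).
#'
#' @param beta_x,se_x SNP-exposure effect and SE.
#' @param beta_y,se_y SNP-outcome effect and SE.
#' @return An [mr_estimate()].
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y) {
  if (beta_x == 0) stop("beta_x must be nonzero", call. = FALSE)
  mr_estimate("wald_ratio",
    beta = beta_y / beta_x, se = se_y / abs(beta_x), k = 1L
  )
}

#' Inverse-variance-weighted estimator
#'
#' Weighted regression of SNP-outcome on SNP-exposure effects through the
#' origin with weights `1/se_y^2`:
#' `beta = sum(w bx by) / sum(w bx^2)`, fixed-effect
#' `se = sqrt(1 / sum(w bx^2))`. Under the multiplicative random-effects
#' model the SE is inflated by `max(1, sqrt(Q / (k - 1)))` with Q Cochran's
#' heterogeneity statistic; `model = "auto"` applies that inflation when the
#' Q test rejects at 0.05 and reports the model used in `model_note`.
#'
#' With a single instrument the Wald ratio is returned (signalled via the
#' estimate's `method`).
#'
#' @param h A `harmonized_set` with `k >= 1`.
#' @param model `"fixed"`, `"random"` (multiplicative random effects) or
#'   `"auto"`.
#' @return An [mr_estimate()].
#' @export
ivw <- function(h, model = c("fixed", "random", "auto")) {
  model <- match.arg(model)
  stopifnot(inherits(h, "harmonized_set"))
  s <- h$snps
  if (h$k < 1) stop("empty harmonized set", call. = FALSE)
  if (h$k == 1) {
    return(wald_ratio(s$beta_x, s$se_x, s$beta_y, s$se_y))
  }
  w <- 1 / s$se_y^2
  sxx <- sum(w * s$beta_x^2)
  beta <- sum(w * s$beta_x * s$beta_y) / sxx
  se_fixed <- sqrt(1 / sxx)
  q <- cochran_q(h)
  if (model == "auto") {
    model <- if (q$q_pvalue < 0.05) "random" else "fixed"
  }
  if (model == "random") {
    se <- se_fixed * max(1, sqrt(q$q_value / (h$k - 1)))
    note <- "multiplicative_random_effects"
  } else {
    se <- se_fixed
    note <- "fixed"
  }
  mr_estimate("ivw", beta = beta, se = se, k = h$k, model_note = note)
}

# Weighted least squares of y on X (with intercept if requested); SEs use a
# multiplicative overdispersion factor max(1, sigma) where sigma^2 is the
# weighted RSS over residual df.
.wls <- function(y, X, w, intercept = TRUE) {
  df <- if (intercept) {
    stats::lm(y ~ X, weights = w)
  } else {
    stats::lm(y ~ X - 1, weights = w)
  }
  cf <- stats::coef(df)
  if (any(is.na(cf))) {
    stop("rank-deficient weighted regression (collinear predictors)",
      call. = FALSE
    )
  }
  sm <- summary(df)
  sigma <- sm$sigma
  se_unscaled <- sqrt(diag(stats::vcov(df))) / sigma
  list(
    coef = cf, se = se_unscaled * max(1, sigma),
    sigma = sigma, fit = df
  )
}

#' MR-Egger regression
#'
#' Weighted regression of SNP-outcome on SNP-exposure effects with an
#' intercept (weights `1/se_y^2`), after orienting every SNP so its exposure
#' effect is non-negative. The slope estimates the causal effect; a nonzero
#' intercept indicates directional horizontal pleiotropy. Standard errors use
#' the multiplicative overdispersion factor `max(1, sqrt(RSS/(k-2)))`.
#'
#' @param h A `harmonized_set` with `k >= 3`.
#' @return An [mr_estimate()] whose `extra` holds `intercept`,
#'   `intercept_se`, `intercept_p`.
#' @export
egger <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  if (h$k < 3) stop("MR-Egger requires at least 3 instruments", call. = FALSE)
  s <- h$snps
  flip <- ifelse(s$beta_x < 0, -1, 1)
  bx <- s$beta_x * flip
  by <- s$beta_y * flip
  w <- 1 / s$se_y^2
  fit <- .wls(by, bx, w, intercept = TRUE)
  mr_estimate("egger",
    beta = unname(fit$coef[2]), se = unname(fit$se[2]), k = h$k,
    model_note = "multiplicative_random_effects",
    extra = list(
      intercept = unname(fit$coef[1]),
      intercept_se = unname(fit$se[1]),
      intercept_p = p_from_z(unname(fit$coef[1]), unname(fit$se[1]))
    )
  )
}

# Weighted median of values x with weights w (normalized internally):
# linear interpolation of the sorted values at cumulative weight 0.5 using
# percentile positions p_j = cumsum(w_j) - w_j / 2.
.weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  stats::approx(p, x, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median estimator
#'
#' The inverse-variance weighted median of the per-SNP Wald ratios;
#' consistent when instruments contributing at least half the weight are
#' valid. The standard error comes from a seeded parametric bootstrap that
#' resamples `beta_x` and `beta_y` from their sampling distributions.
#'
#' @param h A `harmonized_set` with `k >= 3`.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return An [mr_estimate()].
#' @export
weighted_median <- function(h, n_boot = 1000, seed = 1) {
  stopifnot(inherits(h, "harmonized_set"))
  if (h$k < 3) {
    stop("weighted median requires at least 3 instruments", call. = FALSE)
  }
  r <- .ratio_estimates(h)
  w <- 1 / r$se^2
  est <- .weighted_median(r$theta, w)
  se <- .boot_se(h, n_boot, seed, function(bx, by, s) {
    th <- by / bx
    .weighted_median(th, bx^2 / s$se_y^2)
  })
  mr_estimate("weighted_median", beta = est, se = se, k = h$k)
}

# Parametric bootstrap SE: redraw (beta_x, beta_y) from normals centred on
# the observed values, recompute the point estimate, return the SD.
.boot_se <- function(h, n_boot, seed, point_fun) {
  s <- h$snps
  k <- h$k
  set.seed(seed)
  bx <- matrix(stats::rnorm(k * n_boot, s$beta_x, s$se_x), nrow = k)
  by <- matrix(stats::rnorm(k * n_boot, s$beta_y, s$se_y), nrow = k)
  ests <- vapply(
    seq_len(n_boot),
    function(b) point_fun(bx[, b], by[, b], s), numeric(1)
  )
  stats::sd(ests)
}

# Mode of the ratio estimates by a normal-kernel density, Silverman
# normal-reference bandwidth on theta scaled by bandwidth_factor.
.kde_mode <- function(theta, w, bandwidth_factor) {
  w <- w / sum(w)
  mu <- sum(w * theta)
  s <- sqrt(sum(w * (theta - mu)^2))
  if (s <= 1e-12 * max(1, abs(mu))) {
    # numerically a point mass
    return(mu)
  }
  bw <- bandwidth_factor * 1.06 * s * length(theta)^(-1 / 5)
  grid <- seq(min(theta) - 3 * bw, max(theta) + 3 * bw, length.out = 512)
  dens <- colSums(w * stats::dnorm(outer(theta, grid, "-") / bw))
  best <- grid[which.max(dens)]
  step <- grid[2] - grid[1]
  if (!(best - step < best + step)) {
    return(best)
  }
  opt <- stats::optimize(
    function(x) sum(w * stats::dnorm(x, theta, bw)),
    lower = best - step, upper = best + step, maximum = TRUE
  )
  opt$maximum
}

#' Mode-based estimators (simple and weighted mode)
#'
#' Kernel-density mode of the per-SNP Wald ratios: consistent when the
#' largest group of instruments sharing a causal estimate is valid (ZEMPA).
#' The weighted variant weights each ratio by its inverse variance; the
#' simple variant weights equally. Bandwidth is the normal-reference rule on
#' the ratio scale times `bandwidth_factor`; the SE comes from a seeded
#' parametric bootstrap.
#'
#' @param h A `harmonized_set` with `k >= 3`.
#' @param variant `"simple"` or `"weighted"`.
#' @param bandwidth_factor Multiplier on the normal-reference bandwidth.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @return An [mr_estimate()].
#' @export
mode_estimators <- function(h, variant = c("simple", "weighted"),
                            bandwidth_factor = 1.0, n_boot = 1000, seed = 1) {
  variant <- match.arg(variant)
  stopifnot(inherits(h, "harmonized_set"))
  if (h$k < 3) {
    stop("mode estimators require at least 3 instruments", call. = FALSE)
  }
  r <- .ratio_estimates(h)
  w <- if (variant == "weighted") 1 / r$se^2 else rep(1, h$k)
  est <- .kde_mode(r$theta, w, bandwidth_factor)
  se <- .boot_se(h, n_boot, seed, function(bx, by, s) {
    th <- by / bx
    ww <- if (variant == "weighted") bx^2 / s$se_y^2 else rep(1, length(th))
    .kde_mode(th, ww, bandwidth_factor)
  })
  mr_estimate(
    if (variant == "weighted") "weighted_mode" else "simple_mode",
    beta = est, se = se, k = h$k
  )
}

#' Run every applicable univariable MR method
#'
#' With one instrument only the Wald ratio applies; with two, IVW; from three
#' instruments the full set of five methods is computed (IVW under the
#' auto fixed/random-effects rule, MR-Egger, weighted median, weighted and
#' simple mode). A direction-consistency flag records whether all estimates
#' share the same sign.
#'
#' @param h A `harmonized_set`.
#' @param seed Integer seed driving the bootstrap-based methods.
#' @param n_boot Bootstrap replicates for median/mode SEs.
#' @return Named list of [mr_estimate()] objects with attribute
#'   `direction_consistent`.
#' @export
run_all_methods <- function(h, seed = 1, n_boot = 1000) {
  stopifnot(inherits(h, "harmonized_set"))
  if (h$k < 1) stop("empty harmonized set", call. = FALSE)
  out <- if (h$k == 1) {
    s <- h$snps
    list(wald_ratio = wald_ratio(s$beta_x, s$se_x, s$beta_y, s$se_y))
  } else if (h$k == 2) {
    list(ivw = ivw(h, model = "auto"))
  } else {
    list(
      ivw = ivw(h, model = "auto"),
      egger = egger(h),
      weighted_median = weighted_median(h, n_boot = n_boot, seed = seed),
      weighted_mode = mode_estimators(h, "weighted",
        n_boot = n_boot, seed = seed + 1
      ),
      simple_mode = mode_estimators(h, "simple",
        n_boot = n_boot, seed = seed + 2
      )
    )
  }
  betas <- vapply(out, function(e) e$beta, numeric(1))
  attr(out, "direction_consistent") <-
    all(betas > 0) || all(betas < 0)
  out
}
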