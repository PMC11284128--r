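# Multivariable MR (joint exposures) and the two-step mediation
# decomposition.

#' Harmonize several exposures and one outcome to a common effect allele
#'
#' Builds the joint instrument matrix for multivariable MR: the union of the
#' per-exposure instrument sets, clumped jointly with the minimum p-value
#' across exposures as the ranking key, restricted to SNPs present in every
#' exposure and in the outcome, palindromes dropped, and every trait's
#' effect aligned to the first exposure's effect allele (strand complements
#' resolved, irreconcilable allele sets dropped).
#'
#' @param inst_list List of [instrument_set()]s, one per exposure, in the
#'   same order as `exposures`.
#' @param exposures List of [summary_stats()] objects (length m >= 2).
#' @param outcome A [summary_stats()] object.
#' @param ld Optional [ld_table()] for the joint clump.
#' @param r2_max,window_kb Clumping parameters.
#' @return An object of class `mv_harmonized_set` with matrices `beta_X`,
#'   `se_X` (k x m), vectors `beta_y`, `se_y`, `variant_id`, and counts `k`,
#'   `m`.
#' @export
mvmr_harmonize <- function(inst_list, exposures, outcome, ld = NULL,
                           r2_max = 0.001, window_kb = 10000) {
  stopifnot(length(exposures) >= 2, length(inst_list) == length(exposures))
  m <- length(exposures)
  exposure_names <- vapply(exposures, function(e) e$trait_name, "")

  # union of selected instruments, ranked by min p across exposures
  union_ids <- unique(unlist(lapply(inst_list, function(i) i$members$variant_id)))
  if (length(union_ids) == 0) {
    stop("insufficient instruments: empty union set", call. = FALSE)
  }
  ref <- exposures[[1]]$records
  min_p <- rep(Inf, length(union_ids))
  for (ex in exposures) {
    idx <- match(union_ids, ex$records$variant_id)
    p <- ex$records$pvalue[idx]
    min_p <- pmin(min_p, ifelse(is.na(p), Inf, p))
  }
  # SNP must be present in all exposures and the outcome
  present <- rep(TRUE, length(union_ids))
  for (ex in exposures) {
    present <- present & union_ids %in% ex$records$variant_id
  }
  present <- present & union_ids %in% outcome$records$variant_id
  union_ids <- union_ids[present]
  min_p <- min_p[present]
  if (length(union_ids) == 0) {
    stop("insufficient instruments: no SNP present in all datasets",
      call. = FALSE
    )
  }

  ridx <- match(union_ids, ref$variant_id)
  members <- ref[ridx, , drop = FALSE]
  members$pvalue <- min_p
  joint <- clump(
    instrument_set("mvmr_union", members),
    ld,
    r2_max = r2_max, window_kb = window_kb
  )
  mm <- joint$members

  pal <- is_palindromic(mm$effect_allele, mm$other_allele)
  mm <- mm[!pal, , drop = FALSE]
  if (nrow(mm) == 0) {
    stop("insufficient instruments: all palindromic", call. = FALSE)
  }

  # align every trait to the reference (first exposure) effect allele
  align <- function(trait_records, ids, ref_ea, ref_oa) {
    idx <- match(ids, trait_records$variant_id)
    t_ea <- trait_records$effect_allele[idx]
    t_oa <- trait_records$other_allele[idx]
    same <- t_ea == ref_ea & t_oa == ref_oa
    swap <- t_ea == ref_oa & t_oa == ref_ea
    comp_same <- COMPLEMENT[t_ea] == ref_ea & COMPLEMENT[t_oa] == ref_oa
    comp_swap <- COMPLEMENT[t_ea] == ref_oa & COMPLEMENT[t_oa] == ref_ea
    ok <- same | swap | comp_same | comp_swap
    sgn <- ifelse((swap | comp_swap) & !same & !comp_same, -1, 1)
    list(
      ok = ok, beta = sgn * trait_records$beta[idx],
      se = trait_records$se[idx]
    )
  }

  ids <- mm$variant_id
  traits <- c(exposures, list(outcome))
  aligned <- lapply(traits, function(t) {
    align(t$records,
      ids = ids,
      ref_ea = mm$effect_allele, ref_oa = mm$other_allele
    )
  })
  ok <- Reduce(`&`, lapply(aligned, `[[`, "ok"))
  ids <- ids[ok]
  k <- length(ids)
  if (k <= m) {
    stop(sprintf(
      "insufficient instruments: k = %d <= m = %d after filtering", k, m
    ), call. = FALSE)
  }
  beta_X <- vapply(aligned[seq_len(m)], function(a) a$beta[ok], numeric(k))
  se_X <- vapply(aligned[seq_len(m)], function(a) a$se[ok], numeric(k))
  beta_X <- matrix(beta_X, nrow = k, dimnames = list(ids, exposure_names))
  se_X <- matrix(se_X, nrow = k, dimnames = list(ids, exposure_names))
  structure(
    list(
      outcome_name = outcome$trait_name, exposure_names = exposure_names,
      variant_id = ids, beta_X = beta_X, se_X = se_X,
      beta_y = aligned[[m + 1]]$beta[ok], se_y = aligned[[m + 1]]$se[ok],
      k = k, m = m
    ),
    class = "mv_harmonized_set"
  )
}

#' Build a multivariable harmonized set from aligned matrices
#'
#' Direct constructor for simulations and tests with pre-aligned effects.
#'
#' @param beta_X,se_X k x m matrices of exposure effects and SEs.
#' @param beta_y,se_y Outcome effect and SE vectors (length k).
#' @param exposure_names Column labels.
#' @param variant_id Optional SNP ids.
#' @export
mv_harmonized_set <- function(beta_X, se_X, beta_y, se_y,
                              exposure_names = colnames(beta_X),
                              variant_id = sprintf("snp%d", seq_len(nrow(beta_X)))) {
  beta_X <- as.matrix(beta_X)
  se_X <- as.matrix(se_X)
  if (is.null(exposure_names)) {
    exposure_names <- sprintf("exposure%d", seq_len(ncol(beta_X)))
  }
  colnames(beta_X) <- exposure_names
  colnames(se_X) <- exposure_names
  stopifnot(
    nrow(beta_X) == length(beta_y), nrow(beta_X) == length(se_y),
    all(se_y > 0), nrow(beta_X) > ncol(beta_X)
  )
  structure(
    list(
      outcome_name = "outcome", exposure_names = exposure_names,
      variant_id = variant_id, beta_X = beta_X, se_X = se_X,
      beta_y = beta_y, se_y = se_y,
      k = nrow(beta_X), m = ncol(beta_X)
    ),
    class = "mv_harmonized_set"
  )
}

# An exposure whose effect column is identically zero carries no
# information; it is excluded from the fit (estimate NA) with a warning so
# the remaining exposures nest the lower-dimensional model.
.split_zero_cols <- function(mv) {
  zero <- colSums(abs(mv$beta_X)) == 0
  if (any(zero)) {
    warning("exposure column(s) identically zero, excluded from fit: ",
      paste(mv$exposure_names[zero], collapse = ", "),
      call. = FALSE
    )
  }
  zero
}

.mvmr_check_rank <- function(X, w, exposure_names) {
  qrx <- qr(sqrt(w) * X)
  if (qrx$rank < ncol(X)) {
    stop("collinearity among exposures: ",
      paste(exposure_names, collapse = ", "),
      call. = FALSE
    )
  }
}

.mvmr_estimates_df <- function(names, beta, se, k) {
  pvalue <- or <- ci_low <- ci_high <- rep(NA_real_, length(beta))
  ok <- !is.na(beta) & !is.na(se)
  if (any(ok)) {
    conv <- beta_to_or(beta[ok], se[ok])
    pvalue[ok] <- p_from_z(beta[ok], se[ok])
    or[ok] <- conv$or_value
    ci_low[ok] <- conv$ci_low
    ci_high[ok] <- conv$ci_high
  }
  data.frame(
    exposure = names, beta = beta, se = se, pvalue = pvalue,
    or = or, ci_low = ci_low, ci_high = ci_high,
    k = k, row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Multivariable IVW
#'
#' Weighted multiple regression of outcome effects on the m exposure-effect
#' columns without intercept, weights `1/se_y^2`. Each coefficient is that
#' exposure's direct effect conditional on the others. Standard errors carry
#' the multiplicative overdispersion factor `max(1, sqrt(RSS/(k-m)))`.
#'
#' @param mv An `mv_harmonized_set` with `k > m`.
#' @return A data frame of per-exposure estimates (class `mvmr_estimates`).
#' @export
mvmr_ivw <- function(mv) {
  stopifnot(inherits(mv, "mv_harmonized_set"))
  if (mv$k <= mv$m) stop("need k > m instruments", call. = FALSE)
  w <- 1 / mv$se_y^2
  zero <- .split_zero_cols(mv)
  X <- mv$beta_X[, !zero, drop = FALSE]
  .mvmr_check_rank(X, w, mv$exposure_names[!zero])
  fit <- .wls(mv$beta_y, X, w, intercept = FALSE)
  beta <- se <- rep(NA_real_, mv$m)
  beta[!zero] <- unname(fit$coef)
  se[!zero] <- unname(fit$se)
  out <- .mvmr_estimates_df(mv$exposure_names, beta, se, k = mv$k)
  class(out) <- c("mvmr_estimates", class(out))
  attr(out, "sigma") <- fit$sigma
  out
}

#' Multivariable MR-Egger
#'
#' As [mvmr_ivw()] plus an intercept column, after orienting every SNP so the
#' first-listed exposure's effect is non-negative. The intercept estimates
#' directional pleiotropy not captured by the exposures.
#'
#' @param mv An `mv_harmonized_set` with `k > m + 1`.
#' @return Per-exposure estimates with attributes `intercept`,
#'   `intercept_se`, `intercept_p`.
#' @export
mvmr_egger <- function(mv) {
  stopifnot(inherits(mv, "mv_harmonized_set"))
  if (mv$k <= mv$m + 1) stop("need k > m + 1 instruments", call. = FALSE)
  flip <- ifelse(mv$beta_X[, 1] < 0, -1, 1)
  X <- mv$beta_X * flip
  y <- mv$beta_y * flip
  w <- 1 / mv$se_y^2
  .mvmr_check_rank(cbind(1, X), w, c("(intercept)", mv$exposure_names))
  fit <- .wls(y, X, w, intercept = TRUE)
  out <- .mvmr_estimates_df(mv$exposure_names, unname(fit$coef[-1]),
    unname(fit$se[-1]),
    k = mv$k
  )
  class(out) <- c("mvmr_estimates", class(out))
  attr(out, "intercept") <- unname(fit$coef[1])
  attr(out, "intercept_se") <- unname(fit$se[1])
  attr(out, "intercept_p") <- p_from_z(unname(fit$coef[1]), unname(fit$se[1]))
  out
}

# Exact weighted L1 (least absolute deviations) regression for small
# designs: the LAD solution interpolates m observations, so enumerating all
# m-subsets and keeping the candidate with minimal weighted L1 objective is
# exact and deterministic. The m = 2 case (one exposure plus one mediator,
# the standard mediation design) is fully vectorized.
.lad_exact <- function(y, X, w) {
  k <- nrow(X)
  m <- ncol(X)
  if (m == 1) {
    th <- y / X[, 1]
    ww <- w * abs(X[, 1])
    obj <- vapply(th, function(b) sum(w * abs(y - X[, 1] * b)), numeric(1))
    return(th[which.min(obj)])
  }
  if (m == 2) {
    cmb <- utils::combn(k, 2)
    i <- cmb[1, ]
    j <- cmb[2, ]
    a1i <- X[i, 1]
    a2i <- X[i, 2]
    a1j <- X[j, 1]
    a2j <- X[j, 2]
    det <- a1i * a2j - a1j * a2i
    ok <- abs(det) > 1e-14
    b1 <- (y[i] * a2j - y[j] * a2i)[ok] / det[ok]
    b2 <- (a1i * y[j] - a1j * y[i])[ok] / det[ok]
    resid <- abs(y - outer(X[, 1], b1) - outer(X[, 2], b2))
    obj <- colSums(w * resid)
    best <- which.min(obj)
    return(c(b1[best], b2[best]))
  }
  cmb <- utils::combn(k, m)
  best_obj <- Inf
  best_b <- NULL
  for (p in seq_len(ncol(cmb))) {
    idx <- cmb[, p]
    A <- X[idx, , drop = FALSE]
    bb <- tryCatch(solve(A, y[idx]), error = function(e) NULL)
    if (is.null(bb)) next
    o <- sum(w * abs(y - X %*% bb))
    if (o < best_obj) {
      best_obj <- o
      best_b <- as.numeric(bb)
    }
  }
  best_b
}

# IRLS fallback for designs too large to enumerate; epsilon-continuation
# anneals the smoothing floor downward as each smoothed problem stabilises.
.l1_wls <- function(y, X, w, tol = 1e-10, max_iter = 500,
                    max_candidates = 5000) {
  k <- nrow(as.matrix(X))
  m <- ncol(as.matrix(X))
  if (m <= 3 && choose(k, m) <= max_candidates) {
    return(.lad_exact(y, as.matrix(X), w))
  }
  b <- stats::coef(stats::lm(y ~ X - 1, weights = w))
  scale <- stats::median(abs(y - X %*% b)) + 1e-12
  it <- 0L
  for (eps in scale * 10^(-(2:8))) {
    repeat {
      it <- it + 1L
      if (it > max_iter) {
        stop("median regression failed to converge in ", max_iter,
          " iterations",
          call. = FALSE
        )
      }
      r <- as.numeric(y - X %*% b)
      wi <- w / pmax(abs(r), eps)
      b_new <- stats::coef(stats::lm(y ~ X - 1, weights = wi))
      delta <- max(abs(b_new - b)) / (1 + max(abs(b)))
      b <- b_new
      if (delta < max(tol, eps * 1e-3)) break
    }
  }
  as.numeric(b)
}

#' Multivariable weighted-median regression
#'
#' Weighted L1 regression of outcome on exposure effects (weights
#' `1/se_y^2`), robust to a minority of contaminated instruments. Because
#' the least-absolute-deviations solution interpolates m observations, small
#' designs are solved exactly by enumerating the candidate vertices; larger
#' designs fall back to iteratively reweighted least squares with an
#' epsilon-continuation schedule, converged to coefficient tolerance 1e-10.
#' SEs come from a seeded parametric bootstrap resampling all effect
#' estimates from their sampling distributions.
#'
#' @param mv An `mv_harmonized_set` with `k > m`.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return Per-exposure estimates (class `mvmr_estimates`).
#' @export
mvmr_median <- function(mv, n_boot = 1000, seed = 1) {
  stopifnot(inherits(mv, "mv_harmonized_set"))
  if (mv$k <= mv$m) stop("need k > m instruments", call. = FALSE)
  w <- 1 / mv$se_y^2
  .mvmr_check_rank(mv$beta_X, w, mv$exposure_names)
  b <- .l1_wls(mv$beta_y, mv$beta_X, w)
  set.seed(seed)
  boots <- matrix(NA_real_, n_boot, mv$m)
  for (i in seq_len(n_boot)) {
    Xb <- mv$beta_X + matrix(stats::rnorm(mv$k * mv$m), mv$k) * mv$se_X
    yb <- stats::rnorm(mv$k, mv$beta_y, mv$se_y)
    boots[i, ] <- tryCatch(
      .l1_wls(yb, Xb, 1 / mv$se_y^2),
      error = function(e) rep(NA_real_, mv$m)
    )
  }
  se <- apply(boots, 2, stats::sd, na.rm = TRUE)
  out <- .mvmr_estimates_df(mv$exposure_names, unname(b), se, k = mv$k)
  class(out) <- c("mvmr_estimates", class(out))
  out
}

#' Two-step mediation decomposition
#'
#' Product-of-coefficients decomposition: the mediated effect is
#' `beta_xz * beta_zy` (exposure->mediator times mediator->outcome direct
#' effect) and its share of the total effect is
#' `(beta_xz * beta_zy) / beta_total`. A mediating effect is considered to
#' exist only when the mediated and total effects share direction; a zero
#' mediated effect is treated as inconsistent with any nonzero total.
#'
#' @param beta_total Total exposure->outcome effect (nonzero).
#' @param beta_xz Exposure->mediator effect.
#' @param beta_zy Mediator->outcome direct effect (from MVMR).
#' @return A `mediation_result` with `mediated_effect`,
#'   `proportion_mediated` (fraction) and `direction_consistent`.
#' @export
mediation_decompose <- function(beta_total, beta_xz, beta_zy) {
  if (beta_total == 0) stop("beta_total must be nonzero", call. = FALSE)
  mediated <- beta_xz * beta_zy
  structure(
    list(
      beta_total = beta_total, beta_xz = beta_xz, beta_zy = beta_zy,
      mediated_effect = mediated,
      proportion_mediated = mediated / beta_total,
      direction_consistent = sign(mediated) != 0 &&
        sign(mediated) == sign(beta_total)
    ),
    class = "mediation_result"
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Mediation: total = %.3f, X->Z = %.3f, Z->Y = %.3f\n",
      "  mediated effect = %.3f (%.2f%% of total), direction %s\n"
    ),
    x$beta_total, x$beta_xz, x$beta_zy, x$mediated_effect,
    100 * x$proportion_mediated,
    if (x$direction_consistent) "consistent" else "inconsistent"
  ))
  invisible(x)
}

#' Run the full two-step mediation analysis
#'
#' Step one estimates the total exposure->outcome effect and the
#' exposure->mediator effect by univariable IVW on the exposure's selected
#' instruments. Step two estimates the mediator's direct effect on the
#' outcome by multivariable IVW with exposure and mediator jointly
#' instrumented. The product decomposition then gives the mediated effect
#' and its proportion of the total. All intermediate estimates and
#' sensitivity reports are attached.
#'
#' @param exposure,mediator,outcome [summary_stats()] objects.
#' @param p_threshold Instrument p-value threshold (default 1e-5).
#' @param ld Optional [ld_table()].
#' @param exclude Optional exclusion-list ids.
#' @param r2_max,window_kb,min_f Selection parameters.
#' @param seed Integer seed for bootstrap/PRESSO stages.
#' @param n_sim MR-PRESSO simulation count for the attached reports.
#' @param sensitivity Compute sensitivity reports for both univariable
#'   stages (default TRUE; disable for large simulation studies).
#' @return List of class `two_step_result` with `mediation`
#'   (a `mediation_result`), the stage estimates and reports.
#' @export
run_two_step <- function(exposure, mediator, outcome,
                         p_threshold = 1e-5, ld = NULL, exclude = NULL,
                         r2_max = 0.001, window_kb = 10000, min_f = 10,
                         seed = 1, n_sim = 1000, sensitivity = TRUE) {
  h_total <- select_instruments(exposure, outcome,
    p_threshold = p_threshold,
    ld = ld, exclude = exclude, r2_max = r2_max, window_kb = window_kb,
    min_f = min_f
  )
  if (h_total$k < 1) {
    stop("insufficient instruments at stage exposure->outcome", call. = FALSE)
  }
  h_xz <- select_instruments(exposure, mediator,
    p_threshold = p_threshold,
    ld = ld, exclude = exclude, r2_max = r2_max, window_kb = window_kb,
    min_f = min_f
  )
  if (h_xz$k < 1) {
    stop("insufficient instruments at stage exposure->mediator", call. = FALSE)
  }
  est_total <- ivw(h_total, model = "auto")
  est_xz <- ivw(h_xz, model = "auto")

  sel <- function(stats_obj) {
    inst <- select_by_pvalue(stats_obj, p_threshold)
    inst <- clump(inst, ld, r2_max = r2_max, window_kb = window_kb)
    inst <- drop_weak_instruments(inst, min_f = min_f)
    if (!is.null(exclude)) inst <- apply_exclusion_list(inst, exclude)
    inst
  }
  mv <- tryCatch(
    mvmr_harmonize(
      list(sel(exposure), sel(mediator)),
      list(exposure, mediator), outcome,
      ld = ld, r2_max = r2_max, window_kb = window_kb
    ),
    error = function(e) {
      stop("insufficient instruments at stage MVMR: ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  est_mv <- mvmr_ivw(mv)
  beta_zy <- est_mv$beta[est_mv$exposure == mediator$trait_name]

  med <- mediation_decompose(est_total$beta, est_xz$beta, beta_zy)
  reports <- NULL
  if (sensitivity) {
    reports <- list(
      total = sensitivity_report(h_total, n_sim = n_sim, seed = seed),
      xz = sensitivity_report(h_xz, n_sim = n_sim, seed = seed + 1)
    )
  }
  structure(
    list(
      mediation = med,
      estimate_total = est_total, estimate_xz = est_xz,
      mvmr_estimates = est_mv, mv_harmonized = mv,
      harmonized_total = h_total, harmonized_xz = h_xz,
      sensitivity = reports
    ),
    class = "two_step_result"
  )
}
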