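#' Construct an instrument set
#'
#' Ordered collection of exposure-side variant associations surviving the
#' selection pipeline, together with a per-step count log.
#'
#' @param exposure_name Exposure label.
#' @param members Data frame of canonical summary-statistic records.
#' @param selection_log Named integer vector of per-step counts.
#' @export
instrument_set <- function(exposure_name, members,
                           selection_log = c(initial = nrow(members))) {
  structure(
    list(
      exposure_name = exposure_name, members = members,
      selection_log = selection_log
    ),
    class = "instrument_set"
  )
}

#' Treat every record of a summary-statistics set as an instrument
#' @param stats A [summary_stats()] object.
#' @export
as_instrument_set <- function(stats) {
  stopifnot(inherits(stats, "summary_stats"))
  instrument_set(stats$trait_name, stats$records)
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf(
    "Instrument set for %s: %d SNPs\n", x$exposure_name, nrow(x$members)
  ))
  log <- x$selection_log
  cat(paste0("  ", names(log), " = ", log, collapse = "\n"), "\n")
  invisible(x)
}

.log_step <- function(inst, step, count) {
  inst$selection_log <- c(inst$selection_log, stats::setNames(count, step))
  inst
}

#' Select instruments by association p-value
#'
#' Retains variants with `pvalue` strictly below the threshold (a variant at
#' exactly the threshold is excluded). An empty result is not an error; the
#' orchestration layer records such exposures as skipped.
#'
#' @param stats A [summary_stats()] object.
#' @param threshold Significance threshold in (0, 1); the locus-wide default
#'   is `1e-5`, the genome-wide cutoff `5e-8`.
#' @return An [instrument_set()].
#' @export
select_by_pvalue <- function(stats, threshold = 1e-5) {
  stopifnot(inherits(stats, "summary_stats"))
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  keep <- stats$records$pvalue < threshold
  inst <- instrument_set(stats$trait_name, stats$records[keep, , drop = FALSE])
  inst$selection_log <- c(
    initial = nrow(stats$records),
    post_threshold = sum(keep)
  )
  inst
}

#' Greedy LD clumping
#'
#' Iteratively takes the remaining variant with the smallest p-value as the
#' index SNP and removes every other variant on the same chromosome within
#' `window_kb` of it whose pairwise r-squared with the index exceeds
#' `r2_max`. Pairs absent from the LD table are treated as unlinked (r2 = 0)
#' and kept. Ties on p are broken by (chrom, pos, variant_id), so the result
#' does not depend on input row order.
#'
#' @param inst An [instrument_set()] whose members carry `chrom`/`pos`.
#' @param ld An [ld_table()] or `NULL` (no linkage anywhere).
#' @param r2_max r-squared threshold (default 0.001).
#' @param window_kb Window half-width in kb around the index SNP (default
#'   10000, i.e. +/- 10 Mb).
#' @return The clumped [instrument_set()].
#' @export
clump <- function(inst, ld = NULL, r2_max = 0.001, window_kb = 10000) {
  stopifnot(inherits(inst, "instrument_set"))
  m <- inst$members
  if (nrow(m) <= 1) {
    return(.log_step(inst, "post_clump", nrow(m)))
  }
  ord <- order(m$pvalue, m$chrom, m$pos, m$variant_id)
  m <- m[ord, , drop = FALSE]
  window_bp <- window_kb * 1000
  alive <- rep(TRUE, nrow(m))
  keep <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive & m$chrom == m$chrom[i] &
      abs(m$pos - m$pos[i]) <= window_bp)
    if (length(cand) > 0) {
      r2 <- ld_lookup(ld, m$variant_id[i], m$variant_id[cand])
      alive[cand[r2 > r2_max]] <- FALSE
    }
  }
  out <- m[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$variant_id), , drop = FALSE]
  inst$members <- out
  .log_step(inst, "post_clump", nrow(out))
}

#' Instrument-strength F statistic
#'
#' `F = R2 (n - 1 - k) / ((1 - R2) k)` with `R2` the variance in the exposure
#' explained by the `k` instruments and `n` the GWAS sample size. Values
#' below 10 flag weak instruments.
#'
#' @param r2_total Explained variance, in \[0, 1).
#' @param n Sample size (must exceed `k + 1`).
#' @param k Number of instruments (>= 1).
#' @return An `fstat_report` list with `r2_total`, `n`, `k`, `f_value` and
#'   logical `weak`.
#' @export
f_statistic <- function(r2_total, n, k) {
  if (r2_total < 0 || r2_total >= 1) {
    stop("r2_total must lie in [0, 1)", call. = FALSE)
  }
  if (k < 1 || n <= k + 1) stop("need n > k + 1 >= 2", call. = FALSE)
  f <- r2_total * (n - 1 - k) / ((1 - r2_total) * k)
  structure(
    list(r2_total = r2_total, n = n, k = k, f_value = f, weak = f < 10),
    class = "fstat_report"
  )
}

#' Per-SNP explained variance
#'
#' Default is the z-score approximation `r2 = z^2 / (z^2 + n - 2)` with
#' `z = beta/se`, which needs neither allele frequency nor phenotype
#' variance. With `method = "eaf"` (standardized continuous traits only) the
#' alternative `2 p (1-p) beta^2` is used instead.
#'
#' @param beta,se Effect and standard error (se > 0).
#' @param n Sample size (> 2).
#' @param eaf Effect-allele frequency (required for `method = "eaf"`).
#' @param method `"z"` (default) or `"eaf"`.
#' @export
snp_r2 <- function(beta, se, n, eaf = NA, method = c("z", "eaf")) {
  method <- match.arg(method)
  stopifnot(all(se > 0), all(n > 2))
  if (method == "z") {
    z2 <- (beta / se)^2
    z2 / (z2 + n - 2)
  } else {
    if (any(is.na(eaf))) stop("eaf required for method = 'eaf'", call. = FALSE)
    2 * eaf * (1 - eaf) * beta^2
  }
}

#' Drop instruments weaker than F = 10
#'
#' Computes a per-SNP F statistic (`k = 1`) from each variant's own explained
#' variance and removes those with `F < 10`; also attaches the set-level
#' F-statistic report (k = set size, R2 summed over retained instruments).
#'
#' @param inst An [instrument_set()].
#' @param min_f Weak-instrument cutoff (default 10).
#' @param r2_method Passed to [snp_r2()].
#' @return The filtered [instrument_set()] with an `fstat` element.
#' @export
drop_weak_instruments <- function(inst, min_f = 10, r2_method = "z") {
  stopifnot(inherits(inst, "instrument_set"))
  m <- inst$members
  if (nrow(m) == 0) {
    inst <- .log_step(inst, "post_f", 0L)
    inst$fstat <- NULL
    return(inst)
  }
  r2 <- snp_r2(m$beta, m$se, m$n, m$eaf, method = r2_method)
  f_snp <- r2 * (m$n - 2) / (1 - r2)
  keep <- f_snp >= min_f
  inst$members <- m[keep, , drop = FALSE]
  inst <- .log_step(inst, "post_f", sum(keep))
  if (sum(keep) > 0) {
    mm <- inst$members
    r2k <- snp_r2(mm$beta, mm$se, mm$n, mm$eaf, method = r2_method)
    r2_total <- min(sum(r2k), 1 - 1e-12)
    n_eff <- round(stats::median(mm$n))
    if (n_eff > nrow(mm) + 1) {
      inst$fstat <- f_statistic(r2_total, n_eff, nrow(mm))
    }
  }
  inst
}

#' Remove instruments more strongly associated with the outcome
#'
#' Drops SNP j iff its outcome p-value is strictly smaller than its exposure
#' p-value. SNPs absent from the outcome set pass through unchanged.
#'
#' @param inst An [instrument_set()].
#' @param outcome A [summary_stats()] object.
#' @export
drop_outcome_associated <- function(inst, outcome) {
  stopifnot(inherits(inst, "instrument_set"), inherits(outcome, "summary_stats"))
  m <- inst$members
  idx <- match(m$variant_id, outcome$records$variant_id)
  p_out <- outcome$records$pvalue[idx]
  drop <- !is.na(p_out) & p_out < m$pvalue
  inst$members <- m[!drop, , drop = FALSE]
  .log_step(inst, "post_outcome_filter", sum(!drop))
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) COMPLEMENT[a1] == a2

#' Harmonize exposure instruments with outcome summary statistics
#'
#' Aligns the outcome effect to the exposure's effect allele for every
#' instrument. Palindromic SNPs (A/T or G/C pairs) are dropped outright, as
#' their strand cannot be resolved without frequency inference. SNPs absent
#' from the outcome set are dropped. If the outcome's effect allele matches
#' the exposure's other allele (directly or after strand complement), the
#' outcome beta sign is flipped and the effect-allele frequency complemented;
#' allele sets irreconcilable even after complement are dropped.
#'
#' Harmonizing an already-aligned pair is a no-op on the retained SNPs.
#'
#' @param inst An [instrument_set()].
#' @param outcome A [summary_stats()] object.
#' @param outcome_name Optional outcome label (defaults to the trait name).
#' @return An object of class `harmonized_set`: per retained SNP the aligned
#'   `beta_x`, `se_x`, `beta_y`, `se_y`, plus `k`. `k = 0` signals an empty
#'   harmonized set (the pipeline skips such pairs).
#' @export
harmonize <- function(inst, outcome, outcome_name = outcome$trait_name) {
  stopifnot(inherits(inst, "instrument_set"), inherits(outcome, "summary_stats"))
  m <- inst$members
  o <- outcome$records
  idx <- match(m$variant_id, o$variant_id)
  present <- !is.na(idx)
  m <- m[present, , drop = FALSE]
  idx <- idx[present]
  n_dropped_missing <- sum(!present)

  pal <- nrow(m) > 0 & is_palindromic(m$effect_allele, m$other_allele)
  n_dropped_pal <- sum(pal)
  m <- m[!pal, , drop = FALSE]
  idx <- idx[!pal]

  o_ea <- o$effect_allele[idx]
  o_oa <- o$other_allele[idx]
  same <- o_ea == m$effect_allele & o_oa == m$other_allele
  swap <- o_ea == m$other_allele & o_oa == m$effect_allele
  comp_same <- COMPLEMENT[o_ea] == m$effect_allele &
    COMPLEMENT[o_oa] == m$other_allele
  comp_swap <- COMPLEMENT[o_ea] == m$other_allele &
    COMPLEMENT[o_oa] == m$effect_allele
  keep <- same | swap | comp_same | comp_swap
  flip <- (swap | comp_swap) & !same & !comp_same
  n_dropped_mismatch <- sum(!keep)

  m <- m[keep, , drop = FALSE]
  idx <- idx[keep]
  flip <- flip[keep]
  sgn <- ifelse(flip, -1, 1)

  h <- data.frame(
    variant_id = m$variant_id, chrom = m$chrom, pos = m$pos,
    effect_allele = m$effect_allele, other_allele = m$other_allele,
    beta_x = m$beta, se_x = m$se, pvalue_x = m$pvalue, n_x = m$n,
    eaf_x = m$eaf,
    beta_y = sgn * o$beta[idx], se_y = o$se[idx],
    pvalue_y = o$pvalue[idx], n_y = o$n[idx],
    eaf_y = ifelse(flip, 1 - o$eaf[idx], o$eaf[idx]),
    stringsAsFactors = FALSE
  )
  log <- c(inst$selection_log, post_palindrome = nrow(h))
  structure(
    list(
      exposure_name = inst$exposure_name, outcome_name = outcome_name,
      snps = h, k = nrow(h), selection_log = log,
      dropped = c(
        missing_from_outcome = n_dropped_missing,
        palindromic = n_dropped_pal, allele_mismatch = n_dropped_mismatch
      )
    ),
    class = "harmonized_set"
  )
}

#' Build a harmonized set directly from aligned effect vectors
#'
#' Convenience constructor for simulation studies and tests where the
#' exposure and outcome effects are already on a common effect allele.
#'
#' @param beta_x,se_x,beta_y,se_y Aligned per-SNP effects and SEs.
#' @param variant_id Optional ids (defaults to snp1, snp2, ...).
#' @param exposure_name,outcome_name Labels.
#' @export
harmonized_set <- function(beta_x, se_x, beta_y, se_y,
                           variant_id = sprintf("snp%d", seq_along(beta_x)),
                           exposure_name = "exposure",
                           outcome_name = "outcome") {
  stopifnot(
    length(beta_x) == length(se_x), length(beta_x) == length(beta_y),
    length(beta_x) == length(se_y), all(se_x > 0), all(se_y > 0)
  )
  h <- data.frame(
    variant_id = variant_id, beta_x = beta_x, se_x = se_x,
    beta_y = beta_y, se_y = se_y, stringsAsFactors = FALSE
  )
  structure(
    list(
      exposure_name = exposure_name, outcome_name = outcome_name,
      snps = h, k = nrow(h),
      selection_log = c(initial = nrow(h)), dropped = c()
    ),
    class = "harmonized_set"
  )
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf(
    "Harmonized set %s -> %s: k = %d SNPs\n",
    x$exposure_name, x$outcome_name, x$k
  ))
  invisible(x)
}

#' Subset a harmonized set by SNP index or id
#' @param h A `harmonized_set`.
#' @param keep Logical/integer index or character ids to retain.
#' @export
subset_harmonized <- function(h, keep) {
  stopifnot(inherits(h, "harmonized_set"))
  if (is.character(keep)) keep <- h$snps$variant_id %in% keep
  h$snps <- h$snps[keep, , drop = FALSE]
  h$k <- nrow(h$snps)
  h
}

#' Remove named variants (confounder-associated SNP exclusion)
#'
#' Applies a user-supplied exclusion list — the stand-in for a confounder
#' lookup — to an instrument set or a harmonized set. Ids not present are
#' ignored.
#'
#' @param x An [instrument_set()] or `harmonized_set`.
#' @param excluded_ids Character vector of variant ids to remove.
#' @export
apply_exclusion_list <- function(x, excluded_ids) {
  UseMethod("apply_exclusion_list")
}

#' @export
apply_exclusion_list.instrument_set <- function(x, excluded_ids) {
  keep <- !(x$members$variant_id %in% excluded_ids)
  x$members <- x$members[keep, , drop = FALSE]
  .log_step(x, "post_exclusion", sum(keep))
}

#' @export
apply_exclusion_list.harmonized_set <- function(x, excluded_ids) {
  keep <- !(x$snps$variant_id %in% excluded_ids)
  x$snps <- x$snps[keep, , drop = FALSE]
  x$k <- nrow(x$snps)
  x$selection_log <- c(x$selection_log, post_exclusion = x$k)
  x
}

#' Full instrument-selection and harmonization pipeline
#'
#' Runs the fixed selection order: p-value threshold, LD clumping, per-SNP
#' F >= 10 filter, outcome-association filter (P_outcome < P_exposure),
#' harmonization with palindrome exclusion, then the confounder exclusion
#' list. Selection-log counts are non-increasing along these steps.
#'
#' @param exposure,outcome [summary_stats()] objects.
#' @param p_threshold Instrument significance threshold (default 1e-5).
#' @param ld Optional [ld_table()].
#' @param exclude Optional character vector of variant ids to remove last.
#' @param r2_max,window_kb Clumping parameters.
#' @param min_f Weak-instrument cutoff.
#' @param r2_method Per-SNP R2 formula, see [snp_r2()].
#' @return A `harmonized_set` (possibly with `k = 0`).
#' @export
select_instruments <- function(exposure, outcome, p_threshold = 1e-5,
                               ld = NULL, exclude = NULL,
                               r2_max = 0.001, window_kb = 10000,
                               min_f = 10, r2_method = "z") {
  inst <- select_by_pvalue(exposure, p_threshold)
  inst <- clump(inst, ld, r2_max = r2_max, window_kb = window_kb)
  inst <- drop_weak_instruments(inst, min_f = min_f, r2_method = r2_method)
  inst <- drop_outcome_associated(inst, outcome)
  h <- harmonize(inst, outcome)
  if (!is.null(exclude)) h <- apply_exclusion_list(h, exclude)
  h
}
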