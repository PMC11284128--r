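# Orchestration of the full study design: forward screen, reverse MR,
# strict-threshold rerun, replication meta-analysis, report rendering.

# FNV-1a hash of a string, hex-encoded; used for config fingerprints so a
# report manifest changes iff the configuration changes.
.fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    # xor with the byte touches only the low 8 bits
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit multiply by the FNV prime 16777619 without exceeding 2^53:
    # split h into 16-bit halves so every partial product stays exact
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Study configuration
#'
#' Bundles the selection and analysis parameters shared by the screening
#' functions. All randomness flows from `seed`.
#'
#' @param p_threshold Primary instrument threshold (default 1e-5).
#' @param p_threshold_strict Genome-wide threshold (default 5e-8).
#' @param r2_max,window_kb LD-clumping parameters.
#' @param min_f Weak-instrument cutoff.
#' @param exclude Character vector of confounder-associated variant ids.
#' @param n_sim MR-PRESSO simulation count.
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param seed Integer master seed.
#' @export
study_config <- function(p_threshold = 1e-5, p_threshold_strict = 5e-8,
                         r2_max = 0.001, window_kb = 10000, min_f = 10,
                         exclude = NULL, n_sim = 1000, n_boot = 1000,
                         seed = 1) {
  stopifnot(
    p_threshold > 0, p_threshold < 1,
    p_threshold_strict > 0, p_threshold_strict < 1
  )
  structure(
    list(
      p_threshold = p_threshold, p_threshold_strict = p_threshold_strict,
      r2_max = r2_max, window_kb = window_kb, min_f = min_f,
      exclude = exclude, n_sim = n_sim, n_boot = n_boot, seed = seed
    ),
    class = "study_config"
  )
}

# One exposure-outcome pair: selection, estimation, sensitivity, gate.
.screen_pair <- function(exposure, outcome, cfg, ld, pair_seed, p_threshold) {
  h <- select_instruments(exposure, outcome,
    p_threshold = p_threshold, ld = ld,
    exclude = cfg$exclude, r2_max = cfg$r2_max,
    window_kb = cfg$window_kb, min_f = cfg$min_f
  )
  if (h$k == 0) {
    return(list(status = "skipped", reason = "no_instruments", harmonized = h))
  }
  estimates <- run_all_methods(h, seed = pair_seed, n_boot = cfg$n_boot)
  report <- sensitivity_report(h, n_sim = cfg$n_sim, seed = pair_seed)
  # remove-and-rerun: if PRESSO flagged outliers, all methods are re-run on
  # the reduced set and the gate judges the corrected analysis
  if (length(report$presso_outliers) > 0 &&
    report$presso_harmonized$k >= 1) {
    h <- report$presso_harmonized
    estimates <- run_all_methods(h, seed = pair_seed, n_boot = cfg$n_boot)
  }
  gate <- sensitivity_gate(estimates, report)
  list(
    status = "ok", harmonized = h, estimates = estimates,
    sensitivity = report, gate = gate
  )
}

.screen_row <- function(exposure_name, outcome_name, group, rec) {
  if (rec$status != "ok") {
    return(data.frame(
      exposure = exposure_name, outcome = outcome_name, group = group,
      status = rec$status, k = 0L, beta = NA_real_, se = NA_real_,
      pvalue = NA_real_, or = NA_real_, ci_low = NA_real_,
      ci_high = NA_real_, model_note = NA_character_,
      q_pvalue = NA_real_, egger_intercept_p = NA_real_,
      presso_global_p = NA_real_, n_presso_outliers = NA_integer_,
      verdict = "skipped", stringsAsFactors = FALSE
    ))
  }
  est <- rec$estimates[["ivw"]]
  if (is.null(est)) est <- rec$estimates[["wald_ratio"]]
  data.frame(
    exposure = exposure_name, outcome = outcome_name, group = group,
    status = "ok", k = est$k, beta = est$beta, se = est$se,
    pvalue = est$pvalue, or = est$or_value, ci_low = est$ci_low,
    ci_high = est$ci_high, model_note = rec$gate$model_note,
    q_pvalue = rec$sensitivity$q_pvalue,
    egger_intercept_p = rec$sensitivity$egger_intercept_p,
    presso_global_p = rec$sensitivity$presso_global_p,
    n_presso_outliers = length(rec$sensitivity$presso_outliers),
    verdict = rec$gate$verdict, stringsAsFactors = FALSE
  )
}

#' Forward causal screen over exposure-outcome pairs
#'
#' For every (exposure, outcome) pair: instrument selection, harmonization,
#' all applicable MR methods, the sensitivity suite (including MR-PRESSO
#' remove-and-rerun), the robustness gate, then grouped FDR correction of
#' the IVW p-values within each (group, outcome) family and the
#' significant/potential/none classification. Pairs with empty instrument
#' sets are recorded as skipped; per-pair failures are quarantined and do
#' not abort the screen. Identical inputs and seed give identical output.
#'
#' @param exposures Named list of [summary_stats()] objects.
#' @param outcomes Named list of [summary_stats()] objects.
#' @param cfg A [study_config()].
#' @param ld Optional [ld_table()].
#' @param groups Optional character vector (parallel to `exposures`) of
#'   FDR-family labels, e.g. taxonomic ranks; defaults to one family.
#' @param p_threshold Overrides `cfg$p_threshold` when given.
#' @return A `screen_result`: `table` (one row per pair) and `records`
#'   (full per-pair objects).
#' @export
run_forward_screen <- function(exposures, outcomes, cfg = study_config(),
                               ld = NULL, groups = NULL, p_threshold = NULL) {
  stopifnot(length(exposures) >= 1, length(outcomes) >= 1)
  if (is.null(names(exposures))) {
    names(exposures) <- vapply(exposures, function(e) e$trait_name, "")
  }
  if (is.null(names(outcomes))) {
    names(outcomes) <- vapply(outcomes, function(o) o$trait_name, "")
  }
  if (is.null(groups)) groups <- rep("all", length(exposures))
  if (is.null(p_threshold)) p_threshold <- cfg$p_threshold

  rows <- list()
  records <- list()
  i <- 0L
  for (ei in seq_along(exposures)) {
    for (oi in seq_along(outcomes)) {
      i <- i + 1L
      pair_seed <- cfg$seed + 1000L * ei + oi
      rec <- tryCatch(
        .screen_pair(
          exposures[[ei]], outcomes[[oi]], cfg, ld, pair_seed, p_threshold
        ),
        error = function(e) {
          list(status = "failed", reason = conditionMessage(e))
        }
      )
      key <- paste(names(exposures)[ei], names(outcomes)[oi], sep = " -> ")
      records[[key]] <- rec
      rows[[i]] <- .screen_row(
        names(exposures)[ei], names(outcomes)[oi], groups[ei], rec
      )
    }
  }
  table <- do.call(rbind, rows)
  ok <- table$status == "ok"
  table$p_fdr <- NA_real_
  if (any(ok)) {
    fam <- paste(table$group[ok], table$outcome[ok], sep = ":")
    table$p_fdr[ok] <- bh_adjust(table$pvalue[ok], fam)
  }
  table$call <- ifelse(ok,
    classify_association(table$pvalue, table$p_fdr), "none"
  )
  # the gate vetoes calls it judged not robust
  table$call[ok & table$verdict != "positive"] <- "none"
  structure(
    list(table = table, records = records, config = cfg),
    class = "screen_result"
  )
}

#' Reverse MR screen (outcomes as exposures)
#'
#' Runs the same machinery with roles swapped to probe reverse causation;
#' heterogeneous pairs are reported under multiplicative random effects via
#' the usual auto rule.
#'
#' @inheritParams run_forward_screen
#' @export
run_reverse <- function(exposures, outcomes, cfg = study_config(),
                        ld = NULL, groups = NULL) {
  run_forward_screen(outcomes, exposures, cfg = cfg, ld = ld, groups = groups)
}

#' Forward screen at the genome-wide threshold
#'
#' Re-runs the screen with the strict 5e-8 cutoff. Single-SNP pairs fall
#' back to the Wald ratio; pairs with fewer than three instruments cannot
#' support the heterogeneity and pleiotropy diagnostics and are flagged
#' `unconfirmed`.
#'
#' @inheritParams run_forward_screen
#' @export
run_strict_threshold <- function(exposures, outcomes, cfg = study_config(),
                                 ld = NULL, groups = NULL) {
  res <- run_forward_screen(exposures, outcomes,
    cfg = cfg, ld = ld,
    groups = groups, p_threshold = cfg$p_threshold_strict
  )
  res$table$unconfirmed <- res$table$status == "ok" & res$table$k < 3
  res
}

#' Replication meta-analysis across outcome cohorts
#'
#' For each exposure, computes the IVW estimate against every outcome cohort
#' and pools them by inverse-variance meta-analysis. The fixed-effect model
#' is primary; the DerSimonian-Laird model is reported alongside when the
#' heterogeneity test is suggestive (Q p < 0.1). An exposure retains its
#' causal claim iff the pooled p-value is below 0.05.
#'
#' @param exposures Named list of [summary_stats()] objects.
#' @param outcome_cohorts Named list of [summary_stats()] objects for the
#'   same phenotype measured in different cohorts (>= 2).
#' @param cfg A [study_config()].
#' @param ld Optional [ld_table()].
#' @return Data frame with one row per exposure: pooled estimate, I2,
#'   heterogeneity p, DL estimate where computed, and `retained`.
#' @export
run_replication_meta <- function(exposures, outcome_cohorts,
                                 cfg = study_config(), ld = NULL) {
  stopifnot(length(outcome_cohorts) >= 2)
  if (is.null(names(exposures))) {
    names(exposures) <- vapply(exposures, function(e) e$trait_name, "")
  }
  rows <- lapply(names(exposures), function(en) {
    ests <- lapply(outcome_cohorts, function(oc) {
      h <- select_instruments(exposures[[en]], oc,
        p_threshold = cfg$p_threshold, ld = ld, exclude = cfg$exclude,
        r2_max = cfg$r2_max, window_kb = cfg$window_kb, min_f = cfg$min_f
      )
      if (h$k == 0) {
        return(NULL)
      }
      ivw(h, model = "auto")
    })
    ests <- ests[!vapply(ests, is.null, TRUE)]
    if (length(ests) < 2) {
      return(data.frame(
        exposure = en, n_cohorts = length(ests), pooled_beta = NA_real_,
        pooled_se = NA_real_, pooled_p = NA_real_, i_squared = NA_real_,
        q_pvalue = NA_real_, dl_beta = NA_real_, dl_p = NA_real_,
        retained = FALSE, stringsAsFactors = FALSE
      ))
    }
    b <- vapply(ests, function(e) e$beta, numeric(1))
    s <- vapply(ests, function(e) e$se, numeric(1))
    mr <- meta_combine(b, s, model = "fixed")
    dl <- if (!is.na(mr$q_pvalue) && mr$q_pvalue < 0.1) {
      meta_combine(b, s, model = "dersimonian_laird")
    } else {
      NULL
    }
    data.frame(
      exposure = en, n_cohorts = length(ests),
      pooled_beta = mr$pooled_beta, pooled_se = mr$pooled_se,
      pooled_p = mr$pooled_p, i_squared = mr$i_squared,
      q_pvalue = mr$q_pvalue,
      dl_beta = if (is.null(dl)) NA_real_ else dl$pooled_beta,
      dl_p = if (is.null(dl)) NA_real_ else dl$pooled_p,
      retained = mr$pooled_p < 0.05, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write a report bundle (stage tables + reproducibility manifest)
#'
#' Writes each named data frame as a tab-separated file `<name>.tsv` under
#' `dir` (an empty frame yields a header-only file) plus `manifest.json`
#' with a configuration fingerprint, the master seed and package version.
#' The fingerprint changes iff the configuration changes, so identical runs
#' produce byte-identical bundles.
#'
#' @param tables Named list of data frames.
#' @param dir Output directory (created if needed).
#' @param cfg The [study_config()] used (optional but recommended).
#' @return Paths of the files written, invisibly.
#' @export
render_report <- function(tables, dir, cfg = NULL) {
  stopifnot(is.list(tables))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (length(tables) > 0 && is.null(names(tables))) {
    names(tables) <- sprintf("table%d", seq_along(tables))
  }
  paths <- character()
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], p,
      sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = TRUE
    )
    paths <- c(paths, p)
  }
  cfg_json <- jsonlite::toJSON(
    if (is.null(cfg)) list() else unclass(cfg),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  manifest <- list(
    config = if (is.null(cfg)) NULL else unclass(cfg),
    config_hash = .fnv1a(as.character(cfg_json)),
    seed = if (is.null(cfg)) NULL else cfg$seed,
    tables = as.list(names(tables)),
    package_version = as.character(utils::packageVersion("chainMR"))
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp,
    auto_unbox = TRUE, digits = NA,
    pretty = TRUE, null = "null"
  )
  invisible(c(paths, mp))
}
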