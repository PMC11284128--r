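#' @keywords internal
"_PACKAGE"

# Canonical column set for the fixed summary-statistics dialect.
SUMSTATS_COLS <- c(
  "variant_id", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pvalue", "n"
)

VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a summary-statistics object
#'
#' One trait's per-variant GWAS association records plus trait metadata.
#' Records are validated on construction; an invalid record set never yields
#' an object.
#'
#' @param trait_name Trait label.
#' @param trait_type `"continuous"` (effects in trait-SD units) or `"binary"`
#'   (effects on the log-odds scale).
#' @param records Data frame with the canonical columns: `variant_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pvalue`, `n`.
#' @return An object of class `summary_stats`.
#' @export
summary_stats <- function(trait_name, trait_type = c("continuous", "binary"),
                          records) {
  trait_type <- match.arg(trait_type)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SUMSTATS_COLS, names(records))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  records <- records[, SUMSTATS_COLS]
  validate_sumstats_records(records)
  structure(
    list(trait_name = trait_name, trait_type = trait_type, records = records),
    class = "summary_stats"
  )
}

# Row-level invariant checks; errors cite 1-based data-row numbers
# (offset arg shifts to file line numbers when called from read_sumstats).
validate_sumstats_records <- function(records, line_offset = 0L) {
  loc <- function(i) paste(i + line_offset, collapse = ", ")
  dup <- records$variant_id[duplicated(records$variant_id)]
  if (length(dup) > 0) {
    stop("duplicate variant_id: ", paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(records) == 0) {
    return(invisible(TRUE))
  }
  bad <- which(!(records$effect_allele %in% VALID_ALLELES) |
    !(records$other_allele %in% VALID_ALLELES))
  if (length(bad) > 0) {
    stop("alleles must be single uppercase bases A/C/G/T (biallelic SNPs ",
      "only); offending row(s): ", loc(bad),
      call. = FALSE
    )
  }
  bad <- which(records$effect_allele == records$other_allele)
  if (length(bad) > 0) {
    stop("effect_allele equals other_allele on row(s): ", loc(bad),
      call. = FALSE
    )
  }
  bad <- which(!is.finite(records$pos) | records$pos < 1 |
    records$pos != floor(records$pos))
  if (length(bad) > 0) {
    stop("pos must be a positive 1-based integer; row(s): ", loc(bad),
      call. = FALSE
    )
  }
  bad <- which(!is.finite(records$se) | records$se <= 0)
  if (length(bad) > 0) {
    stop("se must be strictly positive; row(s): ", loc(bad), call. = FALSE)
  }
  bad <- which(!is.finite(records$pvalue) | records$pvalue <= 0 |
    records$pvalue > 1)
  if (length(bad) > 0) {
    stop("pvalue must lie in (0, 1]; row(s): ", loc(bad), call. = FALSE)
  }
  bad <- which(!is.finite(records$n) | records$n < 2)
  if (length(bad) > 0) {
    stop("n must be >= 2; row(s): ", loc(bad), call. = FALSE)
  }
  bad <- which(!is.na(records$eaf) & (records$eaf <= 0 | records$eaf >= 1))
  if (length(bad) > 0) {
    stop("eaf must lie in (0, 1) or be NA; row(s): ", loc(bad), call. = FALSE)
  }
  bad <- which(!is.finite(records$beta))
  if (length(bad) > 0) {
    stop("beta must be finite; row(s): ", loc(bad), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf(
    "GWAS summary statistics: %s (%s), %d variants\n",
    x$trait_name, x$trait_type, nrow(x$records)
  ))
  invisible(x)
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' The file must carry a header naming the ten canonical columns
#' (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `pvalue`, `n`) in any order; `eaf` may be `NA`. Rows
#' violating the record invariants abort the read with the offending file
#' line number — no partially valid object is returned.
#'
#' @param path File path.
#' @param trait_name Trait label for the resulting object.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param quiet Suppress the record-count message.
#' @return A [summary_stats()] object.
#' @export
read_sumstats <- function(path, trait_name,
                          trait_type = c("continuous", "binary"),
                          quiet = TRUE) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path,
    header = TRUE, sep = "\t",
    colClasses = "character", check.names = FALSE
  )
  missing_cols <- setdiff(SUMSTATS_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("format error in ", path, ": missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  df <- df[, SUMSTATS_COLS]
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  # header occupies line 1, so data row i sits on file line i + 1
  validate_sumstats_records(df, line_offset = 1L)
  out <- summary_stats(trait_name, trait_type, df)
  if (!quiet) {
    message(sprintf("read %d records for %s from %s", nrow(df), trait_name, path))
  }
  out
}

#' Write GWAS summary statistics to a tab-separated file
#'
#' Numeric fields are serialized with 17 significant digits so that
#' `read_sumstats(write_sumstats(s))` reproduces `s` bit-identically.
#'
#' @param stats A [summary_stats()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  stopifnot(inherits(stats, "summary_stats"))
  df <- stats$records
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  out <- data.frame(
    variant_id = df$variant_id, chrom = as.character(df$chrom),
    pos = sprintf("%d", as.integer(df$pos)),
    effect_allele = df$effect_allele, other_allele = df$other_allele,
    eaf = fmt(df$eaf), beta = fmt(df$beta), se = fmt(df$se),
    pvalue = fmt(df$pvalue), n = fmt(df$n),
    stringsAsFactors = FALSE
  )
  ok <- tryCatch(
    {
      utils::write.table(out, path,
        sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = TRUE
      )
      TRUE
    },
    error = function(e) {
      stop("cannot write ", path, ": ", conditionMessage(e), call. = FALSE)
    }
  )
  invisible(path)
}

#' Construct a pairwise LD table
#'
#' Holds r-squared values for unordered variant pairs; a pair absent from the
#' table is treated as r-squared 0 (unlinked).
#'
#' @param id1,id2 Character vectors of variant ids.
#' @param r2 Numeric vector of r-squared values in \[0, 1\].
#' @return An object of class `ld_table`.
#' @export
ld_table <- function(id1 = character(), id2 = character(), r2 = numeric()) {
  stopifnot(length(id1) == length(id2), length(id1) == length(r2))
  if (any(!is.finite(r2) | r2 < 0 | r2 > 1)) {
    stop("r2 must lie in [0, 1]", call. = FALSE)
  }
  key <- paste(pmin(id1, id2), pmax(id1, id2), sep = "\r")
  structure(list(r2 = stats::setNames(r2, key)), class = "ld_table")
}

#' Read a three-column LD table (id1, id2, r2), tab-separated with header
#' @param path File path.
#' @return An [ld_table()].
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  if (ncol(df) < 3) stop("LD table needs columns id1, id2, r2", call. = FALSE)
  ld_table(as.character(df[[1]]), as.character(df[[2]]), as.numeric(df[[3]]))
}

#' Look up pairwise r-squared values
#'
#' Symmetric in its arguments; unknown pairs return 0.
#'
#' @param ld An [ld_table()] (or `NULL`, meaning all pairs unlinked).
#' @param a,b Variant-id vectors (recycled to common length).
#' @export
ld_lookup <- function(ld, a, b) {
  if (is.null(ld)) {
    return(rep(0, max(length(a), length(b))))
  }
  stopifnot(inherits(ld, "ld_table"))
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  out <- unname(ld$r2[key])
  out[is.na(out)] <- 0
  out
}

#' Write an LD table to a tab-separated file
#' @param ld An [ld_table()].
#' @param path Output path.
#' @export
write_ld_table <- function(ld, path) {
  stopifnot(inherits(ld, "ld_table"))
  parts <- strsplit(names(ld$r2), "\r", fixed = TRUE)
  df <- data.frame(
    id1 = vapply(parts, `[`, "", 1),
    id2 = vapply(parts, `[`, "", 2),
    r2 = sprintf("%.17g", unname(ld$r2)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}
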