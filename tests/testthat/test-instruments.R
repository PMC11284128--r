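test_that("p-value selection uses a strict threshold", {
  rec <- make_records(2, pvalue = c(1e-6, 1e-4))
  s <- summary_stats("x", "continuous", rec)
  inst <- select_by_pvalue(s, 1e-5)
  expect_equal(nrow(inst$members), 1L)
  expect_equal(inst$members$variant_id, "rs1")

  # a p-value exactly at the threshold is excluded
  rec2 <- make_records(1, pvalue = 1e-5)
  inst2 <- select_by_pvalue(summary_stats("x", "continuous", rec2), 1e-5)
  expect_equal(nrow(inst2$members), 0L)
  expect_error(select_by_pvalue(s, 0), "threshold")
})

test_that("selection matches a brute-force filter on a simulated exposure", {
  sim <- simulate_chain(chain_sim_config(
    n_snps = 500, n_snps_mediator = 0,
    n_exposure = 50000, seed = 31
  ))
  inst <- select_by_pvalue(sim$exposure, 5e-8)
  oracle <- sim$exposure$records$variant_id[sim$exposure$records$pvalue < 5e-8]
  expect_setequal(inst$members$variant_id, oracle)
  expect_gt(length(oracle), 0)
})

test_that("clumping keeps the best SNP and respects the window", {
  df <- make_records(2, pos = c(1e6, 6e6), pvalue = c(1e-8, 1e-6))
  inst <- instrument_set("x", df)
  ld <- ld_table("rs1", "rs2", 0.5)
  out <- clump(inst, ld)
  expect_equal(out$members$variant_id, "rs1")

  # outside the 10 Mb window both survive despite high r2
  df2 <- make_records(2, pos = c(1e6, 21.5e6), pvalue = c(1e-8, 1e-6))
  out2 <- clump(instrument_set("x", df2), ld_table("rs1", "rs2", 0.9))
  expect_setequal(out2$members$variant_id, c("rs1", "rs2"))

  # missing LD entries are treated as unlinked
  out3 <- clump(instrument_set("x", df), NULL)
  expect_equal(nrow(out3$members), 2L)
})

test_that("clumping equals the brute-force greedy oracle on LD blocks", {
  for (s in 1:5) {
    sim <- simulate_chain(chain_sim_config(
      n_snps = 40, n_snps_mediator = 0, ld_block_size = 5, ld_r2 = 0.3,
      palindrome_frac = 0, seed = 50 + s
    ))
    rec <- sim$exposure$records
    parts <- strsplit(names(sim$ld$r2), "\r", fixed = TRUE)
    ld_df <- data.frame(
      id1 = vapply(parts, `[`, "", 1), id2 = vapply(parts, `[`, "", 2),
      r2 = unname(sim$ld$r2), stringsAsFactors = FALSE
    )
    got <- clump(as_instrument_set(sim$exposure), sim$ld, r2_max = 0.2)
    expect_identical(
      sort(got$members$variant_id),
      oracle_clump(rec, ld_df, r2_max = 0.2)
    )
  }
})

test_that("clumping is invariant to input row order", {
  sim <- simulate_chain(chain_sim_config(
    n_snps = 30, n_snps_mediator = 0,
    ld_block_size = 3, ld_r2 = 0.4, palindrome_frac = 0, seed = 77
  ))
  rec <- sim$exposure$records
  a <- clump(instrument_set("x", rec), sim$ld, r2_max = 0.2)
  set.seed(1)
  b <- clump(
    instrument_set("x", rec[sample(nrow(rec)), ]), sim$ld,
    r2_max = 0.2
  )
  expect_identical(a$members$variant_id, b$members$variant_id)
})

test_that("the F statistic reproduces its defining formula", {
  r <- f_statistic(0, 1000, 5)
  expect_equal(r$f_value, 0)
  expect_true(r$weak)
  r2 <- f_statistic(0.02, 1000, 5)
  expect_equal(r2$f_value, 0.02 * 994 / (0.98 * 5), tolerance = 1e-12)
  expect_true(r2$weak)
  r3 <- f_statistic(0.05, 5000, 10)
  expect_equal(r3$f_value, 0.05 * 4989 / (0.95 * 10), tolerance = 1e-12)
  expect_false(r3$weak)
  expect_error(f_statistic(1, 100, 2), "r2_total")
  expect_error(f_statistic(0.1, 3, 2), "n > k")
})

test_that("per-SNP explained variance follows the z-based approximation", {
  expect_equal(snp_r2(0, 0.1, 1000), 0)
  expect_equal(snp_r2(0.05, 0.01, 10000), 25 / 10023, tolerance = 1e-12)
  expect_equal(snp_r2(0.2, 0.05, 500, eaf = 0.3, method = "eaf"),
    2 * 0.3 * 0.7 * 0.04,
    tolerance = 1e-12
  )
  # summed r2 over an instrument set matches direct recomputation
  sim <- simulate_chain(chain_sim_config(n_snps = 50, seed = 13))
  inst <- select_by_pvalue(sim$exposure, 1e-5)
  m <- inst$members
  z2 <- (m$beta / m$se)^2
  expect_equal(
    sum(snp_r2(m$beta, m$se, m$n)), sum(z2 / (z2 + m$n - 2)),
    tolerance = 1e-12
  )
})

test_that("weak instruments are excluded per SNP at F < 10", {
  rec <- make_records(3)
  rec$beta <- c(0.2, 0.001, 0.15)
  rec$se <- c(0.01, 0.01, 0.01)
  rec$n <- rep(5000, 3)
  inst <- drop_weak_instruments(instrument_set("x", rec))
  expect_setequal(inst$members$variant_id, c("rs1", "rs3"))
  z2 <- (0.001 / 0.01)^2
  r2 <- z2 / (z2 + 4998)
  expect_lt(r2 * 4998 / (1 - r2), 10)
})

test_that("outcome-association filter removes P_outcome < P_exposure strictly", {
  rec <- make_records(3, pvalue = c(1e-6, 1e-6, 1e-6))
  inst <- instrument_set("x", rec)
  out_rec <- rec
  out_rec$pvalue <- c(1e-8, 0.3, 1e-6) # smaller, larger, tie
  outcome <- summary_stats("y", "binary", out_rec)
  kept <- drop_outcome_associated(inst, outcome)
  expect_setequal(kept$members$variant_id, c("rs2", "rs3"))
  # SNPs missing from the outcome pass through
  outcome2 <- summary_stats("y", "binary", out_rec[1, , drop = FALSE])
  kept2 <- drop_outcome_associated(inst, outcome2)
  expect_setequal(kept2$members$variant_id, c("rs2", "rs3"))
})

test_that("harmonization aligns, flips, complements and drops palindromes", {
  exp_rec <- make_records(3)
  exp_rec$effect_allele <- c("A", "A", "A")
  exp_rec$other_allele <- c("G", "T", "G")
  exp_rec$beta <- c(0.10, 0.10, 0.10)
  out_rec <- exp_rec
  # rs1: swapped alleles -> sign flip; rs2: palindrome -> dropped;
  # rs3: strand complement (A/G seen as T/C) -> aligned without flip
  out_rec$effect_allele <- c("G", "A", "T")
  out_rec$other_allele <- c("A", "T", "C")
  out_rec$beta <- c(-0.05, 0.3, 0.07)
  out_rec$eaf <- c(0.2, 0.5, 0.4)
  h <- harmonize(
    instrument_set("x", exp_rec),
    summary_stats("y", "binary", out_rec)
  )
  expect_equal(h$k, 2L)
  expect_setequal(h$snps$variant_id, c("rs1", "rs3"))
  expect_equal(h$snps$beta_y[h$snps$variant_id == "rs1"], 0.05)
  expect_equal(h$snps$eaf_y[h$snps$variant_id == "rs1"], 0.8)
  expect_equal(h$snps$beta_y[h$snps$variant_id == "rs3"], 0.07)

  # irreconcilable allele sets are dropped (A/G cannot match A/C)
  out_rec2 <- exp_rec[1, , drop = FALSE]
  out_rec2$effect_allele <- "A"
  out_rec2$other_allele <- "C"
  h2 <- harmonize(
    instrument_set("x", exp_rec[1, , drop = FALSE]),
    summary_stats("y", "binary", out_rec2)
  )
  expect_equal(h2$k, 0L)
})

test_that("harmonization is idempotent on an already-aligned pair", {
  sim <- simulate_chain(chain_sim_config(n_snps = 30, seed = 3))
  inst <- select_by_pvalue(sim$exposure, 1e-4)
  h1 <- harmonize(inst, sim$outcome)
  # rebuild the outcome side already expressed on the exposure effect allele
  exp_idx <- match(h1$snps$variant_id, inst$members$variant_id)
  aligned_rec <- inst$members[exp_idx, ]
  aligned_rec$beta <- h1$snps$beta_y
  aligned_rec$se <- h1$snps$se_y
  aligned_rec$pvalue <- h1$snps$pvalue_y
  aligned_rec$n <- h1$snps$n_y
  inst1 <- instrument_set("x", inst$members[exp_idx, ])
  h2 <- harmonize(inst1, summary_stats("y", "binary", aligned_rec))
  expect_equal(h2$k, h1$k)
  expect_identical(h2$snps$beta_y, h1$snps$beta_y)
  expect_identical(h2$snps$beta_x, h1$snps$beta_x)
})

test_that("exclusion lists remove exactly the named SNPs", {
  rec <- make_records(3)
  rec$variant_id <- c("rs10774624", "rs2016057", "rs999")
  inst <- instrument_set("x", rec)
  out <- apply_exclusion_list(inst, "rs10774624")
  expect_setequal(out$members$variant_id, c("rs2016057", "rs999"))
  # empty list is the identity
  expect_identical(
    apply_exclusion_list(inst, character())$members, inst$members
  )
  # absent ids are a no-op
  expect_identical(
    apply_exclusion_list(inst, "rs0")$members, inst$members
  )
})

test_that("the selection pipeline logs non-increasing counts in fixed order", {
  sim <- simulate_chain(chain_sim_config(
    n_snps = 200, n_snps_mediator = 0,
    n_exposure = 50000, palindrome_frac = 0.2, seed = 17
  ))
  h <- select_instruments(sim$exposure, sim$outcome,
    exclude = sim$exposure$records$variant_id[1]
  )
  log <- h$selection_log
  expect_identical(
    names(log),
    c(
      "initial", "post_threshold", "post_clump", "post_f",
      "post_outcome_filter", "post_palindrome", "post_exclusion"
    )
  )
  expect_true(all(diff(as.integer(log)) <= 0))
  expect_equal(unname(log[["post_exclusion"]]), h$k)
})
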