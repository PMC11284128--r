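# Direct construction of an MVMR fixture with known direct effects.
make_mv <- function(k = 30, seed = 1, tau = -0.2, delta = -0.5,
                    se_y = 0.01) {
  set.seed(seed)
  # half the SNPs instrument the exposure, half the mediator
  bx <- c(runif(k / 2, 0.05, 0.2) * sample(c(-1, 1), k / 2, TRUE), rep(0, k / 2))
  bz <- c(0.3 * bx[1:(k / 2)], runif(k / 2, 0.05, 0.2) * sample(c(-1, 1), k / 2, TRUE))
  by <- tau * bx + delta * bz + rnorm(k) * se_y
  mv_harmonized_set(
    cbind(bx, bz), matrix(0.002, k, 2), by, rep(se_y, k),
    exposure_names = c("exposure", "mediator")
  )
}

test_that("multivariable IVW matches the normal-equations oracle to 1e-10", {
  mv <- make_mv(30, seed = 4)
  est <- mvmr_ivw(mv)
  o <- oracle_wls(mv$beta_y, mv$beta_X, 1 / mv$se_y^2, intercept = FALSE)
  expect_equal(est$beta, o$coef, tolerance = 1e-10)
  expect_equal(est$se, o$se, tolerance = 1e-10)
  expect_equal(est$exposure, c("exposure", "mediator"))
})

test_that("multivariable IVW recovers the chain's direct effects", {
  ests <- t(vapply(1:50, function(i) {
    mv <- make_mv(40, seed = 100 + i, tau = 0, delta = -0.5)
    mvmr_ivw(mv)$beta
  }, numeric(2)))
  mcse <- apply(ests, 2, sd) / sqrt(50)
  expect_lt(abs(mean(ests[, 1]) - 0), 3 * mcse[1])
  expect_lt(abs(mean(ests[, 2]) - (-0.5)), 3 * mcse[2])
})

test_that("multivariable IVW reduces to univariable IVW when m = 1", {
  h <- make_h(15, seed = 6, theta = 0.3)
  mv <- mv_harmonized_set(
    matrix(h$snps$beta_x), matrix(h$snps$se_x),
    h$snps$beta_y, h$snps$se_y
  )
  expect_equal(mvmr_ivw(mv)$beta, ivw(h, "fixed")$beta, tolerance = 1e-12)
})

test_that("a degenerate all-zero exposure column nests the univariable fit", {
  h <- make_h(12, seed = 19, theta = 0.4)
  mv <- mv_harmonized_set(
    cbind(h$snps$beta_x, 0), cbind(h$snps$se_x, 0.001),
    h$snps$beta_y, h$snps$se_y,
    exposure_names = c("real", "null")
  )
  est <- suppressWarnings(mvmr_ivw(mv))
  expect_equal(
    est$beta[est$exposure == "real"], ivw(h, "fixed")$beta,
    tolerance = 1e-10
  )
  expect_true(is.na(est$beta[est$exposure == "null"]))
})

test_that("collinear exposures raise an error naming the design", {
  set.seed(3)
  bx <- runif(10, 0.05, 0.2)
  mv <- mv_harmonized_set(
    cbind(bx, 2 * bx), matrix(0.001, 10, 2),
    0.3 * bx + rnorm(10, 0, 0.01), rep(0.01, 10),
    exposure_names = c("a", "b")
  )
  expect_error(mvmr_ivw(mv), "collinearity.*a, b")
})

test_that("multivariable Egger matches its oracle and is orientation invariant", {
  mv <- make_mv(30, seed = 9)
  est <- mvmr_egger(mv)
  flip <- ifelse(mv$beta_X[, 1] < 0, -1, 1)
  o <- oracle_wls(
    mv$beta_y * flip, mv$beta_X * flip, 1 / mv$se_y^2,
    intercept = TRUE
  )
  expect_equal(attr(est, "intercept"), o$coef[1], tolerance = 1e-10)
  expect_equal(est$beta, o$coef[-1], tolerance = 1e-10)

  # flipping a SNP's alleles (negating its row everywhere) changes nothing
  mv2 <- mv
  mv2$beta_X[4, ] <- -mv$beta_X[4, ]
  mv2$beta_y[4] <- -mv$beta_y[4]
  est2 <- mvmr_egger(mv2)
  expect_equal(est2$beta, est$beta, tolerance = 1e-12)
  expect_equal(attr(est2, "intercept"), attr(est, "intercept"),
    tolerance = 1e-12
  )
})

test_that("multivariable Egger intercept is near zero without pleiotropy", {
  ints <- vapply(1:40, function(i) {
    attr(mvmr_egger(make_mv(30, seed = 500 + i)), "intercept")
  }, numeric(1))
  expect_lt(abs(mean(ints)), 3 * sd(ints) / sqrt(40))
})

test_that("multivariable median agrees with IVW on clean data and is seeded", {
  mv <- make_mv(30, seed = 21)
  med <- mvmr_median(mv, n_boot = 100, seed = 21)
  iv <- mvmr_ivw(mv)
  expect_lt(max(abs(med$beta - iv$beta) / med$se), 2)
  med2 <- mvmr_median(mv, n_boot = 100, seed = 21)
  expect_identical(med$se, med2$se)
})

test_that("multivariable median resists contaminated outcome effects", {
  wins <- vapply(1:60, function(i) {
    mv <- make_mv(30, seed = 700 + i, tau = -0.2, delta = -0.5)
    bad <- sample(30, 9) # 30% contamination
    mv$beta_y[bad] <- mv$beta_y[bad] + runif(9, 0.05, 0.15)
    b_med <- chainMR:::.l1_wls(mv$beta_y, mv$beta_X, 1 / mv$se_y^2)
    b_ivw <- mvmr_ivw(mv)$beta
    truth <- c(-0.2, -0.5)
    sum(abs(b_med - truth)) < sum(abs(b_ivw - truth))
  }, logical(1))
  expect_gte(mean(wins), 0.7)
})

test_that("MVMR harmonization unions, clumps jointly and aligns alleles", {
  sim <- simulate_chain(chain_sim_config(
    n_snps = 60, n_snps_mediator = 30, n_exposure = 2e5, n_mediator = 2e5,
    n_outcome = 2e5, palindrome_frac = 0.15, seed = 33
  ))
  sel <- function(s) clump(select_by_pvalue(s, 1e-5))
  i1 <- sel(sim$exposure)
  i2 <- sel(sim$mediator)
  mv <- mvmr_harmonize(
    list(i1, i2), list(sim$exposure, sim$mediator), sim$outcome
  )
  union_ids <- union(i1$members$variant_id, i2$members$variant_id)
  expect_true(all(mv$variant_id %in% union_ids))
  # no palindromic SNP survives
  rec <- sim$exposure$records
  pal <- rec$variant_id[chainMR:::is_palindromic(
    rec$effect_allele, rec$other_allele
  )]
  expect_length(intersect(mv$variant_id, pal), 0)
  expect_gt(mv$k, mv$m)
  # SNP missing from the mediator data is dropped
  med2 <- sim$mediator
  med2$records <- med2$records[-match(mv$variant_id[1], med2$records$variant_id), ]
  mv2 <- mvmr_harmonize(
    list(i1, i2), list(sim$exposure, med2), sim$outcome
  )
  expect_false(mv$variant_id[1] %in% mv2$variant_id)
})

test_that("mediation decomposition reproduces published worked examples", {
  r1 <- mediation_decompose(-1.065, 0.214, -1.046)
  expect_equal(r1$mediated_effect, 0.214 * -1.046, tolerance = 1e-15)
  expect_equal(round(r1$mediated_effect, 3), -0.224)
  expect_equal(round(100 * r1$proportion_mediated, 2), 21.02)
  expect_true(r1$direction_consistent)

  r2 <- mediation_decompose(0.354, -0.091, -0.291)
  expect_equal(round(r2$mediated_effect, 3), 0.026)
  expect_equal(round(100 * r2$proportion_mediated, 2), 7.48)
  expect_true(r2$direction_consistent)

  r0 <- mediation_decompose(0.5, 0, -0.3)
  expect_equal(r0$mediated_effect, 0)
  expect_equal(r0$proportion_mediated, 0)
  expect_false(r0$direction_consistent)
  expect_error(mediation_decompose(0, 0.1, 0.1), "beta_total")
})

test_that("mediation identities hold to machine precision for random inputs", {
  set.seed(42)
  for (i in 1:50) {
    bt <- runif(1, -2, 2)
    if (bt == 0) next
    bxz <- runif(1, -1, 1)
    bzy <- runif(1, -1, 1)
    r <- mediation_decompose(bt, bxz, bzy)
    expect_identical(r$mediated_effect, bxz * bzy)
    expect_identical(r$proportion_mediated, (bxz * bzy) / bt)
    expect_identical(
      r$direction_consistent,
      sign(bxz * bzy) != 0 && sign(bxz * bzy) == sign(bt)
    )
  }
})

test_that("the two-step analysis is deterministic and handles a null chain", {
  cfg <- chain_sim_config(
    n_exposure = 2e5, n_mediator = 2e5, n_outcome = 2e5, seed = 8
  )
  sim <- simulate_chain(cfg)
  a <- run_two_step(sim$exposure, sim$mediator, sim$outcome,
    seed = 5, n_sim = 200
  )
  b <- run_two_step(sim$exposure, sim$mediator, sim$outcome,
    seed = 5, n_sim = 200
  )
  expect_identical(a$mediation, b$mediation)
  expect_identical(a$sensitivity$total$presso_global_p,
    b$sensitivity$total$presso_global_p)
  expect_s3_class(a$mediation, "mediation_result")

  # gamma = 0: nothing flows through the mediator
  cfg0 <- chain_sim_config(
    theta_xz = 0, n_exposure = 5e5, n_mediator = 5e5, n_outcome = 5e5,
    exposure_effect_sd = 0.1, mediator_effect_sd = 0.1, seed = 9
  )
  sim0 <- simulate_chain(cfg0)
  r0 <- run_two_step(sim0$exposure, sim0$mediator, sim0$outcome,
    seed = 5, sensitivity = FALSE
  )
  expect_lt(abs(r0$mediation$proportion_mediated), 0.05)
})
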