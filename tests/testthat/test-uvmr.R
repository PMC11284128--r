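test_that("the Wald ratio follows its defining arithmetic", {
  e <- wald_ratio(0.1, 0.02, 0.2, 0.05)
  expect_equal(e$beta, 2)
  expect_equal(e$se, 0.5)
  expect_equal(e$k, 1L)
  e0 <- wald_ratio(0.1, 0.02, 0, 0.05)
  expect_equal(e0$beta, 0)
  expect_equal(e0$pvalue, 1)
  expect_error(wald_ratio(0, 0.02, 0.2, 0.05), "beta_x")
})

test_that("first-order Wald SE agrees with the second-order delta SE for strong instruments", {
  bx <- 0.2
  se_x <- 0.015 # |bx|/se_x > 10
  by <- 0.1
  se_y <- 0.03
  first <- se_y / abs(bx)
  second <- sqrt(se_y^2 / bx^2 + by^2 * se_x^2 / bx^4)
  expect_lt(abs(second - first) / first, 0.05)
})

test_that("IVW matches the weighted-least-squares oracle to 1e-10", {
  h <- make_h(20, seed = 5, theta = -0.4)
  e <- ivw(h, model = "fixed")
  s <- h$snps
  o <- oracle_wls(s$beta_y, matrix(s$beta_x), 1 / s$se_y^2, intercept = FALSE)
  expect_equal(e$beta, o$coef[1], tolerance = 1e-10)
  # fixed-effect SE has no overdispersion factor
  w <- 1 / s$se_y^2
  expect_equal(e$se, sqrt(1 / sum(w * s$beta_x^2)), tolerance = 1e-12)
})

test_that("IVW equals the precision-weighted mean of per-SNP Wald ratios", {
  h <- make_h(15, seed = 9, theta = 0.3)
  s <- h$snps
  theta_j <- s$beta_y / s$beta_x
  w_j <- s$beta_x^2 / s$se_y^2
  expect_equal(ivw(h, "fixed")$beta, sum(w_j * theta_j) / sum(w_j),
    tolerance = 1e-10
  )
})

test_that("IVW degenerate cases behave as specified", {
  # two SNPs with identical beta_x and se_y, ratios 1 and 3 -> estimate 2
  h <- harmonized_set(c(0.1, 0.1), c(0.01, 0.01),
    c(0.1, 0.3), c(0.02, 0.02))
  expect_equal(ivw(h, "fixed")$beta, 2)
  # single instrument delegates to the Wald ratio
  h1 <- harmonized_set(0.1, 0.01, 0.25, 0.02)
  e <- ivw(h1)
  expect_equal(e$method, "wald_ratio")
  expect_equal(e$beta, 2.5)
})

test_that("random-effects IVW inflates the SE by the Q-based factor", {
  h <- make_h(20, seed = 11, theta = 0.2, se_y = 0.001)
  # add gross heterogeneity
  h$snps$beta_y <- h$snps$beta_y + rep(c(-0.05, 0.05), 10)
  q <- cochran_q(h)
  expect_lt(q$q_pvalue, 0.05)
  ef <- ivw(h, "fixed")
  er <- ivw(h, "random")
  expect_equal(er$se, ef$se * sqrt(q$q_value / (h$k - 1)), tolerance = 1e-10)
  expect_equal(er$model_note, "multiplicative_random_effects")
  expect_equal(ivw(h, "auto")$se, er$se)
})

test_that("MR-Egger matches the intercept-regression oracle to 1e-10", {
  h <- make_h(20, seed = 7, theta = 0.5)
  e <- egger(h)
  s <- h$snps
  flip <- ifelse(s$beta_x < 0, -1, 1)
  o <- oracle_wls(
    s$beta_y * flip, matrix(s$beta_x * flip), 1 / s$se_y^2,
    intercept = TRUE
  )
  expect_equal(e$extra$intercept, o$coef[1], tolerance = 1e-10)
  expect_equal(e$beta, o$coef[2], tolerance = 1e-10)
  expect_equal(e$extra$intercept_se, o$se[1], tolerance = 1e-10)
  expect_equal(e$se, o$se[2], tolerance = 1e-10)
})

test_that("a constant shift in outcome effects moves only the Egger intercept", {
  h <- make_h(15, seed = 13, theta = 0.4)
  h$snps$beta_x <- abs(h$snps$beta_x) # uniform orientation
  h$snps$beta_y <- abs(h$snps$beta_x) * 0.4 + rnorm(15, 0, 0.01)
  e1 <- egger(h)
  h2 <- h
  h2$snps$beta_y <- h$snps$beta_y + 0.03
  e2 <- egger(h2)
  expect_equal(e2$beta, e1$beta, tolerance = 1e-10)
  expect_equal(e2$extra$intercept, e1$extra$intercept + 0.03,
    tolerance = 1e-10
  )
})

test_that("the weighted median interpolates at cumulative weight one half", {
  # equal weights, ratios {1, 2, 9} -> 2
  h <- harmonized_set(
    c(1, 1, 1), c(0.01, 0.01, 0.01),
    c(1, 2, 9), c(1, 1, 1)
  )
  e <- weighted_median(h, n_boot = 50, seed = 1)
  expect_equal(e$beta, 2)
  # identical seed reproduces the bootstrap SE bit-identically
  e2 <- weighted_median(h, n_boot = 50, seed = 1)
  expect_identical(e$se, e2$se)
  expect_false(identical(
    e$se, weighted_median(h, n_boot = 50, seed = 2)$se
  ))
  expect_error(weighted_median(make_h(2)), "3 instruments")
})

test_that("the weighted median resists up to half gross pleiotropy better than IVW", {
  wins <- logical(200)
  theta <- 0.3
  for (i in 1:200) {
    set.seed(6000 + i)
    k <- 20
    bx <- runif(k, 0.05, 0.2)
    se_y <- rep(0.01, k)
    by <- theta * bx + rnorm(k) * se_y
    bad <- 1:9 # 45% invalid with gross positive pleiotropy
    by[bad] <- by[bad] + runif(9, 0.05, 0.15)
    h <- harmonized_set(bx, rep(0.001, k), by, se_y)
    wm <- .weighted_median_point(h)
    iv <- ivw(h, "fixed")$beta
    wins[i] <- abs(wm - theta) < abs(iv - theta)
  }
  expect_gte(mean(wins), 0.8)
})

test_that("mode estimators find point masses and majority clusters", {
  h <- harmonized_set(
    rep(1, 5), rep(0.01, 5),
    rep(3, 5), rep(0.5, 5)
  )
  expect_equal(mode_estimators(h, "simple", n_boot = 20, seed = 1)$beta, 3)
  expect_equal(mode_estimators(h, "weighted", n_boot = 20, seed = 1)$beta, 3)

  set.seed(7)
  k <- 10
  bx <- rep(1, k)
  by <- c(rnorm(9, 2, 0.05), 50)
  h2 <- harmonized_set(bx, rep(0.01, k), by, rep(0.1, k))
  e <- mode_estimators(h2, "weighted", n_boot = 50, seed = 7)
  expect_lt(abs(e$beta - 2), 0.3)
  e2 <- mode_estimators(h2, "weighted", n_boot = 50, seed = 7)
  expect_identical(e$se, e2$se)
})

test_that("printed odds ratios and p-values reproduce published conversions", {
  a <- beta_to_or(-1.046, 0.338)
  expect_equal(round(a$or_value, 2), 0.35)
  expect_equal(round(a$ci_low, 2), 0.18)
  expect_equal(round(a$ci_high, 2), 0.68)
  expect_equal(signif(p_from_z(-1.046, 0.338), 3), 1.97e-3)
  expect_equal(p_from_z(0, 1), 1)
  b <- beta_to_or(0, 1)
  expect_equal(round(b$or_value, 2), 1)
  expect_equal(round(b$ci_low, 2), 0.14)
  expect_equal(round(b$ci_high, 2), 7.1)
})

test_that("two-sided p equals the integrated normal tail", {
  for (pair in list(c(-1.046, 0.338), c(0.5, 0.3), c(2, 0.4))) {
    z <- abs(pair[1] / pair[2])
    quad <- 2 * integrate(dnorm, -Inf, -z, rel.tol = 1e-13)$value
    expect_equal(p_from_z(pair[1], pair[2]), quad, tolerance = 1e-10)
  }
})

test_that("se_from_ci inverts the Wald interval", {
  expect_equal(se_from_ci(0.002, 0.426), 0.424 / 3.92, tolerance = 1e-12)
  expect_equal(se_from_ci(-1.96, 1.96), 1)
  # inverse pair with beta_to_or on the log scale
  or <- beta_to_or(-0.291, 0.134)
  expect_equal(se_from_ci(log(or$ci_low), log(or$ci_high)), 0.134,
    tolerance = 1e-12
  )
  expect_error(se_from_ci(1, 1), "high > low")
})

test_that("causal estimates are scale equivariant in the exposure", {
  h <- make_h(12, seed = 3, theta = 0.6)
  for (cc in c(2, -3)) {
    h2 <- h
    h2$snps$beta_x <- h$snps$beta_x * cc
    h2$snps$se_x <- h$snps$se_x * abs(cc)
    expect_equal(ivw(h2, "fixed")$beta, ivw(h, "fixed")$beta / cc,
      tolerance = 1e-10
    )
    expect_equal(egger(h2)$beta, egger(h)$beta / cc, tolerance = 1e-10)
    expect_equal(
      .weighted_median_point(h2), .weighted_median_point(h) / cc,
      tolerance = 1e-10
    )
  }
})

test_that("run_all_methods adapts to the instrument count deterministically", {
  h1 <- harmonized_set(0.1, 0.01, 0.2, 0.05)
  out1 <- run_all_methods(h1)
  expect_length(out1, 1L)
  expect_equal(out1[[1]]$method, "wald_ratio")

  sim <- simulate_chain(chain_sim_config(
    n_snps = 8, n_snps_mediator = 0, n_exposure = 1e6, n_outcome = 1e5,
    palindrome_frac = 0, seed = 3
  ))
  h5 <- harmonize(select_by_pvalue(sim$exposure, 1e-5), sim$outcome)
  out5 <- run_all_methods(h5, seed = 3, n_boot = 100)
  expect_setequal(
    names(out5),
    c("ivw", "egger", "weighted_median", "weighted_mode", "simple_mode")
  )
  betas <- vapply(out5, function(e) e$beta, numeric(1))
  expect_true(all(betas < 0)) # truth is -0.35
  expect_true(attr(out5, "direction_consistent"))
  out5b <- run_all_methods(h5, seed = 3, n_boot = 100)
  expect_identical(
    vapply(out5, function(e) e$se, numeric(1)),
    vapply(out5b, function(e) e$se, numeric(1))
  )
})
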