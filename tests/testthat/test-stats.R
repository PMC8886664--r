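# Panel preprocessing, group comparisons, screening, mediation, BH
# correction, and stitched-matrix PCA.

test_that("z-score and log transforms behave and are reusable", {
  coh <- tiny_cohort(n = 50, pairs = 2L, grid = c(12L, 12L, 12L), seed = 1)
  z <- preprocess_panel(coh$panel, "zscore")
  for (p in BLOOD_PARAMS) {
    expect_lt(abs(mean(z[[p]])), 1e-12)
    expect_equal(sd(z[[p]]), 1, tolerance = 1e-12)
  }
  # reapplying stored parameters reproduces the transform exactly
  z2 <- preprocess_panel(coh$panel, "zscore", params = attr(z, "transform"))
  expect_identical(z2[BLOOD_PARAMS], z[BLOOD_PARAMS])

  lg <- preprocess_panel(coh$panel, "log")
  expect_equal(lg$NFL, log(coh$panel$NFL))
  bad <- coh$panel; bad$TG[3] <- -1
  expect_error(preprocess_panel(bad, "log"), "TG")
})

test_that("log of a log-normally generated parameter is Gaussian", {
  # log TREM2 is exactly Gaussian by construction, so failures are the
  # Shapiro test's own 5% type-I rate; 0.85 leaves binomial headroom
  hits <- vapply(1:20, function(s) {
    coh <- tiny_cohort(n = 200, pairs = 2L, grid = c(12L, 12L, 12L), seed = s)
    stats::shapiro.test(log(coh$panel$TREM2))$p.value >= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})

test_that("amyloid ratios are derived, recomputable, and analysis-only", {
  pan <- data.frame(subject_id = "s1", Abeta40 = 100, Abeta42 = 10, Ttau = 4)
  out <- add_ratios(pan)
  expect_equal(out$Abeta42_40, 0.1)
  expect_equal(out$Abeta42_Ttau, 2.5)
  expect_identical(out$Abeta40, pan$Abeta40)
  pan0 <- pan; pan0$Ttau <- 0
  expect_error(add_ratios(pan0), "zero denominator")
  expect_error(add_ratios(pan[, 1:2]), "missing column")
})

test_that("chi-squared on a 2x2 table matches the closed form", {
  v <- rep(c("x", "y", "x", "y"), c(10, 20, 20, 10))
  g <- rep(c("A", "B"), c(30, 30))
  res <- compare_groups(v, g)
  expect_identical(res$test, "chi-squared")
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)   # 6.667 uncorrected
})

test_that("the ANOVA path is calibrated and detects a shifted group", {
  # type-I calibration under a common normal distribution
  set.seed(5)
  rej <- vapply(1:200, function(i) {
    y <- rnorm(45)
    g <- rep(c("a", "b", "c"), each = 15)
    compare_groups(y, g)$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.10)

  # power: group means 0/0/2, SD 1, n = 30 each
  set.seed(6)
  y <- c(rnorm(30), rnorm(30), rnorm(30, 2))
  g <- rep(c("a", "b", "c"), each = 30)
  res <- compare_groups(y, g)
  expect_identical(res$test, "anova")
  expect_lt(res$p, 0.001)
  expect_true(res$eta_sq > 0 && res$eta_sq < 1)
  p3 <- res$posthoc$p[grepl("c", res$posthoc$contrast)]
  expect_true(all(p3 < 0.01))
  expect_gt(res$posthoc$p[res$posthoc$contrast %in%
                            c("a - b", "b - a")], 0.5)
})

test_that("a confounding covariate switches the test to ANCOVA", {
  set.seed(7)
  n <- 90
  g <- rep(c("a", "b", "c"), each = n / 3)
  sex <- rbinom(n, 1, 0.5)
  y <- 2 * sex + rnorm(n)                 # sex drives y, groups do not
  res <- compare_groups(y, g, covariates = data.frame(sex = sex))
  expect_identical(res$test, "ancova")
  expect_lt(res$covariate_p[["sex"]], 0.05)
  expect_gt(res$p, 0.05)
  expect_identical(nrow(res$posthoc), 3L)

  # with a null covariate the ANCOVA group F agrees closely with the ANOVA F
  z <- rnorm(n)
  y2 <- ifelse(g == "c", 1, 0) + rnorm(n)
  res_cov <- compare_groups(y2, g, covariates = data.frame(z = z))
  res_plain <- compare_groups(y2, g)
  expect_identical(res_cov$test, "anova")  # covariate not significant
  expect_equal(res_cov$statistic, res_plain$statistic, tolerance = 1e-12)
})

test_that("predictor screening keeps true signals at the nominal error rate", {
  set.seed(8)
  n <- 100
  age <- runif(n, 50, 85)
  feats <- data.frame(signal = age + rnorm(n, 0, 3),
                      matrix(rnorm(n * 40), n,
                             dimnames = list(NULL, sprintf("noise%02d", 1:40))))
  scr <- screen_predictors(feats, age)
  expect_true("signal" %in% scr$selected)
  # ~5% of the 40 null features pass by chance
  expect_lte(sum(scr$selected != "signal"), 7)
  expect_identical(scr$n_screen, length(scr$selected))
  feats$flat <- 1
  expect_warning(scr2 <- screen_predictors(feats, age), "constant")
  expect_false("flat" %in% scr2$selected)
})

test_that("mediation recovers direct-only and fully mediated structures", {
  # y = x exactly, mediator pure noise: ADE ~ 1, ACME ~ 0
  set.seed(9)
  x <- rnorm(200); m <- rnorm(200); y <- x
  res <- mediate(x, m, y, n_boot = 300, seed = 1)
  expect_equal(res$ade$estimate, 1, tolerance = 1e-10)
  expect_lt(abs(res$acme$estimate), 1e-10)
  expect_identical(res$classification, "none")   # ACME interval covers 0

  # full mediation a = b = 0.5, c' = 0
  tr <- simulate_mediation_triple(1000, 0.5, 0.5, 0, seed = 11)
  res2 <- mediate(tr$x, tr$m, tr$y, n_boot = 500, seed = 2)
  expect_equal(res2$acme$estimate,
               brainfuse:::mediation_point(tr$x, tr$m, tr$y)$acme)
  expect_identical(res2$classification, "full")
  expect_lt(res2$acme$p, 0.05)
  # linear consistency: total = ADE + ACME
  expect_equal(res2$total$estimate,
               res2$ade$estimate + res2$acme$estimate, tolerance = 1e-12)
  expect_true(res2$acme$ci[1] <= res2$acme$ci[2])

  expect_error(mediate(x, x + 1e-9 * rnorm(200), y), "collinear")
  expect_error(mediate(x[1:10], m[1:10], y[1:10]), "n >= 20")
})

test_that("ACME interval covers zero under the no-mediation null", {
  cover <- vapply(1:60, function(s) {
    tr <- simulate_mediation_triple(120, a = 0, b = 0.5, cprime = 0.3,
                                    seed = 500 + s)
    res <- mediate(tr$x, tr$m, tr$y, n_boot = 250, seed = s)
    res$acme$ci[1] <= 0 && res$acme$ci[2] >= 0
  }, logical(1))
  expect_gte(mean(cover), 0.85)
})

test_that("BH correction matches the step-up rule", {
  expect_equal(bh_correct(0.03), 0.03)
  expect_equal(bh_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_correct(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.02, 0.9, 0.04)
  q <- bh_correct(p)
  expect_true(all(q >= p))
  # order invariance
  ord <- c(3, 1, 4, 2)
  expect_equal(bh_correct(p[ord]), q[ord])
  expect_error(bh_correct(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("stitched PCA has the right dimension and spectral structure", {
  set.seed(10)
  emb <- matrix(rnorm(40 * 256), 40, 256)
  blood <- matrix(rnorm(40 * 14), 40, 14)
  pc <- pca_stitched(emb, blood)
  expect_identical(pc$input_dim, 270L)
  expect_identical(dim(pc$loadings), c(270L, 2L))
  expect_identical(dim(pc$scores), c(40L, 2L))
  # loadings orthonormal; explained variance sorted and <= 1 in total
  expect_equal(crossprod(pc$loadings), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_lte(sum(pc$explained), 1 + 1e-12)

  # rank-1 latent structure: first component explains almost everything
  t1 <- rnorm(30)
  X <- outer(t1, rnorm(20)) + matrix(rnorm(30 * 20, 0, 1e-3), 30, 20)
  pc1 <- pca_stitched(X[, 1:10], X[, 11:20])
  expect_gt(pc1$explained[1], 0.99)

  # two-component reconstruction error is bounded by discarded eigenvalues
  Z <- scale(cbind(emb, blood))
  rec <- pc$scores %*% t(pc$loadings)
  frob_err <- sum((Z - rec)^2)
  expect_equal(frob_err / sum(Z^2), 1 - sum(pc$explained[1:2]),
               tolerance = 1e-10)

  cst <- blood; cst[, 1] <- 5
  expect_warning(pc2 <- pca_stitched(emb, cst), "constant")
  expect_identical(length(pc2$kept), 269L)
})
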