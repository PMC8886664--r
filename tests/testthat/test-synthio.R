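# Synthetic cohort generator: atlas geometry, statistical structure of the
# generated data, determinism, and serialization.

test_that("atlas regions are mirror-symmetric pairs that partition labels", {
  atl <- make_atlas(c(24, 28, 24), n_region_pairs = 1, seed = 7)
  counts <- table(atl$labels)
  expect_setequal(as.integer(names(counts)), c(0L, 1L, 2L))
  # mirror image: label 2 is label 1 reflected about the mid-sagittal plane
  expect_equal(sum(atl$labels == 1L), sum(atl$labels == 2L))
  mirrored <- atl$labels[dim(atl$labels)[1]:1, , ]
  expect_true(all((mirrored == 1L) == (atl$labels == 2L)))

  full <- make_atlas(c(24, 28, 24), n_region_pairs = 45, seed = 7)
  labs <- sort(unique(as.vector(full$labels)))
  expect_identical(labs, 0:90)          # 90 labeled regions + background
  cnt <- tabulate(full$labels, nbins = 90)
  expect_true(all(cnt > 0))
  left <- cnt[seq(1, 89, by = 2)]
  right <- cnt[seq(2, 90, by = 2)]
  expect_identical(left, right)         # pair voxel counts equal
  # pair names equal modulo hemisphere suffix
  expect_identical(sub("\\.L$", "", full$names[seq(1, 89, 2)]),
                   sub("\\.R$", "", full$names[seq(2, 90, 2)]))
})

test_that("atlas construction is seed-deterministic and capacity-checked", {
  a1 <- make_atlas(c(24, 28, 24), 6, seed = 7)
  a2 <- make_atlas(c(24, 28, 24), 6, seed = 7)
  expect_identical(a1$labels, a2$labels)
  a3 <- make_atlas(c(24, 28, 24), 6, seed = 8)
  expect_false(identical(a1$labels, a3$labels))
  expect_error(make_atlas(c(8, 8, 8), 45), "cannot pack")
  expect_error(make_atlas(c(4, 24, 24), 1), ">= 8")
  expect_error(make_atlas(c(24, 24, 24), 0), "between 1 and 45")
})

test_that("identical config gives a bit-identical cohort", {
  c1 <- tiny_cohort(n = 6, seed = 42)
  c2 <- tiny_cohort(n = 6, seed = 42)
  expect_identical(c1$volumes, c2$volumes)
  expect_identical(c1$panel, c2$panel)
  expect_identical(c1$subjects, c2$subjects)
  c3 <- tiny_cohort(n = 6, seed = 43)
  expect_false(identical(c1$volumes[[1]], c3$volumes[[1]]))
})

test_that("subject records respect their invariants", {
  coh <- tiny_cohort(n = 120, seed = 5)
  s <- coh$subjects
  expect_true(all(s$age >= 50 & s$age <= 85))
  expect_true(all(s$mmse >= 25 & s$mmse <= 30))
  expect_true(all(s$moca >= 18 & s$moca <= 30))
  expect_identical(s$apoe_e4_carrier, s$apoe_e4_count > 0)
  # age group consistent with age (left-closed bins, last closed at 85)
  expect_true(all(s$age_group[s$age < 60] == "50-60"))
  expect_true(all(s$age_group[s$age >= 60 & s$age < 70] == "60-70"))
  expect_true(all(s$age_group[s$age >= 70] == "70-85"))
  expect_true(all(sapply(coh$volumes, function(v) all(is.finite(v) & v >= 0))))
})

test_that("configured blood slopes reproduce their correlation signs", {
  for (seed in 1:3) {
    coh <- tiny_cohort(n = 500, pairs = 2L, grid = c(12L, 12L, 12L),
                       slopes = rep(0, 2), seed = seed)
    age <- coh$subjects$age
    ct <- suppressWarnings(
      stats::cor.test(coh$panel$NFL, age, method = "spearman", exact = FALSE))
    expect_gt(ct$estimate, 0)
    expect_lt(ct$p.value, 0.05)
    expect_gt(cor(coh$panel$ApoA1, age, method = "spearman"), 0)
    expect_gt(cor(coh$panel$Abeta40, age, method = "spearman"), 0)
    expect_lt(cor(coh$panel$VLDLR, age, method = "spearman"), 0)
    # derived ratio trends negative because Abeta40 rises while Abeta42 is flat
    expect_lt(cor(coh$panel$Abeta42 / coh$panel$Abeta40, age,
                  method = "spearman"), 0)
  }
})

test_that("null generator is calibrated: no spurious age-blood correlation", {
  be <- default_blood_effects()
  be$slope[] <- 0
  hits <- 0L; total <- 0L
  for (seed in 1:30) {
    cfg <- simulation_config(n_subjects = 60, grid_shape = c(12L, 12L, 12L),
                             n_region_pairs = 2L, atrophy_slopes = rep(0, 2),
                             blood_effects = be, seed = seed)
    coh <- simulate_cohort(cfg)
    for (p in BLOOD_PARAMS) {
      pv <- suppressWarnings(stats::cor.test(coh$panel[[p]], coh$subjects$age,
                                             method = "spearman",
                                             exact = FALSE))$p.value
      hits <- hits + (pv < 0.05)
      total <- total + 1L
    }
  }
  rate <- hits / total   # 390 nominal-5% tests; binomial 95% band
  expect_gt(rate, 0.05 - 2.2 * sqrt(0.05 * 0.95 / total))
  expect_lt(rate, 0.05 + 2.2 * sqrt(0.05 * 0.95 / total))
})

test_that("regional atrophy follows the configured slopes", {
  coh <- tiny_cohort(n = 300, pairs = 3L, slopes = c(0.010, 0.004, 0),
                     seed = 9)
  rm_feats <- region_mean_features(coh$volumes, coh$atlas)
  age <- coh$subjects$age
  fit1 <- coef(lm(rm_feats[, 1] ~ age))[2]
  fit2 <- coef(lm(rm_feats[, 2] ~ age))[2]
  fit3 <- coef(lm(rm_feats[, 3] ~ age))[2]
  expect_equal(unname(fit1), -0.010, tolerance = 0.15)
  expect_equal(unname(fit2), -0.004, tolerance = 0.25)
  expect_lt(abs(fit3), 0.001)
})

test_that("mediation-triple generator recovers its path coefficients by OLS", {
  # the product-of-coefficients estimate has sd ~0.022 at n = 1000, so the
  # 10% recovery property is assessed on the mean over replicate datasets
  acmes <- cprimes <- numeric(5)
  for (r in 1:5) {
    tr <- simulate_mediation_triple(1000, a = -0.5, b = -0.5, cprime = 0,
                                    seed = 100 + r)
    a_hat <- coef(lm(m ~ x, tr))[2]
    cf <- coef(lm(y ~ x + m, tr))
    acmes[r] <- unname(a_hat * cf["m"])
    cprimes[r] <- unname(cf["x"])
    expect_identical(attr(tr, "truth")$acme, 0.25)
  }
  expect_equal(mean(acmes), 0.25, tolerance = 0.10)
  expect_lt(abs(mean(cprimes)), 0.1)
})

test_that("cohort serialization round-trips and the manifest is complete", {
  dir <- withr::local_tempdir()
  coh <- tiny_cohort(n = 5, pairs = 2L, grid = c(12L, 12L, 12L), seed = 21)
  man <- write_cohort(coh, dir)
  # one volume file per subject plus the six sidecars
  expect_equal(sum(grepl("^volumes/", man$file)), 5)
  expect_true(all(c("panel.csv", "demographics.csv", "atlas.nii",
                    "atlas.json", "truth.json", "config.yaml",
                    "manifest.csv") %in%
                    c(man$file, "manifest.csv")))
  back <- read_cohort(dir, verify = TRUE)
  for (i in 1:5) {
    expect_identical(as.vector(back$volumes[[i]]), as.vector(coh$volumes[[i]]))
  }
  expect_equal(back$panel[BLOOD_PARAMS], coh$panel[BLOOD_PARAMS])
  expect_identical(back$atlas$labels, coh$atlas$labels)
  # the panel file carries all 14 parameters (13 concentrations + APOE)
  expect_true(all(c(BLOOD_PARAMS, "APOE") %in% names(back$panel)))
  expect_equal(attr(back$volumes[[1]], "voxel_size"), 1.5)
})
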