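# Synthetic cohort generator: gray-matter volumes with region-specific
# age-dependent atrophy, a 14-parameter blood panel with configurable
# age effects, and demographics matching the study population structure
# (ages 50-85, three age groups, APOE genotyping, MMSE/MoCA screening).

#' Blood-panel parameter names
#'
#' The 13 concentration parameters plus the APOE genotype column. Unicode
#' symbols are transliterated for file safety: `Abeta40`/`Abeta42` stand for
#' the amyloid-beta peptides, `Ttau` for total tau.
#' @export
BLOOD_PARAMS <- c("GLU", "TG", "TC", "ApoA1", "ApoB", "HCY", "NFL", "TREM2",
                  "Abeta40", "Abeta42", "Ttau", "TIMP1", "VLDLR")

#' Default per-parameter blood generation settings
#'
#' Concentrations are generated on the log scale (hence strictly positive and
#' exactly Gaussianized by a log transform). `slope` is the change in log
#' concentration per year of age; signs follow the age correlations reported
#' for elderly cohorts: ApoA1, NFL and Abeta40 rise with age, VLDLR falls,
#' Abeta42 stays flat so the derived Abeta42/Abeta40 ratio falls.
#'
#' @return data.frame with one row per blood parameter: `base` (log median),
#'   `slope` (log units / year), `sd` (log-scale noise SD).
#' @export
default_blood_effects <- function() {
  data.frame(
    param = BLOOD_PARAMS,
    base  = log(c(5.3, 1.4, 4.9, 1.40, 0.95, 12, 12, 60, 250, 11, 2.6, 120, 20)),
    slope = c(0.003, 0.000, 0.002, 0.004, 0.002, 0.006, 0.020, 0.000,
              0.010, 0.000, 0.002, 0.000, -0.010),
    sd    = c(0.12, 0.35, 0.18, 0.12, 0.20, 0.25, 0.30, 0.30,
              0.20, 0.22, 0.30, 0.20, 0.25),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic cohort generator
#'
#' @param n_subjects number of subjects (>= 2).
#' @param age_range two ages in years; subjects are drawn from this range
#'   (default 50-85, the study population's range).
#' @param age_dist `"uniform"` (default) or `"truncnorm"` (mean 62.1, SD 8.6
#'   truncated to `age_range`, mimicking a recruited elderly cohort).
#' @param grid_shape voxel triple for the gray-matter grid. Default is a
#'   small 24x28x24 grid; the full-scale 121x145x121 grid is supported.
#' @param n_region_pairs hemisphere pairs in the atlas (default 45, i.e. the
#'   90 labels of an AAL-style parcellation).
#' @param atrophy_slopes per-pair decline in mean gray-matter intensity per
#'   year of age; `NULL` draws defaults in \[0.003, 0.009\] from `seed`.
#' @param blood_effects data.frame as [default_blood_effects()].
#' @param mediation_spec optional list of `list(param, region, a, cprime)`
#'   entries: parameter `param`'s log value receives `a` times the subject's
#'   standardized idiosyncratic deviation of region-pair `region` and
#'   `cprime` times standardized age (both in units of the parameter's noise
#'   SD), wiring a brain-mediated and a direct age path into the blood panel.
#' @param sex_ratio fraction of female subjects.
#' @param apoe_e4_freq population frequency of the APOE epsilon-4 allele.
#' @param baseline mean gray-matter intensity of a region at the youngest age.
#' @param region_sd SD of the per-subject, per-region idiosyncratic deviation
#'   (shared by both hemispheres of a pair).
#' @param voxel_sd SD of per-voxel noise within a region.
#' @param seed integer seed; identical configs give bit-identical cohorts.
#' @return object of class `bf_simconfig`.
#' @export
simulation_config <- function(n_subjects,
                              age_range = c(50, 85),
                              age_dist = c("uniform", "truncnorm"),
                              grid_shape = c(24L, 28L, 24L),
                              n_region_pairs = 45L,
                              atrophy_slopes = NULL,
                              blood_effects = default_blood_effects(),
                              mediation_spec = list(),
                              sex_ratio = 0.6,
                              apoe_e4_freq = 0.15,
                              baseline = 0.75,
                              region_sd = 0.04,
                              voxel_sd = 0.03,
                              seed = 1L) {
  age_dist <- match.arg(age_dist)
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2L) stop("n_subjects must be >= 2", call. = FALSE)
  stopifnot(length(age_range) == 2L, age_range[1L] < age_range[2L])
  if (!is.null(atrophy_slopes) && length(atrophy_slopes) != n_region_pairs) {
    stop("atrophy_slopes must have one entry per region pair", call. = FALSE)
  }
  stopifnot(is.data.frame(blood_effects),
            all(c("param", "base", "slope", "sd") %in% names(blood_effects)))
  if (any(blood_effects$sd < 0) || region_sd < 0 || voxel_sd < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  for (ms in mediation_spec) {
    stopifnot(all(c("param", "region", "a", "cprime") %in% names(ms)))
    if (!ms$param %in% BLOOD_PARAMS) {
      stop(sprintf("unknown blood parameter in mediation_spec: %s", ms$param),
           call. = FALSE)
    }
    if (ms$region < 1 || ms$region > n_region_pairs) {
      stop(sprintf("mediation_spec region %d not in atlas (1..%d)",
                   ms$region, n_region_pairs), call. = FALSE)
    }
  }
  structure(list(n_subjects = n_subjects, age_range = as.numeric(age_range),
                 age_dist = age_dist, grid_shape = as.integer(grid_shape),
                 n_region_pairs = as.integer(n_region_pairs),
                 atrophy_slopes = atrophy_slopes,
                 blood_effects = blood_effects,
                 mediation_spec = mediation_spec,
                 sex_ratio = sex_ratio, apoe_e4_freq = apoe_e4_freq,
                 baseline = baseline, region_sd = region_sd,
                 voxel_sd = voxel_sd, seed = as.integer(seed)),
            class = "bf_simconfig")
}

# cut ages into the study's groups: [50,60), [60,70), [70,85]
age_group_of <- function(age, edges = c(50, 60, 70, 85)) {
  labs <- sprintf("%d-%d", edges[-length(edges)], edges[-1L])
  g <- cut(age, breaks = edges, right = FALSE, labels = labs,
           include.lowest = TRUE)
  # last bin is closed on the right
  g[age == edges[length(edges)]] <- labs[length(labs)]
  if (anyNA(g)) stop("age outside the configured bins", call. = FALSE)
  g
}

#' Simulate a synthetic cohort
#'
#' Draws demographics, gray-matter volumes with region-specific age-dependent
#' atrophy, and a blood panel whose parameters trend with age (and, for
#' mediated parameters, with regional gray matter) according to the
#' configuration. The returned ground truth records every generating
#' coefficient for recovery tests.
#'
#' Generating model, per subject `s` and region pair `p`:
#' mean intensity `m[s,p] = baseline - slope[p] * (age_s - age_min) + u[s,p]`
#' with `u ~ N(0, region_sd)` shared by both hemispheres; voxels add
#' `N(0, voxel_sd)` noise; background sits at a low constant plus noise; all
#' values are clamped at 0. Log blood values are linear in age (and in the
#' standardized region deviation for mediated parameters), then exponentiated.
#'
#' @param config a [simulation_config()].
#' @param atlas optional [make_atlas()] result matching `config`; built from
#'   the config when `NULL`.
#' @return object of class `bf_cohort`: list with `subjects` (data.frame),
#'   `volumes` (list of 3D arrays), `panel` (data.frame), `atlas`, and
#'   `truth` (generating parameters incl. per-subject region deviations).
#' @examples
#' cfg <- simulation_config(n_subjects = 4, grid_shape = c(12, 12, 12),
#'                          n_region_pairs = 2, seed = 3)
#' coh <- simulate_cohort(cfg)
#' names(coh)
#' @export
simulate_cohort <- function(config, atlas = NULL) {
  stopifnot(inherits(config, "bf_simconfig"))
  if (is.null(atlas)) {
    atlas <- make_atlas(config$grid_shape, config$n_region_pairs,
                        seed = derive_seed(config$seed, "atlas"))
  }
  stopifnot(inherits(atlas, "bf_atlas"))
  if (!identical(atlas$grid_shape, config$grid_shape)) {
    stop("atlas grid does not match config grid_shape", call. = FALSE)
  }
  if (atlas$n_pairs != config$n_region_pairs) {
    stop("atlas region pairs do not match config", call. = FALSE)
  }
  n <- config$n_subjects
  P <- config$n_region_pairs

  with_seed(config$seed, {
    ages <- switch(config$age_dist,
      uniform = stats::runif(n, config$age_range[1L], config$age_range[2L]),
      truncnorm = {
        a <- numeric(0)
        while (length(a) < n) {
          cand <- stats::rnorm(2L * n, mean = 62.1, sd = 8.6)
          a <- c(a, cand[cand >= config$age_range[1L] & cand <= config$age_range[2L]])
        }
        a[seq_len(n)]
      })
    sex <- ifelse(stats::runif(n) < config$sex_ratio, "female", "male")
    freqs <- c(e2 = 0.08, e3 = 1 - 0.08 - config$apoe_e4_freq,
               e4 = config$apoe_e4_freq)
    a1 <- sample(names(freqs), n, replace = TRUE, prob = freqs)
    a2 <- sample(names(freqs), n, replace = TRUE, prob = freqs)
    apoe <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
    e4_count <- (a1 == "e4") + (a2 == "e4")
    mmse <- pmin(30L, pmax(25L, as.integer(round(
      29.2 - 0.03 * (ages - 50) + stats::rnorm(n, 0, 0.9)))))
    moca <- pmin(30L, pmax(18L, as.integer(round(
      28.0 - 0.06 * (ages - 50) + stats::rnorm(n, 0, 1.6)))))

    slopes <- config$atrophy_slopes
    if (is.null(slopes)) slopes <- stats::runif(P, 0.003, 0.009)
    baselines <- config$baseline + stats::runif(P, -0.03, 0.03)

    # per-subject, per-pair idiosyncratic deviation (shared across hemis)
    u <- matrix(stats::rnorm(n * P, 0, config$region_sd), n, P)
    region_mean <- matrix(baselines, n, P, byrow = TRUE) -
      outer(ages - config$age_range[1L], slopes) + u

    vox_of_pair <- lapply(seq_len(P), function(p) {
      list(L = which(atlas$labels == 2L * p - 1L),
           R = which(atlas$labels == 2L * p))
    })
    bg <- which(atlas$labels == 0L)
    V <- prod(config$grid_shape)

    volumes <- vector("list", n)
    for (s in seq_len(n)) {
      v <- numeric(V)
      v[bg] <- 0.08 + stats::rnorm(length(bg), 0, 0.02)
      for (p in seq_len(P)) {
        vx <- vox_of_pair[[p]]
        nv <- length(vx$L) + length(vx$R)
        v[c(vx$L, vx$R)] <- region_mean[s, p] +
          stats::rnorm(nv, 0, config$voxel_sd)
      }
      v[v < 0] <- 0
      volumes[[s]] <- array(v, dim = config$grid_shape)
    }

    # blood panel on the log scale
    be <- config$blood_effects
    age_mid <- mean(config$age_range)
    age_sd <- diff(config$age_range) / sqrt(12)  # SD of the uniform draw
    logx <- matrix(0, n, length(BLOOD_PARAMS),
                   dimnames = list(NULL, BLOOD_PARAMS))
    for (j in seq_along(BLOOD_PARAMS)) {
      row <- be[be$param == BLOOD_PARAMS[j], ]
      logx[, j] <- row$base + row$slope * (ages - age_mid) +
        stats::rnorm(n, 0, row$sd)
    }
    for (ms in config$mediation_spec) {
      j <- match(ms$param, BLOOD_PARAMS)
      sdj <- be$sd[be$param == ms$param]
      u_z <- u[, ms$region] / config$region_sd
      logx[, j] <- logx[, j] + sdj * (ms$a * u_z +
        ms$cprime * (ages - age_mid) / age_sd)
    }
    panel <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                        exp(logx), APOE = apoe,
                        stringsAsFactors = FALSE)
  })

  subjects <- data.frame(
    id = sprintf("S%04d", seq_len(n)),
    age = ages, sex = sex, apoe_genotype = apoe,
    apoe_e4_carrier = e4_count > 0L, apoe_e4_count = as.integer(e4_count),
    mmse = mmse, moca = moca,
    age_group = age_group_of(ages, c(config$age_range[1L], 60, 70,
                                     config$age_range[2L])),
    stringsAsFactors = FALSE
  )

  truth <- list(atrophy_slopes = slopes, baselines = baselines,
                region_sd = config$region_sd, voxel_sd = config$voxel_sd,
                blood_effects = config$blood_effects,
                mediation_spec = config$mediation_spec,
                region_deviation = u, region_mean = region_mean,
                config = config)

  structure(list(subjects = subjects, volumes = volumes, panel = panel,
                 atlas = atlas, truth = truth, voxel_size = 1.5),
            class = "bf_cohort")
}

#' @export
print.bf_cohort <- function(x, ...) {
  cat(sprintf("<bf_cohort> n = %d subjects, %s grid, %d region pairs\n",
              nrow(x$subjects), paste(dim(x$volumes[[1L]]), collapse = "x"),
              x$atlas$n_pairs))
  invisible(x)
}

#' Simulate a linear mediation triple
#'
#' Structural equations `x ~ N(0,1)`, `m = a*x + N(0, sd_m)`,
#' `y = cprime*x + b*m + N(0, sd_y)`, so the population indirect effect
#' (ACME) is `a*b`, the direct effect (ADE) is `cprime`, and the total effect
#' is `cprime + a*b`. Used to validate [mediate()] against known truth.
#'
#' @param n sample size.
#' @param a,b,cprime path coefficients.
#' @param sd_m,sd_y error SDs (default 1: unit error variances).
#' @param seed integer seed.
#' @return data.frame with columns `x`, `m`, `y` and attribute `truth`.
#' @export
simulate_mediation_triple <- function(n, a, b, cprime, sd_m = 1, sd_y = 1,
                                      seed = 1L) {
  stopifnot(n >= 3)
  with_seed(seed, {
    x <- stats::rnorm(n)
    m <- a * x + stats::rnorm(n, 0, sd_m)
    y <- cprime * x + b * m + stats::rnorm(n, 0, sd_y)
  })
  out <- data.frame(x = x, m = m, y = y)
  attr(out, "truth") <- list(acme = a * b, ade = cprime, total = cprime + a * b)
  out
}
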