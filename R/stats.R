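# Blood-panel preprocessing, group comparisons (chi-squared / ANCOVA with
# sex and APOE-e4 covariates / one-way ANOVA with Bonferroni post-hoc),
# predictor screening, linear-model mediation with bias-corrected bootstrap
# CIs and Benjamini-Hochberg correction, and PCA of the stitched image +
# blood feature matrix.

#' Transform the blood panel
#'
#' `"zscore"` standardizes each parameter column; `"log"` takes natural
#' logs (parameters are generated log-normally, so the log transform is
#' exactly Gaussianizing). Transform parameters are stored in the result's
#' `"transform"` attribute and can be reapplied to held-out data via
#' `params`, so test folds are scaled with training statistics.
#'
#' @param panel data.frame containing the [BLOOD_PARAMS] columns.
#' @param mode `"zscore"` or `"log"`.
#' @param params optional stored transform (attribute of a previous result).
#' @return panel with transformed parameter columns.
#' @export
preprocess_panel <- function(panel, mode = c("zscore", "log"), params = NULL) {
  mode <- match.arg(mode)
  cols <- intersect(BLOOD_PARAMS, names(panel))
  if (length(cols) == 0L) stop("panel has no blood parameter columns", call. = FALSE)
  out <- panel
  if (mode == "log") {
    for (cl in cols) {
      bad <- which(panel[[cl]] <= 0)
      if (length(bad)) {
        stop(sprintf("non-positive value under log: subject %s, parameter %s",
                     panel$subject_id[bad[1L]] %||% bad[1L], cl), call. = FALSE)
      }
      out[[cl]] <- log(panel[[cl]])
    }
    attr(out, "transform") <- list(mode = "log")
  } else {
    if (is.null(params)) {
      params <- list(mode = "zscore",
                     mean = vapply(panel[cols], mean, numeric(1L)),
                     sd = vapply(panel[cols], stats::sd, numeric(1L)))
      params$sd[params$sd == 0] <- 1
    }
    for (cl in cols) {
      out[[cl]] <- (panel[[cl]] - params$mean[[cl]]) / params$sd[[cl]]
    }
    attr(out, "transform") <- params
  }
  out
}

#' Append the derived amyloid ratios
#'
#' Adds `Abeta42_40` (Abeta42 / Abeta40) and `Abeta42_Ttau` (Abeta42 /
#' Ttau) as analysis-only columns; base columns are untouched and the
#' ratios are always recomputed from them, never stored independently.
#'
#' @param panel blood panel with positive `Abeta40`, `Abeta42`, `Ttau`.
#' @return panel with the two ratio columns.
#' @export
add_ratios <- function(panel) {
  need <- c("Abeta40", "Abeta42", "Ttau")
  miss <- setdiff(need, names(panel))
  if (length(miss)) {
    stop(sprintf("missing column: %s", paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (any(panel$Abeta40 == 0) || any(panel$Ttau == 0)) {
    stop("zero denominator in amyloid ratio", call. = FALSE)
  }
  panel$Abeta42_40 <- panel$Abeta42 / panel$Abeta40
  panel$Abeta42_Ttau <- panel$Abeta42 / panel$Ttau
  panel
}

#' Group comparison with the covariate-gated test policy
#'
#' Categorical variables are compared with an (uncorrected) chi-squared
#' test. Continuous variables are first fit as an ANCOVA with the supplied
#' covariates (sex, APOE-e4 carriage); if either covariate is significant at
#' `alpha` the ANCOVA is kept, with eta-squared (group sum of squares over
#' total) as effect size and Bonferroni-adjusted pairwise contrasts on the
#' covariate-adjusted means. Otherwise the model is refit as a one-way
#' ANOVA with Bonferroni post-hoc pairwise t-tests.
#'
#' @param values numeric vector (continuous) or factor/character
#'   (categorical).
#' @param groups grouping factor (>= 2 non-empty groups).
#' @param covariates optional data.frame of covariates (e.g. columns `sex`,
#'   `apoe_e4_carrier`); ignored for categorical values.
#' @param alpha significance level for the covariate gate.
#' @return list of class `bf_groupcomp`: `variable_type`, `test`,
#'   `statistic`, `p`, `eta_sq`, `covariate_p`, `posthoc` (data.frame of
#'   pairwise Bonferroni p-values, continuous only).
#' @export
compare_groups <- function(values, groups, covariates = NULL, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L || any(table(groups) == 0L)) {
    stop("need >= 2 non-empty groups", call. = FALSE)
  }
  if (is.character(values) || is.factor(values) || is.logical(values)) {
    tab <- table(factor(values), groups)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    return(structure(list(variable_type = "categorical", test = "chi-squared",
                          statistic = unname(ct$statistic), p = ct$p.value,
                          eta_sq = NA_real_, covariate_p = NULL,
                          posthoc = NULL),
                     class = "bf_groupcomp"))
  }
  if (any(table(groups) < 2L)) {
    stop("each group needs >= 2 observations for variance-based tests",
         call. = FALSE)
  }
  dat <- data.frame(y = values, g = groups)
  has_cov <- !is.null(covariates) && ncol(as.data.frame(covariates)) > 0L
  if (has_cov) {
    cv <- as.data.frame(covariates)
    dat <- cbind(dat, cv)
    fml <- stats::as.formula(paste("y ~", paste(names(cv), collapse = " + "), "+ g"))
    fit <- stats::lm(fml, data = dat)
    an <- stats::anova(fit)
    cov_p <- an[names(cv), "Pr(>F)"]
    names(cov_p) <- names(cv)
    confounded <- any(cov_p < alpha, na.rm = TRUE)
  } else {
    confounded <- FALSE
    cov_p <- NULL
  }
  if (confounded) {
    ss <- an[, "Sum Sq"]
    eta <- an["g", "Sum Sq"] / sum(ss)
    em <- emmeans::emmeans(fit, "g")
    ph <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                          adjust = "bonferroni"))
    posthoc <- data.frame(contrast = as.character(ph$contrast),
                          p = ph$p.value, stringsAsFactors = FALSE)
    return(structure(list(variable_type = "continuous", test = "ancova",
                          statistic = an["g", "F value"], p = an["g", "Pr(>F)"],
                          eta_sq = eta, covariate_p = cov_p, posthoc = posthoc),
                     class = "bf_groupcomp"))
  }
  fit1 <- stats::lm(y ~ g, data = dat)
  an1 <- stats::anova(fit1)
  eta <- an1["g", "Sum Sq"] / sum(an1[, "Sum Sq"])
  pw <- stats::pairwise.t.test(dat$y, dat$g, p.adjust.method = "bonferroni")
  pm <- pw$p.value
  posthoc <- do.call(rbind, lapply(rownames(pm), function(r) {
    cols <- colnames(pm)[!is.na(pm[r, ])]
    if (!length(cols)) return(NULL)
    data.frame(contrast = paste(cols, "-", r), p = pm[r, cols],
               stringsAsFactors = FALSE)
  }))
  rownames(posthoc) <- NULL
  structure(list(variable_type = "continuous", test = "anova",
                 statistic = an1["g", "F value"], p = an1["g", "Pr(>F)"],
                 eta_sq = eta, covariate_p = cov_p, posthoc = posthoc),
            class = "bf_groupcomp")
}

#' Screen predictors by univariate regression on age
#'
#' Per feature, a simple linear regression of age on the feature; features
#' whose slope is significant at `alpha` are selected. Constant features
#' are excluded with a warning.
#'
#' @param features numeric matrix or data.frame (n x p, named columns).
#' @param outcome age vector.
#' @param alpha selection threshold (default .05).
#' @return list: `selected` (names), `p` (named vector), `n_screen`.
#' @export
screen_predictors <- function(features, outcome, alpha = 0.05) {
  features <- as.data.frame(features)
  stopifnot(nrow(features) >= 5L, nrow(features) == length(outcome))
  p <- vapply(names(features), function(nm) {
    f <- features[[nm]]
    if (stats::sd(f) == 0) {
      warning(sprintf("constant feature '%s' excluded", nm), call. = FALSE)
      return(NA_real_)
    }
    stats::summary.lm(stats::lm(outcome ~ f))$coefficients[2L, 4L]
  }, numeric(1L))
  selected <- names(p)[!is.na(p) & p < alpha]
  list(selected = selected, p = p, n_screen = length(selected))
}

#' Linear-model mediation analysis with bootstrap confidence intervals
#'
#' Product-of-coefficients mediation: `m ~ x` gives the path `a`, and
#' `y ~ x + m` gives the direct effect `c'` (ADE) and the path `b`; the
#' average causal mediation effect (ACME) is `a*b` and the total effect is
#' `c' + a*b`. Subjects are resampled with replacement `n_boot` times and
#' bias-corrected percentile intervals are formed for each effect.
#' Two-sided bootstrap p-values are twice the smaller tail proportion at 0,
#' floored at `1/n_boot`. Classification: "partial" when both the ACME and
#' ADE intervals exclude 0, "full" when only the ACME interval does,
#' otherwise "none".
#'
#' @param x exposure; `m` mediator; `y` outcome (complete triples, n >= 20).
#' @param m,y see above.
#' @param n_boot bootstrap draws (default 1000).
#' @param seed RNG seed.
#' @param conf confidence level (default .95, bias-corrected percentile).
#' @return object of class `bf_mediation` with `acme`, `ade`, `total`
#'   (each: estimate, ci, p) and `classification`.
#' @export
mediate <- function(x, m, y, n_boot = 1000L, seed = 1L, conf = 0.95) {
  n <- length(x)
  stopifnot(length(m) == n, length(y) == n, n >= 20L)
  if (anyNA(x) || anyNA(m) || anyNA(y)) stop("incomplete triples", call. = FALSE)
  if (abs(stats::cor(x, m)) > 0.999) {
    stop("exposure and mediator are collinear (|r| > 0.999)", call. = FALSE)
  }
  est <- mediation_point(x, m, y)
  Xm <- cbind(1, x)
  Xy <- cbind(1, x, m)
  boot <- matrix(0, n_boot, 3L,
                 dimnames = list(NULL, c("acme", "ade", "total")))
  with_seed(seed, {
    for (i in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      a <- stats::.lm.fit(Xm[idx, , drop = FALSE], m[idx])$coefficients[2L]
      cf <- stats::.lm.fit(Xy[idx, , drop = FALSE], y[idx])$coefficients
      boot[i, ] <- c(a * cf[3L], cf[2L], cf[2L] + a * cf[3L])
    }
  })
  one <- function(name) {
    b <- boot[, name]
    ci <- bc_ci(b, est[[name]], conf)
    p <- 2 * min(mean(b <= 0), mean(b >= 0))
    list(estimate = est[[name]], ci = ci,
         p = max(min(p, 1), 1 / n_boot))
  }
  acme <- one("acme"); ade <- one("ade"); total <- one("total")
  excl <- function(e) e$ci[1L] > 0 || e$ci[2L] < 0
  classification <- if (excl(acme) && excl(ade)) "partial"
  else if (excl(acme)) "full" else "none"
  structure(list(acme = acme, ade = ade, total = total, n = n,
                 n_boot = as.integer(n_boot), conf = conf,
                 classification = classification, seed = as.integer(seed)),
            class = "bf_mediation")
}

mediation_point <- function(x, m, y) {
  a <- stats::.lm.fit(cbind(1, x), m)$coefficients[2L]
  cf <- stats::.lm.fit(cbind(1, x, m), y)$coefficients
  list(acme = a * cf[3L], ade = cf[2L], total = cf[2L] + a * cf[3L])
}

# bias-corrected (BC, no acceleration) percentile interval
bc_ci <- function(boot, estimate, conf = 0.95) {
  prop <- mean(boot < estimate)
  prop <- min(max(prop, 1e-6), 1 - 1e-6)
  z0 <- stats::qnorm(prop)
  za <- stats::qnorm((1 + conf) / 2)
  lo <- stats::pnorm(2 * z0 - za)
  hi <- stats::pnorm(2 * z0 + za)
  unname(stats::quantile(boot, c(lo, hi), type = 7))
}

#' @export
print.bf_mediation <- function(x, ...) {
  f <- function(e, nm) sprintf("%s %.4f [%.4f, %.4f] p=%.3g", nm,
                               e$estimate, e$ci[1L], e$ci[2L], e$p)
  cat(sprintf("<bf_mediation> n=%d, %d bootstraps: %s; %s; %s; %s\n",
              x$n, x$n_boot, f(x$acme, "ACME"), f(x$ade, "ADE"),
              f(x$total, "total"), x$classification))
  invisible(x)
}

#' Run the mediation grid
#'
#' All exposure x mediator combinations against one outcome, with
#' Benjamini-Hochberg correction of the ACME p-values across the grid.
#'
#' @param exposures,mediators data.frames of candidate variables.
#' @param outcome age vector.
#' @param n_boot,seed,conf as in [mediate()].
#' @return data.frame: one row per (exposure, mediator) with effects, CIs,
#'   p-values, BH q-values and classification.
#' @export
mediation_grid <- function(exposures, mediators, outcome, n_boot = 1000L,
                           seed = 1L, conf = 0.95) {
  exposures <- as.data.frame(exposures)
  mediators <- as.data.frame(mediators)
  rows <- list()
  k <- 0L
  for (ex in names(exposures)) for (md in names(mediators)) {
    k <- k + 1L
    fit <- mediate(exposures[[ex]], mediators[[md]], outcome,
                   n_boot = n_boot, seed = derive_seed(seed, k), conf = conf)
    rows[[k]] <- data.frame(
      exposure = ex, mediator = md,
      acme = fit$acme$estimate, acme_lo = fit$acme$ci[1L],
      acme_hi = fit$acme$ci[2L], acme_p = fit$acme$p,
      ade = fit$ade$estimate, ade_lo = fit$ade$ci[1L],
      ade_hi = fit$ade$ci[2L], ade_p = fit$ade$p,
      total = fit$total$estimate, classification = fit$classification,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$acme_q <- bh_correct(out$acme_p)
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (wraps `p.adjust`), with input
#' validation.
#'
#' @param pvals p-values in \[0, 1\].
#' @return q-values, elementwise >= the input p-values.
#' @export
bh_correct <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' PCA of the stitched image + blood feature matrix
#'
#' Columns of the stitched matrix (256 image features + 14 blood features =
#' 270 at the defaults) are z-scored; constant columns are dropped with a
#' warning. Returns the first two principal components.
#'
#' @param embeddings image embeddings (n x p).
#' @param panel_features blood features (n x q).
#' @return list of class `bf_pca`: `loadings` (columns PC1, PC2), `scores`
#'   (n x 2), `explained` (variance fractions, all components),
#'   `input_dim`, `kept` (column names retained).
#' @export
pca_stitched <- function(embeddings, panel_features) {
  X <- cbind(as.matrix(embeddings), as.matrix(panel_features))
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
  stopifnot(nrow(X) >= 3L)
  input_dim <- ncol(X)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("%d constant column(s) dropped before PCA", sum(sds == 0)),
            call. = FALSE)
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  Z <- scale(X)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = pc$rotation[, 1:2, drop = FALSE],
                 scores = pc$x[, 1:2, drop = FALSE],
                 explained = expl, input_dim = input_dim,
                 kept = colnames(X)),
            class = "bf_pca")
}
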