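# Prediction-accuracy metrics, age-group breakdowns, the normality-gated
# correlation policy, and the pooled-error permutation test.

#' Mean absolute error of a prediction set
#'
#' @param predictions a [prediction_set()] (or any data.frame with
#'   `chronological` and `predicted` columns).
#' @return MAE in years.
#' @export
mae <- function(predictions) {
  if (NROW(predictions) == 0L) stop("empty prediction set", call. = FALSE)
  mean(abs(predictions$predicted - predictions$chronological))
}

#' Percent reduction of MAE
#'
#' `(mae_before - mae_after) / mae_before * 100`; negative values indicate
#' worsening.
#'
#' @param mae_before,mae_after MAEs in years; `mae_before` must be > 0.
#' @return reduction in percent.
#' @examples
#' reduction_of_mae(7.14, 4.78)  # 33.05
#' @export
reduction_of_mae <- function(mae_before, mae_after) {
  if (mae_before <= 0) stop("mae_before must be > 0", call. = FALSE)
  (mae_before - mae_after) / mae_before * 100
}

#' Accuracy metrics by age group
#'
#' Per bin: subject count, MAE, and the variance of the signed predictive
#' error (population definition by default). When `reference` is supplied
#' the percent reduction of MAE against it is added per bin.
#'
#' @param predictions a [prediction_set()].
#' @param edges age-bin edges, default `c(50, 60, 70, 85)` (left-closed
#'   bins, the last closed on the right).
#' @param reference optional second prediction set (the "before" model).
#' @param var_type `"population"` (divide by n) or `"sample"`.
#' @return data.frame: `group`, `n`, `mae`, `error_variance`, and
#'   `reduction_pct` when a reference is given.
#' @export
group_breakdown <- function(predictions, edges = c(50, 60, 70, 85),
                            reference = NULL,
                            var_type = c("population", "sample")) {
  var_type <- match.arg(var_type)
  grp <- age_group_of(predictions$chronological, edges)
  vfun <- function(e) {
    if (var_type == "population") mean((e - mean(e))^2) else stats::var(e)
  }
  levs <- levels(grp)
  out <- do.call(rbind, lapply(levs, function(g) {
    sel <- grp == g
    err <- predictions$predicted[sel] - predictions$chronological[sel]
    data.frame(group = g, n = sum(sel),
               mae = if (any(sel)) mean(abs(err)) else NA_real_,
               error_variance = if (sum(sel) >= 1L) vfun(err) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(reference)) {
    rgrp <- age_group_of(reference$chronological, edges)
    out$reduction_pct <- vapply(levs, function(g) {
      rsel <- rgrp == g
      if (!any(rsel) || is.na(out$mae[out$group == g])) return(NA_real_)
      rerr <- reference$predicted[rsel] - reference$chronological[rsel]
      reduction_of_mae(mean(abs(rerr)), out$mae[out$group == g])
    }, numeric(1L))
  }
  out
}

#' Correlation with the normality-gated method policy
#'
#' Shapiro-Wilk normality is assessed for each variable at `alpha`; if
#' either fails, Spearman's rank correlation is used, otherwise Pearson's.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @param alpha normality-test level (default .05).
#' @return list: `method` ("pearson"/"spearman"), `r`, `p` (two-sided),
#'   `normal_x`, `normal_y`.
#' @export
correlation_with_policy <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y), length(x) >= 4L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  nx <- stats::shapiro.test(x)$p.value >= alpha
  ny <- stats::shapiro.test(y)$p.value >= alpha
  method <- if (nx && ny) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  list(method = method, r = unname(ct$estimate), p = ct$p.value,
       normal_x = nx, normal_y = ny)
}

#' Permutation test of the difference in mean prediction errors
#'
#' The observed statistic is `mean(errors_a) - mean(errors_b)`. Both error
#' sets are pooled; each permutation reassigns the pooled values at random
#' to two groups of the original sizes and records the mean difference. The
#' null distribution consists of the `n_perm` permuted differences plus the
#' observed one (1,000 values at the default 999 permutations), and the
#' one-sided p-value is the rank of the observed difference in that set:
#' `p = #\{null >= observed\} / (n_perm + 1)`.
#'
#' @param errors_a,errors_b prediction errors of the two models (use
#'   absolute errors to test MAE improvement; `a` minus `b` positive means
#'   `a` is worse).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @param alternative `"greater"` (default, the top-5 percent reading),
#'   `"less"`, or `"two.sided"`.
#' @return object of class `bf_permutation`: `observed`, `null` (length
#'   `n_perm + 1`), `p`, `n_perm`, `alternative`, `seed`.
#' @export
permutation_test <- function(errors_a, errors_b, n_perm = 999L, seed = 1L,
                             alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(errors_a) == 0L || length(errors_b) == 0L) {
    stop("both error sets must be non-empty", call. = FALSE)
  }
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  na <- length(errors_a)
  pooled <- c(errors_a, errors_b)
  observed <- mean(errors_a) - mean(errors_b)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pooled), na)
    mean(pooled[idx]) - mean(pooled[-idx])
  }, numeric(1L)))
  null <- c(perm, observed)
  p <- switch(alternative,
    greater = sum(null >= observed) / (n_perm + 1L),
    less = sum(null <= observed) / (n_perm + 1L),
    two.sided = sum(abs(null) >= abs(observed)) / (n_perm + 1L))
  structure(list(observed = observed, null = null, p = p,
                 n_perm = as.integer(n_perm), alternative = alternative,
                 seed = as.integer(seed)),
            class = "bf_permutation")
}

#' @export
print.bf_permutation <- function(x, ...) {
  cat(sprintf("<bf_permutation> observed diff %.4f, p = %.4f (%s, %d permutations)\n",
              x$observed, x$p, x$alternative, x$n_perm))
  invisible(x)
}
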