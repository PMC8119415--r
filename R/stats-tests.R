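#' Kolmogorov-Smirnov normality test
#'
#' One-sample KS test of the values against a normal distribution with the
#' sample mean and SD (the convention of the platform's normality checks);
#' a Lilliefors-corrected p-value is available as an option.
#'
#' @param values Numeric vector, n >= 8, non-constant.
#' @param lilliefors Use the Lilliefors correction for estimated parameters.
#' @return Tibble with `statistic`, `p_value`, `method`, `n`.
#' @export
ks_normality <- function(values, lilliefors = FALSE) {
  values <- values[!is.na(values)]
  if (length(values) < 8) abort("need at least 8 values.")
  if (sd(values) == 0) abort("constant input; normality test undefined.")
  if (lilliefors) {
    ht <- nortest::lillie.test(values)
    tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
           method = "lilliefors", n = length(values))
  } else {
    ht <- suppressWarnings(ks.test(values, "pnorm", mean(values), sd(values)))
    tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
           method = "ks", n = length(values))
  }
}

#' Two-tailed t-test for a metric under treatment
#'
#' Standard two-tailed Student's t-test, paired by default (the platform
#' measures the same microtissues before and after exposure), returning the
#' mean difference used by the signature maps. A paired comparison with
#' zero-variance differences is degenerate and flagged rather than tested.
#'
#' @param before,after Numeric vectors; equal length when paired.
#' @param paired Paired test (default) or two-sample.
#' @return Tibble with `t`, `p_value`, `mean_diff` (after - before), `n`,
#'   `degenerate`.
#' @export
paired_metric_test <- function(before, after, paired = TRUE) {
  if (paired && length(before) != length(after)) {
    abort("paired test needs equal-length vectors.")
  }
  ok <- !is.na(before) & !is.na(after)
  if (paired) { before <- before[ok]; after <- after[ok] }
  n <- if (paired) length(before) else min(sum(!is.na(before)), sum(!is.na(after)))
  if (n < 2) abort("need at least 2 observations.")
  d <- after - before
  if (paired && sd(d) <= 1e-10 * max(abs(d), 1)) {
    return(tibble(t = NA_real_, p_value = if (all(d == 0)) 1 else NA_real_,
                  mean_diff = mean(d), n = n, degenerate = TRUE))
  }
  ht <- t.test(after, before, paired = paired, var.equal = !paired)
  tibble(t = unname(ht$statistic), p_value = ht$p.value,
         mean_diff = if (paired) mean(d) else mean(after, na.rm = TRUE) - mean(before, na.rm = TRUE),
         n = n, degenerate = FALSE)
}

#' Sample size to detect a relative change in a metric
#'
#' Smallest integer n at which a two-sided t-test at level `alpha` attains
#' the requested power against an effect `delta = rel_change * mean`,
#' computed by noncentral-t iteration ([stats::power.t.test()]). For the
#' paired design, `sd` is the SD of the within-unit differences.
#'
#' @param mean Metric mean (e.g. APD80, ms).
#' @param sd Metric SD at the design's unit level, same units as `mean`.
#' @param rel_change Relative change to detect, in (0, 1].
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @param design `"one_sample"` or `"paired"`.
#' @return Integer sample size (>= 2).
#' @export
sample_size_for_change <- function(mean, sd, rel_change, alpha = 0.05,
                                   power = 0.8,
                                   design = c("one_sample", "paired")) {
  design <- match.arg(design)
  if (sd <= 0) abort("`sd` must be > 0.")
  if (rel_change <= 0 || rel_change > 1) abort("`rel_change` must be in (0, 1].")
  delta <- rel_change * mean
  type <- if (design == "paired") "paired" else "one.sample"
  p2 <- power.t.test(n = 2, delta = delta, sd = sd, sig.level = alpha,
                     type = type, alternative = "two.sided")$power
  if (p2 >= power) return(2L) # n = 2 is the minimum for a variance estimate
  n <- power.t.test(delta = delta, sd = sd, sig.level = alpha, power = power,
                    type = type, alternative = "two.sided")$n
  as.integer(ceiling(n - 1e-9))
}

#' Per-dose triangulation-vs-APD_MxR slope comparison
#'
#' Fits, per dose, an ordinary least-squares regression of APD_tri on
#' APD_MxR over tissues, and tests each dose's slope against the control
#' slope with the two-slope Z statistic
#' `Z = (b_d - b_ctr) / sqrt(SE_d^2 + SE_ctr^2)` (two-sided normal p).
#' An increased slope under treatment is the hERG/I_Kr-block indicator.
#'
#' @param data Data frame with columns `dose`, `apd_mxr_ms`, `apd_tri_ms`
#'   (one row per tissue).
#' @param control Control dose label.
#' @return A tibble of class `"tri_mxr_slopes"` with per-dose `slope`,
#'   `intercept`, `se`, `n`, `z_vs_control`, `p_value` (`NA` for the control
#'   row and degenerate fits).
#' @export
tri_mxr_slopes <- function(data, control = 0) {
  stopifnot(all(c("dose", "apd_mxr_ms", "apd_tri_ms") %in% names(data)))
  if (!control %in% data$dose) abort("control dose not present in `data`.")
  fits <- data %>%
    filter(!is.na(.data$apd_mxr_ms), !is.na(.data$apd_tri_ms)) %>%
    group_by(.data$dose) %>%
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3 || sd(d$apd_mxr_ms) == 0) {
        return(tibble(slope = NA_real_, intercept = NA_real_, se = NA_real_,
                      n = nrow(d)))
      }
      fit <- lm(apd_tri_ms ~ apd_mxr_ms, data = d)
      sm <- summary(fit)$coefficients
      tibble(slope = sm[2, 1], intercept = sm[1, 1], se = sm[2, 2],
             n = nrow(d))
    }) %>%
    ungroup()
  ctr <- filter(fits, .data$dose == control)
  out <- fits %>%
    mutate(
      z_vs_control = ifelse(.data$dose == control, NA_real_,
                            (.data$slope - ctr$slope) /
                              sqrt(.data$se^2 + ctr$se^2)),
      p_value = 2 * pnorm(-abs(.data$z_vs_control))
    )
  structure(out, class = c("tri_mxr_slopes", class(tibble())),
            control = control)
}

#' @exportS3Method generics::tidy
tidy.tri_mxr_slopes <- function(x, ...) as_tibble(x)

#' @exportS3Method generics::glance
glance.tri_mxr_slopes <- function(x, ...) {
  ctr <- x[x$dose == attr(x, "control"), ]
  tibble(control_dose = attr(x, "control"), control_slope = ctr$slope,
         n_doses = nrow(x), n_significant = sum(x$p_value < 0.05, na.rm = TRUE))
}
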