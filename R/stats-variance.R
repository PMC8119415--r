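#' Nested variance components of a hierarchical APD dataset
#'
#' Decomposes APD variability across the platform's replicate levels with
#' the sequential-SD scheme the replicate analysis uses (plain SDs of means
#' at each nesting level, not a mixed-model fit):
#' * beat: SD across beats within each microtissue, averaged within batch,
#'   reported mean +/- SD across batches;
#' * tissue: SD of tissue means within each mold, averaged per batch,
#'   mean +/- SD across batches;
#' * mold: SD of mold means within each batch, mean +/- SD across batches;
#' * batch: SD of batch means — a single number with no dispersion of its
#'   own.
#'
#' @param data Data frame with columns `batch`, `mold`, `tissue`, `apd_ms`
#'   (one row per beat).
#' @return A tibble of class `"variance_components"` with columns `level`,
#'   `sd_ms` and `sd_of_sd_ms` (`NA` for the batch level and for levels with
#'   fewer than 2 units).
#' @export
variance_components <- function(data) {
  stopifnot(all(c("batch", "mold", "tissue", "apd_ms") %in% names(data)))
  safe_sd <- function(x) if (length(x) >= 2) sd(x) else NA_real_
  safe_mean <- function(x) {
    x <- x[!is.na(x)]
    if (length(x)) mean(x) else NA_real_
  }
  # beat level: per-tissue SD across beats -> per-batch mean -> across batches
  beat_b <- data %>%
    group_by(.data$batch, .data$mold, .data$tissue) %>%
    summarise(s = safe_sd(.data$apd_ms), .groups = "drop") %>%
    group_by(.data$batch) %>%
    summarise(s = safe_mean(.data$s), .groups = "drop")
  # tissue level: SD of tissue means within mold -> per-batch mean
  tis_b <- data %>%
    group_by(.data$batch, .data$mold, .data$tissue) %>%
    summarise(m = mean(.data$apd_ms), .groups = "drop") %>%
    group_by(.data$batch, .data$mold) %>%
    summarise(s = safe_sd(.data$m), .groups = "drop") %>%
    group_by(.data$batch) %>%
    summarise(s = safe_mean(.data$s), .groups = "drop")
  # mold level: SD of mold means within batch
  mold_b <- data %>%
    group_by(.data$batch, .data$mold) %>%
    summarise(m = mean(.data$apd_ms), .groups = "drop") %>%
    group_by(.data$batch) %>%
    summarise(s = safe_sd(.data$m), .groups = "drop")
  batch_means <- data %>%
    group_by(.data$batch) %>%
    summarise(m = mean(.data$apd_ms), .groups = "drop")
  lvl <- function(x) c(safe_mean(x), safe_sd(x[!is.na(x)]))
  out <- tibble(
    level = c("beat", "tissue", "mold", "batch"),
    sd_ms = c(lvl(beat_b$s)[1], lvl(tis_b$s)[1], lvl(mold_b$s)[1],
              safe_sd(batch_means$m)),
    sd_of_sd_ms = c(lvl(beat_b$s)[2], lvl(tis_b$s)[2], lvl(mold_b$s)[2],
                    NA_real_)
  )
  structure(out, class = c("variance_components", class(tibble())))
}

#' @exportS3Method generics::tidy
tidy.variance_components <- function(x, ...) as_tibble(x)

#' Empirical cumulative distribution curve
#'
#' Right-continuous empirical CDF evaluated at the sorted unique values,
#' as used for dose-wise APD distribution comparison (a wider distribution
#' shows as a shallower maximum slope).
#'
#' @param values Numeric vector (n >= 1).
#' @return Tibble with columns `value` and `cum_prob`.
#' @export
ecdf_curve <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) abort("need at least one value.")
  v <- sort(unique(values))
  tibble(value = v, cum_prob = ecdf(values)(v))
}

#' Restitution curve summary
#'
#' Per-cycle-length mean +/- SD of APD, ordered by cycle length, for
#' rate-dependence (restitution) analysis.
#'
#' @param data Data frame with columns `cycle_length_ms` and `apd_ms`.
#' @return Tibble of class `"restitution_curve"`: `cycle_length_ms`,
#'   `mean_apd_ms`, `sd_apd_ms`, `n`.
#' @export
restitution_curve <- function(data) {
  stopifnot(all(c("cycle_length_ms", "apd_ms") %in% names(data)))
  if (length(unique(data$cycle_length_ms)) < 1) abort("no cycle lengths.")
  out <- data %>%
    group_by(.data$cycle_length_ms) %>%
    summarise(mean_apd_ms = mean(.data$apd_ms),
              sd_apd_ms = if (dplyr::n() >= 2) sd(.data$apd_ms) else NA_real_,
              n = dplyr::n(), .groups = "drop") %>%
    arrange(.data$cycle_length_ms)
  structure(out, class = c("restitution_curve", class(tibble())))
}
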