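# Dose-response analytics: sigma-shift maps and mean-difference signatures.
#
# The dose table is a tidy tissue x dose x metric frame: one row per
# (tissue, dose, metric) with `value` and an `excitable` flag. Non-excitable
# tissues carry no metric values (rendered black in heatmaps).

check_dose_table <- function(table, control) {
  need <- c("tissue", "dose", "metric", "value", "excitable")
  stopifnot(all(need %in% names(table)))
  if (!control %in% table$dose) abort("control dose not present in the table.")
  invisible(table)
}

#' Per-tissue sigma-shift map across doses
#'
#' Expresses every tissue's metric value at every dose as its shift from the
#' control-group mean in units of the control-group SD:
#' `shift = (value - mean_control) / sd_control`, per metric. Cells of
#' non-excitable tissues are `NA` (displayed black). Metrics whose control
#' SD is zero are flagged and left `NA`.
#'
#' @param table Tidy dose table (columns `tissue`, `dose`, `metric`, `value`,
#'   `excitable`).
#' @param control Control dose label (default 0).
#' @return A tibble of class `"shift_map"`: `tissue`, `dose`, `metric`,
#'   `shift`, `excitable`; control statistics in attribute
#'   `"control_stats"`.
#' @export
sigma_shift_map <- function(table, control = 0) {
  check_dose_table(table, control)
  ctrl <- table %>%
    filter(.data$dose == control, .data$excitable, !is.na(.data$value)) %>%
    group_by(.data$metric) %>%
    summarise(mean_ctrl = mean(.data$value), sd_ctrl = sd(.data$value),
              n_ctrl = dplyr::n(), .groups = "drop")
  if (any(ctrl$n_ctrl < 2)) abort("need >= 2 excitable control tissues per metric.")
  if (any(ctrl$sd_ctrl == 0)) {
    warn(paste("zero control SD for metric(s):",
               paste(ctrl$metric[ctrl$sd_ctrl == 0], collapse = ", ")))
  }
  out <- table %>%
    left_join(ctrl, by = "metric") %>%
    mutate(shift = ifelse(.data$excitable & .data$sd_ctrl > 0,
                          (.data$value - .data$mean_ctrl) / .data$sd_ctrl,
                          NA_real_)) %>%
    select("tissue", "dose", "metric", "shift", "excitable")
  structure(out, class = c("shift_map", class(tibble())),
            control = control, control_stats = ctrl)
}

#' Dose-response signature map
#'
#' Per (metric, dose): the mean paired difference from control across
#' tissues, normalized by the metric's control SD (sigma_CTR), with
#' two-tailed paired t-test significance at p < 0.05. The sign encodes the
#' response direction (increase/decrease); the control column is exactly 0.
#' Pairs come from tissues excitable (with values) at both doses; cells
#' with fewer than 3 pairs are flagged and left `NA`.
#'
#' @inheritParams sigma_shift_map
#' @param adjust P-value adjustment method (default `"none"`, matching the
#'   per-comparison p < 0.05 convention; `"holm"` available).
#' @return A tibble of class `"signature_map"`: `metric`, `dose`,
#'   `effect_sigma`, `mean_diff`, `p_value`, `significant`, `n_pairs`.
#' @export
mean_difference_signature <- function(table, control = 0, adjust = "none") {
  check_dose_table(table, control)
  ctrl_vals <- table %>%
    filter(.data$dose == control, .data$excitable, !is.na(.data$value)) %>%
    select("tissue", "metric", ctrl_value = "value")
  sd_ctrl <- ctrl_vals %>%
    group_by(.data$metric) %>%
    summarise(sd_ctrl = sd(.data$ctrl_value), .groups = "drop")
  out <- table %>%
    filter(.data$excitable, !is.na(.data$value)) %>%
    dplyr::inner_join(ctrl_vals, by = c("tissue", "metric")) %>%
    left_join(sd_ctrl, by = "metric") %>%
    group_by(.data$metric, .data$dose) %>%
    dplyr::group_modify(function(d, key) {
      if (key$dose == control) {
        return(tibble(effect_sigma = 0, mean_diff = 0, p_value = NA_real_,
                      significant = FALSE, n_pairs = nrow(d)))
      }
      if (nrow(d) < 3 || d$sd_ctrl[1] == 0) {
        return(tibble(effect_sigma = NA_real_, mean_diff = NA_real_,
                      p_value = NA_real_, significant = NA, n_pairs = nrow(d)))
      }
      ht <- paired_metric_test(d$ctrl_value, d$value, paired = TRUE)
      tibble(effect_sigma = ht$mean_diff / d$sd_ctrl[1],
             mean_diff = ht$mean_diff, p_value = ht$p_value,
             significant = !is.na(ht$p_value) & ht$p_value < 0.05,
             n_pairs = nrow(d))
    }) %>%
    ungroup()
  if (adjust != "none") {
    padj <- p.adjust(out$p_value, method = adjust)
    out <- mutate(out, p_value = padj,
                  significant = !is.na(padj) & padj < 0.05)
  }
  structure(out, class = c("signature_map", class(tibble())),
            control = control)
}

#' Assemble a tidy dose table from per-tissue summaries
#'
#' Stacks per-tissue metric summaries recorded at several doses into the
#' tidy tissue x dose x metric table consumed by [sigma_shift_map()],
#' [mean_difference_signature()] and [tri_mxr_slopes()]. Non-excitable
#' tissues (excitability 0) contribute `NA` metric values.
#'
#' @param summaries Named list: one [summarize_tissues()] tibble per dose
#'   (names are dose labels, coerced with `as.numeric`).
#' @param metrics Metric mean columns to keep (default the eight-metric set).
#' @return Tidy dose table tibble.
#' @export
build_dose_table <- function(summaries,
                             metrics = c("stim_delay_ms", "rise_time_ms",
                                         "apd30_ms", "apd50_ms", "apd80_ms",
                                         "apd_mxr_ms", "apd_tri_ms")) {
  purrr::imap(summaries, function(sm, dose) {
    sm %>%
      select("tissue", "excitability_pct",
             all_of(paste0(metrics, "_mean"))) %>%
      dplyr::rename_with(~ sub("_mean$", "", .x)) %>%
      tidyr::pivot_longer(all_of(metrics), names_to = "metric",
                          values_to = "value") %>%
      mutate(dose = as.numeric(dose),
             excitable = .data$excitability_pct > 0) %>%
      select("tissue", "dose", "metric", "value", "excitable")
  }) %>% bind_rows()
}
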