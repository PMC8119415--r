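# Study-level statistics.

make_dose_table <- function(n_tissue = 35, doses = c(0, 1, 2), shift = 0,
                            seed = 1, metric = "apd80_ms") {
  set.seed(seed)
  base <- rnorm(n_tissue, 260, 30)
  purrr::map_dfr(doses, function(d) {
    tibble::tibble(tissue = seq_len(n_tissue), dose = d, metric = metric,
                   value = base + (d > 0) * shift * 30 + rnorm(n_tissue, 0, 5),
                   excitable = TRUE)
  })
}

test_that("variance components are zero for constant data and order-invariant", {
  d0 <- sample_hierarchical_apds(
    variance_spec(sd_beat = 0, sd_tissue = 0, sd_mold = 0, sd_batch = 0),
    seed = 1)
  vc0 <- variance_components(d0)
  expect_equal(vc0$sd_ms, rep(0, 4))
  d <- sample_hierarchical_apds(variance_spec(), seed = 5)
  vc1 <- variance_components(d)
  vc2 <- variance_components(d[sample(nrow(d)), ])
  expect_equal(vc1$sd_ms, vc2$sd_ms)
  expect_true(is.na(vc1$sd_of_sd_ms[4])) # batch level has no dispersion
})

test_that("variance components shift-invariant and scale equivariant", {
  d <- sample_hierarchical_apds(variance_spec(), seed = 6)
  vc <- variance_components(d)
  vc_shift <- variance_components(dplyr::mutate(d, apd_ms = apd_ms + 100))
  expect_equal(vc$sd_ms, vc_shift$sd_ms)
  vc_scale <- variance_components(dplyr::mutate(d, apd_ms = apd_ms * 3))
  expect_equal(vc_scale$sd_ms, 3 * vc$sd_ms)
})

test_that("KS normality is calibrated on normal data and detects bimodality", {
  set.seed(31)
  ok <- replicate(100, ks_normality(rnorm(105, 260, 40))$p_value > 0.05)
  expect_gte(mean(ok), 0.9)
  bim <- c(rnorm(100, -3), rnorm(100, 3))
  expect_lt(ks_normality(bim)$p_value, 0.01)
  # affine invariance of the statistic
  x <- rnorm(50)
  expect_equal(ks_normality(x)$statistic, ks_normality(5 + 2 * x)$statistic)
  expect_error(ks_normality(rep(1, 20)), "constant")
})

test_that("paired t-test handles identity, degeneracy and returns mean diff", {
  x <- rnorm(10)
  r <- paired_metric_test(x, x)
  expect_true(r$degenerate)
  expect_equal(r$p_value, 1)
  expect_equal(r$mean_diff, 0)
  r2 <- paired_metric_test(x, x + 10)
  expect_true(r2$degenerate) # constant shift: zero-variance differences
  expect_equal(r2$mean_diff, 10)
  set.seed(32)
  r3 <- paired_metric_test(rnorm(35, 260, 30), rnorm(35, 290, 30))
  expect_false(r3$degenerate)
  expect_lt(r3$p_value, 0.05)
})

test_that("sample size is monotone in effect size and power", {
  n_small <- sample_size_for_change(100, 10, 0.20)
  n_big <- sample_size_for_change(100, 10, 0.05)
  expect_lte(n_small, n_big)
  n_p80 <- sample_size_for_change(100, 10, 0.10, power = 0.80)
  n_p95 <- sample_size_for_change(100, 10, 0.10, power = 0.95)
  expect_lte(n_p80, n_p95)
  # overwhelming effect needs only the minimum n for a variance estimate
  expect_equal(sample_size_for_change(100, 0.01, 1), 2L)
  expect_error(sample_size_for_change(100, 10, 0), "rel_change")
})

test_that("sigma-shift control column self-normalizes to mean 0, SD 1", {
  tab <- make_dose_table()
  sm <- sigma_shift_map(tab, control = 0)
  ctr <- dplyr::filter(sm, dose == 0)
  expect_equal(mean(ctr$shift), 0, tolerance = 1e-10)
  expect_equal(sd(ctr$shift), 1, tolerance = 1e-10)
})

test_that("a value 2 control SDs above the control mean maps to +2", {
  tab <- make_dose_table(doses = c(0, 1))
  st <- attr(sigma_shift_map(tab, control = 0), "control_stats")
  tab$value[tab$dose == 1][1] <- st$mean_ctrl + 2 * st$sd_ctrl
  sm <- sigma_shift_map(tab, control = 0)
  expect_equal(dplyr::filter(sm, dose == 1, tissue == 1)$shift, 2,
               tolerance = 1e-10)
})

test_that("non-excitable cells are unavailable in the shift map", {
  tab <- make_dose_table(doses = c(0, 1))
  tab$excitable[tab$dose == 1 & tab$tissue == 3] <- FALSE
  sm <- sigma_shift_map(tab, control = 0)
  expect_true(is.na(dplyr::filter(sm, dose == 1, tissue == 3)$shift))
})

test_that("signature map: control column 0; a +1 sigma shift is significant", {
  tab <- make_dose_table(doses = c(0, 1), shift = 0)
  # engineer a +1 control-SD mean shift at dose 1 (small per-tissue noise)
  st <- attr(sigma_shift_map(tab, control = 0), "control_stats")
  set.seed(42)
  tab$value[tab$dose == 1] <- tab$value[tab$dose == 0] + st$sd_ctrl +
    rnorm(sum(tab$dose == 1), 0, 0.01 * st$sd_ctrl)
  sig <- mean_difference_signature(tab, control = 0)
  ctr <- dplyr::filter(sig, dose == 0)
  expect_equal(ctr$effect_sigma, 0)
  d1 <- dplyr::filter(sig, dose == 1)
  expect_equal(d1$effect_sigma, 1, tolerance = 0.01)
  expect_true(d1$significant)
})

test_that("a biphasic dose series yields (+, ~0, -) signature signs", {
  set.seed(41)
  base <- rnorm(35, 260, 30)
  mk <- function(d, delta) tibble::tibble(
    tissue = 1:35, dose = d, metric = "apd80_ms",
    value = base + delta + rnorm(35, 0, 3), excitable = TRUE)
  tab <- dplyr::bind_rows(mk(0, 0), mk(1, 40), mk(2, 0), mk(3, -40))
  sig <- mean_difference_signature(tab, control = 0)
  expect_gt(dplyr::filter(sig, dose == 1)$effect_sigma, 0)
  expect_true(dplyr::filter(sig, dose == 1)$significant)
  expect_false(dplyr::filter(sig, dose == 2)$significant)
  expect_lt(dplyr::filter(sig, dose == 3)$effect_sigma, 0)
  expect_true(dplyr::filter(sig, dose == 3)$significant)
})

test_that("ecdf curve is right-continuous and translates with its input", {
  cv <- ecdf_curve(c(1, 2, 3))
  expect_equal(cv$cum_prob[cv$value == 2], 2 / 3)
  x <- rnorm(50)
  c1 <- ecdf_curve(x)
  c2 <- ecdf_curve(x + 50)
  expect_equal(c2$value, c1$value + 50)
  expect_equal(c2$cum_prob, c1$cum_prob)
})

test_that("restitution summary orders cycle lengths and handles edge cases", {
  d <- tibble::tibble(cycle_length_ms = rep(c(2000, 800, 1000), each = 3),
                      apd_ms = rep(c(265, 255, 260), each = 3) + rep(c(-1, 0, 1), 3))
  rc <- restitution_curve(d)
  expect_equal(rc$cycle_length_ms, c(800, 1000, 2000))
  expect_true(all(diff(rc$mean_apd_ms) > 0))
  one <- restitution_curve(d[d$cycle_length_ms == 800, ])
  expect_equal(nrow(one), 1)
  flat <- restitution_curve(tibble::tibble(
    cycle_length_ms = rep(c(800, 1000), each = 2), apd_ms = 250))
  expect_true(all(flat$mean_apd_ms == 250))
})

test_that("identical point clouds give slope Z = 0, p = 1", {
  set.seed(51)
  x <- rnorm(20, 300, 40)
  y <- 0.2 * x + rnorm(20, 0, 5)
  d <- dplyr::bind_rows(
    tibble::tibble(dose = 0, apd_mxr_ms = x, apd_tri_ms = y),
    tibble::tibble(dose = 1, apd_mxr_ms = x, apd_tri_ms = y))
  s <- tri_mxr_slopes(d, control = 0)
  expect_equal(s$z_vs_control[s$dose == 1], 0)
  expect_equal(s$p_value[s$dose == 1], 1)
  expect_true(is.na(s$z_vs_control[s$dose == 0]))
})

test_that("degenerate slope fits are flagged rather than fitted", {
  d <- tibble::tibble(dose = rep(c(0, 1), each = 5),
                      apd_mxr_ms = c(rnorm(5, 300, 10), rep(300, 5)),
                      apd_tri_ms = rnorm(10, 50, 5))
  s <- tri_mxr_slopes(d, control = 0)
  expect_true(is.na(s$slope[s$dose == 1]))
})

test_that("tidy and glance methods return tibbles with fit metadata", {
  set.seed(52)
  d <- purrr::map_dfr(0:2, function(dd) tibble::tibble(
    dose = dd, apd_mxr_ms = rnorm(10, 300, 30),
    apd_tri_ms = rnorm(10, 50, 8)))
  s <- tri_mxr_slopes(d, control = 0)
  td <- generics::tidy(s)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("slope", "se", "z_vs_control") %in% names(td)))
  gl <- generics::glance(s)
  expect_equal(gl$control_dose, 0)
  expect_equal(gl$n_doses, 3)
})
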