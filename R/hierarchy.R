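#' Specification for nested hierarchical APD data
#'
#' Describes the four-level replicate structure of the microtissue platform:
#' beats within microtissues (technical replicates), microtissues within
#' molds, molds within batches (biological replicates) and batches
#' (experimental replicates). Defaults follow the lactate-purified study
#' conditions: grand mean APD80 259 ms with level SDs 6.4 (beat), 36.1
#' (tissue), 31.8 (mold) and 19.3 ms (batch), at 4 batches x 3 molds x
#' 35 tissues x 5 beats.
#'
#' @param grand_mean_apd Grand mean APD, ms.
#' @param sd_beat,sd_tissue,sd_mold,sd_batch Level SDs, ms (>= 0).
#' @param n_batches,n_molds_per_batch,n_tissues_per_mold,n_beats_per_tissue
#'   Nesting sizes (>= 1).
#' @return A list of class `"variance_spec"`.
#' @export
variance_spec <- function(grand_mean_apd = 259, sd_beat = 6.4, sd_tissue = 36.1,
                          sd_mold = 31.8, sd_batch = 19.3, n_batches = 4,
                          n_molds_per_batch = 3, n_tissues_per_mold = 35,
                          n_beats_per_tissue = 5) {
  sds <- c(sd_beat, sd_tissue, sd_mold, sd_batch)
  ns <- c(n_batches, n_molds_per_batch, n_tissues_per_mold, n_beats_per_tissue)
  if (any(sds < 0)) abort("all SDs must be >= 0.")
  if (any(ns < 1)) abort("all counts must be >= 1.")
  structure(
    list(grand_mean_apd = grand_mean_apd, sd_beat = sd_beat,
         sd_tissue = sd_tissue, sd_mold = sd_mold, sd_batch = sd_batch,
         n_batches = n_batches, n_molds_per_batch = n_molds_per_batch,
         n_tissues_per_mold = n_tissues_per_mold,
         n_beats_per_tissue = n_beats_per_tissue),
    class = "variance_spec"
  )
}

#' Sample a nested hierarchical APD dataset
#'
#' Draws `APD(b,m,t,k) = grand_mean + B_b + M_bm + T_bmt + eps_bmtk` with
#' independent normal effects at the stated SDs, reproducibly under `seed`.
#'
#' @param spec A [variance_spec()] object.
#' @param seed Integer seed.
#' @return Tibble with columns `batch`, `mold`, `tissue`, `beat`, `apd_ms`.
#' @export
sample_hierarchical_apds <- function(spec = variance_spec(), seed = 1) {
  stopifnot(inherits(spec, "variance_spec"))
  set.seed(seed)
  nb <- spec$n_batches; nm <- spec$n_molds_per_batch
  nt <- spec$n_tissues_per_mold; nk <- spec$n_beats_per_tissue
  B <- rnorm(nb, 0, spec$sd_batch)
  M <- rnorm(nb * nm, 0, spec$sd_mold)
  Tt <- rnorm(nb * nm * nt, 0, spec$sd_tissue)
  eps <- rnorm(nb * nm * nt * nk, 0, spec$sd_beat)
  df <- tidyr::expand_grid(batch = seq_len(nb), mold = seq_len(nm),
                           tissue = seq_len(nt), beat = seq_len(nk))
  i_m <- (df$batch - 1) * nm + df$mold
  i_t <- (i_m - 1) * nt + df$tissue
  i_k <- (i_t - 1) * nk + df$beat
  mutate(df, apd_ms = spec$grand_mean_apd + B[.data$batch] + M[i_m] +
           Tt[i_t] + eps[i_k])
}
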