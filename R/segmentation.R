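# Movie -> per-microtissue traces: spectral active-pixel detection,
# thresholding, 8-connected grouping, size filtering, signal averaging.

#' Pacing-band spectral activity map
#'
#' Scores every pixel by the fraction of its (detrended) temporal power
#' spectrum lying in narrow bands around the pacing frequency and its first
#' three harmonics (+/- 1 frequency bin each), relative to total power
#' excluding the zero-frequency bin. Pixels carrying paced APs concentrate
#' power in those bands; background pixels do not. Scores lie in \[0, 1\].
#'
#' @param movie A `movie_stack` (list with `frames` T x H x W and
#'   `frame_rate_hz`), e.g. from [render_movie()] or [read_movie_tiff()].
#' @param pacing_freq_hz Pacing frequency, Hz.
#' @param n_harmonics Number of harmonics above the fundamental to include.
#' @param band_halfwidth_bins Half-width of each band in frequency bins.
#' @return An H x W numeric matrix of class `"activity_map"` with attributes
#'   `pacing_freq_hz`.
#' @export
pixel_activity <- function(movie, pacing_freq_hz = 0.5, n_harmonics = 3,
                           band_halfwidth_bins = 1) {
  frames <- movie$frames
  fs <- movie$frame_rate_hz
  T_ <- dim(frames)[1]; H <- dim(frames)[2]; W <- dim(frames)[3]
  dur_s <- T_ / fs
  if (dur_s < 2 / pacing_freq_hz) {
    abort("recording shorter than 2 pacing periods; frequency resolution insufficient.")
  }
  n_half <- floor(T_ / 2) # one-sided bins, DC excluded
  df_hz <- fs / T_
  band_bins <- unique(unlist(lapply(seq_len(1 + n_harmonics), function(h) {
    k <- round(h * pacing_freq_hz / df_hz)
    (k - band_halfwidth_bins):(k + band_halfwidth_bins)
  })))
  band_bins <- band_bins[band_bins >= 1 & band_bins <= n_half]
  # linear detrend projections (shared across pixels)
  tt <- seq_len(T_)
  tt_c <- tt - mean(tt)
  ss <- sum(tt_c^2)
  x <- matrix(frames, nrow = T_) # T x (H*W), column-major over (H, W)
  score <- numeric(H * W)
  chunk <- 512L
  for (j0 in seq(1L, ncol(x), by = chunk)) {
    j <- j0:min(j0 + chunk - 1L, ncol(x))
    xc <- x[, j, drop = FALSE]
    mu <- colMeans(xc)
    slope <- colSums(xc * tt_c) / ss
    xc <- xc - rep(mu, each = T_) - outer(tt_c, slope)
    pw <- Mod(mvfft(xc))^2
    tot <- colSums(pw[1 + seq_len(n_half), , drop = FALSE])
    bnd <- colSums(pw[1 + band_bins, , drop = FALSE])
    score[j] <- ifelse(tot > 0, bnd / tot, 0)
  }
  structure(matrix(pmin(pmax(score, 0), 1), H, W),
            class = "activity_map", pacing_freq_hz = pacing_freq_hz)
}

# 8-connected component labelling of a logical matrix (BFS; deterministic,
# components numbered in first-encounter raster order).
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  off <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  off <- off[!(off[, 1] == 0 & off[, 2] == 0), ]
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    queue <- matrix(c(r0, c0), 1, 2)
    lab[r0, c0] <- nxt
    while (nrow(queue)) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      nb <- cbind(p[1] + off[, 1], p[2] + off[, 2])
      ok <- nb[, 1] >= 1 & nb[, 1] <= H & nb[, 2] >= 1 & nb[, 2] <= W
      nb <- nb[ok, , drop = FALSE]
      inm <- mask[nb] & lab[nb] == 0L
      if (any(inm)) {
        nb <- nb[inm, , drop = FALSE]
        lab[nb] <- nxt
        queue <- rbind(queue, nb)
      }
    }
  }
  lab
}

#' Segment microtissue regions from an activity map
#'
#' Binarizes the activity map (Otsu threshold by default, or a fixed value),
#' labels 8-connected components, fills single-pixel holes, discards
#' components not strictly larger than `min_pixels`, and orders the retained
#' regions by centroid in row-major order. Components touching the field
#' border are retained.
#'
#' @param activity An `"activity_map"` matrix from [pixel_activity()].
#' @param min_pixels Strict minimum area: components with area
#'   `<= min_pixels` are discarded (default 60, i.e. only regions greater
#'   than 60 pixels are analysed).
#' @param threshold `"otsu"` or a numeric fixed threshold in \[0, 1\].
#' @return A tibble of class `"tissue_rois"` with columns `label`, `area_px`,
#'   `centroid_r`, `centroid_c`, and the relabelled H x W label image in
#'   attribute `"labels"` (0 = background). An empty tibble when no
#'   component survives.
#' @export
segment_rois <- function(activity, min_pixels = 60, threshold = "otsu") {
  if (!all(is.finite(activity))) abort("activity map must be finite.")
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(matrix(activity, nrow(activity)), range = c(0, 1))
  } else if (is.numeric(threshold)) threshold else {
    abort("`threshold` must be \"otsu\" or a number.")
  }
  mask <- activity > thr
  lab <- label_components(mask)
  # fill single-pixel holes: background pixels whose 4-neighbours all share
  # one component label
  H <- nrow(lab); W <- ncol(lab)
  holes <- which(lab == 0L, arr.ind = TRUE)
  for (i in seq_len(nrow(holes))) {
    r <- holes[i, 1]; c <- holes[i, 2]
    if (r == 1 || r == H || c == 1 || c == W) next
    nb <- c(lab[r - 1, c], lab[r + 1, c], lab[r, c - 1], lab[r, c + 1])
    if (all(nb > 0L) && length(unique(nb)) == 1L) lab[r, c] <- nb[1]
  }
  sizes <- tabulate(lab)
  keep <- which(sizes > min_pixels) # strictly greater
  out_lab <- matrix(0L, H, W)
  rows <- purrr::map(keep, function(k) {
    px <- which(lab == k, arr.ind = TRUE)
    tibble(area_px = nrow(px), centroid_r = mean(px[, 1]),
           centroid_c = mean(px[, 2]), old = k)
  }) %>% bind_rows()
  if (!nrow(rows)) {
    return(structure(tibble(label = integer(), area_px = integer(),
                            centroid_r = numeric(), centroid_c = numeric()),
                     class = c("tissue_rois", class(tibble())),
                     labels = out_lab, threshold = thr))
  }
  rows <- rows %>%
    arrange(.data$centroid_r, .data$centroid_c) %>%
    mutate(label = dplyr::row_number())
  for (i in seq_len(nrow(rows))) out_lab[lab == rows$old[i]] <- rows$label[i]
  structure(select(rows, "label", "area_px", "centroid_r", "centroid_c"),
            class = c("tissue_rois", class(tibble())),
            labels = out_lab, threshold = thr)
}

#' Extract per-tissue averaged voltage-proxy traces
#'
#' Averages raw intensities over each region's pixels per frame, corrects the
#' dye polarity (negating when inverted), and normalizes to Delta-F/F using
#' F0 = the mean of the lowest-quartile samples of the polarity-corrected
#' averaged trace, so diastole sits near 0 and the upstroke is positive.
#'
#' @param movie A `movie_stack`.
#' @param rois A `"tissue_rois"` object from [segment_rois()], or an H x W
#'   integer label matrix.
#' @param dye_polarity `"inverted"` or `"direct"`; defaults to the movie's
#'   own polarity when recorded, else `"inverted"`.
#' @return Long tibble with columns `tissue`, `time_ms`, `df_f`, and a named
#'   `n_pixels` attribute (pixels averaged per tissue).
#' @export
extract_traces <- function(movie, rois, dye_polarity = NULL) {
  labels <- if (is.matrix(rois)) rois else attr(rois, "labels")
  if (is.null(dye_polarity)) {
    dye_polarity <- if (!is.null(movie$dye_polarity)) movie$dye_polarity else "inverted"
  }
  frames <- movie$frames
  T_ <- dim(frames)[1]
  t_ms <- (seq_len(T_) - 1) * 1000 / movie$frame_rate_hz
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids)) abort("no regions to extract.")
  flat <- matrix(frames, nrow = T_)
  npx <- setNames(integer(length(ids)), ids)
  out <- purrr::map(ids, function(k) {
    cols <- which(labels == k)
    if (!length(cols)) abort("empty region.")
    avg <- rowMeans(flat[, cols, drop = FALSE])
    if (dye_polarity == "inverted") avg <- -avg
    qs <- sort(avg)[seq_len(max(1L, floor(length(avg) / 4)))]
    f0 <- mean(qs)
    # baseline fluorescence must be a positive count (negative of it when the
    # polarity correction negated the trace)
    bad <- if (dye_polarity == "inverted") f0 >= 0 else f0 <= 0
    if (bad || abs(f0) < .Machine$double.eps) {
      abort("zero or negative baseline F0; corrupt input.")
    }
    npx[as.character(k)] <<- length(cols)
    tibble(tissue = k, time_ms = t_ms, df_f = (avg - f0) / abs(f0))
  }) %>% bind_rows()
  attr(out, "n_pixels") <- npx
  out
}
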