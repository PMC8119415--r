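# Deterministic readers/writers for the pipeline's artifacts.
# Conventions: times in ms, frequencies in Hz; CSV for tables, JSON sidecars
# for metadata, YAML for run configuration. Every writer embeds a schema
# version so files are self-describing.

SCHEMA_VERSION <- "1.0"

#' Write a movie stack as multi-page TIFF with a JSON sidecar
#'
#' Frames are stored as 16-bit pages (counts are divided by 65535 for the
#' TIFF container and restored on read, so integer count data round-trips
#' bit-identically). The sidecar records frame rate, pixel size, dye
#' polarity and schema version.
#'
#' @param movie A `movie_stack` (list with `frames` T x H x W,
#'   `frame_rate_hz`, `pixel_size_um`, `dye_polarity`).
#' @param tiff_path,sidecar_path Output paths; the sidecar defaults to
#'   `<tiff_path>.json`.
#' @return `tiff_path`, invisibly.
#' @export
write_movie_tiff <- function(movie, tiff_path,
                             sidecar_path = paste0(tiff_path, ".json")) {
  frames <- movie$frames
  if (any(frames < 0) || any(frames > 65535)) {
    abort("frame intensities must lie in [0, 65535] for 16-bit storage.")
  }
  pages <- purrr::map(seq_len(dim(frames)[1]), function(i) {
    matrix(round(frames[i, , ]) / 65535, dim(frames)[2], dim(frames)[3])
  })
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16, compression = "none")
  meta <- list(schema_version = SCHEMA_VERSION,
               frame_rate_hz = movie$frame_rate_hz,
               pixel_size_um = movie$pixel_size_um,
               dye_polarity = movie$dye_polarity %||% "inverted",
               n_frames = dim(frames)[1],
               height_px = dim(frames)[2], width_px = dim(frames)[3])
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a movie stack from multi-page TIFF plus JSON sidecar
#'
#' @param tiff_path Multi-page TIFF (>= 2 pages, identical page shapes).
#' @param sidecar_path JSON sidecar; must name `frame_rate_hz`.
#' @return A `movie_stack` list with `frames` (T x H x W, camera counts),
#'   `frame_rate_hz`, `pixel_size_um`, `dye_polarity`.
#' @export
read_movie_tiff <- function(tiff_path, sidecar_path = paste0(tiff_path, ".json")) {
  if (!file.exists(sidecar_path)) abort("sidecar JSON not found.")
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(meta$frame_rate_hz)) abort("sidecar is missing `frame_rate_hz`.")
  pages <- tiff::readTIFF(tiff_path, all = TRUE, as.is = FALSE)
  if (length(pages) < 2) abort("movie must have at least 2 pages.")
  shp <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1)))) {
    abort("TIFF page shapes differ.")
  }
  frames <- array(0, dim = c(length(pages), shp[1], shp[2]))
  for (i in seq_along(pages)) frames[i, , ] <- round(pages[[i]] * 65535)
  structure(list(frames = frames,
                 frame_rate_hz = meta$frame_rate_hz,
                 pixel_size_um = meta$pixel_size_um %||% NA_real_,
                 dye_polarity = meta$dye_polarity %||% "inverted"),
            class = "movie_stack")
}

#' Write / read per-tissue traces as CSV
#'
#' Wide CSV: a strictly increasing `time_ms` column plus one column per
#' tissue (`tissue_<label>`). Full float precision (shortest round-trip
#' representation), stable column order.
#'
#' @param traces Long tibble (`tissue`, `time_ms`, `df_f`).
#' @param path CSV path.
#' @return `path` invisibly (writer); long trace tibble (reader).
#' @export
write_traces <- function(traces, path) {
  wide <- traces %>%
    mutate(tissue = paste0("tissue_", .data$tissue)) %>%
    tidyr::pivot_wider(names_from = "tissue", values_from = "df_f") %>%
    arrange(.data$time_ms)
  if (anyDuplicated(names(wide))) abort("duplicate tissue columns.")
  readr::write_csv(wide, path)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  wide <- readr::read_csv(path, show_col_types = FALSE)
  if (anyDuplicated(names(wide))) abort("duplicate tissue columns.")
  if (!"time_ms" %in% names(wide)) abort("traces CSV needs a `time_ms` column.")
  if (is.unsorted(wide$time_ms, strictly = TRUE)) {
    abort("`time_ms` must be strictly increasing.")
  }
  cols <- setdiff(names(wide), "time_ms")
  if (!length(cols)) {
    warn("empty trace table.")
    return(tibble(tissue = integer(), time_ms = numeric(), df_f = numeric()))
  }
  wide %>%
    tidyr::pivot_longer(all_of(cols), names_to = "tissue",
                        values_to = "df_f") %>%
    mutate(tissue = as.integer(sub("^tissue_", "", .data$tissue))) %>%
    select("tissue", "time_ms", "df_f") %>%
    arrange(.data$tissue, .data$time_ms)
}

#' Read / write a stimulation protocol as JSON
#'
#' When `pulse_times_ms` is present it wins; otherwise the pulse train is
#' derived from `cycle_length_ms` and `first_pulse_ms` over
#' `recording_duration_ms`.
#'
#' @param path JSON path.
#' @return A [stim_protocol()] object (reader); `path` invisibly (writer).
#' @export
read_protocol <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(js$cycle_length_ms) && is.null(js$pulse_times_ms)) {
    abort("protocol JSON needs `cycle_length_ms` or `pulse_times_ms`.")
  }
  stim_protocol(
    cycle_length_ms = js$cycle_length_ms %||% 2000,
    first_pulse_ms = js$first_pulse_ms %||% 500,
    pulse_duration_ms = js$pulse_duration_ms %||% 4,
    recording_duration_ms = js$recording_duration_ms %||% 10000,
    pulse_times_ms = js$pulse_times_ms
  )
}

#' @rdname read_protocol
#' @param protocol A [stim_protocol()] object.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "stim_protocol"))
  jsonlite::write_json(
    c(list(schema_version = SCHEMA_VERSION), unclass(protocol)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' All pipeline tunables with their defaults; unknown keys are rejected so
#' typos cannot silently fall back to defaults.
#'
#' @param path YAML path (optional; `NULL` returns pure defaults).
#' @return Named list of resolved settings.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(
    pacing_freq_hz = 0.5, min_pixels = 60, threshold = "otsu",
    capture_window_ms = 300, capture_amp_frac = 0.5, smooth_window_ms = 5,
    mxr_smooth_window_ms = 11, ead_min_amp_frac = 0.05,
    ead_min_duration_ms = 20, dye_polarity = "inverted", seed = 1
  )
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  }
  utils::modifyList(defaults, user)
}
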