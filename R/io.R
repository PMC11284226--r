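#' Read a fluorescence time-lapse movie
#'
#' Reads a multi-page 8-bit grayscale TIFF into a `fluor_movie`: an integer
#' array with dimensions rows x cols x frames and pixel values in [0, 255],
#' with the frame interval attached from the configuration.
#'
#' @param path Multi-page grayscale TIFF file.
#' @param frame_interval_s Frame interval in seconds.
#' @return A `fluor_movie` object.
#' @export
read_movie <- function(path, frame_interval_s = neuract_config()$calcium$frame_interval_s) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(!vapply(pages, function(p) length(dim(p)) == 2L, logical(1)))) {
    abort("movie must be grayscale: found multi-channel (e.g. RGB) pages")
  }
  dims <- vapply(pages, dim, integer(2))
  if (ncol(dims) > 1 && any(dims[, -1, drop = FALSE] != dims[, 1])) {
    abort("ragged stack: all frames must share the same dimensions")
  }
  arr <- array(0L, dim = c(dims[1, 1], dims[2, 1], length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- as.integer(round(pages[[i]] * 255))
  new_fluor_movie(arr, frame_interval_s)
}

new_fluor_movie <- function(pixels, frame_interval_s) {
  stopifnot(length(dim(pixels)) == 3L, frame_interval_s > 0)
  if (min(pixels) < 0 || max(pixels) > 255) {
    abort("pixel values must lie in [0, 255]")
  }
  structure(list(pixels = pixels, frame_interval_s = frame_interval_s),
            class = "fluor_movie")
}

#' @export
print.fluor_movie <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fluor_movie> %d x %d px, %d frames @ %.3g s/frame (%.3g s)\n",
              d[1], d[2], d[3], x$frame_interval_s, d[3] * x$frame_interval_s))
  invisible(x)
}

#' @rdname read_movie
#' @param movie A `fluor_movie`.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "fluor_movie"))
  pages <- lapply(seq_len(dim(movie$pixels)[3]),
                  function(i) movie$pixels[, , i] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}

#' Read a raw extracellular recording
#'
#' The recording is stored as a flat little-endian float32 file holding the
#' channels one after another (all samples of channel 1, then channel 2, ...),
#' with a JSON sidecar carrying `sampling_rate_hz`, `channel_ids` and an
#' optional `compartment_map` (channel id -> compartment label; channels
#' without an entry are assigned `"default"`).
#'
#' @param data_path Flat float32 voltage file (microvolts).
#' @param meta_path JSON sidecar path.
#' @return A `raw_recording`: channels x samples matrix plus metadata.
#' @export
read_recording <- function(data_path, meta_path) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$sampling_rate_hz)) abort("sidecar missing sampling_rate_hz")
  if (is.null(meta$channel_ids)) abort("sidecar missing channel_ids")
  ids <- as.character(meta$channel_ids)
  if (anyDuplicated(ids)) abort("channel_ids must be unique")
  n_bytes <- file.size(data_path)
  vals <- readBin(data_path, what = "numeric", size = 4L,
                  n = n_bytes %/% 4L, endian = "little")
  if (length(vals) %% length(ids) != 0) {
    abort(sprintf("element count %d not divisible by %d channels",
                  length(vals), length(ids)))
  }
  samples <- matrix(vals, nrow = length(ids), byrow = TRUE,
                    dimnames = list(ids, NULL))
  cmap <- setNames(rep("default", length(ids)), ids)
  if (!is.null(meta$compartment_map)) {
    cm <- unlist(meta$compartment_map)
    cmap[names(cm)] <- as.character(cm)
  }
  new_raw_recording(samples, meta$sampling_rate_hz, cmap)
}

new_raw_recording <- function(samples, sampling_rate_hz, compartment_map = NULL) {
  stopifnot(is.matrix(samples), sampling_rate_hz > 0)
  if (is.null(rownames(samples))) {
    rownames(samples) <- paste0("ch", seq_len(nrow(samples)))
  }
  if (is.null(compartment_map)) {
    compartment_map <- setNames(rep("default", nrow(samples)), rownames(samples))
  }
  structure(list(samples = samples,
                 sampling_rate_hz = sampling_rate_hz,
                 channel_ids = rownames(samples),
                 compartment_map = compartment_map),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz (%.3g s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate_hz,
              ncol(x$samples) / x$sampling_rate_hz))
  invisible(x)
}

#' @rdname read_recording
#' @param recording A `raw_recording`.
#' @export
write_recording <- function(recording, data_path, meta_path) {
  stopifnot(inherits(recording, "raw_recording"))
  writeBin(as.numeric(t(recording$samples)), data_path, size = 4L,
           endian = "little")
  jsonlite::write_json(list(sampling_rate_hz = recording$sampling_rate_hz,
                            channel_ids = recording$channel_ids,
                            compartment_map = as.list(recording$compartment_map)),
                       meta_path, auto_unbox = TRUE, digits = NA)
  invisible(data_path)
}

table_schemas <- list(
  traces = character(0), # time_s plus >= 1 roi_* column, checked specially
  spikes = c("channel", "spike_time_s"),
  rates = c("network_id", "group", "condition", "rate_hz"),
  ct = c("sample", "target", "ct")
)

#' Read a typed CSV table
#'
#' Reads one of the pipeline's tabular inputs and validates its schema.
#' Missing cells are preserved as `NA`, never silently coerced to zero.
#'
#' @param path CSV file with a header row.
#' @param schema One of `"traces"` (`time_s` plus `roi_*` columns),
#'   `"spikes"` (`channel`, `spike_time_s`), `"rates"` (`network_id`, `group`,
#'   `condition`, `rate_hz`, extra columns such as `layout`/`compartment`
#'   kept), or `"ct"` (`sample`, `target`, `ct`).
#' @return A tibble with typed columns.
#' @export
read_table <- function(path, schema = c("traces", "spikes", "rates", "ct")) {
  schema <- match.arg(schema)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (schema == "traces") {
    roi_cols <- grep("^roi_", names(df), value = TRUE)
    if (!"time_s" %in% names(df) || length(roi_cols) == 0) {
      abort("trace table needs a time_s column and at least one roi_* column")
    }
    df <- df[, c("time_s", roi_cols)]
    df[] <- lapply(df, as.numeric)
  } else {
    missing_cols <- setdiff(table_schemas[[schema]], names(df))
    if (length(missing_cols) > 0) {
      abort(paste0("missing mandatory column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    num <- intersect(c("spike_time_s", "rate_hz", "ct"), names(df))
    df[num] <- lapply(df[num], as.numeric)
    if (schema == "spikes" && any(df$spike_time_s < 0, na.rm = TRUE)) {
      abort("spike_time_s must be non-negative")
    }
  }
  as_tibble(df)
}

#' @rdname read_table
#' @param table Data frame to write.
#' @export
write_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}
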