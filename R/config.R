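#' Analysis configuration
#'
#' Builds the validated configuration object shared by the calcium, MEA and
#' pharmacology pipelines. Defaults are the acquisition/analysis settings the
#' pipeline was designed around: 1-min widefield movies sampled every 0.28 s,
#' an 8-bit soma threshold of 50 with a 20 px^2 particle filter, a 10-point
#' moving average, a lowest-20% F0, a 0.05 dF/F0 peak-prominence criterion and
#' a 3-peak neuron retention rule; 12.5 kHz extracellular sampling with
#' electrode retention at 10 spikes/min (conventional wells) or 1 spike/min
#' (tripartite compartments).
#'
#' @param frame_interval_s Calcium frame interval, seconds.
#' @param roi_threshold Soma foreground threshold on the 0-255 intensity scale;
#'   pixels strictly brighter than this are foreground.
#' @param min_roi_area_px Minimum ROI area, square pixels.
#' @param smoothing_window Moving-average window, frames.
#' @param f0_fraction Fraction of lowest samples defining the F0 baseline,
#'   in (0, 1].
#' @param peak_prominence Minimum topographic prominence of a retained calcium
#'   peak, dF/F0 units.
#' @param min_peaks_per_neuron Neurons with fewer detected peaks are discarded.
#' @param sampling_rate_hz MEA sampling rate, Hz.
#' @param wavelet_name Wavelet for the stationary transform (only "sym5" is
#'   built in).
#' @param swt_level Stationary wavelet decomposition depth.
#' @param teo_smooth_window Teager-energy smoothing window, samples.
#' @param threshold_multiplier Detection threshold in robust-MAD units of the
#'   smoothed Teager energy.
#' @param refractory_s Minimum separation between accepted spikes, seconds.
#' @param min_spikes_per_min Electrode retention threshold, spikes per minute
#'   (10 for conventional layouts, 1 for tripartite).
#' @param tonic_rate_hz Electrodes firing above this rate are flagged tonic.
#' @param n_components Number of principal components retained.
#' @param overlap_projection_axes Length-2 integer vector: the component pair
#'   defining the 2D overlap projection.
#' @param seed Integer seed recorded with the configuration.
#'
#' @return A validated list of class `neuract_config`.
#' @export
#' @examples
#' cfg <- neuract_config()
#' cfg$calcium$peak_prominence
neuract_config <- function(frame_interval_s = 0.28,
                           roi_threshold = 50,
                           min_roi_area_px = 20,
                           smoothing_window = 10,
                           f0_fraction = 0.20,
                           peak_prominence = 0.05,
                           min_peaks_per_neuron = 3,
                           sampling_rate_hz = 12500,
                           wavelet_name = "sym5",
                           swt_level = 3,
                           teo_smooth_window = 25,
                           threshold_multiplier = 8,
                           refractory_s = 0.001,
                           min_spikes_per_min = 10,
                           tonic_rate_hz = 100,
                           n_components = 3,
                           overlap_projection_axes = c(1L, 2L),
                           seed = 1L) {
  cfg <- structure(list(
    calcium = list(
      frame_interval_s = frame_interval_s,
      roi_threshold = roi_threshold,
      min_roi_area_px = min_roi_area_px,
      smoothing_window = smoothing_window,
      f0_fraction = f0_fraction,
      peak_prominence = peak_prominence,
      min_peaks_per_neuron = min_peaks_per_neuron
    ),
    mea = list(
      sampling_rate_hz = sampling_rate_hz,
      wavelet_name = wavelet_name,
      swt_level = swt_level,
      teo_smooth_window = teo_smooth_window,
      threshold_multiplier = threshold_multiplier,
      refractory_s = refractory_s,
      min_spikes_per_min = min_spikes_per_min,
      tonic_rate_hz = tonic_rate_hz
    ),
    pharm = list(
      n_components = n_components,
      overlap_projection_axes = as.integer(overlap_projection_axes)
    ),
    seed = as.integer(seed)
  ), class = "neuract_config")
  validate_config(cfg)
}

#' Validate a configuration object
#'
#' @param cfg A `neuract_config` list.
#' @return `cfg`, invisibly unchanged, or an error describing the violation.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "neuract_config"))
  ca <- cfg$calcium
  me <- cfg$mea
  pos <- c(
    frame_interval_s = ca$frame_interval_s,
    min_roi_area_px = ca$min_roi_area_px,
    smoothing_window = ca$smoothing_window,
    peak_prominence = ca$peak_prominence,
    min_peaks_per_neuron = ca$min_peaks_per_neuron,
    sampling_rate_hz = me$sampling_rate_hz,
    swt_level = me$swt_level,
    teo_smooth_window = me$teo_smooth_window,
    threshold_multiplier = me$threshold_multiplier,
    refractory_s = me$refractory_s,
    min_spikes_per_min = me$min_spikes_per_min,
    tonic_rate_hz = me$tonic_rate_hz,
    n_components = cfg$pharm$n_components
  )
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad) > 0) {
    abort(paste0("config fields must be strictly positive: ",
                 paste(bad, collapse = ", ")))
  }
  if (ca$roi_threshold < 0 || ca$roi_threshold > 255) {
    abort("roi_threshold must lie in [0, 255]")
  }
  if (ca$f0_fraction <= 0 || ca$f0_fraction > 1) {
    abort("f0_fraction must lie in (0, 1]")
  }
  if (length(cfg$pharm$overlap_projection_axes) != 2L) {
    abort("overlap_projection_axes must name exactly two components")
  }
  invisible(cfg)
}

#' Read a configuration file
#'
#' Reads a YAML file whose keys mirror the arguments of [neuract_config()];
#' keys may be given flat or grouped under `calcium` / `mea` / `pharm`.
#' Unknown keys are an error. `overrides` (a named list, e.g. from
#' command-line flags) take precedence over file values.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides Named list of values overriding the file.
#' @return A validated `neuract_config`.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    raw <- yaml::read_yaml(path)
    for (k in names(raw)) {
      if (k %in% c("calcium", "mea", "pharm")) {
        vals <- c(vals, raw[[k]])
      } else {
        vals[[k]] <- raw[[k]]
      }
    }
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(neuract_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(neuract_config, vals)
}

#' @export
print.neuract_config <- function(x, ...) {
  cat("<neuract_config>\n")
  for (sec in c("calcium", "mea", "pharm")) {
    cat(" ", sec, ":\n", sep = "")
    for (k in names(x[[sec]])) {
      cat("    ", k, " = ", paste(x[[sec]][[k]], collapse = ","), "\n", sep = "")
    }
  }
  cat("  seed = ", x$seed, "\n", sep = "")
  invisible(x)
}
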