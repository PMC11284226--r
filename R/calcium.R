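# Calcium-oscillation quantification: soma ROI detection on a reference
# frame, trace extraction, background subtraction + smoothing + dF/F0 +
# detrending, prominence-based peak detection, per-neuron and per-recording
# summaries.

# 8-connected component labelling of a logical matrix (union-find)
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(matrix(0L, nr, nc))
  parent <- seq_along(idx)
  pos <- integer(nr * nc); pos[idx] <- seq_along(idx)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  for (k in seq_along(idx)) {
    r <- rows[k]; cc <- cols[k]
    # neighbours already visited in column-major order: same col above,
    # and the three in the previous column
    nb <- c(if (r > 1) idx[k] - 1L,
            if (cc > 1) idx[k] - nr + c(if (r > 1) -1L else NULL, 0L,
                                        if (r < nr) 1L else NULL))
    for (j in nb) {
      if (j >= 1 && pos[j] > 0L) {
        a <- find(k); b <- find(pos[j])
        if (a != b) parent[a] <- b
      }
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  lab <- matrix(0L, nr, nc)
  lab[idx] <- match(roots, unique(roots))
  lab
}

#' Detect somatic ROIs on a reference frame
#'
#' Thresholds the reference frame (foreground = intensity strictly above
#' `threshold` on the 0-255 scale), labels 8-connected components, discards
#' components smaller than `min_area`, and auto-selects a background ROI as
#' the darkest square window (side `ceiling(sqrt(min_area))`) that touches no
#' foreground component.
#'
#' @param movie A `fluor_movie`.
#' @param reference_frame_index 1-based frame used for segmentation.
#' @param threshold Foreground threshold, 0-255.
#' @param min_area Minimum ROI area, square pixels.
#' @return A tibble with `roi_id`, `area`, `is_background` and a `pixels`
#'   list-column of (row, col) matrices. The background ROI is always last.
#' @export
detect_rois <- function(movie, reference_frame_index = 1,
                        threshold = neuract_config()$calcium$roi_threshold,
                        min_area = neuract_config()$calcium$min_roi_area_px) {
  stopifnot(inherits(movie, "fluor_movie"))
  nf <- dim(movie$pixels)[3]
  if (reference_frame_index < 1 || reference_frame_index > nf) {
    abort("reference frame outside the stack")
  }
  if (threshold < 0 || threshold > 255) abort("threshold must lie in [0, 255]")
  frame <- movie$pixels[, , reference_frame_index]
  mask <- frame > threshold
  lab <- label_components(mask)
  comps <- list()
  if (max(lab) > 0) {
    for (l in seq_len(max(lab))) {
      px <- which(lab == l, arr.ind = TRUE)
      if (nrow(px) >= min_area) comps[[length(comps) + 1]] <- unname(px)
    }
  }
  # darkest clear square window for the background ROI
  side <- ceiling(sqrt(min_area))
  nr <- nrow(frame); nc <- ncol(frame)
  if (side > nr || side > nc) abort("min_area window larger than the frame")
  best <- NULL; best_mean <- Inf
  occupied <- mask | (lab > 0)
  for (r0 in seq_len(nr - side + 1)) {
    for (c0 in seq_len(nc - side + 1)) {
      win_occ <- occupied[r0:(r0 + side - 1), c0:(c0 + side - 1)]
      if (any(win_occ)) next
      m <- mean(frame[r0:(r0 + side - 1), c0:(c0 + side - 1)])
      if (m < best_mean) { best_mean <- m; best <- c(r0, c0) }
    }
  }
  if (is.null(best)) abort("no cell-free window available for a background ROI")
  bg_px <- as.matrix(expand.grid(row = best[1]:(best[1] + side - 1),
                                 col = best[2]:(best[2] + side - 1)))
  ids <- c(if (length(comps) > 0) paste0("roi_", seq_along(comps)), "background")
  tibble(roi_id = ids,
         area = c(vapply(comps, nrow, integer(1)), nrow(bg_px)),
         is_background = c(rep(FALSE, length(comps)), TRUE),
         pixels = c(comps, list(unname(bg_px))))
}

#' Extract mean-intensity traces for a set of ROIs
#'
#' @param movie A `fluor_movie`.
#' @param rois ROI tibble from [detect_rois()].
#' @return A tibble with `time_s`, one column per non-background ROI (named
#'   by `roi_id`) and a `background` column if a background ROI is present.
#' @export
extract_traces <- function(movie, rois) {
  stopifnot(inherits(movie, "fluor_movie"))
  d <- dim(movie$pixels)
  out <- tibble(time_s = (seq_len(d[3]) - 1) * movie$frame_interval_s)
  for (i in seq_len(nrow(rois))) {
    px <- rois$pixels[[i]]
    if (any(px < 1) || any(px[, 1] > d[1]) || any(px[, 2] > d[2])) {
      abort(paste0("ROI ", rois$roi_id[i], " references out-of-bounds pixels"))
    }
    flat <- (px[, 2] - 1) * d[1] + px[, 1]
    vals <- vapply(seq_len(d[3]),
                   function(f) mean(movie$pixels[, , f][flat]), numeric(1))
    nm <- if (rois$is_background[i]) "background" else rois$roi_id[i]
    out[[nm]] <- vals
  }
  out
}

# centered symmetric moving average with half-width floor(w/2), shrinking
# symmetrically at the edges; every window is symmetric about its sample,
# so affine trends pass through unchanged (the detrending step then removes
# them exactly)
moving_average <- function(x, w) {
  n <- length(x)
  h <- floor(w / 2)
  vapply(seq_len(n), function(i) {
    l <- min(h, i - 1, n - i)
    mean(x[(i - l):(i + l)])
  }, numeric(1))
}

#' Normalize a raw calcium trace to detrended dF/F0
#'
#' Pipeline, in order: (1) pointwise background subtraction; (2) centered
#' moving average of `smoothing_window` samples (shrinking at the edges);
#' (3) dF/F0 with F0 = mean of the lowest `f0_fraction` of the smoothed
#' samples (k = ceiling(fraction * n)); (4) least-squares line fit of dF/F0
#' against frame index, with the slope component (slope * (t - mean(t)))
#' subtracted so trends are removed but the mean level is preserved.
#'
#' An unsmoothed dF/F0 (same F0 and detrend) is carried alongside for
#' peak-time refinement.
#'
#' @param raw_trace Numeric raw intensity trace.
#' @param background_trace Numeric background trace of the same length
#'   (or a scalar, recycled).
#' @param time_s Frame times, seconds; defaults to 0.28 s spacing.
#' @param smoothing_window,f0_fraction See [neuract_config()].
#' @param roi_id Label used in messages and outputs.
#' @return A `normalized_trace`: list with `roi_id`, `time_s`, `dff`,
#'   `dff_unsmoothed`, `f0`, `slope_removed` (dF/F0 per frame).
#' @export
normalize_trace <- function(raw_trace, background_trace = 0,
                            time_s = (seq_along(raw_trace) - 1) * 0.28,
                            smoothing_window = neuract_config()$calcium$smoothing_window,
                            f0_fraction = neuract_config()$calcium$f0_fraction,
                            roi_id = "roi") {
  n <- length(raw_trace)
  bg <- rep_len(background_trace, n)
  stopifnot(length(time_s) == n)
  x <- raw_trace - bg
  xs <- moving_average(x, smoothing_window)
  k <- ceiling(f0_fraction * n)
  f0 <- mean(sort(xs)[seq_len(k)])
  if (!is.finite(f0) || f0 <= 0) {
    abort(paste0("non-positive F0 for ", roi_id,
                 ": baseline fluorescence must exceed background"))
  }
  dff <- (xs - f0) / f0
  dff_raw <- (x - f0) / f0
  frame <- seq_len(n) - 1
  slope <- coef(lm(dff ~ frame))[["frame"]]
  dff <- dff - slope * (frame - mean(frame))
  dff_raw <- dff_raw - slope * (frame - mean(frame))
  structure(list(roi_id = roi_id, time_s = time_s, dff = dff,
                 dff_unsmoothed = dff_raw, f0 = f0, slope_removed = slope),
            class = "normalized_trace")
}

# topographic prominence of peak at index p (brute force over the trace)
peak_prominence_at <- function(x, p) {
  n <- length(x)
  h <- x[p]
  left_min <- right_min <- h
  i <- p
  while (i > 1) {
    i <- i - 1
    if (x[i] > h) break
    left_min <- min(left_min, x[i])
  }
  i <- p
  while (i < n) {
    i <- i + 1
    if (x[i] > h) break
    right_min <- min(right_min, x[i])
  }
  h - max(left_min, right_min)
}

# interpolated crossing times of level `ref` on each side of peak p
half_prominence_width <- function(x, time_s, p, ref) {
  n <- length(x)
  tl <- time_s[1]; tr <- time_s[n]
  i <- p
  while (i > 1) {
    if (x[i - 1] <= ref) {
      tl <- time_s[i - 1] + (time_s[i] - time_s[i - 1]) *
        (ref - x[i - 1]) / (x[i] - x[i - 1])
      break
    }
    i <- i - 1
  }
  i <- p
  while (i < n) {
    if (x[i + 1] <= ref) {
      tr <- time_s[i] + (time_s[i + 1] - time_s[i]) *
        (x[i] - ref) / (x[i] - x[i + 1])
      break
    }
    i <- i + 1
  }
  c(tl, tr)
}

#' Detect calcium peaks by topographic prominence
#'
#' Local maxima of the normalized trace whose prominence reaches the
#' threshold. Height and prominence are measured on the smoothed dF/F0;
#' duration is the full width at half prominence with interpolated
#' crossings; the reported peak time is refined to the maximum of the
#' unsmoothed dF/F0 within half a smoothing window of the detection.
#'
#' Peaks whose maximum falls within `edge_exclude` frames of either trace
#' end are dropped: there the shrinking smoothing window under-averages the
#' noise, so threshold crossings at the boundary are unreliable.
#'
#' @param norm_trace A `normalized_trace` (or plain numeric dF/F0 vector).
#' @param prominence_threshold Minimum prominence, dF/F0 units.
#' @param refine_window Frames searched on each side for time refinement.
#' @param edge_exclude Frames at each boundary where peaks are not accepted.
#' @return Tibble of peaks ordered by time: `time_s`, `height`,
#'   `prominence`, `duration_s`.
#' @export
detect_calcium_peaks <- function(norm_trace,
                                 prominence_threshold = neuract_config()$calcium$peak_prominence,
                                 refine_window = 5,
                                 edge_exclude = refine_window) {
  if (is.numeric(norm_trace)) {
    norm_trace <- list(dff = norm_trace, dff_unsmoothed = NULL,
                       time_s = (seq_along(norm_trace) - 1) * 0.28)
  }
  x <- norm_trace$dff
  time_s <- norm_trace$time_s
  n <- length(x)
  if (n < 3) return(tibble(time_s = numeric(0), height = numeric(0),
                           prominence = numeric(0), duration_s = numeric(0)))
  is_peak <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  is_peak <- is_peak[is_peak > edge_exclude & is_peak <= n - edge_exclude]
  # refinement trace: lightly pre-averaged (3-point) so the argmax is robust
  # to noise while keeping the full-window smoothing lag out of the time
  xr <- if (!is.null(norm_trace$dff_unsmoothed)) {
    moving_average(norm_trace$dff_unsmoothed, 3)
  }
  out <- list()
  for (p in is_peak) {
    prom <- peak_prominence_at(x, p)
    if (prom < prominence_threshold) next
    wd <- half_prominence_width(x, time_s, p, x[p] - prom / 2)
    tp <- time_s[p]
    if (!is.null(xr)) {
      lo <- max(1, p - refine_window); hi <- min(n, p + refine_window)
      tp <- time_s[lo + which.max(xr[lo:hi]) - 1L]
    }
    out[[length(out) + 1]] <- tibble(time_s = tp, height = x[p],
                                     prominence = prom,
                                     duration_s = max(wd[2] - wd[1], 0))
  }
  if (length(out) == 0) {
    return(tibble(time_s = numeric(0), height = numeric(0),
                  prominence = numeric(0), duration_s = numeric(0)))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$time_s)
}

#' Per-neuron activity metrics
#'
#' Neurons with fewer than `min_peaks` detected peaks are discarded
#' (`retained = FALSE`, metrics `NA`); otherwise the peak parameters are
#' averaged and the oscillation frequency is peaks per second.
#'
#' @param peaks Peak tibble from [detect_calcium_peaks()].
#' @param duration_s Recording duration, seconds.
#' @param min_peaks Retention threshold on the peak count.
#' @param roi_id Label copied into the output.
#' @return One-row tibble: `roi_id`, `n_peaks`, `amplitude`, `prominence`,
#'   `duration_s`, `peak_to_peak_s`, `frequency_hz`, `retained`.
#' @export
neuron_metrics <- function(peaks, duration_s,
                           min_peaks = neuract_config()$calcium$min_peaks_per_neuron,
                           roi_id = "roi") {
  n <- nrow(peaks)
  if (n < min_peaks) {
    return(tibble(roi_id = roi_id, n_peaks = n, amplitude = NA_real_,
                  prominence = NA_real_, duration_s = NA_real_,
                  peak_to_peak_s = NA_real_, frequency_hz = NA_real_,
                  retained = FALSE))
  }
  freq <- n / duration_s # recording duration, not the mean peak duration
  tibble(roi_id = roi_id, n_peaks = n,
         amplitude = mean(peaks$height),
         prominence = mean(peaks$prominence),
         duration_s = mean(peaks$duration_s),
         peak_to_peak_s = mean(diff(peaks$time_s)),
         frequency_hz = freq,
         retained = TRUE)
}

#' Per-recording summary: medians over retained neurons
#'
#' @param metrics Row-bound output of [neuron_metrics()].
#' @return One-row tibble of medians of the five activity parameters plus
#'   `n_neurons` (retained) and an `empty` flag when none were retained.
#' @export
recording_summary <- function(metrics) {
  kept <- dplyr::filter(metrics, .data$retained)
  if (nrow(kept) == 0) {
    return(tibble(n_neurons = 0L, amplitude = NA_real_, prominence = NA_real_,
                  duration_s = NA_real_, peak_to_peak_s = NA_real_,
                  frequency_hz = NA_real_, empty = TRUE))
  }
  tibble(n_neurons = nrow(kept),
         amplitude = median(kept$amplitude),
         prominence = median(kept$prominence),
         duration_s = median(kept$duration_s),
         peak_to_peak_s = median(kept$peak_to_peak_s),
         frequency_hz = median(kept$frequency_hz),
         empty = FALSE)
}

#' Run the full calcium pipeline on a trace table
#'
#' Normalizes every `roi_*` column against the `background` column (zeros if
#' absent), detects peaks and assembles per-neuron metrics and the
#' per-recording summary.
#'
#' @param traces Tibble with `time_s`, `roi_*` columns and optionally
#'   `background`.
#' @param config A [neuract_config()].
#' @return A `calcium_result`: list with `metrics` (per-neuron tibble),
#'   `summary` (one-row tibble), `peaks` (named list of peak tibbles) and
#'   `normalized` (named list of `normalized_trace`s).
#' @export
analyze_calcium <- function(traces, config = neuract_config()) {
  roi_cols <- grep("^roi_", names(traces), value = TRUE)
  if (length(roi_cols) == 0) abort("no roi_* columns in trace table")
  bg <- if ("background" %in% names(traces)) traces$background else 0
  duration_s <- nrow(traces) *
    (if (nrow(traces) > 1) diff(traces$time_s[1:2]) else config$calcium$frame_interval_s)
  peaks <- list(); norms <- list(); mets <- list()
  for (rc in roi_cols) {
    nt <- normalize_trace(traces[[rc]], bg, time_s = traces$time_s,
                          smoothing_window = config$calcium$smoothing_window,
                          f0_fraction = config$calcium$f0_fraction,
                          roi_id = rc)
    pk <- detect_calcium_peaks(nt, config$calcium$peak_prominence,
                               refine_window = floor(config$calcium$smoothing_window / 2))
    norms[[rc]] <- nt
    peaks[[rc]] <- pk
    mets[[rc]] <- neuron_metrics(pk, duration_s,
                                 config$calcium$min_peaks_per_neuron, rc)
  }
  structure(list(metrics = dplyr::bind_rows(mets),
                 summary = recording_summary(dplyr::bind_rows(mets)),
                 peaks = peaks, normalized = norms),
            class = "calcium_result")
}

#' @export
print.calcium_result <- function(x, ...) {
  cat(sprintf("<calcium_result> %d neurons (%d retained)\n",
              nrow(x$metrics), sum(x$metrics$retained)))
  print(x$summary)
  invisible(x)
}
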