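# Extracellular spike detection and firing-rate analysis. The detector
# combines a stationary (undecimated) wavelet transform with the Teager
# energy operator: transients concentrate energy in the deep detail band,
# the TEO sharpens them against background noise, and a robust
# MAD-derived threshold picks events.

# sym5 decomposition filters (PyWavelets convention, lowpass/highpass)
sym5_dec_lo <- c(0.027333068345077982, 0.029519490925774643,
                 -0.039134249302383094, 0.1993975339773936,
                 0.7234076904024206, 0.6339789634582119,
                 0.01660210576452232, -0.17532808990845047,
                 -0.021101834024758855, 0.019538882735286728)
sym5_dec_hi <- c(-0.019538882735286728, -0.021101834024758855,
                 0.17532808990845047, 0.01660210576452232,
                 -0.6339789634582119, 0.7234076904024206,
                 -0.1993975339773936, -0.039134249302383094,
                 -0.029519490925774643, 0.027333068345077982)

# upsample a filter by inserting 2^(level-1)-1 zeros between taps (a trous)
upsample_filter <- function(f, level) {
  if (level == 1) return(f)
  step <- 2^(level - 1)
  out <- numeric((length(f) - 1) * step + 1)
  out[seq(1, length(out), by = step)] <- f
  out
}

# causal FIR convolution with reflection padding; returns same length as x
fir_reflect <- function(x, f) {
  p <- length(f) - 1
  n <- length(x)
  pad <- x[pmin(p:1, n)] # reflected left edge (clipped for short signals)
  y <- stats::filter(c(pad, x), f, method = "convolution", sides = 1)
  as.numeric(y[(p + 1):(p + n)])
}

# detail coefficients of the stationary wavelet transform at `level`,
# shifted to compensate the cascade's group delay
swt_detail <- function(x, level, lo = sym5_dec_lo, hi = sym5_dec_hi) {
  a <- x
  delay <- 0
  for (j in seq_len(level)) {
    hj <- upsample_filter(lo, j)
    gj <- upsample_filter(hi, j)
    if (j < level) {
      a_next <- fir_reflect(a, hj)
    } else {
      a_next <- fir_reflect(a, gj)
    }
    delay <- delay + (length(hj) - 1) / 2
    a <- a_next
  }
  shift <- round(delay)
  n <- length(a)
  c(a[(shift + 1):n], rep(a[n], shift))
}

# Teager energy operator, zero at the edges
teager_energy <- function(x) {
  n <- length(x)
  psi <- numeric(n)
  psi[2:(n - 1)] <- x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n]
  psi
}

#' Detect spikes on one channel with the SWT + Teager-energy detector
#'
#' Steps: (1) stationary wavelet transform to `swt_level`, keeping the
#' deepest detail band (group-delay compensated); (2) Teager energy
#' psi(n) = x(n)^2 - x(n-1) x(n+1); (3) smoothing with a unit-sum Hamming
#' window of `teo_smooth_window` samples; (4) threshold
#' T = `threshold_multiplier` * median(|psi|)/0.6745; (5) time-ordered local
#' maxima above T with `refractory_s` enforced between accepted events;
#' (6) each event time refined to the largest absolute raw-signal excursion
#' within +/- 0.5 ms.
#'
#' @param channel_signal Numeric voltage trace, microvolts.
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param swt_level,teo_smooth_window,threshold_multiplier,refractory_s
#'   Detector settings; see [neuract_config()].
#' @return Numeric vector of spike times, seconds, strictly increasing.
#' @export
swtteo_detect <- function(channel_signal, sampling_rate_hz,
                          swt_level = 3, teo_smooth_window = 25,
                          threshold_multiplier = 8, refractory_s = 0.001) {
  if (any(!is.finite(channel_signal))) abort("signal contains non-finite samples")
  n <- length(channel_signal)
  if (n < 2^swt_level * length(sym5_dec_lo)) {
    abort("signal too short for the requested decomposition level")
  }
  d <- swt_detail(channel_signal, swt_level)
  psi <- teager_energy(d)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, 1, length.out = teo_smooth_window))
  w <- w / sum(w)
  half <- floor(teo_smooth_window / 2)
  psi_s <- fir_reflect(psi, w)
  psi_s <- c(psi_s[(half + 1):n], rep(psi_s[n], half)) # center the window
  thr <- threshold_multiplier * median(abs(psi_s)) / 0.6745
  cand <- which(psi_s[2:(n - 1)] > psi_s[1:(n - 2)] &
                  psi_s[2:(n - 1)] >= psi_s[3:n] &
                  psi_s[2:(n - 1)] > thr) + 1L
  if (length(cand) == 0) return(numeric(0))
  refr <- refractory_s * sampling_rate_hz
  accepted <- cand[1]
  for (i in cand[-1]) {
    if (i - accepted[length(accepted)] >= refr) accepted <- c(accepted, i)
  }
  half_ms <- round(0.0005 * sampling_rate_hz)
  # amplitude validation: the raw excursion at the refined time must clear
  # 3 robust SDs of the channel, rejecting wavelet-sidelobe ghosts that land
  # on featureless signal
  amp_floor <- 3 * median(abs(channel_signal - median(channel_signal))) / 0.6745
  refined <- vapply(accepted, function(i) {
    lo <- max(1, i - half_ms); hi <- min(n, i + half_ms)
    j <- lo + which.max(abs(channel_signal[lo:hi])) - 1L
    if (abs(channel_signal[j]) > amp_floor) j else NA_real_
  }, numeric(1))
  refined <- refined[!is.na(refined)]
  sort(unique(refined - 1)) / sampling_rate_hz
}

#' Detect spikes on every channel of a recording
#'
#' @param recording A `raw_recording`.
#' @param config A [neuract_config()].
#' @return A `spike_train_set`: spike table (`channel`, `spike_time_s`),
#'   recording duration, sampling rate, compartment map and a QC table
#'   (initially all channels retained).
#' @export
detect_spikes <- function(recording, config = neuract_config()) {
  stopifnot(inherits(recording, "raw_recording"))
  me <- config$mea
  rows <- lapply(recording$channel_ids, function(ch) {
    st <- swtteo_detect(recording$samples[ch, ], recording$sampling_rate_hz,
                        me$swt_level, me$teo_smooth_window,
                        me$threshold_multiplier, me$refractory_s)
    if (length(st) == 0) return(NULL)
    tibble(channel = ch, spike_time_s = st)
  })
  new_spike_train_set(dplyr::bind_rows(rows),
                      duration_s = ncol(recording$samples) / recording$sampling_rate_hz,
                      sampling_rate_hz = recording$sampling_rate_hz,
                      compartment_map = recording$compartment_map)
}

#' Construct a spike-train set from a spike table
#'
#' @param spikes Tibble with `channel` and `spike_time_s`.
#' @param duration_s Recording duration, seconds.
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param compartment_map Named character vector channel -> compartment;
#'   channels absent from the spike table but present here count as silent.
#' @return A `spike_train_set`.
#' @export
new_spike_train_set <- function(spikes, duration_s, sampling_rate_hz = 12500,
                                compartment_map = NULL) {
  stopifnot(duration_s > 0)
  spikes <- dplyr::arrange(spikes, .data$channel, .data$spike_time_s)
  if (nrow(spikes) > 0 &&
      (min(spikes$spike_time_s) < 0 || max(spikes$spike_time_s) >= duration_s)) {
    abort("spike times must lie within [0, duration)")
  }
  channels <- unique(c(names(compartment_map), spikes$channel))
  if (is.null(compartment_map)) {
    compartment_map <- setNames(rep("default", length(channels)), channels)
  } else {
    missing_ch <- setdiff(channels, names(compartment_map))
    compartment_map[missing_ch] <- "default"
  }
  counts <- table(factor(spikes$channel, levels = channels))
  qc <- tibble(channel = channels,
               compartment = unname(compartment_map[channels]),
               n_spikes = as.integer(counts),
               rate_hz = as.numeric(counts) / duration_s,
               retained = TRUE, reason = NA_character_)
  structure(list(spikes = spikes, duration_s = duration_s,
                 sampling_rate_hz = sampling_rate_hz,
                 compartment_map = compartment_map, qc = qc),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("<spike_train_set> %d channels (%d retained), %d spikes, %.3g s\n",
              nrow(x$qc), sum(x$qc$retained), nrow(x$spikes), x$duration_s))
  invisible(x)
}

#' Electrode quality control
#'
#' A channel is retained iff its firing rate is at least
#' `min_spikes_per_min` per minute (inclusive), at most `tonic_rate_hz`
#' (electrodes above it are flagged as tonically spiking), and not on the
#' manual exclusion list. The operation recomputes retention from the spike
#' table, so applying it twice gives the same result.
#'
#' @param sts A `spike_train_set`.
#' @param min_spikes_per_min Retention threshold, spikes per minute
#'   (10 for conventional wells, 1 for tripartite compartments).
#' @param tonic_rate_hz Upper rate bound, Hz.
#' @param manual_exclusions Character vector of channel ids to drop
#'   (artifact/noise calls made by inspection).
#' @return The `spike_train_set` with an updated QC table.
#' @export
filter_electrodes <- function(sts,
                              min_spikes_per_min = neuract_config()$mea$min_spikes_per_min,
                              tonic_rate_hz = neuract_config()$mea$tonic_rate_hz,
                              manual_exclusions = character(0)) {
  stopifnot(inherits(sts, "spike_train_set"))
  qc <- sts$qc
  qc$retained <- TRUE
  qc$reason <- NA_character_
  low <- qc$rate_hz < min_spikes_per_min / 60
  tonic <- qc$rate_hz > tonic_rate_hz
  manual <- qc$channel %in% manual_exclusions
  qc$retained <- !(low | tonic | manual)
  qc$reason[low] <- "low_rate"
  qc$reason[tonic] <- "tonic"
  qc$reason[manual] <- "manual"
  sts$qc <- qc
  sts
}

#' Mean firing rate over retained electrodes
#'
#' Per-channel rate is spike count over duration; the summary is the
#' arithmetic mean over retained channels, for the whole well or per
#' compartment.
#'
#' @param sts A filtered `spike_train_set`.
#' @param scope `"well"` (one row) or `"compartment"` (one row per
#'   compartment).
#' @return Tibble: `scope`, `mean_firing_rate_hz`, `n_retained`, `empty`.
#' @export
firing_summary <- function(sts, scope = c("well", "compartment")) {
  scope <- match.arg(scope)
  stopifnot(inherits(sts, "spike_train_set"))
  kept <- dplyr::filter(sts$qc, .data$retained)
  if (scope == "well") {
    return(tibble(scope = "well",
                  mean_firing_rate_hz = if (nrow(kept) > 0) mean(kept$rate_hz) else NA_real_,
                  n_retained = nrow(kept), empty = nrow(kept) == 0))
  }
  out <- dplyr::summarise(dplyr::group_by(kept, scope = .data$compartment),
                          mean_firing_rate_hz = mean(.data$rate_hz),
                          n_retained = dplyr::n(), .groups = "drop")
  out$empty <- FALSE
  all_comps <- unique(sts$qc$compartment)
  absent <- setdiff(all_comps, out$scope)
  if (length(absent) > 0) {
    out <- dplyr::bind_rows(out, tibble(scope = absent,
                                        mean_firing_rate_hz = NA_real_,
                                        n_retained = 0L, empty = TRUE))
  }
  dplyr::arrange(out, .data$scope)
}

#' Percent change relative to a reference
#'
#' `100 * (value - reference) / reference`, vectorized; a zero or missing
#' reference (or missing value) yields `NA` so missingness propagates
#' explicitly instead of producing infinities.
#'
#' @param value,reference Numeric vectors (recycled).
#' @return Numeric vector of percent changes.
#' @export
percent_change <- function(value, reference) {
  out <- 100 * (value - reference) / reference
  out[is.na(reference) | is.na(value) | reference == 0] <- NA_real_
  out
}
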