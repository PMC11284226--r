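# Seeded generators for the three modalities. Each returns the simulated
# object plus a ground-truth record so detection stages can be scored.

#' Calcium simulation settings
#'
#' Defaults emulate a 1-min widefield Fluo-4 recording at 0.28 s intervals:
#' somata are disks of elevated baseline on a dim background, transients
#' follow a fast-rise/slow-decay double-exponential kernel, and the whole
#' frame carries a linear drift plus i.i.d. Gaussian noise, clipped to the
#' 8-bit range after noise addition.
#'
#' @param n_cells Number of somata.
#' @param image_size Side length of the square frame, pixels.
#' @param n_frames Number of frames (>= 3). Default 214 = 60 s at 0.28 s.
#' @param frame_interval_s Frame interval, seconds.
#' @param cell_radius_px Soma disk radius, pixels.
#' @param baseline_intensity Soma resting intensity (0-255).
#' @param background_intensity Cell-free background intensity (0-255).
#' @param drift_slope Global linear drift, intensity units per frame.
#' @param transient_amplitude Peak intensity added by one event.
#' @param rise_tau_s,decay_tau_s Kernel time constants, seconds. The kernel
#'   (1 - exp(-u/rise)) * exp(-u/decay) is rescaled so its maximum equals
#'   `transient_amplitude`.
#' @param event_rate_hz Per-cell Poisson event rate, Hz.
#' @param refractory_s Absolute refractory period between events, seconds.
#' @param noise_sd Gaussian pixel noise SD, intensity units.
#' @param seed Integer seed.
#' @return A validated list of class `calcium_sim_spec`.
#' @export
calcium_sim_spec <- function(n_cells = 12, image_size = 96, n_frames = 214,
                             frame_interval_s = 0.28, cell_radius_px = 4,
                             baseline_intensity = 80, background_intensity = 10,
                             drift_slope = 0, transient_amplitude = 20,
                             rise_tau_s = 0.3, decay_tau_s = 2.5,
                             event_rate_hz = 0.1, refractory_s = 5,
                             noise_sd = 2, seed = 1L) {
  spec <- structure(as.list(environment()), class = "calcium_sim_spec")
  stopifnot(n_frames >= 3, frame_interval_s > 0, rise_tau_s > 0,
            decay_tau_s > 0, event_rate_hz >= 0, noise_sd >= 0,
            refractory_s >= 0, n_cells >= 0)
  if (baseline_intensity + transient_amplitude > 255 ||
      background_intensity < 0) {
    abort("baseline plus transient amplitude must stay within [0, 255]")
  }
  spec
}

# scale factor making the kernel's maximum equal 1
kernel_peak_value <- function(rise, decay) {
  u_peak <- rise * log((rise + decay) / rise)
  (1 - exp(-u_peak / rise)) * exp(-u_peak / decay)
}

#' Time of the transient kernel's maximum after an event
#' @param spec A `calcium_sim_spec`.
#' @return Lag from event onset to kernel maximum, seconds.
#' @export
kernel_peak_lag <- function(spec) {
  spec$rise_tau_s * log((spec$rise_tau_s + spec$decay_tau_s) / spec$rise_tau_s)
}

# unit-peak transient kernel evaluated at lags u (seconds)
calcium_kernel <- function(u, rise, decay) {
  out <- numeric(length(u))
  pos <- u >= 0
  out[pos] <- (1 - exp(-u[pos] / rise)) * exp(-u[pos] / decay)
  out / kernel_peak_value(rise, decay)
}

# homogeneous Poisson train on [0, t_max) thinned by an absolute refractory
draw_event_train <- function(rate_hz, t_max, refractory_s) {
  if (rate_hz <= 0 || t_max <= 0) return(numeric(0))
  n <- rpois(1, rate_hz * t_max)
  times <- sort(runif(n, 0, t_max))
  if (refractory_s > 0 && length(times) > 1) {
    keep <- times[1]
    for (t in times[-1]) if (t - keep[length(keep)] >= refractory_s) keep <- c(keep, t)
    times <- keep
  }
  times
}

# noiseless fluorescence of one cell sampled at frame times
cell_signal <- function(time_s, events, spec) {
  sig <- rep(spec$baseline_intensity, length(time_s))
  for (te in events) {
    sig <- sig + spec$transient_amplitude *
      calcium_kernel(time_s - te, spec$rise_tau_s, spec$decay_tau_s)
  }
  sig
}

#' Simulate a calcium fluorescence movie
#'
#' Places non-overlapping soma disks (keeping the top-left corner cell-free
#' so a background ROI always exists), draws per-cell refractory-thinned
#' Poisson event trains, renders the transient kernel, adds global linear
#' drift and Gaussian noise, then clips to [0, 255] and rounds to 8-bit.
#'
#' @param spec A [calcium_sim_spec()].
#' @return A list with `movie` (a `fluor_movie`) and `truth` (ROI masks,
#'   per-cell event times and the dF/F0-scale event amplitude).
#' @export
simulate_calcium_movie <- function(spec) {
  stopifnot(inherits(spec, "calcium_sim_spec"))
  set.seed(spec$seed)
  sz <- spec$image_size
  r <- spec$cell_radius_px
  reserve <- 12 # top-left square kept cell-free for the background ROI
  centers <- matrix(numeric(0), ncol = 2)
  tries <- 0
  while (nrow(centers) < spec$n_cells) {
    cand <- runif(2, r + 1, sz - r)
    ok <- all(cand > reserve + r) ||
      !(cand[1] <= reserve + r && cand[2] <= reserve + r)
    if (ok && nrow(centers) > 0) {
      ok <- all(sqrt(rowSums(sweep(centers, 2, cand)^2)) > 2 * r + 2)
    }
    if (ok) centers <- rbind(centers, cand)
    tries <- tries + 1
    if (tries > 2000 * max(spec$n_cells, 1)) {
      abort("could not place cells without overlap; reduce n_cells or radius")
    }
  }
  time_s <- (seq_len(spec$n_frames) - 1) * spec$frame_interval_s
  t_max <- spec$n_frames * spec$frame_interval_s
  # events sit far enough from both ends that their maxima (and smoothed
  # maxima, for a 10-point analysis window) stay interior to the recording
  edge <- kernel_peak_lag(spec) + 10 * spec$frame_interval_s
  edge0 <- max(0, 10 * spec$frame_interval_s - kernel_peak_lag(spec))
  events <- lapply(seq_len(spec$n_cells), function(i) {
    draw_event_train(spec$event_rate_hz, max(t_max - edge - edge0, 0),
                     spec$refractory_s) + edge0
  })
  rowcol <- expand.grid(row = seq_len(sz), col = seq_len(sz))
  masks <- lapply(seq_len(spec$n_cells), function(i) {
    d2 <- (rowcol$row - centers[i, 1])^2 + (rowcol$col - centers[i, 2])^2
    as.matrix(rowcol[d2 <= r^2, c("row", "col")])
  })
  base <- matrix(spec$background_intensity, sz, sz)
  for (m in masks) base[m] <- spec$baseline_intensity
  arr <- array(rep(base, spec$n_frames), dim = c(sz, sz, spec$n_frames))
  for (i in seq_len(spec$n_cells)) {
    sig <- cell_signal(time_s, events[[i]], spec) - spec$baseline_intensity
    for (f in seq_len(spec$n_frames)) arr[, , f][masks[[i]]] <-
        arr[, , f][masks[[i]]] + sig[f]
  }
  drift <- spec$drift_slope * (seq_len(spec$n_frames) - 1)
  arr <- sweep(arr, 3, drift, "+")
  if (spec$noise_sd > 0) {
    arr <- arr + array(rnorm(length(arr), 0, spec$noise_sd), dim = dim(arr))
  }
  arr <- round(pmin(pmax(arr, 0), 255))
  truth <- list(masks = masks, event_times = events,
                amplitude_dff = spec$transient_amplitude / spec$baseline_intensity,
                peak_lag_s = kernel_peak_lag(spec))
  list(movie = new_fluor_movie(arr, spec$frame_interval_s), truth = truth)
}

#' Simulate calcium traces without rasterization
#'
#' Fast path generating per-cell intensity traces directly under the same
#' model as [simulate_calcium_movie()] (baseline + drift + kernel + noise,
#' no pixel clipping), for statistical tests at scale.
#'
#' @param spec A [calcium_sim_spec()].
#' @return A list with `traces` (tibble: `time_s`, `roi_1` ... `roi_n`),
#'   `background` (numeric vector of the cell-free background trace) and
#'   `truth` (per-trace event times and dF/F0-scale amplitude).
#' @export
simulate_calcium_traces <- function(spec) {
  stopifnot(inherits(spec, "calcium_sim_spec"))
  set.seed(spec$seed)
  time_s <- (seq_len(spec$n_frames) - 1) * spec$frame_interval_s
  t_max <- spec$n_frames * spec$frame_interval_s
  # events sit far enough from both ends that their maxima (and smoothed
  # maxima, for a 10-point analysis window) stay interior to the recording
  edge <- kernel_peak_lag(spec) + 10 * spec$frame_interval_s
  edge0 <- max(0, 10 * spec$frame_interval_s - kernel_peak_lag(spec))
  drift <- spec$drift_slope * (seq_len(spec$n_frames) - 1)
  events <- vector("list", spec$n_cells)
  traces <- matrix(0, spec$n_frames, spec$n_cells)
  for (i in seq_len(spec$n_cells)) {
    events[[i]] <- draw_event_train(spec$event_rate_hz,
                                    max(t_max - edge - edge0, 0),
                                    spec$refractory_s) + edge0
    traces[, i] <- cell_signal(time_s, events[[i]], spec) + drift +
      rnorm(spec$n_frames, 0, spec$noise_sd)
  }
  # the background trace emulates a pixel-averaged background ROI (a 5x5
  # window in the movie pipeline), so its noise is the pixel noise / 5
  background <- spec$background_intensity + drift +
    rnorm(spec$n_frames, 0, spec$noise_sd / 5)
  out <- as_tibble(as.data.frame(traces, optional = TRUE),
                   .name_repair = ~ paste0("roi_", seq_len(spec$n_cells)))
  out <- dplyr::bind_cols(tibble(time_s = time_s), out)
  truth <- list(event_times = events,
                amplitude_dff = spec$transient_amplitude / spec$baseline_intensity,
                peak_lag_s = kernel_peak_lag(spec))
  list(traces = out, background = background, truth = truth)
}

#' MEA simulation settings
#'
#' Defaults emulate one compartment of a tripartite microelectrode array:
#' 24 channels at 12.5 kHz, refractory-thinned Poisson spiking, a biphasic
#' 1-ms template of 100 uV peak amplitude in 20 uV Gaussian noise (SNR 5).
#' Duration defaults to 60 s, a scaled-down stand-in for 10-min sessions.
#'
#' @param n_channels Number of electrodes.
#' @param duration_s Recording length, seconds.
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param firing_rate_hz Scalar or per-channel vector of Poisson rates, Hz.
#' @param amplitude_uv Template peak absolute amplitude, microvolts.
#' @param width_ms Template support, milliseconds.
#' @param noise_sd_uv Gaussian noise SD, microvolts.
#' @param refractory_s Absolute refractory period, seconds (>= template width).
#' @param compartments Scalar or per-channel compartment labels.
#' @param seed Integer seed.
#' @return A validated list of class `mea_sim_spec`.
#' @export
mea_sim_spec <- function(n_channels = 24, duration_s = 60,
                         sampling_rate_hz = 12500, firing_rate_hz = 5,
                         amplitude_uv = 100, width_ms = 1,
                         noise_sd_uv = 20, refractory_s = 0.002,
                         compartments = "default", seed = 1L) {
  spec <- structure(as.list(environment()), class = "mea_sim_spec")
  stopifnot(n_channels >= 1, duration_s > 0, sampling_rate_hz > 0,
            all(firing_rate_hz >= 0), amplitude_uv > 0, width_ms > 0,
            noise_sd_uv >= 0)
  if (refractory_s < width_ms / 1000) {
    abort("refractory_s must be at least the template width")
  }
  if (width_ms / 1000 > duration_s) abort("template longer than recording")
  spec
}

#' Biphasic spike template
#'
#' A Hann-windowed single-cycle sine (negative phase first, as recorded
#' extracellularly), rescaled so the largest absolute excursion equals
#' `amplitude_uv`.
#'
#' @param spec An [mea_sim_spec()].
#' @return Numeric template, one value per sample.
#' @export
spike_template <- function(spec) {
  n <- max(round(spec$width_ms / 1000 * spec$sampling_rate_hz), 3)
  ph <- seq(0, 1, length.out = n)
  w <- -sin(2 * pi * ph) * (0.5 - 0.5 * cos(2 * pi * ph))
  w / max(abs(w)) * spec$amplitude_uv
}

#' Simulate a raw multi-channel extracellular recording
#'
#' Per channel: refractory-thinned homogeneous Poisson spike times, the
#' biphasic template added at each spike, Gaussian noise superposed.
#'
#' @param spec An [mea_sim_spec()].
#' @return A list with `recording` (a `raw_recording`) and `truth`
#'   (per-channel spike times, seconds; spike time = time of the template's
#'   largest absolute excursion).
#' @export
simulate_mea_recording <- function(spec) {
  stopifnot(inherits(spec, "mea_sim_spec"))
  set.seed(spec$seed)
  fs <- spec$sampling_rate_hz
  n_samp <- round(spec$duration_s * fs)
  tmpl <- spike_template(spec)
  peak_off <- which.max(abs(tmpl)) - 1L # samples from template start to peak
  rates <- rep_len(spec$firing_rate_hz, spec$n_channels)
  comps <- rep_len(spec$compartments, spec$n_channels)
  sig <- matrix(0, spec$n_channels, n_samp)
  truth_times <- vector("list", spec$n_channels)
  margin_s <- length(tmpl) / fs
  for (ch in seq_len(spec$n_channels)) {
    times <- draw_event_train(rates[ch],
                              max(spec$duration_s - 2 * margin_s, 0),
                              spec$refractory_s) + margin_s
    starts <- round(times * fs) - peak_off
    for (s in starts) sig[ch, s + seq_along(tmpl)] <-
        sig[ch, s + seq_along(tmpl)] + tmpl
    truth_times[[ch]] <- (starts + peak_off) / fs
  }
  if (spec$noise_sd_uv > 0) {
    sig <- sig + matrix(rnorm(length(sig), 0, spec$noise_sd_uv), nrow(sig))
  }
  ids <- paste0("ch", seq_len(spec$n_channels))
  rownames(sig) <- ids
  rec <- new_raw_recording(sig, fs, setNames(comps, ids))
  list(recording = rec, truth = list(spike_times = setNames(truth_times, ids)))
}

#' Pharmacology-cohort simulation settings
#'
#' Emulates the serial glutamatergic stimulation protocol: per network and
#' compartment, two baseline draws from a lognormal firing-rate distribution;
#' agonist/antagonist conditions as multiplicative factors on the relevant
#' baseline with lognormal multiplicative noise; missing values injected
#' completely at random.
#'
#' @param n_per_group Networks per group.
#' @param layout `"conventional"` (one compartment) or `"tripartite"`
#'   (proximal, distal1, distal2).
#' @param baseline_meanlog,baseline_sdlog Lognormal baseline rate parameters
#'   (log-Hz scale).
#' @param control_factors,treated_factors Named numeric vectors with entries
#'   `NMDA_gly`, `D_AP5`, `AMPA`, `CNQX`: multiplicative response factors
#'   applied to the governing baseline (baseline1 for NMDA_gly/D_AP5,
#'   baseline2 for AMPA/CNQX). Defaults give the control group strong
#'   agonist responses and deep antagonist suppression, and the treated
#'   group blunted responses.
#' @param missing_prob Probability a recorded rate is missing, in [0, 1).
#' @param noise_cv Coefficient of variation of the multiplicative rate noise.
#' @param seed Integer seed.
#' @return A validated list of class `pharm_sim_spec`.
#' @export
pharm_sim_spec <- function(n_per_group = 20,
                           layout = c("conventional", "tripartite"),
                           baseline_meanlog = log(2), baseline_sdlog = 0.4,
                           control_factors = c(NMDA_gly = 1.8, D_AP5 = 0.5,
                                               AMPA = 2.0, CNQX = 0.3),
                           treated_factors = c(NMDA_gly = 1.2, D_AP5 = 0.8,
                                               AMPA = 1.3, CNQX = 0.6),
                           missing_prob = 0.05, noise_cv = 0.2, seed = 1L) {
  layout <- match.arg(layout)
  spec <- structure(as.list(environment()), class = "pharm_sim_spec")
  need <- c("NMDA_gly", "D_AP5", "AMPA", "CNQX")
  stopifnot(n_per_group >= 1,
            all(need %in% names(control_factors)),
            all(need %in% names(treated_factors)),
            all(control_factors > 0), all(treated_factors > 0),
            missing_prob >= 0, missing_prob < 1, noise_cv >= 0)
  spec
}

pharm_conditions <- c("baseline1", "NMDA_gly", "D_AP5",
                      "baseline2", "AMPA", "CNQX")

#' Simulate a two-group pharmacology experiment
#'
#' @param spec A [pharm_sim_spec()].
#' @return A list with `rates` (long tibble: `network_id`, `group`, `layout`,
#'   `compartment`, `condition`, `rate_hz`, `NA` where missing) and `truth`
#'   (noise-free condition rates and group labels).
#' @export
simulate_pharm_experiment <- function(spec) {
  stopifnot(inherits(spec, "pharm_sim_spec"))
  set.seed(spec$seed)
  comps <- if (spec$layout == "tripartite") {
    c("proximal", "distal1", "distal2")
  } else "single"
  sdlog_noise <- sqrt(log(1 + spec$noise_cv^2))
  rows <- list()
  true_rows <- list()
  for (grp in c("control", "treated")) {
    fac <- if (grp == "control") spec$control_factors else spec$treated_factors
    for (i in seq_len(spec$n_per_group)) {
      nid <- paste0(grp, "_", sprintf("%02d", i))
      for (cp in comps) {
        b1 <- rlnorm(1, spec$baseline_meanlog, spec$baseline_sdlog)
        b2 <- rlnorm(1, spec$baseline_meanlog, spec$baseline_sdlog)
        true_rate <- c(baseline1 = b1,
                       NMDA_gly = b1 * fac[["NMDA_gly"]],
                       D_AP5 = b1 * fac[["D_AP5"]],
                       baseline2 = b2,
                       AMPA = b2 * fac[["AMPA"]],
                       CNQX = b2 * fac[["CNQX"]])
        noise <- if (spec$noise_cv > 0) {
          rlnorm(6, -sdlog_noise^2 / 2, sdlog_noise) # unit-mean noise
        } else rep(1, 6)
        obs <- true_rate * noise
        obs[runif(6) < spec$missing_prob] <- NA_real_
        rows[[length(rows) + 1]] <- tibble(
          network_id = nid, group = grp, layout = spec$layout,
          compartment = cp, condition = pharm_conditions,
          rate_hz = as.numeric(obs[pharm_conditions]))
        true_rows[[length(true_rows) + 1]] <- tibble(
          network_id = nid, group = grp, compartment = cp,
          condition = pharm_conditions,
          rate_hz = as.numeric(true_rate[pharm_conditions]))
      }
    }
  }
  list(rates = dplyr::bind_rows(rows),
       truth = list(rates = dplyr::bind_rows(true_rows)))
}
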