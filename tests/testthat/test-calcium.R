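make_disk_frame <- function(size, centers, radius, value = 200, bg = 0) {
  f <- matrix(bg, size, size)
  for (k in seq_len(nrow(centers))) {
    for (r in 1:size) for (cc in 1:size) {
      if ((r - centers[k, 1])^2 + (cc - centers[k, 2])^2 <= radius[k]^2) {
        f[r, cc] <- value
      }
    }
  }
  f
}

movie_from_frames <- function(frames, dt = 0.28) {
  arr <- array(0L, dim = c(nrow(frames[[1]]), ncol(frames[[1]]), length(frames)))
  for (i in seq_along(frames)) arr[, , i] <- frames[[i]]
  neuract:::new_fluor_movie(arr, dt)
}

test_that("ROI detection: empty frames, single disks, and the area filter", {
  mv <- movie_from_frames(list(matrix(0, 32, 32)))
  rois <- detect_rois(mv, threshold = 50, min_area = 20)
  expect_equal(sum(!rois$is_background), 0)
  expect_equal(sum(rois$is_background), 1)

  f <- make_disk_frame(32, matrix(c(16, 16), 1), 3) # 29-px disk
  rois <- detect_rois(movie_from_frames(list(f)), threshold = 50, min_area = 20)
  expect_equal(sum(!rois$is_background), 1)
  expect_equal(rois$area[1], sum(f > 50))

  # 25-px and 13-px disks: only the larger survives min_area = 20
  f2 <- make_disk_frame(40, matrix(c(10, 10, 30, 30), 2, byrow = TRUE),
                        c(2.9, 2))
  lab <- oracle_components(f2 > 50)
  sizes <- table(lab[lab > 0])
  expect_equal(sort(as.integer(sizes)), c(13, 25))
  rois <- detect_rois(movie_from_frames(list(f2)), threshold = 50, min_area = 20)
  expect_equal(sum(!rois$is_background), 1)
  expect_equal(rois$area[1], 25)
})

test_that("connected components agree with a flood-fill oracle and are 8-connected", {
  set.seed(42)
  for (rep in 1:20) {
    mask <- matrix(runif(15 * 15) < 0.3, 15, 15)
    got <- neuract:::label_components(mask)
    want <- oracle_components(mask)
    # same partition: label images are equal up to renaming
    expect_equal(max(got), max(want))
    for (l in seq_len(max(got))) {
      expect_equal(length(unique(want[got == l])), 1)
    }
  }
  diag2 <- matrix(FALSE, 3, 3); diag2[1, 1] <- diag2[2, 2] <- TRUE
  expect_equal(max(neuract:::label_components(diag2)), 1)
})

test_that("ROI detection ignores the ordering of non-reference frames", {
  sim <- simulate_calcium_movie(calcium_sim_spec(n_cells = 4, image_size = 48,
                                                 n_frames = 12, seed = 8))
  rois1 <- detect_rois(sim$movie, reference_frame_index = 1)
  perm <- sim$movie
  perm$pixels <- perm$pixels[, , c(1, sample(2:12))]
  rois2 <- detect_rois(perm, reference_frame_index = 1)
  expect_identical(rois1$pixels, rois2$pixels)
})

test_that("trace extraction averages member pixels", {
  f1 <- matrix(10, 8, 8); f2 <- matrix(10, 8, 8)
  f2[1, 1] <- 4; f2[1, 2] <- 6
  mv <- movie_from_frames(list(f1, f2))
  rois <- tibble::tibble(roi_id = "roi_1", area = 2L, is_background = FALSE,
                         pixels = list(matrix(c(1, 1, 1, 2), 2, byrow = TRUE)))
  tr <- extract_traces(mv, rois)
  expect_equal(tr$roi_1, c(10, 5))

  bad <- rois
  bad$pixels <- list(matrix(c(9, 1), 1))
  expect_error(extract_traces(mv, bad), "out-of-bounds")
})

test_that("normalization: constant traces, ramps, and the lowest-20% baseline", {
  nt <- normalize_trace(rep(5, 50), 0)
  expect_equal(nt$dff, rep(0, 50))
  expect_equal(nt$f0, 5)

  ramp <- normalize_trace(seq(10, 30, length.out = 100), 0)
  expect_lt(max(abs(ramp$dff - mean(ramp$dff))), 1e-9)

  # 16 samples at 1.0 and 4 at 2.0: F0 = mean of the lowest 4 = 1.0,
  # dF/F0 at the high samples = 1.0 before detrending
  x <- c(rep(1, 16), rep(2, 4))
  xs <- neuract:::moving_average(x, 1) # window 1: no smoothing
  k <- ceiling(0.2 * 20)
  expect_equal(mean(sort(xs)[1:k]), 1.0)
  nt <- normalize_trace(x, 0, smoothing_window = 1)
  expect_equal(nt$f0, 1.0)
  raw_dff <- (x - nt$f0) / nt$f0
  expect_equal(raw_dff[17:20], rep(1, 4))
})

test_that("dF/F0 is invariant to positive scaling of the corrected trace", {
  set.seed(1)
  raw <- 50 + cumsum(rnorm(80))
  for (c_scale in c(0.5, 3, 17)) {
    a <- normalize_trace(raw, 0)
    b <- normalize_trace(raw * c_scale, 0)
    expect_equal(a$dff, b$dff, tolerance = 1e-12)
    expect_equal(b$f0, a$f0 * c_scale, tolerance = 1e-12)
  }
})

test_that("peak detection honours the prominence threshold", {
  expect_equal(nrow(detect_calcium_peaks(rep(0.3, 60), 0.05)), 0)

  bump <- c(rep(0, 10), seq(0, 0.2, length.out = 6),
            seq(0.2, 0, length.out = 6)[-1], rep(0, 10))
  pk <- detect_calcium_peaks(bump, 0.05)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$prominence, 0.2)

  base <- rep(0, 120)
  add_bump <- function(x, at, h, hw = 4) {
    x[(at - hw):(at + hw)] <- x[(at - hw):(at + hw)] +
      h * (1 - abs(seq(-hw, hw)) / (hw + 1))
    x
  }
  x <- add_bump(add_bump(add_bump(base, 20, 0.04), 60, 0.05), 100, 0.30)
  pk <- detect_calcium_peaks(x, 0.05)
  expect_equal(nrow(pk), 2)
  for (p in which(diff(sign(diff(x))) == -2) + 1) {
    expect_equal(neuract:::peak_prominence_at(x, p), oracle_prominence(x, p))
  }
})

test_that("peak duration is the interpolated width at half prominence", {
  # symmetric triangle: height h, half-prominence crossings at half the base
  x <- c(rep(0, 5), seq(0, 0.4, length.out = 11),
         seq(0.4, 0, length.out = 11)[-1], rep(0, 5))
  dt <- 0.28
  pk <- detect_calcium_peaks(x, 0.05)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$duration_s, 10 * dt, tolerance = 1e-9)
})

test_that("neuron metrics enforce the 3-peak rule and report arithmetic", {
  few <- tibble::tibble(time_s = c(1, 2), height = 1, prominence = 1,
                        duration_s = 1)
  expect_false(neuron_metrics(few, 60, min_peaks = 3)$retained)

  pk <- tibble::tibble(time_s = c(10, 20, 40), height = c(1, 2, 3),
                       prominence = c(1, 2, 3), duration_s = c(1, 1, 1))
  m <- neuron_metrics(pk, 60, min_peaks = 3)
  expect_true(m$retained)
  expect_equal(m$peak_to_peak_s, 15)
  expect_equal(m$frequency_hz, 0.05)
  expect_equal(m$amplitude, 2)
})

test_that("recording summary is the median over retained neurons", {
  one <- neuron_metrics(tibble::tibble(time_s = c(1, 5, 9), height = 1,
                                       prominence = 1, duration_s = 1),
                        60, 3, "roi_1")
  s <- recording_summary(one)
  expect_equal(s$frequency_hz, one$frequency_hz)
  expect_equal(s$n_neurons, 1)

  three <- dplyr::bind_rows(lapply(c(0.1, 0.2, 0.9), function(f) {
    m <- one; m$frequency_hz <- f; m
  }))
  expect_equal(recording_summary(three)$frequency_hz, 0.2)
  empty <- one; empty$retained <- FALSE
  expect_true(recording_summary(empty)$empty)
})

test_that("noiseless end-to-end recovery finds every event at the right time", {
  spec <- calcium_sim_spec(n_cells = 60, noise_sd = 0, seed = 21)
  sim <- simulate_calcium_traces(spec)
  res <- analyze_calcium(dplyr::bind_cols(sim$traces,
                                          background = sim$background))
  dt <- spec$frame_interval_s
  for (i in 1:60) {
    truth <- sim$truth$event_times[[i]] + sim$truth$peak_lag_s
    pk <- res$peaks[[paste0("roi_", i)]]
    expect_equal(nrow(pk), length(truth))
    if (length(truth) > 0) {
      expect_lt(max(abs(sort(pk$time_s) - sort(truth))), dt + 1e-9)
    }
  }
})

test_that("doubling the event rate doubles the recovered median frequency", {
  base <- calcium_sim_spec(n_cells = 50, noise_sd = 0.01, event_rate_hz = 0.05,
                           n_frames = 640, refractory_s = 3, seed = 31)
  fast <- calcium_sim_spec(n_cells = 50, noise_sd = 0.01, event_rate_hz = 0.1,
                           n_frames = 640, refractory_s = 3, seed = 32)
  f_of <- function(spec) {
    sim <- simulate_calcium_traces(spec)
    res <- analyze_calcium(dplyr::bind_cols(sim$traces,
                                            background = sim$background))
    truth_freq <- mean(lengths(sim$truth$event_times)) /
      (spec$n_frames * spec$frame_interval_s)
    c(got = res$summary$frequency_hz, truth = truth_freq)
  }
  a <- f_of(base); b <- f_of(fast)
  expect_equal(b[["got"]] / a[["got"]], b[["truth"]] / a[["truth"]],
               tolerance = 0.1)
})
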