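# ---- small DSP kernel (no DSP package in the supported stack) ----

# linear-phase windowed-sinc band-pass (Hamming window, odd length);
# Hamming gives ~53 dB stop-band attenuation
fir_bandpass <- function(fs, low, high, n_taps = NULL) {
  if (is.null(n_taps)) {
    trans <- max(1, min(low / 2, (fs / 2 - high) / 2, 4))  # Hz
    n_taps <- ceiling(3.3 * fs / trans)
  }
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  m <- (n_taps - 1) / 2
  k <- -m:m
  sinc <- function(fc) {
    h <- 2 * fc / fs * sin(pi * 2 * fc / fs * k) / (pi * 2 * fc / fs * k)
    h[k == 0] <- 2 * fc / fs
    h
  }
  h <- sinc(high) - sinc(low)
  w <- 0.54 + 0.46 * cos(pi * k / m)  # Hamming
  h * w
}

# centred ("same") FFT convolution; h must have odd length
conv_same <- function(x, h) {
  n <- length(x); m <- length(h)
  nfft <- nextn(n + m - 1, 2)
  y <- Re(fft(fft(c(x, numeric(nfft - n))) *
               fft(c(h, numeric(nfft - m))), inverse = TRUE)) / nfft
  y[((m - 1) / 2 + 1):((m - 1) / 2 + n)]
}

# analytic-signal magnitude via the frequency-domain Hilbert construction
hilbert_envelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

#' Band-limited amplitude envelope
#'
#' Zero-phase FIR band-pass (windowed sinc, linear phase, ~53 dB stop band)
#' followed by the analytic-signal magnitude. Samples within half the
#' filter length of either edge are unreliable; their count is attached as
#' attribute `edge`.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param band Two-element band in Hz (default 13-30).
#' @param n_taps Optional FIR length override.
#' @return Numeric envelope, same length as `x`, with attributes `edge`,
#'   `fs` and `band`.
#' @export
band_envelope <- function(x, fs, band = c(13, 30), n_taps = NULL) {
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2])
  if (band[2] >= fs / 2) stop("band must lie below the Nyquist frequency")
  h <- fir_bandpass(fs, band[1], band[2], n_taps)
  env <- hilbert_envelope(conv_same(as.numeric(x), h))
  attr(env, "edge") <- (length(h) - 1) / 2
  attr(env, "fs") <- fs
  attr(env, "band") <- band
  env
}

#' Burst threshold from a rest-period envelope
#'
#' The detection threshold is a percentile (default the 75th; the median is
#' the control choice) of the amplitude envelope recorded at rest, so one
#' common threshold per subject applies across performance blocks.
#'
#' @param rest_envelope Numeric envelope from a rest recording.
#' @param percentile Percentile in \[0, 100\] (default 75).
#' @return Scalar threshold (a.u.).
#' @export
threshold_from_rest <- function(rest_envelope, percentile = 75) {
  if (length(rest_envelope) == 0) stop("rest envelope is empty")
  stopifnot(percentile >= 0, percentile <= 100)
  edge <- attr(rest_envelope, "edge")
  x <- as.numeric(rest_envelope)
  if (!is.null(edge) && edge > 0 && length(x) > 2 * edge) {
    x <- x[(edge + 1):(length(x) - edge)]
  }
  as.numeric(quantile(x, percentile / 100, type = 7, names = FALSE))
}

#' Detect oscillation bursts in an amplitude envelope
#'
#' Contiguous above-threshold runs are extracted; runs separated by less
#' than `merge_gap_ms` are merged into one burst; merged runs shorter than
#' `min_dur_ms` (one band cycle, 50 ms by default) are discarded. Events
#' are half-open `[onset, onset + duration)` in seconds.
#'
#' @param envelope Numeric envelope (e.g. from [band_envelope()]).
#' @param fs Sampling rate in Hz.
#' @param threshold Positive detection threshold.
#' @param min_dur_ms Minimum burst duration in ms (default 50).
#' @param merge_gap_ms Gaps shorter than this are bridged (default 50).
#' @param channel Optional channel label stored with the events.
#' @return data.frame with columns `channel`, `onset_s`, `duration_ms`,
#'   `peak_amplitude` (possibly 0 rows).
#' @export
detect_bursts <- function(envelope, fs, threshold, min_dur_ms = 50,
                          merge_gap_ms = 50, channel = "ch1") {
  stopifnot(threshold > 0)
  x <- as.numeric(envelope)
  above <- x > threshold
  empty <- data.frame(channel = character(0), onset_s = numeric(0),
                      duration_ms = numeric(0), peak_amplitude = numeric(0))
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by < merge_gap_ms
  gap_smp <- merge_gap_ms / 1000 * fs
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1) {
    for (i in 2:nrow(seg)) {
      last <- nrow(merged)
      if (seg$start[i] - merged$end[last] - 1 < gap_smp) {
        merged$end[last] <- seg$end[i]
      } else {
        merged <- rbind(merged, seg[i, ])
      }
    }
  }
  dur_ms <- (merged$end - merged$start + 1) / fs * 1000
  keep <- dur_ms >= min_dur_ms
  if (!any(keep)) return(empty)
  merged <- merged[keep, , drop = FALSE]
  dur_ms <- dur_ms[keep]
  peak <- mapply(function(s, e) max(x[s:e]), merged$start, merged$end)
  data.frame(channel = channel, onset_s = (merged$start - 1) / fs,
             duration_ms = dur_ms, peak_amplitude = peak)
}

#' Burst duration distribution and life-time exponent
#'
#' Histograms burst durations into 20 log-equidistant bins on
#' \[50, 2000\] ms and fits a straight line through the double-log
#' representation of the probability density (counts normalized by total
#' count and bin width in ms). The life-time exponent `tau` is the absolute
#' slope; empty bins and, following convention, the first bin are excluded
#' from the fit. Fitting the density rather than raw per-bin probability is
#' what makes `tau` recover the exponent of a `d^-tau` sample under
#' log-spaced bins (see the methods vignette).
#'
#' @param events data.frame from [detect_bursts()], or a numeric vector of
#'   durations in ms.
#' @param n_bins Number of bins (default 20).
#' @param range_ms Histogram range in ms (default `c(50, 2000)`).
#' @param exclude_first Exclude the first bin from the fit (default TRUE).
#' @return A `burst_distribution` list: `bin_edges` (n_bins + 1), `counts`,
#'   `probability`, `density`, `centers_ms`, `tau`, `fit_bins`,
#'   `intercept`.
#' @export
duration_distribution <- function(events, n_bins = 20,
                                  range_ms = c(50, 2000),
                                  exclude_first = TRUE) {
  dur <- if (is.data.frame(events)) events$duration_ms else as.numeric(events)
  dur <- dur[dur >= range_ms[1] & dur <= range_ms[2]]
  if (length(dur) < 1) stop("no events within the histogram range")
  edges <- exp(seq(log(range_ms[1]), log(range_ms[2]),
                   length.out = n_bins + 1))
  counts <- tabulate(findInterval(dur, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  widths <- diff(edges)
  centers <- sqrt(edges[-1] * edges[-(n_bins + 1)])
  prob <- counts / sum(counts)
  dens <- prob / widths
  fit_bins <- which(counts > 0)
  if (exclude_first) fit_bins <- setdiff(fit_bins, 1L)
  if (length(fit_bins) < 3) {
    stop("insufficient support: fewer than 3 non-empty bins in the fit range")
  }
  fit <- stats::lm.fit(cbind(1, log10(centers[fit_bins])),
                       log10(dens[fit_bins]))
  structure(list(bin_edges = edges, counts = counts, probability = prob,
                 density = dens, centers_ms = centers,
                 tau = abs(unname(fit$coefficients[2])),
                 intercept = unname(fit$coefficients[1]),
                 fit_bins = fit_bins, n_events = length(dur)),
            class = "burst_distribution")
}

#' Time course of the burst rate across trial epochs
#'
#' Bins burst onsets on a common epoch grid (GO at 0 s) and returns the
#' across-trial onset rate in bursts/s, optionally restricted to brief
#' (< 300 ms) or long (> 500 ms) bursts. Bursts are assigned to bins by
#' onset; events outside the epoch are dropped and counted.
#'
#' @param events_by_trial List (one element per trial) of data.frames with
#'   `onset_s` (relative to GO) and `duration_ms`.
#' @param epoch Two-element epoch window in s (default `c(-1, 11)`).
#' @param bin_s Bin width in s (default 0.1, the TF hop).
#' @param class `"all"`, `"brief"` (< `brief_max_ms`) or `"long"`
#'   (> `long_min_ms`).
#' @param brief_max_ms,long_min_ms Duration class cut-offs (300 / 500 ms).
#' @return Numeric rate series (bursts/s) with attributes `times` (bin left
#'   edges, s) and `n_dropped`.
#' @export
burst_rate_timecourse <- function(events_by_trial, epoch = c(-1, 11),
                                  bin_s = 0.1,
                                  class = c("all", "brief", "long"),
                                  brief_max_ms = 300, long_min_ms = 500) {
  class <- match.arg(class)
  stopifnot(is.list(events_by_trial), length(events_by_trial) >= 1)
  edges <- seq(epoch[1], epoch[2], by = bin_s)
  n_bins <- length(edges) - 1
  counts <- numeric(n_bins)
  dropped <- 0L
  for (ev in events_by_trial) {
    if (is.null(ev) || nrow(ev) == 0) next
    keep <- switch(class,
                   all = rep(TRUE, nrow(ev)),
                   brief = ev$duration_ms < brief_max_ms,
                   long = ev$duration_ms > long_min_ms)
    on <- ev$onset_s[keep]
    out <- on < epoch[1] | on >= epoch[2]
    dropped <- dropped + sum(out)
    on <- on[!out]
    if (length(on)) {
      idx <- pmin(floor((on - epoch[1]) / bin_s) + 1, n_bins)
      counts <- counts + tabulate(idx, nbins = n_bins)
    }
  }
  rate <- counts / (length(events_by_trial) * bin_s)
  attr(rate, "times") <- edges[-length(edges)]
  attr(rate, "n_dropped") <- dropped
  rate
}
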