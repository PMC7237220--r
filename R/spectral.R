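#' Welch power spectral density
#'
#' Averaged modified periodogram: 1 s Hann segments with 50% overlap by
#' default, segment means removed, one-sided density scaling (power units
#' squared per Hz).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param window_s Segment length in seconds (default 1).
#' @param overlap Fractional overlap in \[0, 1) (default 0.5).
#' @return data.frame with columns `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, window_s = 1, overlap = 0.5) {
  x <- as.numeric(x)
  nseg <- round(fs * window_s)
  step <- round(nseg * (1 - overlap))
  if (length(x) < nseg + step) stop("signal too short for 2 Welch segments")
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nseg - 1)) / nseg)  # periodic Hann
  starts <- seq(1, length(x) - nseg + 1, by = step)
  scale <- 1 / (fs * sum(w^2))
  acc <- numeric(nseg %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[seq_len(nseg %/% 2 + 1)]
    acc <- acc + Mod(X)^2 * scale
  }
  psd <- acc / length(starts)
  one_sided <- rep(2, length(psd))
  one_sided[1] <- 1
  if (nseg %% 2 == 0) one_sided[length(psd)] <- 1
  data.frame(freq = (seq_along(psd) - 1) * fs / nseg, psd = psd * one_sided)
}

#' Decibel normalization of a PSD against rest
#'
#' `10 * log10(block / rest)` per frequency; the rest PSD (e.g. from the
#' initial rest recording) must be strictly positive.
#'
#' @param psd_block,psd_rest Numeric vectors on the same frequency grid.
#' @return Numeric dB series.
#' @export
db_normalize <- function(psd_block, psd_rest) {
  if (length(psd_block) != length(psd_rest)) stop("PSD grids differ")
  if (any(psd_rest <= 0)) stop("rest PSD must be strictly positive")
  10 * log10(psd_block / psd_rest)
}

#' Trial epochs container
#'
#' @param data Numeric array `trials x channels x samples` (a matrix is
#'   taken as `trials x samples` of a single channel; a vector as one trial
#'   of one channel).
#' @param fs Sampling rate in Hz.
#' @param t_start Time of the first sample relative to GO (default -1 s).
#' @param channels Optional channel labels.
#' @param markers Named numeric vector of event times in s (default GO 0,
#'   STOP 7, feedback 9).
#' @return A `trial_epochs` list.
#' @export
trial_epochs <- function(data, fs, t_start = -1, channels = NULL,
                         markers = c(go = 0, stop = 7, feedback = 9)) {
  if (is.vector(data)) data <- array(data, c(1, 1, length(data)))
  if (is.matrix(data)) data <- array(data, c(nrow(data), 1, ncol(data)))
  stopifnot(length(dim(data)) == 3)
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[2]))
  structure(list(data = data, fs = fs, t_start = t_start,
                 channels = channels, markers = markers,
                 times = t_start + (seq_len(dim(data)[3]) - 1) / fs),
            class = "trial_epochs")
}

# complex Morlet kernel at frequency f; sqrt(2)-scaled amplitude
# normalization so a pure tone of amplitude A yields squared magnitude
# A^2/2, i.e. power in variance units comparable to integrated Welch PSD
morlet_kernel <- function(f, fs, n_cycles) {
  sd_t <- n_cycles / (2 * pi * f)
  half <- ceiling(4 * sd_t * fs)
  t <- (-half:half) / fs
  g <- exp(-t^2 / (2 * sd_t^2))
  sqrt(2) * g * exp(2i * pi * f * t) / sum(g)
}

# centred complex FFT convolution
conv_same_cplx <- function(x, h) {
  n <- length(x); m <- length(h)
  nfft <- nextn(n + m - 1, 2)
  y <- fft(fft(c(x, numeric(nfft - n))) *
            fft(c(h, rep(0 + 0i, nfft - m))), inverse = TRUE) / nfft
  y[((m - 1) / 2 + 1):((m - 1) / 2 + n)]
}

#' Morlet time-frequency power of trial epochs
#'
#' Convolves every trial and channel with 7-cycle complex Morlet wavelets
#' at 1 Hz steps over the beta range (13-30 Hz by default), takes the
#' squared magnitude (wavelet energy) and samples it on a 100 ms hop grid.
#'
#' @param epochs A [trial_epochs()] object.
#' @param freqs Analysis frequencies in Hz (default `13:30`).
#' @param n_cycles Wavelet width in cycles (default 7).
#' @param hop_s Hop of the output grid in s (default 0.1).
#' @param keep_trials Keep the trial dimension (default `TRUE`); otherwise
#'   power is averaged across trials.
#' @return A `tf_power` list: `power` (array `trial x channel x freq x
#'   time`, or `channel x freq x time` when averaged), `dims`, `freqs`,
#'   `times`, `fs`, `channels`, `markers`, `normalization = "none"`.
#' @export
morlet_tf <- function(epochs, freqs = 13:30, n_cycles = 7, hop_s = 0.1,
                      keep_trials = TRUE) {
  stopifnot(inherits(epochs, "trial_epochs"))
  d <- dim(epochs$data)
  n_smp <- d[3]
  kernels <- lapply(freqs, morlet_kernel, fs = epochs$fs,
                    n_cycles = n_cycles)
  too_long <- vapply(kernels, length, integer(1)) > n_smp
  if (any(too_long)) {
    stop(sprintf("epoch too short for the %g Hz wavelet (%d taps > %d samples)",
                 freqs[which(too_long)[1]],
                 length(kernels[[which(too_long)[1]]]), n_smp))
  }
  t_end <- epochs$times[n_smp]
  out_times <- seq(epochs$t_start, t_end, by = hop_s)
  out_idx <- round((out_times - epochs$t_start) * epochs$fs) + 1
  out_idx <- pmin(out_idx, n_smp)
  pw <- array(NA_real_, c(d[1], d[2], length(freqs), length(out_times)))
  for (tr in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      x <- epochs$data[tr, ch, ]
      for (fi in seq_along(freqs)) {
        e <- Mod(conv_same_cplx(x, kernels[[fi]]))^2
        pw[tr, ch, fi, ] <- e[out_idx]
      }
    }
  }
  dims <- c("trial", "channel", "freq", "time")
  if (!keep_trials) {
    pw <- apply(pw, c(2, 3, 4), mean)
    dims <- dims[-1]
  }
  structure(list(power = pw, dims = dims, freqs = freqs, times = out_times,
                 fs = epochs$fs, channels = epochs$channels,
                 markers = epochs$markers, normalization = "none"),
            class = "tf_power")
}

#' Baseline z-normalization of time-frequency power
#'
#' Per channel, frequency (and trial, when present): subtract the mean and
#' divide by the sd of the power inside the baseline window.
#'
#' @param tf A `tf_power` object.
#' @param baseline Two-element window in s (default `c(-1, 0)`, the
#'   pre-movement period).
#' @return The z-normalized `tf_power` (`normalization = "z-baseline"`).
#' @export
baseline_z <- function(tf, baseline = c(-1, 0)) {
  stopifnot(inherits(tf, "tf_power"))
  bidx <- which(tf$times >= baseline[1] & tf$times <= baseline[2])
  if (length(bidx) < 2) stop("baseline window not inside the epoch")
  tdim <- length(tf$dims)
  pw <- tf$power
  apply_z <- function(series) {
    m <- mean(series[bidx]); s <- stats::sd(series[bidx])
    if (!is.finite(s) || s == 0) stop("zero baseline sd")
    (series - m) / s
  }
  pw2 <- apply(pw, seq_len(tdim - 1), apply_z)  # time becomes dim 1
  pw <- aperm(pw2, order(c(tdim, seq_len(tdim - 1))))
  tf$power <- pw
  tf$normalization <- "z-baseline"
  tf
}

#' Average time-frequency power across a frequency band
#'
#' @param tf A `tf_power` object.
#' @param band Optional two-element frequency range in Hz; defaults to all
#'   frequencies present.
#' @return The `tf_power` with the frequency dimension collapsed (`dims`
#'   loses `"freq"`).
#' @export
band_average <- function(tf, band = NULL) {
  stopifnot(inherits(tf, "tf_power"))
  fdim <- which(tf$dims == "freq")
  sel <- if (is.null(band)) seq_along(tf$freqs) else
    which(tf$freqs >= band[1] & tf$freqs <= band[2])
  if (!length(sel)) stop("no frequencies in band")
  pw <- apply(tf$power, setdiff(seq_along(tf$dims), fdim), function(v) mean(v[sel]))
  # apply() with a dim subset collapses in the order given; dims follow
  tf$power <- pw
  tf$dims <- tf$dims[-fdim]
  tf
}

#' Average time-frequency power across trials
#'
#' @param tf A `tf_power` object with a trial dimension.
#' @return The `tf_power` averaged across trials.
#' @export
tf_average <- function(tf) {
  stopifnot(inherits(tf, "tf_power"), tf$dims[1] == "trial")
  tf$power <- apply(tf$power, seq_along(tf$dims)[-1], mean)
  tf$dims <- tf$dims[-1]
  tf
}

#' Per-trial feedback-locked scalar measure
#'
#' Averages a per-trial power (or burst-rate) representation over the
#' post-feedback window (400-1600 ms after the feedback marker by default)
#' and over a channel set, returning one value per trial.
#'
#' @param tf A `tf_power` object with a trial dimension (any remaining
#'   frequency dimension is averaged too), or a numeric matrix `trials x
#'   time` with `times` supplied.
#' @param window_ms Window relative to feedback onset in ms (default
#'   `c(400, 1600)`).
#' @param feedback_s Feedback marker time in s (default taken from the
#'   epoch markers, 9 s).
#' @param channels Channel labels or indices to average (default all).
#' @param times Time grid, required when `tf` is a plain matrix.
#' @return Numeric vector, one value per trial.
#' @export
feedback_locked_measure <- function(tf, window_ms = c(400, 1600),
                                    feedback_s = NULL, channels = NULL,
                                    times = NULL) {
  if (is.matrix(tf)) {
    if (is.null(times)) stop("times required for matrix input")
    if (is.null(feedback_s)) feedback_s <- 9
    win <- feedback_s + window_ms / 1000
    if (win[2] > max(times) + 1e-9) stop("window extends past the epoch")
    idx <- which(times >= win[1] & times <= win[2])
    return(rowMeans(tf[, idx, drop = FALSE]))
  }
  stopifnot(inherits(tf, "tf_power"), tf$dims[1] == "trial")
  if (is.null(feedback_s)) {
    feedback_s <- if (!is.null(tf$markers) && "feedback" %in% names(tf$markers))
      tf$markers[["feedback"]] else 9
  }
  win <- feedback_s + window_ms / 1000
  if (win[2] > max(tf$times) + 1e-9) stop("window extends past the epoch")
  tidx <- which(tf$times >= win[1] & tf$times <= win[2])
  cdim <- which(tf$dims == "channel")
  cidx <- seq_len(dim(tf$power)[cdim])
  if (!is.null(channels)) {
    cidx <- if (is.character(channels)) match(channels, tf$channels) else channels
    if (any(is.na(cidx))) stop("unknown channel label")
  }
  n_tr <- dim(tf$power)[1]
  vapply(seq_len(n_tr), function(tr) {
    sl <- switch(paste(tf$dims, collapse = ","),
                 "trial,channel,freq,time" = tf$power[tr, cidx, , tidx, drop = FALSE],
                 "trial,channel,time" = tf$power[tr, cidx, tidx, drop = FALSE],
                 stop("unsupported tf layout: ",
                      paste(tf$dims, collapse = ",")))
    mean(sl)
  }, numeric(1))
}
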