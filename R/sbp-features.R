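#' Spiking-band-power extraction configuration
#'
#' The SBP chain: raw broadband (default 30 ksps) is anti-alias decimated to
#' 2 ksps, bandpass filtered to 300-1000 Hz, and rectified; the rectified
#' signal is then averaged into non-overlapping bins (default 50 ms).
#'
#' @param fs_in input sampling rate, Hz.
#' @param fs_mid intermediate rate after decimation, Hz.
#' @param band numeric length-2 bandpass edges, Hz.
#' @param bin_ms bin width, ms.
#' @param filter_order Butterworth order for the bandpass (applied
#'   forward-backward, so zero-phase).
#' @return an `sbp_config` list.
#' @export
sbp_config <- function(fs_in = 30000, fs_mid = 2000, band = c(300, 1000),
                       bin_ms = 50, filter_order = 4) {
  if (fs_in < 2 * band[2]) {
    stop("sbp_config: fs_in must be at least twice the upper band edge")
  }
  if (band[1] <= 0 || band[2] > fs_mid / 2) {
    stop("sbp_config: band must lie inside (0, fs_mid/2]")
  }
  if (fs_in %% fs_mid != 0) {
    stop("sbp_config: fs_in must be an integer multiple of fs_mid")
  }
  structure(list(fs_in = fs_in, fs_mid = fs_mid, band = band, bin_ms = bin_ms,
                 filter_order = filter_order), class = "sbp_config")
}

#' Extract the rectified spiking-band-power signal
#'
#' Polyphase anti-aliased decimation to `fs_mid`, zero-phase Butterworth
#' bandpass over `config$band`, then full-wave rectification. Output is
#' nonnegative and positively homogeneous in the input amplitude.
#'
#' @param raw 1-D numeric broadband signal at `config$fs_in`.
#' @param config an [sbp_config()].
#' @return nonnegative numeric vector at `config$fs_mid`.
#' @export
extract_sbp <- function(raw, config = sbp_config()) {
  dec <- config$fs_in / config$fs_mid
  if (length(raw) < 8 * dec) {
    stop("extract_sbp: input shorter than one filter settling span")
  }
  x <- if (dec > 1) {
    # a long FIR keeps the passband flat well past the 300-1000 Hz band
    signal::decimate(raw, dec, n = 10 * dec, ftype = "fir")
  } else {
    raw
  }
  nyq <- config$fs_mid / 2
  # with the upper edge at Nyquist the bandpass degenerates to a highpass
  bf <- if (config$band[2] >= 0.999 * nyq) {
    signal::butter(config$filter_order, config$band[1] / nyq, type = "high")
  } else {
    signal::butter(config$filter_order, config$band / nyq, type = "pass")
  }
  abs(signal::filtfilt(bf, x))
}

#' Average a rectified signal into non-overlapping bins
#'
#' @param sbp_2k numeric vector at `fs` Hz.
#' @param bin_ms bin width, ms.
#' @param fs sampling rate of `sbp_2k`, Hz.
#' @return numeric vector of bin means; a trailing partial bin is dropped.
#' @export
bin_sbp <- function(sbp_2k, bin_ms = 50, fs = 2000) {
  per <- round(fs * bin_ms / 1000)
  if (length(sbp_2k) < per) stop("bin_sbp: input shorter than one bin")
  n_bins <- length(sbp_2k) %/% per
  colMeans(matrix(sbp_2k[seq_len(n_bins * per)], nrow = per))
}

#' Build time-history feature windows
#'
#' Window t stacks bins t - n_history .. t of every channel, so each decoder
#' input spans (n_history + 1) * bin_ms of SBP (the default 2 bins of
#' lookback plus the current bin = 150 ms). The first `n_history` bins yield
#' no window and are dropped; the returned alignment maps each window row to
#' its velocity row.
#'
#' Window rows are laid out channel-major: for channel c the `n_history + 1`
#' lags (oldest to current) occupy consecutive columns.
#'
#' @param binned T x C matrix of binned SBP.
#' @param n_history number of lookback bins (default 2).
#' @return list with `windows` ((T - n_history) x (C*(n_history+1)) matrix),
#'   `target_rows` (1-based row indices into the original T rows), and
#'   `n_history`.
#' @export
build_history_windows <- function(binned, n_history = 2) {
  binned <- as.matrix(binned)
  T <- nrow(binned); C <- ncol(binned)
  H <- n_history + 1
  if (T <= n_history) {
    stop("build_history_windows: need more rows than history bins")
  }
  n_win <- T - n_history
  # lag l in 0..n_history contributes rows (n_history - l + 1) .. (T - l)
  cols <- vector("list", C)
  win <- matrix(0, n_win, C * H)
  for (l in 0:(H - 1)) {
    rows <- (n_history - l + 1):(T - l)
    # lag l is the (H - l)-th column within each channel block
    win[, seq.int(H - l, C * H, by = H)] <- binned[rows, , drop = FALSE]
  }
  list(windows = win, target_rows = (n_history + 1):T, n_history = n_history)
}
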