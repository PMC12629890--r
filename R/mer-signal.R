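#' One raw microelectrode recording segment
#'
#' A single depth step of an MER trajectory: ~10 s of extracellular signal
#' recorded while the electrode is held at a fixed depth.  Depth is signed
#' millimetres relative to the planned target (negative above the target),
#' advancing in nominal 0.5 mm steps.
#'
#' @param samples numeric vector of signal amplitudes (microvolts).
#' @param sampling_rate sampling rate in Hz (nominal 24000).
#' @param depth signed depth in mm relative to the planned target.
#' @param trajectory_id channel label, conventionally one of `"Central"`,
#'   `"Anterior"`, `"Posterior"`, `"Medial"`, `"Lateral"`.
#' @return An object of class `mer_segment`.
#' @export
mer_segment <- function(samples, sampling_rate = 24000, depth = 0,
                        trajectory_id = "Central") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("samples must be non-empty")
  if (!is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be positive")
  }
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 depth = depth, trajectory_id = trajectory_id),
            class = "mer_segment")
}

#' Root-mean-square amplitude of a segment
#'
#' @param segment a [mer_segment()] or a bare numeric vector.
#' @return RMS amplitude in the units of the input (microvolts).
#' @export
compute_rms <- function(segment) {
  x <- if (inherits(segment, "mer_segment")) segment$samples else as.numeric(segment)
  if (length(x) == 0L) stop("cannot compute RMS of an empty segment")
  sqrt(mean(x^2))
}

#' Normalised RMS sequence for one trajectory
#'
#' The NRMS feature: per-depth RMS divided by the mean RMS over the first
#' `n_baseline` recording depths of the trajectory, so that pre-STN
#' background activity sits near 1 and STN activity well above it.  The
#' baseline count is a package choice (the normalisation window of the
#' upstream platform is not standardised); it is configurable and recorded
#' in the output.
#'
#' @param segments ordered list of [mer_segment()] objects from one
#'   trajectory, in acquisition (depth) order.
#' @param n_baseline number of initial depths averaged into the baseline
#'   (default 5).
#' @param labels optional 0/1 vector of STN labels per depth; a warning is
#'   emitted if any baseline depth is labelled STN (the baseline should be
#'   pre-STN background).
#' @return An object of class `nrms_sequence`: a list with
#'   `trajectory_id`, `depth` (mm), `nrms` (dimensionless, baseline mean
#'   exactly 1), `baseline_rms` (microvolts) and `n_baseline`.
#' @export
compute_nrms <- function(segments, n_baseline = 5, labels = NULL) {
  if (length(segments) < n_baseline) {
    stop(sprintf("need at least n_baseline = %d segments, got %d",
                 n_baseline, length(segments)))
  }
  ids <- unique(vapply(segments, function(s) s$trajectory_id, character(1)))
  if (length(ids) != 1L) stop("all segments must come from one trajectory")
  rms <- vapply(segments, compute_rms, numeric(1))
  baseline <- mean(rms[seq_len(n_baseline)])
  if (baseline <= 0) stop("baseline RMS is zero; cannot normalise")
  if (!is.null(labels) && any(labels[seq_len(n_baseline)] == 1)) {
    warning("baseline depths include STN-labelled segments; NRMS baseline is contaminated")
  }
  nrms_sequence(trajectory_id = ids,
                depth = vapply(segments, function(s) s$depth, numeric(1)),
                nrms = rms / baseline,
                baseline_rms = baseline,
                n_baseline = n_baseline)
}

#' Construct an NRMS sequence directly
#'
#' Container used when NRMS values are precomputed (e.g. loaded from a CSV
#' table) rather than derived from raw segments.
#'
#' @param trajectory_id channel label.
#' @param depth ordered numeric depths (mm).
#' @param nrms strictly positive NRMS value per depth.
#' @param baseline_rms normalising constant (microvolts), `NA` if unknown.
#' @param n_baseline baseline depth count used, `NA` if unknown.
#' @return An object of class `nrms_sequence`.
#' @export
nrms_sequence <- function(trajectory_id, depth, nrms, baseline_rms = NA_real_,
                          n_baseline = NA_integer_) {
  depth <- as.numeric(depth)
  nrms <- as.numeric(nrms)
  if (length(depth) != length(nrms)) stop("depth and nrms lengths differ")
  if (length(nrms) == 0L) stop("empty NRMS sequence")
  if (any(!is.finite(nrms)) || any(nrms <= 0)) stop("nrms must be positive and finite")
  structure(list(trajectory_id = trajectory_id, depth = depth, nrms = nrms,
                 baseline_rms = baseline_rms, n_baseline = n_baseline),
            class = "nrms_sequence")
}

#' @export
print.nrms_sequence <- function(x, ...) {
  cat(sprintf("nrms_sequence [%s]: %d depths (%.1f to %.1f mm), NRMS %.2f-%.2f\n",
              x$trajectory_id, length(x$depth), min(x$depth), max(x$depth),
              min(x$nrms), max(x$nrms)))
  invisible(x)
}

#' Zero-phase band-pass filter for simulated raw signals
#'
#' Frequency-domain Butterworth-magnitude band-pass (order `order` for each
#' of the low and high edges, zero phase by construction).  Real MER inputs
#' are already band-passed by the acquisition chain (500-5000 Hz) and should
#' not be re-filtered; this filter exists so simulated raw signals match the
#' stated acquisition chain.
#'
#' @param x numeric signal.
#' @param sampling_rate Hz.
#' @param low,high band edges in Hz.
#' @param order filter order per edge (default 4).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, sampling_rate, low = 500, high = 5000, order = 4) {
  n <- length(x)
  if (high >= sampling_rate / 2) stop("high edge must be below Nyquist")
  freqs <- seq(0, sampling_rate - sampling_rate / n, length.out = n)
  freqs <- pmin(freqs, sampling_rate - freqs)  # two-sided spectrum folding
  h <- bandpass_gain(freqs, low, high, order)
  Re(fft(fft(x) * h, inverse = TRUE)) / n
}

# |H(f)| of the band-pass: Butterworth high-pass at `low` times Butterworth
# low-pass at `high`
bandpass_gain <- function(freqs, low, high, order) {
  hp <- 1 / sqrt(1 + (low / pmax(freqs, 1e-12))^(2 * order))
  lp <- 1 / sqrt(1 + (freqs / high)^(2 * order))
  hp * lp
}

# RMS gain of the band-pass applied to white noise at `sampling_rate`
# (used by the simulator to compensate so target RMS refers to the
# filtered, in-band signal)
bandpass_noise_gain <- function(sampling_rate, low = 500, high = 5000,
                                order = 4, n = 4096) {
  freqs <- seq(0, sampling_rate / 2, length.out = n)
  sqrt(mean(bandpass_gain(freqs, low, high, order)^2))
}
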