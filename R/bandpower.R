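#' Region-level time series container
#'
#' Holds one amplitude time series per parcellated cortical region, all at a
#' common sampling rate. This is the entry point of the spectral pipeline;
#' sensor-level processing (artifact removal, source reconstruction) is
#' assumed to have happened upstream.
#'
#' @param data numeric matrix, regions x samples.
#' @param region_ids character vector of unique region labels, one per row.
#' @param fs sampling rate in Hz (> 0).
#' @return An object of class `region_ts` with fields `region_ids`, `data`,
#'   `fs` and `duration_s`.
#' @export
region_ts <- function(data, region_ids, fs) {
  data <- as.matrix(data)
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number (Hz)")
  if (length(region_ids) != nrow(data))
    stop("need one region id per row of data")
  if (anyDuplicated(region_ids)) stop("region_ids must be unique")
  bad <- which(!apply(data, 1, function(r) all(is.finite(r))))
  if (length(bad))
    stop("non-finite samples in region(s): ",
         paste(region_ids[bad], collapse = ", "))
  structure(list(region_ids = as.character(region_ids), data = data,
                 fs = fs, duration_s = ncol(data) / fs),
            class = "region_ts")
}

#' @export
print.region_ts <- function(x, ...) {
  cat(sprintf("Region time series: %d regions x %d samples (%.1f s @ %g Hz)\n",
              nrow(x$data), ncol(x$data), x$duration_s, x$fs))
  invisible(x)
}

#' Welch power spectral density of region time series
#'
#' Averages Hann-tapered, constant-detrended modified periodograms over
#' sliding windows (a final incomplete window is dropped). The one-sided
#' density is scaled so that summing `psd * df` over the grid recovers the
#' mean squared amplitude of the windowed signal.
#'
#' @param ts a [region_ts()].
#' @param window_s window length in seconds; the frequency resolution is
#'   `1 / window_s` Hz. Default 2.
#' @param overlap_frac fractional overlap between consecutive windows, in
#'   `[0, 1)`. Default 0.5.
#' @return An object of class `regional_psd` with fields `region_ids`,
#'   `freqs` (Hz grid from 0 to Nyquist) and `psd` (regions x bins, power
#'   per Hz).
#' @examples
#' t <- seq(0, 10, by = 1 / 256)[-1]
#' ts <- region_ts(rbind(sin(2 * pi * 10 * t)), "roi_1", fs = 256)
#' psd <- welch_psd(ts)
#' psd$freqs[which.max(psd$psd[1, ])]  # 10 Hz
#' @export
welch_psd <- function(ts, window_s = 2, overlap_frac = 0.5) {
  stopifnot(inherits(ts, "region_ts"))
  nper <- round(window_s * ts$fs)
  if (nper < 2) stop("window_s * fs must be at least 2 samples")
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("overlap_frac must be in [0, 1)")
  n <- ncol(ts$data)
  if (n < nper)
    stop("signal shorter than one window for region(s): ",
         paste(ts$region_ids, collapse = ", "))
  hop <- max(1L, as.integer(round(nper * (1 - overlap_frac))))
  starts <- seq(1L, n - nper + 1L, by = hop)
  w <- as.numeric(signal::hanning(nper))
  scale <- 1 / (ts$fs * sum(w^2))
  nfreq <- nper %/% 2 + 1L
  freqs <- (seq_len(nfreq) - 1L) * ts$fs / nper
  psd <- matrix(0, nrow(ts$data), nfreq,
                dimnames = list(ts$region_ids, NULL))
  for (s in starts) {
    seg <- ts$data[, s:(s + nper - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)                       # constant detrend
    seg <- sweep(seg, 2, w, `*`)
    ft <- t(stats::mvfft(t(seg)))
    p <- (Mod(ft[, seq_len(nfreq), drop = FALSE])^2) * scale
    p[, -c(1L, if (nper %% 2 == 0) nfreq)] <-
      2 * p[, -c(1L, if (nper %% 2 == 0) nfreq)]     # one-sided
    psd <- psd + p
  }
  psd <- psd / length(starts)
  structure(list(region_ids = ts$region_ids, freqs = freqs, psd = psd),
            class = "regional_psd")
}

#' @export
print.regional_psd <- function(x, ...) {
  cat(sprintf("Regional PSD: %d regions, %d bins, %g-%g Hz (df = %g Hz)\n",
              nrow(x$psd), length(x$freqs), min(x$freqs), max(x$freqs),
              x$freqs[2] - x$freqs[1]))
  invisible(x)
}

#' Absolute band power from a regional PSD
#'
#' Band power is the sum of PSD bins whose center frequency lies in the
#' band's half-open `[low, high)` range (minus excluded sub-ranges),
#' multiplied by the bin width. With this rule a flat unit density yields
#' exactly the effective bandwidth of each band.
#'
#' @param psd a `regional_psd` from [welch_psd()].
#' @param scheme a [band_scheme()]; default [default_band_scheme()].
#' @return Numeric matrix, regions x bands, of absolute power (signal
#'   units squared).
#' @export
band_power <- function(psd, scheme = default_band_scheme()) {
  stopifnot(inherits(psd, "regional_psd"), inherits(scheme, "band_scheme"))
  df <- psd$freqs[2] - psd$freqs[1]
  covered <- psd$freqs[1] <= scheme$low & max(psd$freqs) + df / 2 >= scheme$high
  if (any(!covered))
    stop("PSD frequency grid does not cover band(s): ",
         paste(scheme$name[!covered], collapse = ", "))
  out <- matrix(0, nrow(psd$psd), nrow(scheme),
                dimnames = list(psd$region_ids, scheme$name))
  for (i in seq_len(nrow(scheme))) {
    idx <- band_bin_index(psd$freqs, scheme, i)
    if (length(idx))
      out[, i] <- rowSums(psd$psd[, idx, drop = FALSE]) * df
  }
  out
}

#' Relative band power table
#'
#' Scales each region's absolute band powers by their total (the sum over the
#' scheme's bands, so an excluded notch is absent from numerator and
#' denominator alike), yielding a composition over bands that sums to 1 per
#' region.
#'
#' @param abs_powers non-negative numeric matrix, regions x bands, with
#'   region ids as row names and band names as column names.
#' @param subject_id subject label stored on the table.
#' @return A `band_power_table`: fields `subject_id`, `region_ids`,
#'   `band_names`, `values` (regions x bands, rows sum to 1).
#' @export
relative_band_power <- function(abs_powers, subject_id = "subject") {
  abs_powers <- as.matrix(abs_powers)
  if (any(abs_powers < 0)) stop("absolute band powers must be non-negative")
  tot <- rowSums(abs_powers)
  zero <- which(tot == 0)
  if (length(zero))
    stop("all-zero band power (relative power undefined) in region(s): ",
         paste(rownames(abs_powers)[zero], collapse = ", "))
  band_power_table(abs_powers / tot, subject_id = subject_id)
}

#' Construct a validated band-power table
#'
#' @param values regions x bands matrix of relative power fractions; row
#'   names are region ids, column names band names.
#' @param subject_id subject label.
#' @param validate check the row-stochastic invariant (rows sum to 1 within
#'   1e-9, all values in `[0, 1]`). Default TRUE.
#' @return A `band_power_table` object.
#' @export
band_power_table <- function(values, subject_id = "subject", validate = TRUE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values needs region row names and band column names")
  if (validate) {
    if (any(values < -1e-12) || any(values > 1 + 1e-12))
      stop("relative powers must lie in [0, 1]")
    bad <- which(abs(rowSums(values) - 1) > 1e-9)
    if (length(bad))
      stop("rows must sum to 1; violated by region(s): ",
           paste(rownames(values)[bad], collapse = ", "))
  }
  structure(list(subject_id = as.character(subject_id),
                 region_ids = rownames(values),
                 band_names = colnames(values),
                 values = values),
            class = "band_power_table")
}

#' @export
print.band_power_table <- function(x, ...) {
  cat(sprintf("Band-power table '%s': %d regions x %d bands\n",
              x$subject_id, length(x$region_ids), length(x$band_names)))
  print(utils::head(x$values, 4))
  if (length(x$region_ids) > 4) cat("...\n")
  invisible(x)
}
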