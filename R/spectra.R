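#' Charge current of an atom group
#'
#' \eqn{J(t_k) = \sum_{i \in group} q_i v_i(t_k)} per frame, in e nm/ps.
#' Additive over disjoint groups; identically zero for neutral groups.
#'
#' @param traj an \code{md_trajectory} carrying velocities.
#' @param group integer vector of atom indices, or the name of a group
#'   defined in the topology.
#' @return An \code{n_frames} x 3 matrix.
#' @export
charge_current <- function(traj, group) {
  if (is.null(traj$velocities))
    stop("trajectory has no velocities; re-sample the run with velocities recorded")
  group <- resolve_group(traj$topology, group)
  if (!length(group)) stop("group is empty")
  q <- traj$topology$charges[group]
  nf <- length(traj$times)
  J <- matrix(0, nf, 3L)
  for (k in 1:3) {
    vk <- traj$velocities[, group, k, drop = FALSE]
    dim(vk) <- c(nf, length(group))
    J[, k] <- vk %*% q
  }
  J
}

resolve_group <- function(topology, group) {
  if (is.character(group)) {
    if (!group %in% names(topology$groups))
      stop("no group named '", group, "' in topology")
    topology$groups[[group]]
  } else as.integer(group)
}

#' Autocorrelation of a (possibly vector-valued) time series
#'
#' Biased (1/N) estimator \eqn{C(\tau) = \frac{1}{N}\sum_t J(t)\cdot
#' J(t+\tau)}, summed over vector components, computed by the
#' Wiener-Khinchin route (FFT with zero padding). The biased normalization
#' guarantees a non-negative spectral estimate. \code{C(0)} is the mean
#' squared amplitude.
#'
#' @param series numeric vector or matrix (columns = components).
#' @param max_lag maximum lag in steps; must be < series length.
#' @return Numeric vector of length \code{max_lag + 1}: \code{C(0..max_lag)}.
#' @export
autocorrelation <- function(series, max_lag) {
  series <- as.matrix(series)
  n <- nrow(series)
  if (max_lag >= n) stop("series length (", n, ") must exceed max_lag")
  npad <- 2L^ceiling(log2(2L * n))
  acf_total <- numeric(max_lag + 1L)
  for (k in seq_len(ncol(series))) {
    x <- c(series[, k], rep(0, npad - n))
    sp <- stats::fft(x)
    cc <- Re(stats::fft(sp * Conj(sp), inverse = TRUE)) / npad
    acf_total <- acf_total + cc[1:(max_lag + 1L)] / n
  }
  acf_total
}

#' Absorption spectrum from the charge-current autocorrelation
#'
#' Classical group-resolved absorption: the mean current is subtracted,
#' \eqn{C(\tau)} is estimated to \code{max_lag} (default half the series), a
#' window is applied, and the one-sided cosine transform is evaluated on the
#' grid \eqn{f_k = k / (N \Delta t)} up to the Nyquist frequency
#' \eqn{1/(2\Delta t)}. Peak positions, the quantity of interest, are
#' insensitive to window and normalization; amplitudes are in arbitrary
#' units, by default normalized to the band maximum.
#'
#' @param traj an \code{md_trajectory} with velocities and uniform sampling.
#' @param group atom indices or group name.
#' @param window \code{"hann"} (default) or \code{"none"}, applied to the ACF.
#' @param max_lag maximum ACF lag in steps (default \code{N/2}).
#' @param normalization \code{"max"} (band maximum = 1) or \code{"none"}.
#' @return An object of class \code{spectrum_result}: \code{frequencies}
#'   (THz, from 0), \code{absorption} (non-negative), \code{group_name},
#'   \code{resolution} (THz), \code{nyquist} (THz), \code{window},
#'   \code{normalization}.
#' @export
absorption_spectrum <- function(traj, group, window = c("hann", "none"),
                                max_lag = NULL,
                                normalization = c("max", "none")) {
  window <- match.arg(window)
  normalization <- match.arg(normalization)
  if (is.na(traj$dt_sample))
    stop("non-uniform frame spacing: spectra require uniform sampling")
  dt <- traj$dt_sample
  J <- charge_current(traj, group)
  n <- nrow(J)
  if (is.null(max_lag)) max_lag <- n %/% 2L
  J <- sweep(J, 2L, colMeans(J))
  acf_c <- autocorrelation(J, max_lag)
  w <- if (window == "hann") {
    0.5 * (1 + cos(pi * (0:max_lag) / max_lag))
  } else rep(1, max_lag + 1L)
  a <- numeric(n)
  a[1] <- acf_c[1]
  a[2:(max_lag + 1L)] <- 2 * w[-1] * acf_c[-1]
  s <- Re(stats::fft(a))
  n_keep <- n %/% 2L + 1L
  freq <- (seq_len(n_keep) - 1L) / (n * dt)
  amp <- pmax(s[seq_len(n_keep)], 0) * dt
  if (normalization == "max" && max(amp) > 0) amp <- amp / max(amp)
  structure(list(
    frequencies = freq, absorption = amp,
    group_name = if (is.character(group)) group else "custom",
    resolution = 1 / (n * dt), nyquist = 1 / (2 * dt),
    window = window, normalization = normalization
  ), class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  pk <- tryCatch(find_peak(x), error = function(e) NULL)
  cat(sprintf("<spectrum_result> group '%s': %d bins, resolution %.4g THz, nyquist %g THz\n",
              x$group_name, length(x$frequencies), x$resolution, x$nyquist))
  if (!is.null(pk))
    cat(sprintf("  top peak: %.3f THz (height %.3g%s)\n", pk["frequency"],
                pk["height"],
                if (attr(pk, "no_distinct_peak")) ", no distinct peak" else ""))
  invisible(x)
}

#' Locate the dominant peak of a spectrum
#'
#' Argmax over the requested band refined by three-point parabolic
#' interpolation around the maximal bin. When the spectrum is nearly flat
#' (band maximum < 2x band median) the result carries attribute
#' \code{no_distinct_peak = TRUE}; ties go to the lowest frequency.
#'
#' @param spectrum a \code{spectrum_result}.
#' @param band length-2 numeric, THz interval to search (default full range).
#' @return Named numeric \code{c(frequency =, height =)} with attribute
#'   \code{no_distinct_peak}.
#' @export
find_peak <- function(spectrum, band = NULL) {
  f <- spectrum$frequencies
  a <- spectrum$absorption
  if (is.null(band)) band <- range(f)
  if (band[1] > spectrum$nyquist || band[2] < 0)
    stop("band outside [0, nyquist]")
  sel <- which(f >= band[1] & f <= band[2])
  if (!length(sel)) stop("empty band: no frequency bins in [",
                         band[1], ", ", band[2], "] THz")
  i <- sel[which.max(a[sel])]  # which.max takes the first (lowest-f) tie
  freq <- f[i]; height <- a[i]
  if (i > 1L && i < length(f)) {
    y1 <- a[i - 1L]; y2 <- a[i]; y3 <- a[i + 1L]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > .Machine$double.eps) {
      delta <- 0.5 * (y1 - y3) / den
      if (abs(delta) <= 1) {
        freq <- f[i] + delta * spectrum$resolution
        height <- y2 - 0.25 * (y1 - y3) * delta
      }
    }
  }
  med <- stats::median(a[sel])
  flat <- !(max(a[sel]) > 2 * med)
  structure(c(frequency = freq, height = height), no_distinct_peak = flat)
}
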