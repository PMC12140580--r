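# Windowed wavelet-coherence connectivity: region-by-time panels are
# decomposed with the maximal-overlap discrete wavelet transform (MODWT),
# sliced into overlapping windows, and turned into symmetric coherence
# networks with a shuffle-null significance threshold.

#' Construct a region-by-time signal panel
#'
#' The unit of connectivity analysis: an N x T matrix of regional signals at a
#' fixed sampling interval. Rows are (re-)z-scored on construction so that
#' every region has mean 0 and unit standard deviation.
#'
#' @param x numeric matrix, one row per region, one column per volume.
#' @param tr sampling interval in seconds (repetition time).
#' @param subject optional subject identifier.
#' @param regions optional character vector of region ids (defaults to
#'   `r1..rN`).
#' @return an object of class `timeseries_panel`.
#' @export
timeseries_panel <- function(x, tr, subject = NA_character_, regions = NULL) {
  x <- as.matrix(x)
  if (anyNA(x) || !all(is.finite(x))) stop_("panel contains missing values")
  check_number(tr, "tr", lower = 1e-9)
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0)) stop_("constant region signal: cannot z-score")
  # idempotent normalization: rows already z-scored are left untouched, so
  # serialized panels round-trip bit-exactly
  if (max(abs(rowMeans(x))) > 1e-10 || max(abs(sds - 1)) > 1e-10) {
    x <- (x - rowMeans(x)) / sds
  }
  regions <- regions %||% paste0("r", seq_len(nrow(x)))
  if (length(regions) != nrow(x)) stop_("regions must match rows of x")
  structure(list(x = x, tr = tr, subject = subject, regions = regions),
            class = "timeseries_panel")
}

#' @export
print.timeseries_panel <- function(x, ...) {
  cat(sprintf("<timeseries_panel> subject=%s  %d regions x %d volumes, tr=%gs\n",
              x$subject, nrow(x$x), ncol(x$x), x$tr))
  invisible(x)
}

#' Sliding-window specification
#'
#' @param length window length in volumes (default 32, i.e. 64 s at a 2-s
#'   sampling interval).
#' @param step step between window starts in volumes (default 16, i.e. 50%
#'   overlap).
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(length = 32L, step = 16L) {
  check_number(length, "length", lower = 2, integer = TRUE)
  check_number(step, "step", lower = 1, integer = TRUE)
  if (step > length) stop_("step must satisfy 0 < step <= length")
  structure(list(length = as.integer(length), step = as.integer(step)),
            class = "window_spec")
}

#' Enumerate sliding windows over a series
#'
#' Windows start at volume 1 and advance by `spec$step`; only windows lying
#' fully inside the series are returned, giving
#' `floor((T - length)/step) + 1` windows.
#'
#' @param n_volumes series length T.
#' @param spec a [window_spec()].
#' @return data.frame with 1-based inclusive columns `start`, `end`.
#' @export
window_slices <- function(n_volumes, spec = window_spec()) {
  check_number(n_volumes, "n_volumes", lower = 1, integer = TRUE)
  if (n_volumes < spec$length) stop_("series too short for one window")
  starts <- seq.int(1L, n_volumes - spec$length + 1L, by = spec$step)
  data.frame(start = starts, end = starts + spec$length - 1L)
}

# MODWT Haar filters, scaled for the maximal-overlap transform
.modwt_haar_h <- c(0.5, -0.5) # wavelet (detail)
.modwt_haar_g <- c(0.5, 0.5)  # scaling (smooth)

# one pyramid step at level j with periodic boundary: filter upsampled by
# 2^(j-1)
.modwt_step <- function(v, filt, j) {
  n <- length(v)
  shift <- 2L^(j - 1L)
  idx0 <- seq_len(n)
  idx1 <- ((idx0 - 1L - shift) %% n) + 1L
  filt[1L] * v + filt[2L] * v[idx1]
}

#' Maximal-overlap discrete wavelet transform (Haar)
#'
#' Undecimated Haar wavelet decomposition with periodic boundary handling.
#' Returns the detail coefficient series `W1..Wn_levels` and the final smooth
#' `V`. The transform is energy preserving:
#' `sum(x^2) == sum over levels of sum(W_j^2) + sum(V^2)`.
#'
#' @param x numeric series.
#' @param n_levels number of decomposition levels.
#' @return list with `W` (list of detail series) and `V` (smooth series).
#' @export
modwt_haar <- function(x, n_levels = 1L) {
  check_number(n_levels, "n_levels", lower = 1, integer = TRUE)
  if (length(x) < 2L^n_levels) stop_("series shorter than filter support")
  v <- as.numeric(x)
  W <- vector("list", n_levels)
  for (j in seq_len(n_levels)) {
    W[[j]] <- .modwt_step(v, .modwt_haar_h, j)
    v <- .modwt_step(v, .modwt_haar_g, j)
  }
  list(W = W, V = v)
}

#' Scale-j MODWT detail coefficients with their passband
#'
#' The scale-`scale` Haar detail series of a signal sampled every `tr`
#' seconds. Scale j is associated with the frequency band
#' `[1/(2^(j+1) tr), 1/(2^j tr)]` Hz; at scale 1 and tr = 2 s this is
#' 0.125-0.25 Hz.
#'
#' @param x numeric series (one region).
#' @param scale decomposition level (default 1).
#' @param tr sampling interval in seconds.
#' @return numeric coefficient series (same length as `x`) with attribute
#'   `band` giving the passband in Hz.
#' @export
modwt_band_coefficients <- function(x, scale = 1L, tr = 2.0) {
  check_number(tr, "tr", lower = 1e-9)
  w <- modwt_haar(x, n_levels = scale)$W[[scale]]
  attr(w, "band") <- modwt_band(scale, tr)
  w
}

#' Passband of a MODWT scale
#' @param scale decomposition level.
#' @param tr sampling interval in seconds.
#' @return numeric length-2 vector, band edges in Hz (low, high).
#' @export
modwt_band <- function(scale = 1L, tr = 2.0) {
  check_number(scale, "scale", lower = 1, integer = TRUE)
  c(1 / (2^(scale + 1) * tr), 1 / (2^scale * tr))
}

# ---------------------------------------------------------------------------
# Welch-style band coherence
#
# Averaged tapered overlapping segment periodograms; defaults (16-sample Hann
# segments, 50% overlap) are the recorded estimator configuration for 32-
# sample windows.

.welch_segments <- function(n, seg_length, overlap) {
  step <- max(1L, as.integer(round(seg_length * (1 - overlap))))
  starts <- seq.int(1L, n - seg_length + 1L, by = step)
  list(starts = starts, step = step)
}

# segment FFTs for a window matrix (rows = samples, cols = series): returns
# complex array [freq, series, segment]
.segment_ffts <- function(xmat, seg_length, overlap) {
  n <- nrow(xmat)
  segs <- .welch_segments(n, seg_length, overlap)$starts
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg_length - 1) / seg_length)
  nf <- seg_length %/% 2L + 1L
  out <- array(0 + 0i, dim = c(nf, ncol(xmat), length(segs)))
  for (s in seq_along(segs)) {
    seg <- xmat[segs[s]:(segs[s] + seg_length - 1L), , drop = FALSE]
    seg <- sweep(seg, 2L, colMeans(seg)) * taper
    Z <- stats::mvfft(seg)
    out[, , s] <- Z[seq_len(nf), , drop = FALSE]
  }
  out
}

.band_bins <- function(seg_length, tr, band) {
  freqs <- (seq_len(seg_length %/% 2L + 1L) - 1L) / (seg_length * tr)
  which(freqs >= band[1] - 1e-12 & freqs <= band[2] + 1e-12)
}

#' Band-averaged magnitude-squared coherence of two windows
#'
#' Magnitude-squared coherence estimated from averaged, Hann-tapered,
#' 50%-overlapping segment periodograms, then averaged over the discrete
#' frequencies falling inside `band`.
#'
#' @param x,y equal-length numeric windows (wavelet-coefficient series).
#' @param tr sampling interval in seconds.
#' @param band frequency interval in Hz (default: scale-1 passband for `tr`).
#' @param seg_length segment length in samples (default 16).
#' @param overlap fractional overlap of consecutive segments (default 0.5).
#' @return coherence value in `[0, 1]`.
#' @export
band_coherence <- function(x, y, tr = 2.0, band = modwt_band(1L, tr),
                           seg_length = 16L, overlap = 0.5) {
  if (length(x) != length(y)) stop_("windows must have equal length")
  if (length(x) < 8L) stop_("window too short for spectral estimation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop_("degenerate window")
  Z <- .segment_ffts(cbind(x, y), seg_length, overlap)
  bins <- .band_bins(seg_length, tr, band)
  sxx <- rowSums(abs(Z[, 1L, , drop = FALSE])^2)[bins]
  syy <- rowSums(abs(Z[, 2L, , drop = FALSE])^2)[bins]
  sxy <- rowSums(Z[, 1L, , drop = FALSE] *
                   Conj(Z[, 2L, , drop = FALSE]), dims = 1L)[bins]
  if (any(sxx == 0) || any(syy == 0)) stop_("degenerate window")
  mean(pmin(1, abs(sxy)^2 / (sxx * syy)))
}

# all-pairs band coherence for one window: N x N symmetric matrix with zero
# diagonal; xmat is samples x regions
.coherence_matrix <- function(xmat, tr, band, seg_length = 16L,
                              overlap = 0.5) {
  Z <- .segment_ffts(xmat, seg_length, overlap)
  bins <- .band_bins(seg_length, tr, band)
  N <- ncol(xmat)
  acc <- matrix(0, N, N)
  for (f in bins) {
    Zf <- Z[f, , , drop = TRUE]
    if (is.null(dim(Zf))) Zf <- matrix(Zf, nrow = N)
    S <- Zf %*% Conj(t(Zf)) # cross-spectra summed over segments
    auto <- Re(diag(S))
    if (any(auto == 0)) {
      bad <- which(auto == 0)[1L]
      stop_("degenerate window (region ", bad, ")")
    }
    acc <- acc + pmin(abs(S)^2 / outer(auto, auto), 1)
  }
  C <- acc / length(bins)
  diag(C) <- 0
  (C + t(C)) / 2
}

#' Null-model coherence threshold
#'
#' Builds the shuffle null for coherence: repeatedly pick two distinct regions
#' and random window start times, permute the sample order independently
#' inside each chosen window of the wavelet-coefficient series, and compute
#' the band coherence of the shuffled pair. Returns the requested percentile
#' of the null distribution (default the 95th of 10,000 draws).
#'
#' @param panel a [timeseries_panel()].
#' @param spec a [window_spec()].
#' @param scale MODWT scale (default 1).
#' @param n_iter number of null iterations (default 10,000).
#' @param percentile percentile of the null returned (default 95).
#' @param seed integer seed.
#' @param seg_length,overlap coherence estimator settings.
#' @return the threshold coherence value, with attribute `null` holding the
#'   null draws.
#' @export
coherence_null_threshold <- function(panel, spec = window_spec(), scale = 1L,
                                     n_iter = 10000L, percentile = 95,
                                     seed = 1L, seg_length = 16L,
                                     overlap = 0.5) {
  stopifnot(inherits(panel, "timeseries_panel"))
  check_number(n_iter, "n_iter", lower = 1, integer = TRUE)
  if (n_iter < 100) stop_("null too small")
  check_number(percentile, "percentile", lower = 0, upper = 100)
  N <- nrow(panel$x); Tn <- ncol(panel$x)
  if (Tn < spec$length) stop_("series too short")
  band <- modwt_band(scale, panel$tr)
  coefs <- t(apply(panel$x, 1L, function(r) modwt_haar(r, scale)$W[[scale]]))
  wl <- spec$length
  with_seed(seed, {
    draws <- numeric(n_iter)
    chunk <- 500L
    done <- 0L
    while (done < n_iter) {
      m <- min(chunk, n_iter - done)
      ra <- sample.int(N, m, replace = TRUE)
      rb <- vapply(ra, function(a) sample.int(N - 1L, 1L), integer(1L))
      rb <- ifelse(rb >= ra, rb + 1L, rb)
      sa <- sample.int(Tn - wl + 1L, m, replace = TRUE)
      sb <- sample.int(Tn - wl + 1L, m, replace = TRUE)
      # columns: the two shuffled windows of every iteration in the chunk
      xa <- matrix(0, wl, m); xb <- matrix(0, wl, m)
      for (k in seq_len(m)) {
        xa[, k] <- coefs[ra[k], sa[k]:(sa[k] + wl - 1L)][sample.int(wl)]
        xb[, k] <- coefs[rb[k], sb[k]:(sb[k] + wl - 1L)][sample.int(wl)]
      }
      Za <- .segment_ffts(xa, seg_length, overlap)
      Zb <- .segment_ffts(xb, seg_length, overlap)
      bins <- .band_bins(seg_length, panel$tr, band)
      sxx <- apply(abs(Za)^2, c(1L, 2L), sum)[bins, , drop = FALSE]
      syy <- apply(abs(Zb)^2, c(1L, 2L), sum)[bins, , drop = FALSE]
      sxy <- apply(Za * Conj(Zb), c(1L, 2L), sum)[bins, , drop = FALSE]
      draws[done + seq_len(m)] <- colMeans(pmin(abs(sxy)^2 / (sxx * syy), 1))
      done <- done + m
    }
    thr <- unname(stats::quantile(draws, percentile / 100))
    attr(thr, "null") <- draws
    thr
  })
}

#' Build a thresholded multislice coherence network
#'
#' Decomposes the full panel once at the requested MODWT scale, windows the
#' coefficient series, computes band-averaged magnitude-squared coherence for
#' every region pair in every window, and zeroes entries below `threshold`.
#'
#' @param panel a [timeseries_panel()].
#' @param spec a [window_spec()].
#' @param scale MODWT scale (default 1).
#' @param threshold coherence threshold (from [coherence_null_threshold()] or
#'   user-supplied); entries strictly below it are set to 0.
#' @param seg_length,overlap coherence estimator settings.
#' @return object of class `multilayer_network`: list of layer matrices plus
#'   band, threshold, realized sparsity and window spec.
#' @export
build_multilayer <- function(panel, spec = window_spec(), scale = 1L,
                             threshold = 0, seg_length = 16L, overlap = 0.5) {
  stopifnot(inherits(panel, "timeseries_panel"))
  check_number(threshold, "threshold", lower = 0, upper = 1)
  band <- modwt_band(scale, panel$tr)
  sl <- window_slices(ncol(panel$x), spec)
  coefs <- t(apply(panel$x, 1L, function(r) modwt_haar(r, scale)$W[[scale]]))
  layers <- vector("list", nrow(sl))
  for (w in seq_len(nrow(sl))) {
    xw <- t(coefs[, sl$start[w]:sl$end[w], drop = FALSE])
    C <- tryCatch(
      .coherence_matrix(xw, panel$tr, band, seg_length, overlap),
      error = function(e) stop_("window ", w, ": ", conditionMessage(e)))
    C[C < threshold] <- 0
    layers[[w]] <- C
  }
  N <- nrow(panel$x)
  off <- N * (N - 1)
  sparsity <- mean(vapply(layers, function(A) sum(A == 0) - N, 0) / off)
  structure(list(layers = layers, window_spec = spec, band = band,
                 threshold = threshold, sparsity = sparsity, tr = panel$tr,
                 regions = panel$regions, subject = panel$subject),
            class = "multilayer_network")
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat(sprintf(paste0("<multilayer_network> %d regions x %d layers, band ",
                     "%.3f-%.3f Hz, threshold %.3f, sparsity %.1f%%\n"),
              nrow(x$layers[[1L]]), length(x$layers), x$band[1], x$band[2],
              x$threshold, 100 * x$sparsity))
  invisible(x)
}

#' Node strength of a multilayer network
#'
#' Per region and layer, the sum of incident edge weights; the subject-level
#' scalar is the mean over regions and layers.
#'
#' @param net a `multilayer_network`.
#' @return list with `strength` (N x L matrix) and `subject` (scalar mean).
#' @export
node_strength <- function(net) {
  stopifnot(inherits(net, "multilayer_network"))
  S <- vapply(net$layers, rowSums, numeric(nrow(net$layers[[1L]])))
  S <- matrix(S, nrow = nrow(net$layers[[1L]]))
  rownames(S) <- net$regions
  list(strength = S, subject = mean(S))
}

#' Enforce uniform sparsity across layers
#'
#' Per layer, retain the top `ceiling(density * N(N-1)/2)` edges by weight and
#' zero the rest; ties are broken by stable (row-major upper-triangle) edge
#' index order. Used as a control for threshold-induced density differences
#' between subjects.
#'
#' @param net a `multilayer_network`.
#' @param density fraction of edges to keep, in (0, 1].
#' @return a `multilayer_network` with uniformly sparse layers.
#' @export
enforce_uniform_sparsity <- function(net, density) {
  stopifnot(inherits(net, "multilayer_network"))
  check_number(density, "density", lower = 1e-12, upper = 1)
  N <- nrow(net$layers[[1L]])
  ut <- which(upper.tri(matrix(0, N, N)))
  keep_n <- ceiling(density * length(ut))
  layers <- lapply(net$layers, function(A) {
    w <- A[ut]
    ord <- order(-w, seq_along(w))
    drop <- ord[-seq_len(keep_n)]
    A[ut[drop]] <- 0
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    A
  })
  out <- net
  out$layers <- layers
  off <- N * (N - 1)
  out$sparsity <- mean(vapply(layers, function(A) sum(A == 0) - N, 0) / off)
  out
}
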