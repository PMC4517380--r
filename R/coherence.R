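## Discrete prolate spheroidal sequences (Slepian tapers).
##
## Computed from the symmetric tridiagonal matrix whose eigenvectors are the
## DPSS (Percival & Walden formulation): diagonal ((N-1-2t)/2)^2 cos(2*pi*W),
## off-diagonal t(N-t)/2. The top `k` eigenvectors, unit-normalized, are the
## tapers. Cached per (n, nw, k) because the lattice weighting evaluates
## thousands of voxel pairs with identical taper parameters.
.dpss_cache <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw = 4, k = 7L) {
  if (k < 1L) stop("need at least one taper")
  if (k > n) stop("more tapers than samples")
  if (nw <= 0 || nw >= n / 2) stop("'nw' must lie in (0, n/2)")
  key <- sprintf("%d_%s_%d", n, format(nw, digits = 12), k)
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  t_ <- seq_len(n) - 1
  dg <- ((n - 1 - 2 * t_) / 2)^2 * cos(2 * pi * w)
  od <- t_[-1] * (n - t_[-1]) / 2
  A <- diag(dg)
  A[cbind(2:n, 1:(n - 1))] <- od
  A[cbind(1:(n - 1), 2:n)] <- od
  ev <- eigen(A, symmetric = TRUE)
  V <- ev$vectors[, seq_len(k), drop = FALSE]
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  # conventional polarity: symmetric tapers average positive, antisymmetric
  # tapers start with positive slope (sign cancels in coherence anyway)
  for (j in seq_len(k)) {
    s <- sum(V[, j])
    if (abs(s) > 1e-8) { if (s < 0) V[, j] <- -V[, j] }
    else if (V[2, j] < V[1, j]) V[, j] <- -V[, j]
  }
  .dpss_cache[[key]] <- V
  V
}

## one-sided eigencoefficients: FFT of each tapered copy of x, rows 1..nf
eigen_coefs <- function(x, tapers) {
  n <- length(x)
  nf <- n %/% 2L + 1L
  stats::mvfft(tapers * x)[seq_len(nf), , drop = FALSE]
}

msc_from_coefs <- function(ex, ey) {
  sxx <- rowMeans(Mod(ex)^2)
  syy <- rowMeans(Mod(ey)^2)
  sxy <- rowMeans(ex * Conj(ey))
  msc <- Mod(sxy)^2 / (sxx * syy)
  pmin(pmax(msc, 0), 1)
}

#' Multitaper magnitude-squared coherence
#'
#' Estimates the magnitude-squared coherence (MSC) between two equal-length
#' time series using Slepian (DPSS) tapers: cross- and auto-spectra are
#' averaged over tapers and combined as
#' \eqn{|S_{xy}|^2 / (S_{xx} S_{yy})}, giving a frequency-resolved measure of
#' linear association in \[0, 1\].
#'
#' @param x,y numeric vectors of equal length (at least 16 samples), finite,
#'   non-constant.
#' @param sampling_interval_s sampling interval in seconds (the fMRI TR).
#' @param half_bandwidth_product time-half-bandwidth product NW; default 4.
#' @param n_tapers number of tapers; default 7 (2NW - 1).
#' @return An object of class `coherence_spectrum`: list with `frequencies`
#'   (Hz, 0 to Nyquist) and `msc` (values in \[0, 1\]).
#' @export
multitaper_msc <- function(x, y, sampling_interval_s,
                           half_bandwidth_product = 4, n_tapers = 7L) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 16L) stop("need at least 16 samples for spectral estimation")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values in input")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero-variance input: coherence undefined for constant series")
  if (sampling_interval_s <= 0) stop("'sampling_interval_s' must be positive")
  V <- dpss_tapers(n, half_bandwidth_product, as.integer(n_tapers))
  ex <- eigen_coefs(x, V)
  ey <- eigen_coefs(y, V)
  nf <- n %/% 2L + 1L
  freqs <- (seq_len(nf) - 1) / (n * sampling_interval_s)
  structure(list(frequencies = freqs, msc = msc_from_coefs(ex, ey)),
            class = "coherence_spectrum")
}

trapezoid <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)

#' Band-limited coherence weight
#'
#' Integrates an MSC spectrum over a frequency band (trapezoidal rule, with
#' linear interpolation at the band edges). By default the integral is
#' divided by the band width so the weight lies in \[0, 1\]; the raw area is
#' available with `normalize = FALSE`. Normalization rescales every edge
#' weight by the same constant, so the modularity-optimal partition is
#' unaffected.
#'
#' @param spectrum a [multitaper_msc()] result.
#' @param f_lo,f_hi band limits in Hz; defaults 0.005 and 0.12, the
#'   low-frequency band of resting-state BOLD fluctuations.
#' @param normalize divide by `f_hi - f_lo` (default `TRUE`).
#' @return nonnegative scalar.
#' @export
band_weight <- function(spectrum, f_lo = 0.005, f_hi = 0.12, normalize = TRUE) {
  stopifnot(inherits(spectrum, "coherence_spectrum"))
  f <- spectrum$frequencies
  if (!(f_lo < f_hi)) stop("'f_lo' must be below 'f_hi'")
  if (f_hi > max(f) + 1e-12) stop("'f_hi' exceeds the Nyquist frequency")
  inside <- f >= f_lo & f <= f_hi
  if (sum(inside) < 2L)
    stop("fewer than 2 frequency samples inside the band; series too short")
  fg <- unique(sort(c(f_lo, f[inside], f_hi)))
  mg <- stats::approx(f, spectrum$msc, xout = fg, rule = 2)$y
  area <- trapezoid(fg, mg)
  if (normalize) area / (f_hi - f_lo) else area
}

#' Attach coherence band weights to a lattice
#'
#' Computes, for every lattice edge, the band-limited multitaper coherence
#' weight of its two endpoint voxel time series. Eigencoefficients are
#' computed once per voxel, so the cost is one FFT set per voxel plus one
#' cross-spectrum per edge.
#'
#' @param lattice an unweighted [build_lattice()] result.
#' @param bold 4D numeric array (x, y, z, t) on the same grid.
#' @param sampling_interval_s sampling interval in seconds.
#' @param f_lo,f_hi coherence band in Hz.
#' @param half_bandwidth_product,n_tapers multitaper parameters.
#' @param normalize passed to [band_weight()].
#' @return The lattice with a `weights` field, values in \[0, 1\] (up to
#'   normalization).
#' @export
weight_lattice <- function(lattice, bold, sampling_interval_s = 2,
                           f_lo = 0.005, f_hi = 0.12,
                           half_bandwidth_product = 4, n_tapers = 7L,
                           normalize = TRUE) {
  stopifnot(inherits(lattice, "lattice_graph"))
  dims <- dim(bold)
  if (length(dims) != 4L) stop("'bold' must be a 4D array (x, y, z, t)")
  if (!is.null(lattice$dims) && !identical(dims[1:3], lattice$dims))
    stop("'bold' spatial dimensions do not match the lattice grid")
  nt <- dims[4L]
  M <- matrix(bold, ncol = nt)
  vox <- lattice$voxels
  bad <- vox[apply(M[vox, , drop = FALSE], 1L, stats::var) == 0]
  if (length(bad))
    stop("zero-variance time series at voxel linear index ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "")
  V <- dpss_tapers(nt, half_bandwidth_product, as.integer(n_tapers))
  nf <- nt %/% 2L + 1L
  freqs <- (seq_len(nf) - 1) / (nt * sampling_interval_s)
  n <- length(vox)
  ec <- vector("list", n)
  for (i in seq_len(n)) ec[[i]] <- eigen_coefs(M[vox[i], ], V)
  sxx <- vapply(ec, function(e) rowMeans(Mod(e)^2), numeric(nf))
  m <- nrow(lattice$edges)
  w <- numeric(m)
  for (e in seq_len(m)) {
    i <- lattice$edges[e, 1L]; j <- lattice$edges[e, 2L]
    sxy <- rowMeans(ec[[i]] * Conj(ec[[j]]))
    msc <- pmin(pmax(Mod(sxy)^2 / (sxx[, i] * sxx[, j]), 0), 1)
    spec <- structure(list(frequencies = freqs, msc = msc),
                      class = "coherence_spectrum")
    w[e] <- band_weight(spec, f_lo, f_hi, normalize = normalize)
  }
  lattice$weights <- w
  lattice
}
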