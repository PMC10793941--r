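#' Pixel coordinates in degrees of visual angle
#'
#' Returns the coordinate (deg) of each pixel center along one axis, with 0 at
#' the image center.
#'
#' @param n number of pixels
#' @param ppd pixels per degree
#' @return numeric vector of length `n`
#' @keywords internal
deg_grid <- function(n, ppd) {
  ((seq_len(n)) - (n + 1) / 2) / ppd
}

pad_matrix <- function(m, n1, n2) {
  out <- matrix(0, n1, n2)
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  out
}

next_fast <- function(n) nextn(n, c(2L, 3L, 5L))

#' 2-D convolution with output the size of the first argument
#'
#' Frequency-domain linear convolution (zero padded, so no wrap-around),
#' cropped to the "same" region: `out[i, j]` corresponds to the kernel
#' centered at pixel `(i, j)` of `a`, with the kernel center at
#' `floor(dim(b)/2) + 1`.
#'
#' @param a image matrix
#' @param b kernel matrix (may be complex; the result is then complex)
#' @return matrix with `dim(a)`
#' @export
conv2_same <- function(a, b) {
  da <- dim(a); db <- dim(b)
  n1 <- next_fast(da[1] + db[1] - 1L)
  n2 <- next_fast(da[2] + db[2] - 1L)
  fa <- fft(pad_matrix(a, n1, n2))
  fb <- fft(pad_matrix(b, n1, n2))
  full <- fft(fa * fb, inverse = TRUE) / (n1 * n2)
  r0 <- floor(db[1] / 2); c0 <- floor(db[2] / 2)
  out <- full[r0 + seq_len(da[1]), c0 + seq_len(da[2])]
  if (is.complex(b)) out else Re(out)
}

#' Radially averaged amplitude spectrum
#'
#' Embeds `m` in an `nfft x nfft` zero-padded array, takes the DFT magnitude,
#' and averages it over annular frequency bins up to the Nyquist frequency.
#' Used to verify the spectral contract of the band-pass kernel and the
#' band-pass property of generated stimuli.
#'
#' @param m real matrix (kernel or image)
#' @param ppd pixels per degree of `m`
#' @param nfft FFT size (zero padding gives a dense radial frequency grid)
#' @return list with `f` (cycles/deg) and `a` (mean amplitude per bin)
#' @export
radial_spectrum <- function(m, ppd, nfft = 512L) {
  n <- max(dim(m))
  if (nfft < n) nfft <- next_fast(n)
  amp <- abs(fft(pad_matrix(m, nfft, nfft)))
  fx <- c(0:(nfft / 2), -((nfft / 2 - 1):1)) * ppd / nfft
  fr <- sqrt(outer(fx^2, fx^2, "+"))
  keep <- fr <= ppd / 2
  br <- seq(0, ppd / 2, by = ppd / nfft)
  idx <- findInterval(fr[keep], br)
  prof <- tapply(amp[keep], idx, mean)
  list(f = br[as.integer(names(prof))], a = as.numeric(prof))
}

#' Half-maximum crossings of a spectral profile
#'
#' Locates the peak of `a` over `f` and the two frequencies at which the
#' profile crosses half of the peak value (linear interpolation between grid
#' points). `NA` if a crossing does not exist on the grid.
#'
#' @param f frequency grid (cycles/deg), increasing
#' @param a amplitude profile
#' @return named vector `c(peak, lo, hi)`
#' @export
half_max_crossings <- function(f, a) {
  i0 <- which.max(a)
  pk <- f[i0]
  h <- a[i0] / 2
  lo <- NA_real_; hi <- NA_real_
  if (i0 > 1L) {
    below <- which(a[seq_len(i0)] <= h)
    if (length(below)) {
      j <- max(below)
      lo <- f[j] + (f[j + 1] - f[j]) * (h - a[j]) / (a[j + 1] - a[j])
    }
  }
  post <- a[i0:length(a)]
  j <- which(post <= h)[1]
  if (!is.na(j) && j > 1L) {
    j <- i0 + j - 1L
    hi <- f[j - 1] + (f[j] - f[j - 1]) * (h - a[j - 1]) / (a[j] - a[j - 1])
  }
  c(peak = pk, lo = lo, hi = hi)
}

#' RMS of a numeric array
#' @param x numeric
#' @return scalar root-mean-square
#' @export
rms <- function(x) sqrt(mean(x^2))

`%||%` <- function(a, b) if (is.null(a)) b else a

# condition helpers -----------------------------------------------------------

vn_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "visnorm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
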