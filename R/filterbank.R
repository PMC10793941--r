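#' A single Gabor kernel
#'
#' Cosine (`phase_deg = 0`) or sine (`phase_deg = 90`) carrier of 4 cycles,
#' windowed by an isotropic Gaussian with SD of 1 cycle, realized on a square
#' support of 4 carrier wavelengths. The kernel mean is removed so that a
#' constant (gray) image yields exactly zero response.
#'
#' @param theta_deg contour orientation the filter responds to (0 =
#'   horizontal, CCW positive)
#' @param f_cpd peak spatial frequency (cycles/deg)
#' @param phase_deg carrier phase, 0 or 90
#' @param ppd pixels per degree
#' @return numeric matrix (odd side length)
#' @export
gabor_kernel <- function(theta_deg, f_cpd, phase_deg, ppd) {
  lambda <- 1 / f_cpd
  half <- round(2 * lambda * ppd) # 4 wavelengths total support
  n <- 2L * half + 1L
  if (n < 3L)
    vn_stop(sprintf("Gabor support at %g cycles/deg is below 3 px at ppd %g",
                    f_cpd, ppd), "visnorm_resolution_error")
  xs <- deg_grid(n, ppd)
  th <- theta_deg * pi / 180
  t <- outer(xs * cos(th), -xs * sin(th), "+")
  r2 <- outer(xs^2, xs^2, "+")
  carrier <- if (phase_deg == 90) sin(2 * pi * f_cpd * t) else
    cos(2 * pi * f_cpd * t)
  g <- carrier * exp(-r2 / (2 * lambda^2))
  g - mean(g)
}

#' Build the quadrature Gabor filter bank
#'
#' 8 orientations spaced 22.5 deg, 8 peak spatial frequencies log-spaced from
#' 0.75 to 6 cycles/deg, and 2 phases in quadrature: 128 kernels. Quadrature
#' pairs are stored combined as complex kernels (even phase real, odd phase
#' imaginary), so the squared modulus of one complex convolution equals the
#' phase-summed energy of the pair.
#'
#' @param ppd pixels per degree of the images the bank will be applied to;
#'   must be at least 12 (the energy-map resolution)
#' @param n_ori number of orientation channels
#' @param freqs peak frequencies (cycles/deg); default 8 log-spaced 0.75-6
#' @return object of class `filter_bank`: list with `kernels` (complex
#'   matrices indexed by `info`), `info` (data frame with theta/f per kernel),
#'   `orientations`, `freqs`, `phases`, `ppd`, `max_support` (px), `n_kernels`
#' @export
build_filterbank <- function(ppd, n_ori = 8L, freqs = NULL) {
  if (ppd < 12)
    vn_stop("ppd must be >= 12 (energy maps are computed at 12 px/deg)",
            "visnorm_resolution_error")
  if (is.null(freqs)) freqs <- exp(seq(log(0.75), log(6), length.out = 8L))
  orientations <- (seq_len(n_ori) - 1L) * 180 / n_ori
  grid <- expand.grid(f = freqs, theta = orientations,
                      KEEP.OUT.ATTRS = FALSE)
  kernels <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    even <- gabor_kernel(grid$theta[i], grid$f[i], 0, ppd)
    odd <- gabor_kernel(grid$theta[i], grid$f[i], 90, ppd)
    kernels[[i]] <- even + 1i * odd
  }
  n_banks <- (.vn_cache$n_banks %||% 0L) + 1L
  .vn_cache$n_banks <- n_banks
  uid <- sprintf("fb%06d", n_banks)
  structure(
    list(kernels = kernels, info = grid, orientations = orientations,
         freqs = freqs, phases = c(0, 90), ppd = ppd,
         max_support = max(vapply(kernels, nrow, 0L)),
         n_kernels = 2L * nrow(grid), uid = uid),
    class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf(
    "<filter_bank> %d Gabor kernels: %d orientations x %d frequencies (%.2f-%g cpd) x 2 phases at %g ppd\n",
    x$n_kernels, length(x$orientations), length(x$freqs),
    min(x$freqs), max(x$freqs), x$ppd))
  invisible(x)
}

#' Extract one real Gabor kernel from a bank
#'
#' @param bank `filter_bank`
#' @param theta_idx,freq_idx,phase_idx 1-based channel indices (phase 1 =
#'   even/cosine, 2 = odd/sine)
#' @return numeric matrix
#' @export
bank_kernel <- function(bank, theta_idx, freq_idx, phase_idx = 1L) {
  i <- which(bank$info$theta == bank$orientations[theta_idx] &
               bank$info$f == bank$freqs[freq_idx])
  k <- bank$kernels[[i]]
  if (phase_idx == 1L) Re(k) else Im(k)
}
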