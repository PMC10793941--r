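#' Oriented contrast energy of a stimulus
#'
#' Pads the stimulus with uniform gray (zeros) on all sides by the width of
#' the largest filter, convolves it with every Gabor kernel in the bank,
#' squares and sums the outputs over the two quadrature phases and the eight
#' spatial-frequency bands (uniform weights), and downsamples the result to
#' 12 px/deg by block (area-weighted) averaging. The output is one
#' non-negative energy image per orientation channel, covering the padded
#' canvas.
#'
#' @param img [stim_image()] (its `ppd` must match the bank's)
#' @param bank [build_filterbank()] output
#' @param down_ppd output resolution (px/deg)
#' @return object of class `energy_map`: list with `values` (3-D array
#'   y-by-x-by-orientation, all values >= 0), `ppd` (= `down_ppd`),
#'   `orientations`
#' @export
compute_energy <- function(img, bank, down_ppd = 12) {
  stopifnot(inherits(img, "stim_image"), inherits(bank, "filter_bank"))
  if (abs(img$ppd - bank$ppd) > 1e-9)
    vn_stop(sprintf("image ppd (%g) does not match filter bank ppd (%g)",
                    img$ppd, bank$ppd), "visnorm_geometry_error")
  pad <- bank$max_support
  n0 <- dim(img$pixels)
  np <- n0 + 2L * pad
  P <- matrix(0, np[1], np[2])
  P[pad + seq_len(n0[1]), pad + seq_len(n0[2])] <- img$pixels

  n1 <- next_fast(np[1] + bank$max_support - 1L)
  n2 <- next_fast(np[2] + bank$max_support - 1L)
  kf <- bank_ffts(bank, n1, n2)
  fP <- fft(pad_matrix(P, n1, n2))

  n_ori <- length(bank$orientations)
  energy <- array(0, c(np[1], np[2], n_ori))
  for (i in seq_along(bank$kernels)) {
    kb <- bank$kernels[[i]]
    db <- nrow(kb)
    full <- fft(fP * kf[[i]], inverse = TRUE) / (n1 * n2)
    r0 <- floor(db / 2); c0 <- floor(db / 2)
    resp <- full[r0 + seq_len(np[1]), c0 + seq_len(np[2])]
    ti <- match(bank$info$theta[i], bank$orientations)
    energy[, , ti] <- energy[, , ti] + Mod(resp)^2
  }

  if (abs(bank$ppd - down_ppd) > 1e-9) {
    W1 <- resample_weights(np[1], bank$ppd, down_ppd)
    W2 <- resample_weights(np[2], bank$ppd, down_ppd)
    out <- array(0, c(nrow(W1), nrow(W2), n_ori))
    for (t in seq_len(n_ori))
      out[, , t] <- W1 %*% energy[, , t] %*% t(W2)
    energy <- out
  }
  structure(list(values = energy, ppd = down_ppd,
                 orientations = bank$orientations),
            class = "energy_map")
}

# FFTs of the complex quadrature kernels at a given size, cached per bank
# (only the most recent size is kept, to bound memory)
bank_ffts <- function(bank, n1, n2) {
  key <- paste0("fft:", bank$uid)
  hit <- .vn_cache[[key]]
  if (!is.null(hit) && identical(hit$size, c(n1, n2))) return(hit$ffts)
  ffts <- lapply(bank$kernels, function(k) fft(pad_matrix(k, n1, n2)))
  .vn_cache[[key]] <- list(size = c(n1, n2), ffts = ffts)
  ffts
}

# area-weighted 1-D resampling matrix (rows sum to 1: block mean)
resample_weights <- function(n_in, ppd_in, ppd_out) {
  n_out <- round(n_in * ppd_out / ppd_in)
  block <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    a <- (i - 1) * block; b <- i * block
    j <- seq.int(floor(a) + 1L, ceiling(b))
    j <- j[j <= n_in]
    w <- pmin(j, b) - pmax(j - 1, a)
    W[i, j] <- w / sum(w)
  }
  W
}

#' @export
print.energy_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<energy_map> %dx%d px at %g ppd, %d orientation channels; mean %.3g\n",
              d[1], d[2], x$ppd, d[3], mean(x$values)))
  invisible(x)
}

#' Oriented energy: spatial mean per orientation channel
#'
#' Sums the contrast energy across space within each orientation band and
#' divides by the pixel count, giving one value per channel.
#'
#' @param E [compute_energy()] output
#' @return named numeric vector, one non-negative value per orientation
#' @export
oriented_energy <- function(E) {
  stopifnot(inherits(E, "energy_map"))
  e <- apply(E$values, 3, mean)
  names(e) <- paste0("theta", E$orientations)
  e
}

#' Circular variance of an oriented-energy vector
#'
#' 1 - |sum(e * exp(2i*theta))| / sum(e): 0 when all energy is at one
#' orientation, 1 when energy is spread uniformly.
#'
#' @param e oriented-energy vector (names or attribute-free; orientations are
#'   assumed equally spaced over 180 deg)
#' @return scalar in `[0, 1]`
#' @export
circular_variance <- function(e) {
  th <- (seq_along(e) - 1) * pi / length(e)
  1 - Mod(sum(e * exp(2i * th))) / sum(e)
}
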