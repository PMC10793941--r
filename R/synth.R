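# Synthesis of the band-pass texture families. All families share the same
# conventions: patterns are constructed on a square canvas, band-pass limited
# near 3 cycles/deg, scaled so that contrast c maps the extreme pixel to c/2
# (so c = 1 fills the full [-0.5, 0.5] range), and blended into the gray
# background through a half-cosine aperture. Orientation 0 deg means
# horizontal contours; angles increase counterclockwise.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

check_contrast <- function(contrast) {
  if (!is.numeric(contrast) || length(contrast) != 1L ||
      contrast < 0 || contrast > 1)
    vn_stop("contrast must be a single value in [0, 1]",
            "visnorm_domain_error")
}

# rotated coordinate perpendicular to contours at `orientation_deg`
contour_coord <- function(n, ppd, orientation_deg) {
  xs <- deg_grid(n, ppd)
  th <- orientation_deg * pi / 180
  outer(xs * cos(th), -xs * sin(th), "+") # t = y cos(th) - x sin(th)
}

# white noise low-passed by a hard isotropic cutoff in the frequency domain
lowpass_noise <- function(n, ppd, cutoff_cpd) {
  noise <- matrix(rnorm(n * n), n, n)
  fx <- c(0:floor(n / 2), -((ceiling(n / 2) - 1):1)) * ppd / n
  fr <- sqrt(outer(fx^2, fx^2, "+"))
  Re(fft(fft(noise) * (fr <= cutoff_cpd), inverse = TRUE)) / (n * n)
}

#' Density levels for the snakes family
#'
#' Low-pass cutoff frequencies (cycles/deg) defining the five density levels,
#' ordered densest to sparsest.
#' @return numeric vector
#' @export
snake_density_cutoffs <- function() c(2.8, 1.6, 0.9, 0.5, 0.3)

#' Contour spacings for the gratings / noise-bars density ladders
#' @return numeric vector of spacings (deg), densest last
#' @export
grating_density_spacings <- function() c(3, 2.5, 1.75, 1, 1 / 3)

#' Synthesize snakes (curved-contour band-pass textures)
#'
#' Each exemplar is built by low-pass filtering white noise at `level_cpd`,
#' thresholding at the median, marking level crossings with first-difference
#' derivative filters in x and y (combined by maximum), inverting polarity so
#' edges are dark, band-pass filtering, contrast scaling, and aperture
#' blending. Smaller cutoffs give sparser contours
#' (see [snake_density_cutoffs()]).
#'
#' @param level_cpd low-pass cutoff (cycles/deg) controlling contour density;
#'   sane range 0.1-5
#' @param contrast contrast fraction in `[0, 1]`
#' @param n_exemplars number of independent exemplar images
#' @param size_deg canvas side (deg)
#' @param ppd pixels per degree
#' @param seed integer seed; exemplar i uses `seed + i - 1`
#' @param aperture_deg aperture diameter (deg); defaults to the canvas size
#' @param blend_deg half-cosine blend width (deg)
#' @return [stim_set()]
#' @export
synth_snakes <- function(level_cpd = 0.5, contrast = 1, n_exemplars = 9,
                         size_deg = 12.5, ppd = 32, seed = 1,
                         aperture_deg = size_deg, blend_deg = 0.5,
                         manipulation = c("contrast", "density")) {
  manipulation <- match.arg(manipulation)
  check_contrast(contrast)
  if (level_cpd < 0.1 || level_cpd > 5)
    vn_stop("level_cpd outside the sane range 0.1-5 cycles/deg",
            "visnorm_domain_error")
  bp <- make_bandpass_kernel(ppd)
  n <- round(size_deg * ppd)
  exemplars <- lapply(seq_len(n_exemplars), function(i) {
    pat <- with_seed(seed + i - 1L, snake_pattern(n, ppd, level_cpd, bp))
    finish_stimulus(pat, contrast, ppd, aperture_deg, blend_deg)
  })
  level <- if (manipulation == "contrast") contrast else level_cpd
  stim_set("snakes", manipulation, level, exemplars, seed)
}

snake_pattern <- function(n, ppd, cutoff_cpd, bp) {
  lp <- lowpass_noise(n, ppd, cutoff_cpd)
  bw <- lp > median(lp)
  dx <- cbind(bw[, -1] != bw[, -ncol(bw)], FALSE)
  dy <- rbind(bw[-1, ] != bw[-nrow(bw), ], FALSE)
  edges <- pmax(dx, dy) # max of |d/dx|, |d/dy| on the binary image
  apply_bandpass(-edges, bp) # negative polarity: edges are black
}

#' Synthesize gratings (straight parallel band-pass contours)
#'
#' In `"lines"` mode, parallel one-pixel lines spaced every `spacing_deg` are
#' convolved with the band-pass kernel; exemplars differ in a random phase
#' offset of the line comb. In `"sinusoid"` mode the stimulus is a 3 cycle/deg
#' sinusoid at Michelson contrast `contrast`, and the exemplars step through
#' `n_exemplars` phases equally spaced over `[0, 2*pi)` (the `spacing_deg`
#' argument is ignored).
#'
#' @inheritParams synth_snakes
#' @param spacing_deg line spacing (deg); must be at least one pixel
#' @param orientation_deg contour orientation (0 = horizontal, CCW positive)
#' @param mode `"lines"` or `"sinusoid"`
#' @return [stim_set()]
#' @export
synth_gratings <- function(spacing_deg = 1.75, contrast = 0.25,
                           orientation_deg = 0,
                           mode = c("lines", "sinusoid"),
                           n_exemplars = 9, size_deg = 12.5, ppd = 32,
                           seed = 1, aperture_deg = size_deg,
                           blend_deg = 0.5,
                           manipulation = c("contrast", "density",
                                            "orientation")) {
  mode <- match.arg(mode)
  manipulation <- match.arg(manipulation)
  check_contrast(contrast)
  n <- round(size_deg * ppd)
  t <- contour_coord(n, ppd, orientation_deg)
  if (mode == "lines") {
    if (spacing_deg < 1 / ppd)
      vn_stop("spacing_deg is below one pixel (degenerate spacing)",
              "visnorm_domain_error")
    bp <- make_bandpass_kernel(ppd)
    offsets <- with_seed(seed, runif(n_exemplars, 0, spacing_deg))
    exemplars <- lapply(seq_len(n_exemplars), function(i) {
      phase <- (t - offsets[i]) %% spacing_deg
      lines <- (phase < 1 / ppd) * 1
      finish_stimulus(apply_bandpass(lines, bp), contrast, ppd,
                      aperture_deg, blend_deg)
    })
  } else {
    phases <- 2 * pi * (seq_len(n_exemplars) - 1L) / n_exemplars
    exemplars <- lapply(phases, function(ph) {
      # Michelson contrast fixes the amplitude analytically at c/2; scaling
      # by the sampled maximum would inflate phases whose extrema fall
      # between pixels
      pat <- (contrast / 2) * cos(2 * pi * 3 * t + ph)
      finish_stimulus(pat, contrast, ppd, aperture_deg, blend_deg,
                      scale = "none")
    })
  }
  level <- switch(manipulation, contrast = contrast, density = spacing_deg,
                  orientation = orientation_deg)
  stim_set("gratings", manipulation, level, exemplars, seed)
}

# angular Gaussian window in the Fourier plane, centered on the frequency
# direction perpendicular to contours at `orientation_deg`; symmetric across
# half-planes (distances taken mod 180 deg)
orientation_filter <- function(pattern, ppd, orientation_deg, sd_deg = 20) {
  n <- nrow(pattern)
  fx <- c(0:floor(n / 2), -((ceiling(n / 2) - 1):1)) * ppd / n
  ang <- atan2(outer(fx, rep(1, n)), outer(rep(1, n), fx)) * 180 / pi
  d <- (ang - (orientation_deg + 90)) %% 180
  d <- pmin(d, 180 - d)
  w <- exp(-0.5 * (d / sd_deg)^2)
  w[1, 1] <- 0
  Re(fft(fft(pattern) * w, inverse = TRUE)) / (n * n)
}

#' Synthesize waves (orientation-filtered snakes)
#'
#' Identical to [synth_snakes()] except that, before contrast scaling, the
#' pattern is filtered in the Fourier plane by an angular Gaussian window
#' (SD `ori_sd_deg`, applied symmetrically to both half-planes) so that power
#' concentrates at or near `orientation_deg`.
#'
#' @inheritParams synth_snakes
#' @param orientation_deg orientation the power is concentrated at
#' @param ori_sd_deg angular SD of the Fourier-plane window (deg)
#' @return [stim_set()]
#' @export
synth_waves <- function(level_cpd = 0.5, contrast = 1, orientation_deg = 0,
                        n_exemplars = 9, size_deg = 12.5, ppd = 32, seed = 1,
                        aperture_deg = size_deg, blend_deg = 0.5,
                        ori_sd_deg = 20) {
  check_contrast(contrast)
  if (level_cpd < 0.1 || level_cpd > 5)
    vn_stop("level_cpd outside the sane range 0.1-5 cycles/deg",
            "visnorm_domain_error")
  bp <- make_bandpass_kernel(ppd)
  n <- round(size_deg * ppd)
  exemplars <- lapply(seq_len(n_exemplars), function(i) {
    pat <- with_seed(seed + i - 1L, snake_pattern(n, ppd, level_cpd, bp))
    pat <- orientation_filter(pat, ppd, orientation_deg, ori_sd_deg)
    finish_stimulus(pat, contrast, ppd, aperture_deg, blend_deg)
  })
  stim_set("waves", "orientation", orientation_deg, exemplars, seed)
}

#' Synthesize noise bars (bands of isotropic band-pass noise)
#'
#' Parallel bands with the same spacings as the gratings
#' ([grating_density_spacings()]), but each band contains band-pass filtered
#' noise with power spread equally across orientations rather than oriented
#' contours. The contrast envelope is a raised-cosine band profile (full width
#' 1/3 deg, the band-pass wavelength, clipped to half the spacing) repeated
#' every `spacing_deg`, multiplied into the isotropic noise carrier.
#'
#' @inheritParams synth_gratings
#' @return [stim_set()]
#' @export
synth_noise_bars <- function(spacing_deg = 1.75, contrast = 0.25,
                             orientation_deg = 0, n_exemplars = 9,
                             size_deg = 12.5, ppd = 32, seed = 1,
                             aperture_deg = size_deg, blend_deg = 0.5) {
  check_contrast(contrast)
  if (spacing_deg < 1 / ppd)
    vn_stop("spacing_deg is below one pixel (degenerate spacing)",
            "visnorm_domain_error")
  bp <- make_bandpass_kernel(ppd)
  n <- round(size_deg * ppd)
  t <- contour_coord(n, ppd, orientation_deg)
  width <- min(1 / 3, spacing_deg / 2)
  offsets <- with_seed(seed, runif(n_exemplars, 0, spacing_deg))
  exemplars <- lapply(seq_len(n_exemplars), function(i) {
    d <- (t - offsets[i]) %% spacing_deg
    d <- pmin(d, spacing_deg - d) # distance to nearest band center
    env <- ifelse(d < width / 2, 0.5 * (1 + cos(2 * pi * d / width)), 0)
    carrier <- with_seed(seed + 1000L + i,
                         apply_bandpass(matrix(rnorm(n * n), n, n), bp))
    finish_stimulus(env * carrier, contrast, ppd, aperture_deg, blend_deg)
  })
  stim_set("noise_bars", "density", spacing_deg, exemplars, seed)
}

#' Synthesize multi-component gratings (plaid and circular families)
#'
#' The sum of `n_orientations` sinusoids at 3 cycles/deg, equally spaced in
#' orientation over 180 deg, each with an independent random phase. The sum is
#' rescaled so that its RMS contrast (before aperture blending) matches the
#' mean RMS of a sinusoidal grating set at the same Michelson contrast
#' (`n_orientations = 2` gives the plaid family, 16 the circular family).
#'
#' @inheritParams synth_snakes
#' @param n_orientations number of sinusoidal components
#' @return [stim_set()]
#' @export
synth_multi_component <- function(n_orientations = 2, contrast = 0.25,
                                  n_exemplars = 9, size_deg = 12.5, ppd = 32,
                                  seed = 1, aperture_deg = size_deg,
                                  blend_deg = 0.5) {
  check_contrast(contrast)
  stopifnot(n_orientations >= 1)
  n <- round(size_deg * ppd)
  # reference RMS: sinusoid at Michelson contrast `contrast` (amplitude c/2)
  ref <- rms(cos(2 * pi * 3 * contour_coord(n, ppd, 0))) * contrast / 2
  oris <- (seq_len(n_orientations) - 1L) * 180 / n_orientations
  exemplars <- lapply(seq_len(n_exemplars), function(i) {
    phases <- with_seed(seed + i - 1L, runif(n_orientations, 0, 2 * pi))
    pat <- Reduce(`+`, lapply(seq_len(n_orientations), function(k) {
      cos(2 * pi * 3 * contour_coord(n, ppd, oris[k]) + phases[k])
    }))
    if (contrast > 0) pat <- pat * ref / rms(pat)
    finish_stimulus(pat, contrast, ppd, aperture_deg, blend_deg,
                    scale = "none")
  })
  family <- if (n_orientations >= 3) "circular" else "plaid"
  stim_set(family, "contrast", contrast, exemplars, seed)
}

#' Synthesize cross gratings (contours interrupted by periodic blanks)
#'
#' Line gratings whose contours are interrupted by periodic blank regions
#' perpendicular to the contours, with a thin (25%) or thick (50%) duty cycle.
#'
#' @inheritParams synth_gratings
#' @param blank_spacing_deg spacing of the perpendicular blanks (deg)
#' @param duty fraction of each blank period that is blanked (0.25 or 0.5)
#' @return [stim_set()]
#' @export
synth_gratings_cross <- function(spacing_deg = 1 / 3, contrast = 0.25,
                                 blank_spacing_deg = 1.75, duty = 0.25,
                                 orientation_deg = 0, n_exemplars = 9,
                                 size_deg = 12.5, ppd = 32, seed = 1,
                                 aperture_deg = size_deg, blend_deg = 0.5) {
  check_contrast(contrast)
  base <- synth_gratings(spacing_deg, contrast = 1,
                         orientation_deg = orientation_deg, mode = "lines",
                         n_exemplars = n_exemplars, size_deg = size_deg,
                         ppd = ppd, seed = seed, aperture_deg = aperture_deg,
                         blend_deg = blend_deg)
  n <- round(size_deg * ppd)
  u <- contour_coord(n, ppd, orientation_deg + 90) # along the contours
  mask <- ((u %% blank_spacing_deg) >= duty * blank_spacing_deg) * 1
  exemplars <- lapply(base$exemplars, function(e) {
    finish_stimulus(e$pixels * mask, contrast, ppd, aperture_deg, blend_deg)
  })
  stim_set("gratings_cross", "density", spacing_deg, exemplars, seed)
}

#' Canvas geometry presets
#'
#' Display geometries of the three acquisition setups: `"ds1"` (12.5 deg,
#' 400 px), `"ds2"` (18.75 deg, 600 px), `"ds34"` (12.5 deg at the 256 px
#' construction resolution).
#'
#' @param name dialect name
#' @return list with `size_deg`, `n_px`, `ppd`
#' @export
canvas_dialect <- function(name = c("ds1", "ds2", "ds34")) {
  name <- match.arg(name)
  switch(name,
    ds1  = list(size_deg = 12.5,  n_px = 400L, ppd = 32),
    ds2  = list(size_deg = 18.75, n_px = 600L, ppd = 32),
    ds34 = list(size_deg = 12.5,  n_px = 256L, ppd = 256 / 12.5))
}
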