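#' Stimulus image container
#'
#' A preprocessed grayscale stimulus: pixel values are contrast (luminance
#' relative to the mean-gray background), lie in `[-0.5, 0.5]`, have spatial
#' mean near 0, and are exactly 0 outside the circular aperture.
#'
#' @param pixels square numeric matrix
#' @param ppd pixels per degree
#' @param aperture_deg diameter of the circular aperture (deg)
#' @return object of class `stim_image`
#' @export
stim_image <- function(pixels, ppd, aperture_deg) {
  stopifnot(is.matrix(pixels), is.numeric(pixels), ppd > 0, aperture_deg > 0)
  structure(list(pixels = pixels, ppd = ppd, aperture_deg = aperture_deg),
            class = "stim_image")
}

#' @export
print.stim_image <- function(x, ...) {
  cat(sprintf("<stim_image> %dx%d px, %g ppd, aperture %g deg, RMS %.4f\n",
              nrow(x$pixels), ncol(x$pixels), x$ppd, x$aperture_deg,
              rms(x$pixels)))
  invisible(x)
}

#' Stimulus set container
#'
#' An ordered collection of exemplar images from one texture family at one
#' manipulation level. All exemplars share geometry.
#'
#' @param family one of `"snakes"`, `"gratings"`, `"noise_bars"`, `"waves"`,
#'   `"plaid"`, `"circular"`, `"gratings_cross"`
#' @param manipulation `"contrast"`, `"density"`, or `"orientation"`
#' @param level manipulation level (contrast fraction, spacing in deg, cutoff
#'   in cycles/deg, or angle in deg)
#' @param exemplars list of [stim_image()] objects (at least one)
#' @param seed integer seed the exemplars were generated from
#' @return object of class `stim_set`
#' @export
stim_set <- function(family, manipulation, level, exemplars, seed) {
  family <- match.arg(family, c("snakes", "gratings", "noise_bars", "waves",
                                "plaid", "circular", "gratings_cross"))
  manipulation <- match.arg(manipulation,
                            c("contrast", "density", "orientation"))
  stopifnot(length(exemplars) >= 1L,
            all(vapply(exemplars, inherits, TRUE, "stim_image")))
  ppd <- exemplars[[1]]$ppd
  ap <- exemplars[[1]]$aperture_deg
  for (e in exemplars)
    if (e$ppd != ppd || e$aperture_deg != ap)
      vn_stop("exemplars do not share ppd/aperture", "visnorm_geometry_error")
  structure(list(family = family, manipulation = manipulation, level = level,
                 exemplars = exemplars, seed = seed, ppd = ppd,
                 aperture_deg = ap),
            class = "stim_set")
}

#' @export
print.stim_set <- function(x, ...) {
  cat(sprintf("<stim_set> %s (%s = %g): %d exemplars, %g ppd, seed %d\n",
              x$family, x$manipulation, x$level, length(x$exemplars),
              x$ppd, x$seed))
  invisible(x)
}

aperture_weight <- function(n, ppd, aperture_deg, blend_deg = 0.5) {
  xs <- deg_grid(n, ppd)
  r <- sqrt(outer(xs^2, xs^2, "+"))
  R <- aperture_deg / 2
  w <- matrix(0, n, n)
  w[r <= R - blend_deg] <- 1
  ramp <- r > R - blend_deg & r < R
  w[ramp] <- 0.5 * (1 + cos(pi * (r[ramp] - (R - blend_deg)) / blend_deg))
  w
}

#' Blend a stimulus into the gray background through a circular aperture
#'
#' Pixels beyond the aperture radius are set to 0 (background gray); the
#' outer `blend_deg` of the aperture is attenuated by a half-cosine ramp
#' (value 1 at the inner edge of the annulus, 0.5 at its midpoint, 0 at the
#' aperture edge); the interior is unchanged.
#'
#' @param img `stim_image` or numeric matrix
#' @param aperture_deg aperture diameter (deg); defaults to the image's
#' @param blend_deg width of the half-cosine ramp (deg)
#' @param ppd required when `img` is a bare matrix
#' @return `stim_image`
#' @export
apply_aperture <- function(img, aperture_deg = NULL, blend_deg = 0.5,
                           ppd = NULL) {
  if (inherits(img, "stim_image")) {
    ppd <- img$ppd
    if (is.null(aperture_deg)) aperture_deg <- img$aperture_deg
    px <- img$pixels
  } else {
    stopifnot(!is.null(ppd), !is.null(aperture_deg))
    px <- img
  }
  w <- aperture_weight(nrow(px), ppd, aperture_deg, blend_deg)
  stim_image(px * w, ppd, aperture_deg)
}

# scale a raw pattern so max|pixel| = contrast/2, blend through the aperture,
# and recenter the mean without disturbing the gray surround
finish_stimulus <- function(pattern, contrast, ppd, aperture_deg, blend_deg,
                            scale = c("max", "none")) {
  scale <- match.arg(scale)
  if (contrast == 0 || max(abs(pattern)) == 0) {
    return(stim_image(matrix(0, nrow(pattern), ncol(pattern)), ppd,
                      aperture_deg))
  }
  if (scale == "max") pattern <- pattern * (contrast / 2) / max(abs(pattern))
  w <- aperture_weight(nrow(pattern), ppd, aperture_deg, blend_deg)
  px <- pattern * w
  m <- mean(px)
  if (abs(m) > 1e-12) px <- px - m * w / mean(w) # keeps surround at 0
  px <- pmin(pmax(px, -0.5), 0.5)
  stim_image(px, ppd, aperture_deg)
}

# PNG / JSON serialization -----------------------------------------------------

#' Write a stimulus set as 8-bit grayscale PNGs with a JSON sidecar
#'
#' Contrast 0 maps to gray level 128; the full `[-0.5, 0.5]` range maps to
#' `[1, 255]` (value = 128 + round(254 * pixel)). The sidecar mirrors the
#' set's metadata (family, manipulation, level, seed, ppd, aperture) plus the
#' achieved RMS per exemplar.
#'
#' @param set `stim_set`
#' @param dir output directory (created if missing)
#' @param prefix file-name prefix
#' @return invisibly, the sidecar path
#' @export
write_stim_png <- function(set, dir, prefix = NULL) {
  stopifnot(inherits(set, "stim_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(prefix))
    prefix <- sprintf("%s_%s_%g", set$family, set$manipulation, set$level)
  files <- character(length(set$exemplars))
  for (i in seq_along(set$exemplars)) {
    px <- set$exemplars[[i]]$pixels
    g <- (128 + round(254 * px)) / 255
    files[i] <- file.path(dir, sprintf("%s_ex%02d.png", prefix, i))
    png::writePNG(pmin(pmax(g, 0), 1), files[i])
  }
  meta <- list(family = set$family, manipulation = set$manipulation,
               level = set$level, seed = set$seed, ppd = set$ppd,
               aperture_deg = set$aperture_deg,
               rms = vapply(set$exemplars, function(e) rms(e$pixels), 0),
               files = basename(files))
  sidecar <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a stimulus set written by [write_stim_png()]
#' @param sidecar path to the JSON sidecar
#' @return `stim_set`
#' @export
read_stim_png <- function(sidecar) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dir <- dirname(sidecar)
  exemplars <- lapply(meta$files, function(f) {
    g <- png::readPNG(file.path(dir, f))
    if (length(dim(g)) == 3L) g <- g[, , 1]
    stim_image((round(g * 255) - 128) / 254, meta$ppd, meta$aperture_deg)
  })
  stim_set(meta$family, meta$manipulation, meta$level, exemplars, meta$seed)
}
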