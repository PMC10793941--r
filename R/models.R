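# The four pooling functionals and the power-law output stage. All models map
# an oriented contrast-energy image E(x, y, theta) to a scalar drive s, then
# to a predicted BOLD amplitude r = g * s^alpha (percent signal change).

EPS_DENOM <- 1e-12

#' Spatial Gaussian normalization-pool kernel
#'
#' The divisive-normalization pool weights distance by a 2-D Gaussian whose
#' standard deviation is a fixed fraction (default 4%) of the padded image
#' width, evaluated at the energy-map resolution. Each orientation plane of
#' the pool sums to 1, and the pool sums contributions over all 8 planes, so
#' a uniform energy field `E = c` yields `Z = 8 c`. In the orientation-tuned
#' variant the full Gaussian applies only to the same-orientation plane;
#' other-orientation planes contribute through the center pixel only
#' (cross-orientation suppression).
#'
#' @param E an [compute_energy()] output (geometry source), or an integer
#'   vector of spatial dimensions
#' @param sd_frac Gaussian SD as a fraction of the padded image width
#' @param tuned logical; orientation-tuned pool structure
#' @param cross_weight weight of the one-pixel cross-orientation term in the
#'   tuned pool, relative to a unit of energy. The default is the peak value
#'   of the unit-sum surround Gaussian: the off-diagonal (other-orientation)
#'   kernels are narrow Gaussians with the same amplitude as the diagonal
#'   one, so their integral is one pixel's worth of the wide Gaussian. (If
#'   the one-pixel kernels instead carried unit sum, the tuned pool would be
#'   numerically indistinguishable from the untuned pool for spatially
#'   homogeneous textures, abolishing the tuned model's defining behavior.)
#' @return object of class `norm_kernel`: list with `G` (unit-sum matrix),
#'   `sd_px`, `sd_frac`, `tuned`, `cross_weight`
#' @export
norm_kernel <- function(E, sd_frac = 0.04, tuned = FALSE,
                        cross_weight = NULL) {
  dims <- if (inherits(E, "energy_map")) dim(E$values)[1:2] else E[1:2]
  sd_px <- sd_frac * max(dims)
  half <- ceiling(3 * sd_px)
  xs <- (-half):half
  g1 <- exp(-0.5 * (xs / sd_px)^2)
  G <- outer(g1, g1)
  G <- G / sum(G)
  structure(list(G = G, sd_px = sd_px, sd_frac = sd_frac, tuned = tuned,
                 cross_weight = cross_weight %||% max(G)),
            class = "norm_kernel")
}

#' Normalization pool Z for the divisive-normalization models
#'
#' Untuned: the same pool for every channel, the spatial Gaussian convolution
#' of the orientation-summed energy (all 8 orientation planes contribute with
#' full Gaussian weight; a uniform field `E = c` gives `Z = 8 c`). Tuned: per
#' channel, the Gaussian convolution of the same-orientation plane plus the
#' energy of the other orientations at the center pixel only, weighted by
#' the kernel's `cross_weight` (amplitude-matched one-pixel kernels; see
#' [norm_kernel()]).
#'
#' @param E [compute_energy()] output
#' @param kern [norm_kernel()]; its `tuned` flag selects the pool structure
#' @return 3-D array with `dim(E$values)`
#' @export
norm_pool <- function(E, kern) {
  stopifnot(inherits(E, "energy_map"), inherits(kern, "norm_kernel"))
  v <- E$values
  total <- apply(v, c(1, 2), sum)
  n_ori <- dim(v)[3]
  Z <- array(0, dim(v))
  if (!kern$tuned) {
    Zs <- conv2_same(total, kern$G)
    for (t in seq_len(n_ori)) Z[, , t] <- Zs
  } else {
    for (t in seq_len(n_ori))
      Z[, , t] <- conv2_same(v[, , t], kern$G) +
        kern$cross_weight * (total - v[, , t])
  }
  Z
}

#' Contrast-energy pooling: mean energy over space and orientation
#'
#' @param E [compute_energy()] output
#' @return scalar drive `s`
#' @export
pool_ce <- function(E) {
  stopifnot(inherits(E, "energy_map"))
  mean(E$values)
}

#' Untuned divisive-normalization pooling
#'
#' Each energy sample is divided by `sigma` plus the untuned normalization
#' pool ([norm_pool()]); the normalized energy is then averaged over space and
#' orientation. Large `sigma` approaches the contrast-energy model (up to the
#' `1/sigma` gain, absorbed by the fitted gain).
#'
#' @param E [compute_energy()] output
#' @param sigma semisaturation constant, >= 0
#' @param kern optional [norm_kernel()] (untuned); built from `E` if missing
#' @return scalar drive `s`
#' @export
pool_dn <- function(E, sigma, kern = NULL) {
  stopifnot(sigma >= 0)
  if (is.null(kern)) kern <- norm_kernel(E, tuned = FALSE)
  kern$tuned <- FALSE
  Z <- norm_pool(E, kern)
  mean(E$values / pmax(sigma + Z, EPS_DENOM))
}

#' Orientation-tuned normalization pooling
#'
#' As [pool_dn()], but the pool at surrounding locations is restricted to the
#' same orientation channel (orientation-tuned surround), while other
#' orientations contribute only at the center pixel (cross-orientation
#' suppression). With an untuned kernel this reduces exactly to [pool_dn()].
#'
#' @inheritParams pool_dn
#' @param kern optional [norm_kernel()]; built tuned from `E` if missing
#' @return scalar drive `s`
#' @export
pool_otn <- function(E, sigma, kern = NULL) {
  stopifnot(sigma >= 0)
  if (is.null(kern)) kern <- norm_kernel(E, tuned = TRUE)
  Z <- norm_pool(E, kern)
  mean(E$values / pmax(sigma + Z, EPS_DENOM))
}

#' Normalization by orientation anisotropy
#'
#' Pools the squared oriented energy, normalized by the anisotropy of the
#' oriented-energy vector: `s = mean(e^2) / (sigma^2 + V)` with
#' `V = sum((e - mean(e))^2)` (the sum of squared deviations across the 8
#' orientation channels; numerator and `sigma` are squared to keep parameter
#' scales comparable across models). `variant = "sqrt"` uses the square-root
#' form `mean(e) / (sigma + sqrt(V))` instead.
#'
#' @param e oriented-energy vector ([oriented_energy()]), or an `energy_map`
#' @param sigma semisaturation constant, >= 0
#' @param variant `"squared"` (default) or `"sqrt"`
#' @return scalar drive `s`
#' @export
pool_noa <- function(e, sigma, variant = c("squared", "sqrt")) {
  variant <- match.arg(variant)
  stopifnot(sigma >= 0)
  if (inherits(e, "energy_map")) e <- oriented_energy(e)
  V <- sum((e - mean(e))^2)
  if (variant == "squared") {
    mean(e^2) / pmax(sigma^2 + V, EPS_DENOM)
  } else {
    mean(e) / pmax(sigma + sqrt(V), EPS_DENOM)
  }
}

#' Power-law output nonlinearity
#'
#' `r = g * s^alpha`, the predicted BOLD amplitude in percent signal change.
#'
#' @param s pooled drive (>= 0)
#' @param g gain
#' @param alpha exponent in (0, 1]; compressive when < 1
#' @return predicted response
#' @export
respond <- function(s, g, alpha) {
  g * s^alpha
}

#' Model specification
#'
#' Bundles a pooling-model name with its parameters. CE has two free
#' parameters (g, alpha); DN, OTN and NOA add the semisaturation sigma.
#'
#' @param name `"ce"`, `"dn"`, `"otn"`, or `"noa"`
#' @param g gain (>= 0, percent-signal-change scale)
#' @param alpha power-law exponent in (0, 1]
#' @param sigma semisaturation constant (ignored for `"ce"`)
#' @return object of class `vn_model`
#' @export
model_spec <- function(name = c("ce", "dn", "otn", "noa"), g = 1, alpha = 1,
                       sigma = NA_real_) {
  name <- match.arg(name)
  if (name != "ce" && (is.na(sigma) || sigma < 0))
    vn_stop(sprintf("model '%s' requires sigma >= 0", name),
            "visnorm_domain_error")
  stopifnot(g >= 0, alpha > 0, alpha <= 1)
  structure(list(name = name, g = g, alpha = alpha, sigma = sigma),
            class = "vn_model")
}

#' Names and parameter counts of the model registry
#' @return data frame with `model` and `n_params`
#' @export
model_registry <- function() {
  data.frame(model = c("ce", "dn", "otn", "noa"),
             n_params = c(2L, 3L, 3L, 3L))
}

#' @export
print.vn_model <- function(x, ...) {
  cat(sprintf("<vn_model> %s: g = %.4g, alpha = %.4g, sigma = %.4g\n",
              x$name, x$g, x$alpha, x$sigma))
  invisible(x)
}

pool_drive <- function(model, E, kern = NULL) {
  switch(model$name,
    ce  = pool_ce(E),
    dn  = pool_dn(E, model$sigma, kern),
    otn = pool_otn(E, model$sigma, kern),
    noa = pool_noa(E, model$sigma))
}

#' Predicted response to a multi-exemplar stimulus
#'
#' Runs each exemplar through the energy pipeline, pools it with the model's
#' functional, applies the power law, and averages the predictions across
#' exemplars.
#'
#' @param model [model_spec()]
#' @param stim [stim_set()]
#' @param bank [build_filterbank()] matching the stimulus ppd
#' @param kern optional [norm_kernel()] (built per exemplar otherwise)
#' @param emaps optional precomputed list of energy maps (one per exemplar),
#'   bypassing `bank`
#' @return scalar predicted response (percent signal change)
#' @export
predict_stimulus <- function(model, stim, bank = NULL, kern = NULL,
                             emaps = NULL) {
  stopifnot(inherits(model, "vn_model"))
  if (is.null(emaps)) {
    stopifnot(inherits(stim, "stim_set"), inherits(bank, "filter_bank"))
    emaps <- lapply(stim$exemplars, compute_energy, bank = bank)
  }
  preds <- vapply(emaps, function(E) {
    k <- kern
    if (is.null(k) && model$name %in% c("dn", "otn"))
      k <- norm_kernel(E, tuned = model$name == "otn")
    respond(pool_drive(model, E, k), model$g, model$alpha)
  }, 0)
  mean(preds)
}
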