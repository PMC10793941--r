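# Pooling contexts: per-stimulus precomputations that make the sigma-dependent
# pooling step cheap inside the fitting loop. Filtering (the expensive part)
# happens once; only pooling is re-evaluated per candidate sigma.
#
# - ce:      the pooled drive s is sigma-free and cached as a scalar.
# - dn/otn:  s(sigma) = (1/N) sum_j E_j / (sigma + Z_j). Pixels with E_j = 0
#            contribute nothing for any sigma and are dropped exactly; the
#            remaining (E, Z) pairs are compressed into Z-quantile bins
#            (energy-weighted mean Z per bin), so each evaluation is O(nbin).
# - noa:     the oriented-energy vector e is cached; s(sigma) is closed form.

#' Precompute pooling contexts for fitting
#'
#' @param model_name `"ce"`, `"dn"`, `"otn"`, or `"noa"`
#' @param sets list of [stim_set()] objects, one per stimulus
#' @param bank [build_filterbank()] output (ignored when `emaps` given)
#' @param emaps optional list (per stimulus) of lists of energy maps
#' @param nbin number of Z-quantile bins for dn/otn compression
#' @param sd_frac normalization-pool Gaussian SD fraction
#' @return object of class `pooling_context`
#' @export
pooling_context <- function(model_name, sets = NULL, bank = NULL,
                            emaps = NULL, nbin = 512L, sd_frac = 0.04) {
  model_name <- match.arg(model_name, c("ce", "dn", "otn", "noa"))
  if (is.null(emaps)) {
    stopifnot(!is.null(sets), !is.null(bank))
    emaps <- lapply(sets, function(s)
      lapply(s$exemplars, compute_energy, bank = bank))
  }
  stim <- lapply(emaps, function(maps)
    lapply(maps, exemplar_context, model_name = model_name, nbin = nbin,
           sd_frac = sd_frac))
  structure(list(model = model_name, stim = stim, n_stim = length(stim),
                 nbin = nbin, sd_frac = sd_frac),
            class = "pooling_context")
}

exemplar_context <- function(E, model_name, nbin, sd_frac) {
  switch(model_name,
    ce = list(s = pool_ce(E)),
    noa = {
      e <- oriented_energy(E)
      list(me2 = mean(e^2), V = sum((e - mean(e))^2))
    },
    { # dn / otn
      kern <- norm_kernel(E, sd_frac = sd_frac,
                          tuned = model_name == "otn")
      Z <- norm_pool(E, kern)
      ev <- as.numeric(E$values); zv <- as.numeric(Z)
      N <- length(ev)
      keep <- ev > 0
      ev <- ev[keep]; zv <- zv[keep]
      if (length(ev) == 0L) return(list(w = numeric(0), z = numeric(0), N = N))
      o <- order(zv)
      ev <- ev[o]; zv <- zv[o]
      nb <- min(nbin, length(ev))
      grp <- ceiling(seq_along(ev) / length(ev) * nb)
      w <- as.numeric(rowsum(ev, grp))
      z <- as.numeric(rowsum(ev * zv, grp)) / w
      list(w = w, z = z, N = N)
    })
}

# pooled drive s for one exemplar context at a given sigma
ctx_drive <- function(ctx, model_name, sigma) {
  switch(model_name,
    ce = ctx$s,
    noa = ctx$me2 / pmax(sigma^2 + ctx$V, EPS_DENOM),
    {
      if (length(ctx$w) == 0L) return(0)
      sum(ctx$w / pmax(sigma + ctx$z, EPS_DENOM)) / ctx$N
    })
}

# d s / d sigma for one exemplar context
ctx_drive_grad <- function(ctx, model_name, sigma) {
  switch(model_name,
    ce = 0,
    noa = -2 * sigma * ctx$me2 / pmax(sigma^2 + ctx$V, EPS_DENOM)^2,
    {
      if (length(ctx$w) == 0L) return(0)
      -sum(ctx$w / pmax(sigma + ctx$z, EPS_DENOM)^2) / ctx$N
    })
}

# per-stimulus drives: list of numeric vectors (one value per exemplar)
context_drives <- function(context, sigma, subset = NULL) {
  stim <- if (is.null(subset)) context$stim else context$stim[subset]
  lapply(stim, function(ex)
    vapply(ex, ctx_drive, 0, model_name = context$model, sigma = sigma))
}

context_drive_grads <- function(context, sigma, subset = NULL) {
  stim <- if (is.null(subset)) context$stim else context$stim[subset]
  lapply(stim, function(ex)
    vapply(ex, ctx_drive_grad, 0, model_name = context$model, sigma = sigma))
}

#' Predictions from a pooling context
#'
#' Exemplar-wise drives are passed through the power law and averaged within
#' each stimulus.
#'
#' @param context [pooling_context()]
#' @param g,alpha,sigma model parameters
#' @param subset optional stimulus indices
#' @return numeric vector of predicted responses
#' @export
predict_context <- function(context, g, alpha, sigma = NA_real_,
                            subset = NULL) {
  drives <- context_drives(context, sigma, subset)
  vapply(drives, function(s) mean(g * s^alpha), 0)
}
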