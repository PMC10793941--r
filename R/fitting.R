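# Multi-start least-squares estimation. The search space is transformed so
# every start is unconstrained: alpha through a sigmoid to (0, 1) and sigma
# through exp to (0, Inf). The gain g is profiled out in closed form at every
# objective evaluation (ordinary least squares given alpha and sigma, floored
# at 0), which removes the scale pathology of searching g directly; at the
# optimum this is identical to searching all parameters jointly.

#' Fit a pooling model to per-stimulus responses
#'
#' Minimizes the (unweighted) squared error between model predictions and
#' responses with a gradient-based local optimizer (BFGS, analytic
#' gradients), restarted from `n_starts` random initializations in the
#' transformed parameter space (standard normal scaled by `init_sd`,
#' deterministic given `seed`). The best (lowest-SSE) solution is returned;
#' ties break toward the earliest start.
#'
#' @param context [pooling_context()] for the stimuli
#' @param responses numeric vector of observed responses (one per stimulus)
#' @param n_starts number of random initializations
#' @param seed integer seed controlling the starts
#' @param subset optional stimulus indices to fit on (used by [loo_cv()])
#' @param init_sd SD of the random starts in transformed space
#' @param maxit maximum optimizer iterations per start
#' @return object of class `fit_result`: list with `model`, `params`
#'   ([model_spec()]), `sse`, `n_starts`, `seed`, `start_values` (per-start
#'   best SSE), `best_start`
#' @export
fit_model <- function(context, responses, n_starts = 40L, seed = 1L,
                      subset = NULL, init_sd = 2, maxit = 500L) {
  stopifnot(inherits(context, "pooling_context"))
  idx <- if (is.null(subset)) seq_len(context$n_stim) else subset
  r <- responses[idx]
  has_sigma <- context$model != "ce"
  npar <- if (has_sigma) 2L else 1L
  if (length(r) < npar + 1L)
    vn_stop("too few stimuli for the number of free parameters",
            "visnorm_domain_error")

  eval_parts <- function(u) {
    # clamp away from the open interval's endpoints (plogis underflows to
    # exactly 0/1 for |u| beyond ~745)
    alpha <- min(max(plogis(u[1]), 1e-8), 1 - 1e-8)
    sigma <- if (has_sigma) exp(u[2]) else NA_real_
    drives <- context_drives(context, sigma, idx)
    q <- vapply(drives, function(s) mean(s^alpha), 0)
    g <- sum(q * r) / max(sum(q^2), EPS_DENOM)
    g <- max(g, 0)
    list(alpha = alpha, sigma = sigma, drives = drives, q = q, g = g,
         resid = r - g * q)
  }
  fn <- function(u) sum(eval_parts(u)$resid^2)
  gr <- function(u) {
    p <- eval_parts(u)
    dq_da <- vapply(p$drives, function(s) {
      pos <- s > 0
      if (!any(pos)) return(0)
      mean(ifelse(pos, s^p$alpha * log(pmax(s, EPS_DENOM)), 0))
    }, 0)
    g1 <- -2 * p$g * sum(p$resid * dq_da) * p$alpha * (1 - p$alpha)
    if (!has_sigma) return(g1)
    dgr <- context_drive_grads(context, p$sigma, idx)
    dq_ds <- mapply(function(s, ds) {
      pos <- s > 0
      if (!any(pos)) return(0)
      mean(ifelse(pos, p$alpha * s^(p$alpha - 1) * ds, 0))
    }, p$drives, dgr)
    g2 <- -2 * p$g * sum(p$resid * dq_ds) * p$sigma
    c(g1, g2)
  }

  starts <- with_seed(seed, matrix(rnorm(n_starts * npar, 0, init_sd),
                                   n_starts, npar))
  best <- NULL
  start_values <- rep(NA_real_, n_starts)
  for (k in seq_len(n_starts)) {
    fit <- tryCatch(
      optim(starts[k, ], fn, gr, method = "BFGS",
            control = list(maxit = maxit, reltol = 1e-9)),
      error = function(e) NULL)
    if (is.null(fit)) next
    start_values[k] <- fit$value
    if (is.null(best) || fit$value < best$value - 1e-12) {
      best <- fit
      best$start <- k
    }
  }
  if (is.null(best))
    vn_stop("all optimization starts failed",
            "visnorm_optimization_error", start_values = start_values)
  p <- eval_parts(best$par)
  structure(
    list(model = context$model,
         params = model_spec(context$model, g = p$g, alpha = p$alpha,
                             sigma = p$sigma),
         sse = best$value, n_starts = n_starts, seed = seed,
         start_values = start_values, best_start = best$start),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: g = %.4g, alpha = %.4g, sigma = %.4g; SSE %.4g (%d starts)\n",
              x$model, x$params$g, x$params$alpha, x$params$sigma,
              x$sse, x$n_starts))
  invisible(x)
}

#' Leave-one-out cross-validation of a pooling model
#'
#' For each stimulus, the model is fit ([fit_model()]) to all other stimuli
#' and the held-out response is predicted; predictions are scored with
#' [r_squared()]. The number of fits equals the number of stimuli.
#'
#' @inheritParams fit_model
#' @return object of class `cv_report`: list with `heldout_pred` (one value
#'   per stimulus), `r2`, `fold_params` (list of [model_spec()]), `observed`
#' @export
loo_cv <- function(context, responses, n_starts = 40L, seed = 1L) {
  stopifnot(length(responses) == context$n_stim)
  n <- context$n_stim
  heldout <- rep(NA_real_, n)
  fold_params <- vector("list", n)
  for (i in seq_len(n)) {
    fit <- fit_model(context, responses, n_starts = n_starts, seed = seed,
                     subset = setdiff(seq_len(n), i))
    p <- fit$params
    heldout[i] <- predict_context(context, p$g, p$alpha, p$sigma,
                                  subset = i)
    fold_params[[i]] <- p
  }
  structure(list(heldout_pred = heldout, r2 = r_squared(heldout, responses),
                 fold_params = fold_params, observed = responses),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d stimuli, cross-validated R^2 = %.3f\n",
              length(x$heldout_pred), x$r2))
  invisible(x)
}

#' Variance explained by predictions
#'
#' `R^2 = 1 - sum((data - pred)^2) / sum((data - mean(data))^2)`. A perfect
#' prediction gives 1; predicting the data mean gives 0; worse-than-mean
#' predictions give negative values (not clipped).
#'
#' @param pred predicted values
#' @param data observed values
#' @return scalar (at most 1, possibly negative)
#' @export
r_squared <- function(pred, data) {
  stopifnot(length(pred) == length(data))
  1 - sum((data - pred)^2) / sum((data - mean(data))^2)
}

#' Serialize fit and cross-validation results
#'
#' Writes a `fit_result` or `cv_report` to JSON; for `cv_report`, also writes
#' a per-fold CSV (stim_id, heldout_pred, observed) when `csv` is given.
#'
#' @param x `fit_result` or `cv_report`
#' @param path output JSON path
#' @param csv optional per-fold CSV path (cv_report only)
#' @return invisibly, `path`
#' @export
write_fit_json <- function(x, path, csv = NULL) {
  if (inherits(x, "fit_result")) {
    out <- list(model = x$model,
                params = list(g = x$params$g, alpha = x$params$alpha,
                              sigma = x$params$sigma),
                sse = x$sse, n_starts = x$n_starts, seed = x$seed)
  } else if (inherits(x, "cv_report")) {
    out <- list(r2 = x$r2, heldout_pred = x$heldout_pred,
                observed = x$observed,
                fold_params = lapply(x$fold_params, function(p)
                  list(g = p$g, alpha = p$alpha, sigma = p$sigma)))
    if (!is.null(csv)) {
      write.csv(data.frame(stim_id = seq_along(x$heldout_pred),
                           heldout_pred = x$heldout_pred,
                           observed = x$observed),
                csv, row.names = FALSE)
    }
  } else vn_stop("unsupported object", "visnorm_domain_error")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
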