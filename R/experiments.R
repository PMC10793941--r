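# Diagnostic experiments: the snakes/gratings ratio, the contrast-slope
# analysis, the center-surround suppression simulation, the ROI-beta adapter,
# and the synthetic-BOLD generator used for parameter recovery.

#' Energy-matched snakes/gratings target battery
#'
#' Builds the two target stimulus classes over a contrast ladder: snakes
#' (curved contours, low-pass cutoff `snake_cutoff` cycles/deg) and line
#' gratings (spacing `grating_spacing` deg). Within each contrast level the
#' grating and snake sets are equated in total contrast energy: the class
#' with more energy is scaled down by the square root of the energy ratio
#' (energy is quadratic in pixel contrast, so the match is exact up to
#' arithmetic). The achieved per-level energy ratios are reported.
#'
#' @param contrasts contrast ladder (fractions)
#' @param snake_cutoff snakes low-pass cutoff (cycles/deg)
#' @param grating_spacing grating line spacing (deg)
#' @param n_exemplars exemplars per stimulus
#' @param size_deg,ppd canvas geometry
#' @param seed integer seed
#' @param bank optional [build_filterbank()]; built at `ppd` if missing
#' @return object of class `target_battery`: list with `snakes`, `gratings`
#'   (lists of [stim_set()] per contrast), `emaps_snakes`, `emaps_gratings`
#'   (energy maps after matching), `energy_match` (data frame with the
#'   achieved snake/grating energy ratio per level), `contrasts`, `bank`
#' @export
make_target_battery <- function(contrasts = c(0.03, 0.10, 0.25, 0.50, 1.00),
                                snake_cutoff = 0.5, grating_spacing = 1.75,
                                n_exemplars = 3, size_deg = 8, ppd = 12,
                                seed = 1, bank = NULL) {
  if (is.null(bank)) bank <- build_filterbank(ppd)
  snakes <- lapply(contrasts, function(cc)
    synth_snakes(snake_cutoff, cc, n_exemplars, size_deg, ppd, seed))
  gratings <- lapply(contrasts, function(cc)
    synth_gratings(grating_spacing, cc, mode = "lines",
                   n_exemplars = n_exemplars, size_deg = size_deg,
                   ppd = ppd, seed = seed + 500L))
  set_energy <- function(s) {
    maps <- lapply(s$exemplars, compute_energy, bank = bank)
    list(maps = maps, total = mean(vapply(maps, pool_ce, 0)))
  }
  es <- lapply(snakes, set_energy)
  eg <- lapply(gratings, set_energy)
  match <- data.frame(contrast = contrasts, ratio_before = NA_real_,
                      ratio_after = NA_real_)
  for (i in seq_along(contrasts)) {
    r0 <- es[[i]]$total / eg[[i]]$total
    match$ratio_before[i] <- r0
    if (is.finite(r0) && r0 > 0) {
      if (r0 > 1) { # snakes carry more energy: scale snakes down
        snakes[[i]] <- scale_set(snakes[[i]], 1 / sqrt(r0))
        es[[i]] <- set_energy(snakes[[i]])
      } else if (r0 < 1) {
        gratings[[i]] <- scale_set(gratings[[i]], sqrt(r0))
        eg[[i]] <- set_energy(gratings[[i]])
      }
    }
    match$ratio_after[i] <- es[[i]]$total / eg[[i]]$total
  }
  structure(list(snakes = snakes, gratings = gratings,
                 emaps_snakes = lapply(es, `[[`, "maps"),
                 emaps_gratings = lapply(eg, `[[`, "maps"),
                 energy_match = match, contrasts = contrasts, bank = bank),
            class = "target_battery")
}

scale_set <- function(s, factor) {
  s$exemplars <- lapply(s$exemplars, function(e) {
    e$pixels <- e$pixels * factor
    e
  })
  s
}

#' The 30-stimulus parameter-recovery battery
#'
#' A fixed synthetic design mirroring the dataset-1 stimulus table: the
#' 3/10/25/50/100% contrast ladder for each of snakes, line gratings, waves
#' and noise bars (20 stimuli), plus the snakes density ladder (cutoffs
#' 2.8/1.6/0.9/0.5/0.3 cycles/deg) and the gratings density ladder (spacings
#' 3/2.5/1.75/1/0.33 deg), both at 25% contrast (10 stimuli). One exemplar
#' per stimulus at the analysis resolution keeps recovery studies tractable.
#'
#' @param size_deg,ppd canvas geometry
#' @param seed base integer seed (stimulus k draws from `seed + 7 k`)
#' @param n_exemplars exemplars per stimulus
#' @return list of 30 [stim_set()] objects
#' @export
recovery_battery <- function(size_deg = 8, ppd = 12, seed = 1,
                             n_exemplars = 1) {
  contrasts <- c(0.03, 0.10, 0.25, 0.50, 1.00)
  sets <- list()
  k <- 0L
  nxt <- function() seed + 7L * (k + 1L)
  for (cc in contrasts) {
    k <- k + 1L
    sets[[k]] <- synth_snakes(0.5, cc, n_exemplars, size_deg, ppd, nxt())
    k <- k + 1L
    sets[[k]] <- synth_gratings(1.75, cc, mode = "lines",
                                n_exemplars = n_exemplars,
                                size_deg = size_deg, ppd = ppd, seed = nxt())
    k <- k + 1L
    sets[[k]] <- synth_waves(0.5, cc, 0, n_exemplars, size_deg, ppd, nxt())
    k <- k + 1L
    sets[[k]] <- synth_noise_bars(1.75, cc, 0, n_exemplars, size_deg, ppd,
                                  nxt())
  }
  for (cut in snake_density_cutoffs()) {
    k <- k + 1L
    sets[[k]] <- synth_snakes(cut, 0.25, n_exemplars, size_deg, ppd, nxt(),
                              manipulation = "density")
  }
  for (sp in grating_density_spacings()) {
    k <- k + 1L
    sets[[k]] <- synth_gratings(sp, 0.25, mode = "lines",
                                n_exemplars = n_exemplars,
                                size_deg = size_deg, ppd = ppd, seed = nxt(),
                                manipulation = "density")
  }
  sets
}

#' Mid-range semisaturation constant for a model
#'
#' A data-driven default for sigma: for dn/otn, the energy-weighted geometric
#' mean of the normalization pool Z over the supplied energy maps; for noa,
#' the square root of the geometric mean of the anisotropy V; for ce, `NA`.
#'
#' @param model_name model name
#' @param emaps flat list of energy maps
#' @param sd_frac normalization-pool Gaussian SD fraction
#' @return scalar sigma
#' @export
suggest_sigma <- function(model_name, emaps, sd_frac = 0.04) {
  model_name <- match.arg(model_name, c("ce", "dn", "otn", "noa"))
  if (model_name == "ce") return(NA_real_)
  if (model_name == "noa") {
    v <- vapply(emaps, function(E) {
      e <- oriented_energy(E)
      sum((e - mean(e))^2)
    }, 0)
    v <- v[v > 0]
    return(sqrt(exp(mean(log(v)))))
  }
  logs <- vapply(emaps, function(E) {
    kern <- norm_kernel(E, sd_frac = sd_frac, tuned = model_name == "otn")
    Z <- norm_pool(E, kern)
    w <- as.numeric(E$values); z <- as.numeric(Z)
    keep <- w > 0 & z > 0
    if (!any(keep)) return(NA_real_)
    weighted.mean(log(z[keep]), w[keep])
  }, 0)
  exp(mean(logs, na.rm = TRUE))
}

battery_predictions <- function(model, battery) {
  kern_cache <- new.env(parent = emptyenv())
  pred_set <- function(maps) {
    kern <- NULL
    if (model$name %in% c("dn", "otn")) {
      key <- paste(dim(maps[[1]]$values)[1:2], collapse = "x")
      kern <- kern_cache[[key]]
      if (is.null(kern)) {
        kern <- norm_kernel(maps[[1]], tuned = model$name == "otn")
        kern_cache[[key]] <- kern
      }
    }
    predict_stimulus(model, emaps = maps, kern = kern)
  }
  list(snakes = vapply(battery$emaps_snakes, pred_set, 0),
       gratings = vapply(battery$emaps_gratings, pred_set, 0))
}

#' Snakes-to-gratings response ratio per model
#'
#' Predicts the response of each model to every stimulus in the target
#' battery, averages predictions within class, and reports the ratio
#' mean(snakes) / mean(gratings). When `params` is `NULL`, each model uses
#' g = 1, alpha = 1, and a mid-range sigma from [suggest_sigma()] so the
#' ratio reflects the pooling functional alone.
#'
#' @param models character vector of model names
#' @param battery [make_target_battery()] output
#' @param params optional named list of [model_spec()] overriding the default
#' @return list of `ratio_report` objects (one per model): `model`, `ratio`,
#'   `per_class_means`, `pred_snakes`, `pred_gratings`, `params`
#' @export
run_ratio_experiment <- function(models = c("ce", "dn", "otn", "noa"),
                                 battery, params = NULL) {
  if (length(models) == 0L)
    vn_stop("empty model list", "visnorm_domain_error")
  all_maps <- c(do.call(c, battery$emaps_snakes),
                do.call(c, battery$emaps_gratings))
  out <- lapply(models, function(m) {
    spec <- params[[m]] %||%
      model_spec(m, g = 1, alpha = 1, sigma = suggest_sigma(m, all_maps))
    pr <- battery_predictions(spec, battery)
    means <- c(snakes = mean(pr$snakes), gratings = mean(pr$gratings))
    structure(list(model = m, ratio = means[["snakes"]] / means[["gratings"]],
                   per_class_means = means, pred_snakes = pr$snakes,
                   pred_gratings = pr$gratings, params = spec),
              class = "ratio_report")
  })
  names(out) <- models
  out
}

#' @export
print.ratio_report <- function(x, ...) {
  cat(sprintf("<ratio_report> %s: mean(snakes)/mean(gratings) = %.3f\n",
              x$model, x$ratio))
  invisible(x)
}

#' Snake-minus-grating prediction gap along the contrast ladder
#'
#' For each model, the difference between the predicted snake and grating
#' responses at every contrast level of the battery. Models with
#' orientation-dependent normalization predict a gap that grows with
#' contrast; untuned models predict a nearly constant (near-zero) gap on
#' energy-matched stimuli.
#'
#' @inheritParams run_ratio_experiment
#' @return data frame with columns `model`, `contrast`, `pred_snake`,
#'   `pred_grating`, `gap`
#' @export
contrast_gap_experiment <- function(models = c("ce", "dn", "otn", "noa"),
                                    battery, params = NULL) {
  reports <- run_ratio_experiment(models, battery, params)
  do.call(rbind, lapply(reports, function(rep) {
    data.frame(model = rep$model, contrast = battery$contrasts,
               pred_snake = rep$pred_snakes,
               pred_grating = rep$pred_gratings,
               gap = rep$pred_snakes - rep$pred_gratings)
  }))
}

#' Center-surround suppression simulation
#'
#' Builds composite static 3 cycles/deg grating stimuli: a center disc at
#' `center_dir` surrounded by an annulus at each of `surround_dirs` (hard
#' edges), plus a center-only baseline, and reads out a single model unit
#' preferring `preferred_dir` at the image center. The unit's feedforward
#' drive is its classical receptive field's response to the center stimulus
#' alone (the surround lies outside the RF and does not drive the unit); the
#' normalization pool is computed on the composite stimulus. For OTN the
#' readout is d = E_center(x0, theta_pref) / (sigma + Z_composite(x0,
#' theta_pref)) with the tuned pool; for NOA it is E_center(x0, theta_pref)^2
#' / (sigma^2 + V_composite) with V the anisotropy of the full-image oriented
#' energy. Responses are reported relative to the center-only baseline (the
#' fixed drive cancels), so the minimum of the curve marks the surround
#' direction of greatest suppression.
#'
#' @param model_name `"otn"` or `"noa"`
#' @param center_dir center grating orientation (deg)
#' @param surround_dirs surround orientations to probe (deg)
#' @param preferred_dir preferred orientation of the read-out unit (deg);
#'   must be one of the bank's channels
#' @param sigma semisaturation constant; mid-range
#'   ([suggest_sigma()] on the composite stimuli) if `NULL`
#' @param geometry list: `center_radius_deg`, `surround_inner_deg`,
#'   `surround_outer_deg`, `size_deg`, `ppd`, `sf_cpd`, `contrast`
#' @param bank optional [build_filterbank()]
#' @return object of class `suppression_curve`: `surround_dirs`, `response`
#'   (relative to baseline), `baseline`, `center_dir`, `preferred_dir`,
#'   `model`, `sigma`, `argmin_dir`
#' @export
simulate_center_surround <- function(model_name = c("otn", "noa"),
                                     center_dir = 0,
                                     surround_dirs = seq(0, 157.5, by = 22.5),
                                     preferred_dir = 0, sigma = NULL,
                                     geometry = list(), bank = NULL) {
  model_name <- match.arg(model_name)
  geo <- modifyList(list(center_radius_deg = 1, surround_inner_deg = 1,
                         surround_outer_deg = 3, size_deg = 8, ppd = 12,
                         sf_cpd = 3, contrast = 1,
                         surround_contrast = NULL), geometry)
  if (is.null(geo$surround_contrast)) geo$surround_contrast <- geo$contrast
  if (is.null(bank)) bank <- build_filterbank(geo$ppd)
  n <- round(geo$size_deg * geo$ppd)
  xs <- deg_grid(n, geo$ppd)
  r <- sqrt(outer(xs^2, xs^2, "+"))
  disc <- r <= geo$center_radius_deg
  annulus <- r > geo$surround_inner_deg & r <= geo$surround_outer_deg
  patt <- function(dir, contrast) {
    (contrast / 2) * cos(2 * pi * geo$sf_cpd *
                           contour_coord(n, geo$ppd, dir))
  }
  composite <- function(sdir) {
    px <- patt(center_dir, geo$contrast) * disc
    if (!is.na(sdir)) px <- px + patt(sdir, geo$surround_contrast) * annulus
    compute_energy(stim_image(px, geo$ppd, geo$size_deg), bank)
  }
  maps <- lapply(c(NA, surround_dirs), composite) # first = baseline
  if (is.null(sigma)) sigma <- suggest_sigma(model_name, maps)
  pref_idx <- which.min(abs(bank$orientations - preferred_dir %% 180))
  d <- dim(maps[[1]]$values)
  cy <- floor(d[1] / 2) + 1L; cx <- floor(d[2] / 2) + 1L
  drive <- maps[[1]]$values[cy, cx, pref_idx] # RF drive: center alone
  readout <- function(E) {
    if (model_name == "otn") {
      kern <- norm_kernel(E, tuned = TRUE)
      Z <- norm_pool(E, kern)
      drive / pmax(sigma + Z[cy, cx, pref_idx], EPS_DENOM)
    } else {
      e <- oriented_energy(E)
      V <- sum((e - mean(e))^2)
      drive^2 / pmax(sigma^2 + V, EPS_DENOM)
    }
  }
  resp <- vapply(maps, readout, 0)
  baseline <- resp[1]
  rel <- resp[-1] / baseline
  structure(list(surround_dirs = surround_dirs, response = rel,
                 baseline = baseline, center_dir = center_dir,
                 preferred_dir = preferred_dir, model = model_name,
                 sigma = sigma,
                 argmin_dir = surround_dirs[which.min(rel)]),
            class = "suppression_curve")
}

#' @export
print.suppression_curve <- function(x, ...) {
  cat(sprintf(
    "<suppression_curve> %s, center %g deg, preferred %g deg: greatest suppression at surround %g deg\n",
    x$model, x$center_dir, x$preferred_dir, x$argmin_dir))
  invisible(x)
}

#' Load ROI-averaged beta weights from a Kay-format MAT file
#'
#' Reads the stored 3-D `betas` array (voxels x stimuli x bootstraps) with
#' the `roi`/`roilabels` grouping variables, averages across voxels within
#' each requested ROI separately for every bootstrap (noise is correlated
#' across voxels but not across scans), then summarizes across bootstraps:
#' the mean and the standard deviation of the per-bootstrap voxel means.
#' MAT reading is delegated to a bundled Python converter (scipy.io/h5py for
#' legacy and v7.3 containers).
#'
#' @param path MAT file path
#' @param dialect only `"kay_mat"` is supported
#' @param rois ROI labels to keep
#' @param stim_idx optional stimulus subset (indices into the stimulus axis)
#' @param python python executable
#' @return object of class `roi_response_table`: `roi_names`, `stim_ids`,
#'   `mean_beta` (stimuli x ROIs), `sd_beta` (stimuli x ROIs)
#' @export
load_roi_betas <- function(path, dialect = "kay_mat",
                           rois = c("V1", "V2", "V3"), stim_idx = NULL,
                           python = Sys.which("python")) {
  dialect <- match.arg(dialect, "kay_mat")
  if (!file.exists(path))
    vn_stop(sprintf("file not found: %s", path), "visnorm_format_error")
  if (!nzchar(python)) python <- Sys.which("python3")
  if (!nzchar(python))
    vn_stop("no python executable found for MAT conversion",
            "visnorm_format_error")
  script <- system.file("python", "mat_to_json.py", package = "visnorm")
  out_json <- tempfile(fileext = ".json")
  status <- system2(python, c(script, shQuote(path), shQuote(out_json)),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(out_json))
    vn_stop(paste0("MAT conversion failed: ",
                   paste(status, collapse = "\n")),
            "visnorm_format_error")
  raw <- jsonlite::read_json(out_json, simplifyVector = TRUE)
  unlink(out_json)
  for (f in c("betas", "roi", "roilabels"))
    if (is.null(raw[[f]]))
      vn_stop(sprintf("field '%s' missing from MAT file", f),
              "visnorm_format_error")
  betas <- raw$betas # voxels x stimuli x bootstraps
  if (length(dim(betas)) != 3L)
    vn_stop("field 'betas' does not have rank 3 (voxels x stimuli x bootstraps)",
            "visnorm_format_error")
  roi_of_voxel <- as.integer(raw$roi)
  labels <- as.character(raw$roilabels)
  if (is.null(stim_idx)) stim_idx <- seq_len(dim(betas)[2])
  mean_beta <- matrix(NA_real_, length(stim_idx), length(rois),
                      dimnames = list(NULL, rois))
  sd_beta <- mean_beta
  for (j in seq_along(rois)) {
    lab <- match(rois[j], labels)
    vox <- which(roi_of_voxel == lab)
    if (is.na(lab) || length(vox) == 0L)
      vn_stop(sprintf("ROI '%s' selects no voxels", rois[j]),
              "visnorm_format_error")
    # voxel mean per (stimulus, bootstrap), then summarize over bootstraps
    per_boot <- apply(betas[vox, stim_idx, , drop = FALSE], c(2, 3), mean)
    mean_beta[, j] <- rowMeans(per_boot)
    sd_beta[, j] <- apply(per_boot, 1, sd)
  }
  structure(list(roi_names = rois, stim_ids = stim_idx,
                 mean_beta = mean_beta, sd_beta = sd_beta),
            class = "roi_response_table")
}

#' @export
print.roi_response_table <- function(x, ...) {
  cat(sprintf("<roi_response_table> %d stimuli x %d ROIs (%s)\n",
              nrow(x$mean_beta), length(x$roi_names),
              paste(x$roi_names, collapse = ", ")))
  invisible(x)
}

#' Synthetic BOLD responses from a known model
#'
#' Ground-truth responses for parameter-recovery tests: the model's
#' predictions for each stimulus plus seeded additive Gaussian noise.
#'
#' @param model [model_spec()] (the generating truth)
#' @param sets list of [stim_set()] (or `emaps`, a list of lists of energy
#'   maps, to skip filtering)
#' @param bank [build_filterbank()] (ignored when `emaps` given)
#' @param noise_sd SD of the additive Gaussian noise (percent signal change)
#' @param seed integer seed
#' @param emaps optional precomputed energy maps
#' @param roi name recorded for the synthetic ROI
#' @return `roi_response_table` with one column
#' @export
synth_bold <- function(model, sets = NULL, bank = NULL, noise_sd = 0,
                       seed = 1L, emaps = NULL, roi = "synthetic") {
  stopifnot(inherits(model, "vn_model"))
  if (is.null(emaps)) {
    stopifnot(!is.null(sets), !is.null(bank))
    emaps <- lapply(sets, function(s)
      lapply(s$exemplars, compute_energy, bank = bank))
  }
  preds <- vapply(emaps, function(maps)
    predict_stimulus(model, emaps = maps), 0)
  noise <- with_seed(seed, rnorm(length(preds), 0, noise_sd))
  mb <- matrix(preds + noise, ncol = 1, dimnames = list(NULL, roi))
  structure(list(roi_names = roi, stim_ids = seq_along(preds),
                 mean_beta = mb,
                 sd_beta = matrix(noise_sd, length(preds), 1,
                                  dimnames = list(NULL, roi))),
            class = "roi_response_table")
}

#' Cross-validated model comparison on one response vector
#'
#' Runs [loo_cv()] for each requested model on shared energy maps and
#' returns the cross-validated variance explained per model.
#'
#' @param emaps list (per stimulus) of lists of energy maps
#' @param responses observed responses, one per stimulus
#' @param models model names to compare
#' @param n_starts,seed passed to [loo_cv()]
#' @param nbin context compression level
#' @return data frame with `model`, `r2`, plus the fitted full-data params
#' @export
model_comparison <- function(emaps, responses,
                             models = c("ce", "dn", "otn", "noa"),
                             n_starts = 40L, seed = 1L, nbin = 512L) {
  rows <- lapply(models, function(m) {
    ctx <- pooling_context(m, emaps = emaps, nbin = nbin)
    cv <- loo_cv(ctx, responses, n_starts = n_starts, seed = seed)
    full <- fit_model(ctx, responses, n_starts = n_starts, seed = seed)
    data.frame(model = m, r2 = cv$r2, g = full$params$g,
               alpha = full$params$alpha, sigma = full$params$sigma)
  })
  do.call(rbind, rows)
}
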