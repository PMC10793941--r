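test_that("the target battery equates contrast energy between classes", {
  bat <- target_battery()
  expect_equal(bat$energy_match$ratio_after, rep(1, 5), tolerance = 1e-6)
  expect_true(all(bat$energy_match$ratio_before > 0))
})

test_that("identical stimuli fed as both classes give a ratio of exactly 1", {
  bat <- target_battery()
  fake <- bat
  fake$emaps_gratings <- fake$emaps_snakes
  rep <- run_ratio_experiment("ce", fake)
  expect_identical(rep$ce$ratio, 1)
})

test_that("orientation-sensitive models separate snakes from gratings", {
  bat <- target_battery()
  reports <- run_ratio_experiment(c("ce", "dn", "otn", "noa"), bat)
  ratios <- vapply(reports, `[[`, 0, "ratio")
  expect_equal(ratios[["ce"]], 1, tolerance = 1e-6)
  expect_gt(ratios[["otn"]], ratios[["dn"]])
  expect_gt(ratios[["noa"]], ratios[["dn"]])
  expect_error(run_ratio_experiment(character(0), bat),
               class = "visnorm_domain_error")
})

test_that("tuned/untuned ratio separation is stable across stimulus seeds", {
  for (seed in 1:5) {
    bat <- make_target_battery(contrasts = c(0.25, 1), n_exemplars = 1,
                               size_deg = 6, ppd = 12, seed = seed,
                               bank = bank12())
    reports <- run_ratio_experiment(c("dn", "otn", "noa"), bat)
    expect_gt(reports$otn$ratio, reports$dn$ratio,
              label = sprintf("otn > dn separation, seed %d", seed))
    expect_gt(reports$noa$ratio, reports$dn$ratio,
              label = sprintf("noa > dn separation, seed %d", seed))
  }
})

test_that("the contrast gap table mirrors the ratio experiment predictions", {
  bat <- target_battery()
  gaps <- contrast_gap_experiment(c("ce", "noa"), bat)
  expect_identical(nrow(gaps), 2L * length(bat$contrasts))
  expect_equal(gaps$gap, gaps$pred_snake - gaps$pred_grating,
               tolerance = 1e-12)
})

test_that("surround suppression localizes correctly for one off-preferred center", {
  sc_otn <- simulate_center_surround("otn", center_dir = 45,
                                     preferred_dir = 0, bank = bank12())
  sc_noa <- simulate_center_surround("noa", center_dir = 45,
                                     preferred_dir = 0, bank = bank12())
  expect_identical(sc_otn$argmin_dir, 0)   # matched to the unit's preference
  expect_identical(sc_noa$argmin_dir, 45)  # matched to the center stimulus
  expect_length(sc_otn$response, 8L)
  expect_gt(sc_otn$baseline, 0)
})

test_that("a zero-contrast surround reproduces the center-only baseline", {
  sc <- simulate_center_surround(
    "otn", center_dir = 0, surround_dirs = c(0, 90), preferred_dir = 0,
    bank = bank12(), geometry = list(surround_contrast = 0))
  expect_equal(unname(sc$response), c(1, 1), tolerance = 1e-9)
})

test_that("synthetic BOLD is exact at zero noise and seed-reproducible", {
  bat <- target_battery()
  emaps <- bat$emaps_snakes[1:3]
  m <- model_spec("ce", g = 1, alpha = 0.5)
  tab0 <- synth_bold(m, emaps = emaps, noise_sd = 0, seed = 4)
  preds <- vapply(emaps, function(maps) predict_stimulus(m, emaps = maps), 0)
  expect_identical(unname(tab0$mean_beta[, 1]), preds)
  t1 <- synth_bold(m, emaps = emaps, noise_sd = 0.3, seed = 9)
  t2 <- synth_bold(m, emaps = emaps, noise_sd = 0.3, seed = 9)
  expect_identical(t1$mean_beta, t2$mean_beta)
})

test_that("synthetic noise is calibrated: SD of many draws matches noise_sd", {
  bat <- target_battery()
  emaps <- bat$emaps_snakes[1]
  m <- model_spec("ce", g = 1, alpha = 0.5)
  draws <- vapply(1:1000, function(k)
    synth_bold(m, emaps = emaps, noise_sd = 0.25, seed = k)$mean_beta[1, 1],
    0)
  expect_lt(abs(sd(draws) / 0.25 - 1), 0.05)
})

test_that("Kay-format betas average voxels within ROI per bootstrap", {
  python <- Sys.which("python")
  if (!nzchar(python)) python <- Sys.which("python3")
  expect_true(nzchar(python)) # scientific image always carries python
  dir <- withr::local_tempdir()
  mat <- file.path(dir, "toy_betas.mat")
  # 2 voxels x 3 stimuli x 2 bootstraps with hand-checkable values
  code <- sprintf(paste0(
    "import numpy as np; from scipy.io import savemat; ",
    "b = np.arange(12, dtype=float).reshape(2, 3, 2); ",
    "savemat(%s, {'betas': b, 'roi': np.array([[1, 1]]), ",
    "'roilabels': np.array(['V1'], dtype=object)})"),
    shQuote(mat))
  status <- system2(python, c("-c", shQuote(code)))
  expect_identical(status, 0L)
  tab <- load_roi_betas(mat, rois = "V1")
  # betas[v, s, b] = 6 v + 2 s + b (0-based); voxel mean = 3 + 2 s + b;
  # bootstrap mean = 3.5 + 2 s; bootstrap SD = sd over the two voxel means
  expect_equal(unname(tab$mean_beta[, "V1"]), c(3.5, 5.5, 7.5))
  expect_equal(unname(tab$sd_beta[, "V1"]), rep(sd(c(0, 1)), 3))
  # the SD is across per-bootstrap voxel means, not across voxels
  expect_false(isTRUE(all.equal(unname(tab$sd_beta[1, "V1"]), sd(c(0.5, 6.5)))))
  # stimulus subsetting and error paths
  sub <- load_roi_betas(mat, rois = "V1", stim_idx = c(1, 3))
  expect_equal(unname(sub$mean_beta[, "V1"]), c(3.5, 7.5))
  expect_error(load_roi_betas(mat, rois = "V9"),
               class = "visnorm_format_error")
  expect_error(load_roi_betas(file.path(dir, "absent.mat")),
               class = "visnorm_format_error")
})
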