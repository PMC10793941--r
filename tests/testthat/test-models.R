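test_that("contrast-energy pooling is the mean over space and orientation", {
  v <- array(c(1, 2, 3, 4, 5, 6, 7, 8), c(2, 2, 2))
  E <- toy_emap(v, orientations = c(0, 90))
  expect_identical(pool_ce(E), mean(1:8)) # hand-computed toy mean
  expect_identical(pool_ce(E), 4.5)
  E$values <- E$values * 3 # linearity
  expect_identical(pool_ce(E), 13.5)
  expect_identical(pool_ce(toy_emap(array(0, c(2, 2, 8)))), 0)
})

test_that("the untuned pool of a uniform field is 8c away from the borders", {
  c0 <- 0.7
  E <- toy_emap(array(c0, c(41, 41, 8)))
  kern <- norm_kernel(E, tuned = FALSE)
  Z <- norm_pool(E, kern)
  mid <- 21
  expect_equal(Z[mid, mid, 1], 8 * c0, tolerance = 1e-9)
  d <- E$values[mid, mid, 1] / (2 + Z[mid, mid, 1])
  expect_equal(d, c0 / (2 + 8 * c0), tolerance = 1e-9)
})

test_that("the convolution-based pool matches a direct weighted sum", {
  set.seed(7)
  E <- toy_emap(array(runif(16 * 16 * 8), c(16, 16, 8)))
  kern <- norm_kernel(E, tuned = FALSE)
  Z <- norm_pool(E, kern)
  total <- apply(E$values, c(1, 2), sum)
  Z_direct <- conv2_direct(total, kern$G)
  expect_lt(max(abs(Z[, , 1] - Z_direct)), 1e-8)
  expect_lt(max(abs(Z[, , 5] - Z_direct)), 1e-8) # same pool in every channel
})

test_that("large sigma reduces every normalization model to contrast energy", {
  E <- snake_emap()
  s_ce <- pool_ce(E)
  expect_lt(abs(pool_dn(E, 1e9) * 1e9 / s_ce - 1), 1e-3)
  expect_lt(abs(pool_otn(E, 1e9) * 1e9 / s_ce - 1), 1e-3)
  e <- oriented_energy(E)
  expect_lt(abs(pool_noa(e, 1e9) * 1e18 / mean(e^2) - 1), 1e-3)
  expect_lt(abs(pool_noa(e, 1e9, variant = "sqrt") * 1e9 / mean(e) - 1),
            1e-3)
})

test_that("a tuned pool with an untuned kernel reproduces the untuned model", {
  E <- snake_emap()
  kern <- norm_kernel(E, tuned = FALSE)
  for (sigma in c(0.5, 20)) {
    expect_identical(pool_otn(E, sigma, kern), pool_dn(E, sigma, kern))
  }
})

test_that("the cross-orientation term vanishes for single-channel energy", {
  set.seed(11)
  v <- array(0, c(20, 20, 8))
  v[, , 3] <- matrix(runif(400), 20, 20)
  E <- toy_emap(v)
  kern <- norm_kernel(E, tuned = TRUE)
  Z <- norm_pool(E, kern)
  expect_equal(Z[, , 3], conv2_same(v[, , 3], kern$G), tolerance = 1e-12)
})

test_that("anisotropy pooling matches its closed form", {
  # isotropic energy: V = 0, s = c^2 / sigma^2
  expect_equal(pool_noa(rep(2, 8), 0.5), 4 / 0.25, tolerance = 1e-12)
  # grating-like vs snake-like vectors at sigma = 1 (direct evaluation)
  e_grating <- c(8, 1, 0, 0, 0, 0, 0, 0)
  e_snake <- rep(1.5, 8)
  expect_equal(pool_noa(e_grating, 1), 8.125 / 55.875, tolerance = 1e-12)
  expect_equal(pool_noa(e_snake, 1), 2.25, tolerance = 1e-12)
  expect_lt(pool_noa(e_grating, 1), pool_noa(e_snake, 1))
})

test_that("the power-law output stage follows r = g * s^alpha", {
  expect_identical(respond(1, g = 3.2, alpha = 0.7), 3.2)
  expect_identical(respond(c(0, 2, 5), g = 2, alpha = 1), c(0, 4, 10))
  expect_identical(respond(4, g = 2, alpha = 0.5), 4)
})

test_that("model specs validate their parameters", {
  expect_error(model_spec("otn"), class = "visnorm_domain_error")
  expect_identical(model_spec("ce", g = 2, alpha = 0.5)$name, "ce")
  expect_identical(model_registry()$n_params, c(2L, 3L, 3L, 3L))
})

test_that("stimulus predictions average across exemplars, order-invariantly", {
  bat <- target_battery()
  maps <- bat$emaps_snakes[[3]]
  m <- model_spec("noa", g = 1.5, alpha = 0.6, sigma = 2)
  singles <- vapply(maps, function(E) predict_stimulus(m, emaps = list(E)), 0)
  expect_equal(predict_stimulus(m, emaps = maps), mean(singles),
               tolerance = 1e-12)
  expect_equal(predict_stimulus(m, emaps = rev(maps)),
               predict_stimulus(m, emaps = maps), tolerance = 1e-12)
  # identical exemplars: prediction equals the single-exemplar prediction
  expect_equal(predict_stimulus(m, emaps = maps[c(1, 1, 1)]),
               singles[1], tolerance = 1e-12)
})

test_that("responses are non-decreasing in contrast for every model", {
  bat <- target_battery()
  all_maps <- c(do.call(c, bat$emaps_snakes), do.call(c, bat$emaps_gratings))
  for (name in c("ce", "dn", "otn", "noa")) {
    m <- model_spec(name, g = 1, alpha = 0.7,
                    sigma = suggest_sigma(name, all_maps))
    for (cls in c("emaps_snakes", "emaps_gratings")) {
      preds <- vapply(bat[[cls]], function(maps)
        predict_stimulus(m, emaps = maps), 0)
      expect_true(all(diff(preds) > -1e-12),
                  label = paste(name, cls, "monotone in contrast"))
    }
  }
})
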