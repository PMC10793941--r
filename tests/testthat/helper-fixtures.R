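# Shared fixtures, built once per test run and cached across files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- expr
  .fixtures[[name]]
}

bank12 <- function() fixture("bank12", build_filterbank(12))

# energy-matched snakes/gratings contrast battery (the frozen experiment
# geometry: 8 deg canvas at the 12 px/deg analysis resolution)
target_battery <- function() {
  fixture("target_battery",
          make_target_battery(n_exemplars = 3, size_deg = 8, ppd = 12,
                              seed = 1, bank = bank12()))
}

# the 30-stimulus recovery battery and its energy maps
recovery_emaps <- function() {
  fixture("recovery_emaps", {
    sets <- recovery_battery(size_deg = 8, ppd = 12, seed = 1)
    lapply(sets, function(s)
      lapply(s$exemplars, compute_energy, bank = bank12()))
  })
}

# a small snake energy map for model-level tests
snake_emap <- function() {
  fixture("snake_emap", {
    s <- synth_snakes(0.9, 1, n_exemplars = 1, size_deg = 4, ppd = 12,
                      seed = 3)
    compute_energy(s$exemplars[[1]], bank12())
  })
}

# direct O(n^2 m^2) spatial-domain convolution oracle with the same
# zero-padding and centering conventions as conv2_same
conv2_direct <- function(a, b) {
  da <- dim(a); db <- dim(b)
  r0 <- floor(db[1] / 2); c0 <- floor(db[2] / 2)
  out <- matrix(0, da[1], da[2])
  for (i in seq_len(da[1])) {
    for (j in seq_len(da[2])) {
      acc <- 0
      for (u in seq_len(db[1])) {
        for (v in seq_len(db[2])) {
          ii <- i + r0 - (u - 1L) # convolution: kernel flipped
          jj <- j + c0 - (v - 1L)
          if (ii >= 1L && ii <= da[1] && jj >= 1L && jj <= da[2])
            acc <- acc + a[ii, jj] * b[u, v]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# hand-made energy map from an explicit array
toy_emap <- function(values, orientations = NULL) {
  n_ori <- dim(values)[3]
  structure(list(values = values, ppd = 12,
                 orientations = orientations %||%
                   (seq_len(n_ori) - 1) * 180 / n_ori),
            class = "energy_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
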