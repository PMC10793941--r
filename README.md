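# visnorm

Image-computable encoding models of fMRI BOLD responses in human early
visual cortex (V1–V3) to band-pass textures. The package exists to answer
one question quantitatively: why are population responses to *snakes*
(curved band-pass contours) roughly twice as large as to *gratings*
(straight parallel contours) of matched contrast energy — and which form of
divisive normalization accounts for it.

It implements four models that share an oriented contrast-energy front end
(128 Gabor filters: 8 orientations × 8 spatial frequencies × 2 quadrature
phases) and a compressive output stage r = g·s^α, and differ only in the
pooling functional Φ that turns the energy image E(x, y, θ) into a scalar
drive s:

| model | pooling | free parameters |
|---|---|---|
| `ce`  | mean of E over space and orientation | g, α |
| `dn`  | mean of E/(σ + Z), Z an untuned Gaussian pool over all orientations | g, α, σ |
| `otn` | as `dn`, but the surround pool is orientation-tuned (cross-orientation suppression acts only at the center pixel) | g, α, σ |
| `noa` | mean(e²)/(σ² + V), where e is the oriented energy and V = Σ(e − ē)² its anisotropy | g, α, σ |

Around the models: a synthesizer for the seven texture families used to
probe them (snakes, gratings, noise bars, waves, plaids, circular patterns,
cross gratings), multi-start least-squares fitting with leave-one-out
cross-validation and a variance-explained metric, and the diagnostic
experiments — the snakes/gratings ratio, the contrast-slope analysis, a
center–surround suppression simulation, a Kay-format ROI-beta loader, and a
synthetic-BOLD generator for parameter recovery. See the methods vignette
(`vignettes/normalization-models.Rmd`) for the model equations, conventions
and design decisions.

## A worked example

Build the energy-matched snakes/gratings battery and ask each model for its
snakes-to-gratings prediction ratio:

```r
library(visnorm)

bank <- build_filterbank(ppd = 12)
bat  <- make_target_battery(n_exemplars = 3, size_deg = 8, ppd = 12,
                            seed = 1, bank = bank)
bat$energy_match$ratio_after
#> [1] 1 1 1 1 1

reports <- run_ratio_experiment(c("ce", "dn", "otn", "noa"), bat)
for (r in reports) print(r)
#> <ratio_report> ce: mean(snakes)/mean(gratings) = 1.000
#> <ratio_report> dn: mean(snakes)/mean(gratings) = 1.040
#> <ratio_report> otn: mean(snakes)/mean(gratings) = 2.512
#> <ratio_report> noa: mean(snakes)/mean(gratings) = 4.033
```

The battery equates total contrast energy between the classes exactly
(`ratio_after` is 1 at every contrast), so the contrast-energy model is
pinned to a ratio of 1 and untuned normalization barely moves it — while
both orientation-sensitive models predict at least double the response to
snakes, the signature effect. The same machinery fits data:

```r
sets  <- recovery_battery(seed = 1)                  # 30 synthetic stimuli
emaps <- lapply(sets, function(s)
  lapply(s$exemplars, compute_energy, bank = bank))
truth <- model_spec("otn", g = 1, alpha = 0.5,
                    sigma = suggest_sigma("otn", unlist(emaps, FALSE)))
betas <- synth_bold(truth, emaps = emaps, noise_sd = 0.02, seed = 7)

ctx <- pooling_context("otn", emaps = emaps)
fit <- fit_model(ctx, betas$mean_beta[, 1], n_starts = 40, seed = 1)
print(fit)
#> <fit_result> otn: g = 0.9874, alpha = 0.4978, sigma = 1.214; SSE 0.01392 (40 starts)
loo_cv(ctx, betas$mean_beta[, 1], n_starts = 40, seed = 1)$r2
#> [1] 0.9446486
```

A thin command-line dispatcher (`inst/cli/visnorm.R`) exposes the same
pipeline as `synth`, `fit` and `report` subcommands driven by a YAML/JSON
config, with exit codes 0 (success), 2 (config error), 3 (data-format
error), 4 (optimization failure).

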