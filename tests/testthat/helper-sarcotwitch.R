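# Shared fixtures. Twitch simulations are cached per test file so the
# reference twitches are computed once and reused.

default_params <- function() model_parameters()
default_ct <- function() calcium_transient()

.tw_cache <- new.env(parent = emptyenv())

cached_twitch <- function(l_sarc, ct = default_ct(), ...) {
  key <- paste(l_sarc, ct$ca_peak, ..., sep = "|")
  if (is.null(.tw_cache[[key]]))
    .tw_cache[[key]] <- simulate_twitch(default_params(), l_sarc, ct, ...)
  .tw_cache[[key]]
}

cached_length_sweep <- function() {
  if (is.null(.tw_cache[["length_sweep"]]))
    .tw_cache[["length_sweep"]] <-
      length_sweep(default_params(), ct = default_ct())
  .tw_cache[["length_sweep"]]
}

cached_calcium_sweep <- function() {
  if (is.null(.tw_cache[["calcium_sweep"]]))
    .tw_cache[["calcium_sweep"]] <-
      calcium_sweep(default_params(), ct = default_ct())
  .tw_cache[["calcium_sweep"]]
}

# relative error helper
rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# Fitting fixtures: the ground truth, the synthetic 7-length fixtures and
# the two recovery fits, cached for the whole run (they back both the
# fitting unit tests and the acceptance suite).
fit_truth <- c(a = 1.39, b = 7.76, c_f = 0.283, c_s = 0.127)

cached_noise_free_traces <- function() {
  if (is.null(.tw_cache[["traces0"]]))
    .tw_cache[["traces0"]] <-
      generate_synthetic_traces(default_params(),
                                seq(1.90, 2.20, by = 0.05),
                                default_ct(), noise_sd = 0, seed = 42,
                                t_end = 0.9, n_x = 61L)
  .tw_cache[["traces0"]]
}

cached_fit_noise_free <- function() {
  if (is.null(.tw_cache[["fit0"]]))
    .tw_cache[["fit0"]] <- suppressWarnings(
      fit_parameters(cached_noise_free_traces(), default_ct(),
                     init = fit_truth * c(1.2, 0.8, 1.2, 0.8)))
  .tw_cache[["fit0"]]
}

noisy_sd <- 0.02 * 93   # 2% of the peak tension at l_sarc 2.2 um

cached_noisy_traces <- function() {
  if (is.null(.tw_cache[["traces2"]]))
    .tw_cache[["traces2"]] <-
      generate_synthetic_traces(default_params(),
                                seq(1.90, 2.20, by = 0.05),
                                default_ct(), noise_sd = noisy_sd,
                                seed = 1234, t_end = 0.9, n_x = 61L)
  .tw_cache[["traces2"]]
}

cached_fit_noisy <- function() {
  if (is.null(.tw_cache[["fit2"]]))
    .tw_cache[["fit2"]] <- suppressWarnings(
      fit_parameters(cached_noisy_traces(), default_ct(),
                     init = fit_truth * c(0.85, 1.15, 0.85, 1.15)))
  .tw_cache[["fit2"]]
}

fit_estimates <- function(fit)
  c(a = fit$a, b = fit$b, c_f = fit$c_f, c_s = fit$c_s)
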