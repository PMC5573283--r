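#' Generate a synthetic plasmid-stability dataset
#'
#' Emulates the colony-scoring stability assay: the underlying retention
#' probability `S(g)` comes from an ensemble simulation at the given true
#' parameters, and the observed fraction at each sampled generation is a
#' binomial draw — `colonies_scored` colonies are scored for marker
#' retention, so the measurement noise is `Binomial(colonies, S(g)) /
#' colonies`. Setting `colonies_scored` very large gives effectively
#' noise-free curves.
#'
#' @param alpha,delta,beta,n0 True model parameters (see [sim_params()]).
#' @param generations Generations at which the assay samples the culture
#'   (default every 20th generation up to 200).
#' @param colonies_scored Colonies scored per timepoint (default 100).
#' @param replicates Ensemble size for the underlying `S(g)` (default 50).
#' @param seed RNG seed; the generator is a pure function of its arguments.
#' @param label Curve label.
#' @return A [stability_curve()].
#' @examples
#' gen_stability_dataset(alpha = 0.8, n0 = 20, seed = 1)
#' @export
gen_stability_dataset <- function(alpha = 0, delta = 0.5, beta = 1, n0 = 20,
                                  generations = seq(0, 200, by = 20),
                                  colonies_scored = 100L, replicates = 50L,
                                  seed = 0L, label = "synthetic") {
  stopifnot(colonies_scored >= 1)
  generations <- sort(unique(as.integer(generations)))
  params <- sim_params(alpha = alpha, delta = delta, beta = beta,
                       generations = max(generations), replicates = replicates,
                       seed = seed)
  ens <- simulate_ensemble(init_poisson(n0), params)
  s_true <- ens$S[match(generations, ens$generation)]
  # separate seed stream for the measurement noise, derived from `seed`
  set.seed(seed + 1L)
  frac <- stats::rbinom(length(s_true), colonies_scored, s_true) / colonies_scored
  stability_curve(generations, frac, label = label)
}

#' Generate a synthetic densitometry lane profile
#'
#' Evaluates a [multimer_peak_model()] on a uniform position grid spanning
#' all modeled ranks with a one-monomer margin on each side, and adds
#' Gaussian noise scaled to the maximum model intensity (clipped at zero,
#' as a scanner reports no negative intensity).
#'
#' @param model A `multimer_peak_model`.
#' @param noise_sd Noise standard deviation as a fraction of the maximum
#'   intensity (default 0, noise-free).
#' @param n_samples Number of grid points (>= 50, default 500).
#' @param seed RNG seed.
#' @return A tibble with columns `position`, `intensity`.
#' @export
gen_densitometry_profile <- function(model, noise_sd = 0, n_samples = 500L,
                                     seed = 0L) {
  stopifnot(n_samples >= 50L, noise_sd >= 0)
  x <- seq(0.1 * model$x0, (model$k_max + 1) * model$x0,
           length.out = n_samples)
  y <- peak_model_intensity(x, model)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- pmax(y + stats::rnorm(length(y), sd = noise_sd * max(y)), 0)
  }
  tibble::tibble(position = x, intensity = y)
}
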