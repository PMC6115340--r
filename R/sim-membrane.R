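#' Simulate two-channel membrane line profiles with interdigitating domains
#'
#' Emulates intensity traces sampled along a smooth-muscle cell membrane that
#' alternates between two domain types (caveolae domains interdigitating with
#' dense bands). Each profile is partitioned into segments with geometric
#' lengths (mean `domain_length_mean`, so profiles are aperiodic); channel 1
#' is high (`baseline + amplitude`) in odd segments and at background level
#' in even ones. Channel 2 is the mixture \code{overlap * pattern1 + (1 - overlap) * (1 - pattern1)}
#' scaled by `amplitude`: `overlap = 1` makes the channels coincide,
#' `overlap = 0` makes them perfectly anti-phase. Both channels sit on a
#' constant background intensity `baseline` (real fluorescence never reaches
#' zero), and Gaussian noise with sd `noise_sd` is added and truncated at 0
#' (intensities are nonnegative).
#'
#' @param n_profiles Number of profiles.
#' @param points_per_profile Samples per profile (at least twice
#'   `domain_length_mean`).
#' @param domain_length_mean Mean segment length in points.
#' @param overlap Channel-overlap parameter in `[0, 1]`.
#' @param amplitude High-state intensity above background.
#' @param baseline Background intensity added to both channels (default
#'   `amplitude / 10`).
#' @param noise_sd Noise standard deviation (0 for noise-free traces).
#' @param seed Integer seed.
#' @return A list with `profiles` (tibble: `profile_id`, `position`,
#'   `channel1`, `channel2`) and `truth` (a [new_sim_truth()] recording
#'   `overlap` and the generator settings).
#' @examples
#' sim <- simulate_membrane_profiles(n_profiles = 2, overlap = 0, noise_sd = 0,
#'                                   seed = 1)
#' head(sim$profiles)
#' @export
simulate_membrane_profiles <- function(n_profiles = 12,
                                       points_per_profile = 200,
                                       domain_length_mean = 15,
                                       overlap = 0.5,
                                       amplitude = 100,
                                       baseline = amplitude / 10,
                                       noise_sd = 10,
                                       seed = 1L) {
  stopifnot(n_profiles >= 1, points_per_profile >= 2, domain_length_mean > 0)
  if (overlap < 0 || overlap > 1) abort("`overlap` must lie in [0, 1].")
  if (noise_sd < 0) abort("`noise_sd` must be nonnegative.")
  if (baseline < 0) abort("`baseline` must be nonnegative.")
  if (points_per_profile < 2 * domain_length_mean) {
    abort("`points_per_profile` must be at least 2 * `domain_length_mean`.")
  }

  set.seed(seed)
  profiles <- purrr::map(seq_len(n_profiles), function(i) {
    # alternating domains with geometric lengths (support >= 1)
    pattern <- integer(0)
    state <- 1L
    while (length(pattern) < points_per_profile) {
      len <- rgeom(1, prob = 1 / domain_length_mean) + 1L
      pattern <- c(pattern, rep(state, len))
      state <- 1L - state
    }
    pattern <- pattern[seq_len(points_per_profile)]
    ch1 <- baseline + amplitude * pattern
    ch2 <- baseline + amplitude * (overlap * pattern + (1 - overlap) * (1 - pattern))
    if (noise_sd > 0) {
      ch1 <- pmax(ch1 + rnorm(points_per_profile, sd = noise_sd), 0)
      ch2 <- pmax(ch2 + rnorm(points_per_profile, sd = noise_sd), 0)
    }
    tibble(
      profile_id = sprintf("profile_%02d", i),
      position = seq_len(points_per_profile),
      channel1 = ch1,
      channel2 = ch2
    )
  }) %>% bind_rows()

  truth <- new_sim_truth(
    kind = "membrane_profiles",
    overlap_parameter = overlap,
    amplitude = amplitude,
    baseline = baseline,
    noise_sd = noise_sd,
    domain_length_mean = domain_length_mean,
    seed = seed
  )
  list(profiles = profiles, truth = truth)
}
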