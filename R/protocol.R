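#' Respiratory-rate recovery study on synthetic scenes
#'
#' Runs the full RR pipeline on a set of freshly generated breathing scenes
#' with constant commanded rates drawn uniformly from `rr_range`, and scores
#' each run against the commanded truth. This is the package's standard
#' simulation protocol for validating rate recovery in a species regime:
#' `n_scenes` scenes, each re-rendered with `seeds_per_scene` independent
#' noise/texture seeds. Scene geometry defaults to a 4x-downscaled version
#' of a 640 x 480 px @ 60 fps acquisition.
#'
#' @param species `"rat"` or `"mouse"` (sets the passband).
#' @param rr_range range (breaths/min) the commanded rates are drawn from.
#' @param n_scenes,seeds_per_scene study size.
#' @param width,height,fps,duration_s scene geometry.
#' @param noise_sigma_c sensor noise sd, degrees C.
#' @param amplitude_px chest displacement amplitude.
#' @param seed master seed; all scene rates and render seeds derive from it.
#' @return A data frame with one row per run: `scene`, `rep`, `rr_true`,
#'   `eps_pct`, `rmse_bpm`, `p90_pct`, `bias_bpm`, `n_windows`.
#' @export
rr_recovery_study <- function(species = "rat", rr_range = c(44, 62),
                              n_scenes = 5, seeds_per_scene = 4,
                              width = 160, height = 120, fps = 30,
                              duration_s = 120, noise_sigma_c = 0.3,
                              amplitude_px = 1.5, seed = 1) {
  set.seed(seed)
  rr_true <- runif(n_scenes, rr_range[1], rr_range[2])
  render_seeds <- matrix(sample.int(.Machine$integer.max - 1, n_scenes * seeds_per_scene),
                         n_scenes, seeds_per_scene)
  config <- run_config(species)
  rows <- list()
  for (i in seq_len(n_scenes)) {
    for (j in seq_len(seeds_per_scene)) {
      sc <- make_breathing_video(breath_scene_config(
        width = width, height = height, fps = fps, duration_s = duration_s,
        rr_profile = rr_true[i], noise_sigma_c = noise_sigma_c,
        amplitude_px = amplitude_px, species = species,
        seed = render_seeds[i, j]))
      tr <- rr_trace(sc$video, sc$roi, config)
      ag <- evaluate_against_reference(tr, sc$truth)
      rows[[length(rows) + 1L]] <-
        data.frame(scene = i, rep = j, rr_true = rr_true[i],
                   eps_pct = ag$mean_rel_err_pct, rmse_bpm = ag$rmse_bpm,
                   p90_pct = ag$p90_rel_err_pct,
                   bias_bpm = ag$bland_altman_bias_bpm, n_windows = ag$n_pairs)
      rm(sc, tr)
    }
  }
  do.call(rbind, rows)
}

#' Ramp-following study: correlation against a drifting commanded rate
#'
#' Generates scenes whose commanded rate ramps linearly from `rr_from` to
#' `rr_to` over the scene and reports the Pearson correlation between the
#' median-smoothed estimate and the commanded truth, one row per seed.
#'
#' @param rr_from,rr_to ramp endpoints in breaths/min.
#' @param n_seeds number of independent scenes.
#' @inheritParams rr_recovery_study
#' @return Data frame with `rep`, `pearson_r`, `eps_pct`, `rmse_bpm`.
#' @export
rr_ramp_study <- function(rr_from = 50, rr_to = 60, species = "rat",
                          n_seeds = 10, width = 160, height = 120, fps = 30,
                          duration_s = 120, noise_sigma_c = 0.3,
                          amplitude_px = 1.5, seed = 1) {
  set.seed(seed)
  render_seeds <- sample.int(.Machine$integer.max - 1, n_seeds)
  config <- run_config(species)
  rows <- lapply(seq_len(n_seeds), function(j) {
    sc <- make_breathing_video(breath_scene_config(
      width = width, height = height, fps = fps, duration_s = duration_s,
      rr_profile = function(t) rr_from + (rr_to - rr_from) * t / duration_s,
      noise_sigma_c = noise_sigma_c, amplitude_px = amplitude_px,
      species = species, seed = render_seeds[j]))
    tr <- rr_trace(sc$video, sc$roi, config)
    ag <- evaluate_against_reference(tr, sc$truth)
    data.frame(rep = j, pearson_r = ag$pearson_r, eps_pct = ag$mean_rel_err_pct,
               rmse_bpm = ag$rmse_bpm)
  })
  do.call(rbind, rows)
}
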