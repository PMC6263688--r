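# small scene builders shared across tests (kept well below the acceptance
# problem size so the default suite stays fast)

tiny_breath_scene <- function(rr = 54, duration_s = 20, seed = 1,
                              species = "rat", fps = 30, ...) {
  make_breathing_video(breath_scene_config(
    width = 128, height = 96, fps = fps, duration_s = duration_s,
    rr_profile = rr, species = species, seed = seed, ...))
}

tiny_oft_scene <- function(duration_s = 8, seed = 1, ...) {
  make_oft_video(oft_scene_config(duration_s = duration_s, seed = seed, ...))
}

# synthetic pixel track (no tracker involved) for the activity tests
straight_track <- function(n, fps = 30, x0 = 10, y0 = 10, dx = 0, dy = 0) {
  data.frame(frame = seq_len(n), time_s = (seq_len(n) - 1) / fps,
             x_px = x0 + dx * (seq_len(n) - 1),
             y_px = y0 + dy * (seq_len(n) - 1))
}

unit_calib <- function(w_px = 100, h_px = 100, w_mm = w_px, h_mm = h_px)
  arena_calibration(w_mm, h_mm, rect_roi(0, 0, w_px, h_px))
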