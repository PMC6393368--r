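# Small phantom used throughout the suite: a 160 x 200 px crop at the 4x
# projected pixel size, vessel centered, baseline Fig-like geometry
# (OD 185 um, ID 147 um at 1.3 um/px -> OD ~ 142.3 px).
small_phantom <- function(seed = 1L, blur = 1.5, noise = 3,
                          od = 185, id = 147, tilt = 0, debris = list(),
                          width = 160L, height = 200L, mpp = 1.3) {
  phantom_spec(width_px = width, height_px = height, microns_per_px = mpp,
               outer_diameter_um = od, inner_diameter_um = id,
               centerline_row = (height - 1) / 2, tilt_deg = tilt,
               blur_sigma_px = blur, noise_sigma = noise,
               debris = debris, seed = seed)
}

calib_4x <- function() calibration(microns_per_px = 1.3)

# a quickly measured constant-phantom session shared by session/io tests
quick_session <- function(n_frames = 5L, telemetry = NULL, n_lines = 20L,
                          seed = 1L) {
  sq <- render_sequence(small_phantom(seed = seed),
                        dynamics_spec("constant", n_frames = n_frames, fps = 2))
  run_session(sq$stack, session_config(calib_4x(), n_lines = n_lines),
              telemetry = telemetry)
}
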