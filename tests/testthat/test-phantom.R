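test_that("radial intensity follows the three-level transmural model", {
  sp <- small_phantom()
  expect_equal(radial_intensity(0, sp), sp$intensity_lumen)
  expect_equal(radial_intensity(185 / 2 + 10, sp), sp$intensity_background)
  expect_equal(radial_intensity((147 / 2 + 185 / 2) / 2, sp), sp$intensity_wall)
  # boundaries: lumen < ID/2 <= wall < OD/2 <= background
  expect_equal(radial_intensity(147 / 2, sp), sp$intensity_wall)
  expect_equal(radial_intensity(185 / 2, sp), sp$intensity_background)
  expect_error(radial_intensity(-1, sp), class = "mt_validation_error")
})

test_that("spec invariants are enforced at construction", {
  expect_error(small_phantom(od = 100, id = 120), class = "mt_validation_error")
  expect_error(phantom_spec(intensity_wall = 200, intensity_lumen = 140),
               class = "mt_validation_error")
  # vessel taller than the frame
  expect_error(small_phantom(od = 300, id = 200, height = 200L),
               class = "mt_validation_error")
})

test_that("a noise-free unblurred frame is the sampled step model", {
  sp <- small_phantom(blur = 0, noise = 0)
  img <- render_frame(sp)
  expect_true(all(img %in% c(60L, 140L, 220L)))
  col <- img[, 81]
  # wall band thickness per side ~ (185 - 147) / 2 / 1.3 ~ 14.6 px
  expect_equal(sum(col == 60L) / 2, (185 - 147) / 2 / 1.3, tolerance = 0.1)
  expect_equal(sum(col == 140L), 147 / 1.3, tolerance = 0.02)
  # column profile equals the generative model evaluated per pixel
  prof <- extract_profile(img, 80L)
  d_um <- abs(prof$pos - sp$centerline_row) * sp$microns_per_px
  expect_equal(prof$value, radial_intensity(d_um, sp))
})

test_that("degenerate zero-contrast spec renders a uniform frame", {
  sp <- phantom_spec(width_px = 64L, height_px = 96L,
                     intensity_background = 128L, intensity_wall = 128L,
                     intensity_lumen = 128L, outer_diameter_um = 80,
                     inner_diameter_um = 60, blur_sigma_px = 0,
                     noise_sigma = 0)
  expect_true(all(render_frame(sp) == 128L))
})

test_that("rendering is deterministic for a given seed", {
  sp <- small_phantom(seed = 42L)
  expect_identical(render_frame(sp), render_frame(sp))
  expect_false(identical(render_frame(sp),
                         render_frame(sp, seed = 43L)))
  sq1 <- render_sequence(sp, dynamics_spec("constant", n_frames = 3L))
  sq2 <- render_sequence(sp, dynamics_spec("constant", n_frames = 3L))
  expect_identical(sq1$stack$frames, sq2$stack$frames)
})

test_that("constant dynamics give constant ground truth", {
  sq <- render_sequence(small_phantom(),
                        dynamics_spec("constant", n_frames = 5L, fps = 2))
  expect_equal(nrow(sq$truth), 5L)
  expect_true(all(sq$truth$od_um == 185))
  expect_true(all(sq$truth$id_um == 147))
  expect_equal(sq$truth$time_s, (0:4) / 2)
})

test_that("sinusoid dynamics follow OD(t) = OD0 + A sin(2 pi t / T)", {
  A <- 10; Tp <- 60
  dyn <- dynamics_spec("sinusoid", n_frames = 240L, fps = 2,
                       sinusoid_amplitude_um = A, sinusoid_period_s = Tp)
  sq <- render_sequence(small_phantom(), dyn)
  expect_equal(sq$truth$od_um,
               185 + A * sin(2 * pi * sq$truth$time_s / Tp))
  # ground-truth conservation: extrema = OD0 +/- A
  expect_equal(max(sq$truth$od_um), 185 + A, tolerance = 1e-6)
  expect_equal(min(sq$truth$od_um), 185 - A, tolerance = 1e-6)
  # inner diameter co-varies conserving wall cross-sectional area
  expect_equal(sq$truth$od_um^2 - sq$truth$id_um^2,
               rep(185^2 - 147^2, 240L))
})

test_that("step dynamics switch at the step time", {
  dyn <- dynamics_spec("step", n_frames = 41L, fps = 2, step_time_s = 10,
                       step_od_um = 160, step_id_um = 130)
  sq <- render_sequence(small_phantom(), dyn)
  expect_true(all(sq$truth$od_um[sq$truth$time_s < 10] == 185))
  expect_true(all(sq$truth$od_um[sq$truth$time_s >= 10] == 160))
  expect_true(all(sq$truth$id_um[sq$truth$time_s >= 10] == 130))
})

test_that("dynamics that close the lumen are rejected", {
  expect_error(
    render_sequence(small_phantom(od = 100, id = 60),
                    dynamics_spec("step", n_frames = 5L, step_time_s = 1,
                                  step_od_um = 79)),
    class = "mt_validation_error")
  expect_error(
    render_sequence(small_phantom(),
                    dynamics_spec("sinusoid", n_frames = 5L,
                                  sinusoid_amplitude_um = 80,
                                  sinusoid_period_s = 10)),
    class = "mt_validation_error")
})

test_that("heater-off bath decays exactly as the Euler recurrence predicts", {
  sp <- bath_sim_spec(setpoint_C = 10, ambient_C = 21, start_C = 37,
                      heater_rate_C_per_s = 0, sensor_noise_C = 0,
                      thermal_time_constant_s = 120, dt_s = 1,
                      duration_s = 300)
  sim <- simulate_bath_temperature(sp)
  expect_true(all(diff(sim$temperature_true_C) < 0))
  expect_true(all(sim$temperature_true_C > 21))
  k <- seq_len(nrow(sim)) - 1
  expect_equal(sim$temperature_true_C, 21 + (37 - 21) * (1 - 1 / 120)^k)
})

test_that("setpoint at ambient keeps the heater off and the bath at ambient", {
  sim <- simulate_bath_temperature(
    bath_sim_spec(setpoint_C = 21, ambient_C = 21, sensor_noise_C = 0,
                  duration_s = 120))
  expect_true(all(!sim$heater_on))
  expect_true(all(sim$temperature_C == 21))
})

test_that("bang-bang control holds the bath in a band around the setpoint", {
  sp <- bath_sim_spec(setpoint_C = 37, ambient_C = 21, sensor_noise_C = 0,
                      heater_rate_C_per_s = 0.3,
                      thermal_time_constant_s = 120, dt_s = 1,
                      duration_s = 900)
  sim <- simulate_bath_temperature(sp)
  settled <- sim[sim$time_s > 300, ]
  band <- sp$heater_rate_C_per_s * sp$dt_s +
    (sp$setpoint_C - sp$ambient_C) * sp$dt_s / sp$thermal_time_constant_s
  expect_lt(max(abs(settled$temperature_true_C - 37)), band + 1e-9)
  # heater state is 1 exactly on steps where measured T < setpoint
  expect_identical(sim$heater_on, sim$temperature_C < 37)
})

test_that("saline column height converts to mmHg by the standard constant", {
  expect_equal(hydrostatic_pressure_mmHg(0), 0)
  expect_equal(hydrostatic_pressure_mmHg(10), 7.356, tolerance = 1e-4)
  expect_equal(hydrostatic_pressure_mmHg(135.951), 100)
})
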