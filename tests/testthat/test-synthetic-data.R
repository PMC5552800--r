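test_that("an empty scene has a zero truth mask and background-only channels", {
  spec <- scene_spec(width = 96, height = 96, n_cells = 0,
                     cell_radius_range = c(8, 10),
                     nucleus_radius_range = c(3, 4), rng_seed = 1)
  sc <- generate_scene(spec)
  expect_true(all(sc$truth == 0))
  expect_true(all(sc$nuclei_truth == 0))
  ## fluorescence = illumination field x background + noise
  expect_equal(mean(sc$nuclei_channel[[1]]), 0.08, tolerance = 0.02)
  expect_lt(stats::sd(sc$nuclei_channel[[1]]), 0.05)
})

test_that("placed cell count matches the unique ids in the truth mask", {
  spec <- scene_spec(width = 256, height = 256, n_cells = 10,
                     min_center_distance = 45, rng_seed = 7)
  sc <- generate_scene(spec)
  ids <- sort(unique(sc$truth[sc$truth > 0]))
  expect_identical(ids, 1:10)
  expect_identical(sc$spec$n_placed, 10L)
})

test_that("scenes are bit-reproducible from the spec seed", {
  spec <- scene_spec(width = 128, height = 128, n_cells = 5,
                     min_center_distance = 30, rng_seed = 11)
  expect_identical(generate_scene(spec), generate_scene(spec))
  spec2 <- spec; spec2$rng_seed <- 12L
  expect_false(identical(generate_scene(spec), generate_scene(spec2)))
})

test_that("every cell contains exactly one nucleus with its own id", {
  for (seed in c(3, 14, 77)) {
    spec <- scene_spec(width = 160, height = 160, n_cells = 6,
                       min_center_distance = 38, rng_seed = seed)
    sc <- generate_scene(spec)
    nz <- sc$nuclei_truth > 0
    expect_true(all(sc$nuclei_truth[nz] == sc$truth[nz]))
    ids <- sort(unique(sc$truth[sc$truth > 0]))
    expect_identical(ids, seq_along(ids))
    expect_setequal(unique(sc$nuclei_truth[nz]), ids)
  }
})

test_that("fluorescent cells are brighter than background in a noiseless scene", {
  spec <- scene_spec(width = 160, height = 160, n_cells = 6,
                     min_center_distance = 38, noise_sd = 0,
                     illumination_amplitude = 0, rng_seed = 2)
  sc <- generate_scene(spec)
  inside <- sc$truth > 0
  cyto <- sc$cytoplasm_channel[[1]]
  nuc <- sc$nuclei_channel[[1]]
  expect_gt(mean(cyto[inside]), mean(cyto[!inside]) + 0.3)
  expect_gt(mean(nuc[sc$nuclei_truth > 0]), mean(nuc[!inside]) + 0.5)
})

test_that("invalid scene specs are rejected", {
  expect_error(scene_spec(width = 30, height = 30), "4 cell radii")
  expect_error(scene_spec(nucleus_radius_range = c(4, 15)), "smaller")
  expect_error(scene_spec(z_offsets = c(1, 2)), "3 z-plane")
  expect_error(scene_spec(illumination_amplitude = 1.2), "amplitude")
})

test_that("impossible placement yields fewer cells with a warning, not a hang", {
  spec <- scene_spec(width = 96, height = 96, n_cells = 60,
                     cell_radius_range = c(8, 10),
                     nucleus_radius_range = c(3, 4),
                     min_center_distance = 40, rng_seed = 1)
  expect_warning(sc <- generate_scene(spec), "placed only")
  expect_lt(sc$spec$n_placed, 60)
  expect_gt(sc$spec$n_placed, 0)
})

test_that("a one-frame time series equals a scene plus one bright-field frame", {
  spec <- scene_spec(width = 128, height = 128, n_cells = 4,
                     min_center_distance = 30, rng_seed = 9)
  ts <- generate_time_series(spec, n_timepoints = 1)
  expect_length(ts$frames, 1)
  expect_identical(ts$frames[[1]]$truth, ts$scene$truth)
  expect_length(ts$scene$nuclei_channel, 3)
})

test_that("frame-to-frame drift has the configured magnitude", {
  spec <- scene_spec(width = 256, height = 256, n_cells = 15,
                     min_center_distance = 40, rng_seed = 21)
  ts <- generate_time_series(spec, n_timepoints = 5, drift_sd = 1)
  steps <- c()
  for (t in 2:5)
    steps <- c(steps, ts$frames[[t]]$centers - ts$frames[[t - 1]]$centers)
  expect_equal(stats::sd(steps), 1, tolerance = 0.25)
  expect_equal(mean(steps), 0, tolerance = 0.3)
})

test_that("a 44-time-point series at small size runs to completion", {
  spec <- scene_spec(width = 96, height = 96, n_cells = 3,
                     cell_radius_range = c(8, 10),
                     nucleus_radius_range = c(3, 4),
                     min_center_distance = 25, rng_seed = 4)
  ts <- generate_time_series(spec, n_timepoints = 44)
  expect_length(ts$frames, 44)
  expect_length(ts$frames[[44]]$brightfield, 3)
})

test_that("five-channel mode renders 5 images with a nuclear channel 1", {
  spec <- scene_spec(width = 160, height = 160, n_cells = 6,
                     min_center_distance = 38, rng_seed = 8,
                     mode = "multichannel5")
  sc <- generate_scene(spec)
  expect_length(sc$channels5, 5)
  expect_true(all(vapply(sc$channels5, is.matrix, logical(1))))
  nuc <- sc$channels5[[1]]
  expect_gt(mean(nuc[sc$nuclei_truth > 0]), mean(nuc[sc$truth == 0]) + 0.3)
})

test_that("scene TIFF round trip preserves masks and channel structure", {
  sc <- fixture_scene()
  d <- withr::local_tempdir()
  write_scene(sc, d)
  rt <- read_scene(d)
  expect_identical(rt$truth, sc$truth)
  expect_identical(rt$nuclei_truth, sc$nuclei_truth)
  expect_length(rt$brightfield, 3)
  expect_equal(rt$brightfield[[1]], sc$brightfield[[1]], tolerance = 1e-6)
  expect_equal(rt$spec$rng_seed, sc$spec$rng_seed)
})
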