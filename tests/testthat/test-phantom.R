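test_that("scenes are seeded, valid, and respect geometry invariants", {
  s0 <- make_scene(128, 128, 0, 0, seed = 1)
  expect_true(any(s0$fg_mask))
  expect_true(any(s0$bg_mask))
  expect_false(any(s0$fg_mask & s0$bg_mask))

  s1 <- make_scene(128, 128, 2, 1, seed = 7)
  s2 <- make_scene(128, 128, 2, 1, seed = 7)
  expect_identical(s1, s2)

  s3 <- make_scene(128, 128, 2, 1, seed = 8)
  expect_false(identical(s1$fg_mask, s3$fg_mask))

  # all lesion geometry inside bounds
  for (i in seq_len(nrow(s1$lesions))) {
    L <- s1$lesions[i, ]
    expect_gte(L$row - L$radius, 1)
    expect_lte(L$row + L$radius, 128)
    expect_gte(L$col - L$radius, 1)
    expect_lte(L$col + L$radius, 128)
  }
  expect_error(make_scene(32, 128, 0, 0, seed = 1), "64")
})

test_that("speckle rendering is seeded and mean preserving", {
  s <- make_scene(128, 128, 0, 0, seed = 2)
  s$parenchyma_echogenicity <- 0.5
  # noise-free limit: enormous number of looks collapses to the echo map
  img <- render_bmode(s, 1e6, psf_sigma_px = 0, seed = 1)
  expect_lt(max(abs(img - 0.5)), 0.01)
  # seeded determinism
  expect_identical(render_bmode(s, 4, 1, seed = 9),
                   render_bmode(s, 4, 1, seed = 9))
  expect_false(identical(render_bmode(s, 4, 1, seed = 9),
                         render_bmode(s, 4, 1, seed = 10)))
  # Monte-Carlo mean preservation at 4 looks over ~1e5 pixels
  sb <- make_scene(320, 320, 0, 0, seed = 3)
  sb$parenchyma_echogenicity <- 0.5
  big <- render_bmode(sb, 4, psf_sigma_px = 1, seed = 4)
  se <- (0.5 / sqrt(4)) / sqrt(length(big))
  expect_lt(abs(mean(big) - 0.5), 3 * se)
})

test_that("degradation contract: identity, contrast arithmetic, reverb", {
  img <- rand_img(64, 64, 5)
  ident <- degrade_params(contrast_gain = 1, brightness_offset = 0,
                          speckle_looks = Inf, blur_sigma_px = 0,
                          reverb_band_count = 0)
  expect_identical(degrade(img, ident), img)

  # two-level noiseless image: contrast compression is exact arithmetic
  two <- matrix(rep(c(0.3, 0.7), each = 32 * 64), 64, 64)
  p <- degrade_params(contrast_gain = 0.5, brightness_offset = 0,
                      speckle_looks = Inf, blur_sigma_px = 0,
                      reverb_band_count = 0)
  out <- degrade(two, p)
  expect_equal(sort(unique(as.vector(out))), c(0.4, 0.6))
  gap_in <- abs(mean(two[two > 0.5]) - mean(two[two < 0.5]))
  gap_out <- abs(mean(out[out > 0.5]) - mean(out[out < 0.5]))
  expect_equal(gap_out, gap_in / 2)

  # reverberation bands brighten the top quarter
  p_rev <- degrade_params(contrast_gain = 1, brightness_offset = 0,
                          speckle_looks = Inf, blur_sigma_px = 0,
                          reverb_band_count = 3, reverb_amplitude = 0.25)
  rev <- degrade(img, p_rev)
  expect_gt(mean(rev[1:16, ]), mean(img[1:16, ]))
  expect_equal(rev[17:64, ], img[17:64, ], tolerance = 1e-12)
})

test_that("dataset generation writes unpaired files and a stable manifest", {
  d1 <- withr::local_tempdir()
  m1 <- generate_dataset(4, d1, seed = 0, size = c(64, 64))
  expect_length(list.files(file.path(d1, "X"), pattern = "\\.png$"), 4)
  expect_length(list.files(file.path(d1, "Y"), pattern = "\\.png$"), 4)
  expect_length(list.files(file.path(d1, "masks"), pattern = "\\.png$"), 16)
  expect_true(file.exists(file.path(d1, "manifest.yaml")))

  d2 <- withr::local_tempdir()
  generate_dataset(4, d2, seed = 0, size = c(64, 64))
  expect_identical(readBin(file.path(d1, "manifest.yaml"), "raw", 1e5),
                   readBin(file.path(d2, "manifest.yaml"), "raw", 1e5))
  # unpaired: X scenes differ from Y scenes
  seeds <- vapply(m1$images, function(r) r$scene_seed, numeric(1))
  expect_false(any(duplicated(seeds)))
  # paired debug mode reuses the scene
  d3 <- withr::local_tempdir()
  m3 <- generate_dataset(2, d3, seed = 1, paired = TRUE, size = c(64, 64))
  seeds3 <- vapply(m3$images, function(r) r$scene_seed, numeric(1))
  expect_identical(seeds3[1], seeds3[2])
})
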