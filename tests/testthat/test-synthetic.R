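wl150 <- seq(470, 900, length.out = 150)

test_that("class signatures behave as reflectance spectra", {
  for (cl in c("background", "healthy", "soft_rot")) {
    sig <- class_signature(cl, 0.5, wl150)
    expect_length(sig, 150)
    expect_true(all(sig >= 0 & sig <= 1))
  }
  # soft rot at severity 0 is exactly the healthy curve (continuity limit)
  expect_equal(class_signature("soft_rot", 0, wl150),
               class_signature("healthy", wavelengths = wl150))
  # severe rot is well separated from healthy peel
  expect_gte(signature_separation(wl150, 1), 0.05)
  # severity deforms the curve monotonically towards lower NIR
  nir <- wl150 > 780
  r_mild <- class_signature("soft_rot", 0.3, wl150)
  r_severe <- class_signature("soft_rot", 1, wl150)
  expect_lt(mean(r_severe[nir]), mean(r_mild[nir]))
  expect_error(class_signature("stem", 0, wl150), "unknown class_id")
  expect_error(class_signature("healthy", 1.5, wl150), "severity")
})

test_that("scene specs validate their geometry", {
  expect_error(scene_spec(n_bands = 20), "n_bands")
  expect_error(scene_spec(wavelengths = rep(500, 150)), "increasing")
  expect_error(
    scene_spec(height = 64, width = 64, fruit_semiaxes = c(5, 5),
               lesions = list(list(center = c(60, 60), radius = 3,
                                   severity = 1))),
    "outside the fruit")
  expect_error(
    scene_spec(lesions = list(list(center = c(128, 128), radius = 3,
                                   severity = 1.2))),
    "severity")
})

test_that("scene generation is a pure function of spec and seed", {
  spec <- lesion_scene_spec(size = 48, radius = 10, noise_sd = 0.02)
  a <- generate_scene(spec)
  b <- generate_scene(spec)
  expect_identical(a$cube, b$cube)
  expect_identical(a$mask, b$mask)
  spec2 <- lesion_scene_spec(size = 48, radius = 10, noise_sd = 0.02,
                             seed = 8L)
  expect_false(identical(generate_scene(spec2)$cube, a$cube))
})

test_that("masks reflect the scene composition", {
  no_lesion <- scene_spec(height = 48, width = 48, lesions = list(),
                          noise_sd = 0, seed = 1)
  sc <- generate_scene(no_lesion)
  expect_false(any(sc$mask == 2L))
  # a 20 px lesion centred in a 64 px window covers > 10% of its pixels
  sc2 <- generate_scene(lesion_scene_spec(size = 64, radius = 20))
  frac <- mean(sc2$mask == 2L)
  oracle <- disc_pixel_count(64, c(32, 32), 20) / 64^2
  expect_equal(frac, oracle)
  expect_gt(frac, 0.10)
})

test_that("noiseless spectra recover the mask by nearest signature", {
  spec <- lesion_scene_spec(size = 32, radius = 8, severity = 0.8,
                            noise_sd = 0, ring_width = 2)
  sc <- generate_scene(spec)
  pred <- classify_by_signature(sc$cube)
  expect_equal(mean(pred == unclass(sc$mask)), 1.0)
  # at severity 1 every pair of class spectra differs somewhere by >= 0.05
  sigs <- list(class_signature("background", wavelengths = wl150),
               class_signature("healthy", wavelengths = wl150),
               class_signature("soft_rot", 1, wl150))
  for (i in 1:2) for (j in (i + 1):3)
    expect_gte(max(abs(sigs[[i]] - sigs[[j]])), 0.05)
})

test_that("cubes and masks round-trip through ENVI, TIFF and PNG", {
  spec <- lesion_scene_spec(size = 24, radius = 6, noise_sd = 0.01)
  spec$n_bands <- 150L
  sc <- generate_scene(spec)
  tmp <- withr::local_tempdir()
  write_envi(sc$cube, file.path(tmp, "scene"))
  back <- read_envi(file.path(tmp, "scene"))
  expect_equal(dim(back), dim(sc$cube))
  expect_equal(as.vector(back), as.vector(sc$cube), tolerance = 1e-6)
  expect_equal(attr(back, "wavelengths"), attr(sc$cube, "wavelengths"),
               tolerance = 1e-6)
  write_cube_tiff(sc$cube, file.path(tmp, "scene.tif"))
  back2 <- read_cube_tiff(file.path(tmp, "scene.tif"))
  expect_equal(as.vector(back2), as.vector(sc$cube), tolerance = 1e-6)
  write_mask_png(sc$mask, file.path(tmp, "mask.png"))
  expect_identical(as.vector(read_mask_png(file.path(tmp, "mask.png"))),
                   as.vector(unclass(sc$mask)))
})
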