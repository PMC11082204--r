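test_that("normalize_cube resizes and rescales to [0, 1]", {
  cube <- array(runif(5 * 40 * 40, 0.2, 0.8), c(5, 40, 40))
  out <- normalize_cube(cube, 32)
  expect_equal(dim(out), c(5, 32, 32))
  expect_equal(range(out), c(0, 1))
  # already sized and spanning [0, 1]: identity up to interpolation
  cube2 <- array(runif(3 * 16 * 16), c(3, 16, 16))
  cube2[1, 1, 1] <- 0; cube2[1, 1, 2] <- 1
  expect_equal(normalize_cube(cube2, 16), cube2, ignore_attr = TRUE)
  # degenerate constant cube maps to zeros
  expect_true(all(normalize_cube(array(0.7, c(2, 8, 8)), 8) == 0))
  bad <- cube; bad[1] <- NA
  expect_error(normalize_cube(bad, 32), "non-finite")
})

test_that("patch tiling follows the half-open stride-32 grid", {
  cube <- array(runif(2 * 256 * 256), c(2, 256, 256))
  mask <- matrix(0L, 256, 256)
  pt <- extract_patches(cube, mask, size = 64, stride = 32)
  expect_equal(nrow(pt$info), 49)                      # ((256-64)/32+1)^2
  expect_equal(dim(pt$data), c(2, 64, 64, 49))
  expect_true(all(pt$info$bg_fraction == 1.0))
  expect_equal(pt$info$grid_row, rep(0:6, each = 7))   # row-major order
  expect_equal(pt$info$grid_col, rep(0:6, times = 7))
  # every pixel is covered by at least one window
  cov <- matrix(0L, 256, 256)
  for (i in seq_len(49)) {
    r <- pt$info$grid_row[i] * 32; c <- pt$info$grid_col[i] * 32
    cov[r + 1:64, c + 1:64] <- cov[r + 1:64, c + 1:64] + 1L
  }
  expect_true(all(cov >= 1))
  expect_error(extract_patches(cube, matrix(0L, 100, 100)), "does not match")
  # windows that would overrun are dropped
  pt2 <- extract_patches(array(0, c(1, 70, 70)), matrix(0L, 70, 70),
                         size = 64, stride = 32)
  expect_equal(nrow(pt2$info), 1)
})

test_that("window fractions match a brute-force pixel count", {
  sc <- generate_scene(lesion_scene_spec(size = 64, radius = 20))
  pt <- extract_patches(sc$cube, sc$mask, size = 64, stride = 32)
  oracle <- disc_pixel_count(64, c(32, 32), 20)
  expect_equal(pt$info$rot_fraction, oracle / 4096)
  expect_equal(oracle, 1257)  # pi * 20^2 / 64^2 ~ 0.307
})

test_that("label rules fire in precedence order with strict thresholds", {
  expect_equal(as.character(assign_label(0.15, 0.00)), "soft_rot")
  expect_equal(as.character(assign_label(0.00, 0.60)), "background")
  expect_equal(as.character(assign_label(0.05, 0.20)), "healthy")
  expect_equal(as.character(assign_label(0.12, 0.55)), "soft_rot")  # rot wins
  # "exceeded" means strictly greater
  expect_equal(as.character(assign_label(0.10, 0.50)), "healthy")
  expect_error(assign_label(1.2, 0), "fractions")
  # total and deterministic on a grid over [0,1]^2
  g <- expand.grid(rot = seq(0, 1, 0.1), bg = seq(0, 1, 0.1))
  lab <- assign_label(g$rot, g$bg)
  expect_false(anyNA(lab))
  expect_identical(lab, assign_label(g$rot, g$bg))
})

test_that("image-level splits follow largest-remainder 2:1:1", {
  s8 <- split_images(paste0("i", 1:8), seed = 4)
  expect_equal(unname(table(s8$split)[c("train", "val", "test")]),
               c(4L, 2L, 2L), ignore_attr = TRUE)
  s9 <- split_images(paste0("i", 1:9), seed = 4)
  expect_equal(unname(table(s9$split)[c("train", "val", "test")]),
               c(5L, 2L, 2L), ignore_attr = TRUE)
  expect_identical(split_images(paste0("i", 1:9), seed = 4), s9)
  expect_false(identical(split_images(paste0("i", 1:9), seed = 5)$split,
                         s9$split))
  expect_error(split_images(c("a", "b")), "at least as many images")
})

test_that("augmentation expands only the diseased and healthy classes", {
  patch <- list(data = array(runif(6 * 16 * 16), c(6, 16, 16)),
                label = "background", source_image = "s1",
                grid_pos = c(0L, 0L), augmentation = "none")
  expect_length(augment_patch(patch, seed = 1), 1)
  patch$label <- "healthy"
  reps <- augment_patch(patch, seed = 1)
  expect_length(reps, 4)
  expect_equal(vapply(reps, function(p) p$augmentation, character(1)),
               c("none", "mirror", "crop", "shadow"))
  for (p in reps) {
    expect_equal(dim(p$data), dim(patch$data))
    expect_equal(p$label, "healthy")
  }
})

test_that("mirroring is an involution and transforms are band-coherent", {
  patch <- list(data = array(runif(4 * 16 * 16), c(4, 16, 16)),
                label = "soft_rot", source_image = "s", grid_pos = c(0L, 0L),
                augmentation = "none")
  pol <- augmentation_policy(ops = "mirror")
  m1 <- augment_patch(patch, pol, seed = 1)[[2]]
  m1$augmentation <- "none"
  m2 <- augment_patch(m1, pol, seed = 2)[[2]]
  expect_identical(m2$data, patch$data)
  # shadow: one gain field shared by all bands (per-pixel spectra rescale
  # by a common factor)
  full <- augment_patch(patch, augmentation_policy(), seed = 3)
  shadowed <- full[[which(vapply(full, function(p) p$augmentation,
                                 character(1)) == "shadow")]]
  gain <- shadowed$data / patch$data
  expect_lt(max(apply(gain, c(2, 3), function(v) diff(range(v)))), 1e-10)
  expect_true(all(gain >= 0.7 - 1e-9 & gain <= 1 + 1e-9))
  # crop: the same window in every band preserves cross-band structure
  patch2 <- patch
  patch2$data[2, , ] <- 2 * patch2$data[1, , ]
  cropped <- augment_patch(patch2, augmentation_policy(ops = "crop"),
                           seed = 4)[[2]]
  expect_equal(cropped$data[2, , ], 2 * cropped$data[1, , ],
               tolerance = 1e-10)
  expect_error(augment_patch(cropped, pol, seed = 1), "unaugmented")
})

test_that("count arithmetic: augmentation quadruples augmented classes", {
  pre <- matrix(c(10, 4, 7, 3, 2, 5), nrow = 3,
                dimnames = list(c("background", "healthy", "soft_rot"),
                                c("train", "val")))
  post <- augmented_counts(pre)
  expect_equal(post["background", ], pre["background", ])
  expect_equal(post["healthy", ], 4 * pre["healthy", ])
  expect_equal(post["soft_rot", ], 4 * pre["soft_rot", ])
  expect_equal(sum(post), sum(pre) + 3 * sum(pre[c("healthy", "soft_rot"), ]))
  # empty policy: counts unchanged
  none <- augmentation_policy(ops = character(0))
  expect_equal(augmented_counts(pre, none), pre)
})

test_that("build_dataset keeps splits leakage-free with coherent counts", {
  set.seed(11)
  scenes <- lapply(1:4, function(i) {
    spec <- lesion_scene_spec(size = 48, radius = 14, noise_sd = 0.01,
                              seed = 10L + i)
    c(generate_scene(spec), list(id = paste0("img", i)))
  })
  ds <- build_dataset(scenes, target_size = 64, patch_size = 32,
                      stride = 32, seed = 2)
  ps <- ds$patches
  # no source image appears in two splits
  expect_lte(max(table(unique(data.frame(ps$source, ps$split))[, 1])), 1)
  # patch-level split always matches its image's split
  man <- ds$manifest
  expect_true(all(ps$split == man$split[match(ps$source, man$image)]))
  # count arithmetic holds exactly
  cnt <- attr(man, "counts")
  before <- as.matrix(cnt$before_augmentation)
  after <- as.matrix(cnt$after_augmentation)
  expect_equal(after["background", ], before["background", ])
  expect_equal(after["healthy", ], 4 * before["healthy", ])
  expect_equal(after["soft_rot", ], 4 * before["soft_rot", ])
  expect_equal(cnt$total_after,
               cnt$total_before + 3 * sum(before[c("healthy", "soft_rot"), ]))
  # augmentation preserves shape and label bookkeeping
  expect_equal(dim(ps$data)[1:3], c(150, 32, 32))
  expect_false(anyNA(ps$label))
})

test_that("patch stores round-trip through the array directory format", {
  ps <- tiny_patch_set(2, size = 12)
  tmp <- withr::local_tempdir()
  write_patch_store(ps, tmp)
  expect_true(all(file.exists(file.path(tmp, c("data.bin", "manifest.csv",
                                               "counts.json", "meta.json")))))
  back <- read_patch_store(tmp)
  expect_equal(dim(back$data), dim(ps$data))
  expect_equal(as.vector(back$data), as.vector(ps$data), tolerance = 1e-6)
  expect_equal(back$label, ps$label)
  expect_equal(back$split, ps$split)
})
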