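AUG_LEVELS <- c("none", "mirror", "crop", "shadow")

new_patch_set <- function(data, label, split, source, grid, augmentation,
                          wavelengths) {
  structure(list(data = data, label = label, split = split, source = source,
                 grid = grid, augmentation = augmentation,
                 wavelengths = wavelengths),
            class = "patch_set")
}

#' @export
length.patch_set <- function(x) length(x$label)

#' @export
`[.patch_set` <- function(x, i) {
  new_patch_set(x$data[, , , i, drop = FALSE], x$label[i], x$split[i],
                x$source[i], x$grid[i, , drop = FALSE], x$augmentation[i],
                x$wavelengths)
}

#' @export
print.patch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Patch set: %d patches of %d x %d x %d (bands x h x w)\n",
              d[4], d[1], d[2], d[3]))
  print(table(split = x$split, label = x$label))
  invisible(x)
}

#' Spatially and radiometrically normalize a hyperspectral cube
#'
#' Resizes every band to `target_size` x `target_size` (bilinear) and
#' rescales reflectance to \[0, 1\] by the global minimum and maximum over
#' the whole cube. A constant-valued cube maps to all zeros (the degenerate
#' min = max rule).
#'
#' @param cube an `hsi_cube` (bands x height x width).
#' @param target_size output spatial size in pixels.
#' @return An `hsi_cube` of size bands x target_size x target_size.
#' @export
normalize_cube <- function(cube, target_size = 256) {
  d <- dim(cube)
  if (length(d) != 3 || d[1] < 1) stopf("cube must be a bands x h x w array")
  if (d[2] < 2 || d[3] < 2) stopf("cube spatial dimensions must be >= 2x2")
  if (!all(is.finite(cube))) stopf("cube contains non-finite values")
  out <- array(0, c(d[1], target_size, target_size))
  same <- d[2] == target_size && d[3] == target_size
  for (b in seq_len(d[1]))
    out[b, , ] <- if (same) cube[b, , ] else
      EBImage::resize(cube[b, , ], w = target_size, h = target_size)
  lo <- min(out); hi <- max(out)
  out <- if (hi > lo) (out - lo) / (hi - lo) else array(0, dim(out))
  attr(out, "wavelengths") <- attr(cube, "wavelengths")
  class(out) <- c("hsi_cube", class(out))
  out
}

# nearest-neighbour mask resize, matching normalize_cube's geometry
resize_mask <- function(mask, target_size = 256) {
  if (all(dim(mask) == target_size)) return(mask)
  m <- EBImage::resize(unclass(mask) + 0, w = target_size, h = target_size,
                       filter = "none")
  m <- round(m)
  storage.mode(m) <- "integer"
  class(m) <- c("label_mask", class(m))
  m
}

#' Tile a scene into overlapping patches
#'
#' Slides a `size` x `size` window over the scene at the given stride
#' (half-open windows, 0-based offsets, row-major order; windows that would
#' overrun the image are dropped) and records, for each window, the pixel
#' fraction of soft rot and of background from the ground-truth mask.
#'
#' @param cube an `hsi_cube`, spatially aligned with `mask`.
#' @param mask a `label_mask` of the same height and width.
#' @param size window size in pixels.
#' @param stride step between window origins in pixels.
#' @return A list with `data` (array bands x size x size x n_windows) and
#'   `info` (data frame with 0-based `grid_row`, `grid_col`, and the
#'   `rot_fraction` and `bg_fraction` of each window, in row-major order).
#' @export
extract_patches <- function(cube, mask, size = 64, stride = 32) {
  d <- dim(cube)
  if (!all(dim(mask) == d[2:3]))
    stopf("mask (%dx%d) does not match cube (%dx%d)", dim(mask)[1],
          dim(mask)[2], d[2], d[3])
  if (size > d[2] || size > d[3]) stopf("window size exceeds scene size")
  r_off <- seq(0L, d[2] - size, by = stride)
  c_off <- seq(0L, d[3] - size, by = stride)
  n <- length(r_off) * length(c_off)
  data <- array(0, c(d[1], size, size, n))
  info <- data.frame(grid_row = integer(n), grid_col = integer(n),
                     rot_fraction = numeric(n), bg_fraction = numeric(n))
  k <- 0L
  for (i in seq_along(r_off))      # row-major: row index varies slowest
    for (j in seq_along(c_off)) {
      k <- k + 1L
      rr <- r_off[i] + seq_len(size); cc <- c_off[j] + seq_len(size)
      data[, , , k] <- cube[, rr, cc]
      win <- mask[rr, cc]
      info$grid_row[k] <- i - 1L; info$grid_col[k] <- j - 1L
      info$rot_fraction[k] <- mean(win == 2L)
      info$bg_fraction[k] <- mean(win == 0L)
    }
  list(data = data, info = info)
}

#' Label a patch from its class-pixel fractions
#'
#' Applies the fraction rules in order of precedence: a window with more
#' than 10% soft-rot pixels is soft rot; otherwise a window with more than
#' 50% background pixels is background; the remainder are healthy. Both
#' thresholds are strict inequalities, and soft rot wins when both fire.
#'
#' @param rot_fraction,bg_fraction pixel fractions in \[0, 1\] (vectorized).
#' @param rot_threshold,bg_threshold decision thresholds.
#' @return A factor with levels background, healthy, soft_rot.
#' @export
assign_label <- function(rot_fraction, bg_fraction, rot_threshold = 0.10,
                         bg_threshold = 0.50) {
  if (any(rot_fraction < 0 | rot_fraction > 1 | bg_fraction < 0 |
            bg_fraction > 1))
    stopf("fractions must be in [0, 1]")
  out <- ifelse(rot_fraction > rot_threshold, "soft_rot",
                ifelse(bg_fraction > bg_threshold, "background", "healthy"))
  factor(out, levels = DBSA_CLASSES)
}

#' Split source images into train/validation/test sets
#'
#' Whole images are shuffled by `seed` and apportioned to the three splits
#' as close to the requested ratio as integer counts allow
#' (largest-remainder rounding). Splitting at the image level, before
#' blocking, guarantees that no two patches of one image land in different
#' splits.
#'
#' @param image_ids character or integer ids, one per source image.
#' @param ratio length-3 positive weights for train : validation : test.
#' @param seed integer seed.
#' @return A `split_manifest`: data frame with columns `image` and `split`.
#' @export
split_images <- function(image_ids, ratio = c(2, 1, 1), seed = 1L) {
  if (length(ratio) != 3 || any(ratio <= 0))
    stopf("ratio must be three positive numbers (train, val, test)")
  n <- length(image_ids)
  if (n < 3) stopf("need at least as many images (%d) as splits (3)", n)
  if (anyDuplicated(image_ids)) stopf("image ids must be unique")
  quota <- n * ratio / sum(ratio)
  base <- floor(quota)
  rem <- quota - base
  left <- n - sum(base)
  if (left > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(left)]
    base[give] <- base[give] + 1
  }
  ord <- with_seed(seed, sample.int(n))
  split <- rep(c("train", "val", "test"), times = base)
  out <- data.frame(image = as.character(image_ids)[ord], split = split,
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$image, as.character(image_ids))), ]
  rownames(out) <- NULL
  class(out) <- c("split_manifest", class(out))
  out
}

#' Patch augmentation policy
#'
#' Defines which classes are augmented and by which operations. The default
#' mirrors the dataset-construction recipe: healthy and soft-rot patches are
#' expanded x4 (original + mirrored + random crop-and-resize + shadow
#' noise), background patches are kept as is.
#'
#' @param augment_classes class labels to augment.
#' @param ops ordered augmentation operations among `"mirror"`, `"crop"`,
#'   `"shadow"`.
#' @param crop_fraction side fraction of the random crop before resizing
#'   back to full size.
#' @param shadow_alpha maximum attenuation of the shadow gain field (field
#'   values lie in \[1 - alpha, 1\]).
#' @param shadow_grid size of the coarse random grid that is bilinearly
#'   upsampled into the smooth gain field.
#' @return An `augmentation_policy` object.
#' @export
augmentation_policy <- function(augment_classes = c("healthy", "soft_rot"),
                                ops = c("mirror", "crop", "shadow"),
                                crop_fraction = 0.85, shadow_alpha = 0.3,
                                shadow_grid = 4) {
  stopifnot(all(augment_classes %in% DBSA_CLASSES),
            all(ops %in% c("mirror", "crop", "shadow")),
            crop_fraction > 0, crop_fraction <= 1,
            shadow_alpha >= 0, shadow_alpha < 1)
  structure(list(augment_classes = augment_classes, ops = ops,
                 crop_fraction = crop_fraction, shadow_alpha = shadow_alpha,
                 shadow_grid = shadow_grid),
            class = "augmentation_policy")
}

#' Augmentation factor per class under a policy
#'
#' @param policy an [augmentation_policy()].
#' @param classes class labels.
#' @return Integer factor (1 + number of ops for augmented classes, else 1).
#' @export
augmentation_factor <- function(policy, classes = DBSA_CLASSES) {
  ifelse(classes %in% policy$augment_classes, 1L + length(policy$ops), 1L)
}

#' Post-augmentation sample counts implied by a policy
#'
#' Pure count arithmetic: multiplies per-class counts by the policy's
#' augmentation factor (x4 for augmented classes under the default policy).
#'
#' @param pre_counts matrix of counts, rows named by class.
#' @param policy an [augmentation_policy()].
#' @return Matrix of the same shape.
#' @export
augmented_counts <- function(pre_counts, policy = augmentation_policy()) {
  fac <- augmentation_factor(policy, rownames(pre_counts))
  pre_counts * fac
}

# single-band bilinear crop-resize and shadow field helpers ----------------
crop_resize_band <- function(band, r0, c0, cs, size) {
  EBImage::resize(band[r0 + seq_len(cs), c0 + seq_len(cs)], w = size, h = size)
}

shadow_field <- function(size, alpha, grid) {
  g <- matrix(runif(grid * grid, 1 - alpha, 1), grid, grid)
  EBImage::resize(g, w = size, h = size)
}

#' Augment one patch
#'
#' For classes covered by the policy, returns the original plus one patch
#' per operation: `mirror` flips all bands horizontally (an involution);
#' `crop` takes one random sub-window (the same window in every band) and
#' resizes it back bilinearly; `shadow` multiplies all bands by one smooth
#' random gain field in \[1 - alpha, 1\]. Spatial transforms are identical
#' across bands so per-pixel spectra stay intact. Labels and metadata are
#' inherited.
#'
#' @param patch a list with `data` (bands x s x s), `label`, `source_image`,
#'   `grid_pos`, and `augmentation = "none"`.
#' @param policy an [augmentation_policy()].
#' @param seed integer seed for the random crop window and shadow field.
#' @return A list of patches (length 1 or 1 + length(ops)).
#' @export
augment_patch <- function(patch, policy = augmentation_policy(), seed = 1L) {
  if (!identical(as.character(patch$augmentation), "none"))
    stopf("only unaugmented patches can be augmented")
  if (!(as.character(patch$label) %in% policy$augment_classes))
    return(list(patch))
  d <- dim(patch$data)
  size <- d[2]
  out <- list(patch)
  with_seed(seed, {
    for (op in policy$ops) {
      p <- patch
      p$augmentation <- op
      if (op == "mirror") {
        p$data <- patch$data[, , rev(seq_len(d[3])), drop = FALSE]
      } else if (op == "crop") {
        cs <- max(2L, round(policy$crop_fraction * size))
        r0 <- sample.int(size - cs + 1L, 1) - 1L
        c0 <- sample.int(size - cs + 1L, 1) - 1L
        for (b in seq_len(d[1]))
          p$data[b, , ] <- crop_resize_band(patch$data[b, , ], r0, c0, cs, size)
      } else if (op == "shadow") {
        gf <- shadow_field(size, policy$shadow_alpha, policy$shadow_grid)
        for (b in seq_len(d[1])) p$data[b, , ] <- patch$data[b, , ] * gf
      }
      out[[length(out) + 1L]] <- p
    }
  })
  out
}

# per (split, class, augmentation-status) counts in the dataset-table layout
patch_counts <- function(patches) {
  before <- table(split = patches$split[patches$augmentation == "none"],
                  label = patches$label[patches$augmentation == "none"])
  after <- table(split = patches$split, label = patches$label)
  list(before_augmentation = as.data.frame.matrix(t(before)),
       after_augmentation = as.data.frame.matrix(t(after)),
       total_before = sum(before), total_after = sum(after))
}

#' Build a patch dataset from labeled scenes
#'
#' Runs the full dataset-construction pipeline: normalize every scene to
#' `target_size`, split scenes (not patches) into train/validation/test at
#' `ratio`, tile each scene into `patch_size` windows at `stride`, label
#' each window by its class-pixel fractions, and augment according to the
#' policy. By default every split is augmented, reproducing the published
#' count table; set `augment_eval = FALSE` to augment the training split
#' only.
#'
#' @param scenes list of scenes, each a list with `cube`, `mask` and `id`.
#' @param policy an [augmentation_policy()].
#' @param ratio train : validation : test weights.
#' @param seed integer seed (drives the split and the augmentations).
#' @param target_size,patch_size,stride pipeline geometry.
#' @param rot_threshold,bg_threshold labeling thresholds.
#' @param augment_eval augment validation/test patches too?
#' @return A list with `patches` (a `patch_set`), `manifest` (the
#'   `split_manifest` with a `counts` attribute holding the per split x
#'   class tables before and after augmentation) and `warnings` (character;
#'   records any split left without patches of some class).
#' @export
build_dataset <- function(scenes, policy = augmentation_policy(),
                          ratio = c(2, 1, 1), seed = 1L, target_size = 256,
                          patch_size = 64, stride = 32, rot_threshold = 0.10,
                          bg_threshold = 0.50, augment_eval = TRUE) {
  if (length(scenes) < 3) stopf("need at least 3 scenes (one per split)")
  ids <- vapply(scenes, function(s) as.character(s$id), character(1))
  manifest <- split_images(ids, ratio, seed)
  split_of <- stats::setNames(manifest$split, manifest$image)

  datas <- list(); labs <- character(0); splits <- character(0)
  srcs <- character(0); grids <- NULL; augs <- character(0)
  k <- 0L
  for (s in scenes) {
    cube <- normalize_cube(s$cube, target_size)
    mask <- resize_mask(s$mask, target_size)
    pt <- extract_patches(cube, mask, patch_size, stride)
    labels <- assign_label(pt$info$rot_fraction, pt$info$bg_fraction,
                           rot_threshold, bg_threshold)
    spl <- split_of[[as.character(s$id)]]
    do_aug <- augment_eval || spl == "train"
    for (i in seq_len(nrow(pt$info))) {
      patch <- list(data = pt$data[, , , i, drop = FALSE],
                    label = labels[i], source_image = s$id,
                    grid_pos = c(pt$info$grid_row[i], pt$info$grid_col[i]),
                    augmentation = "none")
      dim(patch$data) <- dim(pt$data)[1:3]
      reps <- if (do_aug)
        augment_patch(patch, policy, sub_seed(seed, k * 100L + i)) else
          list(patch)
      for (p in reps) {
        datas[[length(datas) + 1L]] <- p$data
        labs <- c(labs, as.character(p$label))
        splits <- c(splits, spl)
        srcs <- c(srcs, as.character(s$id))
        grids <- rbind(grids, p$grid_pos)
        augs <- c(augs, p$augmentation)
      }
    }
    k <- k + 1L
  }
  d1 <- dim(datas[[1]])
  data <- array(unlist(datas, use.names = FALSE),
                c(d1, length(datas)))
  ps <- new_patch_set(data, factor(labs, levels = DBSA_CLASSES),
                      factor(splits, levels = c("train", "val", "test")),
                      srcs, unname(grids),
                      factor(augs, levels = AUG_LEVELS),
                      attr(scenes[[1]]$cube, "wavelengths"))
  counts <- patch_counts(ps)
  warn <- character(0)
  for (spl in c("train", "val", "test"))
    for (cl in DBSA_CLASSES)
      if (counts$after_augmentation[cl, spl] == 0)
        warn <- c(warn, sprintf("split '%s' has no '%s' patches", spl, cl))
  attr(manifest, "counts") <- counts
  list(patches = ps, manifest = manifest, warnings = warn)
}

#' Balanced synthetic patch sets for training experiments
#'
#' Generates class-balanced 64 x 64 patches directly from single-window
#' synthetic scenes: background windows (no fruit), healthy windows (peel
#' filling the window) and soft-rot windows (a lesion covering well over
#' the 10% labeling threshold). With `spatially_flat = TRUE` every window
#' is filled by a single class at a uniform severity, so the classes differ
#' only through their per-pixel spectra and noise — the regime in which
#' spectral features alone carry the signal.
#'
#' @param n_per_class patches per class.
#' @param seed integer seed.
#' @param preset difficulty preset passed to the scene generator: `"easy"`
#'   (severity 1, noise sd 0.01) or `"hard"` (mild severities, noise sd
#'   0.05).
#' @param split split tag to assign to all patches.
#' @param spatially_flat remove all spatial class structure (see above).
#' @param size patch size in pixels.
#' @param n_bands number of bands.
#' @param severity_range,noise_sd optional overrides of the preset's lesion
#'   severity range and noise level.
#' @return A `patch_set`.
#' @export
synthetic_patch_set <- function(n_per_class, seed = 1L,
                                preset = c("easy", "hard"), split = "train",
                                spatially_flat = FALSE, size = 64,
                                n_bands = 150, severity_range = NULL,
                                noise_sd = NULL) {
  preset <- match.arg(preset)
  noise_sd <- noise_sd %||% (if (preset == "easy") 0.01 else 0.05)
  sev_range <- severity_range %||%
    (if (preset == "easy") c(1, 1) else c(0.3, 0.7))
  n <- 3L * n_per_class
  data <- array(0, c(n_bands, size, size, n))
  labs <- character(n)
  k <- 0L
  for (cl in DBSA_CLASSES)
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      sseed <- sub_seed(seed, k)
      sev <- with_seed(sub_seed(sseed, 5L),
                       runif(1, sev_range[1], sev_range[2]))
      spec <- if (cl == "background") {
        scene_spec(n_bands = n_bands, height = size, width = size,
                   fruit_semiaxes = c(1e-6, 1e-6), noise_sd = noise_sd,
                   seed = sseed)
      } else if (cl == "healthy" || spatially_flat) {
        base <- scene_spec(n_bands = n_bands, height = size, width = size,
                           fruit_semiaxes = c(size, size) * 2,
                           noise_sd = noise_sd, seed = sseed)
        if (cl == "soft_rot")
          base$lesions <- list(list(center = c(size / 2, size / 2),
                                    radius = 2 * size, severity = sev))
        base
      } else {
        off <- with_seed(sub_seed(sseed, 6L), runif(2, -size / 8, size / 8))
        scene_spec(n_bands = n_bands, height = size, width = size,
                   fruit_semiaxes = c(size, size) * 2,
                   lesions = list(list(center = size / 2 + off,
                                       radius = size / 3, severity = sev)),
                   ring_width = if (spatially_flat) 0 else 3,
                   noise_sd = noise_sd, seed = sseed)
      }
      sc <- generate_scene(spec)
      data[, , , k] <- sc$cube
      labs[k] <- cl
    }
  new_patch_set(data, factor(labs, levels = DBSA_CLASSES),
                factor(rep(split, n), levels = c("train", "val", "test")),
                source = sprintf("synthetic_%s_%d", labs, seq_len(n)),
                grid = cbind(rep(0L, n), rep(0L, n)),
                augmentation = factor(rep("none", n), levels = AUG_LEVELS),
                wavelengths = seq(470, 900, length.out = n_bands))
}
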