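#' Specification of a synthetic hyperspectral fruit scene
#'
#' Describes one simulated scene: a fruit ellipse on a dark background, with
#' zero or more circular soft-rot lesions, imaged in `n_bands` narrow
#' wavelength bands. [generate_scene()] turns a spec into a reflectance cube
#' and a per-pixel ground-truth mask. Defaults mimic a 150-band 470--900 nm
#' snapshot imager.
#'
#' Each lesion is a list with elements `center` (row, col in pixels),
#' `radius` (pixels) and `severity` in \[0, 1\]. A "watery ring" annulus of
#' width `ring_width` at reduced severity surrounds every lesion, mirroring
#' the ringed watery spots typical of the disease.
#'
#' @param n_bands number of spectral bands (>= 35).
#' @param wavelengths band centres in nm, strictly increasing, length
#'   `n_bands`.
#' @param height,width scene size in pixels.
#' @param fruit_center,fruit_semiaxes fruit ellipse (row, col) centre and
#'   (row, col) semi-axes in pixels. `fruit_semiaxes = NULL` gives a fruit
#'   nearly filling the frame.
#' @param lesions list of lesions (see Details); may be empty.
#' @param ring_width width in pixels of the watery ring around each lesion.
#' @param ring_severity severity of ring pixels as a fraction of the lesion
#'   severity.
#' @param noise_sd standard deviation of i.i.d. Gaussian reflectance noise
#'   added per band and pixel (result truncated to \[0, 1\]).
#' @param seed integer seed; a scene is a pure function of (spec, seed).
#' @return An object of class `scene_spec`.
#' @seealso [generate_scene()], [class_signature()], [random_scene_spec()]
#' @export
scene_spec <- function(n_bands = 150,
                       wavelengths = seq(470, 900, length.out = n_bands),
                       height = 256, width = 256,
                       fruit_center = c(height / 2, width / 2),
                       fruit_semiaxes = NULL,
                       lesions = list(),
                       ring_width = 3, ring_severity = 0.5,
                       noise_sd = 0.02, seed = 1L) {
  if (!is_count(n_bands) || n_bands < 35)
    stopf("n_bands must be an integer >= 35 (got %s)", format(n_bands))
  if (length(wavelengths) != n_bands)
    stopf("wavelengths must have length n_bands = %d", n_bands)
  if (any(diff(wavelengths) <= 0))
    stopf("wavelengths must be strictly increasing")
  if (!is_count(height) || !is_count(width))
    stopf("height and width must be positive integers")
  if (is.null(fruit_semiaxes)) fruit_semiaxes <- c(height, width) * 0.46
  for (i in seq_along(lesions)) {
    l <- lesions[[i]]
    if (!all(c("center", "radius", "severity") %in% names(l)))
      stopf("lesion %d needs fields center, radius, severity", i)
    if (l$severity < 0 || l$severity > 1)
      stopf("lesion %d: severity must be in [0, 1]", i)
    if (l$radius <= 0) stopf("lesion %d: radius must be positive", i)
    d <- ((l$center[1] - fruit_center[1]) / fruit_semiaxes[1])^2 +
      ((l$center[2] - fruit_center[2]) / fruit_semiaxes[2])^2
    if (d > 1)
      stopf("lesion %d: center (%g, %g) lies outside the fruit ellipse",
            i, l$center[1], l$center[2])
  }
  structure(list(n_bands = as.integer(n_bands), wavelengths = wavelengths,
                 height = as.integer(height), width = as.integer(width),
                 fruit_center = fruit_center, fruit_semiaxes = fruit_semiaxes,
                 lesions = lesions, ring_width = ring_width,
                 ring_severity = ring_severity, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("Synthetic scene spec: %d bands (%.0f-%.0f nm), %dx%d px, %d lesion(s), noise sd %g, seed %d\n",
              x$n_bands, min(x$wavelengths), max(x$wavelengths), x$height,
              x$width, length(x$lesions), x$noise_sd, x$seed))
  invisible(x)
}

#' Reflectance signatures of the scene classes
#'
#' Smooth parametric reflectance curves for the three pixel classes.
#' The healthy peel follows a vegetation-like curve: low blue reflectance,
#' a green bump near 550 nm, a chlorophyll absorption dip near 670 nm and a
#' red-edge ramp to a near-infrared plateau. The soft-rot signature is a
#' continuous deformation of the healthy curve controlled by `severity`:
#' the NIR plateau is reduced, the red edge shifts to longer wavelengths and
#' the green bump flattens, so mild lesions differ from healthy peel mainly
#' spectrally. The background is low and spectrally flat. At `severity = 0`
#' the soft-rot signature equals the healthy one exactly.
#'
#' @param class_id one of `"background"`, `"healthy"`, `"soft_rot"`.
#' @param severity lesion severity in \[0, 1\]; ignored for the other classes.
#' @param wavelengths band centres in nm.
#' @return A reflectance value in \[0, 1\] per wavelength.
#' @export
class_signature <- function(class_id, severity = 0, wavelengths) {
  if (length(wavelengths) < 1) stopf("wavelengths must be nonempty")
  if (length(severity) != 1 || is.na(severity) || severity < 0 || severity > 1)
    stopf("severity must be a single value in [0, 1]")
  wl <- as.numeric(wavelengths)
  logistic <- function(z) 1 / (1 + exp(-z))
  r <- switch(as.character(class_id),
    background = 0.08 + 2e-5 * (wl - 470),
    healthy = 0.12 + 0.08 * exp(-((wl - 550) / 25)^2) -
      0.04 * exp(-((wl - 670) / 22)^2) + 0.62 * logistic((wl - 715) / 16),
    soft_rot = {
      s <- severity
      0.12 - 0.03 * s + 0.08 * (1 - 0.7 * s) * exp(-((wl - 550) / 25)^2) -
        0.04 * (1 - s) * exp(-((wl - 670) / 22)^2) +
        0.62 * (1 - 0.55 * s) * logistic((wl - (715 + 25 * s)) / 16)
    },
    stopf("unknown class_id '%s' (expected background, healthy or soft_rot)",
          class_id)
  )
  pmin(pmax(r, 0), 1)
}

#' Mean absolute spectral separation between healthy and fully rotten peel
#'
#' Band-wise mean absolute difference between the healthy signature and the
#' soft-rot signature at the given severity; the scene generator guarantees
#' this exceeds `min_separation` at severity 1 (default floor 0.05).
#'
#' @param wavelengths band centres in nm.
#' @param severity soft-rot severity.
#' @return A single number.
#' @export
signature_separation <- function(wavelengths, severity = 1) {
  mean(abs(class_signature("healthy", wavelengths = wavelengths) -
             class_signature("soft_rot", severity, wavelengths)))
}

# rasterize the class and severity maps of a spec
scene_masks <- function(spec) {
  h <- spec$height; w <- spec$width
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(rep(seq_len(w), each = h), h, w)
  inside <- ((rr - spec$fruit_center[1]) / spec$fruit_semiaxes[1])^2 +
    ((cc - spec$fruit_center[2]) / spec$fruit_semiaxes[2])^2 <= 1
  mask <- matrix(0L, h, w)
  mask[inside] <- 1L
  sev <- matrix(0, h, w)
  for (l in spec$lesions) {
    d <- sqrt((rr - l$center[1])^2 + (cc - l$center[2])^2)
    ring <- inside & d <= l$radius + spec$ring_width
    core <- d <= l$radius
    sev[ring & !core] <- pmax(sev[ring & !core], spec$ring_severity * l$severity)
    sev[core & inside] <- pmax(sev[core & inside], l$severity)
    mask[(core | ring) & inside] <- 2L
  }
  list(mask = mask, severity = sev)
}

#' Generate a synthetic hyperspectral scene with its ground-truth mask
#'
#' Renders the scene described by a [scene_spec()]: every pixel receives the
#' noiseless [class_signature()] of its mask class (lesion pixels at their
#' lesion's severity, ring pixels at the reduced ring severity) plus i.i.d.
#' Gaussian noise truncated to \[0, 1\]. Identical spec and seed give
#' bit-identical output.
#'
#' @param spec a [scene_spec()].
#' @return A list with `cube` (array bands x height x width, class
#'   `hsi_cube`, with a `wavelengths` attribute) and `mask` (integer matrix,
#'   class `label_mask`, coded 0 = background, 1 = healthy, 2 = soft rot).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  m <- scene_masks(spec)
  h <- spec$height; w <- spec$width; nb <- spec$n_bands
  flat <- matrix(0, nb, h * w)
  key <- paste(m$mask, signif(m$severity, 8))
  for (k in unique(key)) {
    idx <- which(key == k)
    cls <- DBSA_CLASSES[m$mask[idx[1]] + 1L]
    sig <- class_signature(cls, m$severity[idx[1]], spec$wavelengths)
    flat[, idx] <- sig
  }
  if (spec$noise_sd > 0) {
    noise <- with_seed(sub_seed(spec$seed, 2L),
                       matrix(rnorm(nb * h * w, 0, spec$noise_sd), nb))
    flat <- pmin(pmax(flat + noise, 0), 1)
  }
  cube <- array(flat, c(nb, h, w))
  attr(cube, "wavelengths") <- spec$wavelengths
  class(cube) <- c("hsi_cube", class(cube))
  mask <- m$mask
  class(mask) <- c("label_mask", class(mask))
  list(cube = cube, mask = mask)
}

#' Randomly placed lesions for a scene preset
#'
#' Draws a [scene_spec()] whose lesion count, sizes and severities follow a
#' named difficulty preset, with lesion centres placed uniformly inside the
#' fruit ellipse. `"easy"` uses fully developed lesions (severity 1) and low
#' noise; `"hard"` uses mild lesions (severity 0.2--0.6) and stronger noise.
#'
#' @param seed integer seed driving placement and rendering noise.
#' @param preset `"easy"` or `"hard"`.
#' @param n_lesions number of lesions; `NULL` draws 1--3.
#' @param height,width,n_bands passed to [scene_spec()].
#' @param with_lesions set `FALSE` for a healthy fruit scene.
#' @return A `scene_spec`.
#' @export
random_scene_spec <- function(seed, preset = c("easy", "hard"),
                              n_lesions = NULL, height = 256, width = 256,
                              n_bands = 150, with_lesions = TRUE) {
  preset <- match.arg(preset)
  sev_range <- if (preset == "easy") c(1, 1) else c(0.2, 0.6)
  noise_sd <- if (preset == "easy") 0.01 else 0.05
  center <- c(height / 2, width / 2)
  semi <- c(height, width) * 0.46
  lesions <- list()
  if (with_lesions) {
    with_seed(sub_seed(seed, 1L), {
      if (is.null(n_lesions)) n_lesions <- sample(1:3, 1)
      for (i in seq_len(n_lesions)) {
        repeat {
          p <- c(runif(1, 1, height), runif(1, 1, width))
          if (((p[1] - center[1]) / (0.7 * semi[1]))^2 +
              ((p[2] - center[2]) / (0.7 * semi[2]))^2 <= 1) break
        }
        lesions[[i]] <- list(center = p,
                             radius = runif(1, 0.06, 0.14) * min(height, width),
                             severity = runif(1, sev_range[1], sev_range[2]))
      }
    })
  }
  scene_spec(n_bands = n_bands, height = height, width = width,
             fruit_center = center, fruit_semiaxes = semi, lesions = lesions,
             noise_sd = noise_sd, seed = seed)
}

#' Classify pixels of a cube by nearest class signature
#'
#' Assigns each pixel the class whose noiseless signature (over a grid of
#' soft-rot severities) is nearest in mean absolute difference. Used to
#' check that generated cubes and masks stay aligned.
#'
#' @param cube an `hsi_cube`.
#' @param severities soft-rot severity grid to match against.
#' @return An integer matrix of class codes (0/1/2).
#' @export
classify_by_signature <- function(cube, severities = seq(0.1, 1, by = 0.1)) {
  wl <- attr(cube, "wavelengths")
  sigs <- cbind(class_signature("background", wavelengths = wl),
                class_signature("healthy", wavelengths = wl),
                vapply(severities, function(s)
                  class_signature("soft_rot", s, wl), numeric(length(wl))))
  cls <- c(0L, 1L, rep(2L, length(severities)))
  d <- dim(cube)
  flat <- matrix(cube, d[1])
  best <- apply(sigs, 2, function(s) colMeans(abs(flat - s)))
  matrix(cls[max.col(-best, ties.method = "first")], d[2], d[3])
}
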