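#' Read and write hyperspectral cubes and label masks
#'
#' Cubes travel as ENVI pairs (a plain-text `.hdr` plus a band-sequential
#' `.raw` of little-endian 32-bit floats) or as multi-directory 32-bit-float
#' TIFF (one directory per band). Masks are 8-bit grayscale PNG with the
#' class coding 0 = background, 1 = healthy, 2 = soft rot.
#'
#' @param cube an `hsi_cube` (array bands x height x width with a
#'   `wavelengths` attribute).
#' @param prefix path prefix; `write_envi` creates `<prefix>.hdr` and
#'   `<prefix>.raw`.
#' @return `read_envi` and `read_cube_tiff` return an `hsi_cube`;
#'   the writers return their target path invisibly.
#' @name cube_io
NULL

#' @rdname cube_io
#' @export
write_envi <- function(cube, prefix) {
  d <- dim(cube)
  wl <- attr(cube, "wavelengths")
  hdr <- c("ENVI",
           "description = {synthetic hyperspectral scene}",
           sprintf("samples = %d", d[3]),   # columns
           sprintf("lines = %d", d[2]),     # rows
           sprintf("bands = %d", d[1]),
           "header offset = 0", "file type = ENVI Standard",
           "data type = 4", "interleave = bsq", "byte order = 0",
           sprintf("wavelength units = nm"),
           sprintf("wavelength = {%s}", paste(format(wl, trim = TRUE),
                                              collapse = ", ")))
  writeLines(hdr, paste0(prefix, ".hdr"))
  # BSQ: band-major, within a band row-major scan line by line
  con <- file(paste0(prefix, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(cube, c(3, 2, 1))), con, size = 4,
           endian = "little")
  invisible(prefix)
}

#' @rdname cube_io
#' @export
read_envi <- function(prefix) {
  hdr <- readLines(paste0(prefix, ".hdr"))
  getv <- function(key) {
    ln <- grep(paste0("^", key, " *="), hdr, value = TRUE)[1]
    trimws(sub("^[^=]*=", "", ln))
  }
  samples <- as.integer(getv("samples"))
  lines_ <- as.integer(getv("lines"))
  bands <- as.integer(getv("bands"))
  if (getv("interleave") != "bsq" || as.integer(getv("data type")) != 4L)
    stopf("only BSQ float32 ENVI files are supported")
  wl_txt <- paste(hdr[seq(grep("^wavelength *= *\\{", hdr), length(hdr))],
                  collapse = " ")
  wl <- as.numeric(strsplit(gsub("[{}]|wavelength *=", "", wl_txt),
                            ",")[[1]])
  con <- file(paste0(prefix, ".raw"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = samples * lines_ * bands, size = 4,
                 endian = "little")
  cube <- aperm(array(raw, c(samples, lines_, bands)), c(3, 2, 1))
  attr(cube, "wavelengths") <- wl
  class(cube) <- c("hsi_cube", class(cube))
  cube
}

#' @rdname cube_io
#' @param file path to a `.tif` file.
#' @export
write_cube_tiff <- function(cube, file) {
  planes <- lapply(seq_len(dim(cube)[1]), function(b) cube[b, , ])
  tiff::writeTIFF(planes, file, bits.per.sample = 32)
  wl <- attr(cube, "wavelengths")
  writeLines(format(wl, trim = TRUE), paste0(file, ".wavelengths.txt"))
  invisible(file)
}

#' @rdname cube_io
#' @export
read_cube_tiff <- function(file) {
  planes <- tiff::readTIFF(file, all = TRUE)
  cube <- array(0, c(length(planes), nrow(planes[[1]]), ncol(planes[[1]])))
  for (b in seq_along(planes)) cube[b, , ] <- planes[[b]]
  wlf <- paste0(file, ".wavelengths.txt")
  attr(cube, "wavelengths") <- if (file.exists(wlf))
    as.numeric(readLines(wlf)) else seq(470, 900, length.out = dim(cube)[1])
  class(cube) <- c("hsi_cube", class(cube))
  cube
}

#' @rdname cube_io
#' @param mask an integer `label_mask` matrix.
#' @export
write_mask_png <- function(mask, file) {
  png::writePNG(unclass(mask) / 255, file)
  invisible(file)
}

#' @rdname cube_io
#' @export
read_mask_png <- function(file) {
  m <- round(png::readPNG(file) * 255)
  storage.mode(m) <- "integer"
  class(m) <- c("label_mask", class(m))
  m
}

#' Write or read a patch dataset as an array directory
#'
#' The store is a directory holding `data.bin` (the patch tensor as
#' little-endian 32-bit floats, fastest index first: band, row, column,
#' patch), `manifest.csv` (one row per patch: label, split, source image,
#' grid position, augmentation tag), `counts.json` (per split x class x
#' augmentation-status counts in the layout of the dataset table) and
#' `meta.json` (dimensions, class names, wavelengths).
#'
#' @param patches a `patch_set` (see [build_dataset()]).
#' @param dir target directory (created if missing).
#' @return `read_patch_store` returns a `patch_set`; `write_patch_store`
#'   returns `dir` invisibly.
#' @export
write_patch_store <- function(patches, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "data.bin"), "wb")
  writeBin(as.numeric(patches$data), con, size = 4, endian = "little")
  close(con)
  man <- data.frame(label = as.character(patches$label),
                    split = as.character(patches$split),
                    source = patches$source,
                    grid_row = patches$grid[, 1], grid_col = patches$grid[, 2],
                    augmentation = as.character(patches$augmentation))
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(list(dim = dim(patches$data),
                            classes = DBSA_CLASSES,
                            wavelengths = patches$wavelengths),
                       file.path(dir, "meta.json"), auto_unbox = FALSE,
                       digits = NA)
  jsonlite::write_json(patch_counts(patches),
                       file.path(dir, "counts.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_patch_store
#' @export
read_patch_store <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  d <- as.integer(meta$dim)
  con <- file(file.path(dir, "data.bin"), "rb")
  x <- readBin(con, "numeric", n = prod(d), size = 4, endian = "little")
  close(con)
  man <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  new_patch_set(array(x, d),
                label = factor(man$label, levels = DBSA_CLASSES),
                split = factor(man$split, levels = c("train", "val", "test")),
                source = man$source,
                grid = cbind(man$grid_row, man$grid_col),
                augmentation = factor(man$augmentation,
                                      levels = AUG_LEVELS),
                wavelengths = meta$wavelengths)
}
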