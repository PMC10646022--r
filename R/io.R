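## File formats and configuration. RGB renders travel as ordinary 8/16-bit
## TIFF through the tiff package. Physical maps (um, Pa, nm) need samples
## outside [0, 1], which tiff::writeTIFF clamps, so maps are written with a
## small built-in uncompressed 32-bit-float TIFF writer (single precision on
## disk) plus a JSON sidecar carrying units and geometry; reading uses
## tiff::readTIFF, which handles unclamped float samples.

## ---- minimal little-endian 32-bit float TIFF writer ------------------------

.writeFloatTiffPages <- function(pages, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  nTags <- 10L
  ifdSize <- 2L + nTags * 12L + 4L
  ## layout: header(8) then per page [IFD, pixel data]
  offset <- 8L
  offsets <- integer(length(pages))
  for (i in seq_along(pages)) {
    offsets[i] <- offset
    offset <- offset + ifdSize + length(pages[[i]]) * 4L
  }
  writeBin(offsets[1], con, size = 4, endian = "little")
  writeTag <- function(id, type, count, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {                       # SHORT, padded
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (i in seq_along(pages)) {
    m <- pages[[i]]
    nr <- nrow(m); nc <- ncol(m)
    dataOff <- offsets[i] + ifdSize
    writeBin(nTags, con, size = 2, endian = "little")
    writeTag(256, 3, 1, nc)                 # ImageWidth
    writeTag(257, 3, 1, nr)                 # ImageLength
    writeTag(258, 3, 1, 32)                 # BitsPerSample
    writeTag(259, 3, 1, 1)                  # no compression
    writeTag(262, 3, 1, 1)                  # BlackIsZero
    writeTag(273, 4, 1, dataOff)            # StripOffsets
    writeTag(277, 3, 1, 1)                  # SamplesPerPixel
    writeTag(278, 3, 1, nr)                 # RowsPerStrip
    writeTag(279, 4, 1, nr * nc * 4L)       # StripByteCounts
    writeTag(339, 3, 1, 3)                  # SampleFormat = IEEE float
    nxt <- if (i < length(pages)) offsets[i + 1] else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
    writeBin(as.vector(t(m)), con, size = 4, endian = "little")
  }
  invisible(path)
}

## ---- maps ------------------------------------------------------------------

.mapUnits <- c(HueMap = "hue", WavelengthMap = "nm", DisplacementMap = "um",
               StressMap = "Pa", VelocityMap = "um_per_s")

#' Write / read a pixel map as 32-bit float TIFF with a JSON sidecar
#'
#' The TIFF stores the values (single precision, NA where invalid); the
#' sidecar (`<path>.json`) records the map class, unit, pixel length and
#' extra metadata, so `readMap()` reconstructs the object losslessly (at
#' float32 precision).
#'
#' @param map a [PixelMap-class] derivative.
#' @param path TIFF file path.
#' @param metadata optional named list merged into the sidecar.
#' @return `writeMap()`: `path`, invisibly. `readMap()`: the reconstructed
#'   map object.
#' @export
writeMap <- function(map, path, metadata = list()) {
  stopifnot(is(map, "PixelMap"))
  v <- map@values
  v[!map@valid] <- NaN
  .writeFloatTiffPages(list(v), path)
  cls <- class(map)[1]
  meta <- c(list(class = cls,
                 unit = unname(.mapUnits[cls]),
                 pixel_length_um = map@pixelLength),
            metadata)
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeMap
#' @export
readMap <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing JSON sidecar for map: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  v <- tiff::readTIFF(path)
  valid <- is.finite(v)
  v[!valid] <- NA_real_
  pl <- meta$pixel_length_um
  if (is.null(pl) || !length(pl) || !is.numeric(pl)) pl <- NA_real_
  .mkMap(meta$class, v, valid, pl)
}

#' Read / write an RGB render
#'
#' Plain 8- or 16-bit RGB TIFF through the tiff package; channel values are
#' returned exactly as stored, scaled to `[0, 1]` — no color-management
#' transform is applied.
#'
#' @param path file path.
#' @param image array `(rows, cols, 3)` in `[0, 1]`.
#' @param bitDepth 8 or 16.
#' @return `readImageRGB()`: array `(rows, cols, 3)`; `writeImageRGB()`:
#'   `path`, invisibly.
#' @export
readImageRGB <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop("not a 3-channel image: ", path)
  img[, , 1:3, drop = FALSE]
}

#' @rdname readImageRGB
#' @export
writeImageRGB <- function(image, path, bitDepth = 16L) {
  if (!bitDepth %in% c(8L, 16L))
    stop("unsupported bit depth for ", path, ": ", bitDepth)
  tiff::writeTIFF(image, path, bits.per.sample = as.integer(bitDepth))
  invisible(path)
}

## ---- run configuration -----------------------------------------------------

.configDefaults <- function() list(
  substrate = list(rest_thickness_um = 24, youngs_modulus_pa = 20e3,
                   poisson_nu = 0.49, lambda0_nm = 550),
  camera = list(bit_depth = 16L, read_noise_sigma = 0,
                white_balance = c(1, 1, 1), exposure = 1.8),
  geometry = list(pixel_length_um = 0.18, frame_interval_s = 1 / 19.06),
  analysis = list(saturation_floor = 0.02, bin_width = 0.002,
                  threshold_um = 0.05, min_area_px = 20L,
                  out_of_range = "clamp", lut_path = NULL),
  seed = 1L
)

.checkKeys <- function(given, allowed, where) {
  bad <- setdiff(names(given), allowed)
  if (length(bad))
    stop("unknown configuration key", if (length(bad) > 1) "s", " in ",
         where, ": ", paste(bad, collapse = ", "))
}

#' Read and validate a run configuration
#'
#' YAML with sections `substrate`, `camera`, `geometry`, `analysis` and a
#' top-level `seed`; values are layered over the package defaults. Unknown
#' keys are rejected with an error naming the key; physical values must be
#' positive.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file (flags beat file
#'   beats defaults).
#' @return nested list configuration.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- .configDefaults()
  apply1 <- function(cfg, upd, where) {
    .checkKeys(upd, names(cfg), where)
    for (sec in names(upd)) {
      if (is.list(cfg[[sec]]) && is.list(upd[[sec]])) {
        .checkKeys(upd[[sec]], names(cfg[[sec]]), paste0(where, "$", sec))
        for (k in names(upd[[sec]])) cfg[[sec]][[k]] <- upd[[sec]][[k]]
      } else cfg[[sec]] <- upd[[sec]]
    }
    cfg
  }
  if (!is.null(path)) {
    file <- yaml::read_yaml(path)
    if (!is.list(file)) stop("config must be a YAML mapping: ", path)
    cfg <- apply1(cfg, file, path)
  }
  if (length(overrides)) cfg <- apply1(cfg, overrides, "overrides")
  with(cfg, {
    pos <- c(substrate$rest_thickness_um, substrate$youngs_modulus_pa,
             substrate$lambda0_nm, geometry$pixel_length_um,
             geometry$frame_interval_s, camera$exposure)
    if (any(!is.finite(pos) | pos <= 0))
      stop("all physical configuration values must be positive")
    if (substrate$poisson_nu < 0 || substrate$poisson_nu >= 0.5)
      stop("substrate$poisson_nu must lie in [0, 0.5)")
  })
  cfg
}

#' Substrate and camera objects from a configuration
#'
#' @param cfg configuration list from [readRunConfig()].
#' @return `configSubstrate()`: a [SubstrateSpec-class];
#'   `configCamera()`: a [CameraModel-class].
#' @export
configSubstrate <- function(cfg) {
  SubstrateSpec(restD = cfg$substrate$rest_thickness_um,
                youngsE = cfg$substrate$youngs_modulus_pa,
                poissonNu = cfg$substrate$poisson_nu,
                lambda0 = cfg$substrate$lambda0_nm)
}

#' @rdname configSubstrate
#' @export
configCamera <- function(cfg) {
  defaultCameraModel(bitDepth = cfg$camera$bit_depth,
                     readNoiseSigma = cfg$camera$read_noise_sigma,
                     whiteBalance = unlist(cfg$camera$white_balance),
                     exposure = cfg$camera$exposure)
}

#' Write a region table as CSV
#'
#' Column names carry the units (`area_um2`, `force_nN`, ...); forces are
#' rounded to 2 decimal places (nN) and stresses to the nearest pascal,
#' matching the reporting precision of the rest of the pipeline.
#'
#' @param table data.frame from [regionForces()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeRegionTable <- function(table, path) {
  tab <- table
  for (cl in c("force_nN", "force_up_nN", "force_down_nN"))
    if (cl %in% names(tab)) tab[[cl]] <- round(tab[[cl]], 2)
  for (cl in c("stress_min_Pa", "stress_max_Pa"))
    if (cl %in% names(tab)) tab[[cl]] <- round(tab[[cl]])
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
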