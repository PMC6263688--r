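#' Thermal video container
#'
#' An ordered stack of single-channel frames with a frame rate. Intensities
#' are either radiometric temperatures in degrees Celsius
#' (`"radiometric_celsius"`) or plain 8/16-bit gray levels (`"gray8"`,
#' `"gray16"`). All downstream processing uses intensity rank order only, so
#' both kinds flow through the same pipeline; no temperature calibration is
#' ever applied.
#'
#' @param frames numeric array of dimension (rows, cols, frames).
#' @param fps frames per second, > 0.
#' @param intensity_kind one of `"radiometric_celsius"`, `"gray8"`, `"gray16"`.
#' @param pixel_pitch_mm optional mm-per-pixel scale.
#' @return An object of class `thermal_video`.
#' @export
thermal_video <- function(frames, fps,
                          intensity_kind = c("radiometric_celsius", "gray8", "gray16"),
                          pixel_pitch_mm = NULL) {
  intensity_kind <- match.arg(intensity_kind)
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a (rows, cols, frames) array")
  if (dim(frames)[3] < 2L) stop("a thermal video needs at least 2 frames")
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("`fps` must be a single positive number")
  if (intensity_kind == "radiometric_celsius" && !all(is.finite(frames)))
    stop("radiometric intensities must be finite")
  storage.mode(frames) <- "double"
  structure(list(frames = frames, fps = fps, intensity_kind = intensity_kind,
                 pixel_pitch_mm = pixel_pitch_mm),
            class = "thermal_video")
}

#' @export
print.thermal_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<thermal_video> %d frames of %d x %d px @ %g fps (%.1f s), %s\n",
              d[3], d[2], d[1], x$fps, d[3] / x$fps, x$intensity_kind))
  cat(sprintf("  intensity range [%.3g, %.3g]\n", min(x$frames), max(x$frames)))
  invisible(x)
}

#' @export
dim.thermal_video <- function(x) dim(x$frames)

n_frames <- function(video) dim(video$frames)[3]

#' Number of frames / duration helpers
#' @param video a [thermal_video()].
#' @return duration in seconds.
#' @export
video_duration <- function(video) n_frames(video) / video$fps

# round doubles to the nearest float32-representable value (the precision at
# which radiometric stacks are stored on disk)
float32_round <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric",
          n = length(x), size = 4L)
}

#' Read a thermal video
#'
#' Reads a multipage TIFF stack (float32 radiometric or 8/16-bit gray) or a
#' directory of numbered 8/16-bit grayscale PNG frames. TIFF stacks written
#' by [write_thermal_video()] carry their frame rate in the ImageDescription
#' tag; otherwise `fps` must be supplied. An explicit `fps` always takes
#' precedence over container metadata, since thermal stacks often lack or
#' mis-state timing.
#'
#' @param path TIFF file or directory of PNG frames.
#' @param intensity_kind intensity interpretation; `"auto"` infers it from
#'   the sample format (float = radiometric, else gray8/gray16).
#' @param fps frame-rate override (required when the container has none).
#' @param pixel_pitch_mm optional mm-per-pixel scale, stored on the object.
#' @return A [thermal_video()].
#' @export
read_thermal_video <- function(path, intensity_kind = "auto", fps = NULL,
                               pixel_pitch_mm = NULL) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) < 2L) stop("directory must contain at least 2 PNG frames")
    pages <- lapply(files, function(f) {
      im <- png::readPNG(f)
      if (length(dim(im)) == 3L) im <- im[, , 1L]
      im
    })
    meta_fps <- NULL
    bits <- 16L  # readPNG scales both depths to [0,1]; scale back to 16-bit
    pages <- lapply(pages, function(p) round(p * 65535))
    kind <- if (identical(intensity_kind, "auto")) "gray16" else intensity_kind
  } else {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
                      error = function(e) {
                        if (grepl("as.is", conditionMessage(e)))  # float samples
                          tiff::readTIFF(path, all = TRUE, info = TRUE)
                        else stop(e)
                      })
    if (!is.list(pages)) pages <- list(pages)
    desc <- attr(pages[[1L]], "description")
    meta_fps <- if (!is.null(desc) && grepl("fps=", desc))
      as.numeric(sub(".*fps=([0-9.eE+-]+).*", "\\1", desc)) else NULL
    kind <- if (identical(intensity_kind, "auto")) {
      if (is.double(pages[[1L]])) "radiometric_celsius"
      else if (max(vapply(pages, max, 0)) > 255) "gray16" else "gray8"
    } else intensity_kind
  }
  if (length(pages) < 2L) stop("a thermal video needs at least 2 frames")
  shp <- dim(pages[[1L]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), TRUE)))
    stop("mixed frame shapes in ", path)
  use_fps <- if (!is.null(fps)) fps else meta_fps
  if (is.null(use_fps) || !is.finite(use_fps))
    stop("frame rate not present in container metadata; pass `fps`")
  frames <- array(unlist(pages, use.names = FALSE), dim = c(shp, length(pages)))
  thermal_video(frames, use_fps, kind, pixel_pitch_mm)
}

# ---- minimal multipage TIFF writer ---------------------------------------
# tiff::writeTIFF stores float samples clamped to [0,1], which cannot hold
# radiometric degrees Celsius, so stacks are written directly: little-endian,
# one uncompressed strip per page, float32 / uint16 / uint8 samples. libtiff
# (tiff::readTIFF) reads these files back bit-exactly.
write_tiff_stack <- function(frames, path, kind, fps) {
  nf <- dim(frames)[3]; nr <- dim(frames)[1]; nc <- dim(frames)[2]
  bps  <- switch(kind, radiometric_celsius = 32L, gray16 = 16L, gray8 = 8L)
  sfmt <- switch(kind, radiometric_celsius = 3L, 1L)
  desc <- sprintf("thermowelfare fps=%.10g", fps)
  desc_raw <- c(charToRaw(desc), as.raw(0L))
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L)  # little-endian TIFF header
  n_tags <- 10L
  ifd_size <- 2L + n_tags * 12L + 4L
  strip_bytes <- nr * nc * (bps %/% 8L)
  # layout per page: [pixel data][description][IFD]
  data_off <- 8L
  offs <- vector("list", nf)
  for (i in seq_len(nf)) {
    strip_off <- data_off
    desc_off <- strip_off + strip_bytes
    ifd_off <- desc_off + length(desc_raw)
    offs[[i]] <- c(strip = strip_off, desc = desc_off, ifd = ifd_off)
    data_off <- ifd_off + ifd_size
  }
  w4(offs[[1L]]["ifd"])
  tag <- function(id, type, count, value) {
    w2(id); w2(type); w4(count)
    if (type == 3L && count == 1L) { w2(value); w2(0L) } else w4(value)
  }
  for (i in seq_len(nf)) {
    px <- t(frames[, , i])  # row-major strip
    if (kind == "radiometric_celsius") {
      writeBin(as.numeric(px), con, size = 4L, endian = "little")
    } else {
      v <- as.integer(round(px))
      if (bps == 16L) writeBin(v, con, size = 2L, endian = "little")
      else writeBin(as.raw(v), con)
    }
    writeBin(desc_raw, con)
    o <- offs[[i]]
    w2(n_tags)
    tag(256L, 3L, 1L, nc)                 # ImageWidth
    tag(257L, 3L, 1L, nr)                 # ImageLength
    tag(258L, 3L, 1L, bps)                # BitsPerSample
    tag(259L, 3L, 1L, 1L)                 # Compression: none
    tag(262L, 3L, 1L, 1L)                 # Photometric: min-is-black
    tag(270L, 2L, length(desc_raw), o["desc"])  # ImageDescription
    tag(273L, 4L, 1L, o["strip"])         # StripOffsets
    tag(278L, 3L, 1L, nr)                 # RowsPerStrip
    tag(279L, 4L, 1L, strip_bytes)        # StripByteCounts
    tag(339L, 3L, 1L, sfmt)               # SampleFormat
    w4(if (i < nf) offs[[i + 1L]]["ifd"] else 0L)
  }
  invisible(path)
}

#' Write a thermal video to a multipage TIFF
#'
#' Radiometric stacks are stored as float32 samples (the storage precision of
#' radiometric camera exports); gray stacks as uint8/uint16. The frame rate
#' is recorded in the ImageDescription tag so [read_thermal_video()] can
#' recover it. Round trips are bit-exact at the storage precision: reading a
#' written radiometric stack returns exactly the float32 rounding of the
#' input, and integer stacks return identical values.
#'
#' @param video a [thermal_video()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_thermal_video <- function(video, path) {
  stopifnot(inherits(video, "thermal_video"))
  write_tiff_stack(video$frames, path, video$intensity_kind, video$fps)
  invisible(path)
}
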