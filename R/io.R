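## Image I/O.  8-bit images go through png::writePNG/readPNG.  Encoded
## 16-bit grayscale output uses an in-package PNG encoder because no
## suitable 16-bit PNG writer is available to the package; files it
## produces are read back with png::readPNG, which fully supports 16-bit
## grayscale and acts as an independent check on the encoder.

.crc_env <- new.env(parent = emptyenv())

.crc32_table <- function() {
  if (!is.null(.crc_env$tab)) return(.crc_env$tab)
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      ## bitwShiftR is a logical (zero-padded) shift on the 32-bit pattern
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(-306674912L, bitwShiftR(c, 1))  # 0xEDB88320 polynomial
      } else {
        bitwShiftR(c, 1)
      }
    }
    tab[n + 1L] <- c
  }
  .crc_env$tab <- tab
  tab
}

.crc32 <- function(bytes) {
  tab <- .crc32_table()
  crc <- -1L
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    crc <- bitwXor(bitwShiftR(crc, 8),
                   tab[bitwAnd(bitwXor(crc, b[i]), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

.be_int <- function(x, size = 4L) {
  writeBin(as.integer(x), raw(), size = size, endian = "big")
}

.png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(.be_int(length(data)), body, .be_int(.crc32(body)))
}

#' Write a 16-bit grayscale PNG
#'
#' Minimal PNG encoder (grayscale, bit depth 16, no interlace) for the
#' pipeline's encoded outputs.  Codes are stored big-endian as the PNG
#' standard requires.
#'
#' @param codes Integer matrix of codes in \[0, 65535\].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_png16 <- function(codes, path) {
  stopifnot(is.matrix(codes), all(codes >= 0), all(codes <= 65535))
  h <- nrow(codes); w <- ncol(codes)
  ihdr <- c(.be_int(w), .be_int(h),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # depth 16, gray, deflate
  hi <- t(codes %/% 256L); lo <- t(codes %% 256L)   # columns = scanlines
  scan <- matrix(0L, 2L * w + 1L, h)
  scan[seq(2L, 2L * w, 2L), ] <- hi
  scan[seq(3L, 2L * w + 1L, 2L), ] <- lo
  idat <- memCompress(as.raw(scan), type = "gzip")  # zlib stream
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           .png_chunk("IHDR", ihdr),
           .png_chunk("IDAT", idat),
           .png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

.png_bit_depth <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  head <- readBin(con, "raw", 26L)
  if (length(head) < 2L) stop("not a PNG file: ", path)
  if (identical(head[1:2], as.raw(c(0xff, 0xd8)))) {
    stop("format error: JPEG input rejected (lossy); use PNG")
  }
  if (!identical(head[1:8],
                 as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)))) {
    stop("format error: not a PNG file: ", path)
  }
  list(depth = as.integer(head[25]), color_type = as.integer(head[26]))
}

.sidecar_path <- function(path) sub("\\.png$", ".json", path)

#' Write an encoded image as 16-bit PNG plus JSON sidecar
#'
#' Writes the code matrix as a 16-bit grayscale PNG, the validity mask as
#' an 8-bit PNG (`<stem>_mask.png`, 255 = valid), and a JSON sidecar
#' (`<stem>.json`) with `payload`, `scale_denominator`, `max_code`,
#' `band` and the mask file name.
#'
#' @param enc An [encoded_image()].
#' @param path Output PNG path (must end in `.png`).
#' @return `path`, invisibly.
#' @export
write_encoded_png <- function(enc, path) {
  stopifnot(inherits(enc, "encoded_image"), grepl("\\.png$", path))
  write_png16(enc$codes, path)
  mask_file <- sub("\\.png$", "_mask.png", basename(path))
  png::writePNG(matrix(as.numeric(enc$mask), nrow(enc$mask)),
                file.path(dirname(path), mask_file))
  band <- enc$band
  band_meta <- if (inherits(band, "band_definition")) {
    unclass(band)
  } else if (is.list(band)) {
    lapply(band, function(b) if (inherits(b, "band_definition"))
      unclass(b) else b)
  } else NULL
  jsonlite::write_json(
    list(payload = enc$payload,
         scale_denominator = enc$spec$scale_denominator,
         max_code = enc$spec$max_code,
         band = band_meta,
         mask_file = mask_file),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an 8-bit camera frame as PNG
#'
#' @param img A [digital_image()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_digital_png <- function(img, path) {
  stopifnot(inherits(img, "digital_image"))
  px <- img$pixels / 255
  if (dim(px)[3] == 1L) px <- px[, , 1]
  png::writePNG(px, path)
  invisible(path)
}

#' Read a PNG image
#'
#' 8-bit PNGs load as [digital_image()]s (bit-exact DNs).  16-bit
#' grayscale PNGs require the JSON sidecar written by
#' [write_encoded_png()] and load as [encoded_image()]s.  JPEG input is
#' rejected (lossy compression corrupts digital numbers).
#'
#' @param path PNG file path.
#' @param camera_role Camera role tag for 8-bit images.
#' @param settings [camera_config()] attached to 8-bit images.
#' @return A [digital_image()] or [encoded_image()].
#' @export
read_image <- function(path, camera_role = "red-cam",
                       settings = camera_config()) {
  if (!file.exists(path)) stop("file not found: ", path)
  info <- .png_bit_depth(path)
  raw_img <- png::readPNG(path)
  if (info$depth == 8L) {
    dn <- round(raw_img * 255)
    channels <- if (length(dim(dn)) == 3L) {
      c("red", "green", "blue", "alpha")[seq_len(dim(dn)[3])]
    } else "red"
    digital_image(if (length(dim(dn)) == 3L) dn else as.matrix(dn),
                  channels, camera_role, settings)
  } else if (info$depth == 16L) {
    side <- .sidecar_path(path)
    if (!file.exists(side)) {
      stop("metadata error: missing JSON sidecar for 16-bit PNG: ", side)
    }
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    codes <- matrix(as.integer(round(raw_img * 65535)),
                    nrow(raw_img), ncol(raw_img))
    mask <- NULL
    if (!is.null(meta$mask_file)) {
      mpath <- file.path(dirname(path), meta$mask_file)
      if (file.exists(mpath)) {
        mask <- png::readPNG(mpath) > 0.5
      }
    }
    band <- meta$band
    if (!is.null(band) && !is.null(band$name)) {
      band <- band_definition(band$name, band$center_wavelength, band$fwhm)
    }
    encoded_image(codes, meta$payload,
                  encoding_spec(meta$scale_denominator, meta$max_code),
                  mask, band)
  } else {
    stop("format error: unsupported PNG bit depth ", info$depth)
  }
}
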