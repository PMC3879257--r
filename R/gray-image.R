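# Grayscale image container and file I/O.

#' Create a grayscale image
#'
#' The basic container passed through the whole hierarchy: a rows x cols
#' matrix of finite intensities plus a free-form origin tag.
#'
#' @param pixels Numeric matrix (rows x cols) of intensities.
#' @param origin Character tag recording where the image came from.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, origin = "memory") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stopf("`pixels` must be a numeric matrix")
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stopf("image must be at least 1x1")
  }
  if (!all(is.finite(pixels))) stopf("image contains non-finite values")
  structure(list(pixels = pixels, origin = as.character(origin)[1L]),
            class = "gray_image")
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' @export
as.matrix.gray_image <- function(x, ...) x$pixels

#' @export
print.gray_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<gray_image %d x %d, range [%.4g, %.4g], origin: %s>\n",
              d[1L], d[2L], min(x$pixels), max(x$pixels), x$origin))
  invisible(x)
}

is_gray_image <- function(x) inherits(x, "gray_image")

# ITU-R 601 luminance weights for RGB -> gray conversion.
.luma <- c(0.299, 0.587, 0.114)

#' Load an image as grayscale
#'
#' Reads a PNG, JPEG or PGM file and converts it to a single-channel
#' luminance image (ITU-R 601 weights for color inputs). PNG/JPEG
#' intensities are on the reader's native \[0, 1\] scale; PGM files keep
#' their raw integer values.
#'
#' @param path Path to a PNG, JPEG or PGM file.
#' @return A [gray_image].
#' @export
load_gray <- function(path) {
  if (!is.character(path) || length(path) != 1L) stopf("`path` must be a single string")
  if (!file.exists(path)) stopf("cannot read image: no such file '%s'", path)
  ext <- tolower(tools::file_ext(path))
  px <- tryCatch(
    switch(ext,
      png = {
        a <- png::readPNG(path)
        collapse_channels(a)
      },
      pgm = read_pgm(path),
      jpg = ,
      jpeg = {
        a <- EBImage::readImage(path)
        a <- imageData(a)
        # EBImage stores (x, y[, c]): transpose to rows x cols
        if (length(dim(a)) == 2L) t(a)
        else collapse_channels(aperm(a, c(2L, 1L, 3L)))
      },
      stopf("unsupported image format '%s' for '%s' (PNG/JPEG/PGM supported)",
            ext, path)
    ),
    error = function(e) {
      stopf("failed to read image '%s': %s", path, conditionMessage(e))
    }
  )
  if (!all(is.finite(px))) stopf("failed to read image '%s': non-finite pixels", path)
  gray_image(px, origin = path)
}

# H x W x C array (or matrix) -> luminance matrix.
collapse_channels <- function(a) {
  if (is.matrix(a)) return(a)
  nc <- dim(a)[3L]
  if (nc >= 3L) {
    .luma[1L] * a[, , 1L] + .luma[2L] * a[, , 2L] + .luma[3L] * a[, , 3L]
  } else {
    a[, , 1L]  # gray(+alpha): drop alpha
  }
}

# Minimal PGM (P2 ascii / P5 binary) reader; raw integer values preserved.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  toks <- character(0)
  # Read header tokens, honoring '#' comments.
  read_tok <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || !nzchar(ch)) stop("truncated PGM header")
      if (grepl("^\\s$", ch)) next
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
        next
      }
      tok <- ch
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || grepl("^\\s$", ch)) break
        tok <- paste0(tok, ch)
      }
      return(tok)
    }
  }
  magic <- read_tok()
  if (!magic %in% c("P2", "P5")) stop("not a PGM file (magic ", magic, ")")
  w <- as.integer(read_tok()); h <- as.integer(read_tok())
  maxval <- as.integer(read_tok())
  if (any(is.na(c(w, h, maxval))) || w < 1L || h < 1L) stop("bad PGM header")
  n <- w * h
  if (magic == "P5") {
    bytes_per <- if (maxval > 255L) 2L else 1L
    raw <- readBin(con, "integer", n = n, size = bytes_per, signed = FALSE,
                   endian = "big")
    if (length(raw) < n) stop("truncated PGM pixel data")
    vals <- raw
  } else {
    txt <- readChar(con, 1e8, useBytes = TRUE)
    vals <- suppressWarnings(as.integer(strsplit(trimws(txt), "\\s+")[[1L]]))
    if (length(vals) < n || anyNA(vals[seq_len(n)])) stop("truncated PGM pixel data")
    vals <- vals[seq_len(n)]
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a grayscale image
#'
#' Writes PNG (via the png package) or plain PGM. PNG output is clipped to
#' \[0, 1\] after optional rescaling; PGM output is rounded to \[0, 255\].
#'
#' @param img A [gray_image].
#' @param path Output path ending in .png or .pgm.
#' @param rescale `"none"` writes values as-is; `"minmax"` maps the value
#'   range to \[0, 1\] first (constant images map to 0).
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path, rescale = c("minmax", "none")) {
  rescale <- match.arg(rescale)
  px <- as.matrix(img)
  if (rescale == "minmax") {
    rng <- range(px)
    px <- if (rng[2L] > rng[1L]) (px - rng[1L]) / (rng[2L] - rng[1L]) else px * 0
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(pmin(pmax(px, 0), 1), target = path)
  } else if (ext == "pgm") {
    v <- round(pmin(pmax(px, 0), 1) * 255)
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(v), nrow(v)), con, eos = NULL)
    writeBin(as.integer(t(v)), con, size = 1L)
  } else {
    stopf("unsupported output format '%s' (png/pgm supported)", ext)
  }
  invisible(path)
}

# gray_image <-> EBImage Image (EBImage uses x = columns as first dim).
as_ebimage <- function(img) EBImage::Image(t(as.matrix(img)))
from_ebimage <- function(e, origin) gray_image(t(imageData(e)), origin = origin)

#' @importFrom EBImage imageData
resize_to <- function(img, nrow_out, ncol_out) {
  nrow_out <- max(1L, as.integer(round(nrow_out)))
  ncol_out <- max(1L, as.integer(round(ncol_out)))
  if (all(dim(img) == c(nrow_out, ncol_out))) return(img)
  e <- EBImage::resize(as_ebimage(img), w = ncol_out, h = nrow_out)
  from_ebimage(e, origin = img$origin)
}

#' Resize so the shorter side has a given length
#'
#' Bilinear resize preserving aspect ratio (target dimensions rounded to the
#' nearest integer, at least 1). Images whose shorter side already equals
#' `target` are returned unchanged.
#'
#' @param img A [gray_image].
#' @param target Desired shorter-side length in pixels.
#' @return A [gray_image].
#' @export
resize_shorter_side <- function(img, target) {
  target <- check_count(target, "target")
  d <- dim(img)
  short <- min(d)
  if (short == target) return(img)
  f <- target / short
  resize_to(img, d[1L] * f, d[2L] * f)
}

#' Cap the longer side at a given length
#'
#' If the longer side exceeds `cap`, the image is scaled (bilinear, aspect
#' ratio preserved) so the longer side equals `cap`; otherwise it is
#' returned unchanged.
#'
#' @param img A [gray_image].
#' @param cap Maximum longer-side length in pixels.
#' @return A [gray_image].
#' @export
resize_longer_side_cap <- function(img, cap) {
  cap <- check_count(cap, "cap")
  d <- dim(img)
  long <- max(d)
  if (long <= cap) return(img)
  f <- cap / long
  resize_to(img, d[1L] * f, d[2L] * f)
}
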