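#' Image records
#'
#' An `image_record` bundles a grayscale pixel matrix with the metadata the
#' triage pipeline needs: the physical pixel size in micrometres, the bit
#' depth of the source, a class label (`"normal"`, `"suspicious"` or
#' `"unknown"`) and a source identifier. Pixels are stored as a numeric
#' matrix of nonnegative integers in `[0, 2^bit_depth - 1]`.
#'
#' @param pixels Numeric matrix of nonnegative intensities.
#' @param pixel_size_um Positive physical edge length of one pixel, in
#'   micrometres.
#' @param bit_depth Integer bit depth (values must not exceed
#'   `2^bit_depth - 1`).
#' @param label One of `"normal"`, `"suspicious"`, `"unknown"`.
#' @param source_id Identifier string carried through reports.
#' @return An object of class `image_record`.
#' @export
image_record <- function(pixels, pixel_size_um, bit_depth = 8L,
                         label = "unknown", source_id = "image") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    abort("`pixel_size_um` must be a single positive number.")
  }
  label <- match.arg(label, c("normal", "suspicious", "unknown"))
  if (any(pixels < 0)) abort("`pixels` must be nonnegative.")
  maxval <- 2^bit_depth - 1
  if (any(pixels > maxval)) {
    abort(sprintf("`pixels` exceed the %d-bit range [0, %d].",
                  as.integer(bit_depth), as.integer(maxval)))
  }
  structure(
    list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um),
         bit_depth = as.integer(bit_depth), label = label,
         source_id = as.character(source_id)),
    class = "image_record"
  )
}

#' @export
print.image_record <- function(x, ...) {
  cat(sprintf("<image_record> %s: %d x %d, %d-bit, %.3g um/px, label = %s\n",
              x$source_id, nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              x$pixel_size_um, x$label))
  invisible(x)
}

#' Read a grayscale image into an image record
#'
#' Reads PGM (binary `P5` or ASCII `P2`), PNG or TIFF grayscale images.
#' Pixels are returned exactly as stored (no rescaling); the bit depth is
#' taken from the file header. Color images are refused unless
#' `convert_gray = TRUE`, in which case channels are averaged.
#'
#' @param path Path to a `.pgm`, `.png`, `.tif`/`.tiff` file.
#' @inheritParams image_record
#' @param convert_gray Average the channels of a color image instead of
#'   raising an error.
#' @return An [image_record()].
#' @export
read_image <- function(path, pixel_size_um, label = "unknown",
                       source_id = NULL, convert_gray = FALSE) {
  if (!file.exists(path)) abort(paste0("Cannot read image: ", path))
  ext <- tolower(tools::file_ext(path))
  res <- switch(ext,
    pgm = read_pgm(path),
    png = read_png_gray(path, convert_gray),
    tif = ,
    tiff = read_tiff_gray(path, convert_gray),
    abort(paste0("Unsupported image format '", ext, "': ", path))
  )
  image_record(res$pixels, pixel_size_um, bit_depth = res$bit_depth,
               label = label,
               source_id = source_id %||% sub("\\.[^.]*$", "", basename(path)))
}

# PGM P2/P5 per the netpbm spec: header tokens magic, width, height, maxval
# (comments allowed), then ASCII ints (P2) or raw bytes (P5, big-endian for
# maxval > 255).
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- character(0)
  buf <- character(0)
  # tokenize header byte-wise so we stop exactly where P5 raster begins
  read_token <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0 || !nzchar(ch)) abort(paste0("Truncated PGM header: ", path))
      if (ch == "#") { # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (!length(ch) || ch %in% c("\n", "\r")) break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (length(buf)) break else next
      }
      buf <<- c(buf, ch)
    }
    out <- paste(buf, collapse = "")
    buf <<- character(0)
    out
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) abort(paste0("Not a PGM file (magic '", magic, "'): ", path))
  width <- as.integer(read_token())
  height <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (anyNA(c(width, height, maxval)) || width < 1 || height < 1 || maxval < 1) {
    abort(paste0("Malformed PGM header: ", path))
  }
  n <- width * height
  if (magic == "P5") {
    if (maxval > 255) {
      vals <- readBin(con, "integer", n = n, size = 2, signed = FALSE, endian = "big")
    } else {
      vals <- as.integer(readBin(con, "raw", n = n))
    }
  } else {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(vals) < n) abort(paste0("Truncated PGM raster: ", path))
  px <- matrix(as.numeric(vals), nrow = height, ncol = width, byrow = TRUE)
  list(pixels = px, bit_depth = if (maxval > 255) 16L else 8L)
}

#' Write an image record as binary PGM
#'
#' @param img An [image_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path) {
  stopifnot(inherits(img, "image_record"))
  maxval <- 2^img$bit_depth - 1
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(img$pixels), nrow(img$pixels), maxval),
            con, eos = NULL)
  vals <- as.integer(round(t(img$pixels)))
  if (maxval > 255) {
    writeBin(vals, con, size = 2, endian = "big")
  } else {
    writeBin(as.raw(vals), con)
  }
  invisible(path)
}

read_png_gray <- function(path, convert_gray) {
  # readPNG normalizes to [0,1]; recover integers via the IHDR bit-depth byte
  hdr <- readBin(path, "raw", n = 25L)
  bit_depth <- as.integer(hdr[25L])
  if (!bit_depth %in% c(1L, 2L, 4L, 8L, 16L)) {
    abort(paste0("Cannot parse PNG bit depth: ", path))
  }
  bit_depth <- max(bit_depth, 8L)
  x <- png::readPNG(path)
  list(pixels = round(collapse_gray(x, convert_gray, path) * (2^bit_depth - 1)),
       bit_depth = bit_depth)
}

read_tiff_gray <- function(path, convert_gray) {
  x <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  bits <- attr(x, "bits.per.sample") %||% 8L
  px <- collapse_gray(x, convert_gray, path)
  attributes(px) <- list(dim = dim(px)) # drop TIFF metadata attributes
  list(pixels = px, bit_depth = as.integer(bits))
}

collapse_gray <- function(x, convert_gray, path) {
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] == 1L) return(x[, , 1])
    if (!convert_gray) {
      abort(paste0("Color image (use `convert_gray = TRUE` to average channels): ", path))
    }
    return(apply(x[, , 1:min(3L, dim(x)[3])], c(1, 2), mean))
  }
  x
}

#' Read a label manifest
#'
#' The manifest is a CSV with header `source_id,path,pixel_size_um,label`
#' where `label` is `normal` or `suspicious`. Relative image paths are
#' resolved against the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return A tibble with one row per image.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(paste0("Cannot read manifest: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("source_id", "path", "pixel_size_um", "label")
  if (!all(need %in% names(df))) {
    abort(paste0("Manifest must have columns ", paste(need, collapse = ", ")))
  }
  for (col in c("source_id", "path", "label")) df[[col]] <- as.character(df[[col]])
  df$pixel_size_um <- as.numeric(df$pixel_size_um)
  bad <- setdiff(unique(df$label), c("normal", "suspicious"))
  if (length(bad)) abort(paste0("Unknown labels in manifest: ", paste(bad, collapse = ", ")))
  rel <- !file.exists(df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  tibble::as_tibble(df)
}
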