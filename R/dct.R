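#' Orthonormal 2-D type-II discrete cosine transform
#'
#' Separable DCT-II with orthonormal scaling, applied along rows then
#' columns, so the coefficient matrix satisfies Parseval's identity
#' (`sum(coeffs^2) == sum(pixels^2)`). The DC coefficient sits at `[1, 1]`.
#' Computed with the even-odd FFT reordering identity, O(N^2 log N).
#'
#' @param img An [image_record()] or a square numeric matrix whose side is a
#'   power of two.
#' @return A `dct_map`: list with `coeffs` (matrix) and `side`.
#' @export
dct2d <- function(img) {
  x <- if (inherits(img, "image_record")) img$pixels else img
  n <- nrow(x)
  if (!is.matrix(x) || n != ncol(x)) abort("`img` must be a square matrix.")
  if (n < 2 || bitwAnd(n, n - 1L) != 0L) {
    abort("Image side must be a power of two (>= 2).")
  }
  co <- t(dct_cols(t(dct_cols(x))))
  structure(list(coeffs = co, side = n), class = "dct_map")
}

# DCT-II of each column via FFT of the even-odd reordered sequence:
# X_k = Re(exp(-i pi k / 2N) * FFT(v)_k), v = (x_0, x_2, ..., x_3, x_1),
# then orthonormal scaling sqrt(1/N) for k = 0 and sqrt(2/N) otherwise.
dct_cols <- function(x) {
  n <- nrow(x)
  v <- x[c(seq(1L, n, 2L), rev(seq(2L, n, 2L))), , drop = FALSE]
  ph <- exp(-1i * pi * (seq_len(n) - 1) / (2 * n))
  out <- Re(ph * stats::mvfft(v))
  out * c(sqrt(1 / n), rep(sqrt(2 / n), n - 1L))
}

#' Dyadic L-shaped band partition of DCT coefficients
#'
#' Partitions an `N x N` coefficient grid (`N = 2^B`) into `B` L-shaped
#' bands: band `i` holds the coefficients whose 0-based row/column maximum
#' lies in `[2^(i-1), 2^i)`, i.e. the L between nested origin-anchored
#' squares whose sides double. Band `i` has `3 * 4^(i-1)` coefficients; the
#' bands plus the DC position tile the grid exactly.
#'
#' @param side Power-of-two grid side.
#' @return Integer matrix of band ids (0 marks the DC position at `[1, 1]`).
#' @export
dct_band_partition <- function(side) {
  if (side < 2 || bitwAnd(as.integer(side), as.integer(side) - 1L) != 0L) {
    abort("`side` must be a power of two (>= 2).")
  }
  key <- as.character(side)
  if (!is.null(the$partition[[key]])) return(the$partition[[key]])
  idx0 <- seq_len(side) - 1L
  m <- outer(idx0, idx0, pmax)
  band <- matrix(0L, side, side)
  band[m > 0] <- as.integer(floor(log2(m[m > 0]))) + 1L
  if (is.null(the$partition)) the$partition <- list()
  the$partition[[key]] <- band
  band
}

#' Population moments of a set of band coefficients
#'
#' Mean, standard deviation, skewness and kurtosis with divisor-`n`
#' (population) central moments; kurtosis is Pearson's (normal = 3), not
#' excess. A zero-variance set returns skew = kurt = 0 so constant bands
#' stay finite.
#'
#' @param values Nonempty numeric vector.
#' @return Named numeric vector `c(mean, sd, skew, kurt)`.
#' @export
band_moments <- function(values) {
  if (!length(values)) abort("`values` must be nonempty.")
  m1 <- mean(values)
  d <- values - m1
  m2 <- mean(d^2)
  if (m2 == 0) return(c(mean = m1, sd = 0, skew = 0, kurt = 0))
  c(mean = m1, sd = sqrt(m2),
    skew = mean(d^3) / m2^1.5, kurt = mean(d^4) / m2^2)
}

#' Band-moment feature names for a given image side
#'
#' @param side Power-of-two image side (1024 gives the standard 41 names).
#' @return Character vector `c("dc", "b1_mean", "b1_sd", ..., "b<B>_kurt")`.
#' @export
feature_names <- function(side = 1024L) {
  b <- as.integer(log2(side))
  c("dc", as.vector(t(outer(paste0("b", seq_len(b)),
                            c("mean", "sd", "skew", "kurt"), paste, sep = "_"))))
}

#' Extract the DCT band-moment feature vector of one image
#'
#' Transforms the image (orthonormal DCT-II), partitions coefficients into
#' dyadic L-shaped bands and returns the DC coefficient plus four moments
#' per band: 41 features for a 1024x1024 image (`1 + 4 * log2(side)` in
#' general).
#'
#' @param img An [image_record()] or square power-of-two matrix.
#' @param abs_coeffs Take moments of absolute coefficient values instead of
#'   signed ones (default `FALSE`).
#' @return Named numeric feature vector.
#' @export
extract_features <- function(img, abs_coeffs = FALSE) {
  dm <- dct2d(img)
  co <- dm$coeffs
  band <- dct_band_partition(dm$side)
  vals <- if (abs_coeffs) abs(co) else co
  moms <- vapply(split(vals[band > 0L], band[band > 0L]), band_moments,
                 numeric(4))
  out <- c(co[1, 1], as.vector(moms))
  names(out) <- feature_names(dm$side)
  out
}

#' Build a feature table from image records or a manifest
#'
#' Runs preprocessing (optional) and feature extraction over a set of
#' images and returns a tidy feature table: one row per image with
#' `source_id`, `label` and the named feature columns, ready for
#' [knn_loocv()], [nb_loocv()] and the subset searches.
#'
#' @param x A list of [image_record()]s, or a manifest tibble/CSV path as
#'   understood by [read_manifest()].
#' @param preprocess Mask artifacts and standardize geometry before
#'   extraction (default `TRUE`; set `FALSE` when images are already in the
#'   canonical frame).
#' @param target_side,target_pixel_um Canonical frame passed to
#'   [preprocess_image()].
#' @param abs_coeffs Passed to [extract_features()].
#' @return A tibble with columns `source_id`, `label`, then the features.
#' @export
feature_table <- function(x, preprocess = TRUE, target_side = 1024L,
                          target_pixel_um = 200, abs_coeffs = FALSE) {
  recs <- if (is.list(x) && all(vapply(x, inherits, logical(1), "image_record"))) {
    x
  } else {
    man <- if (is.character(x)) read_manifest(x) else tibble::as_tibble(x)
    purrr::pmap(man, function(source_id, path, pixel_size_um, label, ...) {
      read_image(path, pixel_size_um, label = label, source_id = source_id)
    })
  }
  rows <- purrr::map(recs, function(r) {
    if (preprocess) {
      r <- preprocess_image(r, target_pixel_um = target_pixel_um,
                            target_side = target_side)
    }
    fv <- extract_features(r, abs_coeffs = abs_coeffs)
    tibble::tibble(source_id = r$source_id, label = r$label, !!!as.list(fv))
  })
  dplyr::bind_rows(rows)
}

# Internal: split a feature table into the label vector and feature matrix.
feature_matrix <- function(features) {
  stopifnot(is.data.frame(features))
  meta <- intersect(c("source_id", "label"), names(features))
  if (!"label" %in% meta) abort("Feature table needs a `label` column.")
  fm <- as.matrix(features[setdiff(names(features), meta)])
  if (!is.numeric(fm)) abort("Feature columns must be numeric.")
  list(x = fm,
       label = features$label,
       source_id = if ("source_id" %in% meta) features$source_id
                   else as.character(seq_len(nrow(features))))
}

# Internal: resolve a subset given by names or 1-based positions.
resolve_subset <- function(subset, feat_names) {
  if (is.character(subset)) {
    idx <- match(subset, feat_names)
    if (anyNA(idx)) abort(paste0("Unknown feature(s): ",
                                 paste(subset[is.na(idx)], collapse = ", ")))
  } else {
    idx <- as.integer(subset)
    if (!length(idx) || anyNA(idx) || any(idx < 1 | idx > length(feat_names))) {
      abort("Feature subset indices out of range.")
    }
  }
  if (anyDuplicated(idx)) abort("Feature subset indices must be distinct.")
  idx
}
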