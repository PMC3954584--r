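#' Standardize image geometry to the canonical analysis frame
#'
#' Rescales an image to the target physical resolution (bilinear
#' interpolation) and pads or crops it to a square of `target_side` pixels.
#' The breast content is anchored laterally: the image half with the greater
#' mass of nonzero pixels keeps its edge column, and padding/cropping happens
#' on the opposite side; rows are padded/cropped symmetrically.
#'
#' @param img An [image_record()].
#' @param target_pixel_um Target resolution in micrometres per pixel
#'   (default 200).
#' @param target_side Target square side in pixels (default 1024).
#' @return An [image_record()] of shape `target_side x target_side` at
#'   `target_pixel_um`.
#' @export
standardize_geometry <- function(img, target_pixel_um = 200, target_side = 1024L) {
  stopifnot(inherits(img, "image_record"))
  px <- img$pixels
  if (nrow(px) == 0 || ncol(px) == 0) abort("Cannot standardize an empty image.")
  scale <- img$pixel_size_um / target_pixel_um
  if (scale != 1) {
    new_nr <- max(1L, as.integer(round(nrow(px) * scale)))
    new_nc <- max(1L, as.integer(round(ncol(px) * scale)))
    px <- EBImage::resize(px, w = new_nr, h = new_nc, filter = "bilinear")
    maxval <- 2^img$bit_depth - 1
    px <- pmin(pmax(px, 0), maxval)
  }
  px <- fit_to_square(px, target_side)
  image_record(px, target_pixel_um, bit_depth = img$bit_depth,
               label = img$label, source_id = img$source_id)
}

# Pad with zeros / crop to side x side, anchoring the lateral edge with more
# foreground mass; rows centred.
fit_to_square <- function(px, side) {
  nr <- nrow(px); nc <- ncol(px)
  colmass <- colSums(px > 0)
  half <- ceiling(nc / 2)
  anchor_left <- sum(colmass[seq_len(half)]) >= sum(colmass[seq(nc - half + 1, nc)])

  if (nc > side) {
    px <- if (anchor_left) px[, seq_len(side), drop = FALSE]
          else px[, seq(nc - side + 1, nc), drop = FALSE]
  } else if (nc < side) {
    pad <- matrix(0, nr, side - nc)
    px <- if (anchor_left) cbind(px, pad) else cbind(pad, px)
  }

  nr <- nrow(px)
  if (nr > side) {
    off <- (nr - side) %/% 2
    px <- px[seq(off + 1, off + side), , drop = FALSE]
  } else if (nr < side) {
    top <- (side - nr) %/% 2
    px <- rbind(matrix(0, top, side), px, matrix(0, side - nr - top, side))
  }
  px
}

#' Compute the large-bright-object artifact mask
#'
#' Thresholds the image at its mean (or half its mean) intensity and keeps
#' only the largest 8-connected component of the pixels strictly above the
#' threshold. On a mammogram this component is the breast; smaller bright
#' components such as orientation tags fall outside the mask.
#'
#' @param img An [image_record()].
#' @param rule Threshold rule, `"half_mean"` (default) or `"mean"`.
#' @return A `binary_mask`: list with `mask` ({0,1} matrix matching the image
#'   shape), `threshold_value` and `threshold_rule`.
#' @export
artifact_mask <- function(img, rule = c("half_mean", "mean")) {
  stopifnot(inherits(img, "image_record"))
  rule <- match.arg(rule)
  px <- img$pixels
  if (all(px == 0)) abort("no foreground: image is all zero")
  thr <- if (rule == "mean") mean(px) else mean(px) / 2
  fg <- px > thr
  if (!any(fg)) abort("no foreground: no pixel exceeds the threshold")
  lab <- label_components8(fg)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  structure(
    list(mask = matrix(as.numeric(lab == keep), nrow(px), ncol(px)),
         threshold_value = thr, threshold_rule = rule),
    class = "binary_mask"
  )
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally with a union-find pass over the two diagonal offsets.
label_components8 <- function(fg) {
  lab <- EBImage::bwlabel(fg)
  lab <- matrix(as.integer(lab), nrow(fg), ncol(fg))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  diag_pairs <- function(a, b) {
    hit <- a > 0L & b > 0L & a != b
    if (any(hit)) {
      pr <- unique(cbind(a[hit], b[hit]))
      for (i in seq_len(nrow(pr))) unite(pr[i, 1], pr[i, 2])
    }
  }
  diag_pairs(lab[-nr, -nc], lab[-1, -1])   # down-right neighbours
  diag_pairs(lab[-1, -nc], lab[-nr, -1])   # up-right neighbours
  roots <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

#' Apply a binary mask to an image
#'
#' Elementwise (Hadamard) product of the image with the mask, so pixels
#' outside the mask become zero and metadata is preserved.
#'
#' @param img An [image_record()].
#' @param mask A `binary_mask` from [artifact_mask()] or a {0,1} matrix of
#'   the same shape.
#' @return An [image_record()].
#' @export
apply_mask <- function(img, mask) {
  stopifnot(inherits(img, "image_record"))
  m <- if (inherits(mask, "binary_mask")) mask$mask else mask
  if (!identical(dim(m), dim(img$pixels))) {
    abort("Mask shape does not match image shape.")
  }
  out <- img
  out$pixels <- img$pixels * m
  out
}

#' Preprocess one image record for feature extraction
#'
#' Applies the artifact mask in the raw frame, then standardizes geometry.
#'
#' @inheritParams standardize_geometry
#' @param rule Threshold rule for [artifact_mask()].
#' @param mask_first Mask in the raw frame before rescaling (default) or
#'   after geometry standardization.
#' @return A masked, standardized [image_record()].
#' @export
preprocess_image <- function(img, rule = "half_mean", target_pixel_um = 200,
                             target_side = 1024L, mask_first = TRUE) {
  step <- function(x) apply_mask(x, artifact_mask(x, rule))
  if (mask_first) {
    standardize_geometry(step(img), target_pixel_um, target_side)
  } else {
    step(standardize_geometry(img, target_pixel_um, target_side))
  }
}
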