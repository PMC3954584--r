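#' Phantom image specification
#'
#' Parameters of the synthetic breast-like phantom used to exercise the
#' pipeline without real mammograms. A phantom is a bright half-elliptical
#' tissue region touching the left image edge, filled with correlated
#' power-law (`1/f^beta`) texture whose spectral slope depends on the class;
#' suspicious phantoms may additionally carry bright Gaussian lesion blobs,
#' and a bright rectangular orientation-tag artifact can be placed near the
#' right edge outside the tissue.
#'
#' Defaults emulate the canonical study frame: 1024 pixels at 200 um with a
#' steeper (smoother) spectrum for normal tissue (`beta = 3`) than for
#' suspicious tissue (`beta = 2`), three lesions of amplitude five texture
#' standard deviations, and the orientation tag present.
#'
#' @param side Power-of-two image side (default 1024).
#' @param pixel_size_um Pixel size in micrometres (default 200).
#' @param beta_normal,beta_suspicious Power-law spectral exponents per class.
#' @param lesion_count Number of lesion blobs added to suspicious images.
#' @param lesion_amplitude Lesion peak height in units of the texture
#'   standard deviation.
#' @param lesion_sigma_px Lesion Gaussian width in pixels.
#' @param tag Add the orientation-tag rectangle.
#' @param bit_depth Output bit depth (default 8).
#' @param seed Master seed for deterministic generation.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(side = 1024L, pixel_size_um = 200,
                         beta_normal = 3, beta_suspicious = 2,
                         lesion_count = 3L, lesion_amplitude = 5,
                         lesion_sigma_px = side / 32,
                         tag = TRUE, bit_depth = 8L, seed = 1L) {
  if (side < 4 || bitwAnd(as.integer(side), as.integer(side) - 1L) != 0L) {
    abort("`side` must be a power of two (>= 4).")
  }
  stopifnot(beta_normal > 0, beta_suspicious > 0, lesion_count >= 0,
            lesion_amplitude > 0, lesion_sigma_px > 0)
  if (lesion_sigma_px > side / 4) abort("Lesion larger than the tissue support.")
  structure(list(side = as.integer(side), pixel_size_um = pixel_size_um,
                 beta_normal = beta_normal, beta_suspicious = beta_suspicious,
                 lesion_count = as.integer(lesion_count),
                 lesion_amplitude = lesion_amplitude,
                 lesion_sigma_px = lesion_sigma_px, tag = tag,
                 bit_depth = as.integer(bit_depth), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one phantom image
#'
#' Deterministic given `spec$seed` (and `source_id` only labels the output).
#' Texture is synthesized in Fourier space with isotropic power spectrum
#' `1/f^beta`, rescaled to 20-90% of the dynamic range inside the tissue
#' support, lesions are added for suspicious labels, then the image is
#' quantized to `bit_depth`.
#'
#' @param spec A [phantom_spec()].
#' @param label `"normal"` or `"suspicious"`.
#' @param source_id Identifier for the record.
#' @return An [image_record()].
#' @export
phantom_image <- function(spec, label = c("normal", "suspicious"),
                          source_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  label <- match.arg(label)
  withr::with_seed(spec$seed, phantom_image_impl(spec, label, source_id))
}

phantom_image_impl <- function(spec, label, source_id) {
  n <- spec$side
  maxval <- 2^spec$bit_depth - 1
  # half-ellipse tissue support touching the left edge
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  a <- 0.72 * n # lateral semi-axis (columns, from the left edge)
  b <- 0.42 * n # vertical semi-axis
  support <- ((cc - 1) / a)^2 + ((rr - (n + 1) / 2) / b)^2 <= 1

  beta <- if (label == "suspicious") spec$beta_suspicious else spec$beta_normal
  tex <- power_law_field(n, beta)
  tex_sd <- sd(tex[support])
  # map support texture onto [0.2, 0.9] of the dynamic range
  tr <- range(tex[support])
  tex01 <- if (tr[2] > tr[1]) (tex - tr[1]) / (tr[2] - tr[1]) else tex * 0
  img <- matrix(0, n, n)
  img[support] <- (0.2 + 0.7 * tex01[support]) * maxval
  lesion_sd <- sd(img[support]) # lesion height scales with mapped texture SD

  if (label == "suspicious" && spec$lesion_count > 0) {
    for (i in seq_len(spec$lesion_count)) {
      # rejection-sample a centre comfortably inside the support
      repeat {
        cx <- runif(1, 1, 0.8 * a)
        cy <- runif(1, (n + 1) / 2 - 0.8 * b, (n + 1) / 2 + 0.8 * b)
        if (((cx - 1) / a)^2 + ((cy - (n + 1) / 2) / b)^2 <= 0.64) break
      }
      blob <- spec$lesion_amplitude * lesion_sd *
        exp(-((rr - cy)^2 + (cc - cx)^2) / (2 * spec$lesion_sigma_px^2))
      img[support] <- img[support] + blob[support]
    }
  }

  if (spec$tag) {
    th <- max(2L, n %/% 16L); tw <- max(3L, n %/% 10L)
    r0 <- n %/% 8L
    rows <- seq(r0, r0 + th - 1L)
    cols <- seq(n - tw, n - 1L)
    img[rows, cols] <- 0.95 * maxval
  }

  img <- round(pmin(pmax(img, 0), maxval))
  image_record(img, spec$pixel_size_um, bit_depth = spec$bit_depth,
               label = label, source_id = source_id)
}

# Real-valued random field with isotropic power spectrum ~ 1/f^beta,
# synthesized by shaping white Gaussian noise in Fourier space.
power_law_field <- function(n, beta) {
  fr <- c(seq(0, n / 2), seq(n / 2 - 1, 1)) / n # FFT frequencies (abs)
  f2 <- outer(fr^2, fr^2, "+")
  amp <- matrix(0, n, n)
  amp[f2 > 0] <- f2[f2 > 0]^(-beta / 4) # power 1/f^beta => amplitude f^(-beta/2)
  wn <- matrix(rnorm(n * n), n, n)
  shaped <- fft(fft(wn) * amp, inverse = TRUE) / (n * n)
  Re(shaped)
}

#' Generate a labelled phantom set in memory
#'
#' Per-image seeds are derived from the master seed by fixed increments, so
#' the set is reproducible and each image is independent.
#'
#' @param spec A [phantom_spec()].
#' @param n_normal,n_suspicious Class counts.
#' @return List of [image_record()]s (normals first).
#' @export
phantom_set <- function(spec, n_normal, n_suspicious) {
  stopifnot(n_normal >= 0, n_suspicious >= 0)
  labs <- c(rep("normal", n_normal), rep("suspicious", n_suspicious))
  purrr::imap(labs, function(lab, i) {
    sp <- spec
    sp$seed <- spec$seed + i
    phantom_image(sp, lab, source_id = sprintf("phantom_%03d_%s", i, lab))
  })
}

#' Write a phantom dataset to disk
#'
#' Writes each phantom as a binary PGM plus a label manifest
#' (`source_id,path,pixel_size_um,label`) understood by [read_manifest()].
#'
#' @inheritParams phantom_set
#' @param out_dir Output directory (created if missing).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_phantom_dataset <- function(spec, n_normal, n_suspicious, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste0("Cannot create directory: ", out_dir))
  recs <- phantom_set(spec, n_normal, n_suspicious)
  rows <- purrr::map(recs, function(r) {
    fn <- paste0(r$source_id, ".pgm")
    write_pgm(r, file.path(out_dir, fn))
    tibble::tibble(source_id = r$source_id, path = fn,
                   pixel_size_um = r$pixel_size_um, label = r$label)
  })
  man <- file.path(out_dir, "manifest.csv")
  empty <- tibble::tibble(source_id = character(), path = character(),
                          pixel_size_um = numeric(), label = character())
  utils::write.csv(dplyr::bind_rows(empty, !!!rows), man, row.names = FALSE)
  invisible(man)
}
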