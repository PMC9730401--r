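#' Training-time augmentation configuration
#'
#' Three augmentations are applied on the fly, in the order affine ->
#' mirror -> gray: (1) gray-level disturbance, multiplying the normalized
#' image by one random factor in `[0.9, 1.1]` and adding one random shift in
#' `[-0.1, 0.1]`; (2) an in-plane affine disturbance (rotation, isotropic
#' scale, translation) applied identically to image and label; (3) mirroring
#' about the midline with probability 0.5, with the left/right label
#' channels swapped so laterality stays anatomically consistent.
#'
#' @param gray_scale_range multiplicative range (default `c(0.9, 1.1)`).
#' @param gray_shift_range additive range (default `c(-0.1, 0.1)`).
#' @param rotation_deg maximum rotation magnitude in degrees (default 10).
#' @param scale_range isotropic scale interval (default `c(0.95, 1.05)`).
#' @param translation_frac maximum translation as a fraction of the image
#'   width (default 0.05).
#' @param mirror_probability probability of the mirror-with-swap step.
#' @return object of class `augment_config`.
#' @export
augment_config <- function(gray_scale_range = c(0.9, 1.1),
                           gray_shift_range = c(-0.1, 0.1),
                           rotation_deg = 10,
                           scale_range = c(0.95, 1.05),
                           translation_frac = 0.05,
                           mirror_probability = 0.5) {
  stopifnot(diff(gray_scale_range) >= 0, diff(gray_shift_range) >= 0,
            diff(scale_range) >= 0,
            mirror_probability >= 0, mirror_probability <= 1)
  structure(list(gray_scale_range = gray_scale_range,
                 gray_shift_range = gray_shift_range,
                 rotation_deg = rotation_deg, scale_range = scale_range,
                 translation_frac = translation_frac,
                 mirror_probability = mirror_probability),
            class = "augment_config")
}

#' Gray-level disturbance
#'
#' Multiplies the image by one scalar `m` and adds one scalar `a` (drawn
#' once per sample, not per pixel), then clips back to `[0, 1]`. Labels are
#' never touched.
#'
#' @param image array of normalized intensities in `[0, 1]`.
#' @param config an [augment_config()] supplying the draw ranges.
#' @param m,a optional forced values (bypassing the random draw), for
#'   deterministic use.
#' @return disturbed image, same shape, values in `[0, 1]`.
#' @export
gray_disturbance <- function(image, config = augment_config(), m = NULL, a = NULL) {
  m <- m %||% runif(1L, config$gray_scale_range[1L], config$gray_scale_range[2L])
  a <- a %||% runif(1L, config$gray_shift_range[1L], config$gray_shift_range[2L])
  out <- m * image + a
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

affine_matrix <- function(h, w, rotation_deg, scale, translation) {
  th <- rotation_deg * pi / 180
  A <- scale * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L, 2L)
  center <- c((h + 1) / 2, (w + 1) / 2)
  # content point p (row, col) maps to (p - center) %*% A + center + t
  rbind(A, center - center %*% A + translation)
}

#' In-plane affine shape disturbance
#'
#' Applies one affine map (rotation about the image center, isotropic scale,
#' translation) to the image (bilinear interpolation) and the label
#' (nearest-neighbor, re-binarized), with out-of-frame regions filled with
#' zero. Parameters are drawn from `config` unless `params` forces them.
#'
#' @param image `(H, W, C)` array.
#' @param label `(H, W, 4)` binary array.
#' @param config an [augment_config()].
#' @param params optional list `rotation_deg`, `scale`, `translation`
#'   (pixels, `c(rows, cols)`) to force the transform.
#' @return list with `image`, `label`, `params`.
#' @export
affine_disturbance <- function(image, label, config = augment_config(),
                               params = NULL) {
  d <- dim(image)
  if (is.null(params)) {
    params <- list(
      rotation_deg = runif(1L, -config$rotation_deg, config$rotation_deg),
      scale = runif(1L, config$scale_range[1L], config$scale_range[2L]),
      translation = runif(2L, -1, 1) * config$translation_frac * d[2L]
    )
  }
  m <- affine_matrix(d[1L], d[2L], params$rotation_deg, params$scale,
                     params$translation)
  img <- EBImage::imageData(EBImage::affine(image, m, filter = "bilinear",
                                            bg.col = 0))
  lab <- EBImage::imageData(EBImage::affine(label, m, filter = "none",
                                            bg.col = 0))
  lab <- (lab > 0.5) * 1
  dim(img) <- dim(image)
  dim(lab) <- dim(label)
  list(image = img, label = lab, params = params)
}

#' Mirror about the midline with lateral label swap
#'
#' With the given probability, flips image and label along the column
#' (laterality) axis and swaps the left/right parotid and left/right tumor
#' label channels. Applying a forced flip twice restores the input.
#'
#' @param image `(H, W, C)` array.
#' @param label `(H, W, 4)` binary array in canonical channel order.
#' @param probability flip probability.
#' @param force `TRUE`/`FALSE` to force the decision.
#' @return list with `image`, `label`, `flipped`.
#' @export
mirror_with_label_swap <- function(image, label, probability = 0.5,
                                   force = NULL) {
  if (dim(label)[3L] != 4L) {
    stop("label must have the canonical 4 ROI channels")
  }
  flip <- force %||% (probability > 0 && runif(1L) < probability)
  if (!flip) return(list(image = image, label = label, flipped = FALSE))
  w <- dim(image)[2L]
  list(image = image[, w:1, , drop = FALSE],
       label = label[, w:1, ROI_MIRROR_PERM, drop = FALSE],
       flipped = TRUE)
}

#' Apply the full augmentation pipeline to one slice sample
#'
#' Order: affine -> mirror (with label swap) -> gray disturbance. Draws come
#' from the current RNG stream, so a seeded training loop is reproducible
#' bit-for-bit.
#'
#' @param sample a slice sample from [make_slice_dataset()].
#' @param config an [augment_config()].
#' @return the augmented sample.
#' @export
augment_sample <- function(sample, config = augment_config()) {
  af <- affine_disturbance(sample$image, sample$label, config)
  mi <- mirror_with_label_swap(af$image, af$label, config$mirror_probability)
  sample$image <- gray_disturbance(mi$image, config)
  sample$label <- mi$label
  sample
}
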