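#' Specification of a synthetic multi-sequence phantom
#'
#' Phantoms emulate the geometry of an axial head-and-neck acquisition: an
#' anisotropic voxel grid (slice thickness well above the in-plane pixel
#' size) containing two lateral parotid-like ellipsoids placed symmetrically
#' about the midline, with optional tumor ellipsoids strictly inside the
#' gland(s) named by `laterality`. Each of the three sequences gets its own
#' tissue contrast, so sequence-subset ablations are meaningful. Arrays are
#' indexed `(slice, row, column)`; following radiological display, the
#' anatomical-left structures sit on the high-column half of the image.
#'
#' @param grid_shape integer `(slices, height, width)` voxel counts.
#' @param spacing `(slice_thickness_mm, pixel_mm, pixel_mm)`; the slice
#'   thickness must be at least the pixel size.
#' @param laterality tumor placement: `"left"`, `"right"`, `"both"` or
#'   `"none"`.
#' @param contrast_profile 3x3 numeric matrix of mean intensities on the
#'   normalized `[0, 1]` scale; rows `T1w, T2w, T1wC`, columns
#'   `background, parotid, tumor`.
#' @param noise_sd additive Gaussian noise SD on the `[0, 1]` scale.
#' @param tumor_radius_frac tumor semi-axes as a fraction of the parotid
#'   semi-axes (must be 0 when `laterality = "none"`).
#' @param rotation_deg in-plane rotation of the ellipsoids about each
#'   parotid center.
#' @param intensity_mode `"normalized"` writes intensities on `[0, 1]`;
#'   `"raw"` scales by 1000 and adds an offset of 100, emulating scanner
#'   units so intensity normalization can be exercised downstream.
#' @param preset `"full"` (32 x 512 x 512) or `"small"` (8 x 64 x 64, for
#'   fast tests); explicit `grid_shape` overrides the preset.
#' @param seed integer RNG seed; the same spec always generates bit-identical
#'   phantoms.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = NULL,
                         spacing = c(5, 0.5, 0.5),
                         laterality = c("both", "left", "right", "none"),
                         contrast_profile = default_contrast_profile(),
                         noise_sd = 0.02,
                         tumor_radius_frac = 0.4,
                         rotation_deg = 0,
                         intensity_mode = c("normalized", "raw"),
                         preset = c("full", "small"),
                         seed = 1L) {
  laterality <- match.arg(laterality)
  preset <- match.arg(preset)
  intensity_mode <- match.arg(intensity_mode)
  if (is.null(grid_shape)) {
    grid_shape <- if (preset == "small") c(8L, 64L, 64L) else c(32L, 512L, 512L)
  }
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape <= 0L)) {
    stop("grid_shape must be three positive voxel counts")
  }
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be three positive lengths in mm")
  }
  if (spacing[1L] < spacing[2L]) {
    stop("slice thickness must be at least the in-plane pixel size")
  }
  if (!identical(dim(contrast_profile), c(3L, 3L)) ||
      any(contrast_profile < 0) || any(contrast_profile > 1)) {
    stop("contrast_profile must be a 3x3 matrix of intensities in [0, 1]")
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (laterality == "none" && tumor_radius_frac > 0) {
    stop("laterality = 'none' is incompatible with a nonzero tumor radius")
  }
  if (tumor_radius_frac < 0 || tumor_radius_frac > 0.55) {
    stop("tumor_radius_frac must lie in [0, 0.55] to keep tumors inside the gland")
  }
  dimnames(contrast_profile) <- list(SEQUENCE_NAMES,
                                     c("background", "parotid", "tumor"))
  structure(list(grid_shape = grid_shape, spacing = as.numeric(spacing),
                 laterality = laterality, contrast_profile = contrast_profile,
                 noise_sd = noise_sd, tumor_radius_frac = tumor_radius_frac,
                 rotation_deg = rotation_deg, intensity_mode = intensity_mode,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_contrast_profile <- function() {
  # parotid is T1-bright (fatty gland); tumors are T2-bright and enhance
  # strongly on the contrast sequence
  matrix(c(0.20, 0.60, 0.35,
           0.15, 0.45, 0.75,
           0.20, 0.55, 0.85),
         nrow = 3L, byrow = TRUE,
         dimnames = list(SEQUENCE_NAMES, c("background", "parotid", "tumor")))
}

# Voxel membership of a (possibly in-plane-rotated) ellipsoid, by voxel
# center: ((s-cs)/as)^2 + (u/ar)^2 + (v/ac)^2 <= 1 with (u, v) the rotated
# in-plane offsets.
ellipsoid_mask <- function(grid_shape, center, semi, theta = 0) {
  S <- grid_shape[1L]; H <- grid_shape[2L]; W <- grid_shape[3L]
  dr <- seq_len(H) - center[2L]
  dc <- seq_len(W) - center[3L]
  u <- outer(dr, dc, function(r, c) cos(theta) * r + sin(theta) * c)
  v <- outer(dr, dc, function(r, c) -sin(theta) * r + cos(theta) * c)
  e2 <- (u / semi[2L])^2 + (v / semi[3L])^2
  t1 <- ((seq_len(S) - center[1L]) / semi[1L])^2
  arr <- array(rep(as.vector(e2), each = S), c(S, H, W))
  arr + array(t1, c(S, H, W)) <= 1
}

draw_side_geometry <- function(grid_shape, side, d0, tumor_frac, theta) {
  S <- grid_shape[1L]; H <- grid_shape[2L]; W <- grid_shape[3L]
  mid <- (W + 1) / 2
  # radiological display: anatomical-left on the image-right (high columns)
  col_sign <- if (side == "left") 1 else -1
  jit <- function(x, f = 0.1) x * runif(1L, 1 - f, 1 + f)
  center <- c(S * runif(1L, 0.45, 0.55),
              H * runif(1L, 0.47, 0.53),
              mid + col_sign * jit(d0, 0.08))
  semi <- c(jit(0.30 * S), jit(0.16 * H), jit(0.11 * W))
  geom <- list(parotid_center = center, parotid_semi = semi, theta = theta)
  if (tumor_frac > 0) {
    # normalized offset magnitude keeps the tumor strictly inside the gland:
    # |offset| + radius_frac < 1 in the gland's normalized metric
    dir <- rnorm(3L)
    dir <- dir / sqrt(sum(dir^2))
    mag <- runif(1L, 0, max(0, 0.9 - tumor_frac))
    geom$tumor_center <- center + dir * mag * semi
    geom$tumor_semi <- tumor_frac * semi
  }
  geom
}

#' Generate one synthetic phantom case
#'
#' Draws the per-side ellipsoid geometry under the spec's seed (or uses an
#' explicitly supplied `geometry`, e.g. a mirrored copy of a previous case's
#' `ground_truth_params`), rasterizes parotid and tumor masks by voxel
#' center, paints the three sequences from the contrast profile and adds
#' Gaussian noise. Tumor masks are voxelwise subsets of their same-side
#' parotid masks by construction.
#'
#' @param spec a [phantom_spec()].
#' @param patient_id identifier stored with the case.
#' @param geometry optional explicit geometry (as found in a generated case's
#'   `ground_truth_params`), bypassing the random draw.
#' @return object of class `phantom_case`: `patient_id`, `volume` (a
#'   [multi_sequence_volume()]), `labels` (a [roi_label_volume()]) and
#'   `ground_truth_params`.
#' @export
generate_phantom <- function(spec, patient_id = "phantom001", geometry = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  theta <- spec$rotation_deg * pi / 180
  with_local_seed(spec$seed, {
    if (is.null(geometry)) {
      d0 <- 0.22 * gs[3L]
      tf <- spec$tumor_radius_frac
      geometry <- list(
        left = draw_side_geometry(gs, "left", d0,
                                  if (spec$laterality %in% c("left", "both")) tf else 0,
                                  theta),
        right = draw_side_geometry(gs, "right", d0,
                                   if (spec$laterality %in% c("right", "both")) tf else 0,
                                   theta))
    }
    masks <- array(0, c(gs, 4L), dimnames = list(NULL, NULL, NULL, ROI_NAMES))
    for (side in c("left", "right")) {
      g <- geometry[[side]]
      p_mask <- ellipsoid_mask(gs, g$parotid_center, g$parotid_semi, g$theta)
      masks[, , , paste0(side, "_parotid")] <- p_mask
      if (!is.null(g$tumor_center)) {
        masks[, , , paste0(side, "_tumor")] <-
          ellipsoid_mask(gs, g$tumor_center, g$tumor_semi, g$theta)
      }
    }
    parotid_any <- masks[, , , 1L] | masks[, , , 2L]
    tumor_any <- masks[, , , 3L] | masks[, , , 4L]
    seqs <- list()
    for (sq in SEQUENCE_NAMES) {
      cp <- spec$contrast_profile[sq, ]
      img <- array(cp[["background"]], gs)
      img[parotid_any] <- cp[["parotid"]]
      img[tumor_any] <- cp[["tumor"]]
      if (spec$noise_sd > 0) {
        img <- pmin(pmax(img + array(rnorm(prod(gs), sd = spec$noise_sd), gs), 0), 1)
      }
      if (spec$intensity_mode == "raw") img <- img * 1000 + 100
      seqs[[sq]] <- img
    }
    list(
      patient_id = patient_id,
      volume = multi_sequence_volume(patient_id, seqs, spec$spacing),
      labels = roi_label_volume(masks, spec$spacing),
      ground_truth_params = geometry,
      spec = spec
    ) |> structure(class = "phantom_case")
  })
}

#' Mirror a case geometry about the midline
#'
#' Flips the column coordinates and swaps the left/right roles, producing the
#' geometry of the laterally mirrored phantom; used to validate the
#' mirror-with-label-swap augmentation against regeneration.
#'
#' @param geometry a `ground_truth_params` list.
#' @param width image width in voxels.
#' @return mirrored geometry.
#' @export
mirror_geometry <- function(geometry, width) {
  flip <- function(g) {
    g$parotid_center[3L] <- width + 1 - g$parotid_center[3L]
    if (!is.null(g$tumor_center)) g$tumor_center[3L] <- width + 1 - g$tumor_center[3L]
    g$theta <- -g$theta
    g
  }
  list(left = flip(geometry$right), right = flip(geometry$left))
}

#' Generate a phantom cohort and write it to disk
#'
#' Derives one deterministic seed per case from `seed`, samples each case's
#' tumor laterality from `proportions` (defaulting to the study cohort's
#' left/right/bilateral mix of roughly 45/49/6%), generates the phantoms and,
#' when `out_dir` is given, writes one NIfTI file per sequence plus a
#' 4-channel NIfTI label file per case together with a JSON manifest.
#'
#' @param n_cases number of cases (>= 1).
#' @param base_spec a [phantom_spec()] providing everything but seed and
#'   laterality.
#' @param seed cohort-level seed.
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing.
#' @param proportions named probabilities for `left`, `right`, `both`.
#' @return list of `phantom_case` (invisibly when writing); the manifest path
#'   is attached as attribute `manifest`.
#' @export
generate_cohort <- function(n_cases, base_spec = phantom_spec(), seed = 1L,
                            out_dir = NULL,
                            proportions = c(left = 0.446, right = 0.491, both = 0.063)) {
  if (n_cases < 1L) stop("n_cases must be >= 1")
  stopifnot(all(c("left", "right", "both") %in% names(proportions)))
  draws <- with_local_seed(seed, list(
    seeds = sample.int(.Machine$integer.max - 1L, n_cases),
    lat = sample(c("left", "right", "both"), n_cases, replace = TRUE,
                 prob = proportions[c("left", "right", "both")])
  ))
  cases <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    spec_i <- base_spec
    spec_i$seed <- draws$seeds[i]
    spec_i$laterality <- draws$lat[i]
    cases[[i]] <- generate_phantom(spec_i, patient_id = sprintf("phantom%03d", i))
  }
  if (!is.null(out_dir)) {
    manifest_path <- write_cohort(cases, out_dir)
    attr(cases, "manifest") <- manifest_path
    return(invisible(cases))
  }
  cases
}
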