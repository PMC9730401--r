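#' Dice similarity coefficient between two binary masks
#'
#' `DICE = 2 |A intersect B| / (|A| + |B|)`, an exact ratio of voxel counts.
#' When both masks are empty the value is 1 by convention (the degenerate
#' case is flagged by [case_metrics()]); when exactly one is empty it is 0.
#'
#' @param mask_a,mask_b binary arrays on the same grid.
#' @return fraction in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  check_same_grid(mask_a, mask_b)
  sa <- sum(mask_a == 1); sb <- sum(mask_b == 1)
  if (sa + sb == 0) return(1)
  2 * sum(mask_a == 1 & mask_b == 1) / (sa + sb)
}

#' Jaccard similarity coefficient between two binary masks
#'
#' `JACCARD = |A intersect B| / |A union B|`; related to Dice by
#' `J = D / (2 - D)`. Both-empty returns 1 by convention.
#'
#' @inheritParams dice
#' @return fraction in `[0, 1]`.
#' @export
jaccard <- function(mask_a, mask_b) {
  check_same_grid(mask_a, mask_b)
  inter <- sum(mask_a == 1 & mask_b == 1)
  uni <- sum(mask_a == 1 | mask_b == 1)
  if (uni == 0) return(1)
  inter / uni
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b))) {
    stop("masks must share one grid")
  }
  invisible(TRUE)
}

shift_fill_false <- function(m, axis, by) {
  out <- array(FALSE, dim(m))
  idx_src <- lapply(dim(m), seq_len)
  idx_dst <- idx_src
  n <- dim(m)[axis]
  if (by == 1L) {
    idx_src[[axis]] <- seq_len(n - 1L); idx_dst[[axis]] <- 2:n
  } else {
    idx_src[[axis]] <- 2:n; idx_dst[[axis]] <- seq_len(n - 1L)
  }
  out <- do.call(`[<-`, c(list(out), idx_dst, list(do.call(`[`, c(list(m), idx_src)))))
  out
}

#' Surface voxels of a binary mask
#'
#' Foreground voxels with at least one background face-neighbor
#' (6-connectivity in 3D, 4-connectivity in 2D); out-of-bounds counts as
#' background.
#'
#' @param mask binary 2D or 3D array.
#' @return integer matrix of 1-based voxel coordinates (one row per surface
#'   voxel; zero rows for an empty mask).
#' @export
surface_voxels <- function(mask) {
  m <- mask == 1
  if (!sum(m)) return(matrix(integer(), 0L, length(dim(m))))
  all_fg <- array(TRUE, dim(m))
  for (axis in seq_along(dim(m))) {
    if (dim(m)[axis] == 1L) { all_fg[] <- FALSE; next }
    all_fg <- all_fg & shift_fill_false(m, axis, 1L) & shift_fill_false(m, axis, -1L)
  }
  which(m & !all_fg, arr.ind = TRUE)
}

surface_mm <- function(mask, spacing) {
  coords <- surface_voxels(mask)
  sweep(coords, 2L, spacing[seq_len(ncol(coords))], `*`)
}

#' 95th-percentile Hausdorff surface distance (mm)
#'
#' Euclidean distances between the two mask surfaces are computed in
#' physical units on the anisotropic grid; the directed surface-to-surface
#' distance sets A->B and B->A are pooled and the 95th percentile (linear
#' interpolation) of the pooled set is returned. `pooling =
#' "max_directed"` instead returns the larger of the two directed 95th
#' percentiles (the alternative convention found in the literature).
#'
#' @param mask_a,mask_b nonempty binary masks on one grid.
#' @param spacing physical voxel spacing, one entry per array dimension
#'   (e.g. `(slice_thickness_mm, row_mm, col_mm)`).
#' @param pooling `"pooled"` (default) or `"max_directed"`.
#' @param percentile percentile of the distance distribution (default 0.95;
#'   1 gives the classical Hausdorff distance).
#' @return distance in mm, or `NA` if either mask is empty.
#' @export
hd95 <- function(mask_a, mask_b, spacing = rep(1, length(dim(mask_a))),
                 pooling = c("pooled", "max_directed"), percentile = 0.95) {
  pooling <- match.arg(pooling)
  check_same_grid(mask_a, mask_b)
  if (sum(mask_a == 1) == 0 || sum(mask_b == 1) == 0) return(NA_real_)
  sa <- surface_mm(mask_a, spacing)
  sb <- surface_mm(mask_b, spacing)
  dab <- min_point_dists_cpp(sa, sb)
  dba <- min_point_dists_cpp(sb, sa)
  if (pooling == "pooled") {
    quantile(c(dab, dba), percentile, type = 7, names = FALSE)
  } else {
    max(quantile(dab, percentile, type = 7, names = FALSE),
        quantile(dba, percentile, type = 7, names = FALSE))
  }
}

#' Average Hausdorff surface distance (mm)
#'
#' Mean of the two directed average surface distances:
#' `0.5 * (mean_a min_b d(a, b) + mean_b min_a d(a, b))` over the mask
#' surfaces, in physical units.
#'
#' @inheritParams hd95
#' @return distance in mm, or `NA` if either mask is empty.
#' @export
ahd <- function(mask_a, mask_b, spacing = rep(1, length(dim(mask_a)))) {
  check_same_grid(mask_a, mask_b)
  if (sum(mask_a == 1) == 0 || sum(mask_b == 1) == 0) return(NA_real_)
  sa <- surface_mm(mask_a, spacing)
  sb <- surface_mm(mask_b, spacing)
  0.5 * (mean(min_point_dists_cpp(sa, sb)) + mean(min_point_dists_cpp(sb, sa)))
}

#' Four-metric evaluation of one case
#'
#' DICE, JACCARD, HD95 and AHD per ROI, computed in 3D on the native
#' anisotropic grid. Surface distances are undefined (NA, with a flag) when
#' either mask of an ROI is empty; empty/empty overlap metrics return 1 and
#' one-sided empties 0, both flagged.
#'
#' @param pred,truth [roi_label_volume()] objects (prediction and manual
#'   reference) on one grid.
#' @param patient_id identifier for the output rows.
#' @param pooling HD95 pooling rule, see [hd95()].
#' @return data.frame with one row per ROI: `patient_id, roi, dice, jaccard,
#'   hd95_mm, ahd_mm, flags`.
#' @export
case_metrics <- function(pred, truth, patient_id = "case", pooling = "pooled") {
  stopifnot(inherits(pred, "roi_label_volume"), inherits(truth, "roi_label_volume"))
  spacing <- truth$spacing
  rows <- lapply(seq_along(ROI_NAMES), function(i) {
    p <- pred$masks[, , , i]
    t <- truth$masks[, , , i]
    np <- sum(p == 1); nt <- sum(t == 1)
    flag <- if (np + nt == 0) "both_empty" else if (np == 0) "pred_empty" else
      if (nt == 0) "truth_empty" else ""
    data.frame(patient_id = patient_id, roi = ROI_NAMES[i],
               dice = dice(p, t), jaccard = jaccard(p, t),
               hd95_mm = hd95(p, t, spacing, pooling = pooling),
               ahd_mm = ahd(p, t, spacing), flags = flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aggregate per-case metrics into a cohort report
#'
#' Per-ROI arithmetic means over defined values plus a 95% range. The range
#' is the empirical 2.5th--97.5th percentile of the per-case values
#' (`interval = "percentile"`, the default reading of a cross-patient
#' spread); `interval = "mean_ci"` instead gives a normal-theory 95%
#' confidence interval of the mean. Undefined surface distances are excluded
#' with their count reported.
#'
#' @param per_case data.frame of [case_metrics()] rows (possibly many
#'   cases).
#' @param interval `"percentile"` or `"mean_ci"`.
#' @return object of class `cohort_report`: list with `summary` (per
#'   ROI x metric: mean, lo, hi, n, n_undefined) and `per_case`.
#' @export
aggregate_metrics <- function(per_case, interval = c("percentile", "mean_ci")) {
  interval <- match.arg(interval)
  if (!nrow(per_case)) stop("no cases to aggregate")
  metrics <- c("dice", "jaccard", "hd95_mm", "ahd_mm")
  rows <- list()
  for (roi in unique(per_case$roi)) {
    sub <- per_case[per_case$roi == roi, ]
    for (mt in metrics) {
      v <- sub[[mt]]
      ok <- !is.na(v)
      if (any(ok)) {
        vv <- v[ok]
        if (interval == "percentile") {
          lo <- quantile(vv, 0.025, type = 7, names = FALSE)
          hi <- quantile(vv, 0.975, type = 7, names = FALSE)
        } else {
          se <- if (length(vv) > 1L) stats::sd(vv) / sqrt(length(vv)) else 0
          lo <- mean(vv) - 1.96 * se
          hi <- mean(vv) + 1.96 * se
        }
        rows[[length(rows) + 1L]] <- data.frame(
          roi = roi, metric = mt, mean = mean(vv), lo = lo, hi = hi,
          n = sum(ok), n_undefined = sum(!ok), stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          roi = roi, metric = mt, mean = NA_real_, lo = NA_real_,
          hi = NA_real_, n = 0L, n_undefined = sum(!ok),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(summary = do.call(rbind, rows), per_case = per_case),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort report: %d cases\n",
              length(unique(x$per_case$patient_id))))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
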