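#' Multi-sequence volume container
#'
#' A per-patient stack of co-registered scalar volumes, one per MRI
#' sequence, on a shared `(slice, row, column)` grid with anisotropic voxel
#' spacing. Sequences are stored in the canonical order `T1w, T2w, T1wC`.
#'
#' @param patient_id identifier.
#' @param sequences named list of 3D arrays; names from `T1w, T2w, T1wC`.
#' @param spacing `(slice_thickness_mm, row_mm, col_mm)`.
#' @return object of class `multi_sequence_volume`.
#' @export
multi_sequence_volume <- function(patient_id, sequences, spacing) {
  if (!length(sequences) || !all(names(sequences) %in% SEQUENCE_NAMES)) {
    stop("unknown sequence name; expected a subset of T1w, T2w, T1wC")
  }
  sequences <- sequences[intersect(SEQUENCE_NAMES, names(sequences))]
  dims <- lapply(sequences, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1L]]))) {
    stop("sequences are not co-registered: grid shapes differ")
  }
  structure(list(patient_id = patient_id, sequences = sequences,
                 spacing = as.numeric(spacing)),
            class = "multi_sequence_volume")
}

#' ROI label volume container
#'
#' Four binary masks on the volume grid in the fixed channel order
#' left parotid, right parotid, left tumor, right tumor.
#'
#' @param masks a `(slices, height, width, 4)` array in `{0, 1}`, or a named
#'   list of four binary 3D arrays.
#' @param spacing `(slice_thickness_mm, row_mm, col_mm)`.
#' @return object of class `roi_label_volume` holding the 4-channel stack.
#' @export
roi_label_volume <- function(masks, spacing) {
  if (is.list(masks)) {
    if (!setequal(names(masks), ROI_NAMES)) {
      stop("mask list must be named with the four canonical ROIs")
    }
    arr <- array(0, c(dim(masks[[1L]]), 4L))
    for (i in seq_along(ROI_NAMES)) arr[, , , i] <- masks[[ROI_NAMES[i]]]
    masks <- arr
  }
  if (length(dim(masks)) != 4L || dim(masks)[4L] != 4L) {
    stop("masks must be a (slices, height, width, 4) array")
  }
  if (!all(masks %in% c(0, 1))) stop("label values must be strictly in {0, 1}")
  masks <- masks * 1  # coerce logical to numeric
  dimnames(masks) <- list(NULL, NULL, NULL, ROI_NAMES)
  structure(list(masks = masks, spacing = as.numeric(spacing)),
            class = "roi_label_volume")
}

nifti_write <- function(arr, spacing, path) {
  img <- RNifti::asNifti(unclass(arr))
  RNifti::pixdim(img) <- c(spacing, rep(1, length(dim(arr)) - 3L))
  RNifti::writeNifti(img, path)
  path
}

nifti_read <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim(img)), pixdim = RNifti::pixdim(img))
}

#' Write a phantom cohort as NIfTI files plus a JSON manifest
#'
#' One `.nii.gz` per sequence and one 4-channel `.nii.gz` label file per
#' case. The manifest records ids, paths, spacing, laterality and the
#' laterality-axis convention, and is the entry point for [read_case()] (the
#' same schema describes real co-registered data).
#'
#' @param cases list of `phantom_case`.
#' @param out_dir output directory.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cases, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cases, function(cs) {
    paths <- list()
    for (sq in names(cs$volume$sequences)) {
      f <- sprintf("%s_%s.nii.gz", cs$patient_id, sq)
      nifti_write(cs$volume$sequences[[sq]], cs$volume$spacing,
                  file.path(out_dir, f))
      paths[[sq]] <- f
    }
    lf <- sprintf("%s_labels.nii.gz", cs$patient_id)
    nifti_write(cs$labels$masks, cs$labels$spacing, file.path(out_dir, lf))
    list(patient_id = cs$patient_id, sequences = paths, labels = lf,
         spacing = cs$volume$spacing,
         laterality = cs$spec$laterality %||% NA_character_)
  })
  manifest <- list(
    convention = "arrays indexed (slice, row, col); anatomical-left at high column index (radiological display)",
    roi_order = ROI_NAMES,
    cases = entries
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a cohort manifest
#'
#' @param path path to a `manifest.json` written by [write_cohort()].
#' @return the parsed manifest with an attribute `dir` (its directory).
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path)
  attr(m, "dir") <- dirname(path)
  m
}

#' Read one case from a manifest entry
#'
#' Loads the listed sequence volumes and masks, validates co-registration
#' (identical grids), reads spacing from the NIfTI headers and canonicalizes
#' channel order. Masks are accepted either as one 4-channel file (`labels`)
#' or four binary files (`labels` as a named list).
#'
#' @param entry one element of a manifest's `cases` list.
#' @param dir directory that file names are relative to.
#' @param sequences sequences to load (default: all listed).
#' @return list with `volume` ([multi_sequence_volume()]) and `labels`
#'   ([roi_label_volume()]).
#' @export
read_case <- function(entry, dir = ".", sequences = NULL) {
  listed <- names(entry$sequences)
  sequences <- sequences %||% listed
  missing_seq <- setdiff(sequences, listed)
  if (length(missing_seq)) {
    stop(sprintf("case %s is missing requested sequence(s): %s",
                 entry$patient_id, paste(missing_seq, collapse = ", ")))
  }
  vols <- list(); pd <- NULL; shape <- NULL
  for (sq in sequences) {
    nf <- nifti_read(file.path(dir, entry$sequences[[sq]]))
    if (is.null(shape)) {
      shape <- dim(nf$data); pd <- nf$pixdim
    } else if (!identical(dim(nf$data), shape)) {
      stop(sprintf("case %s: sequence %s is not on the shared grid (registration error)",
                   entry$patient_id, sq))
    }
    vols[[sq]] <- nf$data
  }
  spacing <- pd[1:3]
  if (is.list(entry$labels)) {
    masks <- lapply(entry$labels, function(f) {
      arr <- nifti_read(file.path(dir, f))$data
      check_binary(arr)
      arr
    })
    names(masks) <- names(entry$labels)
    labels <- roi_label_volume(masks, spacing)
  } else {
    arr <- nifti_read(file.path(dir, entry$labels))$data
    check_binary(arr)
    labels <- roi_label_volume(arr, spacing)
  }
  if (!identical(dim(labels$masks)[1:3], shape)) {
    stop(sprintf("case %s: label grid does not match the volume grid", entry$patient_id))
  }
  list(patient_id = entry$patient_id,
       volume = multi_sequence_volume(entry$patient_id, vols, spacing),
       labels = labels)
}

check_binary <- function(arr) {
  if (!all(arr %in% c(0, 1))) {
    stop("label file contains values outside {0, 1}")
  }
  invisible(TRUE)
}

#' Normalize volume intensities to [0, 1]
#'
#' Per-volume min--max scaling `x' = (x - min) / (max - min)`, mapping the
#' intensity midpoint to 0.5; a constant-valued volume maps to 0.5
#' everywhere. Applied per sequence, per patient, so inter-slice intensities
#' stay consistent within a volume. Idempotent, and invariant to positive
#' affine rescaling of the input.
#'
#' @param x numeric array with finite values.
#' @return array of the same shape with values in `[0, 1]`.
#' @export
normalize_intensity <- function(x) {
  if (!length(x)) stop("empty volume")
  if (!all(is.finite(x))) stop("volume contains non-finite values")
  rng <- range(x)
  if (rng[1L] == rng[2L]) {
    out <- x
    out[] <- 0.5
    return(out)
  }
  (x - rng[1L]) / (rng[2L] - rng[1L])
}

grid_fit_axis <- function(n, target) {
  if (n >= target) {
    start <- (n - target) %/% 2L
    list(src = (start + 1L):(start + target), dst = seq_len(target))
  } else {
    off <- (target - n) %/% 2L
    list(src = seq_len(n), dst = (off + 1L):(off + n))
  }
}

#' Fit a slice (and its label) to the model's square input grid
#'
#' Center-crops axes larger than `target_size` and symmetrically zero-pads
#' axes smaller than it, applying the identical transform to image and
#' label. The returned `mapping` lets [fit_to_grid_inverse()] place
#' predictions back on the native grid.
#'
#' @param image `(H, W, C)` array (2D input is treated as one channel).
#' @param label optional `(H, W, 4)` binary array.
#' @param target_size side length of the model input.
#' @return list with `image`, `label`, `mapping`.
#' @export
fit_to_grid <- function(image, label = NULL, target_size) {
  if (length(dim(image) %||% integer()) == 0L) stop("image must be a matrix or array")
  if (length(dim(image)) == 2L) dim(image) <- c(dim(image), 1L)
  d <- dim(image)
  rows <- grid_fit_axis(d[1L], target_size)
  cols <- grid_fit_axis(d[2L], target_size)
  place <- function(arr) {
    out <- array(0, c(target_size, target_size, dim(arr)[3L]))
    out[rows$dst, cols$dst, ] <- arr[rows$src, cols$src, , drop = FALSE]
    out
  }
  mapping <- list(native_shape = d[1:2], rows = rows, cols = cols,
                  target_size = target_size)
  list(image = place(image),
       label = if (!is.null(label)) place(label),
       mapping = mapping)
}

#' @rdname fit_to_grid
#' @param prediction `(target_size, target_size, C)` array on the model grid.
#' @param mapping the `mapping` returned by `fit_to_grid`.
#' @export
fit_to_grid_inverse <- function(prediction, mapping) {
  if (length(dim(prediction)) == 2L) dim(prediction) <- c(dim(prediction), 1L)
  out <- array(0, c(mapping$native_shape, dim(prediction)[3L]))
  out[mapping$rows$src, mapping$cols$src, ] <-
    prediction[mapping$rows$dst, mapping$cols$dst, , drop = FALSE]
  out
}

#' Build the axial slice dataset for training
#'
#' Normalizes every sequence volume to `[0, 1]`, then turns every axial
#' slice of every case into one training sample whose image channels are the
#' requested sequences in canonical order. No inter-slice resampling is
#' performed (the native anisotropic grid is kept); when `input_size` is
#' given each slice is fitted to the square model grid.
#'
#' @param cases list of cases (each with `patient_id`, `volume`, `labels`).
#' @param sequences nonempty subset of `T1w, T2w, T1wC`.
#' @param input_size optional model input side length.
#' @return list of slice samples: `image` `(H, W, C)`, `label` `(H, W, 4)`,
#'   `patient_id`, `slice_index`, `spacing` (row/col mm), `mapping`.
#' @export
make_slice_dataset <- function(cases, sequences = SEQUENCE_NAMES,
                               input_size = NULL) {
  if (!length(sequences)) stop("sequence subset must be nonempty")
  if (!all(sequences %in% SEQUENCE_NAMES)) stop("unknown sequence name")
  sequences <- intersect(SEQUENCE_NAMES, sequences)  # canonical channel order
  samples <- list()
  for (cs in cases) {
    have <- names(cs$volume$sequences)
    missing_seq <- setdiff(sequences, have)
    if (length(missing_seq)) {
      stop(sprintf("case %s is missing sequence(s): %s", cs$patient_id,
                   paste(missing_seq, collapse = ", ")))
    }
    norm <- lapply(cs$volume$sequences[sequences], normalize_intensity)
    gs <- dim(norm[[1L]])
    for (s in seq_len(gs[1L])) {
      img <- array(0, c(gs[2L], gs[3L], length(sequences)))
      for (ci in seq_along(sequences)) img[, , ci] <- norm[[ci]][s, , ]
      lab <- if (is.null(cs$labels)) array(0, c(gs[2L], gs[3L], 4L)) else
        array(cs$labels$masks[s, , , ], c(gs[2L], gs[3L], 4L))
      mapping <- NULL
      if (!is.null(input_size)) {
        ft <- fit_to_grid(img, lab, input_size)
        img <- ft$image; lab <- ft$label; mapping <- ft$mapping
      }
      samples[[length(samples) + 1L]] <- list(
        image = img, label = lab, patient_id = cs$patient_id,
        slice_index = s, spacing = cs$volume$spacing[2:3], mapping = mapping)
    }
  }
  samples
}
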