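#' Segment a full case with a trained model
#'
#' Preprocesses the case exactly as in training (per-volume intensity
#' normalization, slice extraction, grid fitting), runs per-slice forward
#' passes in inference mode, thresholds the sigmoid outputs and maps the
#' binary masks back onto the native grid through the recorded grid-fit
#' inverse.
#'
#' @param model a trained `parotid_unet`.
#' @param case a case list with `volume` (and optionally `labels`).
#' @param threshold probability threshold for foreground (default 0.5).
#' @param sequences sequence subset matching the model's input channels;
#'   defaults to all sequences present in the case.
#' @param batch_size slices per forward pass.
#' @return a [roi_label_volume()] of predicted masks on the native grid.
#' @export
predict_case <- function(model, case, threshold = 0.5, sequences = NULL,
                         batch_size = 8L) {
  sequences <- sequences %||% intersect(SEQUENCE_NAMES, names(case$volume$sequences))
  if (length(sequences) != model$config$in_channels) {
    stop(sprintf("model expects %d input channels but %d sequences were selected",
                 model$config$in_channels, length(sequences)))
  }
  samples <- make_slice_dataset(list(case), sequences = sequences,
                                input_size = model$config$input_size)
  gs <- dim(case$volume$sequences[[1L]])
  out <- array(0, c(gs, model$config$out_channels))
  for (i in seq(1L, length(samples), by = batch_size)) {
    batch <- samples[i:min(i + batch_size - 1L, length(samples))]
    sb <- stack_samples(batch)
    prob <- unet_forward(model, sb$x, train = FALSE)$y
    for (k in seq_along(batch)) {
      bin <- (prob[, , , k] >= threshold) * 1
      native <- fit_to_grid_inverse(bin, batch[[k]]$mapping)
      out[batch[[k]]$slice_index, , , ] <- native
    }
  }
  roi_label_volume(out, case$volume$spacing)
}
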