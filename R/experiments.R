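# Sequence-ablation orchestration, the pluggable model registry and report
# writing.

#' Default sequence-ablation plan
#'
#' The seven input-channel combinations evaluated against each other: each
#' single sequence, each pair, and the full three-sequence model.
#'
#' @return named list of sequence subsets (names join the sequences with
#'   `+`).
#' @export
default_ablation_plan <- function() {
  subsets <- list(c("T1w"), c("T2w"), c("T1wC"),
                  c("T1w", "T2w"), c("T1w", "T1wC"), c("T2w", "T1wC"),
                  c("T1w", "T2w", "T1wC"))
  names(subsets) <- vapply(subsets, paste, "", collapse = "+")
  subsets
}

validate_plan <- function(plan) {
  if (!length(plan)) stop("ablation plan is empty")
  keys <- vapply(plan, function(s) paste(sort(s), collapse = "+"), "")
  if (anyDuplicated(keys)) stop("ablation plan has duplicate combinations")
  for (s in plan) {
    if (!length(s) || !all(s %in% SEQUENCE_NAMES)) {
      stop("ablation subsets must be nonempty subsets of the canonical sequences")
    }
  }
  invisible(TRUE)
}

#' Run the sequence-ablation experiment
#'
#' One cross-validation run per channel combination (the model's input
#' channel count follows the subset size), with shared fold splits and
#' seeds so combinations are compared on identical partitions. A
#' combination whose required sequence is absent from the cohort is
#' recorded as failed and the run continues.
#'
#' @param cases phantom (or real) cohort.
#' @param plan list of sequence subsets, see [default_ablation_plan()].
#' @param model_config base [model_config()]; `in_channels` is overridden
#'   per combination.
#' @param config a [train_config()].
#' @param augment optional [augment_config()].
#' @param metric_opts passed to [case_metrics()].
#' @return object of class `ablation_result`: list with `reports` (named
#'   cohort reports, `NULL` where failed), `errors` (named messages) and
#'   `table` (rows = combination, columns = ROI x metric means).
#' @export
run_ablation <- function(cases, plan = default_ablation_plan(),
                         model_config = NULL, config = train_config(),
                         augment = NULL, metric_opts = list()) {
  validate_plan(plan)
  if (is.null(names(plan))) {
    names(plan) <- vapply(plan, paste, "", collapse = "+")
  }
  reports <- list(); errors <- list()
  for (nm in names(plan)) {
    subset <- plan[[nm]]
    mc <- model_config
    mc$in_channels <- length(subset)
    reports[[nm]] <- tryCatch(
      run_cross_validation(cases, mc, config, augment = augment,
                           sequences = subset, metric_opts = metric_opts),
      error = function(e) {
        errors[[nm]] <<- conditionMessage(e)
        NULL
      })
  }
  structure(list(reports = reports, errors = errors,
                 table = ablation_table(reports)),
            class = "ablation_result")
}

# Table-shaped summary: one row per combination, columns roi.metric means.
ablation_table <- function(reports) {
  rows <- list()
  for (nm in names(reports)) {
    rep <- reports[[nm]]
    if (is.null(rep)) next
    s <- rep$summary
    vals <- stats::setNames(s$mean, paste(s$roi, s$metric, sep = "."))
    rows[[nm]] <- as.data.frame(c(list(combination = nm), as.list(vals)),
                                check.names = FALSE)
  }
  if (!length(rows)) return(data.frame(combination = character()))
  do.call(rbind, rows)
}

# ---- model registry ------------------------------------------------------

.model_registry <- new.env(parent = emptyenv())

#' Register a model builder under a name
#'
#' The registry is the comparison slot for alternative architectures: a
#' builder is any `function(config, seed)` returning a model usable by the
#' training loop. The two gate wirings of the package's network are
#' pre-registered as `attention_unet.bottleneck` and
#' `attention_unet.adjacent_decoder`.
#'
#' @param name unique registry key.
#' @param builder `function(config, seed)`.
#' @return invisibly, the name.
#' @export
register_model <- function(name, builder) {
  if (name %in% ls(.model_registry)) {
    stop(sprintf("model '%s' is already registered", name))
  }
  stopifnot(is.function(builder))
  assign(name, builder, envir = .model_registry)
  invisible(name)
}

#' @rdname register_model
#' @export
get_model_builder <- function(name) {
  if (!name %in% ls(.model_registry)) {
    stop(sprintf("no model registered under '%s'; known: %s", name,
                 paste(list_models(), collapse = ", ")))
  }
  get(name, envir = .model_registry)
}

#' @rdname register_model
#' @export
list_models <- function() sort(ls(.model_registry))

register_builtin_models <- function() {
  if (!"attention_unet.bottleneck" %in% ls(.model_registry)) {
    register_model("attention_unet.bottleneck", function(config, seed = 1L) {
      config$gate_source <- "bottleneck"
      build_model(config, seed)
    })
    register_model("attention_unet.adjacent_decoder", function(config, seed = 1L) {
      config$gate_source <- "adjacent_decoder"
      build_model(config, seed)
    })
  }
  invisible(NULL)
}

# ---- report writing ------------------------------------------------------

#' Write cohort reports to disk
#'
#' Writes a per-case CSV (one row per patient and ROI), a summary CSV and a
#' JSON summary with deterministic file naming; accepts a single cohort
#' report, a named list of them, or an `ablation_result`.
#'
#' @param reports a `cohort_report`, a named list of them, or an
#'   `ablation_result`.
#' @param out_dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(reports, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(reports, "ablation_result")) reports <- reports$reports
  if (inherits(reports, "cohort_report")) reports <- list(run = reports)
  if (!length(reports)) stop("no reports to write")
  per_case <- list(); summaries <- list()
  for (nm in names(reports)) {
    rep <- reports[[nm]]
    if (is.null(rep)) next
    pc <- rep$per_case; pc$run <- nm
    sm <- rep$summary; sm$run <- nm
    per_case[[nm]] <- pc
    summaries[[nm]] <- sm
  }
  paths <- c(file.path(out_dir, "per_case.csv"),
             file.path(out_dir, "summary.csv"),
             file.path(out_dir, "summary.json"))
  write.csv(do.call(rbind, per_case), paths[1L], row.names = FALSE)
  summary_df <- do.call(rbind, summaries)
  write.csv(summary_df, paths[2L], row.names = FALSE)
  jsonlite::write_json(summary_df, paths[3L], dataframe = "rows", digits = NA,
                       na = "null")
  invisible(paths)
}
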