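#' Write a recording to a directory
#'
#' One CSV per channel plus a JSON metadata sidecar:
#' `<subject>_piezo.csv` (column `piezo`), `<subject>_accel.csv` (columns
#' `ax`, `ay`, `az`), `<subject>_annotation.csv` (column `annotation`), and
#' `<subject>_meta.json` holding sampling rates, the generator profile and
#' the activity schedule.
#'
#' @param rec a `sensor_recording`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir) {
  validate_recording(rec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- rec$subject_id
  fp <- function(suffix) file.path(dir, paste0(id, "_", suffix))
  data.table::fwrite(data.table::data.table(piezo = rec$piezo), fp("piezo.csv"))
  data.table::fwrite(data.table::as.data.table(rec$accel), fp("accel.csv"))
  data.table::fwrite(data.table::data.table(annotation = rec$annotation),
                     fp("annotation.csv"))
  meta <- list(
    subject_id = id,
    fs_piezo = rec$metadata$fs_piezo,
    fs_acc = rec$metadata$fs_acc,
    profile = rec$metadata$profile,
    schedule = as.data.frame(rec$schedule)
  )
  jsonlite::write_json(meta, fp("meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a recording written by [write_recording()]
#'
#' @param dir directory containing the channel CSVs and metadata sidecar.
#' @param subject_id the subject whose files to read.
#' @return a `sensor_recording`.
#' @export
read_recording <- function(dir, subject_id) {
  fp <- function(suffix) file.path(dir, paste0(subject_id, "_", suffix))
  for (f in c("piezo.csv", "accel.csv", "annotation.csv", "meta.json")) {
    if (!file.exists(fp(f))) stop("missing file: ", fp(f), call. = FALSE)
  }
  meta <- jsonlite::read_json(fp("meta.json"), simplifyVector = TRUE)
  accel <- as.matrix(data.table::fread(fp("accel.csv")))
  sched <- activity_schedule(meta$schedule$label, meta$schedule$duration)
  rec <- structure(
    list(subject_id = meta$subject_id,
         piezo = data.table::fread(fp("piezo.csv"))$piezo,
         accel = accel,
         annotation = as.integer(data.table::fread(fp("annotation.csv"))$annotation),
         schedule = sched,
         metadata = list(fs_piezo = meta$fs_piezo, fs_acc = meta$fs_acc,
                         profile = meta$profile)),
    class = "sensor_recording"
  )
  validate_recording(rec)
  rec
}

#' List the subjects present in a recording directory
#'
#' @param dir directory of recordings.
#' @return character vector of subject ids.
#' @export
list_subjects <- function(dir) {
  metas <- list.files(dir, pattern = "_meta\\.json$")
  sort(sub("_meta\\.json$", "", metas))
}

#' Write / read a feature table
#'
#' CSV with header `subject,epoch,label,p_rng,p_std,p_eng,p_wl,a_rng,a_std,
#' a_eng,a_wl`.
#'
#' @param features feature table from [featurize_cohort()].
#' @param path CSV file path.
#' @return `path` (write) or the feature table (read).
#' @export
write_features <- function(features, path) {
  data.table::fwrite(features, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  need <- c("subject", "epoch", "label", feature_columns())
  if (!all(need %in% names(df))) {
    stop("feature file lacks required columns", call. = FALSE)
  }
  df$subject <- as.character(df$subject)
  df$label <- as.integer(df$label)
  df
}

#' Serialize / deserialize trained models as JSON
#'
#' Stores weights, bias and the training-fold standardization statistics, so
#' a model can be reloaded and applied elsewhere.
#'
#' @param model a `linear_model`, `ova_model` or `two_stage_model`.
#' @param path JSON file path.
#' @return `path` (write) or the model (read).
#' @export
write_model <- function(model, path) {
  ser_lm <- function(m) list(weights = m$weights, bias = m$bias,
                             center = as.list(m$center),
                             scale = as.list(m$scale), C = m$C)
  obj <- switch(class(model)[1],
    linear_model = list(type = "linear", model = ser_lm(model)),
    ova_model = list(type = "ova", C = model$C,
                     models = lapply(model$models, ser_lm)),
    two_stage_model = list(type = "two_stage", C = model$C,
                           chew_model = ser_lm(model$chew_model),
                           activity_model = ser_lm(model$activity_model)),
    stop("unknown model class", call. = FALSE)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  de_lm <- function(m) structure(
    list(weights = as.numeric(m$weights), bias = m$bias,
         center = unlist(m$center), scale = unlist(m$scale), C = m$C),
    class = "linear_model")
  switch(obj$type,
    linear = de_lm(obj$model),
    ova = structure(list(models = lapply(obj$models, de_lm), C = obj$C),
                    class = "ova_model"),
    two_stage = structure(list(chew_model = de_lm(obj$chew_model),
                               activity_model = de_lm(obj$activity_model),
                               C = obj$C),
                          class = "two_stage_model"),
    stop("unknown model type in ", path, call. = FALSE)
  )
}
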