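# File I/O: recordings travel as a CSV of samples (`time` + one column per
# channel) with a JSON sidecar carrying sampling rate, channel roles,
# annotations, provenance (config hash + seed). Datasets add a JSON
# manifest listing members.

# Small stable content hash (FNV-1a over the serialized object) used to
# stamp artifacts with the configuration that produced them.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%08x", as.integer(h %% 2147483647))
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Write a recording to CSV + JSON sidecar
#'
#' The CSV holds `time` plus one column per channel; the JSON sidecar
#' holds sampling rate, channel roles, annotations, label/subject and a
#' provenance stamp (content hash, optional seed).
#'
#' @param recording An `ssi_recording` with at least one sample.
#' @param path Output CSV path (the sidecar replaces `.csv` with
#'   `.json`).
#' @param seed Optional seed recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, seed = NULL) {
  stopifnot(inherits(recording, "ssi_recording"))
  if (nrow(recording$channels) == 0L) abort("Refusing to write an empty recording.")
  n <- nrow(recording$channels)
  df <- data.frame(time = (seq_len(n) - 1) / recording$sampling_rate,
                   recording$channels, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(
    schema_version = 1L,
    sampling_rate = recording$sampling_rate,
    channels = as.list(stats::setNames(recording$channel_roles,
                                       colnames(recording$channels))),
    annotations = recording$annotations,
    subject = recording$subject,
    label = recording$label,
    config_hash = config_hash(list(recording$channel_roles,
                                   recording$sampling_rate, n)),
    seed = seed
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", null = "null")
  invisible(path)
}

#' Read a recording from CSV + JSON sidecar
#'
#' @param path CSV path written by [write_recording()] (a `.json` sidecar
#'   with sampling rate and channel roles must sit next to it).
#' @return An `ssi_recording`.
#' @export
read_recording <- function(path) {
  side <- sidecar_path(path)
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  if (!file.exists(side)) {
    abort(sprintf("Missing JSON sidecar for %s (expected %s).", path, side))
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$sampling_rate)) abort("Sidecar lacks `sampling_rate`.")
  if (is.null(meta$channels)) abort("Sidecar lacks `channels` roles.")
  df <- utils::read.csv(path, check.names = FALSE)
  ch_names <- names(meta$channels)
  missing_ch <- setdiff(ch_names, names(df))
  if (length(missing_ch)) {
    abort(sprintf("CSV lacks channel column(s): %s.",
                  paste(missing_ch, collapse = ", ")))
  }
  if ("time" %in% names(df) && nrow(df) > 1L) {
    rate_csv <- 1 / stats::median(diff(df$time))
    if (abs(rate_csv - meta$sampling_rate) / meta$sampling_rate > 0.01) {
      abort(sprintf(
        "`sampling_rate`: sidecar says %g Hz but CSV time column implies %g Hz.",
        meta$sampling_rate, rate_csv))
    }
  }
  ann <- meta$annotations
  if (!is.null(ann) && NROW(ann) == 0L) ann <- NULL
  new_recording(as.matrix(df[, ch_names, drop = FALSE]),
                channel_roles = unname(unlist(meta$channels)),
                sampling_rate = meta$sampling_rate,
                annotations = ann,
                subject = meta$subject %||% NA_character_,
                label = meta$label %||% NA_character_)
}

#' Write a phoneme dataset to a directory
#'
#' One CSV + sidecar per recording plus a `manifest.json` listing paths,
#' labels, subjects and the generating seed.
#'
#' @param dataset An `ssi_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ssi_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(dataset$recordings), function(i) {
    p <- file.path(dir, sprintf("sample_%03d.csv", i))
    write_recording(dataset$recordings[[i]], p,
                    seed = dataset$config$seed %||% NULL)
    basename(p)
  }, character(1))
  manifest <- list(schema_version = 1L,
                   samples = data.frame(path = paths,
                                        label = dataset$index$label,
                                        subject = dataset$index$subject),
                   seed = dataset$config$seed %||% NULL,
                   config_hash = config_hash(dataset$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Read a phoneme dataset directory
#'
#' @param dir Directory written by [write_dataset()].
#' @return An `ssi_dataset`.
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) abort(sprintf("No manifest.json in %s.", dir))
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  samples <- manifest$samples
  missing_f <- !file.exists(file.path(dir, samples$path))
  if (any(missing_f)) {
    abort(sprintf("Manifest references missing file(s): %s.",
                  paste(samples$path[missing_f], collapse = ", ")))
  }
  recordings <- lapply(file.path(dir, samples$path), read_recording)
  structure(list(recordings = recordings,
                 index = tibble::tibble(id = seq_len(nrow(samples)),
                                        label = samples$label,
                                        subject = samples$subject),
                 config = list(seed = manifest$seed)),
            class = "ssi_dataset")
}

log_msg <- function(level, module, ...) {
  message(sprintf("[%s] %s %s: %s", level,
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), module,
                  sprintf(...)))
}
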