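# Dataset container: a single-file, schema-versioned store for one or more
# epoched sessions, built on R's native serialization. Every session must
# share the sampling rate and channel count; invariants are re-validated on
# load so a truncated or foreign file fails loudly rather than partially.

CONTAINER_SCHEMA <- "eegclfcnet-container"
CONTAINER_VERSION <- "1.0"

#' Write a dataset container
#'
#' @param recordings A single [eeg_recording()] or a named list of them.
#'   All sessions must share `fs` and channel count.
#' @param path Output file path.
#' @param attrs Optional named list of global attributes (e.g. the
#'   creation seed).
#' @return Invisibly, `path`.
#' @export
write_container <- function(recordings, path, attrs = list()) {
  if (inherits(recordings, "eeg_recording")) {
    recordings <- list(session1 = recordings)
  }
  check_that(length(recordings) >= 1L && !is.null(names(recordings)),
             "recordings must be a named list", "validation_error")
  for (rec in recordings) validate_recording(rec)
  fs <- vapply(recordings, function(r) r$fs, numeric(1))
  nch <- vapply(recordings, function(r) dim(r$signals)[2], integer(1))
  check_that(length(unique(fs)) == 1L,
             "all sessions must share the same sampling rate",
             "validation_error")
  check_that(length(unique(nch)) == 1L,
             "all sessions must share the same channel count",
             "validation_error")
  obj <- list(schema = CONTAINER_SCHEMA, version = CONTAINER_VERSION,
              fs = fs[[1]], n_channels = nch[[1]],
              montage = recordings[[1]]$channel_names,
              attrs = attrs, sessions = lapply(recordings, unclass))
  ok <- tryCatch({
    saveRDS(obj, path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    clfc_error(sprintf("cannot write container to %s: %s",
                       path, conditionMessage(ok)), "io_error")
  }
  clfc_log("debug", "wrote container ", path, " (",
           length(recordings), " session(s))")
  invisible(path)
}

#' Read a dataset container
#'
#' All recording invariants are re-validated on load; schema or version
#' mismatches raise explicit errors naming the problem.
#'
#' @param path Container file path.
#' @return Object of class `eeg_container`: named list of sessions plus
#'   global attributes.
#' @export
read_container <- function(path) {
  check_that(file.exists(path), sprintf("no such file: %s", path),
             "io_error")
  obj <- tryCatch(readRDS(path), error = function(e) {
    clfc_error(sprintf("cannot parse %s as a container (%s)",
                       path, conditionMessage(e)), "schema_error")
  })
  if (!is.list(obj) || !identical(obj$schema, CONTAINER_SCHEMA)) {
    clfc_error(sprintf("%s is missing the container schema marker", path),
               "schema_error")
  }
  if (is.null(obj$version)) {
    clfc_error("container has no schema version", "schema_error")
  }
  if (!identical(obj$version, CONTAINER_VERSION)) {
    clfc_error(sprintf("unsupported container version %s (expected %s)",
                       obj$version, CONTAINER_VERSION), "version_error")
  }
  for (key in c("fs", "n_channels", "sessions")) {
    if (is.null(obj[[key]])) {
      clfc_error(sprintf("container is missing required key '%s'", key),
                 "schema_error")
    }
  }
  sessions <- lapply(obj$sessions, function(s) {
    rec <- structure(s, class = "eeg_recording")
    validate_recording(rec)
    rec
  })
  structure(list(sessions = sessions, fs = obj$fs,
                 n_channels = obj$n_channels, montage = obj$montage,
                 attrs = obj$attrs, version = obj$version),
            class = "eeg_container")
}

#' @export
print.eeg_container <- function(x, ...) {
  cat(sprintf("<eeg_container> v%s: %d session(s), %d channels @ %g Hz\n",
              x$version, length(x$sessions), x$n_channels, x$fs))
  invisible(x)
}
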