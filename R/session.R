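# Session container: the published record layout holds one sample-by-channel
# matrix (iEMG channels in mV, raw force channels in V, the movement-code
# stream and the presented cue level), the channel labels, the movement code
# table and the sampling rate -- elements .Data/.Channels/.Movements/.fs.

iemg_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL, ...)))
}

#' Multi-channel session record
#'
#' Container for one recording session: a sample-by-channel data matrix, its
#' channel labels, the movement-code table and the sampling rate.  Channel
#' roles follow the label convention used throughout the package: labels
#' starting with `force_` are raw force-sensor channels (volts), the labels
#' `movement_code` and `cue` are the protocol streams, everything else is an
#' iEMG channel (mV).
#'
#' @param data numeric matrix, samples in rows, channels in columns.
#' @param channels character vector of labels, one per column.
#' @param movements data frame with columns `code` and `description`; default
#'   is the full protocol table ([movement_table()]).
#' @param fs sampling rate in Hz (the database records use 10240 Hz).
#' @return object of class `session_record`.
#' @export
session_record <- function(data, channels, movements = movement_table(),
                           fs = 10240) {
  data <- unname(as.matrix(data))
  channels <- as.character(channels)
  if (ncol(data) != length(channels))
    iemg_error("iemg_integrity_error",
               sprintf("channel label count (%d) does not match data columns (%d)",
                       length(channels), ncol(data)))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    iemg_error("iemg_integrity_error", "fs must be a positive scalar")
  if (!all(c("code", "description") %in% names(movements)))
    iemg_error("iemg_integrity_error",
               "movements table needs 'code' and 'description' columns")
  rec <- structure(list(data = data, channels = channels,
                        movements = movements[, c("code", "description")],
                        fs = fs),
                   class = "session_record")
  mv <- movement_stream(rec, required = FALSE)
  if (!is.null(mv)) {
    t100 <- code100(movements$code)
    seen <- setdiff(unique(code100(mv)), 0L)
    base <- (seen %/% 10L) * 10L
    bad <- seen[!(seen %in% t100 | base %in% t100)]
    if (length(bad))
      iemg_error("iemg_integrity_error",
                 paste("movement-code stream holds codes absent from the",
                       "movements table:",
                       paste(sprintf("%.2f", bad / 100), collapse = ", ")))
  }
  rec
}

channel_index <- function(rec, pattern, required = TRUE, what = pattern) {
  idx <- grep(pattern, rec$channels)
  if (required && !length(idx))
    iemg_error("iemg_integrity_error",
               paste0("no channel matching '", what, "' in record"))
  idx
}

#' Channel-role accessors
#'
#' Identify columns of a [session_record()] by role using the package's label
#' convention (configurable patterns): `iemg_channels()` returns the indices
#' of the iEMG columns, `force_channel_index()` those of the raw force
#' columns, and `movement_stream()` / `cue_stream()` extract the protocol
#' streams.
#'
#' @param rec a `session_record`.
#' @param force_pattern,movement_pattern,cue_pattern regular expressions
#'   matched against the channel labels.
#' @param required error (rather than return `NULL`) when absent.
#' @return column indices, or a numeric stream for the `_stream` accessors.
#' @export
iemg_channels <- function(rec, force_pattern = "^force_",
                          movement_pattern = "^movement",
                          cue_pattern = "^cue") {
  other <- c(grep(force_pattern, rec$channels),
             grep(movement_pattern, rec$channels),
             grep(cue_pattern, rec$channels))
  setdiff(seq_along(rec$channels), other)
}

#' @rdname iemg_channels
#' @export
force_channel_index <- function(rec, force_pattern = "^force_") {
  channel_index(rec, force_pattern, required = FALSE)
}

#' @rdname iemg_channels
#' @export
movement_stream <- function(rec, movement_pattern = "^movement",
                            required = TRUE) {
  idx <- channel_index(rec, movement_pattern, required, "movement_code")
  if (!length(idx)) return(NULL)
  rec$data[, idx[1]]
}

#' @rdname iemg_channels
#' @export
cue_stream <- function(rec, cue_pattern = "^cue", required = TRUE) {
  idx <- channel_index(rec, cue_pattern, required, "cue")
  if (!length(idx)) return(NULL)
  rec$data[, idx[1]]
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("Session record: %d samples x %d channels at %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs))
  cat("  iEMG channels: ",
      paste(x$channels[iemg_channels(x)], collapse = ", "), "\n", sep = "")
  fi <- force_channel_index(x)
  if (length(fi))
    cat("  force channels:", paste(x$channels[fi], collapse = ", "), "\n")
  invisible(x)
}

#' Read or write a session record file
#'
#' `save_session()` stores a [session_record()] in the published MAT-file
#' layout with top-level elements `Data` (sample-by-channel matrix),
#' `Channels` (cell of labels), `Movements` (n-by-2 cell of code/description
#' pairs) and `fs`.  `load_session()` reads such a file back; a file whose
#' single variable is a struct with those fields is also accepted.  Column
#' order is preserved.
#'
#' @param rec a `session_record`.
#' @param path file path.
#' @return `load_session()` returns a `session_record`; `save_session()`
#'   returns `path` invisibly.
#' @export
save_session <- function(rec, path) {
  stopifnot(inherits(rec, "session_record"))
  write_mat(list(Data = rec$data,
                 Channels = rec$channels,
                 Movements = data.frame(code = rec$movements$code,
                                        description = rec$movements$description),
                 fs = rec$fs),
            path)
  invisible(path)
}

#' @rdname save_session
#' @export
load_session <- function(path) {
  vars <- read_mat(path)
  if (length(vars) == 1L && is.list(vars[[1]]) &&
      any(c("Data", "fs") %in% names(vars[[1]])))
    vars <- vars[[1]]
  for (el in c("Data", "Channels", "Movements", "fs"))
    if (is.null(vars[[el]]))
      iemg_error("iemg_format_error",
                 paste0("session file is missing element '", el, "'"),
                 element = el)
  movements <- parse_movement_cell(vars$Movements)
  session_record(data = vars$Data,
                 channels = unlist(vars$Channels),
                 movements = movements,
                 fs = as.numeric(vars$fs)[1])
}

parse_movement_cell <- function(m) {
  if (is.data.frame(m)) return(m)
  if (is.list(m)) {
    if (!is.null(dim(m)) && length(dim(m)) == 2L && dim(m)[2] >= 2L) {
      data.frame(code = as.numeric(unlist(m[, 1])),
                 description = as.character(unlist(m[, 2])))
    } else if (all(c("code", "description") %in% names(m))) {
      data.frame(code = as.numeric(unlist(m$code)),
                 description = as.character(unlist(m$description)))
    } else {
      iemg_error("iemg_format_error",
                 "Movements element is not a two-column code/description table",
                 element = "Movements")
    }
  } else {
    iemg_error("iemg_format_error",
               "Movements element is not a two-column code/description table",
               element = "Movements")
  }
}
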