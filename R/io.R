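# ---- file formats: tidy CSV tables, raw float binary + JSON sidecar ----

#' Write a tidy performance table
#'
#' Columns: subject, group, trial, position, iki_ms, kvel, score.
#'
#' @param perf data.frame in the tidy performance layout.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_performance_csv <- function(perf, path) {
  need <- c("subject", "group", "trial", "position", "iki_ms", "kvel", "score")
  missing <- setdiff(need, names(perf))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  write.csv(perf[, need], path, row.names = FALSE)
  invisible(path)
}

#' Read a tidy performance table
#'
#' @param path CSV path written by [write_performance_csv()].
#' @return data.frame.
#' @export
read_performance_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a signal as raw float binary plus JSON sidecar
#'
#' The samples go to `<prefix>.bin` (little-endian float32) and the
#' metadata (`fs`, `n_samples`, `channels`, event markers as sample
#' indices) to `<prefix>.json`.
#'
#' @param x Numeric signal (single channel).
#' @param fs Sampling rate in Hz.
#' @param prefix Output path prefix.
#' @param markers Named numeric vector of event times in seconds.
#' @param channel Channel label.
#' @return The prefix, invisibly.
#' @export
write_signal <- function(x, fs, prefix, markers = NULL, channel = "ch1") {
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  meta <- list(fs = fs, n_samples = length(x), channels = list(channel))
  if (!is.null(markers)) {
    meta$markers <- lapply(as.list(markers),
                           function(t) round(t * fs) + 1)
  }
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' Read a signal written by [write_signal()]
#'
#' @param prefix Path prefix of the `.bin`/`.json` pair.
#' @return List with `signal`, `fs`, `markers` (times in s) and `channels`.
#' @export
read_signal <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = meta$n_samples, size = 4,
               endian = "little")
  markers <- if (!is.null(meta$markers)) {
    vapply(meta$markers, function(i) (i - 1) / meta$fs, numeric(1))
  } else NULL
  list(signal = x, fs = meta$fs, markers = markers,
       channels = unlist(meta$channels))
}
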