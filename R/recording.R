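# MultichannelRecording container and delimited-text I/O.

#' Multichannel recording container
#'
#' @param data real matrix (samples x channels), no missing values.
#' @param fs sampling rate (Hz).
#' @param channel_labels unique channel names; defaults to column names or
#'   `ch1, ch2, ...`.
#' @return object of class `multichannel_recording`.
#' @export
multichannel_recording <- function(data, fs, channel_labels = colnames(data)) {
  if (is.null(dim(data))) data <- matrix(data, ncol = 1L)
  data <- as.matrix(data)
  stopifnot_scalar(fs, "fs", positive = TRUE)
  if (anyNA(data)) stop("recording contains missing samples", call. = FALSE)
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(ncol(data)))
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique", call. = FALSE)
  colnames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels),
            class = "multichannel_recording")
}

#' @export
print.multichannel_recording <- function(x, ...) {
  cat(sprintf("<multichannel_recording> %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs))
  cat("channels:", paste(utils::head(x$channel_labels, 8L), collapse = ", "),
      if (ncol(x$data) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Read a recording from delimited text
#'
#' Expects one column per channel with a header row of labels. The sampling
#' rate is taken from a leading `# fs: <Hz>` comment line if present,
#' otherwise from the `fs` argument.
#'
#' @param path file path.
#' @param fs sampling rate (Hz); overrides any header comment when given.
#' @param sep field separator.
#' @return a [multichannel_recording()].
#' @export
read_recording <- function(path, fs = NULL, sep = ",") {
  first <- readLines(path, n = 1L)
  header_fs <- NULL
  if (grepl("^#\\s*fs\\s*[:=]", first))
    header_fs <- as.numeric(sub("^#\\s*fs\\s*[:=]\\s*", "", first))
  fs <- fs %||% header_fs
  if (is.null(fs)) stop("sampling rate not given and not found in header",
                        call. = FALSE)
  d <- read.table(path, header = TRUE, sep = sep, comment.char = "#",
                  check.names = FALSE)
  multichannel_recording(as.matrix(d), fs, colnames(d))
}

#' Write a recording to delimited text
#'
#' @param rec a [multichannel_recording()].
#' @param path output file path.
#' @param sep field separator.
#' @export
write_recording <- function(rec, path, sep = ",") {
  stopifnot(inherits(rec, "multichannel_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs: %.10g", rec$fs), con)
  write.table(rec$data, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
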