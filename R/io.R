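#' Save / load epoched EEG as a single-file container
#'
#' Epochs are stored in a compact single-file binary container: a magic tag,
#' a JSON metadata block (times, sampling rate, labels, pair ids, rejection
#' mask, subject id, channel names, array dimensions), then the voltage array
#' as little-endian float32. The round trip is exact on all metadata and
#' float32-lossless on voltages.
#'
#' @param epochs an [eeg_epochs] object.
#' @param path file path (conventionally `.eeg`).
#' @return `save_epochs` returns `path` invisibly; `load_epochs` returns an
#'   [eeg_epochs].
#' @export
save_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  meta <- list(
    format = "n400mvpa-epochs", version = 1L,
    dims = dim(epochs$voltages),
    channels = channel_names(epochs),
    times = epochs$times, srate = epochs$srate,
    condition = epochs$condition, pair_id = epochs$pair_id,
    rejected = epochs$rejected, subject_id = epochs$subject_id)
  hdr <- charToRaw(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("N400EPO1"), con)
  writeBin(length(hdr), con, size = 4L, endian = "little")
  writeBin(hdr, con)
  writeBin(as.numeric(epochs$voltages), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname save_epochs
#' @export
load_epochs <- function(path) {
  if (!file.exists(path))
    stop("epochs file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (!identical(magic, "N400EPO1"))
    stop("not an n400mvpa epochs container: ", path)
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!length(hlen) || hlen <= 0L) stop("corrupt epochs container: ", path)
  meta <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  n <- prod(meta$dims)
  v <- readBin(con, "numeric", n, size = 4L, endian = "little")
  if (length(v) != n) stop("corrupt epochs container (truncated): ", path)
  eeg_epochs(array(v, dim = meta$dims), times = meta$times,
             srate = meta$srate, condition = meta$condition,
             pair_id = meta$pair_id, channels = meta$channels,
             rejected = meta$rejected, subject_id = meta$subject_id)
}
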