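#' Electrode montage on the unit sphere
#'
#' A montage holds channel names and idealised 3-D electrode positions on a
#' unit sphere, distinguishing scalp channels from the mastoid reference
#' channels (and, optionally, EOG channels, which are excluded from the scalp
#' set). Positions are normalised to unit radius on construction. The package
#' ships an idealised 64-channel 10-20/10-10 layout plus left/right mastoids,
#' loadable with [default_montage()].
#'
#' @param names character vector of unique channel labels (10-20 style).
#' @param positions numeric matrix, one row per channel, columns x, y, z.
#'   Rows are renormalised to unit length.
#' @param mastoids labels of the two mastoid reference channels (may be
#'   absent from `names` if the data carry no mastoid channels).
#' @param eog optional labels of EOG channels, excluded from the scalp set.
#' @return An object of class `eeg_montage`.
#' @seealso [default_montage()], [read_montage()], [channel_neighbourhood()]
#' @export
eeg_montage <- function(names, positions, mastoids = c("M1", "M2"),
                        eog = character()) {
  names <- as.character(names)
  if (anyDuplicated(names))
    stop("channel names must be unique")
  positions <- as.matrix(positions)
  if (nrow(positions) != length(names) || ncol(positions) != 3L)
    stop("positions must be a length(names) x 3 matrix")
  if (!all(is.finite(positions)))
    stop("positions must be finite")
  nrm <- sqrt(rowSums(positions^2))
  if (any(nrm == 0))
    stop("zero-length position vector")
  positions <- positions / nrm
  rownames(positions) <- names
  colnames(positions) <- c("x", "y", "z")
  scalp <- setdiff(names, c(mastoids, eog))
  structure(
    list(names = names, positions = positions,
         mastoids = as.character(mastoids), eog = as.character(eog),
         scalp = scalp),
    class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$scalp), " scalp channels",
      if (length(intersect(x$mastoids, x$names)))
        paste0(" + mastoids (", paste(x$mastoids, collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Read a montage from a CSV file
#'
#' The file must have columns `name,x,y,z`; positions are projected to the
#' unit sphere.
#'
#' @param path CSV file path.
#' @inheritParams eeg_montage
#' @return An `eeg_montage`.
#' @export
read_montage <- function(path, mastoids = c("M1", "M2"), eog = character()) {
  if (!file.exists(path))
    stop("montage file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("montage CSV must have columns name,x,y,z")
  eeg_montage(df$name, as.matrix(df[, c("x", "y", "z")]),
              mastoids = mastoids, eog = eog)
}

#' The bundled idealised 64-channel 10-20 montage
#'
#' Unit-sphere positions for the standard 64-channel 10-20/10-10 scalp layout
#' (Fp1 ... O2) plus the two mastoids M1/M2.
#'
#' @return An `eeg_montage` with 64 scalp channels.
#' @export
default_montage <- function() {
  path <- system.file("extdata", "montage_1020_64.csv", package = "n400mvpa",
                      mustWork = TRUE)
  read_montage(path)
}

#' Scalp channel names of a montage
#' @param montage an `eeg_montage`.
#' @return Character vector of scalp channel labels.
#' @export
scalp_channels <- function(montage) {
  stopifnot(inherits(montage, "eeg_montage"))
  montage$scalp
}

#' k-nearest scalp-channel neighbourhood
#'
#' Returns the centre channel plus its `k - 1` nearest scalp channels by
#' Euclidean (chord) distance on the unit sphere. Distance ties are broken by
#' lexicographic channel name, so the result is deterministic.
#'
#' @param montage an `eeg_montage`.
#' @param center scalp channel label.
#' @param k neighbourhood size (including the centre), between 1 and the
#'   number of scalp channels.
#' @return Character vector of `k` channel names, the centre first.
#' @export
channel_neighbourhood <- function(montage, center, k) {
  stopifnot(inherits(montage, "eeg_montage"))
  if (!center %in% montage$scalp)
    stop("unknown scalp channel: ", center)
  k <- as.integer(k)
  if (k < 1L || k > length(montage$scalp))
    stop("k must be between 1 and the number of scalp channels")
  pos <- montage$positions[montage$scalp, , drop = FALSE]
  d <- sqrt(colSums((t(pos) - pos[center, ])^2))
  ord <- order(d, montage$scalp)
  montage$scalp[ord][seq_len(k)]
}

# chord distances between a point and scalp channel positions
.chord_dist <- function(positions, point) {
  sqrt(colSums((t(positions) - point)^2))
}
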