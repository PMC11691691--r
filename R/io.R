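# Native on-disk containers: epochs as a gzipped binary array with a JSON
# sidecar and a CSV trial table; RDMs and triplet responses as CSV.

#' Save an epoch set to the native container
#'
#' Writes a directory with `data.bin.gz` (little-endian doubles, trial ->
#' channel -> time order), `meta.json` (dimensions, channels, time axis) and
#' `trials.csv`. The sidecar/CSV pair keeps the metadata diff-able and
#' language-portable.
#'
#' @param epochs an `epoch_set`.
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
save_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(dim = dim(epochs$data),
               channels = epochs$channels,
               time = epochs$time,
               format = "hemidyn-epochs-v1")
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(epochs$trials, file.path(path, "trials.csv"), row.names = FALSE)
  con <- gzfile(file.path(path, "data.bin.gz"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(epochs$data), con, size = 8, endian = "little")
  invisible(path)
}

#' Load an epoch set from the native container
#'
#' @param path directory written by [save_epochs()].
#' @return an `epoch_set` identical to the one saved.
#' @export
load_epochs <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  if (!identical(meta$format, "hemidyn-epochs-v1"))
    stop("not a native epoch container: ", path)
  trials <- read.csv(file.path(path, "trials.csv"))
  con <- gzfile(file.path(path, "data.bin.gz"), "rb")
  on.exit(close(con))
  n <- prod(meta$dim)
  data <- array(readBin(con, "double", n = n, size = 8, endian = "little"),
                dim = meta$dim)
  channels <- as.data.frame(meta$channels)
  structure(list(data = data, trials = trials, channels = channels,
                 time = as.numeric(meta$time)),
            class = "epoch_set")
}

#' Import epoched data
#'
#' Reads an epoch set for decoding. Only the package's native container is
#' supported; epoched data exported from other acquisition toolchains must
#' first be converted to the native layout (binary double array + JSON
#' sidecar + CSV trial table, see [save_epochs()]). The channel table must
#' contain the cluster electrodes ([electrode_clusters()] 10-20 names) and
#' the time axis must be at 1-ms resolution.
#'
#' @param path container directory.
#' @param format only "native".
#' @return an `epoch_set`.
#' @export
import_epochs <- function(path, format = "native") {
  format <- match.arg(format)
  epochs <- load_epochs(path)
  if (any(diff(epochs$time) != 1))
    stop("epoch time axis must be at 1-ms resolution")
  for (side in c("left", "right")) {
    n_side <- sum(epochs$channels$cluster == side)
    if (n_side == 0) stop("no channels assigned to the ", side, " cluster")
    expect <- electrode_clusters(min(n_side, 6))[[side]]
    absent <- setdiff(expect, epochs$channels$name)
    if (length(absent))
      stop("missing cluster channel(s): ", paste(absent, collapse = ", "))
  }
  epochs
}

#' Write / read triplet responses as CSV
#'
#' @param responses a `triplet_responses` data.frame.
#' @param path CSV file path.
#' @return the path (write) or the responses data.frame (read).
#' @export
write_triplet_csv <- function(responses, path) {
  write.csv(as.data.frame(responses), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_triplet_csv
#' @export
read_triplet_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "trial", "stim_a", "stim_b", "stim_c", "chosen")
  missing <- setdiff(need, names(out))
  if (length(missing)) stop("triplet CSV lacks column(s): ",
                            paste(missing, collapse = ", "))
  class(out) <- c("triplet_responses", "data.frame")
  out
}

#' Write / read an RDM as a CSV matrix with stimulus-id headers
#'
#' @param rdm a square RDM matrix or `behavioral_rdm`.
#' @param path CSV file path.
#' @export
write_rdm_csv <- function(rdm, path) {
  m <- rdm_values(rdm)
  rownames(m) <- colnames(m) <- seq_len(nrow(m))
  write.csv(m, path)
  invisible(path)
}

#' @rdname write_rdm_csv
#' @export
read_rdm_csv <- function(path) {
  m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  colnames(m) <- rownames(m)
  stopifnot(nrow(m) == ncol(m))
  m
}
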