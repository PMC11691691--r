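#' Construct a neural RDM series from an array
#'
#' Wraps a stimulus x stimulus x time dissimilarity array (e.g. pairwise
#' decoding accuracies computed elsewhere) in the container used by the RSA,
#' behavior and commonality modules. The array must be symmetric in its
#' first two dimensions at every time point; the diagonal is masked.
#'
#' @param values n x n x T numeric array.
#' @param time time axis in ms (length T).
#' @param stimuli stimulus ids on the matrix axes.
#' @param split "all", "odd" or "even".
#' @param condition,hemifield,hemisphere labels.
#' @return object of class `rdm_series`.
#' @export
rdm_series <- function(values, time = seq_len(dim(values)[3]),
                       stimuli = seq_len(dim(values)[1]),
                       split = "all", condition = "single",
                       hemifield = "RVF", hemisphere = "left") {
  stopifnot(length(dim(values)) == 3, dim(values)[1] == dim(values)[2],
            length(time) == dim(values)[3], length(stimuli) == dim(values)[1])
  sym <- vapply(seq_len(dim(values)[3]), function(t) {
    m <- values[, , t]
    diag(m) <- 0
    isTRUE(all.equal(m, t(m)))
  }, logical(1))
  if (!all(sym)) stop("RDM stack must be symmetric at every time point")
  for (t in seq_len(dim(values)[3])) values[cbind(seq_along(stimuli), seq_along(stimuli), t)] <- NA_real_
  structure(list(values = values, stimuli = as.integer(stimuli),
                 time = as.numeric(time), split = split, condition = condition,
                 hemifield = hemifield, hemisphere = hemisphere,
                 n_folds = NA_integer_),
            class = "rdm_series")
}
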