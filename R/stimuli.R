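#' Construct the experimental stimulus set
#'
#' The default set reproduces the 36-stimulus design: four image exemplars of
#' each of six basic object concepts (bird, fish, tree, boat, face, tool;
#' 24 images) plus the matching word labels in two case variants per concept
#' (12 words). Reduced sets for fast simulations are obtained by restricting
#' the concepts or the exemplar/variant counts; the image/word composition is
#' preserved so modality- and concept-level model RDMs remain well defined.
#'
#' @param concepts character vector of object concepts.
#' @param n_exemplars image exemplars per concept (default 4).
#' @param n_word_variants case variants per word label (default 2).
#' @return data.frame of class `stimulus_set` with columns `stimulus_id`
#'   (1..n), `modality` ("image"/"word"), `concept`, `exemplar`, `name`.
#' @examples
#' stim <- stimulus_set()
#' nrow(stim)                     # 36
#' table(stim$modality)           # 24 images, 12 words
#' @export
stimulus_set <- function(concepts = c("bird", "fish", "tree", "boat", "face", "tool"),
                         n_exemplars = 4, n_word_variants = 2) {
  stopifnot(length(concepts) >= 1, !anyDuplicated(concepts),
            n_exemplars >= 1, n_word_variants >= 1)
  images <- expand.grid(concept = concepts, exemplar = seq_len(n_exemplars),
                        stringsAsFactors = FALSE)
  images <- images[order(match(images$concept, concepts), images$exemplar), ]
  images$modality <- "image"
  words <- expand.grid(concept = concepts, exemplar = seq_len(n_word_variants),
                       stringsAsFactors = FALSE)
  words <- words[order(match(words$concept, concepts), words$exemplar), ]
  words$modality <- "word"
  out <- rbind(images, words)
  out$stimulus_id <- seq_len(nrow(out))
  case <- c("lower", "upper", paste0("variant", seq_len(max(0, n_word_variants - 2)) + 2))
  out$name <- ifelse(out$modality == "image",
                     paste0(out$concept, out$exemplar),
                     paste0("word-", out$concept, "-", case[out$exemplar]))
  out <- out[, c("stimulus_id", "modality", "concept", "exemplar", "name")]
  rownames(out) <- NULL
  if (anyDuplicated(out[, c("modality", "concept", "exemplar")]))
    stop("(modality, concept, exemplar) must be unique")
  class(out) <- c("stimulus_set", "data.frame")
  out
}
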