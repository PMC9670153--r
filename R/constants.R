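#' Expression label vocabulary
#'
#' The fixed seven-way label vocabulary used throughout the package:
#' neutral plus the six basic emotions. The order is significant — it is
#' the output-unit order of the classifier and the tie-breaking order of
#' [predict_label()].
#'
#' @format Character vector of length 7.
#' @export
EXPRESSIONS <- c("neutral", "happy", "fearful", "sad", "angry",
                 "surprised", "disgusted")

#' FACS action units analyzed by the package
#'
#' `AU_IDS` holds the 20 action-unit numbers of the Facial Action Coding
#' System that the stimulus generator can render and the probe analyses
#' cover; `AU_NAMES` maps each id to its standard facial-movement name.
#'
#' @format `AU_IDS`: integer vector of length 20. `AU_NAMES`: named
#'   character vector keyed by `"AU<id>"`.
#' @export
AU_IDS <- c(1L, 2L, 4L, 5L, 6L, 7L, 9L, 10L, 11L, 12L,
            15L, 16L, 17L, 20L, 22L, 23L, 24L, 25L, 26L, 27L)

#' @rdname AU_IDS
#' @export
AU_NAMES <- c(
  AU1  = "inner brow raiser",
  AU2  = "outer brow raiser",
  AU4  = "brow lowerer",
  AU5  = "upper lid raiser",
  AU6  = "cheek raiser",
  AU7  = "lid tightener",
  AU9  = "nose wrinkler",
  AU10 = "upper lip raiser",
  AU11 = "nasolabial furrow deepener",
  AU12 = "lip corner puller",
  AU15 = "lip corner depressor",
  AU16 = "lower lip depressor",
  AU17 = "chin raiser",
  AU20 = "lip stretcher",
  AU22 = "lip funneler",
  AU23 = "lip tightener",
  AU24 = "lip pressor",
  AU25 = "lips part",
  AU26 = "jaw drop",
  AU27 = "mouth stretch"
)

au_keys <- function() paste0("AU", AU_IDS)
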