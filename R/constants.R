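## Label schema: FACS action-unit id sets used throughout the package.

#' Action-unit id sets of the label schema
#'
#' `auDetectIds()` returns the 8 AUs targeted by the presence detector
#' (AU 5, 6, 8, 9, 10, 12, 14, 18); `auIntensityIds()` the 5 AUs with
#' intensity labels (AU 6, 10, 12, 14, 17); `auRareIds()` the 7 low-presence
#' AUs addressed through augmentation; `auUniverse()` every AU id the
#' simulator can activate (the union of the emotion sets and the label
#' schema).
#'
#' @return Integer vector of FACS AU ids.
#' @export
auDetectIds <- function() c(5L, 6L, 8L, 9L, 10L, 12L, 14L, 18L)

#' @rdname auDetectIds
#' @export
auIntensityIds <- function() c(6L, 10L, 12L, 14L, 17L)

#' @rdname auDetectIds
#' @export
auRareIds <- function() c(1L, 2L, 7L, 15L, 20L, 23L, 25L)

#' @rdname auDetectIds
#' @export
auUniverse <- function() {
  sort(unique(c(unlist(emotionAUMap(), use.names = FALSE),
                auDetectIds(), auIntensityIds(), auRareIds())))
}

#' Emotion to action-unit map
#'
#' The prototypical AU sets associated with facial expressions of emotion
#' under FACS. The embarrassment set (AU 7, 12, 14, 15, 24 — controlled
#' smile with lip press) is taken from the FACS literature on
#' self-conscious emotion displays.
#'
#' @return Named list of integer AU id vectors.
#' @export
emotionAUMap <- function() {
  list(
    happiness     = c(6L, 7L, 12L, 25L, 26L),
    sadness       = c(1L, 4L, 6L, 15L, 17L),
    fear          = c(1L, 2L, 4L, 5L, 7L, 20L, 25L),
    anger         = c(4L, 5L, 17L, 23L, 24L),
    disgust       = c(7L, 9L, 19L, 25L, 26L),
    embarrassment = c(7L, 12L, 14L, 15L, 24L),
    pain          = c(4L, 6L, 7L, 9L, 17L, 18L, 23L, 24L)
  )
}

#' FACS names for the detector's target AUs
#' @return Named character vector keyed by AU id.
#' @export
auFACSNames <- function() {
  c("5" = "Upper lid raiser", "6" = "Cheek raiser",
    "8" = "Lips toward each other", "9" = "Nose wrinkler",
    "10" = "Upper lip raiser", "12" = "Lip corner puller",
    "14" = "Dimpler", "18" = "Lip pucker")
}

## Topology registry: point counts of the supported landmark topologies.
.topologyPoints <- c(mesh478 = 478L, bp4d83 = 83L)

.topologyFromN <- function(n) {
  hit <- names(.topologyPoints)[match(n, .topologyPoints)]
  if (is.na(hit)) "custom" else hit
}
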