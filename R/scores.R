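#' Neurobehavioural score registry
#'
#' The fixed registry of the 13 neonatal neurobehavioural items the pipeline
#' knows about: postural/tone items and motor activity scored 0-3 (tone 0-4),
#' the righting reflex as successes out of 10 tries, line crosses per minute,
#' fore-hindpaw distance in mm, suck/swallow and olfactory response scores,
#' and the latency (s) of the aversive smelling response.  \code{kind}
#' determines how synthetic latent scores are discretised; \code{mean} and
#' \code{sd} are the generative baselines for uncoupled synthetic scores.
#'
#' @return data.frame with columns \code{name}, \code{kind}
#'   (\code{"ordinal"}, \code{"count"} or \code{"continuous"}), \code{min},
#'   \code{max}, \code{mean}, \code{sd}, \code{direction} (+1 if larger is
#'   better).
#' @export
scoreRegistry <- function() {
    data.frame(
        name = c("posture", "righting_reflex", "tone", "locomotion",
                 "circular_motion", "intensity", "duration",
                 "lineal_movement", "fore_hindpaw_distance",
                 "sucking_swallowing", "head_turn", "smelling_test",
                 "smelling_test_time"),
        kind = c("ordinal", "count", "ordinal", "ordinal", "ordinal",
                 "ordinal", "ordinal", "count", "continuous", "ordinal",
                 "ordinal", "ordinal", "continuous"),
        min = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
        max = c(3, 10, 4, 3, 3, 3, 3, 30, 60, 3, 3, 3, 60),
        mean = c(2.8, 8.7, 0.5, 2.6, 2.0, 2.7, 2.0, 2.8, 2.0, 2.5, 1.5,
                 2.5, 5.0),
        sd = c(0.5, 1.5, 0.8, 0.7, 0.7, 0.6, 0.5, 1.4, 2.5, 0.9, 1.0,
               0.9, 2.5),
        direction = c(1, 1, -1, 1, 1, 1, 1, 1, -1, 1, 1, 1, -1),
        stringsAsFactors = FALSE)
}

## Discretise a latent Gaussian score onto its registry scale.
discretiseScore <- function(latent, entry) {
    x <- entry$mean + entry$sd * latent
    x <- pmin(pmax(x, entry$min), entry$max)
    if (entry$kind %in% c("ordinal", "count")) x <- round(x)
    x
}
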