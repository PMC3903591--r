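#' Build a gestational-stage physiology configuration
#'
#' Interpolates the staged physiology linearly over E14.5--E18.5: heart rate
#' from 216 to 286 beats/min and ejection-duration ratio from 0.44 to 0.38,
#' with the hematocrit schedule anchored at 20\% at E10.5 and 43.8\% at term.
#' The descending-aorta reference diameter is anchored at 0.573 mm near term
#' and scales linearly down to 55\% of that at E14.5.
#'
#' @param ageDays gestational age in days, in [14.5, 18.5].
#' @param seed integer RNG seed to attach.
#' @param termDay day taken as term (default 19.5 for mouse).
#' @param daoDiameterTerm descending-aorta diameter near term, mm.
#' @return a \linkS4class{StageConfig}.
#' @examples
#' makeStageConfig(14.5)
#' @export
makeStageConfig <- function(ageDays, seed = 1L, termDay = 19.5,
                            daoDiameterTerm = 0.573) {
  if (!is.numeric(ageDays) || length(ageDays) != 1 || !is.finite(ageDays))
    stop("ageDays must be a single finite number")
  if (ageDays < 14.5 || ageDays > 18.5)
    stop("ageDays out of supported range [14.5, 18.5]; got ", ageDays)
  u <- (ageDays - 14.5) / 4
  hr <- 216 + (286 - 216) * u
  ej <- 0.44 + (0.38 - 0.44) * u
  new("StageConfig",
      ageDays = ageDays,
      heartRate = hr,
      omega = 2 * pi * hr / 60,
      ejectionRatio = ej,
      hctAnchorEarly = 0.20,
      hctAnchorTerm = 0.438,
      termDay = termDay,
      daoDiameter = daoDiameterTerm * stageScale(ageDays),
      seed = as.integer(seed))
}

# Linear dimension scale of the tree vs age: 55% of the near-term dimension
# at E14.5, 100% at E18.5 (the stage whose descending aorta is anchored at
# the reference diameter).
stageScale <- function(ageDays) 0.55 + 0.45 * (ageDays - 14.5) / 4
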