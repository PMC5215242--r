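#' @include AllClasses.R
NULL

#' Match inferred events to simulated ground truth
#'
#' Computes interval precision and recall of inferred events against the
#' simulator's ground truth, and the CO/NCO label accuracy on isolated
#' events.
#'
#' A ground-truth event is *visible* when it changed at least one marker
#' call (`nMarkers >= 1`; crossovers are always visible through their flank
#' exchange provided the chromosome carries markers on both sides). A
#' visible truth event is *recovered* when an inferred event interval
#' overlaps its bp interval (for crossovers, the interval spanning the
#' exchange point and its tract). An inferred event is a *true positive*
#' when it overlaps any truth event. A truth event is *isolated* when no
#' other truth event lies within `isolationBp` of it and its interval is
#' more than `endMarginBp` from both chromosome ends -- closer to an end
#' there is no flanking phase block left to anchor the CO/NCO distinction.
#'
#' @param inferred An [EventSet()].
#' @param truth Ground-truth data.frame from [simulateMeiosis()].
#' @param map The [SNPMap()] used.
#' @param isolationBp Minimum distance to the nearest other truth event for
#'   an event to count as isolated (default 3000, twice the merge distance:
#'   crossover switch intervals extend to the flanking homoduplex markers,
#'   so events between one and two merge distances apart can legitimately be
#'   combined by the positional merging rule).
#' @param endMarginBp Minimum distance from the chromosome ends (default
#'   3000).
#'
#' @return list with `precision`, `recall`, `labelAccuracyIsolated`,
#'   `nVisibleTruth`, `nInferred`, `nIsolated`, and the per-truth-event
#'   match table `matches`.
#' @export
matchEventsToTruth <- function(inferred, truth, map,
                               isolationBp = 3000, endMarginBp = 3000) {
  ev <- if (is(inferred, "EventSet")) inferred@events else inferred
  tr <- truth
  if (nrow(tr) == 0L)
    return(list(precision = NA_real_, recall = NA_real_,
                labelAccuracyIsolated = NA_real_, nVisibleTruth = 0L,
                nInferred = nrow(ev), nIsolated = 0L, matches = NULL))
  ## truth bp interval: tract, plus the exchange point for crossovers
  tStart <- ifelse(tr$type == "CO" & !is.na(tr$coPos),
                   pmin(tr$coPos, tr$tractStart), tr$tractStart)
  tEnd <- ifelse(tr$type == "CO" & !is.na(tr$coPos),
                 pmax(tr$coPos, tr$tractEnd), tr$tractEnd)
  visible <- tr$nMarkers >= 1L | tr$type == "CO"
  visible <- visible & tr$category != "restoration"

  L <- map@chromLengths
  isolated <- logical(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    same <- which(tr$chrom == tr$chrom[i])
    same <- setdiff(same, i)
    nearOther <- length(same) &&
      any(tStart[same] <= tEnd[i] + isolationBp &
            tEnd[same] >= tStart[i] - isolationBp)
    nearEnd <- tStart[i] <= endMarginBp ||
      tEnd[i] >= L[[tr$chrom[i]]] - endMarginBp
    isolated[i] <- !nearOther && !nearEnd
  }

  matchedType <- rep(NA_character_, nrow(tr))
  recovered <- logical(nrow(tr))
  evHit <- logical(nrow(ev))
  for (i in seq_len(nrow(tr))) {
    hits <- which(ev$chrom == tr$chrom[i] &
                    ev$start <= tEnd[i] & ev$end >= tStart[i])
    if (length(hits)) {
      recovered[i] <- TRUE
      evHit[hits] <- TRUE
      ## best overlap decides the label comparison
      ov <- pmin(ev$end[hits], tEnd[i]) - pmax(ev$start[hits], tStart[i])
      matchedType[i] <- ev$type[hits[which.max(ov)]]
    }
  }
  vis <- which(visible)
  iso <- which(visible & isolated & recovered)
  list(
    precision = if (nrow(ev)) mean(evHit) else NA_real_,
    recall = if (length(vis)) mean(recovered[vis]) else NA_real_,
    labelAccuracyIsolated = if (length(iso))
      mean(matchedType[iso] == tr$type[iso]) else NA_real_,
    nVisibleTruth = length(vis),
    nInferred = nrow(ev),
    nIsolated = length(iso),
    matches = data.frame(truthIndex = seq_len(nrow(tr)),
                         type = tr$type, visible = visible,
                         isolated = isolated, recovered = recovered,
                         matchedType = matchedType,
                         stringsAsFactors = FALSE))
}
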