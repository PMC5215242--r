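#' @include AllClasses.R
NULL

#' Accessors for octadRecomb objects
#'
#' `markers()` returns the marker table of a [SNPMap()]; `chromLengths()` the
#' named chromosome lengths; `calls()` the 8-strand genotype matrix of an
#' [OctadMatrix()]; `snpMap()` the map an object refers to; `events()` the
#' event table of an [EventSet()]; `nEvents()` its row count;
#' `gammaShape()` / `gammaScale()` the fitted parameters of a [GammaFit()].
#'
#' @param x An octadRecomb object.
#' @return The slot contents described above.
#' @name accessors
#' @examples
#' map <- SNPMap(chrom = "chrI", pos = 50L, alleleP1 = "A", alleleP2 = "C",
#'               chromLengths = c(chrI = 100))
#' markers(map)
#' chromLengths(map)
NULL

#' @rdname accessors
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))

#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname accessors
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname accessors
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))

#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname accessors
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname accessors
#' @export
setGeneric("gammaShape", function(x) standardGeneric("gammaShape"))

#' @rdname accessors
#' @export
setGeneric("gammaScale", function(x) standardGeneric("gammaScale"))

#' @rdname accessors
#' @export
setMethod("markers", "SNPMap", function(x) x@markers)

#' @rdname accessors
#' @export
setMethod("chromLengths", "SNPMap", function(x) x@chromLengths)

#' @rdname accessors
#' @export
setMethod("chromLengths", "SimParams", function(x) x@chromLengths)

#' @rdname accessors
#' @export
setMethod("chromLengths", "EventSet", function(x) x@chromLengths)

#' @rdname accessors
#' @export
setMethod("calls", "OctadMatrix", function(x) x@calls)

#' @rdname accessors
#' @export
setMethod("snpMap", "OctadMatrix", function(x) x@map)

#' @rdname accessors
#' @export
setMethod("snpMap", "ReadCountTable", function(x) x@map)

#' @rdname accessors
#' @export
setMethod("events", "EventSet", function(x) x@events)

#' @rdname accessors
#' @export
setMethod("nEvents", "EventSet", function(x) nrow(x@events))

#' @rdname accessors
#' @export
setMethod("gammaShape", "GammaFit", function(x) x@shape)

#' @rdname accessors
#' @export
setMethod("gammaScale", "GammaFit", function(x) x@scale)

## show methods ---------------------------------------------------------------

setMethod("show", "SNPMap", function(object) {
  m <- object@markers
  cat("SNPMap with", nrow(m), "markers on",
      length(unique(m$chrom)), "chromosome(s)\n")
  if (nrow(m)) {
    cat("  genome:", format(sum(object@chromLengths), big.mark = ","),
        "bp; density",
        signif(nrow(m) / sum(object@chromLengths), 3), "markers/bp\n")
  }
})

setMethod("show", "OctadMatrix", function(object) {
  cl <- object@calls
  cat("OctadMatrix:", nrow(cl), "markers x 8 strands\n")
  if (nrow(cl)) {
    miss <- colMeans(is.na(cl))
    cat("  missingness per strand:",
        paste(sprintf("%s=%.3f", colnames(cl), miss), collapse = " "), "\n")
  }
})

setMethod("show", "ReadCountTable", function(object) {
  cat("ReadCountTable:", nrow(object@nP1), "markers x 8 strand libraries\n")
  if (nrow(object@nP1))
    cat("  mean depth:",
        round(mean(object@nP1 + object@nP2), 1), "reads/marker/strand\n")
})

setMethod("show", "EventSet", function(object) {
  ev <- object@events
  cat("EventSet with", nrow(ev), "events\n")
  if (nrow(ev)) {
    tab <- table(ev$type)
    cat(" ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
    cat("  categories:",
        paste(names(table(ev$category)), table(ev$category),
              sep = "=", collapse = " "), "\n")
  }
})

setMethod("show", "GammaFit", function(object) {
  cat(sprintf("GammaFit: shape = %.1f, scale = %.0f bp (n = %d gaps, loglik = %.2f)\n",
              object@shape, object@scale, object@nGaps, object@loglik))
  if (!object@converged) cat("  WARNING: fit did not converge\n")
})

setMethod("show", "GenotypeCallConfig", function(object) {
  cat(sprintf(paste0("GenotypeCallConfig: single allele in [%g, %g]; ",
                     "two alleles: major in [%g, %g], minor < %g\n"),
              object@monoMin, object@monoMax,
              object@duoMajorMin, object@duoMajorMax, object@duoMinorLt))
})

setMethod("show", "InferenceConfig", function(object) {
  cat(sprintf("InferenceConfig: mergeGapBp = %g, maxMissingRun = %g, minPhaseBlockBp = %g\n",
              object@mergeGapBp, object@maxMissingRun, object@minPhaseBlockBp))
})

setMethod("show", "SimParams", function(object) {
  cat("SimParams:\n")
  cat("  genome:", length(object@chromLengths), "chromosome(s),",
      format(sum(object@chromLengths), big.mark = ","), "bp\n")
  cat("  snpDensity:", signif(object@snpDensity, 4), "markers/bp\n")
  cat(sprintf("  crossovers: gamma shape %.2f, mean gap %g bp\n",
              object@gammaShape, object@meanInterCo))
  cat(sprintf("  ncoRate: %g /bp; tract median %g bp (%s)\n",
              object@ncoRate, object@tractLenDist$median,
              object@tractLenDist$dist))
  cat(sprintf("  hDNA: pTrans = %g, pSym = %g, MMR %s\n",
              object@pTransHdna, object@pSymHdna,
              if (object@mmrActive) "active" else "inactive (msh2-like)"))
})
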