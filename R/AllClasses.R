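#' @import methods
NULL

#' Strand library labels of an octad
#'
#' The eight DNA strands of one meiosis are recovered by letting each of the
#' four spores perform one mitosis and sequencing both daughter cells; daughter
#' `a` and `b` of spore `i` carry the two strands of spore `i`'s chromatid.
#'
#' @return Character vector of the eight strand labels, `s1a` to `s4b`.
#' @export
#' @examples
#' octadStrandNames()
octadStrandNames <- function() {
  paste0("s", rep(1:4, each = 2), rep(c("a", "b"), 4))
}

## ---------------------------------------------------------------------------
## SNPMap
## ---------------------------------------------------------------------------

#' @rdname SNPMap
#' @export
setClass("SNPMap",
  representation(
    markers = "data.frame",       # chrom, pos, alleleP1, alleleP2
    chromLengths = "numeric"      # named, bp
  )
)

setValidity("SNPMap", function(object) {
  m <- object@markers
  need <- c("chrom", "pos", "alleleP1", "alleleP2")
  if (!all(need %in% names(m)))
    return(paste("markers must have columns:", paste(need, collapse = ", ")))
  if (nrow(m) > 0L) {
    if (any(is.na(m$pos)) || any(m$pos < 1))
      return("marker positions must be >= 1 (1-based coordinates)")
    bad <- unlist(lapply(split(m$pos, m$chrom), function(p) any(diff(p) <= 0)))
    if (any(bad))
      return("positions must be strictly increasing within each chromosome")
    if (any(m$alleleP1 == m$alleleP2))
      return("parental alleles must differ at every marker")
    if (!all(unique(m$chrom) %in% names(object@chromLengths)))
      return("every marker chromosome must appear in chromLengths")
    over <- m$pos > object@chromLengths[as.character(m$chrom)]
    if (any(over))
      return("marker positions exceed the stated chromosome length")
  }
  if (length(object@chromLengths) &&
      (is.null(names(object@chromLengths)) || any(object@chromLengths <= 0)))
    return("chromLengths must be a named vector of positive lengths")
  TRUE
})

#' SNP map of a polymorphic hybrid
#'
#' Ordered biallelic markers distinguishing the two parental genomes of a
#' hybrid diploid (e.g. S288C x SK1). Positions are 1-based; alleles are
#' single-character labels and must differ at every marker.
#'
#' @param chrom Character/factor vector of chromosome names.
#' @param pos Integer vector of 1-based positions, strictly increasing within
#'   each chromosome.
#' @param alleleP1,alleleP2 Single-character allele labels of parent 1 and
#'   parent 2.
#' @param chromLengths Named numeric vector of chromosome lengths (bp).
#'
#' @return A `SNPMap` object.
#' @export
#' @examples
#' SNPMap(chrom = c("chrI", "chrI"), pos = c(100L, 500L),
#'        alleleP1 = c("A", "G"), alleleP2 = c("T", "C"),
#'        chromLengths = c(chrI = 1000))
SNPMap <- function(chrom = character(), pos = integer(),
                   alleleP1 = character(), alleleP2 = character(),
                   chromLengths = numeric()) {
  m <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                  alleleP1 = as.character(alleleP1),
                  alleleP2 = as.character(alleleP2),
                  stringsAsFactors = FALSE)
  new("SNPMap", markers = m, chromLengths = chromLengths)
}

## ---------------------------------------------------------------------------
## OctadMatrix
## ---------------------------------------------------------------------------

#' @rdname OctadMatrix
#' @export
setClass("OctadMatrix",
  representation(
    calls = "matrix",   # character, n markers x 8 strands, "P1"/"P2"/NA
    map = "SNPMap"
  )
)

setValidity("OctadMatrix", function(object) {
  cl <- object@calls
  if (!is.character(cl))
    return("calls must be a character matrix")
  if (ncol(cl) != 8L || !identical(colnames(cl), octadStrandNames()))
    return("calls must have exactly 8 columns named s1a..s4b")
  if (nrow(cl) != nrow(object@map@markers))
    return("calls must have one row per marker of the SNP map")
  vals <- cl[!is.na(cl)]
  if (length(vals) && !all(vals %in% c("P1", "P2")))
    return("calls must be 'P1', 'P2' or NA")
  TRUE
})

#' Eight-strand genotype matrix of one meiosis
#'
#' Per-marker parental genotype calls for the 8 DNA strands of an octad,
#' grouped as 4 spore pairs (daughter cells `a` and `b` of each spore).
#'
#' @param calls Character matrix (markers x 8) with values `"P1"`, `"P2"` or
#'   `NA`; columns named `s1a` ... `s4b`.
#' @param map The [SNPMap()] the rows refer to.
#'
#' @return An `OctadMatrix` object.
#' @export
OctadMatrix <- function(calls, map) {
  if (is.null(colnames(calls))) colnames(calls) <- octadStrandNames()
  new("OctadMatrix", calls = calls, map = map)
}

## ---------------------------------------------------------------------------
## ReadCountTable
## ---------------------------------------------------------------------------

#' @rdname ReadCountTable
#' @export
setClass("ReadCountTable",
  representation(
    nP1 = "matrix",   # integer, markers x 8
    nP2 = "matrix",
    map = "SNPMap"
  )
)

setValidity("ReadCountTable", function(object) {
  for (sl in c("nP1", "nP2")) {
    m <- slot(object, sl)
    if (ncol(m) != 8L || !identical(colnames(m), octadStrandNames()))
      return("count matrices must have 8 columns named s1a..s4b")
    if (nrow(m) != nrow(object@map@markers))
      return("count matrices must have one row per marker")
    if (any(m < 0) || any(m != round(m)))
      return("read counts must be non-negative integers")
  }
  TRUE
})

#' Per-strand allele read counts
#'
#' Read counts supporting each parental allele, per marker and per strand
#' library of an octad.
#'
#' @param nP1,nP2 Numeric matrices (markers x 8) of reads supporting the
#'   parent-1 and parent-2 allele; columns named `s1a` ... `s4b`.
#' @param map The [SNPMap()] the rows refer to.
#'
#' @return A `ReadCountTable` object.
#' @export
ReadCountTable <- function(nP1, nP2, map) {
  if (is.null(colnames(nP1))) colnames(nP1) <- octadStrandNames()
  if (is.null(colnames(nP2))) colnames(nP2) <- octadStrandNames()
  new("ReadCountTable", nP1 = nP1, nP2 = nP2, map = map)
}

## ---------------------------------------------------------------------------
## Configuration objects
## ---------------------------------------------------------------------------

#' @rdname GenotypeCallConfig
#' @export
setClass("GenotypeCallConfig",
  representation(
    monoMin = "numeric", monoMax = "numeric",
    duoMajorMin = "numeric", duoMajorMax = "numeric",
    duoMinorLt = "numeric"
  )
)

setValidity("GenotypeCallConfig", function(object) {
  if (object@monoMin > object@monoMax) return("monoMin must be <= monoMax")
  if (object@duoMajorMin > object@duoMajorMax)
    return("duoMajorMin must be <= duoMajorMax")
  if (object@duoMinorLt < 1) return("duoMinorLt must be >= 1")
  TRUE
})

#' Read-count thresholds for genotype validity
#'
#' A SNP genotype is valid when only one allele is observed and its read count
#' lies in `[monoMin, monoMax]`, or when both alleles are observed, the more
#' abundant lies in `[duoMajorMin, duoMajorMax]` and the less abundant is
#' strictly below `duoMinorLt`. Anything else (including ties) is missing.
#'
#' @param monoMin,monoMax Inclusive bounds on the count when a single allele
#'   is observed (defaults 15 and 150).
#' @param duoMajorMin,duoMajorMax Inclusive bounds on the majority count when
#'   both alleles are observed (defaults 40 and 150).
#' @param duoMinorLt Strict upper bound on the minority count (default 5).
#'
#' @return A `GenotypeCallConfig` object.
#' @export
#' @examples
#' GenotypeCallConfig()
GenotypeCallConfig <- function(monoMin = 15, monoMax = 150,
                               duoMajorMin = 40, duoMajorMax = 150,
                               duoMinorLt = 5) {
  new("GenotypeCallConfig", monoMin = monoMin, monoMax = monoMax,
      duoMajorMin = duoMajorMin, duoMajorMax = duoMajorMax,
      duoMinorLt = duoMinorLt)
}

#' @rdname InferenceConfig
#' @export
setClass("InferenceConfig",
  representation(
    mergeGapBp = "numeric",
    maxMissingRun = "numeric",
    minMarkersPerTract = "numeric",
    minPhaseBlockBp = "numeric"
  )
)

setValidity("InferenceConfig", function(object) {
  if (object@mergeGapBp <= 0) return("mergeGapBp must be > 0")
  if (object@maxMissingRun < 0) return("maxMissingRun must be >= 0")
  if (object@minMarkersPerTract < 1) return("minMarkersPerTract must be >= 1")
  if (object@minPhaseBlockBp <= 0) return("minPhaseBlockBp must be > 0")
  TRUE
})

#' Event-inference parameters
#'
#' @param mergeGapBp Tracts and crossover points separated by less than this
#'   many bp are attributed to the same DSB and combined (default 1500).
#' @param maxMissingRun Maximum run of uninformative markers bridged inside a
#'   candidate tract (default 2).
#' @param minMarkersPerTract Minimum number of deviating markers for a tract
#'   (default 1).
#' @param minPhaseBlockBp Minimum bp span of a homoduplex run for it to anchor
#'   a parental phase block rather than be treated as a candidate conversion
#'   tract (default 10000).
#'
#' @return An `InferenceConfig` object.
#' @export
#' @examples
#' InferenceConfig(mergeGapBp = 1500)
InferenceConfig <- function(mergeGapBp = 1500, maxMissingRun = 2,
                            minMarkersPerTract = 1, minPhaseBlockBp = 10000) {
  new("InferenceConfig", mergeGapBp = mergeGapBp,
      maxMissingRun = maxMissingRun,
      minMarkersPerTract = minMarkersPerTract,
      minPhaseBlockBp = minPhaseBlockBp)
}

#' @rdname SimParams
#' @export
setClass("SimParams",
  representation(
    chromLengths = "numeric",
    snpDensity = "numeric",
    gammaShape = "numeric",
    meanInterCo = "numeric",
    ncoRate = "numeric",
    tractLenDist = "list",
    pTransHdna = "numeric",
    pSymHdna = "numeric",
    mmrActive = "logical",
    pConversion = "numeric",
    maxRetries = "numeric"
  )
)

setValidity("SimParams", function(object) {
  pr <- c(object@pTransHdna, object@pSymHdna, object@pConversion)
  if (any(pr < 0 | pr > 1)) return("probabilities must lie in [0, 1]")
  if (object@pTransHdna + object@pSymHdna > 1)
    return("pTransHdna + pSymHdna must be <= 1")
  if (object@gammaShape <= 0) return("gammaShape must be > 0")
  if (object@meanInterCo <= 0) return("meanInterCo must be > 0")
  if (object@ncoRate < 0) return("ncoRate must be >= 0")
  if (object@snpDensity < 0) return("snpDensity must be >= 0")
  if (any(object@chromLengths <= 0) || is.null(names(object@chromLengths)))
    return("chromLengths must be a named vector of positive bp lengths")
  d <- object@tractLenDist
  if (is.null(d$dist) || !d$dist %in% c("exponential", "fixed"))
    return("tractLenDist$dist must be 'exponential' or 'fixed'")
  if (is.null(d$median) || d$median <= 0)
    return("tractLenDist$median must be > 0 (bp)")
  TRUE
})

#' Simulation parameters for a hybrid meiosis
#'
#' Defaults emulate an S288C x SK1-like msh2-deficient hybrid: a ~12.07 Mb
#' 16-chromosome genome carrying ~75,000 biallelic markers, interference-
#' distributed crossovers (gamma shape 2.3), Poisson noncrossovers, and
#' retained heteroduplex DNA (no mismatch repair), with conversion/hDNA tract
#' lengths drawn from a distribution with median ~1 kb.
#'
#' @param chromLengths Named numeric vector of chromosome lengths (bp).
#'   Default: the 16 budding-yeast nuclear chromosomes.
#' @param snpDensity Markers per bp (default 74911 / 12071326, the genome-wide
#'   density of the hybrid's SNP list).
#' @param gammaShape Shape of the gamma inter-crossover model used to place
#'   crossovers (1 = no interference; default 2.3).
#' @param meanInterCo Mean inter-crossover distance in bp (default 130000,
#'   giving roughly 90 crossovers per meiosis genome-wide).
#' @param ncoRate Noncrossover initiations per bp (Poisson; default 8e-6,
#'   roughly 95 noncrossovers per meiosis).
#' @param tractLenDist List describing the conversion/hDNA tract-length
#'   distribution: `list(dist = "exponential", median = 1000)` (bp) or
#'   `list(dist = "fixed", median = L)`.
#' @param pTransHdna Probability that a retained-hDNA tract is a trans tract
#'   (donor strand switches sides across the event; default 0.3).
#' @param pSymHdna Probability of a symmetric heteroduplex (complementary hDNA
#'   on two chromatids over the same interval; default 0.03 -- rare).
#' @param mmrActive If `TRUE`, mismatch repair corrects heteroduplexes: each
#'   tract becomes a full conversion with probability `pConversion`, else a
#'   restoration (invisible). Default `FALSE` (msh2-deficient, hDNA retained).
#' @param pConversion Probability of conversion (vs restoration) when
#'   `mmrActive` is `TRUE` (default 0.5).
#' @param maxRetries Retry cap when a drawn event overlaps an existing event
#'   on the same chromatid (default 20).
#'
#' @return A `SimParams` object.
#' @export
#' @examples
#' SimParams(chromLengths = c(chr1 = 2e5), meanInterCo = 1e5)
SimParams <- function(chromLengths = yeastChromLengths(),
                      snpDensity = 74911 / 12071326,
                      gammaShape = 2.3,
                      meanInterCo = 130000,
                      ncoRate = 8e-6,
                      tractLenDist = list(dist = "exponential", median = 1000),
                      pTransHdna = 0.3,
                      pSymHdna = 0.03,
                      mmrActive = FALSE,
                      pConversion = 0.5,
                      maxRetries = 20) {
  new("SimParams", chromLengths = chromLengths, snpDensity = snpDensity,
      gammaShape = gammaShape, meanInterCo = meanInterCo, ncoRate = ncoRate,
      tractLenDist = tractLenDist, pTransHdna = pTransHdna,
      pSymHdna = pSymHdna, mmrActive = mmrActive, pConversion = pConversion,
      maxRetries = maxRetries)
}

#' Budding-yeast nuclear chromosome lengths
#'
#' Lengths (bp) of the 16 S. cerevisiae nuclear chromosomes (R64-1-1
#' assembly), totalling ~12.07 Mb.
#'
#' @return Named numeric vector of 16 lengths.
#' @export
#' @examples
#' sum(yeastChromLengths())
yeastChromLengths <- function() {
  c(chrI = 230218, chrII = 813184, chrIII = 316620, chrIV = 1531933,
    chrV = 576874, chrVI = 270161, chrVII = 1090940, chrVIII = 562643,
    chrIX = 439888, chrX = 745751, chrXI = 666816, chrXII = 1078177,
    chrXIII = 924431, chrXIV = 784333, chrXV = 1091291, chrXVI = 948066)
}

## ---------------------------------------------------------------------------
## EventSet and GammaFit
## ---------------------------------------------------------------------------

#' @rdname EventSet
#' @export
setClass("EventSet",
  representation(
    events = "data.frame",
    chromLengths = "numeric"
  )
)

.eventColumns <- c("chrom", "start", "end", "eventId", "type", "category",
                   "spores", "coPos", "lenMin", "lenMid", "lenMax",
                   "nMarkers", "meiosis", "genotype")

setValidity("EventSet", function(object) {
  ev <- object@events
  if (!all(.eventColumns %in% names(ev)))
    return(paste("events must have columns:",
                 paste(.eventColumns, collapse = ", ")))
  if (nrow(ev) > 0L) {
    if (!all(ev$type %in% c("CO", "NCO")))
      return("type must be 'CO' or 'NCO'")
    ok <- c("full_conversion", "SDSA_like_hDNA", "trans_hDNA",
            "symmetric_hDNA", "complex", "none", "restoration")
    if (!all(ev$category %in% ok))
      return(paste("unknown event category; allowed:",
                   paste(ok, collapse = ", ")))
    if (any(ev$start > ev$end)) return("event start must be <= end")
  }
  TRUE
})

#' A set of recombination events
#'
#' One row per recombination event (one DSB): interval, CO/NCO type, hDNA
#' category, involved spores and tract lengths under the min/mid/max
#' conventions. Intervals are stored 1-based inclusive on marker positions;
#' use [eventsAsGRanges()] for BED-style 0-based half-open export.
#'
#' @param events A data.frame with (at least) columns `chrom`, `start`,
#'   `end`, `eventId`, `type`, `category`, `spores`, `coPos`, `lenMin`,
#'   `lenMid`, `lenMax`, `nMarkers`, `meiosis`, `genotype`.
#' @param chromLengths Named numeric vector of chromosome lengths (bp).
#'
#' @return An `EventSet` object.
#' @export
EventSet <- function(events = emptyEventFrame(), chromLengths = numeric()) {
  new("EventSet", events = events, chromLengths = chromLengths)
}

#' @rdname EventSet
#' @export
emptyEventFrame <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             eventId = character(), type = character(), category = character(),
             spores = character(), coPos = numeric(), lenMin = numeric(),
             lenMid = numeric(), lenMax = numeric(), nMarkers = integer(),
             meiosis = character(), genotype = character(),
             stringsAsFactors = FALSE)
}

#' @rdname GammaFit
#' @export
setClass("GammaFit",
  representation(
    shape = "numeric",
    scale = "numeric",
    loglik = "numeric",
    nGaps = "integer",
    converged = "logical"
  )
)

#' Gamma fit of inter-crossover distances
#'
#' Result of maximum-likelihood fitting of a gamma distribution to
#' inter-crossover distances. The shape parameter is the interference
#' statistic: 1 means no interference, larger values stronger positive
#' interference.
#'
#' @param shape,scale MLE of the gamma shape (unitless) and scale (bp).
#' @param loglik Maximised log-likelihood (nats).
#' @param nGaps Number of gaps fitted.
#' @param converged Logical convergence flag.
#'
#' @return A `GammaFit` object.
#' @export
GammaFit <- function(shape, scale, loglik, nGaps, converged = TRUE) {
  new("GammaFit", shape = shape, scale = scale, loglik = loglik,
      nGaps = as.integer(nGaps), converged = converged)
}
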