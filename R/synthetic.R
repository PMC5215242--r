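#' @include AllClasses.R
NULL

## Deterministic per-chromosome child seeds derived from one root seed, so a
## meiosis is reproducible chromosome by chromosome. Kept below 2^31 - 1.
childSeed <- function(rootSeed, i) {
  as.integer((as.numeric(rootSeed) * 48271 + i * 7919) %% 2147483647)
}

#' Build a synthetic SNP map
#'
#' Samples biallelic marker positions along each chromosome, either uniformly
#' at random at a given density (marker count per chromosome is Poisson) or on
#' a fixed pitch. At the default density a ~12.07 Mb genome carries ~75,000
#' markers, the genome-wide scale of an S288C x SK1 hybrid SNP list.
#'
#' @param chromLengths Named numeric vector of chromosome lengths (bp).
#' @param snpDensity Markers per bp (ignored when `spacing = "fixed"`).
#' @param seed Integer seed.
#' @param spacing `"uniform"` (random positions) or `"fixed"` (regular pitch).
#' @param pitch Marker pitch in bp for `spacing = "fixed"`.
#'
#' @return A [SNPMap()].
#' @export
#' @examples
#' map <- buildSnpMap(c(chr1 = 10000), spacing = "fixed", pitch = 1000)
#' markers(map)$pos
buildSnpMap <- function(chromLengths, snpDensity = 74911 / 12071326,
                        seed = 1L, spacing = c("uniform", "fixed"),
                        pitch = NULL) {
  spacing <- match.arg(spacing)
  if (any(chromLengths < 0)) stop("chromosome lengths must be >= 0")
  if (snpDensity < 0) stop("snpDensity must be >= 0")
  if (is.null(names(chromLengths)))
    names(chromLengths) <- paste0("chr", seq_along(chromLengths))
  set.seed(as.integer(seed))
  pieces <- lapply(seq_along(chromLengths), function(i) {
    L <- chromLengths[[i]]
    if (spacing == "fixed") {
      if (is.null(pitch) || pitch <= 0) stop("fixed spacing requires pitch > 0")
      pos <- seq(pitch, L, by = pitch)
    } else {
      n <- stats::rpois(1L, L * snpDensity)
      n <- min(n, floor(L))
      pos <- sort(sample.int(floor(L), n))
    }
    n <- length(pos)
    if (n == 0L) return(NULL)
    a1 <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    shift <- sample.int(3L, n, replace = TRUE)
    bases <- c("A", "C", "G", "T")
    a2 <- bases[(match(a1, bases) - 1L + shift) %% 4L + 1L]
    data.frame(chrom = names(chromLengths)[i], pos = pos,
               alleleP1 = a1, alleleP2 = a2, stringsAsFactors = FALSE)
  })
  m <- do.call(rbind, pieces)
  if (is.null(m))
    m <- data.frame(chrom = character(), pos = numeric(),
                    alleleP1 = character(), alleleP2 = character())
  new("SNPMap", markers = m, chromLengths = chromLengths)
}

## Draw one value from the equilibrium (forward-recurrence) distribution of a
## stationary renewal process with gamma(shape, scale) gaps. Its CDF is
##   Fe(x) = [ x (1 - F_k(x)) + k*scale * F_{k+1}(x) ] / (k*scale),
## inverted numerically.
rStationaryGap <- function(shape, scale) {
  mu <- shape * scale
  u <- stats::runif(1L)
  Fe <- function(x)
    (x * (1 - stats::pgamma(x, shape, scale = scale)) +
       mu * stats::pgamma(x, shape + 1, scale = scale)) / mu
  upper <- mu
  while (Fe(upper) < u) upper <- upper * 2
  stats::uniroot(function(x) Fe(x) - u, lower = 0, upper = upper,
                 tol = 1e-8 * mu)$root
}

#' Place interfering crossovers along a chromosome
#'
#' Crossover positions follow a stationary gamma-renewal process: the first
#' point is drawn from the equilibrium forward-recurrence distribution and
#' subsequent gaps are i.i.d. gamma with the given shape and mean. Shape 1
#' reduces to a Poisson process (no interference); larger shapes yield more
#' evenly spaced crossovers (positive interference).
#'
#' @param chromLength Chromosome length in bp.
#' @param gammaShape Gamma shape (> 0).
#' @param meanInterCo Mean inter-crossover distance in bp (> 0).
#' @param seed Optional integer seed; if `NULL` the current RNG state is used.
#'
#' @return Sorted numeric vector of crossover positions in (0, chromLength).
#' @export
#' @examples
#' placeCrossovers(1e6, gammaShape = 2.3, meanInterCo = 3e5, seed = 1)
placeCrossovers <- function(chromLength, gammaShape, meanInterCo, seed = NULL) {
  if (gammaShape <= 0) stop("gammaShape must be > 0")
  if (meanInterCo <= 0) stop("meanInterCo must be > 0")
  if (chromLength <= 0) return(numeric())
  if (!is.null(seed)) set.seed(as.integer(seed))
  scale <- meanInterCo / gammaShape
  pos <- numeric()
  x <- rStationaryGap(gammaShape, scale)
  while (x < chromLength) {
    pos <- c(pos, x)
    x <- x + stats::rgamma(1L, gammaShape, scale = scale)
  }
  pos
}

.truthRow <- function(chrom, type, category, spores, coPos, tractStart,
                      tractEnd, strandSeg, firstMarker, lastMarker, nMarkers) {
  data.frame(chrom = chrom, type = type, category = category,
             spores = spores, coPos = coPos,
             tractStart = tractStart, tractEnd = tractEnd,
             tractLen = tractEnd - tractStart + 1,
             strandSeg = strandSeg, firstMarker = firstMarker,
             lastMarker = lastMarker, nMarkers = nMarkers,
             stringsAsFactors = FALSE)
}

.drawTractLen <- function(dist) {
  if (dist$dist == "fixed") return(dist$median)
  ## exponential parameterised by its median
  max(1, round(stats::rexp(1L, rate = log(2) / dist$median)))
}

## interval overlap against a spore's used-interval registry
.overlaps <- function(reg, spores, s, e) {
  for (sp in spores) {
    iv <- reg[[sp]]
    if (length(iv) && any(iv$start <= e & iv$end >= s)) return(TRUE)
  }
  FALSE
}

.regAdd <- function(reg, spores, s, e) {
  for (sp in spores) {
    reg[[sp]] <- rbind(reg[[sp]], data.frame(start = s, end = e))
  }
  reg
}

#' Simulate one octad with known ground truth
#'
#' Generates the 8-strand genotype matrix of one meiosis of a polymorphic
#' hybrid, together with the exact list of recombination events written into
#' it. Crossovers are placed by a stationary gamma-renewal process and
#' exchange flanking parental phase between one chromatid of each parent from
#' the exchange point to the (right) chromosome end; each crossover deposits a
#' heteroduplex tract adjacent to its exchange point. Noncrossovers are
#' Poisson-distributed conversion/hDNA tracts on a single chromatid
#' (SDSA-like, trans, or -- rarely -- symmetric on two chromatids). Without
#' mismatch repair (`mmrActive = FALSE`, the msh2-deficient default) hDNA is
#' retained and spore daughter cells disagree across the tract (5:3
#' segregation); with repair each tract becomes a full conversion (6:2) or an
#' invisible restoration.
#'
#' @param map A [SNPMap()].
#' @param params A [SimParams()] object.
#' @param seed Integer root seed; per-chromosome child seeds are derived
#'   deterministically from it.
#'
#' @return A list with elements `octad` (an [OctadMatrix()]), `truth` (a
#'   data.frame of ground-truth events; `nMarkers` counts markers whose calls
#'   the event actually changed, 0 for events falling between markers or
#'   restored by repair), and `collisions` (number of events dropped after
#'   exceeding the overlap retry cap).
#' @export
#' @examples
#' map <- buildSnpMap(c(chr1 = 2e5), seed = 1)
#' sim <- simulateMeiosis(map, SimParams(chromLengths = c(chr1 = 2e5)), seed = 7)
#' sim$octad
simulateMeiosis <- function(map, params, seed = 1L) {
  stopifnot(is(map, "SNPMap"), is(params, "SimParams"))
  validObject(params)
  mk <- map@markers
  strandNames <- octadStrandNames()
  truth <- list()
  collisions <- 0L
  callList <- list()
  chroms <- names(params@chromLengths)
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    L <- params@chromLengths[[chrom]]
    set.seed(childSeed(seed, ci))
    rows <- which(mk$chrom == chrom)
    pos <- mk$pos[rows]
    n <- length(pos)
    ## haplotype-of-origin per strand: spores 1,2 from parent 1; 3,4 parent 2
    H <- matrix(rep(c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L), each = n),
                nrow = n, ncol = 8L, dimnames = list(NULL, strandNames))
    reg <- stats::setNames(vector("list", 4L), as.character(1:4))

    markersIn <- function(s, e) which(pos >= s & pos <= e)
    flip <- function(spore, ab, idx) {
      col <- paste0("s", spore, ab)
      H[idx, col] <<- 3L - H[idx, col]
    }
    ## segments are recorded with global marker row indices (idx is a
    ## contiguous run of chromosome-local indices)
    segStr <- function(spore, ab, idx) {
      if (!length(idx)) return(NA_character_)
      sprintf("s%d%s:%d-%d", spore, ab, rows[min(idx)], rows[max(idx)])
    }

    ## --- crossovers -------------------------------------------------------
    coPos <- placeCrossovers(L, params@gammaShape, params@meanInterCo)
    for (x in coPos) {
      ## interhomolog exchange: partners must carry opposite parental DNA at
      ## the exchange point (after applying all exchanges to the left)
      firstDistal <- match(TRUE, pos > x)
      if (!is.na(firstDistal)) {
        phaseAtX <- H[firstDistal, paste0("s", 1:4, "a")]
      } else {
        phaseAtX <- c(1L, 1L, 2L, 2L)
      }
      g1 <- which(phaseAtX == 1L)
      g2 <- which(phaseAtX == 2L)
      if (!length(g1) || !length(g2)) { g1 <- 1:2; g2 <- 3:4 }
      c1 <- sample(rep(g1, 2L), 1L)
      c2 <- sample(rep(g2, 2L), 1L)
      ## reciprocal exchange of both strands distal to x
      distal <- which(pos > x)
      colsA <- paste0("s", c1, c("a", "b"))
      colsB <- paste0("s", c2, c("a", "b"))
      tmp <- H[distal, colsA]
      H[distal, colsA] <- H[distal, colsB]
      H[distal, colsB] <- tmp

      ## hDNA tract adjacent to the exchange point on one partner
      seg <- NA_character_
      idx <- integer()
      ts <- x; te <- x
      for (try in seq_len(params@maxRetries)) {
        rec <- if (stats::runif(1L) < 0.5) c1 else c2
        len <- .drawTractLen(params@tractLenDist)
        s <- x; e <- min(x + len - 1, L)
        if (!.overlaps(reg, as.character(rec), s, e)) {
          ab <- if (stats::runif(1L) < 0.5) "a" else "b"
          idx <- markersIn(s, e)
          category <- "SDSA_like_hDNA"
          if (params@mmrActive) {
            if (stats::runif(1L) < params@pConversion) {
              flip(rec, "a", idx); flip(rec, "b", idx)
              seg <- paste(stats::na.omit(c(segStr(rec, "a", idx),
                                            segStr(rec, "b", idx))),
                           collapse = ";")
              category <- "full_conversion"
            } else {
              category <- "restoration"; idx <- integer()
            }
          } else {
            flip(rec, ab, idx)
            seg <- segStr(rec, ab, idx)
          }
          reg <- .regAdd(reg, as.character(rec), s, e)
          ts <- s; te <- e
          truth[[length(truth) + 1L]] <- .truthRow(
            chrom, "CO", category,
            paste(sort(c(c1, c2)), collapse = ","), x, ts, te,
            if (is.na(seg)) NA_character_ else seg,
            if (length(idx)) rows[min(idx)] else NA_integer_,
            if (length(idx)) rows[max(idx)] else NA_integer_,
            length(idx))
          break
        }
        if (try == params@maxRetries) {
          collisions <- collisions + 1L
          truth[[length(truth) + 1L]] <- .truthRow(
            chrom, "CO", "none",
            paste(sort(c(c1, c2)), collapse = ","), x, x, x,
            NA_character_, NA_integer_, NA_integer_, 0L)
        }
      }
    }

    ## --- noncrossovers ----------------------------------------------------
    nNco <- stats::rpois(1L, params@ncoRate * L)
    for (k in seq_len(nNco)) {
      placed <- FALSE
      for (try in seq_len(params@maxRetries)) {
        s <- stats::runif(1L, 1, L)
        len <- .drawTractLen(params@tractLenDist)
        e <- min(s + len - 1, L)
        rec <- sample(1:4, 1L)
        u <- stats::runif(1L)
        category <- if (u < params@pSymHdna) "symmetric_hDNA"
                    else if (u < params@pSymHdna + params@pTransHdna) "trans_hDNA"
                    else "SDSA_like_hDNA"
        idx <- markersIn(s, e)
        involved <- as.character(rec)
        partner <- NA_integer_
        if (category == "symmetric_hDNA" && length(idx)) {
          phase <- H[idx[1L], paste0("s", 1:4, "a")]
          others <- which(phase != phase[rec])
          if (length(others)) partner <- sample(rep(others, 2L), 1L)
          if (is.na(partner)) category <- "SDSA_like_hDNA"
          else involved <- as.character(c(rec, partner))
        }
        if (.overlaps(reg, involved, s, e)) next
        seg <- NA_character_
        if (params@mmrActive) {
          if (stats::runif(1L) < params@pConversion) {
            flip(rec, "a", idx); flip(rec, "b", idx)
            seg <- paste(stats::na.omit(c(segStr(rec, "a", idx),
                                          segStr(rec, "b", idx))),
                         collapse = ";")
            category <- "full_conversion"
          } else {
            category <- "restoration"; idx <- integer()
          }
        } else if (category == "trans_hDNA" && length(idx) >= 2L) {
          m <- sample(seq_len(length(idx) - 1L), 1L)
          i1 <- idx[seq_len(m)]; i2 <- idx[(m + 1L):length(idx)]
          flip(rec, "a", i1); flip(rec, "b", i2)
          seg <- paste(c(segStr(rec, "a", i1), segStr(rec, "b", i2)),
                       collapse = ";")
        } else if (category == "symmetric_hDNA" && !is.na(partner)) {
          flip(rec, "a", idx); flip(partner, "a", idx)
          seg <- paste(c(segStr(rec, "a", idx), segStr(partner, "a", idx)),
                       collapse = ";")
        } else {
          if (category == "trans_hDNA") category <- "SDSA_like_hDNA"
          ab <- if (stats::runif(1L) < 0.5) "a" else "b"
          flip(rec, ab, idx)
          seg <- segStr(rec, ab, idx)
        }
        reg <- .regAdd(reg, involved, s, e)
        truth[[length(truth) + 1L]] <- .truthRow(
          chrom, "NCO", category, paste(sort(as.integer(involved)),
                                        collapse = ","),
          NA_real_, s, e,
          seg,
          if (length(idx)) rows[min(idx)] else NA_integer_,
          if (length(idx)) rows[max(idx)] else NA_integer_,
          length(idx))
        placed <- TRUE
        break
      }
      if (!placed) collisions <- collisions + 1L
    }

    callList[[ci]] <- H
  }

  H <- do.call(rbind, callList)
  ## rows of callList follow chromosome blocks in chromLengths order; align to map
  ord <- order(match(mk$chrom, chroms), mk$pos)
  callsM <- matrix(NA_character_, nrow(mk), 8L,
                   dimnames = list(NULL, strandNames))
  callsM[ord, ] <- ifelse(H == 1L, "P1", "P2")
  octad <- new("OctadMatrix", calls = callsM, map = map)
  truthDf <- if (length(truth)) do.call(rbind, truth) else
    .truthRow(character(), character(), character(), character(),
              numeric(), numeric(), numeric(), character(),
              integer(), integer(), integer())[0, ]
  list(octad = octad, truth = truthDf, collisions = collisions)
}

#' Reconstruct an octad matrix from ground truth
#'
#' Replays the recorded crossover exchanges and per-strand transfer segments
#' of a ground-truth table onto a Mendelian octad, reproducing the simulated
#' matrix exactly. Used to verify ground-truth/matrix consistency.
#'
#' @param truth Ground-truth data.frame from [simulateMeiosis()].
#' @param map The [SNPMap()] used for the simulation.
#'
#' @return An [OctadMatrix()].
#' @export
octadFromTruth <- function(truth, map) {
  mk <- map@markers
  n <- nrow(mk)
  strandNames <- octadStrandNames()
  H <- matrix(rep(c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L), each = n),
              nrow = n, ncol = 8L, dimnames = list(NULL, strandNames))
  co <- truth[truth$type == "CO", , drop = FALSE]
  co <- co[order(match(co$chrom, unique(mk$chrom)), co$coPos), , drop = FALSE]
  for (i in seq_len(nrow(co))) {
    sp <- as.integer(strsplit(co$spores[i], ",")[[1L]])[1:2]
    distal <- which(mk$chrom == co$chrom[i] & mk$pos > co$coPos[i])
    colsA <- paste0("s", sp[1L], c("a", "b"))
    colsB <- paste0("s", sp[2L], c("a", "b"))
    tmp <- H[distal, colsA]
    H[distal, colsA] <- H[distal, colsB]
    H[distal, colsB] <- tmp
  }
  segs <- truth$strandSeg[!is.na(truth$strandSeg)]
  for (s in segs) {
    for (piece in strsplit(s, ";")[[1L]]) {
      mm <- regmatches(piece, regexec("^(s[1-4][ab]):([0-9]+)-([0-9]+)$", piece))[[1L]]
      idx <- as.integer(mm[3L]):as.integer(mm[4L])
      H[idx, mm[2L]] <- 3L - H[idx, mm[2L]]
    }
  }
  new("OctadMatrix", calls = matrix(ifelse(H == 1L, "P1", "P2"), n, 8L,
                                    dimnames = list(NULL, strandNames)),
      map = map)
}

#' Simulate sequencing read counts from an octad
#'
#' Per strand library and marker, the total read count is Poisson with the
#' given mean depth; each read reports the true allele with probability
#' `1 - errorRate`, the other parental allele otherwise. Markers with a
#' missing genotype yield no informative reads.
#'
#' @param octad An [OctadMatrix()].
#' @param depth Mean sequencing depth per strand library (default 70).
#' @param errorRate Per-read miscall probability in `[0, 0.5)` (default 0).
#' @param seed Integer seed.
#'
#' @return A [ReadCountTable()].
#' @export
#' @examples
#' map <- buildSnpMap(c(chr1 = 5e4), seed = 1)
#' sim <- simulateMeiosis(map, SimParams(chromLengths = c(chr1 = 5e4)), seed = 1)
#' emitReadCounts(sim$octad, depth = 70, seed = 2)
emitReadCounts <- function(octad, depth = 70, errorRate = 0, seed = 1L) {
  stopifnot(is(octad, "OctadMatrix"))
  if (depth < 0) stop("depth must be >= 0")
  if (errorRate < 0 || errorRate >= 0.5) stop("errorRate must be in [0, 0.5)")
  set.seed(as.integer(seed))
  cl <- octad@calls
  n <- length(cl)
  total <- matrix(stats::rpois(n, depth), nrow(cl), 8L)
  total[is.na(cl)] <- 0L
  correct <- matrix(stats::rbinom(n, as.vector(total), 1 - errorRate),
                    nrow(cl), 8L)
  wrong <- total - correct
  isP1 <- !is.na(cl) & cl == "P1"
  isP2 <- !is.na(cl) & cl == "P2"
  nP1 <- matrix(0L, nrow(cl), 8L, dimnames = dimnames(cl))
  nP2 <- nP1
  nP1[isP1] <- correct[isP1]; nP2[isP1] <- wrong[isP1]
  nP2[isP2] <- correct[isP2]; nP1[isP2] <- wrong[isP2]
  new("ReadCountTable", nP1 = nP1, nP2 = nP2, map = octad@map)
}
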