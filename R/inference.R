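#' @include AllClasses.R
NULL

#' Per-marker segregation profile
#'
#' Counts the parental calls over the 8 strands at every marker. A marker is
#' Mendelian when it segregates 4:4 with no missing strand; any deviation (or
#' missingness) flags it as a candidate for event inference.
#'
#' @param octad An [OctadMatrix()].
#'
#' @return data.frame with columns `chrom`, `pos`, `nP1`, `nP2`, `nMissing`,
#'   `mendelian`.
#' @export
segregationProfile <- function(octad) {
  stopifnot(is(octad, "OctadMatrix"))
  cl <- octad@calls
  nP1 <- rowSums(cl == "P1", na.rm = TRUE)
  nP2 <- rowSums(cl == "P2", na.rm = TRUE)
  nMissing <- rowSums(is.na(cl))
  data.frame(chrom = octad@map@markers$chrom, pos = octad@map@markers$pos,
             nP1 = nP1, nP2 = nP2, nMissing = nMissing,
             mendelian = nP1 == 4L & nP2 == 4L & nMissing == 0L,
             stringsAsFactors = FALSE)
}

#' Per-spore duplex states
#'
#' Combines the two daughter-strand calls of each spore into a duplex state.
#' `HET` (the two daughters disagree) is the signature of retained
#' heteroduplex DNA (5:3 segregation at that marker).
#'
#' @param octad An [OctadMatrix()].
#'
#' @return Character matrix (markers x 4 spores) with values `HOMO_P1`,
#'   `HOMO_P2`, `HET`, `PARTIAL_P1`, `PARTIAL_P2`, `MISSING`.
#' @export
duplexStates <- function(octad) {
  stopifnot(is(octad, "OctadMatrix"))
  cl <- octad@calls
  out <- matrix(NA_character_, nrow(cl), 4L,
                dimnames = list(NULL, paste0("spore", 1:4)))
  for (sp in 1:4) {
    a <- cl[, paste0("s", sp, "a")]
    b <- cl[, paste0("s", sp, "b")]
    st <- rep("MISSING", nrow(cl))
    st[!is.na(a) & !is.na(b) & a == "P1" & b == "P1"] <- "HOMO_P1"
    st[!is.na(a) & !is.na(b) & a == "P2" & b == "P2"] <- "HOMO_P2"
    st[!is.na(a) & !is.na(b) & a != b] <- "HET"
    one <- xor(is.na(a), is.na(b))
    called <- ifelse(is.na(a), b, a)
    st[one & called == "P1"] <- "PARTIAL_P1"
    st[one & called == "P2"] <- "PARTIAL_P2"
    out[, sp] <- st
  }
  out
}

## homoduplex runs of one spore on one chromosome (local indices into `pos`)
.homoRuns <- function(phase, pos) {
  h <- which(!is.na(phase))
  if (!length(h)) return(NULL)
  p <- phase[h]
  r <- rle(p)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  data.frame(phase = r$values,
             firstIdx = h[starts], lastIdx = h[ends],
             firstPos = pos[h[starts]], lastPos = pos[h[ends]],
             span = pos[h[ends]] - pos[h[starts]] + 1)
}

#' Infer the parental phase background of each spore
#'
#' Partitions each chromosome of each spore into parental phase blocks
#' anchored on long runs of concordant homoduplex markers. Boundaries between
#' blocks of opposite phase are candidate crossover points; short deviating
#' runs are left as candidate conversion tracts, not phase switches -- unless
#' their markers still segregate 4:4 with no missing strand, the signature of
#' a genuine phase segment (closely spaced double crossover, or a crossover
#' near a telomere) rather than a conversion tract (which perturbs
#' segregation to 5:3 or 6:2); such runs are promoted to phase blocks with a
#' switch at each edge.
#'
#' @param octad An [OctadMatrix()].
#' @param cfg An [InferenceConfig()]; `minPhaseBlockBp` sets the anchor span
#'   for interior runs, and runs touching a chromosome end anchor at
#'   `mergeGapBp` span.
#'
#' @return A list with elements `phase` (integer matrix, markers x 4, the
#'   expected parental phase 1/2 of each spore), `switches` (data.frame of
#'   phase switches: `spore`, `chrom`, `leftPos`, `rightPos`, `mid`,
#'   `fromPhase`, `toPhase`) and `uncallable` (data.frame of spore x
#'   chromosome combinations with no informative homoduplex marker).
#' @export
inferPhaseBackground <- function(octad, cfg = InferenceConfig()) {
  stopifnot(is(octad, "OctadMatrix"))
  st <- duplexStates(octad)
  segProf <- segregationProfile(octad)
  mk <- octad@map@markers
  n <- nrow(mk)
  bg <- matrix(NA_integer_, n, 4L)
  switches <- list()
  uncallable <- list()
  for (chrom in unique(mk$chrom)) {
    rows <- which(mk$chrom == chrom)
    pos <- mk$pos[rows]
    ## homoduplex phase per spore (1/2/NA), local coordinates
    phm <- matrix(NA_integer_, length(rows), 4L)
    phm[st[rows, ] == "HOMO_P1"] <- 1L
    phm[st[rows, ] == "HOMO_P2"] <- 2L
    runsBySpore <- lapply(1:4, function(sp) .homoRuns(phm[, sp], pos))

    ## anchor determination
    for (sp in 1:4) {
      r <- runsBySpore[[sp]]
      if (is.null(r)) next
      nh <- nrow(r)
      terminal <- seq_len(nh) == 1L | seq_len(nh) == nh
      r$anchor <- r$span >= cfg@minPhaseBlockBp |
        (terminal & r$span >= cfg@mergeGapBp)
      runsBySpore[[sp]] <- r
    }

    ## promote short runs that are genuine phase (double-crossover segments,
    ## crossovers close to a telomere): a homoduplex run whose markers still
    ## segregate 4:4 with no missing strand cannot be a conversion tract
    ## (full conversion is 6:2), so it anchors phase despite its short span
    clean44 <- segProf$nP1[rows] == 4L & segProf$nP2[rows] == 4L &
      segProf$nMissing[rows] == 0L
    for (sp in 1:4) {
      r <- runsBySpore[[sp]]
      if (is.null(r)) next
      for (i in which(!r$anchor)) {
        runMk <- which(!is.na(phm[, sp]))
        runMk <- runMk[runMk >= r$firstIdx[i] & runMk <= r$lastIdx[i]]
        if (length(runMk) && mean(clean44[runMk]) >= 0.5)
          runsBySpore[[sp]]$anchor[i] <- TRUE
      }
    }

    for (sp in 1:4) {
      r <- runsBySpore[[sp]]
      if (is.null(r)) {
        uncallable[[length(uncallable) + 1L]] <-
          data.frame(spore = sp, chrom = chrom, stringsAsFactors = FALSE)
        next
      }
      anchors <- r[r$anchor, , drop = FALSE]
      if (nrow(anchors) == 0L) {
        ## fall back to the longest run as the single anchor
        anchors <- r[which.max(r$span), , drop = FALSE]
      }
      ## collapse consecutive same-phase anchors
      keep <- c(TRUE, diff(anchors$phase) != 0)
      grp <- cumsum(keep)
      anchors <- do.call(rbind, lapply(split(anchors, grp), function(g) {
        data.frame(phase = g$phase[1L], firstIdx = min(g$firstIdx),
                   lastIdx = max(g$lastIdx), firstPos = min(g$firstPos),
                   lastPos = max(g$lastPos), span = NA_real_, anchor = TRUE)
      }))
      ## background assignment and switch placement between anchors
      bgLocal <- rep(NA_integer_, length(rows))
      bgLocal[seq_len(length(rows)) <= anchors$lastIdx[1L]] <- anchors$phase[1L]
      if (nrow(anchors) > 1L) {
        for (j in seq_len(nrow(anchors) - 1L)) {
          a <- anchors[j, ]; b <- anchors[j + 1L, ]
          ## homoduplex markers strictly between the two anchors
          mid <- which(!is.na(phm[, sp]))
          mid <- mid[mid > a$lastIdx & mid < b$firstIdx]
          ## changepoint: maximise agreement (left markers = phase of a,
          ## right markers = phase of b); split k = number assigned left
          if (length(mid)) {
            matchL <- cumsum(phm[mid, sp] == a$phase)
            suffR <- rev(cumsum(rev(phm[mid, sp] == b$phase)))
            score <- c(0, matchL) + c(suffR, 0)
            k <- which.max(score) - 1L
            leftIdx <- if (k > 0L) mid[k] else a$lastIdx
            rightIdx <- if (k < length(mid)) mid[k + 1L] else b$firstIdx
          } else {
            leftIdx <- a$lastIdx
            rightIdx <- b$firstIdx
          }
          splitBp <- (pos[leftIdx] + pos[rightIdx]) / 2
          seg <- which(seq_along(rows) > a$lastIdx &
                         seq_along(rows) <= b$lastIdx)
          bgLocal[seg] <- ifelse(pos[seg] <= splitBp, a$phase, b$phase)
          switches[[length(switches) + 1L]] <- data.frame(
            spore = sp, chrom = chrom,
            leftPos = pos[leftIdx], rightPos = pos[rightIdx],
            mid = splitBp, fromPhase = a$phase, toPhase = b$phase,
            stringsAsFactors = FALSE)
        }
      }
      lastAnchor <- anchors[nrow(anchors), ]
      bgLocal[seq_len(length(rows)) > lastAnchor$lastIdx] <- lastAnchor$phase
      bg[rows, sp] <- bgLocal
    }
  }
  list(
    phase = bg,
    switches = if (length(switches)) do.call(rbind, switches) else
      data.frame(spore = integer(), chrom = character(), leftPos = numeric(),
                 rightPos = numeric(), mid = numeric(), fromPhase = integer(),
                 toPhase = integer(), stringsAsFactors = FALSE),
    uncallable = if (length(uncallable)) do.call(rbind, uncallable) else
      data.frame(spore = integer(), chrom = character(),
                 stringsAsFactors = FALSE)
  )
}

.emptyTractFrame <- function() {
  data.frame(spore = integer(), chrom = character(), firstMarker = integer(),
             lastMarker = integer(), firstPos = numeric(), lastPos = numeric(),
             nDeviant = integer(), carriers = character(),
             stringsAsFactors = FALSE)
}

#' Detect candidate strand-transfer tracts
#'
#' Per spore, finds maximal runs of markers whose duplex state deviates from
#' the inferred phase background: `HET`, opposite-phase `HOMO`, or a
#' `PARTIAL` whose called strand carries the opposite parent. Runs may bridge
#' up to `maxMissingRun` uninformative markers (missing, or partial calls
#' consistent with the background). Each tract records which daughter
#' strand(s) carry the donor allele at each deviant marker (`a`/`b` for a
#' heteroduplex marker, `2` for both strands converted, `p` for a one-strand
#' partial observation).
#'
#' @param octad An [OctadMatrix()].
#' @param phaseBg Result of [inferPhaseBackground()].
#' @param cfg An [InferenceConfig()].
#'
#' @return data.frame with one row per tract: `spore`, `chrom`,
#'   `firstMarker`/`lastMarker` (row indices in the SNP map),
#'   `firstPos`/`lastPos` (bp), `nDeviant`, `carriers` (one code per deviant
#'   marker, in order).
#' @export
detectRawTracts <- function(octad, phaseBg, cfg = InferenceConfig()) {
  stopifnot(is(octad, "OctadMatrix"))
  st <- duplexStates(octad)
  cl <- octad@calls
  mk <- octad@map@markers
  bg <- phaseBg$phase
  out <- list()
  for (chrom in unique(mk$chrom)) {
    rows <- which(mk$chrom == chrom)
    for (sp in 1:4) {
      s <- st[rows, sp]
      p <- bg[rows, sp]
      homoPhase <- ifelse(s == "HOMO_P1", 1L, ifelse(s == "HOMO_P2", 2L, NA))
      partPhase <- ifelse(s == "PARTIAL_P1", 1L,
                          ifelse(s == "PARTIAL_P2", 2L, NA))
      deviant <- (s == "HET") |
        (!is.na(homoPhase) & !is.na(p) & homoPhase != p) |
        (!is.na(partPhase) & !is.na(p) & partPhase != p)
      deviant[is.na(p)] <- FALSE  # uncallable background: nothing to deviate from
      uninf <- s == "MISSING" | (!is.na(partPhase) & !is.na(p) & partPhase == p) |
        is.na(p)
      a <- cl[rows, paste0("s", sp, "a")]

      ## maximal deviant runs bridging short uninformative stretches
      dIdx <- which(deviant)
      if (!length(dIdx)) next
      runStart <- dIdx[1L]
      prev <- dIdx[1L]
      flush <- function(s0, e0) {
        dm <- intersect(s0:e0, dIdx)
        if (length(dm) < cfg@minMarkersPerTract) return()
        ## carrier codes relative to one reference phase per run (the
        ## background at the run's first deviant marker), so a tract lying
        ## across a crossover's background split keeps a coherent donor side
        ref <- p[dm[1L]]
        code <- character(length(dm))
        for (q in seq_along(dm)) {
          mIdx <- dm[q]
          if (s[mIdx] == "HET") {
            code[q] <- if (!is.na(ref) &&
                           a[mIdx] != c("P1", "P2")[ref]) "a" else "b"
          } else if (!is.na(homoPhase[mIdx])) {
            code[q] <- "2"
          } else {
            code[q] <- "p"
          }
        }
        out[[length(out) + 1L]] <<- data.frame(
          spore = sp, chrom = chrom,
          firstMarker = rows[min(dm)], lastMarker = rows[max(dm)],
          firstPos = mk$pos[rows[min(dm)]], lastPos = mk$pos[rows[max(dm)]],
          nDeviant = length(dm),
          carriers = paste(code, collapse = ""),
          stringsAsFactors = FALSE)
      }
      for (i in dIdx[-1L]) {
        gapIdx <- if (i > prev + 1L) (prev + 1L):(i - 1L) else integer()
        bridgeable <- length(gapIdx) <= cfg@maxMissingRun &&
          all(uninf[gapIdx])
        if (!bridgeable) {
          flush(runStart, prev)
          runStart <- i
        }
        prev <- i
      }
      flush(runStart, prev)
    }
  }
  if (length(out)) do.call(rbind, out) else .emptyTractFrame()
}

#' Merge tracts and crossover points into events
#'
#' Single-linkage clustering of candidate tracts and phase switches along
#' each chromosome: items whose bp gap (distance between nearest affected
#' markers) is strictly less than `mergeGapBp` are considered to have arisen
#' from the same DSB and are combined into one event.
#'
#' @param tracts data.frame from [detectRawTracts()].
#' @param switches data.frame of phase switches from [inferPhaseBackground()].
#' @param cfg An [InferenceConfig()].
#'
#' @return A list of clusters; each cluster is a list with elements `tracts`
#'   and `switches` (row subsets) plus `chrom`, `start`, `end` (bp interval
#'   spanned by the cluster's affected markers / switch intervals).
#' @export
mergeEvents <- function(tracts, switches, cfg = InferenceConfig()) {
  items <- rbind(
    if (nrow(tracts)) data.frame(kind = "tract", id = seq_len(nrow(tracts)),
                                 chrom = tracts$chrom,
                                 start = tracts$firstPos,
                                 end = tracts$lastPos,
                                 stringsAsFactors = FALSE),
    if (nrow(switches)) data.frame(kind = "switch",
                                   id = seq_len(nrow(switches)),
                                   chrom = switches$chrom,
                                   start = switches$leftPos,
                                   end = switches$rightPos,
                                   stringsAsFactors = FALSE))
  if (is.null(items) || nrow(items) == 0L) return(list())
  clusters <- list()
  for (chrom in unique(items$chrom)) {
    it <- items[items$chrom == chrom, , drop = FALSE]
    it <- it[order(it$start, it$end), , drop = FALSE]
    grp <- integer(nrow(it))
    g <- 1L
    grp[1L] <- g
    maxEnd <- it$end[1L]
    for (i in seq_len(nrow(it))[-1L]) {
      gap <- it$start[i] - maxEnd
      if (gap >= cfg@mergeGapBp) g <- g + 1L
      grp[i] <- g
      maxEnd <- max(maxEnd, it$end[i])
    }
    for (gg in unique(grp)) {
      sel <- it[grp == gg, , drop = FALSE]
      clusters[[length(clusters) + 1L]] <- list(
        tracts = tracts[sel$id[sel$kind == "tract"], , drop = FALSE],
        switches = switches[sel$id[sel$kind == "switch"], , drop = FALSE],
        chrom = chrom, start = min(sel$start), end = max(sel$end))
    }
  }
  clusters
}

#' Classify a merged event
#'
#' An event is a crossover iff its cluster contains a reciprocal phase switch
#' between two spores (opposite switch directions). Tract patterns determine
#' the heteroduplex category: `full_conversion` (both strands of one spore
#' converted, 6:2), `SDSA_like_hDNA` (one contiguous one-strand heteroduplex
#' tract on a single spore), `trans_hDNA` (the donor-carrying strand switches
#' sides once across the event), `symmetric_hDNA` (complementary heteroduplex
#' on two spores of opposite phase over overlapping markers; net 4:4 but
#' aberrant), and `complex` for anything else. A crossover with no detectable
#' tract is categorised `none`.
#'
#' @param cluster One cluster from [mergeEvents()].
#' @param phaseBg Result of [inferPhaseBackground()] (used to check phase
#'   opposition for symmetric heteroduplex).
#' @param map The [SNPMap()].
#'
#' @return list(type, category, spores, coPos).
#' @export
classifyEvent <- function(cluster, phaseBg, map) {
  tr <- cluster$tracts
  sw <- cluster$switches
  type <- "NCO"
  coPos <- NA_real_
  if (nrow(sw) >= 2L) {
    for (i in seq_len(nrow(sw) - 1L)) {
      for (j in (i + 1L):nrow(sw)) {
        if (sw$spore[i] != sw$spore[j] &&
            sw$fromPhase[i] == sw$toPhase[j] &&
            sw$toPhase[i] == sw$fromPhase[j]) {
          type <- "CO"
          if (is.na(coPos)) coPos <- mean(c(sw$mid[i], sw$mid[j]))
        }
      }
    }
  }
  spores <- sort(unique(c(tr$spore, sw$spore)))

  tractSpores <- unique(tr$spore)
  category <- if (nrow(tr) == 0L) {
    if (type == "CO") "none" else "complex"
  } else if (length(tractSpores) == 1L) {
    carriers <- paste(tr$carriers[order(tr$firstPos)], collapse = "")
    chars <- strsplit(carriers, "")[[1L]]
    core <- chars[chars != "p"]
    if (!length(core)) "complex"
    else if (all(core == "2")) "full_conversion"
    else if (all(core %in% c("a", "b"))) {
      nSwitch <- sum(diff(match(core, c("a", "b"))) != 0)
      if (nSwitch == 0L) "SDSA_like_hDNA"
      else if (nSwitch == 1L) "trans_hDNA"
      else "complex"
    } else "complex"
  } else if (length(tractSpores) == 2L) {
    t1 <- tr[tr$spore == tractSpores[1L], , drop = FALSE]
    t2 <- tr[tr$spore == tractSpores[2L], , drop = FALSE]
    pureHet <- function(tt) all(strsplit(paste(tt$carriers, collapse = ""),
                                         "")[[1L]] %in% c("a", "b"))
    overlap <- min(t1$firstPos) <= max(t2$lastPos) &&
      min(t2$firstPos) <= max(t1$lastPos)
    m1 <- t1$firstMarker[1L]
    opposite <- !is.na(phaseBg$phase[m1, tractSpores[1L]]) &&
      !is.na(phaseBg$phase[m1, tractSpores[2L]]) &&
      phaseBg$phase[m1, tractSpores[1L]] != phaseBg$phase[m1, tractSpores[2L]]
    if (pureHet(t1) && pureHet(t2) && overlap && opposite)
      "symmetric_hDNA" else "complex"
  } else "complex"

  list(type = type, category = category, spores = spores, coPos = coPos)
}

#' Tract length of an event under a measurement convention
#'
#' `min` is the distance spanned by the affected markers themselves
#' (`pos(last) - pos(first) + 1`); `max` extends to just inside the nearest
#' unaffected informative markers on either side; `mid` runs between the
#' midpoints of the two flanking marker intervals. When no informative marker
#' flanks the event on one side, that side clamps to the chromosome end.
#'
#' @param firstMarker,lastMarker Row indices (in the SNP map) of the first
#'   and last affected marker.
#' @param map The [SNPMap()].
#' @param convention `"min"`, `"mid"` or `"max"`.
#' @param informative Optional logical vector (one per map row): whether a
#'   marker is usable as a flanking marker. Defaults to all `TRUE`.
#'
#' @return Length in bp.
#' @export
#' @examples
#' map <- SNPMap(chrom = rep("c", 4), pos = c(9800L, 10000L, 11000L, 11300L),
#'               alleleP1 = rep("A", 4), alleleP2 = rep("C", 4),
#'               chromLengths = c(c = 20000))
#' tractLength(2, 3, map, "min")   # 1001
#' tractLength(2, 3, map, "mid")   # 1250
#' tractLength(2, 3, map, "max")   # 1499
tractLength <- function(firstMarker, lastMarker, map,
                        convention = c("mid", "min", "max"),
                        informative = NULL) {
  convention <- match.arg(convention)
  mk <- map@markers
  if (is.na(firstMarker) || is.na(lastMarker)) return(NA_real_)
  chrom <- mk$chrom[firstMarker]
  L <- map@chromLengths[[chrom]]
  posFirst <- mk$pos[firstMarker]
  posLast <- mk$pos[lastMarker]
  if (convention == "min") return(posLast - posFirst + 1)
  if (is.null(informative)) informative <- rep(TRUE, nrow(mk))
  before <- which(mk$chrom == chrom & mk$pos < posFirst & informative)
  after <- which(mk$chrom == chrom & mk$pos > posLast & informative)
  prevPos <- if (length(before)) mk$pos[max(before)] else 0
  nextPos <- if (length(after)) mk$pos[min(after)] else L + 1
  if (convention == "max") return(nextPos - prevPos - 1)
  (posLast + nextPos) / 2 - (posFirst + prevPos) / 2
}

#' Infer recombination events from an octad
#'
#' Deterministic composition of the inference stages: segregation profile,
#' phase background, tract detection, positional merging (< `mergeGapBp`
#' combines items into one DSB event), classification and tract-length
#' measurement under all three conventions. Events are returned sorted by
#' chromosome and start.
#'
#' @param octad An [OctadMatrix()].
#' @param cfg An [InferenceConfig()].
#' @param meiosis,genotype Labels attached to every event.
#'
#' @return An [EventSet()].
#' @export
#' @examples
#' map <- buildSnpMap(c(chr1 = 3e5), seed = 1)
#' sim <- simulateMeiosis(map, SimParams(chromLengths = c(chr1 = 3e5)), seed = 1)
#' inferEvents(sim$octad)
inferEvents <- function(octad, cfg = InferenceConfig(),
                        meiosis = "m1", genotype = "WT") {
  stopifnot(is(octad, "OctadMatrix"))
  map <- octad@map
  phaseBg <- inferPhaseBackground(octad, cfg)
  tracts <- detectRawTracts(octad, phaseBg, cfg)
  clusters <- mergeEvents(tracts, phaseBg$switches, cfg)
  st <- duplexStates(octad)
  rowsList <- lapply(clusters, function(cl) {
    info <- classifyEvent(cl, phaseBg, map)
    tr <- cl$tracts
    if (nrow(tr)) {
      fm <- min(tr$firstMarker); lm <- max(tr$lastMarker)
      inform <- rowSums(st[, info$spores, drop = FALSE] == "MISSING") == 0L
      lens <- vapply(c("min", "mid", "max"), function(cv)
        tractLength(fm, lm, map, cv, informative = inform), numeric(1L))
      start <- map@markers$pos[fm]; end <- map@markers$pos[lm]
      nMarkers <- length(unique(unlist(lapply(seq_len(nrow(tr)), function(i)
        tr$firstMarker[i]:tr$lastMarker[i]))))
    } else {
      lens <- c(min = NA_real_, mid = NA_real_, max = NA_real_)
      start <- cl$start; end <- cl$end
      nMarkers <- 0L
    }
    data.frame(chrom = cl$chrom, start = start, end = end,
               eventId = NA_character_, type = info$type,
               category = info$category,
               spores = paste(info$spores, collapse = ","),
               coPos = info$coPos,
               lenMin = unname(lens[1L]), lenMid = unname(lens[2L]),
               lenMax = unname(lens[3L]), nMarkers = nMarkers,
               meiosis = meiosis, genotype = genotype,
               stringsAsFactors = FALSE)
  })
  ev <- if (length(rowsList)) do.call(rbind, rowsList) else emptyEventFrame()
  if (nrow(ev)) {
    ev <- ev[order(match(ev$chrom, unique(map@markers$chrom)), ev$start), ,
             drop = FALSE]
    ev$eventId <- sprintf("%s_%s_e%04d", genotype, meiosis, seq_len(nrow(ev)))
    rownames(ev) <- NULL
  }
  new("EventSet", events = ev, chromLengths = map@chromLengths)
}

#' Events as genomic ranges
#'
#' Converts an [EventSet()] to a `GRanges` (0-based half-open intervals are
#' used when exporting to BED via [writeEvents()]; the `GRanges` itself is
#' 1-based closed, the Bioconductor convention).
#'
#' @param x An [EventSet()].
#'
#' @return A [GenomicRanges::GRanges] with event metadata columns.
#' @export
eventsAsGRanges <- function(x) {
  stopifnot(is(x, "EventSet"))
  ev <- x@events
  gr <- GenomicRanges::GRanges(
    seqnames = ev$chrom,
    ranges = IRanges::IRanges(start = ev$start, end = ev$end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    ev[, setdiff(names(ev), c("chrom", "start", "end")), drop = FALSE])
  if (length(x@chromLengths)) {
    present <- intersect(names(x@chromLengths),
                         GenomeInfoDb::seqlevels(gr))
    GenomeInfoDb::seqlengths(gr)[present] <- x@chromLengths[present]
  }
  gr
}
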