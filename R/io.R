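#' @include AllClasses.R
NULL

## checks a TSV for ragged rows before parsing; reports 1-based line numbers
.checkRagged <- function(path, nExpected) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  bad <- which(nf != nExpected)
  if (length(bad))
    stop(sprintf("%s: line(s) %s have %s fields, expected %d",
                 basename(path), paste(bad, collapse = ", "),
                 paste(unique(nf[bad]), collapse = "/"), nExpected))
}

#' Read and write a SNP map
#'
#' The SNP map TSV has columns `chrom  pos  allele_p1  allele_p2` (1-based
#' positions). Chromosome lengths are carried in `## chromLength:` header
#' comment lines on write and recovered on read; absent those, each
#' chromosome length defaults to its last marker position.
#'
#' @param path File path.
#' @param map A [SNPMap()] (for writing).
#'
#' @return `readSnpMap()` returns a [SNPMap()]; `writeSnpMap()` its path,
#'   invisibly.
#' @export
readSnpMap <- function(path) {
  if (!file.exists(path)) stop("SNP map file not found: ", path)
  header <- readLines(path, n = 200L)
  lenLines <- grep("^## chromLength:", header, value = TRUE)
  chromLengths <- numeric()
  if (length(lenLines)) {
    parts <- strsplit(sub("^## chromLength:\\s*", "", lenLines), "\t")
    chromLengths <- stats::setNames(
      as.numeric(vapply(parts, `[`, "", 2L)),
      vapply(parts, `[`, "", 1L))
  }
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "allele_p1", "allele_p2")
  if (!all(need %in% names(d)))
    stop("SNP map must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(d[, c("chrom", "pos")]))
    stop("duplicate marker positions in SNP map")
  unsorted <- unlist(lapply(split(d$pos, d$chrom), function(p) any(diff(p) < 0)))
  if (any(unsorted))
    stop("unsorted positions in SNP map (chromosome ",
         paste(names(unsorted)[unsorted], collapse = ", "), ")")
  if (!length(chromLengths))
    chromLengths <- vapply(split(d$pos, d$chrom), max, numeric(1L))
  chromLengths <- chromLengths[unique(d$chrom)]
  SNPMap(chrom = d$chrom, pos = d$pos, alleleP1 = d$allele_p1,
         alleleP2 = d$allele_p2, chromLengths = chromLengths)
}

#' @rdname readSnpMap
#' @export
writeSnpMap <- function(map, path) {
  stopifnot(is(map, "SNPMap"))
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(map@chromLengths))
    writeLines(sprintf("## chromLength:%s\t%g", ch, map@chromLengths[[ch]]),
               con)
  m <- map@markers
  names(m) <- c("chrom", "pos", "allele_p1", "allele_p2")
  utils::write.table(m, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write an octad genotype matrix
#'
#' The octad TSV has columns `chrom  pos  s1a ... s4b`; calls are `P1`, `P2`
#' or `NA`. Positions must match the SNP map when one is supplied.
#'
#' @param path File path.
#' @param map Optional [SNPMap()]; if `NULL`, a minimal map (alleles `A`/`B`)
#'   is built from the file's coordinates.
#' @param octad An [OctadMatrix()] (for writing).
#'
#' @return `readOctad()` returns an [OctadMatrix()]; `writeOctad()` its
#'   path, invisibly.
#' @export
readOctad <- function(path, map = NULL) {
  if (!file.exists(path)) stop("octad file not found: ", path)
  .checkRagged(path, 10L)
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = "NA", colClasses = "character")
  need <- c("chrom", "pos", octadStrandNames())
  if (!all(need %in% names(d)))
    stop("octad file must have columns: ", paste(need, collapse = ", "))
  d$pos <- as.numeric(d$pos)
  cl <- as.matrix(d[, octadStrandNames()])
  badVals <- stats::na.omit(setdiff(unique(as.vector(cl)), c("P1", "P2")))
  if (length(badVals))
    stop("invalid genotype call value(s): ", paste(badVals, collapse = ", "),
         " (allowed: P1, P2, NA)")
  if (anyDuplicated(d[, c("chrom", "pos")]))
    stop("duplicate marker positions in octad file")
  unsorted <- unlist(lapply(split(d$pos, d$chrom), function(p) any(diff(p) < 0)))
  if (any(unsorted)) stop("unsorted positions in octad file")
  if (is.null(map)) {
    lens <- vapply(split(d$pos, d$chrom), max, numeric(1L))[unique(d$chrom)]
    map <- SNPMap(chrom = d$chrom, pos = d$pos,
                  alleleP1 = rep("A", nrow(d)), alleleP2 = rep("B", nrow(d)),
                  chromLengths = lens)
  } else {
    if (!identical(as.numeric(map@markers$pos), d$pos) ||
        !identical(as.character(map@markers$chrom), d$chrom))
      stop("octad file coordinates do not match the SNP map")
  }
  dimnames(cl) <- list(NULL, octadStrandNames())
  new("OctadMatrix", calls = cl, map = map)
}

#' @rdname readOctad
#' @export
writeOctad <- function(octad, path) {
  stopifnot(is(octad, "OctadMatrix"))
  d <- cbind(octad@map@markers[, c("chrom", "pos")],
             as.data.frame(octad@calls, stringsAsFactors = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read and write per-strand allele read counts
#'
#' Long-format TSV with columns `chrom  pos  strand  n_p1  n_p2`, one row per
#' marker and strand library.
#'
#' @param path File path.
#' @param map A [SNPMap()] giving the marker universe (required for reading).
#' @param counts A [ReadCountTable()] (for writing).
#'
#' @return `readCounts()` returns a [ReadCountTable()]; `writeCounts()` its
#'   path, invisibly.
#' @export
readCounts <- function(path, map) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  .checkRagged(path, 5L)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "strand", "n_p1", "n_p2")
  if (!all(need %in% names(d)))
    stop("counts file must have columns: ", paste(need, collapse = ", "))
  badStrand <- setdiff(unique(d$strand), octadStrandNames())
  if (length(badStrand))
    stop("unknown strand label(s): ", paste(badStrand, collapse = ", "))
  mk <- map@markers
  key <- paste(mk$chrom, mk$pos)
  idx <- match(paste(d$chrom, d$pos), key)
  if (anyNA(idx))
    stop("counts file contains positions absent from the SNP map")
  nP1 <- matrix(0L, nrow(mk), 8L,
                dimnames = list(NULL, octadStrandNames()))
  nP2 <- nP1
  col <- match(d$strand, octadStrandNames())
  nP1[cbind(idx, col)] <- as.integer(d$n_p1)
  nP2[cbind(idx, col)] <- as.integer(d$n_p2)
  new("ReadCountTable", nP1 = nP1, nP2 = nP2, map = map)
}

#' @rdname readCounts
#' @export
writeCounts <- function(counts, path) {
  stopifnot(is(counts, "ReadCountTable"))
  mk <- counts@map@markers
  d <- do.call(rbind, lapply(octadStrandNames(), function(s)
    data.frame(chrom = mk$chrom, pos = mk$pos, strand = s,
               n_p1 = counts@nP1[, s], n_p2 = counts@nP2[, s],
               stringsAsFactors = FALSE)))
  d <- d[order(match(d$chrom, unique(mk$chrom)), d$pos, d$strand), ]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write recombination events
#'
#' BED-flavoured TSV: 0-based half-open `chrom  start  end`, then event id,
#' type, category, spores, CO position, the three tract-length conventions,
#' marker count, meiosis and genotype. Intervals are converted from the
#' package's internal 1-based closed representation in this one place.
#'
#' @param path File path.
#' @param x An [EventSet()] (for writing).
#'
#' @return `readEvents()` returns an [EventSet()]; `writeEvents()` its path,
#'   invisibly.
#' @export
writeEvents <- function(x, path) {
  stopifnot(is(x, "EventSet"))
  ev <- x@events
  bed <- data.frame(chrom = ev$chrom,
                    start = ev$start - 1,   # 0-based half-open
                    end = ev$end,
                    event_id = ev$eventId, type = ev$type,
                    category = ev$category, spores = ev$spores,
                    co_pos = ev$coPos,
                    len_min = ev$lenMin, len_mid = ev$lenMid,
                    len_max = ev$lenMax, n_markers = ev$nMarkers,
                    meiosis = ev$meiosis, genotype = ev$genotype,
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(x@chromLengths))
    writeLines(sprintf("## chromLength:%s\t%g", ch, x@chromLengths[[ch]]),
               con)
  utils::write.table(bed, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path) {
  if (!file.exists(path)) stop("events file not found: ", path)
  header <- readLines(path, n = 200L)
  lenLines <- grep("^## chromLength:", header, value = TRUE)
  chromLengths <- numeric()
  if (length(lenLines)) {
    parts <- strsplit(sub("^## chromLength:\\s*", "", lenLines), "\t")
    chromLengths <- stats::setNames(as.numeric(vapply(parts, `[`, "", 2L)),
                                    vapply(parts, `[`, "", 1L))
  }
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  ev <- data.frame(chrom = d$chrom, start = d$start + 1, end = d$end,
                   eventId = d$event_id, type = d$type,
                   category = d$category, spores = as.character(d$spores),
                   coPos = d$co_pos, lenMin = d$len_min, lenMid = d$len_mid,
                   lenMax = d$len_max, nMarkers = d$n_markers,
                   meiosis = d$meiosis, genotype = d$genotype,
                   stringsAsFactors = FALSE)
  new("EventSet", events = ev, chromLengths = chromLengths)
}

#' Write a summary as JSON
#'
#' @param summary Result of [summarizeEvents()], possibly augmented with
#'   interference fits.
#' @param path Output path.
#'
#' @return The path, invisibly.
#' @export
writeSummary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Import read counts from eight single-sample VCFs
#'
#' Import shim for real octad data: one VCF per strand library, each carrying
#' per-allele depths in the `AD` format field. Sites are matched to the SNP
#' map by chromosome and position; the parent-1 allele is taken to be the
#' REF allele of the map (`alleleP1`) when it matches REF/ALT, and counts
#' default to zero at unmatched sites.
#'
#' @param paths Character vector of 8 VCF paths, in strand order
#'   `s1a` ... `s4b`.
#' @param map A [SNPMap()].
#'
#' @return A [ReadCountTable()].
#' @export
readCountsFromVcfs <- function(paths, map) {
  if (length(paths) != 8L)
    stop("exactly 8 single-sample VCFs are required (strands s1a..s4b)")
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("readCountsFromVcfs requires the VariantAnnotation package")
  mk <- map@markers
  key <- paste(mk$chrom, mk$pos)
  nP1 <- matrix(0L, nrow(mk), 8L, dimnames = list(NULL, octadStrandNames()))
  nP2 <- nP1
  for (i in seq_along(paths)) {
    vcf <- VariantAnnotation::readVcf(paths[i])
    rr <- SummarizedExperiment::rowRanges(vcf)
    chrom <- as.character(GenomeInfoDb::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    ref <- as.character(rr$REF)
    alt <- vapply(as(rr$ALT, "CharacterList"),
                  function(a) if (length(a)) a[[1L]] else ".", "")
    ad <- VariantAnnotation::geno(vcf)$AD
    idx <- match(paste(chrom, pos), key)
    for (j in which(!is.na(idx))) {
      counts <- unlist(ad[j, 1L])
      if (length(counts) < 1L) next
      row <- idx[j]
      c1 <- counts[1L]
      c2 <- if (length(counts) > 1L) counts[2L] else 0L
      if (ref[j] == mk$alleleP1[row] && alt[j] %in% c(mk$alleleP2[row], ".")) {
        nP1[row, i] <- c1; nP2[row, i] <- c2
      } else if (ref[j] == mk$alleleP2[row] &&
                 alt[j] %in% c(mk$alleleP1[row], ".")) {
        nP2[row, i] <- c1; nP1[row, i] <- c2
      }
    }
  }
  new("ReadCountTable", nP1 = nP1, nP2 = nP2, map = map)
}
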