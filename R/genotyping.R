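#' @include AllClasses.R
NULL

#' Call a strand genotype from allele read counts
#'
#' A genotype is valid when only one parental allele has reads and its count
#' lies within the single-allele bounds, or when both alleles have reads, the
#' more abundant lies within the majority bounds and the less abundant is
#' strictly below the minority cutoff. Everything else -- including equal
#' nonzero counts, where no "most abundant" allele exists -- is missing.
#'
#' @param nP1,nP2 Non-negative integer read counts (vectorised) supporting
#'   the parent-1 and parent-2 allele.
#' @param cfg A [GenotypeCallConfig()].
#'
#' @return Character vector with values `"P1"`, `"P2"` or `NA`.
#' @export
#' @examples
#' callGenotype(70, 0)        # "P1"
#' callGenotype(100, 4)       # "P1": major in [40,150], minor < 5
#' callGenotype(c(14, 151, 100, 6), c(0, 0, 5, 6))  # all NA
callGenotype <- function(nP1, nP2, cfg = GenotypeCallConfig()) {
  if (length(nP1) != length(nP2))
    stop("nP1 and nP2 must have equal length")
  if (any(nP1 < 0, na.rm = TRUE) || any(nP2 < 0, na.rm = TRUE))
    stop("read counts must be >= 0")
  hi <- pmax(nP1, nP2)
  lo <- pmin(nP1, nP2)
  mono <- lo == 0 & hi >= cfg@monoMin & hi <= cfg@monoMax
  duo <- lo > 0 & hi > lo &
    hi >= cfg@duoMajorMin & hi <= cfg@duoMajorMax & lo < cfg@duoMinorLt
  out <- rep(NA_character_, length(nP1))
  valid <- mono | duo
  out[valid & nP1 > nP2] <- "P1"
  out[valid & nP2 > nP1] <- "P2"
  out
}

#' Call the full eight-strand genotype matrix
#'
#' Applies [callGenotype()] element-wise to a [ReadCountTable()] and reports
#' per-strand missingness.
#'
#' @param table A [ReadCountTable()] covering the 8 strand libraries.
#' @param cfg A [GenotypeCallConfig()].
#' @param verbose If `TRUE`, print per-strand missingness rates.
#'
#' @return An [OctadMatrix()]. Per-strand missingness rates are attached as
#'   attribute `"missingness"` of the call matrix.
#' @export
callMatrix <- function(table, cfg = GenotypeCallConfig(), verbose = FALSE) {
  stopifnot(is(table, "ReadCountTable"))
  if (ncol(table@nP1) != 8L)
    stop("a read-count table must cover exactly 8 strand libraries")
  cl <- matrix(callGenotype(as.vector(table@nP1), as.vector(table@nP2), cfg),
               nrow(table@nP1), 8L, dimnames = dimnames(table@nP1))
  miss <- colMeans(is.na(cl))
  if (verbose)
    message("per-strand missingness: ",
            paste(sprintf("%s=%.4f", names(miss), miss), collapse = " "))
  attr(cl, "missingness") <- miss
  new("OctadMatrix", calls = cl, map = table@map)
}
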