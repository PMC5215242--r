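#' @include AllClasses.R
NULL

#' Summary statistics over inferred events
#'
#' Tract-length medians and means per genotype and event type (under one
#' length convention), CO/NCO counts per meiosis with the standard error of
#' the mean across meioses of a genotype, and a separate tally of symmetric
#' heteroduplex events (count and mean length), which are rare and reported
#' on their own.
#'
#' Events without a measurable tract (`nMarkers == 0`, e.g. a crossover with
#' no detectable conversion tract) are excluded from the length statistics
#' but counted in the per-meiosis event counts.
#'
#' @param x An [EventSet()] (or plain event data.frame).
#' @param convention Length convention used for the statistics: `"mid"`
#'   (default), `"min"` or `"max"`.
#'
#' @return list with elements:
#'   * `tracts`: data.frame `genotype`, `type`, `n`, `medianBp`, `meanBp`,
#'     `convention`;
#'   * `counts`: data.frame `genotype`, `type`, `meanPerMeiosis`, `se`,
#'     `nMeioses`;
#'   * `perMeiosis`: data.frame `genotype`, `meiosis`, `nCO`, `nNCO`;
#'   * `symmetric`: data.frame `genotype`, `n`, `meanBp`, `nMeioses`.
#' @export
summarizeEvents <- function(x, convention = c("mid", "min", "max")) {
  convention <- match.arg(convention)
  ev <- if (is(x, "EventSet")) x@events else x
  lenCol <- paste0("len", toupper(substring(convention, 1, 1)),
                   substring(convention, 2))
  withLen <- ev[!is.na(ev[[lenCol]]) & ev$nMarkers > 0L, , drop = FALSE]

  tracts <- do.call(rbind, lapply(
    split(withLen, list(withLen$genotype, withLen$type), drop = TRUE),
    function(g) data.frame(genotype = g$genotype[1L], type = g$type[1L],
                           n = nrow(g),
                           medianBp = stats::median(g[[lenCol]]),
                           meanBp = mean(g[[lenCol]]),
                           convention = convention,
                           stringsAsFactors = FALSE)))
  if (is.null(tracts))
    tracts <- data.frame(genotype = character(), type = character(),
                         n = integer(), medianBp = numeric(),
                         meanBp = numeric(), convention = character())

  perMeiosis <- do.call(rbind, lapply(
    split(ev, list(ev$genotype, ev$meiosis), drop = TRUE),
    function(g) data.frame(genotype = g$genotype[1L], meiosis = g$meiosis[1L],
                           nCO = sum(g$type == "CO"),
                           nNCO = sum(g$type == "NCO"),
                           stringsAsFactors = FALSE)))
  if (is.null(perMeiosis))
    perMeiosis <- data.frame(genotype = character(), meiosis = character(),
                             nCO = integer(), nNCO = integer())

  counts <- do.call(rbind, lapply(split(perMeiosis, perMeiosis$genotype),
    function(g) {
      se <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
                        else NA_real_
      rbind(
        data.frame(genotype = g$genotype[1L], type = "CO",
                   meanPerMeiosis = mean(g$nCO), se = se(g$nCO),
                   nMeioses = nrow(g), stringsAsFactors = FALSE),
        data.frame(genotype = g$genotype[1L], type = "NCO",
                   meanPerMeiosis = mean(g$nNCO), se = se(g$nNCO),
                   nMeioses = nrow(g), stringsAsFactors = FALSE))
    }))
  if (is.null(counts))
    counts <- data.frame(genotype = character(), type = character(),
                         meanPerMeiosis = numeric(), se = numeric(),
                         nMeioses = integer())

  sym <- ev[ev$category == "symmetric_hDNA" & !is.na(ev[[lenCol]]), ,
            drop = FALSE]
  symmetric <- do.call(rbind, lapply(split(sym, sym$genotype), function(g)
    data.frame(genotype = g$genotype[1L], n = nrow(g),
               meanBp = mean(g[[lenCol]]),
               nMeioses = length(unique(g$meiosis)),
               stringsAsFactors = FALSE)))
  if (is.null(symmetric))
    symmetric <- data.frame(genotype = character(), n = integer(),
                            meanBp = numeric(), nMeioses = integer())

  rownames(tracts) <- rownames(counts) <- rownames(perMeiosis) <-
    rownames(symmetric) <- NULL
  list(tracts = tracts, counts = counts, perMeiosis = perMeiosis,
       symmetric = symmetric)
}
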