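#' @include AllClasses.R
NULL

#' Inter-crossover distances
#'
#' Successive differences between crossover midpoints, per chromosome of each
#' meiosis. Chromosomes with fewer than two crossovers contribute nothing.
#' Gaps are pooled across chromosomes and meioses within each genotype, the
#' sample on which the interference gamma model is fitted.
#'
#' @param x An [EventSet()] (or plain event data.frame) carrying `coPos`,
#'   `chrom`, `meiosis` and `genotype` for CO events.
#'
#' @return data.frame with columns `genotype`, `meiosis`, `chrom`, `gap` (bp).
#' @export
#' @examples
#' ev <- emptyEventFrame()
#' ev[1:2, c("chrom", "type", "coPos", "meiosis", "genotype")] <-
#'   list("chr1", "CO", c(1e5, 3e5), "m1", "WT")
#' interCoDistances(EventSet(ev, c(chr1 = 5e5)))$gap  # 2e5
interCoDistances <- function(x) {
  ev <- if (is(x, "EventSet")) x@events else x
  co <- ev[ev$type == "CO" & !is.na(ev$coPos), , drop = FALSE]
  if (nrow(co) == 0L)
    return(data.frame(genotype = character(), meiosis = character(),
                      chrom = character(), gap = numeric(),
                      stringsAsFactors = FALSE))
  parts <- split(co, list(co$genotype, co$meiosis, co$chrom), drop = TRUE)
  out <- lapply(parts, function(g) {
    if (nrow(g) < 2L) return(NULL)
    p <- sort(g$coPos)
    data.frame(genotype = g$genotype[1L], meiosis = g$meiosis[1L],
               chrom = g$chrom[1L], gap = diff(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(genotype = character(), meiosis = character(),
                      chrom = character(), gap = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Gamma log-likelihood of a sample
#'
#' @param x Positive sample.
#' @param shape,scale Gamma parameters.
#' @return Log-likelihood in nats.
#' @export
gammaLoglik <- function(x, shape, scale) {
  sum(stats::dgamma(x, shape = shape, scale = scale, log = TRUE))
}

#' Maximum-likelihood gamma fit of inter-crossover distances
#'
#' Fits a gamma distribution by maximum likelihood. The shape MLE solves the
#' score equation `log(shape) - digamma(shape) = log(mean(x)) - mean(log(x))`
#' (solved by safeguarded Newton iteration with a bisection fallback); the
#' scale MLE is `mean(x) / shape`. The shape parameter is the crossover
#' interference statistic: 1 means no interference, values above 1 positive
#' interference.
#'
#' @param gaps Vector of at least two positive, not-all-equal gap lengths.
#' @param tol Convergence tolerance on the score equation (default 1e-10).
#'
#' @return A [GammaFit()].
#' @export
#' @examples
#' set.seed(1)
#' fit <- fitGammaMle(rgamma(500, shape = 2.3, scale = 5e4))
#' gammaShape(fit)
fitGammaMle <- function(gaps, tol = 1e-10) {
  if (length(gaps) < 2L)
    stop("need at least two gaps to fit a gamma distribution")
  if (any(!is.finite(gaps)) || any(gaps <= 0))
    stop("gaps must be positive and finite")
  if (stats::var(gaps) == 0)
    stop("zero variance: all gaps equal, gamma MLE is degenerate")
  m <- mean(gaps)
  s <- log(m) - mean(log(gaps))   # > 0 by Jensen unless degenerate
  ## standard initialisation (Minka/Choi-Wette)
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  f <- function(k) log(k) - digamma(k) - s
  lo <- k; hi <- k
  while (f(lo) < 0) lo <- lo / 2
  while (f(hi) > 0) hi <- hi * 2
  converged <- FALSE
  for (it in 1:100) {
    fk <- f(k)
    if (abs(fk) < tol) { converged <- TRUE; break }
    if (fk > 0) lo <- k else hi <- k
    step <- fk / (1 / k - trigamma(k))
    kNew <- k - step
    if (!is.finite(kNew) || kNew <= lo || kNew >= hi) kNew <- (lo + hi) / 2
    k <- kNew
  }
  scale <- m / k
  GammaFit(shape = k, scale = scale,
           loglik = gammaLoglik(gaps, k, scale),
           nGaps = length(gaps), converged = converged)
}

#' Fit interference per genotype
#'
#' Pools inter-crossover gaps per genotype and fits the gamma model to each.
#'
#' @param gaps data.frame from [interCoDistances()].
#'
#' @return Named list of [GammaFit()] objects, one per genotype. Genotypes
#'   whose gap sample is degenerate (fewer than two gaps, or zero variance)
#'   are dropped with a warning.
#' @export
fitInterference <- function(gaps) {
  fits <- lapply(split(gaps$gap, gaps$genotype), function(g)
    tryCatch(fitGammaMle(g), error = function(e) {
      warning("interference fit skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    }))
  Filter(Negate(is.null), fits)
}
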