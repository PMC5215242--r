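#' @include AllClasses.R
NULL

## All size-n1 subsets of seq_len(n) as a logical membership matrix
## (n x choose(n, n1)); used by the exact permutation-null paths.
.subsetMembership <- function(n, n1) {
  comb <- utils::combn(n, n1)
  m <- matrix(FALSE, n, ncol(comb))
  m[cbind(as.vector(comb), rep(seq_len(ncol(comb)), each = n1))] <- TRUE
  m
}

.ksStatistic <- function(a, b) {
  pool <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(pool)
  Fb <- stats::ecdf(b)(pool)
  max(abs(Fa - Fb))
}

## asymptotic two-sided Kolmogorov tail: Q(t) = 2 sum (-1)^{j-1} exp(-2 j^2 t^2)
.ksAsymptoticP <- function(t) {
  if (t < 1e-3) return(1)
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * t^2))
  min(1, max(0, p))
}

#' Two-sample Kolmogorov-Smirnov comparison of gap distributions
#'
#' Compares two inter-crossover distance (or any other) samples. The D
#' statistic is the maximum absolute difference between the two empirical
#' CDFs. For small samples (enumeration feasible) the p-value is exact,
#' computed over all assignments of the pooled values to the two groups
#' (ties handled by working on the pooled multiset); otherwise the asymptotic
#' Kolmogorov tail is used.
#'
#' @param a,b Numeric samples (nonempty).
#' @param exactLimit Maximum number of enumerated assignments for the exact
#'   path (default 2e5).
#'
#' @return list(statistic = D, p.value, method).
#' @export
#' @examples
#' compareInterference(c(1, 2, 3), c(10, 20, 30))$statistic  # 1
compareInterference <- function(a, b, exactLimit = 2e5) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  n1 <- length(a); n2 <- length(b)
  D <- .ksStatistic(a, b)
  if (choose(n1 + n2, n1) <= exactLimit) {
    pool <- c(a, b)
    pts <- sort(unique(pool))
    below <- outer(pool, pts, "<=")      # (n1+n2) x npts
    memb <- .subsetMembership(n1 + n2, n1)
    ## counts <= each point within group A, for every assignment
    cntA <- crossprod(memb, below)       # nAssign x npts
    cntTot <- matrix(colSums(below), nrow(cntA), ncol(cntA), byrow = TRUE)
    Ds <- apply(abs(cntA / n1 - (cntTot - cntA) / n2), 1L, max)
    p <- mean(Ds >= D - 1e-12)
    return(list(statistic = D, p.value = p, method = "exact enumeration"))
  }
  ne <- n1 * n2 / (n1 + n2)
  list(statistic = D, p.value = .ksAsymptoticP(sqrt(ne) * D),
       method = "asymptotic")
}

#' Wilcoxon rank-sum comparison of tract lengths
#'
#' Rank-sum test with mid-ranks for ties. For small samples (enumeration
#' feasible) the p-value is exact over all assignments of the pooled values
#' to the two groups; otherwise a normal approximation with tie correction is
#' used (no continuity correction, so large-sample p-values approach the
#' enumerated null).
#'
#' @param a,b Numeric samples (nonempty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   referring to the location of `a` relative to `b`.
#' @param exactLimit Maximum number of enumerated assignments for the exact
#'   path (default 2e5).
#'
#' @return list(statistic = U (Mann-Whitney form, for sample `a`), p.value,
#'   method).
#' @export
#' @examples
#' compareTractLengths(c(1, 2, 3), c(10, 20, 30), alternative = "less")
compareTractLengths <- function(a, b,
                                alternative = c("two.sided", "less", "greater"),
                                exactLimit = 2e5) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  n1 <- length(a); n2 <- length(b)
  pool <- c(a, b)
  r <- rank(pool)   # mid-ranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (choose(n1 + n2, n1) <= exactLimit) {
    memb <- .subsetMembership(n1 + n2, n1)
    Us <- as.vector(crossprod(memb, r)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- switch(alternative,
      two.sided = mean(abs(Us - mu) >= abs(U - mu) - eps),
      less = mean(Us <= U + eps),
      greater = mean(Us >= U - eps))
    return(list(statistic = U, p.value = p, method = "exact enumeration"))
  }
  nties <- table(r)
  sigma2 <- n1 * n2 / 12 *
    ((n1 + n2 + 1) - sum(nties^3 - nties) / ((n1 + n2) * (n1 + n2 - 1)))
  z <- (U - mu) / sqrt(sigma2)
  p <- switch(alternative,
    two.sided = 2 * stats::pnorm(-abs(z)),
    less = stats::pnorm(z),
    greater = stats::pnorm(z, lower.tail = FALSE))
  list(statistic = U, p.value = min(1, p), method = "normal approximation")
}
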