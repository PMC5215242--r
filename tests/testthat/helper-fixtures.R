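# Small fixtures built in code: fixed-pitch maps and hand-constructed octads
# with known strand-transfer patterns.

pitchMap <- function(L = 50000, pitch = 250, chrom = "chrA") {
  buildSnpMap(stats::setNames(L, chrom), spacing = "fixed", pitch = pitch)
}

# Mendelian octad: spores 1,2 carry parent 1; spores 3,4 parent 2
mendelianCalls <- function(map) {
  n <- nrow(markers(map))
  matrix(rep(c("P1", "P1", "P1", "P1", "P2", "P2", "P2", "P2"), each = n),
         nrow = n, ncol = 8L, dimnames = list(NULL, octadStrandNames()))
}

mendelianOctad <- function(map) OctadMatrix(mendelianCalls(map), map)

flipCall <- function(x) ifelse(x == "P1", "P2", "P1")

# flip one strand of one spore over marker rows idx
setStrand <- function(calls, spore, ab, idx, value = NULL) {
  col <- paste0("s", spore, ab)
  calls[idx, col] <- if (is.null(value)) flipCall(calls[idx, col]) else value
  calls
}

# reciprocal crossover between two spores: swap both strands beyond marker row
applyCoAt <- function(calls, spores, afterRow) {
  idx <- seq_len(nrow(calls)) > afterRow
  colsA <- paste0("s", spores[1], c("a", "b"))
  colsB <- paste0("s", spores[2], c("a", "b"))
  tmp <- calls[idx, colsA]
  calls[idx, colsA] <- calls[idx, colsB]
  calls[idx, colsB] <- tmp
  calls
}

# ---------------------------------------------------------------------------
# independent oracles

# literal transcription of the read-count validity rule: one type of reads
# with count in [15,150], or two types with the most abundant in [40,150] and
# the less abundant below 5; scalar in, scalar out
oracleGenotype <- function(n1, n2) {
  if (n1 == 0 && n2 == 0) return(NA_character_)
  if (n2 == 0) return(if (n1 >= 15 && n1 <= 150) "P1" else NA_character_)
  if (n1 == 0) return(if (n2 >= 15 && n2 <= 150) "P2" else NA_character_)
  if (n1 == n2) return(NA_character_)  # no most abundant type
  most <- max(n1, n2); less <- min(n1, n2)
  if (most >= 40 && most <= 150 && less < 5)
    return(if (n1 > n2) "P1" else "P2")
  NA_character_
}

# exhaustive-enumeration Wilcoxon rank-sum p-value (mid-ranks under ties)
oracleWilcox <- function(a, b, alternative = "two.sided") {
  pool <- c(a, b)
  n1 <- length(a)
  r <- rank(pool)
  offs <- n1 * (n1 + 1) / 2
  Uobs <- sum(r[seq_len(n1)]) - offs
  mu <- n1 * length(b) / 2
  cmb <- utils::combn(length(pool), n1)
  Us <- apply(cmb, 2L, function(ix) sum(r[ix]) - offs)
  eps <- 1e-9
  switch(alternative,
         two.sided = mean(abs(Us - mu) >= abs(Uobs - mu) - eps),
         less = mean(Us <= Uobs + eps),
         greater = mean(Us >= Uobs - eps))
}

# exhaustive-enumeration two-sample KS p-value
oracleKs <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  pts <- sort(unique(pool))
  Dof <- function(ix) {
    e1 <- vapply(pts, function(p) mean(pool[ix] <= p), 0)
    e2 <- vapply(pts, function(p) mean(pool[-ix] <= p), 0)
    max(abs(e1 - e2))
  }
  Dobs <- Dof(seq_len(n1))
  cmb <- utils::combn(length(pool), n1)
  Ds <- apply(cmb, 2L, Dof)
  mean(Ds >= Dobs - 1e-12)
}

# grid-search oracle for the gamma MLE: profile log-likelihood over shapes
oracleGammaGrid <- function(x, shapes = exp(seq(log(0.05), log(50), length.out = 20001))) {
  ll <- vapply(shapes, function(k) sum(stats::dgamma(x, k, scale = mean(x) / k,
                                                     log = TRUE)), 0)
  list(shape = shapes[which.max(ll)], loglik = max(ll))
}
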