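# Shared fixtures and independent oracles.

# constant-free random PET phantom with a guaranteed hot spot
randomPetPhantom <- function(dim = c(16, 16, 16), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- array(runif(prod(dim), 0, 5), dim)
  hot <- sample(prod(dim), 1)
  a[hot] <- runif(1, 8, 12)
  ImageVolume(a, spacing = 2, modality = "PET_SUV")
}

# independent flood-fill oracle for the fixed-threshold VOI: explicit
# queue-based BFS over thresholded voxels, 26-connectivity
floodFillVoiOracle <- function(vol, thresholdFraction = 0.40,
                               region = NULL) {
  v <- voxelData(vol)
  d <- dim(v)
  if (is.null(region)) region <- array(TRUE, d)
  mx <- max(v[region])
  thr <- region & (v >= thresholdFraction * mx)
  seed <- which(region & v == mx)[1]
  toIjk <- function(lin) {
    lin0 <- lin - 1
    c(lin0 %% d[1], (lin0 %/% d[1]) %% d[2], lin0 %/% (d[1] * d[2])) + 1
  }
  inComp <- array(FALSE, d)
  inComp[seed] <- TRUE
  queue <- list(toIjk(seed))
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- p + c(dx, dy, dz)
      if (any(q < 1) || any(q > d)) next
      if (thr[q[1], q[2], q[3]] && !inComp[q[1], q[2], q[3]]) {
        inComp[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
  }
  inComp
}

# exact two-sided Mann-Whitney p by full enumeration of all C(n1+n2, n1)
# group assignments of the pooled sample (no ties assumed)
enumerateMannWhitneyP <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n2 <- length(y)
  uObs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(ix) {
    xs <- pooled[ix]; ys <- pooled[-ix]
    sum(outer(xs, ys, ">"))
  })
  pLow <- mean(us <= uObs)
  pHigh <- mean(us >= uObs)
  min(1, 2 * min(pLow, pHigh))
}

smallCohort <- function(seed = 11, n = 60) {
  generateCohort(syntheticConfig(seed = seed, nLesions = n))
}

nullConfig <- function(seed, n = 159) {
  syntheticConfig(seed = seed, nLesions = n,
                  ki67SuvTargetRho = 0, ki67AdcTargetRho = 0,
                  subtypeAucTarget = 0.5 + 1e-9)
}
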