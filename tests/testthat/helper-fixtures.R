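# Small scene/stack builders shared across tests.

# One or more circular cells on a zero-background field, for exact oracles.
makeCellScene <- function(atomC = 0.05, atomN = 0.05, radius = 6,
                          centers = NULL, size = 48, yieldC = 50,
                          yieldCN = 100, yieldP = 5, yieldS = 10,
                          background = c(C = 0, CN = 0, P = 0, S = 0),
                          type = "epibiont", pixelSize = 0.1) {
  n <- max(length(atomC), length(atomN),
           if (is.null(centers)) 1L else nrow(centers))
  atomC <- rep_len(atomC, n); atomN <- rep_len(atomN, n)
  if (is.null(centers))
    centers <- cbind(rep(size / 2, n), size / 2)
  cells <- data.frame(
    id = seq_len(n), type = rep_len(type, n),
    cx = centers[, 1], cy = centers[, 2],
    a = radius, b = radius, theta = 0,
    lengthUm = 2 * radius * pixelSize, widthUm = 2 * radius * pixelSize,
    aC13 = atomC, aN15 = atomN,
    yieldC = yieldC, yieldCN = yieldCN, yieldP = yieldP, yieldS = yieldS)
  ColonyScene(cells, background = background, pixelSize = pixelSize)
}

quickAcq <- function(size = 48, planes = 4, drift = matrix(0L, planes, 2)) {
  AcquisitionParams(size, size, planes, drift)
}

# Exhaustive two-sided Mann-Whitney p by enumerating all group assignments.
enumMannWhitneyP <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pool <- c(a, b)
  splits <- utils::combn(n1 + n2, n1)
  uFor <- function(idx) {
    x <- pool[idx]; y <- pool[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  us <- apply(splits, 2, uFor)
  uObs <- uFor(seq_len(n1))
  pL <- mean(us <= uObs); pU <- mean(us >= uObs)
  min(1, 2 * min(pL, pU))
}

# Least-squares slope via the normal equations, as an independent oracle.
neSlope <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)[2]
}
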