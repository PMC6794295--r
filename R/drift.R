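## circular cross-correlation of two equal-size matrices via FFT;
## element [u+1, v+1] (with wrap for negative lags) is
## sum_{i,j} a[i, j] * b[i + u, j + v]
crossCorrelate <- function(a, b) {
  fa <- stats::fft(a); fb <- stats::fft(b)
  Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / length(a)
}

## locate the best integer offset within a +/- window; ties broken toward the
## smallest offset magnitude, then row-major order
bestOffset <- function(cc, window) {
  nr <- nrow(cc); nc <- ncol(cc)
  lags <- expand.grid(dr = -window:window, dc = -window:window)
  idxR <- ifelse(lags$dr >= 0, lags$dr + 1L, nr + lags$dr + 1L)
  idxC <- ifelse(lags$dc >= 0, lags$dc + 1L, nc + lags$dc + 1L)
  vals <- cc[cbind(idxR, idxC)]
  top <- max(vals)
  tol <- 1e-9 * max(abs(top), 1)
  cand <- which(vals >= top - tol)
  degenerate <- length(cand) > 1L
  ord <- order(abs(lags$dr[cand]) + abs(lags$dc[cand]))
  pick <- cand[ord[1]]
  if (degenerate && abs(lags$dr[pick]) + abs(lags$dc[pick]) == 0) {
    dr <- 0L; dc <- 0L
  } else {
    dr <- lags$dr[pick]; dc <- lags$dc[pick]
  }
  list(dr = dr, dc = dc, degenerate = degenerate,
       boundary = !degenerate && (abs(dr) == window || abs(dc) == window))
}

#' Drift-correct an ion image stack by cross-correlation registration
#'
#' Registers every plane of the reference species against plane 1 by integer
#' cross-correlation within a search window, then shifts all species of that
#' plane by the negated offset (zero-filling pixels shifted in from outside).
#' This reproduces the standard drift-correct-then-accumulate treatment of
#' multi-plane nanoSIMS acquisitions.
#'
#' @param stack an [IonImageStack-class].
#' @param referenceSpecies species used for registration; \code{"12C14N"} (the
#'   strongest biomass channel) by default.
#' @param window half-width of the integer search window in pixels.
#' @return list with \code{stack} (the aligned [IonImageStack-class]),
#'   \code{offsets} (\code{planes x 2} matrix of detected (row, col) drift per
#'   plane) and \code{flags} (data.frame per plane with \code{boundary} — the
#'   optimum sat on the window edge, possible unbounded drift — and
#'   \code{degenerate} — ambiguous registration, e.g. a flat reference plane,
#'   resolved as offset (0, 0)).
#' @examples
#' sc <- colonyScenario("aphanizomenon", "in_situ", nEpibionts = 2,
#'                      imageSize = 64, seed = 2)
#' acq <- AcquisitionParams(64, 64, planes = 4,
#'                          drift = cbind(c(0, 1, 2, 2), c(0, 0, -1, -2)))
#' sim <- simulateIonStack(sc$scene, acq, seed = 2)
#' dc <- driftCorrect(sim$stack)
#' dc$offsets
#' @export
setMethod("driftCorrect", "IonImageStack",
  function(stack, referenceSpecies = "12C14N", window = 10L) {
    if (!referenceSpecies %in% ionSpecies(stack))
      stop("reference species not in stack: ", referenceSpecies)
    ref <- ionCounts(stack, referenceSpecies)
    np <- nPlanes(stack)
    target <- ref[, , 1]
    if (sum(target) == 0)
      stop("empty reference plane: plane 1 of ", referenceSpecies,
           " has zero counts")
    offsets <- matrix(0L, np, 2)
    flags <- data.frame(plane = seq_len(np), boundary = FALSE,
                        degenerate = FALSE)
    for (p in seq_len(np)) {
      if (p == 1L) next
      cc <- crossCorrelate(target, ref[, , p])
      b <- bestOffset(cc, window)
      offsets[p, ] <- c(b$dr, b$dc)
      flags$boundary[p] <- b$boundary
      flags$degenerate[p] <- b$degenerate
    }
    counts <- lapply(stack@counts, function(arr) {
      for (p in seq_len(np)) {
        if (offsets[p, 1] != 0 || offsets[p, 2] != 0)
          arr[, , p] <- shiftImage(arr[, , p], -offsets[p, 1], -offsets[p, 2])
      }
      arr
    })
    list(stack = IonImageStack(counts, pixelSize = pixelSize(stack)),
         offsets = offsets, flags = flags)
  })

#' Accumulate an ion image stack over planes
#'
#' Pixelwise sum of all planes per species. On an aligned stack this is the
#' accumulated image the per-cell ratios are computed from; total counts are
#' conserved up to pixels zero-filled at the border during drift correction.
#'
#' @param stack an [IonImageStack-class] (already aligned if it was drifted).
#' @return named list of 2-D summed count matrices, one per species, with a
#'   \code{pixelSize} attribute (um/pixel).
#' @examples
#' a <- array(1, c(4, 4, 3))
#' acc <- accumulate(IonImageStack(list(`12C` = a), pixelSize = 0.1))
#' acc[["12C"]][1, 1]  # 3
#' @export
setMethod("accumulate", "IonImageStack", function(stack) {
  out <- lapply(stack@counts, function(arr) {
    m <- arr[, , 1]
    np <- dim(arr)[3]
    if (np > 1) for (p in 2:np) m <- m + arr[, , p]
    m
  })
  attr(out, "pixelSize") <- pixelSize(stack)
  out
})
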