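#' Shift a 2-D image by integer pixel offsets, zero-filling
#'
#' @param mat numeric matrix.
#' @param dr,dc integer row and column offsets (positive = down / right).
#' @param fill value for pixels shifted in from outside.
#' @return shifted matrix of the same dimensions.
#' @keywords internal
shiftImage <- function(mat, dr, dc, fill = 0) {
  nr <- nrow(mat); nc <- ncol(mat)
  out <- matrix(fill, nr, nc)
  srcR <- seq_len(nr) - dr
  srcC <- seq_len(nc) - dc
  okR <- srcR >= 1 & srcR <= nr
  okC <- srcC >= 1 & srcC <= nc
  if (any(okR) && any(okC))
    out[which(okR), which(okC)] <- mat[srcR[okR], srcC[okC], drop = FALSE]
  out
}

#' Secondary-ion species recorded by the simulated acquisition
#' @return character vector of the six species identifiers.
#' @export
ionSpeciesDefault <- function() c("12C", "13C", "12C14N", "12C15N", "31P", "32S")

## per-species expected counts per pixel per plane, on the drift-free grid.
## The C and CN channels split their elemental yield between the light and
## heavy isotopologue by the cell's true atom fraction; background splits by
## natural abundance.
expectedFields <- function(scene, acq, naC = 0.0111, naN = 0.00366) {
  nr <- acq@height; nc <- acq@width
  cells <- scene@cells
  fields <- list()
  for (s in ionSpeciesDefault()) fields[[s]] <- matrix(0, nr, nc)
  bg <- scene@background
  fields[["12C"]][] <- bg["C"] * (1 - naC)
  fields[["13C"]][] <- bg["C"] * naC
  fields[["12C14N"]][] <- bg["CN"] * (1 - naN)
  fields[["12C15N"]][] <- bg["CN"] * naN
  fields[["31P"]][] <- bg["P"]
  fields[["32S"]][] <- bg["S"]
  mask <- matrix(0L, nr, nc)
  col <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  row <- matrix(rep(seq_len(nr), nc), nr, nc)
  for (k in seq_len(nrow(cells))) {
    cl <- cells[k, ]
    dx <- col - cl$cx; dy <- row - cl$cy
    u <- dx * cos(cl$theta) + dy * sin(cl$theta)
    v <- -dx * sin(cl$theta) + dy * cos(cl$theta)
    inside <- (u / cl$a)^2 + (v / cl$b)^2 <= 1
    if (!any(inside))
      stop("cell ", cl$id, " lies outside the image bounds")
    fields[["12C"]][inside] <- cl$yieldC * (1 - cl$aC13)
    fields[["13C"]][inside] <- cl$yieldC * cl$aC13
    fields[["12C14N"]][inside] <- cl$yieldCN * (1 - cl$aN15)
    fields[["12C15N"]][inside] <- cl$yieldCN * cl$aN15
    fields[["31P"]][inside] <- cl$yieldP
    fields[["32S"]][inside] <- cl$yieldS
    mask[inside] <- cl$id
  }
  list(fields = fields, mask = mask)
}

#' Simulate a multi-plane nanoSIMS ion-count acquisition
#'
#' Renders a [ColonyScene-class] into Poisson-distributed secondary-ion count
#' images for the six recorded species (12C-, 13C-, 12C14N-, 12C15N-, 31P-,
#' 32S-). Expected counts per pixel per plane are the cell's elemental yield
#' split between isotopologues by its true atom fraction (the major species
#' gets yield x (1 - A), the minor yield x A); counts are drawn independently
#' Poisson per pixel, per plane, per species. Each plane is then translated
#' by its integer drift offset with zero fill, emulating stage drift during
#' acquisition. The drift-free ground-truth label mask is returned alongside.
#'
#' Identical \code{seed} gives a bit-identical result; the same seed with a
#' zero-drift [AcquisitionParams-class] yields exactly the drift-free
#' counterpart of a drifted acquisition (the Poisson draws are made on the
#' drift-free grid before translation).
#'
#' @param scene a [ColonyScene-class].
#' @param acq an [AcquisitionParams-class]; its \code{drift} matrix gives the
#'   per-plane offsets.
#' @param seed optional integer seed.
#' @return list with \code{stack} (an [IonImageStack-class]), \code{mask}
#'   (drift-free integer label matrix, 0 = background), \code{drift} (the
#'   applied offsets) and \code{expected} (per-species expected counts per
#'   pixel per plane on the drift-free grid).
#' @examples
#' sc <- colonyScenario("aphanizomenon", "in_situ", nEpibionts = 3,
#'                      imageSize = 64, seed = 1)
#' sim <- simulateIonStack(sc$scene, AcquisitionParams(64, 64, planes = 4),
#'                         seed = 1)
#' sim$stack
#' @export
simulateIonStack <- function(scene, acq, seed = NULL) {
  stopifnot(is(scene, "ColonyScene"), is(acq, "AcquisitionParams"))
  validObject(scene); validObject(acq)
  ef <- expectedFields(scene, acq)
  nr <- acq@height; nc <- acq@width; np <- acq@planes
  drift <- acq@drift

  ## a drift offset must never push a cell fully out of frame
  for (k in seq_len(nrow(scene@cells))) {
    cl <- scene@cells[k, ]
    r <- max(cl$a, cl$b)
    for (p in seq_len(np)) {
      cxp <- cl$cx + drift[p, 2]; cyp <- cl$cy + drift[p, 1]
      if (cxp + r < 1 || cxp - r > nc || cyp + r < 1 || cyp - r > nr)
        stop("drift pushes cell ", cl$id, " fully out of frame at plane ", p)
    }
  }

  if (!is.null(seed)) set.seed(seed)
  counts <- list()
  for (s in ionSpeciesDefault()) {
    lam <- as.vector(ef$fields[[s]])
    arr <- array(stats::rpois(length(lam) * np, lam), c(nr, nc, np))
    for (p in seq_len(np)) {
      if (drift[p, 1] != 0 || drift[p, 2] != 0)
        arr[, , p] <- shiftImage(arr[, , p], drift[p, 1], drift[p, 2])
    }
    counts[[s]] <- arr
  }
  list(stack = IonImageStack(counts, pixelSize = scene@pixelSize),
       mask = ef$mask, drift = drift, expected = ef$fields)
}
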