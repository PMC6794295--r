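#' Construct a ColonyScene
#'
#' @param cells data.frame of per-cell ground truth; see
#'   [ColonyScene-class] for the required columns.
#' @param background named numeric: off-cell expected counts per pixel per
#'   plane for the \code{C}, \code{CN}, \code{P} and \code{S} channels.
#' @param pixelSize micrometres per pixel.
#' @return a validated [ColonyScene-class].
#' @export
ColonyScene <- function(cells, background = c(C = 0.5, CN = 1, P = 0.05, S = 0.1),
                        pixelSize = 15 / 256) {
  new("ColonyScene", cells = as.data.frame(cells),
      background = background, pixelSize = as.numeric(pixelSize))
}

#' Construct AcquisitionParams
#'
#' @param width,height image size in pixels.
#' @param planes number of acquisition planes.
#' @param drift integer \code{planes x 2} matrix of per-plane (row, col)
#'   offsets; defaults to no drift.
#' @return an [AcquisitionParams-class].
#' @seealso [randomWalkDrift()]
#' @export
AcquisitionParams <- function(width = 256L, height = 256L, planes = 40L,
                              drift = matrix(0L, planes, 2)) {
  new("AcquisitionParams", width = as.integer(width),
      height = as.integer(height), planes = as.integer(planes),
      drift = matrix(as.integer(round(drift)), nrow(drift), 2))
}

#' Random-walk per-plane drift offsets
#'
#' Integer-pixel drift accumulating as a random walk with steps in
#' \{-1, 0, 1\} per axis per plane, the typical slow stage/charging drift of
#' a long raster acquisition. Plane 1 is the registration target and has
#' offset (0, 0).
#'
#' @param planes number of planes.
#' @param maxAbs clamp on the cumulative offset magnitude per axis (pixels).
#' @param prob probability of a nonzero step per axis per plane.
#' @param seed optional integer seed.
#' @return integer \code{planes x 2} matrix of (row, col) offsets.
#' @export
randomWalkDrift <- function(planes, maxAbs = 5L, prob = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  step <- function() {
    s <- integer(planes)
    move <- runif(planes - 1) < prob
    s[-1][move] <- sample(c(-1L, 1L), sum(move), replace = TRUE)
    pmax(pmin(cumsum(s), maxAbs), -maxAbs)
  }
  cbind(step(), step())
}

#' Construct LabelingConditions
#'
#' Defaults are the incubation-water labelling of the single-cell
#' experiments: ~11.9 atom% 13C in the DIC pool and ~1.8 atom% 15N in the N2
#' pool over a 24-h incubation, referenced against natural abundances of
#' 1.11 atom% 13C and 0.366 atom% 15N.
#'
#' @param sourceFraction named numeric atom fractions of the labelled pools.
#' @param naturalAbundance named numeric natural-abundance atom fractions.
#' @param duration incubation time in days.
#' @return a [LabelingConditions-class].
#' @export
LabelingConditions <- function(sourceFraction = c(C = 0.119, N = 0.018),
                               naturalAbundance = c(C = 0.0111, N = 0.00366),
                               duration = 1) {
  new("LabelingConditions", sourceFraction = sourceFraction,
      naturalAbundance = naturalAbundance, duration = as.numeric(duration))
}

#' @rdname LabelingConditions
#' @param cond a [LabelingConditions-class].
#' @param element \code{"C"} or \code{"N"}.
#' @export
sourceFraction <- function(cond, element) {
  stopifnot(is(cond, "LabelingConditions"))
  unname(cond@sourceFraction[element])
}

#' @rdname LabelingConditions
#' @export
naturalAbundance <- function(cond, element) {
  stopifnot(is(cond, "LabelingConditions"))
  unname(cond@naturalAbundance[element])
}

#' @rdname LabelingConditions
#' @export
incubationDays <- function(cond) {
  stopifnot(is(cond, "LabelingConditions"))
  cond@duration
}

## lognormal with a given median m and SD s: meanlog = log(m), sdlog solves
## s/m = exp(sig^2/2) * sqrt(exp(sig^2) - 1)
lognormSdlog <- function(median, sd) {
  if (sd <= 0) return(0)
  cv <- sd / median
  f <- function(sig) exp(sig^2 / 2) * sqrt(exp(sig^2) - 1) - cv
  stats::uniroot(f, c(1e-8, 5))$root
}

rlnormMedian <- function(n, median, sd) {
  sig <- lognormSdlog(median, sd)
  stats::rlnorm(n, meanlog = log(median), sdlog = sig)
}

## scenario parameter table ---------------------------------------------------
## Epibiont relative-activity medians/SDs are the study's printed single-cell
## values; cyanobacterial activities encode the observed growth-rate responses
## (activity = growth rate x t / 2) and, for Nodularia, are calibrated so the
## in-situ N share of total fixed N is ~14% with ~20 epibionts per cell.
scenarioTable <- function() {
  rbind(
    data.frame(organism = "aphanizomenon", condition = "in_situ",
               epiActC = 0.03, epiSdC = 0.04, epiActN = 0.03, epiSdN = 0.03,
               cyanoActC = 0.255, cyanoActN = 0.11,
               epiPerCell = 2, cellL = 8, cellW = 5),
    data.frame(organism = "aphanizomenon", condition = "dip_amended",
               epiActC = 0.03, epiSdC = 0.06, epiActN = 0.07, epiSdN = 0.07,
               cyanoActC = 0.19, cyanoActN = 0.145,
               epiPerCell = 2, cellL = 8, cellW = 5),
    data.frame(organism = "nodularia", condition = "in_situ",
               epiActC = 0.08, epiSdC = 0.05, epiActN = 0.08, epiSdN = 0.03,
               cyanoActC = 0.162, cyanoActN = 0.154,
               epiPerCell = 20, cellL = 7.4, cellW = 4.6),
    data.frame(organism = "nodularia", condition = "dip_amended",
               epiActC = 0.05, epiSdC = 0.02, epiActN = 0.05, epiSdN = 0.01,
               cyanoActC = 0.331, cyanoActN = 0.213,
               epiPerCell = 20, cellL = 7.4, cellW = 4.6))
}

#' Preset colony scenarios
#'
#' Builds a [ColonyScene-class] plus its [LabelingConditions-class] for one of
#' the four study conditions: \emph{Aphanizomenon} or \emph{Nodularia}
#' filaments, under in-situ (phosphate-scarce) or DIP-amended (+1 umol L^-1
#' phosphate) incubation. Epibiont relative activities are drawn from a
#' log-normal centred on the condition's median (C/N medians 0.03/0.03,
#' 0.03/0.07, 0.08/0.08, 0.05/0.05) with dispersion matched to the printed SD;
#' epibionts-per-cell medians are 2 (Aphanizomenon) and 20 (Nodularia);
#' epibiont biovolume median 0.84 um^3; labelling 11.9 atom% 13C / 1.8 atom%
#' 15N over 24 h.
#'
#' The scene covers one cyanobacterial cell of a filament crossing the field
#' horizontally, with epibionts placed at random along the filament margin
#' (non-overlapping).
#'
#' @param organism \code{"aphanizomenon"} or \code{"nodularia"}.
#' @param condition \code{"in_situ"} or \code{"dip_amended"}.
#' @param nEpibionts number of epibiont cells in the field; default is about
#'   2.2x the epibionts-per-cell median so cohort medians are stable. Cells
#'   are packed without overlap; a count the field cannot hold is an error.
#' @param imageSize field size in pixels (the physical field is 15 um across).
#' @param seed optional integer seed for the activity draws and placement.
#' @return list with elements \code{scene} ([ColonyScene-class]),
#'   \code{conditions} ([LabelingConditions-class]), and \code{truth}
#'   (a list of the preset parameter values, including per-cell true
#'   activities).
#' @examples
#' sc <- colonyScenario("nodularia", "in_situ", seed = 1)
#' sc$truth$epiActN
#' @export
colonyScenario <- function(organism = c("aphanizomenon", "nodularia"),
                           condition = c("in_situ", "dip_amended"),
                           nEpibionts = NULL, imageSize = 256L, seed = NULL) {
  organism <- match.arg(organism)
  condition <- match.arg(condition)
  tab <- scenarioTable()
  p <- tab[tab$organism == organism & tab$condition == condition, ]
  if (nrow(p) != 1L) stop("unknown preset")
  if (!is.null(seed)) set.seed(seed)
  cond <- LabelingConditions()
  px <- 15 / imageSize
  if (is.null(nEpibionts)) nEpibionts <- max(10L, round(2.2 * p$epiPerCell))

  ## filament cell: horizontal ellipse in the field centre
  cyL <- p$cellL; cyW <- p$cellW
  cyano <- data.frame(
    id = 1L, type = "vegetative",
    cx = imageSize / 2, cy = imageSize / 2,
    a = cyL / 2 / px, b = cyW / 2 / px, theta = 0,
    lengthUm = cyL, widthUm = cyW,
    aC13 = activityToAtomFraction(p$cyanoActC, cond, "C"),
    aN15 = activityToAtomFraction(p$cyanoActN, cond, "N"),
    yieldC = 50, yieldCN = 100, yieldP = 5, yieldS = 10)

  ## epibionts: median biovolume 0.84 um^3 prolate spheroids, L/W ~ 1.6;
  ## sizes truncated to the observed 0.2-3 um^3 range so every cell fits
  actC <- rlnormMedian(nEpibionts, p$epiActC, p$epiSdC)
  actN <- rlnormMedian(nEpibionts, p$epiActN, p$epiSdN)
  vols <- pmin(pmax(rlnormMedian(nEpibionts, 0.84, 0.5), 0.2), 3)
  aspect <- 1.6
  ## V = pi/6 L W^2 with L = aspect * W
  eW <- (6 * vols / (pi * aspect))^(1 / 3)
  eL <- aspect * eW
  ## non-overlapping lane placement along the filament: cells lie with their
  ## long axis parallel to the filament, filling rows on alternating sides;
  ## widest cells first so each lane's height fits its own occupants
  eRadL <- eL / 2 / px
  eRadW <- eW / 2 / px
  gap <- 3; margin <- 2
  cyHalf <- cyW / 2 / px
  xs <- ys <- numeric(nEpibionts)
  ord <- order(eRadW, decreasing = TRUE)
  offset <- c(cyHalf + gap, cyHalf + gap)  # growing per side
  sideSel <- 1L
  x <- margin + gap
  laneMaxW <- 0
  for (j in seq_len(nEpibionts)) {
    i <- ord[j]
    if (x + 2 * eRadL[i] + gap > imageSize - margin) {
      offset[sideSel] <- offset[sideSel] + 2 * laneMaxW + gap
      sideSel <- 3L - sideSel
      x <- margin + gap
      laneMaxW <- 0
    }
    laneMaxW <- max(laneMaxW, eRadW[i])
    side <- if (sideSel == 1L) 1 else -1
    yC <- imageSize / 2 + side * (offset[sideSel] + eRadW[i])
    if (yC - eRadW[i] - 1 < margin || yC + eRadW[i] + 1 > imageSize - margin)
      stop("field too small for ", nEpibionts,
           " epibionts; reduce nEpibionts or enlarge imageSize")
    xs[i] <- x + eRadL[i] + runif(1, -1, 1)
    ys[i] <- yC + runif(1, -0.5, 0.5)
    x <- x + 2 * eRadL[i] + gap
  }
  epi <- data.frame(
    id = seq_len(nEpibionts) + 1L, type = "epibiont",
    cx = xs, cy = ys,
    a = eRadL, b = eRadW,
    theta = 0,
    lengthUm = eL, widthUm = eW,
    aC13 = activityToAtomFraction(actC, cond, "C"),
    aN15 = activityToAtomFraction(actN, cond, "N"),
    yieldC = 50, yieldCN = 100, yieldP = 5, yieldS = 10)

  cells <- rbind(cyano, epi)
  scene <- ColonyScene(cells, pixelSize = px)
  list(scene = scene, conditions = cond,
       truth = list(organism = organism, condition = condition,
                    epiActC = p$epiActC, epiActN = p$epiActN,
                    cyanoActC = p$cyanoActC, cyanoActN = p$cyanoActN,
                    epiPerCell = p$epiPerCell,
                    cellActC = actC, cellActN = actN,
                    cellVolumes = vols))
}

## atom fraction corresponding to a relative activity under given labelling
activityToAtomFraction <- function(activity, cond, element) {
  na <- naturalAbundance(cond, element)
  xi <- sourceFraction(cond, element)
  na + activity * (xi - na)
}
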