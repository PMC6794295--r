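#' Isotope ratio / atom fraction conversions
#'
#' Standard isotope algebra: an isotope ratio r (minor/major counts) and an
#' atom fraction A (minor / (minor + major) atoms) are related by
#' \code{A = r / (1 + r)} and \code{r = A / (1 - A)}.
#'
#' @param r isotope ratio(s), >= 0.
#' @param A atom fraction(s) in [0, 1).
#' @return the converted value(s).
#' @examples
#' atomFraction(0.0117)          # 0.011565...
#' isotopeRatio(atomFraction(2)) # 2
#' @export
atomFraction <- function(r) {
  if (any(r < 0, na.rm = TRUE)) stop("ratio must be >= 0")
  r / (1 + r)
}

#' @rdname atomFraction
#' @export
isotopeRatio <- function(A) {
  if (any(A < 0 | A >= 1, na.rm = TRUE))
    stop("atom fraction must lie in [0, 1)")
  A / (1 - A)
}

#' Relative C or N uptake activity from cellular isotope enrichment
#'
#' The fraction of a cell's element pool replaced by labelled substrate
#' during the incubation: the cell's atom-fraction excess over natural
#' abundance, divided by the source pool's excess,
#' \code{(A_cell - A_na) / (X_I - A_na)}. Negative excess (measurement noise
#' below natural abundance) is clipped to 0; the \code{clipped} attribute
#' flags which values were.
#'
#' @param aCell cellular atom fraction(s) in [0, 1).
#' @param cond a [LabelingConditions-class].
#' @param element \code{"C"} or \code{"N"}.
#' @return numeric activity >= 0, with logical attribute \code{clipped}.
#' @examples
#' cond <- LabelingConditions()
#' relativeActivity(0.00484, cond, "N")  # ~0.082
#' @export
relativeActivity <- function(aCell, cond, element) {
  stopifnot(is(cond, "LabelingConditions"))
  if (any(aCell < 0 | aCell >= 1, na.rm = TRUE))
    stop("cellular atom fraction must lie in [0, 1)")
  na <- naturalAbundance(cond, element)
  xi <- sourceFraction(cond, element)
  if (xi <= na) stop("source fraction must exceed natural abundance (no labelling)")
  act <- (aCell - na) / (xi - na)
  clipped <- !is.na(act) & act < 0
  act[clipped] <- 0
  attr(act, "clipped") <- clipped
  act
}

#' Relative activity under the older-biomass substrate scenario
#'
#' Alternative reading of epibiont enrichment in which the released substrate
#' is not freshly fixed material (at the source-pool labelling) but material
#' with the isotopic composition of the cyanobacterial biomass at the end of
#' the incubation. The cyanobacterial end-point atom fraction replaces the
#' source-pool fraction as the substrate term; since the end point is less
#' enriched than the source pool, this always gives an activity at least as
#' large as [relativeActivity()].
#'
#' @param aEpibiont epibiont atom fraction(s).
#' @param aCyanoEndpoint cyanobacterial end-of-incubation atom fraction
#'   (must exceed natural abundance).
#' @param cond a [LabelingConditions-class].
#' @param element \code{"C"} or \code{"N"}.
#' @return numeric activity >= 0, with logical attribute \code{clipped}.
#' @export
alternativeSubstrateActivity <- function(aEpibiont, aCyanoEndpoint, cond,
                                         element) {
  stopifnot(is(cond, "LabelingConditions"))
  na <- naturalAbundance(cond, element)
  if (aCyanoEndpoint <= na)
    stop("cyanobacterial end-point atom fraction must exceed natural abundance")
  act <- (aEpibiont - na) / (aCyanoEndpoint - na)
  clipped <- !is.na(act) & act < 0
  act[clipped] <- 0
  attr(act, "clipped") <- clipped
  act
}

#' Substrate-based growth rate from relative activity
#'
#' Converts the fraction of cellular C or N replaced during the incubation
#' into a growth rate, assuming an even distribution of isotopes between
#' daughter cells at division: \code{rate = activity * 2 / t}.
#'
#' @param activity relative activity (X_B / X_I), >= 0.
#' @param t incubation time in days.
#' @return growth rate in day^-1.
#' @examples
#' growthRate(0.08, 1)  # 0.16 per day
#' @export
growthRate <- function(activity, t) {
  if (any(activity < 0, na.rm = TRUE)) stop("activity must be >= 0")
  if (t <= 0) stop("t must be > 0")
  as.numeric(activity) * 2 / t
}

#' Prolate-spheroid biovolume
#'
#' \code{V = pi/6 * L * W^2} for a cell of length L and width W (um), the
#' standard biovolume model for rod-shaped bacteria.
#'
#' @param L cell length (um), >= W.
#' @param W cell width (um), > 0.
#' @return biovolume in um^3.
#' @examples
#' biovolumeProlateSpheroid(1.6, 1.0)  # 0.8378
#' @export
biovolumeProlateSpheroid <- function(L, W) {
  if (any(W <= 0)) stop("width must be > 0")
  if (any(L < W)) stop("length must be >= width (axes swapped?)")
  pi / 6 * L * W^2
}

## atomic masses used for molar C:N -> mass conversion
.massC <- 12.011
.massN <- 14.007

#' Cellular C and N content from biovolume
#'
#' C content from a biovolume-to-carbon conversion — either a constant
#' density (fg C per um^3) or a power law \code{a * V^b} (fg C per cell) —
#' and N content from the molar C:N ratio converted via atomic masses
#' (12.011, 14.007).
#'
#' @param V biovolume(s) in um^3.
#' @param cnMolar molar C:N ratio, > 0.
#' @param conversion either a single number (constant fg C um^-3, default
#'   250) or a list \code{list(a = , b = )} for the power law.
#' @return data.frame with columns \code{volume}, \code{carbonFg},
#'   \code{nitrogenFg}.
#' @examples
#' cellContents(0.84, cnMolar = 5)           # 210 fg C
#' cellContents(1, cnMolar = 5, conversion = list(a = 120, b = 0))
#' @export
cellContents <- function(V, cnMolar, conversion = 250) {
  if (any(V <= 0)) stop("biovolume must be > 0")
  if (any(cnMolar <= 0)) stop("C:N ratio must be > 0")
  carbon <- if (is.list(conversion)) {
    stopifnot(all(c("a", "b") %in% names(conversion)))
    conversion$a * V^conversion$b
  } else {
    as.numeric(conversion) * V
  }
  nitrogen <- carbon / cnMolar * (.massN / .massC)
  data.frame(volume = V, carbonFg = carbon, nitrogenFg = nitrogen)
}

#' Cellular assimilation rate
#'
#' Element taken up per cell per day: the fraction of the cell's pool
#' replaced during the incubation (relative activity) times the cellular
#' content, divided by the incubation time.
#'
#' @param activity relative activity, >= 0.
#' @param content cellular content (fg per cell), >= 0.
#' @param t incubation time (days).
#' @return assimilation in fg per cell per day.
#' @examples
#' cellularAssimilation(0.08, 210, 1)  # 16.8 fg C / cell / day
#' @export
cellularAssimilation <- function(activity, content, t) {
  if (any(activity < 0, na.rm = TRUE) || any(content < 0, na.rm = TRUE))
    stop("activity and content must be >= 0")
  if (t <= 0) stop("t must be > 0")
  as.numeric(activity) * content / t
}

#' Per-cell rates table from detection-filtered ROI measurements
#'
#' Chains the single-cell calculation for every measured cell: isotope ratio
#' -> atom fraction -> relative activity (clipping negative excess) ->
#' biovolume (prolate spheroid from the ellipse fit) -> C and N content ->
#' cellular assimilation and substrate-based growth rate, per element.
#'
#' @param measurements data.frame from [applyDetectionLimits()] (the
#'   \code{measurements} element) or [roiRatios()]; must carry \code{ratioC},
#'   \code{ratioN}, \code{lengthUm}, \code{widthUm}. If retention flags are
#'   present, non-retained channels get NA rates.
#' @param cond a [LabelingConditions-class].
#' @param cnMolar molar C:N ratio used for N content.
#' @param conversion biovolume-to-C conversion, as in [cellContents()].
#' @return data.frame with one row per cell: activities, biovolume,
#'   contents, assimilation (fg cell^-1 day^-1) and growth rates (day^-1)
#'   per element, plus clipping flags.
#' @export
cellRates <- function(measurements, cond, cnMolar = 6.625, conversion = 250) {
  m <- measurements
  t <- incubationDays(cond)
  L <- pmax(m$lengthUm, m$widthUm)
  W <- pmin(m$lengthUm, m$widthUm)
  V <- biovolumeProlateSpheroid(L, W)
  cont <- cellContents(V, cnMolar, conversion)

  chan <- function(ratio, valid, retained, element, content) {
    A <- ifelse(!is.na(ratio) & valid, atomFraction(ratio), NA_real_)
    ok <- !is.na(A)
    act <- rep(NA_real_, length(A))
    clip <- rep(NA, length(A))
    if (any(ok)) {
      ra <- relativeActivity(A[ok], cond, element)
      act[ok] <- ra
      clip[ok] <- attr(ra, "clipped")
    }
    act[!retained] <- NA_real_
    list(activity = act, clipped = clip,
         assim = cellularAssimilation(ifelse(is.na(act), 0, act),
                                      content, t) * ifelse(is.na(act), NA, 1),
         growth = ifelse(is.na(act), NA_real_, act * 2 / t))
  }
  retC <- if ("retainedC" %in% names(m)) m$retainedC else
    (!is.na(m$ratioC) & m$validC)
  retN <- if ("retainedN" %in% names(m)) m$retainedN else
    (!is.na(m$ratioN) & m$validN)
  cc <- chan(m$ratioC, m$validC, retC, "C", cont$carbonFg)
  nn <- chan(m$ratioN, m$validN, retN, "N", cont$nitrogenFg)

  data.frame(
    label = m$label, cellType = m$cellType,
    lengthUm = L, widthUm = W, volume = V,
    carbonFg = cont$carbonFg, nitrogenFg = cont$nitrogenFg,
    ratioC = m$ratioC, ratioN = m$ratioN,
    activityC = cc$activity, clippedC = cc$clipped,
    assimC = cc$assim, growthC = cc$growth,
    activityN = nn$activity, clippedN = nn$clipped,
    assimN = nn$assim, growthN = nn$growth,
    retainedC = retC, retainedN = retN)
}
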