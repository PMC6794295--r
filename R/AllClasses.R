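#' @import methods
NULL

#' IonImageStack: multi-plane, multi-species secondary-ion count images
#'
#' Container for a nanoSIMS raster measurement: for each recorded secondary-ion
#' species (e.g. \code{"12C"}, \code{"13C"}, \code{"12C14N"}, \code{"12C15N"},
#' \code{"31P"}, \code{"32S"}) a plane-indexed stack of 2-D integer count
#' images, all sharing the same dimensions and plane count, plus the raster
#' pixel size in micrometres.
#'
#' @slot counts named list, one \code{nrow x ncol x planes} integer array per
#'   species; counts are non-negative.
#' @slot species character vector of species identifiers, in the order of
#'   \code{counts}.
#' @slot pixelSize numeric(1), micrometres per pixel.
#'
#' @seealso [IonImageStack()], [driftCorrect()], [accumulate()]
#' @export
setClass("IonImageStack",
  representation(counts = "list", species = "character", pixelSize = "numeric"))

setValidity("IonImageStack", function(object) {
  msg <- character()
  if (length(object@species) != length(object@counts))
    msg <- c(msg, "species and counts must have the same length")
  if (!identical(names(object@counts), object@species))
    msg <- c(msg, "names(counts) must equal species")
  dims <- lapply(object@counts, dim)
  if (length(dims)) {
    if (any(vapply(dims, length, 0L) != 3L))
      msg <- c(msg, "each species array must be 3-D (rows x cols x planes)")
    else if (!all(vapply(dims, identical, TRUE, y = dims[[1]])))
      msg <- c(msg, "all species arrays must share dimensions and plane count")
    bad <- vapply(object@counts, function(a)
      anyNA(a) || any(a < 0) || any(a != round(a)), TRUE)
    if (any(bad))
      msg <- c(msg, "counts must be non-negative integers")
  }
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' ColonyScene: ground-truth description of a simulated colony field
#'
#' The cell-level truth from which synthetic ion-image stacks are rendered:
#' one row per cell with its type (vegetative, heterocyst or epibiont),
#' ellipse geometry in pixel coordinates, physical length/width in
#' micrometres, true 13C and 15N atom fractions, and per-element secondary-ion
#' yields (expected counts per pixel per plane for the C, CN, P and S
#' channels).
#'
#' @slot cells data.frame with columns \code{id}, \code{type}, \code{cx},
#'   \code{cy}, \code{a}, \code{b}, \code{theta} (ellipse centre, semi-axes in
#'   pixels, orientation in radians), \code{lengthUm}, \code{widthUm},
#'   \code{aC13}, \code{aN15}, \code{yieldC}, \code{yieldCN}, \code{yieldP},
#'   \code{yieldS}.
#' @slot background named numeric, off-cell expected counts per pixel per
#'   plane for channels \code{C}, \code{CN}, \code{P}, \code{S}.
#' @slot pixelSize numeric(1), micrometres per pixel.
#'
#' @seealso [ColonyScene()], [simulateIonStack()], [colonyScenario()]
#' @export
setClass("ColonyScene",
  representation(cells = "data.frame", background = "numeric",
                 pixelSize = "numeric"))

setValidity("ColonyScene", function(object) {
  msg <- character()
  need <- c("id", "type", "cx", "cy", "a", "b", "theta", "lengthUm",
            "widthUm", "aC13", "aN15", "yieldC", "yieldCN", "yieldP", "yieldS")
  missing <- setdiff(need, names(object@cells))
  if (length(missing))
    msg <- c(msg, paste("cells is missing columns:",
                        paste(missing, collapse = ", ")))
  else {
    cl <- object@cells
    if (!all(cl$type %in% c("vegetative", "heterocyst", "epibiont")))
      msg <- c(msg, "cell type must be vegetative, heterocyst or epibiont")
    if (any(cl$aC13 < 0 | cl$aC13 > 1 | cl$aN15 < 0 | cl$aN15 > 1))
      msg <- c(msg, "atom fractions must lie in [0, 1]")
    if (any(cl[, c("yieldC", "yieldCN", "yieldP", "yieldS")] < 0))
      msg <- c(msg, "yields must be >= 0")
    if (any(cl$a <= 0 | cl$b <= 0))
      msg <- c(msg, "ellipse semi-axes must be positive")
    if (any(cl$lengthUm < cl$widthUm))
      msg <- c(msg, "cell length must be >= width")
    if (anyDuplicated(cl$id))
      msg <- c(msg, "cell ids must be unique")
  }
  if (!all(c("C", "CN", "P", "S") %in% names(object@background)) ||
      any(object@background < 0))
    msg <- c(msg, "background must be named non-negative yields for C, CN, P, S")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' AcquisitionParams: raster geometry and per-plane drift of a measurement
#'
#' @slot width,height integer(1), image size in pixels.
#' @slot planes integer(1), number of acquisition planes (>= 1).
#' @slot drift integer matrix \code{planes x 2} of per-plane (row, col) pixel
#'   offsets relative to the drift-free frame; plane 1 is conventionally
#'   (0, 0).
#'
#' @seealso [AcquisitionParams()], [randomWalkDrift()], [simulateIonStack()]
#' @export
setClass("AcquisitionParams",
  representation(width = "integer", height = "integer", planes = "integer",
                 drift = "matrix"))

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  if (object@width < 1L || object@height < 1L)
    msg <- c(msg, "width and height must be >= 1")
  if (object@planes < 1L)
    msg <- c(msg, "planes must be >= 1")
  d <- object@drift
  if (!is.numeric(d) || nrow(d) != object@planes || ncol(d) != 2L)
    msg <- c(msg, "drift must be a planes x 2 matrix")
  else {
    if (any(d != round(d)))
      msg <- c(msg, "drift offsets must be integer-valued")
    if (any(abs(d[, 1]) >= object@height) || any(abs(d[, 2]) >= object@width))
      msg <- c(msg, "|drift| must be smaller than the image size")
  }
  if (length(msg)) msg else TRUE
})

#' LabelingConditions: isotope-labelling context of an incubation
#'
#' Source-pool atom fractions of the heavy isotope per element, the
#' natural-abundance atom fractions they are referenced against, and the
#' incubation duration.
#'
#' @slot sourceFraction named numeric (elements \code{C}, \code{N}): atom
#'   fraction of 13C in the DIC pool and of 15N in the N2 pool.
#' @slot naturalAbundance named numeric (elements \code{C}, \code{N}).
#' @slot duration numeric(1), incubation time in days.
#'
#' @seealso [LabelingConditions()], [relativeActivity()], [growthRate()]
#' @export
setClass("LabelingConditions",
  representation(sourceFraction = "numeric", naturalAbundance = "numeric",
                 duration = "numeric"))

setValidity("LabelingConditions", function(object) {
  msg <- character()
  for (el in c("C", "N")) {
    xi <- object@sourceFraction[el]; na <- object@naturalAbundance[el]
    if (is.na(xi) || is.na(na))
      msg <- c(msg, paste0("element ", el, " missing from source or natural abundance"))
    else if (!(na >= 0 && na < xi && xi <= 1))
      msg <- c(msg, paste0("need 0 <= natural abundance < source fraction <= 1 for ", el))
  }
  if (length(object@duration) != 1L || object@duration <= 0)
    msg <- c(msg, "duration must be a single positive number of days")
  if (length(msg)) msg else TRUE
})

#' RadiotracerDesign: a 33P bulk uptake incubation to simulate
#'
#' @slot rate numeric(1), true DIP uptake rate (nmol P L^-1 h^-1).
#' @slot dip numeric(1), ambient DIP concentration (nmol L^-1).
#' @slot activityKBq numeric(1), added tracer activity (kBq).
#' @slot volumeMl numeric(1), incubation volume (mL).
#' @slot times numeric, sampling times in hours (strictly increasing, >= 0).
#' @slot replicates integer(1), number of live replicate bottles.
#' @slot bindingFraction numeric(1), unspecific-binding fraction seen in
#'   killed/filtered controls (fraction of total counts).
#' @slot countingDelayDays numeric(1), days between sampling and scintillation
#'   counting (decay applies).
#' @slot totalCounts numeric(1), expected scintillation counts corresponding
#'   to the full tracer spike at the counting date before decay; sets the
#'   Poisson noise scale.
#' @slot halfLife numeric(1), tracer half-life in days (33P: 25.4).
#'
#' @seealso [RadiotracerDesign()], [simulateRadiotracer()], [dipUptakeRate()]
#' @export
setClass("RadiotracerDesign",
  representation(rate = "numeric", dip = "numeric", activityKBq = "numeric",
                 volumeMl = "numeric", times = "numeric",
                 replicates = "integer", bindingFraction = "numeric",
                 countingDelayDays = "numeric", totalCounts = "numeric",
                 halfLife = "numeric"))

setValidity("RadiotracerDesign", function(object) {
  msg <- character()
  num1pos <- function(x) length(x) == 1L && is.finite(x) && x >= 0
  if (!num1pos(object@rate)) msg <- c(msg, "rate must be a single number >= 0")
  if (!num1pos(object@dip) || object@dip <= 0)
    msg <- c(msg, "dip must be a single number > 0")
  if (!num1pos(object@activityKBq)) msg <- c(msg, "activityKBq must be >= 0")
  if (!num1pos(object@volumeMl) || object@volumeMl <= 0)
    msg <- c(msg, "volumeMl must be > 0")
  if (length(object@times) < 1L || any(object@times < 0) ||
      is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "times must be strictly increasing and >= 0")
  if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
  if (object@bindingFraction < 0 || object@bindingFraction > 1)
    msg <- c(msg, "bindingFraction must lie in [0, 1]")
  if (object@countingDelayDays < 0) msg <- c(msg, "countingDelayDays must be >= 0")
  if (object@totalCounts <= 0) msg <- c(msg, "totalCounts must be > 0")
  if (object@halfLife <= 0) msg <- c(msg, "halfLife must be > 0")
  if (length(msg)) msg else TRUE
})

#' BulkDesign: a bulk 13C/15N fixation incubation to simulate
#'
#' @slot rateC,rateN numeric(1), true CO2 and N2 fixation rates
#'   (umol L^-1 day^-1).
#' @slot poc,pon numeric(1), particulate organic C and N pools (umol L^-1).
#' @slot sourceFraction,naturalAbundance named numeric per element
#'   (\code{C}, \code{N}): atom fractions of the labelled pools and the
#'   natural-abundance baseline.
#' @slot durationH numeric(1), incubation duration in hours.
#' @slot replicates integer(1), labelled replicate bottles.
#' @slot noiseSD numeric(1), Gaussian measurement noise SD on the measured
#'   particulate atom fraction.
#'
#' @seealso [BulkDesign()], [simulateBulkIncubation()], [bulkFixationRate()]
#' @export
setClass("BulkDesign",
  representation(rateC = "numeric", rateN = "numeric", poc = "numeric",
                 pon = "numeric", sourceFraction = "numeric",
                 naturalAbundance = "numeric", durationH = "numeric",
                 replicates = "integer", noiseSD = "numeric"))

setValidity("BulkDesign", function(object) {
  msg <- character()
  if (object@rateC < 0 || object@rateN < 0) msg <- c(msg, "rates must be >= 0")
  if (object@poc <= 0 || object@pon <= 0) msg <- c(msg, "pools must be > 0")
  if (object@durationH <= 0) msg <- c(msg, "durationH must be > 0")
  if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  for (el in c("C", "N")) {
    xi <- object@sourceFraction[el]; na <- object@naturalAbundance[el]
    if (is.na(xi) || is.na(na) || !(na >= 0 && na < xi && xi <= 1))
      msg <- c(msg, paste0("need 0 <= natural abundance < source fraction <= 1 for ", el))
  }
  if (length(msg)) msg else TRUE
})
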